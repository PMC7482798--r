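#' Adaptive-threshold segmentation parameters
#'
#' The semi-automatic initialization is a user-supplied axis-aligned box of
#' voxel indices containing the lesion; the threshold blends lesion and
#' background intensity with weight `beta` (default 0.3).
#'
#' @param seedBox integer vector `c(z0, z1, y0, y1, x0, x1)` of 1-based
#'   inclusive voxel bounds containing the lesion.
#' @param beta unitless weight in (0, 1].
#' @param backgroundShell thickness (voxels, >= 1) of the background shell
#'   dilated around the seed box.
#' @return A list of class `ThresholdParams`.
#' @export
thresholdParams <- function(seedBox, beta = 0.3, backgroundShell = 2L) {
  seedBox <- as.integer(seedBox)
  if (length(seedBox) != 6L || any(is.na(seedBox)))
    stop("seedBox must be 6 integers: z0, z1, y0, y1, x0, x1")
  if (any(seedBox[c(2, 4, 6)] < seedBox[c(1, 3, 5)]))
    stop("seedBox is empty (upper bound below lower bound)")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must be in (0, 1]")
  backgroundShell <- as.integer(backgroundShell)
  if (backgroundShell < 1L) stop("backgroundShell must be >= 1")
  structure(list(seedBox = seedBox, beta = beta,
                 backgroundShell = backgroundShell),
            class = "ThresholdParams")
}

check_box <- function(box, dims) {
  if (any(box[c(1, 3, 5)] < 1L) || any(box[c(2, 4, 6)] > dims))
    stop("seedBox outside volume bounds")
}

box_index <- function(box) {
  list(box[1]:box[2], box[3]:box[4], box[5]:box[6])
}

#' Adaptive uptake threshold for tumor segmentation
#'
#' Computes the segmentation threshold `T = beta * I70 + Ibackground`,
#' where `I70` is the mean uptake of seed-box voxels with uptake strictly
#' greater than 70% of the seed-box maximum, and `Ibackground` is the mean
#' uptake in a shell of `backgroundShell` voxels dilated outside the seed
#' box, excluding shell voxels above 70% of the seed-box maximum (tumor
#' spill-in).  If every shell voxel is excluded (degenerate, e.g. a uniform
#' volume) the unfiltered shell mean is used and a warning is raised;
#' likewise when `I70 <= Ibackground` the lesion is flagged degenerate but
#' the threshold is still returned.
#'
#' @param vol a [PETVolume-class] (every axis >= 4 voxels).
#' @param params a [thresholdParams()] object.
#' @return list with `threshold`, `i70`, `ibackground`, `beta` and the
#'   logical flag `degenerate`.
#' @export
adaptiveThreshold <- function(vol, params) {
  stopifnot(is(vol, "PETVolume"), inherits(params, "ThresholdParams"))
  d <- dim(vol@data)
  if (any(d < 4L)) stop("volume must be at least 4 voxels along every axis")
  box <- params$seedBox
  check_box(box, d)
  bi <- box_index(box)
  sub <- vol@data[bi[[1]], bi[[2]], bi[[3]]]
  mx <- max(sub)
  hot <- sub > 0.7 * mx
  if (!any(hot)) stop("empty seed box: no voxel above 70% of box maximum")
  i70 <- mean(sub[hot])

  sh <- params$backgroundShell
  outer_box <- c(max(1L, box[1] - sh), min(d[1], box[2] + sh),
                 max(1L, box[3] - sh), min(d[2], box[4] + sh),
                 max(1L, box[5] - sh), min(d[3], box[6] + sh))
  in_outer <- array(FALSE, d)
  oi <- box_index(outer_box)
  in_outer[oi[[1]], oi[[2]], oi[[3]]] <- TRUE
  in_outer[bi[[1]], bi[[2]], bi[[3]]] <- FALSE
  shell_vals <- vol@data[in_outer]
  degenerate <- FALSE
  if (length(shell_vals) == 0L) {
    warning("seed box touches all volume borders: no background shell; ",
            "using Ibackground = 0")
    ibg <- 0
    degenerate <- TRUE
  } else {
    keep <- shell_vals <= 0.7 * mx
    if (!any(keep)) {
      warning("all background-shell voxels exceed 70% of seed-box maximum; ",
              "degenerate lesion, using unfiltered shell mean")
      ibg <- mean(shell_vals)
      degenerate <- TRUE
    } else {
      ibg <- mean(shell_vals[keep])
    }
  }
  thr <- params$beta * i70 + ibg
  if (!degenerate && i70 <= ibg) {
    warning("I70 <= Ibackground: degenerate lesion contrast")
    degenerate <- TRUE
  }
  list(threshold = thr, i70 = i70, ibackground = ibg, beta = params$beta,
       degenerate = degenerate)
}

#' Segment a tumor by adaptive thresholding
#'
#' Voxels inside the seed box with uptake `>= T` (from
#' [adaptiveThreshold()]) are kept, then restricted to the 26-connected
#' component containing the seed-box maximum.
#'
#' @inheritParams adaptiveThreshold
#' @return A [SegmentationMask-class]; errors if no voxel reaches the
#'   threshold.
#' @export
segmentTumor <- function(vol, params) {
  at <- adaptiveThreshold(vol, params)
  d <- dim(vol@data)
  bi <- box_index(params$seedBox)
  cand <- array(FALSE, d)
  cand[bi[[1]], bi[[2]], bi[[3]]] <- vol@data[bi[[1]], bi[[2]], bi[[3]]] >=
    at$threshold
  if (!any(cand)) stop("no lesion above threshold (T = ",
                       format(at$threshold), ")")
  # seed of the flood fill: first global max inside the box
  inbox <- array(FALSE, d)
  inbox[bi[[1]], bi[[2]], bi[[3]]] <- TRUE
  vals <- vol@data
  vals[!inbox] <- -Inf
  seed <- which.max(vals)
  if (!cand[seed]) stop("no lesion above threshold: seed-box maximum below T")
  comp <- .cpp_flood26(cand, as.integer(seed))
  new("SegmentationMask", data = array(comp, d), spacing = vol@spacing)
}

#' Conventional PET features of a segmented lesion
#'
#' @param vol a [PETVolume-class].
#' @param mask non-empty [SegmentationMask-class] aligned with `vol`.
#' @param threshold optional threshold used to produce the mask (carried
#'   through for reporting).
#' @return list with `suv_max`, `suv_mean`, `mtv_ml` (voxel count times
#'   voxel volume in mL) and `threshold_used`.
#' @export
petFeatures <- function(vol, mask, threshold = NA_real_) {
  stopifnot(is(vol, "PETVolume"), is(mask, "SegmentationMask"))
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("mask and volume shapes differ")
  if (!any(mask@data)) stop("empty mask")
  v <- vol@data[mask@data]
  list(suv_max = max(v), suv_mean = mean(v),
       mtv_ml = sum(mask@data) * prod(vol@spacing) / 1000,
       threshold_used = threshold)
}
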