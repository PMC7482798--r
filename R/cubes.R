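#' Extract the network input cube around a segmented lesion
#'
#' A cubic patch of physical side `side_mm` is cut from the (isotropically
#' resampled) volume, centered on the mask centroid and zero-padded where
#' it extends past the volume border.  The full surrounding uptake context
#' is retained (the cube *contains* the lesion, it is not masked to it).
#' With `normMode = "max"` the cube is divided by its maximum so inputs
#' are scanner-scale invariant.
#'
#' @param vol isotropic [PETVolume-class].
#' @param mask non-empty [SegmentationMask-class] aligned with `vol`.
#' @param side_mm physical cube side in mm (default 64, i.e. 32 voxels at
#'   2 mm); must cover the lesion bounding box.
#' @param normMode `"max"` or `"none"`.
#' @param patientId,lesionId identifiers carried on the cube.
#' @return A [TumorCube-class].
#' @export
extractCube <- function(vol, mask, side_mm = 64, normMode = c("max", "none"),
                        patientId = NA_character_, lesionId = NA_character_) {
  normMode <- match.arg(normMode)
  stopifnot(is(vol, "PETVolume"), is(mask, "SegmentationMask"))
  if (!identical(dim(vol@data), dim(mask@data)))
    stop("mask and volume shapes differ")
  sp <- vol@spacing
  if (diff(range(sp)) > 1e-9)
    stop("volume must be isotropically resampled before cube extraction")
  if (!any(mask@data)) stop("empty mask")
  S <- as.integer(round(side_mm / sp[1]))
  if (S < 1L) stop("cube side smaller than one voxel")
  idx <- which(mask@data, arr.ind = TRUE)
  bbox <- apply(idx, 2L, range)
  if (any(bbox[2, ] - bbox[1, ] + 1L > S))
    stop("lesion exceeds cube: bounding box larger than ", S, " voxels")
  centroid <- colMeans(idx)
  # floor(x + 0.5): translation-consistent rounding (round() halves-to-even
  # would break whole-voxel shift equivariance)
  start <- floor(centroid - (S - 1) / 2 + 0.5)
  cube <- array(0, dim = c(S, S, S))
  d <- dim(vol@data)
  src_lo <- pmax(start, 1)
  src_hi <- pmin(start + S - 1, d)
  dst_lo <- src_lo - start + 1
  dst_hi <- src_hi - start + 1
  if (all(src_lo <= src_hi)) {
    cube[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol@data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  if (normMode == "max" && max(cube) > 0) cube <- cube / max(cube)
  new("TumorCube", data = cube, normMode = normMode, spacing = sp[1],
      patientId = as.character(patientId), lesionId = as.character(lesionId))
}

#' Rotation augmentation policy
#'
#' Each augmented copy is produced by three independent rotation angles
#' drawn uniformly in `angleRange` degrees and applied about the array
#' axes in fixed order (z, then y, then x) with trilinear interpolation
#' and zero fill.  Fifteen copies per lesion and angles in [0, 90] degrees
#' are the defaults used during training.
#'
#' @param nCopies number of rotated copies (>= 1, default 15).
#' @param angleRange two-element range in degrees (default `c(0, 90)`).
#' @param seed integer seed; the same seed reproduces the batch
#'   bit-for-bit.
#' @return A list of class `AugmentationPolicy`.
#' @export
augmentationPolicy <- function(nCopies = 15L, angleRange = c(0, 90),
                               seed = NULL) {
  nCopies <- as.integer(nCopies)
  if (is.na(nCopies) || nCopies < 1L) stop("nCopies must be >= 1")
  if (length(angleRange) != 2L || angleRange[2] < angleRange[1])
    stop("angleRange must be an increasing 2-element vector (degrees)")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(nCopies = nCopies, angleRange = as.numeric(angleRange),
                 seed = seed),
            class = "AugmentationPolicy")
}

#' Rotate a cube by fixed angles
#'
#' @param cube a [TumorCube-class].
#' @param angles numeric(3) degrees about the z, y, x axes (applied in
#'   that order).
#' @return Rotated [TumorCube-class].
#' @export
rotateCube <- function(cube, angles) {
  stopifnot(is(cube, "TumorCube"), length(angles) == 3L)
  out <- .cpp_rotate3(cube@data, angles[1], angles[2], angles[3])
  initialize(cube, data = out, normMode = "none")
}

#' Randomly rotated copies of a cube
#'
#' @param cube a [TumorCube-class].
#' @param policy an [augmentationPolicy()]; if its seed is NULL one is
#'   drawn from the session RNG.
#' @return list of `nCopies` rotated [TumorCube-class] objects; the drawn
#'   angles are attached as attribute `"angles"` (nCopies x 3 matrix).
#' @export
randomRotations <- function(cube, policy = augmentationPolicy()) {
  stopifnot(is(cube, "TumorCube"), inherits(policy, "AugmentationPolicy"))
  seed <- policy$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- .cpp_random_rotations(cube@data, policy$nCopies,
                               policy$angleRange[1], policy$angleRange[2],
                               seed)
  cubes <- lapply(res$cubes, function(a) initialize(cube, data = a,
                                                    normMode = "none"))
  attr(cubes, "angles") <- res$angles
  cubes
}
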