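#' Phantom cohort specification
#'
#' Describes a seeded cohort of ellipsoidal PET lesion phantoms whose
#' uptake *texture* monotonically encodes a latent immune score u ~ N(0,1):
#' the rim-to-core uptake ratio is `exp(contrastK * u)` (overall lesion
#' amplitude is held fixed so mean uptake alone is uninformative) and the
#' intralesional speckle amplitude rises sigmoidally with u.  Each lesion
#' sits on a noisy background in its own volume, with the ground-truth
#' mask and u recorded.
#'
#' @param nPatients number of patients.
#' @param lesionProbs probability of 1..4 lesions per patient.
#' @param shape volume voxel dimensions (z, y, x).
#' @param spacing_mm isotropic voxel spacing.
#' @param radiusRange_mm sampled lesion semi-axis range (mm).
#' @param bgMean,bgSd background uptake mean and voxel noise (SUV-like).
#' @param amplitude lesion uptake amplitude above background (SUV-like).
#' @param contrastK texture-link strength: rim/core ratio = exp(contrastK u).
#' @param speckleRange speckle amplitude range, mapped through plogis(u).
#' @param noiseSd additive acquisition noise on every voxel.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return list of class `PhantomSpec`.
#' @export
phantomSpec <- function(nPatients = 100L, lesionProbs = c(0.35, 0.3, 0.2, 0.15),
                        shape = c(32L, 32L, 32L), spacing_mm = 2,
                        radiusRange_mm = c(8, 14), bgMean = 0.5, bgSd = 0.05,
                        amplitude = 5, contrastK = 0.8,
                        speckleRange = c(0.05, 0.25), noiseSd = 0.05,
                        seed = 1L) {
  stopifnot(nPatients >= 1, length(lesionProbs) >= 1, all(lesionProbs >= 0),
            sum(lesionProbs) > 0, length(shape) == 3L, spacing_mm > 0,
            radiusRange_mm[1] > 0, diff(radiusRange_mm) >= 0, contrastK > 0,
            bgMean >= 0)
  structure(list(nPatients = as.integer(nPatients),
                 lesionProbs = lesionProbs / sum(lesionProbs),
                 shape = as.integer(shape), spacing_mm = spacing_mm,
                 radiusRange_mm = radiusRange_mm, bgMean = bgMean,
                 bgSd = bgSd, amplitude = amplitude, contrastK = contrastK,
                 speckleRange = speckleRange, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

# single lesion phantom; returns list(volume, mask) given drawn geometry
build_phantom <- function(spec, u, center_vox, radii_mm) {
  d <- spec$shape
  sp <- spec$spacing_mm
  if (any(2 * radii_mm > (d - 2) * sp))
    stop("lesion larger than volume")
  ax <- lapply(seq_len(3L), function(k)
    ((seq_len(d[k]) - center_vox[k]) * sp) / radii_mm[k])
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  ratio <- exp(spec$contrastK * u)
  core <- spec$amplitude * 2 / (1 + ratio)
  rim <- spec$amplitude * 2 * ratio / (1 + ratio)
  s <- pmin(dist, 1)
  profile <- core + (rim - core) * (s^2 * (3 - 2 * s))
  taper <- ifelse(dist <= 0.75, 1,
                  ifelse(dist >= 1.25, 0,
                         0.5 * (1 + cos(pi * (dist - 0.75) / 0.5))))
  lesion <- profile * taper
  amp <- spec$speckleRange[1] +
    diff(spec$speckleRange) * plogis(u)
  speckle <- 1 + amp * array(rnorm(prod(d)), dim = d)
  lesion <- lesion * ifelse(lesion > 0, speckle, 1)
  bg <- spec$bgMean + spec$bgSd * array(rnorm(prod(d)), dim = d)
  vol <- bg + lesion + spec$noiseSd * array(rnorm(prod(d)), dim = d)
  list(volume = PETVolume(pmax(vol, 0), spacing = rep(sp, 3), units = "SUV"),
       mask = new("SegmentationMask", data = dist <= 1,
                  spacing = rep(sp, 3)))
}

#' Generate a phantom PET cohort
#'
#' One volume per lesion (axes z, y, x) with its ground-truth mask and
#' latent score.  Deterministic in the spec seed.
#'
#' @param spec a [phantomSpec()].
#' @return list with `volumes` (list of [PETVolume-class]), `masks`
#'   (list of [SegmentationMask-class]) and `lesions`, a data.frame of
#'   `patient_id`, `lesion_id`, `u`, the drawn geometry and texture
#'   parameters.
#' @export
genPhantomCohort <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_seed(spec$seed, {
    nles <- sample(seq_along(spec$lesionProbs), spec$nPatients,
                   replace = TRUE, prob = spec$lesionProbs)
    volumes <- list()
    masks <- list()
    rows <- list()
    li <- 0L
    for (p in seq_len(spec$nPatients)) {
      for (l in seq_len(nles[p])) {
        li <- li + 1L
        u <- rnorm(1)
        center <- round(spec$shape / 2) + sample(-2:2, 3L, replace = TRUE)
        radii <- runif(3L, spec$radiusRange_mm[1], spec$radiusRange_mm[2])
        ph <- build_phantom(spec, u, center, radii)
        volumes[[li]] <- ph$volume
        masks[[li]] <- ph$mask
        rows[[li]] <- data.frame(
          patient_id = sprintf("P%03d", p),
          lesion_id = sprintf("P%03d_L%d", p, l), u = u,
          center_z = center[1], center_y = center[2], center_x = center[3],
          radius_z_mm = radii[1], radius_y_mm = radii[2],
          radius_x_mm = radii[3],
          rim_core_ratio = exp(spec$contrastK * u),
          speckle_amp = spec$speckleRange[1] +
            diff(spec$speckleRange) * plogis(u),
          stringsAsFactors = FALSE)
      }
    }
    list(volumes = volumes, masks = masks, lesions = do.call(rbind, rows))
  })
}

#' Generate paired synthetic gene expression for latent immune scores
#'
#' GZMA and PRF1 log2 expression are affine in u plus independent noise,
#' so with zero noise CytAct of the output equals the z-standardized u
#' exactly.  The six interferon-gamma signature genes are driven by a
#' latent `w = corrIfng * u + sqrt(1 - corrIfng^2) * z` so the CytAct/IFNG
#' correlation targets `corrIfng`.
#'
#' @param u named numeric vector of latent scores (names become sample
#'   ids).
#' @param noiseSd per-gene log2 noise sd.
#' @param corrIfng target correlation between the IFNG driver and u.
#' @param seed integer seed.
#' @return An [ExpressionMatrix-class] (log2 scale) with 8 gene rows.
#' @export
genExpression <- function(u, noiseSd = 0.25, corrIfng = 0.5, seed = 1L) {
  stopifnot(is.numeric(u), length(u) >= 2L, abs(corrIfng) <= 1)
  ids <- names(u)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(u))
  with_seed(seed, {
    n <- length(u)
    w <- corrIfng * u + sqrt(1 - corrIfng^2) * rnorm(n)
    g <- function(b0, b1, driver) b0 + b1 * driver + noiseSd * rnorm(n)
    m <- rbind(
      GZMA = g(6, 1.5, u),
      PRF1 = g(5, 1.2, u),
      IDO1 = g(4, 1.0, w),
      CXCL9 = g(5, 1.3, w),
      CXCL10 = g(5.5, 1.1, w),
      IFNG = g(3, 0.9, w),
      `HLA-DRA` = g(8, 1.2, w),
      STAT1 = g(7, 0.8, w))
    colnames(m) <- ids
    ExpressionMatrix(m, logScale = TRUE)
  })
}

#' Treatment-outcome specification for the synthetic ICB cohort
#'
#' Lesion size change is linear in the latent score,
#' `pct = a - b * u + noise`, optionally penalized by within-patient
#' heterogeneity (`hetPenalty` percent per sd of u).  Best response is PR
#' when every lesion shrinks past `responseThreshold`, PD when any lesion
#' grows past `pdThreshold`, SD otherwise -- so response is driven by the
#' worst lesion.  Survival times are proportional-hazards exponential with
#' log-hazard `-hazardC * min(u) + hazardD * var(u)`.
#'
#' @param a,b size-change intercept and (positive) slope in percent.
#' @param noiseSd size-change noise sd (percent).
#' @param responseThreshold per-lesion shrinkage for PR (default -30).
#' @param pdThreshold per-lesion growth for PD (default +20).
#' @param hetPenalty percent added to every lesion's size change per sd of
#'   the patient's latent scores (variance-linked resistance; 0 disables).
#' @param hazardC,hazardD log-hazard coefficients on min(u) and var(u).
#' @param medianPFS,medianOS baseline median survival (months).
#' @param followupMonths administrative censoring horizon.
#' @param censorRate probability of random early censoring.
#' @param predNoiseSd sd of the noise added to u to emulate predicted
#'   CytAct for the lesion table.
#' @param seed integer seed.
#' @return list of class `OutcomeSpec`.
#' @export
outcomeSpec <- function(a = -30, b = 15, noiseSd = 8, responseThreshold = -30,
                        pdThreshold = 20, hetPenalty = 0, hazardC = 0.8,
                        hazardD = 0, medianPFS = 6, medianOS = 14,
                        followupMonths = 24, censorRate = 0.15,
                        predNoiseSd = 0.35, seed = 1L) {
  stopifnot(b > 0, noiseSd >= 0, hazardC > 0, medianPFS > 0, medianOS > 0,
            followupMonths > 0, censorRate >= 0, censorRate < 1)
  structure(list(a = a, b = b, noiseSd = noiseSd,
                 responseThreshold = responseThreshold,
                 pdThreshold = pdThreshold, hetPenalty = hetPenalty,
                 hazardC = hazardC, hazardD = hazardD, medianPFS = medianPFS,
                 medianOS = medianOS, followupMonths = followupMonths,
                 censorRate = censorRate, predNoiseSd = predNoiseSd,
                 seed = as.integer(seed)),
            class = "OutcomeSpec")
}

SITE_PROBS <- c(lung = 20, lymph_node = 17, adrenal = 7, bone = 6,
                mediastinum = 4, pleura = 3, soft_tissue = 3)

#' Generate a synthetic multi-lesion ICB cohort
#'
#' Takes per-lesion latent scores (e.g. from [genPhantomCohort()]) and
#' draws lesion sites/sizes, size changes, best response, and PFS/OS with
#' censoring according to an [outcomeSpec()].  The output schema matches
#' the biomarker module inputs; `predicted_cytact` is u plus noise of sd
#' `predNoiseSd`, emulating model predictions.
#'
#' @param lesions data.frame with `patient_id`, `lesion_id`, `u`.
#' @param spec an [outcomeSpec()].
#' @return list with `lesions` (lesion records) and `patients`
#'   (patient records).
#' @export
genICBCohort <- function(lesions, spec = outcomeSpec()) {
  stopifnot(inherits(spec, "OutcomeSpec"), is.data.frame(lesions),
            all(c("patient_id", "lesion_id", "u") %in% names(lesions)))
  with_seed(spec$seed, {
    n <- nrow(lesions)
    les <- lesions[, c("patient_id", "lesion_id", "u")]
    les$site <- sample(names(SITE_PROBS), n, replace = TRUE,
                       prob = SITE_PROBS)
    les$baseline_size_mm <- ifelse(les$site == "lymph_node",
                                   runif(n, 15, 35), runif(n, 10, 60))
    sdu <- tapply(les$u, les$patient_id, function(v)
      if (length(v) >= 2L) sd(v) else 0)
    les$size_change_pct <- pmax(
      -100,
      spec$a - spec$b * les$u + spec$noiseSd * rnorm(n) +
        spec$hetPenalty * as.numeric(sdu[les$patient_id]))
    les$predicted_cytact <- les$u + spec$predNoiseSd * rnorm(n)

    ids <- unique(les$patient_id)
    per <- lapply(ids, function(pid) {
      li <- les[les$patient_id == pid, ]
      min_u <- min(li$u)
      var_u <- if (nrow(li) >= 2L) var(li$u) else 0
      resp <- if (all(li$size_change_pct <= spec$responseThreshold)) "PR"
              else if (any(li$size_change_pct >= spec$pdThreshold)) "PD"
              else "SD"
      loghaz <- -spec$hazardC * min_u + spec$hazardD * var_u
      draw_surv <- function(median_t) {
        t_ev <- rexp(1, rate = log(2) / median_t * exp(loghaz))
        cens <- if (runif(1) < spec$censorRate)
          runif(1, 0.5, spec$followupMonths) else spec$followupMonths
        c(time = max(min(t_ev, cens), 0.05), event = as.integer(t_ev <= cens))
      }
      pfs <- draw_surv(spec$medianPFS)
      os <- draw_surv(spec$medianOS)
      data.frame(patient_id = pid, best_response = resp,
                 responder = resp == "PR",
                 pfs_months = pfs["time"], pfs_event = as.integer(pfs["event"]),
                 os_months = os["time"], os_event = as.integer(os["event"]),
                 pdl1_pct = round(100 * rbeta(1, 2, 1.5)),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    list(lesions = les, patients = do.call(rbind, per))
  })
}
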