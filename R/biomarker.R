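LESION_SITES <- c("lung", "lymph_node", "adrenal", "bone", "mediastinum",
                  "pleura", "soft_tissue", "other")

#' Filter measurable target lesions (RECIST 1.1 size floors)
#'
#' Keeps lymph nodes with short-axis size >= 15 mm and all other lesions
#' with long-axis size >= 10 mm.  `baseline_size_mm` is the short axis for
#' nodes and the long axis otherwise.
#'
#' @param lesions data.frame with at least `site` and `baseline_size_mm`.
#' @return the filtered data.frame.
#' @export
filterTargetLesions <- function(lesions) {
  stopifnot(is.data.frame(lesions),
            all(c("site", "baseline_size_mm") %in% names(lesions)))
  unknown <- setdiff(unique(lesions$site), LESION_SITES)
  if (length(unknown) > 0)
    stop("unknown site tag(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(lesions$baseline_size_mm) |
          lesions$baseline_size_mm <= 0))
    stop("baseline_size_mm must be positive")
  keep <- ifelse(lesions$site == "lymph_node",
                 lesions$baseline_size_mm >= 15,
                 lesions$baseline_size_mm >= 10)
  lesions[keep, , drop = FALSE]
}

#' Per-patient CytAct biomarkers
#'
#' Aggregates each patient's lesion-level predicted CytAct into the
#' minimum (the representative patient biomarker), mean and maximum, plus
#' the inter-lesion variance (n - 1 denominator) as the heterogeneity
#' measure.  Variance is undefined (NA) for single-lesion patients, which
#' are excluded from heterogeneity analyses.  Aggregation is invariant to
#' lesion order.
#'
#' @param lesions data.frame with `patient_id` and `predicted_cytact`.
#' @return data.frame with one row per patient: `patient_id`, `n_lesions`,
#'   `min_cytact`, `mean_cytact`, `max_cytact`, `cytact_variance`.
#' @export
aggregatePatients <- function(lesions) {
  stopifnot(is.data.frame(lesions),
            all(c("patient_id", "predicted_cytact") %in% names(lesions)))
  if (nrow(lesions) == 0L) stop("empty lesion list")
  if (any(!is.finite(lesions$predicted_cytact)))
    stop("predicted_cytact must be finite")
  sp <- split(lesions$predicted_cytact, lesions$patient_id)
  out <- data.frame(
    patient_id = names(sp),
    n_lesions = vapply(sp, length, integer(1)),
    min_cytact = vapply(sp, min, numeric(1)),
    mean_cytact = vapply(sp, mean, numeric(1)),
    max_cytact = vapply(sp, max, numeric(1)),
    cytact_variance = vapply(sp, function(v)
      if (length(v) >= 2L) var(v) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Association between lesion-level predicted CytAct and size change
#'
#' Spearman correlation between per-lesion predicted CytAct and the
#' post-treatment size change.  By default lesions are treated as
#' independent observations (as lesion-wise response plots do); with
#' `clusterAware = TRUE` lesions are first averaged within each patient,
#' which avoids pseudo-replication from multi-lesion patients at the cost
#' of discarding within-patient contrast.
#'
#' @param lesions data.frame with `patient_id`, `predicted_cytact`,
#'   `size_change_pct`.
#' @param clusterAware collapse to patient means before correlating.
#' @return list from [spearmanRho()].
#' @export
cytActSizeAssociation <- function(lesions, clusterAware = FALSE) {
  stopifnot(is.data.frame(lesions),
            all(c("patient_id", "predicted_cytact", "size_change_pct") %in%
                  names(lesions)))
  if (clusterAware) {
    x <- tapply(lesions$predicted_cytact, lesions$patient_id, mean)
    y <- tapply(lesions$size_change_pct, lesions$patient_id, mean)
    spearmanRho(as.numeric(x), as.numeric(y))
  } else {
    spearmanRho(lesions$predicted_cytact, lesions$size_change_pct)
  }
}

#' Dichotomize patients at a representative-CytAct cutoff
#'
#' Patients with minimum predicted CytAct strictly greater than `cutoff`
#' are labelled `"high"`, all others (ties included) `"low"`.  The default
#' cutoff -0.107 is the Youden-optimal point for discriminating partial
#' responders in the reference analysis; for a new cohort derive a cutoff
#' from [rocAnalysis()].
#'
#' @param biomarkers data.frame from [aggregatePatients()].
#' @param cutoff representative CytAct cutoff (default -0.107).
#' @return `biomarkers` with an added factor column `group`
#'   (levels low, high).
#' @export
dichotomizeCytAct <- function(biomarkers, cutoff = -0.107) {
  stopifnot(is.data.frame(biomarkers), "min_cytact" %in% names(biomarkers))
  if (any(!is.finite(biomarkers$min_cytact)))
    stop("min_cytact must be defined for all patients")
  biomarkers$group <- factor(ifelse(biomarkers$min_cytact > cutoff,
                                    "high", "low"),
                             levels = c("low", "high"))
  biomarkers
}
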