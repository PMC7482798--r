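# rim/core uptake ratio measured directly from generated voxels,
# using the recorded lesion geometry
texture_statistic <- function(vol, row, spacing = 2) {
  d <- dim(petData(vol))
  ax <- lapply(1:3, function(k) {
    ctr <- row[[c("center_z", "center_y", "center_x")[k]]]
    rad <- row[[c("radius_z_mm", "radius_y_mm", "radius_x_mm")[k]]]
    ((seq_len(d[k]) - ctr) * spacing) / rad
  })
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  v <- petData(vol)
  mean(v[dist > 0.6 & dist <= 1]) / mean(v[dist <= 0.4])
}

test_that("the phantom cohort is deterministic under a fixed seed", {
  s <- phantomSpec(nPatients = 4, seed = 42)
  c1 <- genPhantomCohort(s)
  c2 <- genPhantomCohort(s)
  expect_equal(c1$lesions, c2$lesions)
  for (i in seq_along(c1$volumes))
    expect_identical(petData(c1$volumes[[i]]), petData(c2$volumes[[i]]))
})

test_that("noise-free equal-score lesions are identical up to placement", {
  s <- phantomSpec(nPatients = 5, lesionProbs = 1, radiusRange_mm = c(10, 10),
                   bgSd = 0, noiseSd = 0, speckleRange = c(0, 0), seed = 3)
  coh <- genPhantomCohort(s)
  coh$lesions$u <- NULL # u varies; regenerate with forced u = 0
  vols <- lapply(seq_len(5), function(i)
    immunoPET:::build_phantom(s, 0,
                              c(16, 16, 16) + ((i %% 3) - 1), rep(10, 3)))
  ref <- sort(as.numeric(petData(vols[[1]]$volume)))
  for (i in 2:5)
    expect_equal(sort(as.numeric(petData(vols[[i]]$volume))), ref)
})

test_that("the texture statistic is strictly monotone in the latent score", {
  s <- phantomSpec(nPatients = 1, bgSd = 0, noiseSd = 0,
                   speckleRange = c(0, 0), seed = 5)
  geom <- list(center = c(16, 16, 16), radii = rep(12, 3))
  stats <- vapply(c(-2, -0.5, 0.5, 2), function(u) {
    ph <- immunoPET:::build_phantom(s, u, geom$center, geom$radii)
    row <- list(center_z = 16, center_y = 16, center_x = 16,
                radius_z_mm = 12, radius_y_mm = 12, radius_x_mm = 12)
    texture_statistic(ph$volume, row)
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("latent scores are recoverable from voxel texture across a cohort", {
  spec <- phantomSpec(nPatients = 300, lesionProbs = 1, seed = 1)
  coh <- genPhantomCohort(spec)
  stats <- vapply(seq_len(nrow(coh$lesions)), function(i)
    texture_statistic(coh$volumes[[i]], as.list(coh$lesions[i, ])),
    numeric(1))
  expect_gte(cor(stats, coh$lesions$u, method = "spearman"), 0.9)
})

test_that("noise-free expression reproduces z-standardized latent scores", {
  set.seed(7)
  u <- rnorm(40)
  em <- genExpression(u, noiseSd = 0, seed = 9)
  expect_equal(unname(cytAct(em)), unname((u - mean(u)) / sd(u)),
               tolerance = 1e-12)
})

test_that("degenerate outcome slopes behave as specified", {
  les <- make_lesion_table(21, n_patients = 15)
  z <- genICBCohort(les, outcomeSpec(a = -40, b = 1e-9, noiseSd = 0,
                                     seed = 23))
  expect_lt(diff(range(z$lesions$size_change_pct)), 1e-6)
  expect_true(all(z$patients$best_response == "PR")) # a below PR threshold

  m <- genICBCohort(les, outcomeSpec(b = 25, noiseSd = 0, seed = 29))
  expect_equal(cor(m$lesions$u, m$lesions$size_change_pct,
                   method = "spearman"), -1)
})

test_that("latent score correlates negatively with size change lesion-wise", {
  rhos <- vapply(1:20, function(s) {
    les <- make_lesion_table(3000 + s)
    icb <- genICBCohort(les, outcomeSpec(seed = 4000 + s))
    cor(icb$lesions$u, icb$lesions$size_change_pct, method = "spearman")
  }, numeric(1))
  expect_lte(median(rhos), -0.5)
})

test_that("generated tables satisfy the biomarker input schema", {
  les <- make_lesion_table(31)
  icb <- genICBCohort(les, outcomeSpec(seed = 33))
  expect_true(all(c("patient_id", "lesion_id", "site", "baseline_size_mm",
                    "size_change_pct", "predicted_cytact") %in%
                    names(icb$lesions)))
  expect_true(all(icb$lesions$baseline_size_mm > 0))
  expect_true(all(icb$lesions$size_change_pct >= -100))
  expect_true(all(c("patient_id", "best_response", "responder", "pfs_months",
                    "pfs_event", "os_months", "os_event") %in%
                    names(icb$patients)))
  expect_true(all(icb$patients$pfs_months > 0))
  expect_identical(icb$patients$responder,
                   icb$patients$best_response == "PR")
  # downstream modules consume them without special-casing
  bio <- dichotomizeCytAct(
    aggregatePatients(filterTargetLesions(icb$lesions)))
  expect_true(all(bio$min_cytact <= bio$mean_cytact + 1e-12))
  expect_true(all(bio$mean_cytact <= bio$max_cytact + 1e-12))
})
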