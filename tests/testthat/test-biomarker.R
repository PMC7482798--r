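test_that("RECIST size floors are applied per site", {
  les <- data.frame(
    patient_id = "P1", lesion_id = paste0("L", 1:6),
    site = c("lymph_node", "lymph_node", "lung", "lung", "adrenal", "bone"),
    baseline_size_mm = c(14, 15, 10, 9.9, 25, 8),
    predicted_cytact = rnorm(6))
  kept <- filterTargetLesions(les)
  expect_equal(kept$lesion_id, c("L2", "L3", "L5"))

  # brute-force agreement on a mixed seeded list
  set.seed(7)
  mix <- data.frame(
    patient_id = "P2", lesion_id = paste0("M", 1:40),
    site = sample(c("lymph_node", "lung", "pleura", "soft_tissue"), 40, TRUE),
    baseline_size_mm = runif(40, 5, 40), predicted_cytact = rnorm(40))
  kept2 <- filterTargetLesions(mix)
  manual <- mix[ifelse(mix$site == "lymph_node",
                       mix$baseline_size_mm >= 15,
                       mix$baseline_size_mm >= 10), ]
  expect_equal(kept2$lesion_id, manual$lesion_id)

  bad <- les; bad$site[1] <- "brain"
  expect_error(filterTargetLesions(bad), "unknown site.*brain")
})

test_that("patient aggregation computes min/mean/max/variance correctly", {
  les <- data.frame(patient_id = rep("P1", 3),
                    predicted_cytact = c(0.5, -0.2, 1.0))
  b <- aggregatePatients(les)
  expect_equal(b$min_cytact, -0.2)
  expect_equal(b$mean_cytact, 1.3 / 3, tolerance = 1e-12)
  expect_equal(b$max_cytact, 1.0)
  expect_equal(b$cytact_variance, var(c(0.5, -0.2, 1.0)))
  expect_equal(round(b$cytact_variance, 4), 0.3633)

  single <- aggregatePatients(data.frame(patient_id = "P2",
                                         predicted_cytact = 0.7))
  expect_equal(single$min_cytact, 0.7)
  expect_equal(single$mean_cytact, 0.7)
  expect_equal(single$max_cytact, 0.7)
  expect_true(is.na(single$cytact_variance))

  same <- aggregatePatients(data.frame(patient_id = "P3",
                                       predicted_cytact = c(1, 1, 1)))
  expect_equal(same$cytact_variance, 0)
  expect_error(aggregatePatients(data.frame(patient_id = character(0),
                                            predicted_cytact = numeric(0))),
               "empty")
})

test_that("aggregation is invariant to lesion order", {
  set.seed(11)
  les <- data.frame(patient_id = rep(c("A", "B"), c(4, 3)),
                    predicted_cytact = rnorm(7))
  b1 <- aggregatePatients(les)
  b2 <- aggregatePatients(les[sample(7), ])
  expect_equal(b1, b2)
})

test_that("dichotomization assigns ties to the low group", {
  b <- data.frame(patient_id = c("A", "B", "C", "D"),
                  min_cytact = c(-0.107, -0.5, 0.0, 0.3))
  g <- dichotomizeCytAct(b, cutoff = -0.107)
  expect_equal(as.character(g$group), c("low", "low", "high", "high"))
  expect_equal(levels(g$group), c("low", "high"))

  set.seed(13)
  b2 <- data.frame(patient_id = paste0("P", 1:50), min_cytact = rnorm(50))
  g2 <- dichotomizeCytAct(b2)
  manual <- ifelse(b2$min_cytact > -0.107, "high", "low")
  expect_equal(as.character(g2$group), manual)
})

test_that("size-change association supports lesion-wise and cluster-aware modes", {
  les <- make_lesion_table(17)
  icb <- genICBCohort(les, outcomeSpec(seed = 19))
  flat <- cytActSizeAssociation(icb$lesions)
  expect_equal(flat$rho, spearmanRho(icb$lesions$predicted_cytact,
                                     icb$lesions$size_change_pct)$rho)
  expect_lt(flat$rho, 0) # higher predicted CytAct, more shrinkage
  cl <- cytActSizeAssociation(icb$lesions, clusterAware = TRUE)
  expect_equal(cl$n, length(unique(icb$lesions$patient_id)))
  expect_lt(cl$rho, 0)
})

test_that("minimum CytAct discriminates better than maximum on worst-lesion cohorts", {
  ord <- logical(20)
  for (s in 1:20) {
    les <- make_lesion_table(1000 + s)
    icb <- genICBCohort(les, outcomeSpec(seed = 2000 + s))
    bio <- merge(aggregatePatients(filterTargetLesions(icb$lesions)),
                 icb$patients, by = "patient_id")
    if (length(unique(bio$responder)) < 2) { ord[s] <- NA; next }
    a_min <- suppressWarnings(rocAnalysis(bio$min_cytact, bio$responder))
    a_max <- suppressWarnings(rocAnalysis(bio$max_cytact, bio$responder))
    ord[s] <- a_min$auc >= a_max$auc
  }
  expect_gte(mean(ord, na.rm = TRUE), 0.8)
})

test_that("nonresponder CytAct variance dominates under heterogeneity-linked resistance", {
  pvals <- numeric(20)
  for (s in 1:20) {
    les <- make_lesion_table(1000 + s)
    icb <- genICBCohort(les, outcome_spec_het(2000 + s))
    bio <- merge(aggregatePatients(filterTargetLesions(icb$lesions)),
                 icb$patients, by = "patient_id")
    multi <- bio[!is.na(bio$cytact_variance), ]
    pvals[s] <- if (length(unique(multi$responder)) == 2)
      wilcox.test(multi$cytact_variance[!multi$responder],
                  multi$cytact_variance[multi$responder],
                  alternative = "greater", exact = FALSE)$p.value else NA
  }
  expect_lt(median(pvals, na.rm = TRUE), 0.05)
})
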