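test_that("Spearman rho hits the monotone extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanRho(x, rank(x))$rho, 1)
  expect_equal(spearmanRho(x, -x)$rho, -1)
  expect_error(spearmanRho(1:4, 1:5), "length")
  expect_error(spearmanRho(rep(1, 5), 1:5), "tied")
})

test_that("small-sample Spearman p matches full permutation enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 6) # one tie pair
  res <- spearmanRho(x, y)
  expect_identical(res$method, "exact permutation")
  expect_equal(res$p.value, oracle_spearman_p(x, y))

  set.seed(3)
  for (i in 1:3) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(spearmanRho(a, b)$p.value, oracle_spearman_p(a, b))
  }
})

test_that("Wilcoxon rank-sum: exact enumeration and symmetry", {
  res <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$method, "exact enumeration")
  expect_equal(res$p.value, 0.1) # 2 / choose(6, 3)
  expect_equal(res$statistic, 0)

  same <- rankSumTest(c(1, 2, 2, 5), c(5, 2, 1, 2))
  expect_equal(same$p.value, 1)
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p decreases monotonically with group separation", {
  set.seed(5)
  base <- rnorm(30)
  ps <- vapply(c(0, 0.5, 1, 2), function(shift)
    rankSumTest(base, base + shift)$p.value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("rank-sum type-I error is near nominal under the null", {
  set.seed(7)
  rej <- mean(replicate(5000, {
    rankSumTest(rnorm(10), rnorm(10))$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("AUC equals all-pairs concordance and handles degenerate scores", {
  perfect <- rocAnalysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flat <- suppressWarnings(rocAnalysis(rep(2, 8), rep(c(0, 1), 4)))
  expect_equal(flat$auc, 0.5)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n)
    r <- suppressWarnings(rocAnalysis(scores, labels))
    expect_equal(r$auc, oracle_auc(scores, labels))
    if (all(is.finite(r$ci95)))
      expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  }
  expect_error(rocAnalysis(1:5, rep(1, 5)), "both classes")
})

test_that("logistic regression matches closed forms and a likelihood grid", {
  f0 <- logisticFit(y ~ 1, data.frame(y = c(1, 0, 0, 0)))
  expect_equal(f0$estimate, log(1 / 3), tolerance = 1e-8)

  set.seed(13)
  df <- data.frame(x = rnorm(25))
  df$y <- rbinom(25, 1, plogis(0.4 + 0.8 * df$x))
  if (length(unique(df$y)) == 2) {
    fit <- logisticFit(y ~ x, df)
    loglik <- function(b0, b1) {
      p <- plogis(b0 + b1 * df$x)
      sum(df$y * log(p) + (1 - df$y) * log(1 - p))
    }
    # coarse-to-fine likelihood grid search around zero
    ctr <- c(0, 0); width <- 4
    for (pass in 1:8) {
      g0 <- seq(ctr[1] - width, ctr[1] + width, length.out = 21)
      g1 <- seq(ctr[2] - width, ctr[2] + width, length.out = 21)
      ll <- outer(g0, g1, Vectorize(loglik))
      best <- arrayInd(which.max(ll), dim(ll))
      ctr <- c(g0[best[1]], g1[best[2]])
      width <- width / 5
    }
    expect_equal(fit$estimate, ctr, tolerance = 1e-4)
  }

  sep <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = 1:6)
  expect_error(logisticFit(y ~ x, sep), "separation.*firth")
  firth <- logisticFit(y ~ x, sep, firth = TRUE)
  expect_true(all(is.finite(firth$estimate)))
  expect_true(all(is.finite(firth$se)))
})

test_that("survival analysis: symmetry, hand-tabulated log-rank, KM censoring", {
  idg <- survivalAnalysis(rep(c(1, 2, 3), 2), rep(1, 6),
                          rep(c("A", "B"), each = 3))
  expect_equal(idg$logrank_p, 1)
  expect_equal(idg$hazard_ratio, 1, tolerance = 1e-6)

  # events A at 1,2 and B at 3,4; hand tabulation gives
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi2 = (7/6)^2 / (17/36)
  toy <- suppressWarnings(
    survivalAnalysis(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B")))
  expect_equal(toy$logrank_chi2, (7 / 6)^2 / (17 / 36), tolerance = 1e-8)

  km <- survivalAnalysis(c(1, 2.5, 4, 1, 2.5, 4), c(1, 0, 1, 1, 0, 1),
                         rep(c("A", "B"), each = 3))
  a <- km$km[km$km$group == "A", ]
  expect_equal(a$surv[a$time == 2.5], a$surv[a$time == 1]) # censor: no drop
  expect_equal(a$n_risk[a$time == 4], 1)                    # but risk set shrinks
  expect_error(survivalAnalysis(c(0, 1), c(1, 1), c("A", "B")), "positive")
})

test_that("log-rank is invariant to monotone transforms of time", {
  set.seed(17)
  time <- rexp(40, 0.1) + 0.1
  event <- rbinom(40, 1, 0.8)
  group <- rep(c("A", "B"), 20)
  s1 <- survivalAnalysis(time, event, group)
  s2 <- survivalAnalysis(log1p(time), event, group)
  expect_equal(s1$logrank_chi2, s2$logrank_chi2)
  s3 <- survivalAnalysis(time^2, event, group)
  expect_equal(s1$logrank_chi2, s3$logrank_chi2)
})

test_that("groups without events yield a flagged, undefined hazard ratio", {
  res <- survivalAnalysis(c(1, 2, 3, 4), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_false(res$hr_defined)
  expect_true(is.na(res$hazard_ratio))
})
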