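#' Spearman rank correlation
#'
#' Midrank-based rho.  For n <= 9 the p-value is computed by exhaustive
#' permutation enumeration (two-sided, valid under ties); for larger n the
#' usual t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `rho`, `p.value`, `n`, `method`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("all-tied input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    m <- matrix(ry[perms], nrow = nrow(perms))
    # rho is affine in sum(rx * ry[perm]); compare on that scale
    s_obs <- sum(rx * ry)
    s_mean <- n * mean(rx) * mean(ry)
    s_perm <- as.numeric(m %*% rx)
    p <- mean(abs(s_perm - s_mean) >= abs(s_obs - s_mean) - 1e-9)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p.value = min(1, p), n = n, method = method)
}

# all n! permutations of 1:n as a matrix (rows); n <= 9
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    # keep integer matrix shape
    block <- matrix(as.integer(block), nrow = nrow(sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For pooled size `m + n <= 12` the null distribution of the
#' Mann-Whitney U statistic is enumerated exhaustively over all
#' `choose(m+n, m)` group assignments (valid under ties); the two-sided p
#' is `2 * min(P(U <= u), P(U >= u))` capped at 1.  Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `statistic` (U of group a), `p.value`, `method`.
#' @export
rankSumTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 12L) {
    combs <- combn(m + n, m)
    usum <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- 2 * min(mean(usum <= u_obs + 1e-9), mean(usum >= u_obs - 1e-9))
    method <- "exact enumeration"
  } else {
    wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(statistic = u_obs, p.value = min(1, p), method = method)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' AUC by the midrank (Mann-Whitney) formula with a DeLong 95% confidence
#' interval; the reported cutoff maximizes Youden's J = sensitivity +
#' specificity - 1.  Higher scores are treated as indicating the positive
#' class.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (logical, 0/1, or 2-level factor).
#' @return list with `auc`, `ci95`, `optimal_cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
rocAnalysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  # DeLong CI; degenerate (AUC 0 or 1) curves give a zero-width interval
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE] # deterministic choice on ties
  list(auc = as.numeric(pROC::auc(r)), ci95 = c(ci[1], ci[3]),
       optimal_cutoff = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity)
}

#' Logistic regression with separation guard and optional Firth penalty
#'
#' Maximum-likelihood fit via `glm`; if the fit shows complete separation
#' an error advises the Firth option, which maximizes the Jeffreys-prior
#' penalized likelihood (bias-reduced scores `X'(y - p + h(0.5 - p))`) and
#' remains finite under separation.  Wald p-values in both cases.
#'
#' @param formula model formula with a binary response.
#' @param data data.frame.
#' @param firth use the Firth penalty.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p.value`.
#' @export
logisticFit <- function(formula, data, firth = FALSE) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(as.logical(y))
  X <- model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) <= ncol(X))
    stop("need more observations than coefficients")
  if (firth) return(firth_fit(X, y))
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  p <- fit$fitted.values
  eps <- 1e-8
  separated <- all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps)
  if (separated || any(abs(fit$coefficients) > 25))
    stop("perfect separation detected; consider firth = TRUE")
  W <- p * (1 - p)
  cov <- solve(crossprod(X, X * W))
  se <- sqrt(diag(cov))
  est <- fit$coefficients
  data.frame(term = colnames(X), estimate = unname(est), se = se,
             z = unname(est) / se, p.value = 2 * pnorm(-abs(est / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

firth_fit <- function(X, y, maxit = 100, tol = 1e-10) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X, X * W)
    inv <- solve(XtWX)
    # leverages of the weighted design
    h <- rowSums((X %*% inv) * X) * W
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- as.numeric(inv %*% U)
    # damp very large steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  W <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * W))))
  data.frame(term = colnames(X), estimate = beta, se = se, z = beta / se,
             p.value = 2 * pnorm(-abs(beta / se)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-group survival analysis
#'
#' Kaplan-Meier product-limit curves per group, the two-group log-rank
#' test, and the hazard ratio of the second group level versus the first
#' from a Cox fit with Efron tie handling.  If one group has no events the
#' hazard ratio is undefined and flagged.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @param group 2-level grouping (factor or coercible).
#' @return list with `km` (data.frame: group, time, surv, n_risk),
#'   `logrank_chi2`, `logrank_p`, `hazard_ratio`, `hr_ci95`,
#'   `hr_defined`.
#' @export
survivalAnalysis <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  event <- as.integer(event)
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                   surv = sf$surv, n_risk = sf$n.risk,
                   stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- sd_$chisq
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  events_per_group <- tapply(event, group, sum)
  if (any(events_per_group == 0)) {
    hr <- NA_real_; ci <- c(NA_real_, NA_real_); defined <- FALSE
  } else {
    cx <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                          ties = "efron")
    hr <- unname(exp(coef(cx)))
    se <- sqrt(diag(cx$var))
    ci <- exp(coef(cx) + c(-1, 1) * 1.96 * se)
    defined <- TRUE
  }
  list(km = km, logrank_chi2 = unname(chi2), logrank_p = unname(p),
       hazard_ratio = hr, hr_ci95 = unname(ci), hr_defined = defined)
}
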