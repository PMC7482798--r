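# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity with plain loops over voxels
# or exhaustive enumeration, sharing nothing with the package internals.

# adaptive threshold recomputed voxel-by-voxel from its definition
oracle_threshold <- function(a, box, beta = 0.3, shell = 2L) {
  d <- dim(a)
  in_box <- function(i, j, k) {
    i >= box[1] && i <= box[2] && j >= box[3] && j <= box[4] &&
      k >= box[5] && k <= box[6]
  }
  in_outer <- function(i, j, k) {
    i >= max(1, box[1] - shell) && i <= min(d[1], box[2] + shell) &&
      j >= max(1, box[3] - shell) && j <= min(d[2], box[4] + shell) &&
      k >= max(1, box[5] - shell) && k <= min(d[3], box[6] + shell)
  }
  box_vals <- c()
  shell_vals <- c()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (in_box(i, j, k)) box_vals <- c(box_vals, a[i, j, k])
    else if (in_outer(i, j, k)) shell_vals <- c(shell_vals, a[i, j, k])
  }
  mx <- max(box_vals)
  i70 <- mean(box_vals[box_vals > 0.7 * mx])
  keep <- shell_vals[shell_vals <= 0.7 * mx]
  ibg <- if (length(shell_vals) == 0) 0
         else if (length(keep) == 0) mean(shell_vals) else mean(keep)
  list(threshold = beta * i70 + ibg, i70 = i70, ibackground = ibg)
}

# 26-connected flood fill from the seed-box maximum at threshold thr
oracle_segment <- function(a, box, thr) {
  d <- dim(a)
  cand <- array(FALSE, d)
  cand[box[1]:box[2], box[3]:box[4], box[5]:box[6]] <-
    a[box[1]:box[2], box[3]:box[4], box[5]:box[6]] >= thr
  inbox <- array(FALSE, d)
  inbox[box[1]:box[2], box[3]:box[4], box[5]:box[6]] <- TRUE
  vals <- a
  vals[!inbox] <- -Inf
  seed <- arrayInd(which.max(vals), d)
  out <- array(FALSE, d)
  if (!cand[seed]) return(out)
  queue <- list(as.integer(seed))
  out[seed] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (o1 in -1:1) for (o2 in -1:1) for (o3 in -1:1) {
      if (o1 == 0 && o2 == 0 && o3 == 0) next
      w <- v + c(o1, o2, o3)
      if (any(w < 1) || any(w > d)) next
      if (cand[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue <- c(queue, list(w))
      }
    }
  }
  out
}

# AUC as the all-pairs concordance count (ties worth 0.5)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive-permutation two-sided Spearman p, recomputing rho via cor()
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho_obs <- cor(rank(x), rank(y))
  perms <- gen_perms(seq_len(n))
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

gen_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- gen_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# random Gaussian-blob phantom on noisy background for oracle comparisons
make_blob_volume <- function(seed, side = 16L, spacing = 2) {
  set.seed(seed)
  ctr <- side / 2 + runif(3, -2, 2)
  sig <- runif(1, 1.5, 3)
  amp <- runif(1, 3, 8)
  sq <- lapply(1:3, function(k) (seq_len(side) - ctr[k])^2)
  g <- amp * exp(-outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+") /
                   (2 * sig^2))
  g <- g + array(runif(side^3, 0, 0.3), dim = rep(side, 3))
  PETVolume(array(g, rep(side, 3)), spacing = spacing, units = "SUV")
}

# small latent lesion table for synthetic ICB cohorts
make_lesion_table <- function(seed, n_patients = 40) {
  set.seed(seed)
  nles <- sample(1:4, n_patients, replace = TRUE,
                 prob = c(0.35, 0.3, 0.2, 0.15))
  data.frame(patient_id = rep(sprintf("P%03d", seq_len(n_patients)), nles),
             lesion_id = paste0("L", seq_len(sum(nles))),
             u = rnorm(sum(nles)),
             stringsAsFactors = FALSE)
}

# outcome preset with variance-linked resistance enabled: the size-change
# intercept is deepened so response rates stay realistic under the penalty
outcome_spec_het <- function(seed) {
  outcomeSpec(a = -60, hetPenalty = 40, seed = seed)
}
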