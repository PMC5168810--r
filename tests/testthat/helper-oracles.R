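# Independent reference implementations used as oracles. These are written
# from the estimator's definition, deliberately avoiding the package's code
# paths (explicit loops, naive counting), so agreement is evidence of
# correctness rather than repetition.

# lower-interpolation quantile: smallest value v in the pooled set with
# #(pooled <= v) >= lambda * n
oracle_lower_quantile <- function(pooled, lambda) {
  vals <- sort(unique(pooled))
  n <- length(pooled)
  for (v in vals) {
    if (sum(pooled <= v) >= lambda * n) return(v)
  }
  vals[length(vals)]
}

# brute-force composition of the permutation FDR estimate for a fixed
# discriminant value set (tau already applied)
oracle_fdr <- function(d, perm_list, lambda = 0.5, e_b_mode = "median") {
  M <- length(d)
  pooled <- unlist(perm_list)
  d_lambda <- oracle_lower_quantile(pooled, lambda)
  n0 <- 0L
  for (v in d) if (v <= d_lambda) n0 <- n0 + 1L
  n0_use <- max(n0, 1L)
  counts <- vapply(perm_list, function(q) sum(q > 0), 0)
  eb <- if (e_b_mode == "median") stats::median(counts) else mean(counts)
  r <- sum(d > 0)
  min(n0_use * eb / ((1 - lambda) * max(r, 1) * M), 1)
}

# exhaustive cutoff search: evaluate the FDR estimate at every candidate
# threshold by brute force and keep the feasible one with the most calls
# (ties toward the larger threshold)
oracle_tune <- function(d0, perm_list, psi, lambda = 0.5, e_b_mode = "median") {
  cands <- c(min(d0) - 1, sort(unique(d0)))
  best <- NULL
  for (tau in cands) {
    d <- d0 - tau
    pl <- lapply(perm_list, function(q) q - tau)
    r <- sum(d > 0)
    if (r == 0L) next
    fdr <- oracle_fdr(d, pl, lambda, e_b_mode)
    if (fdr < psi && (is.null(best) || r > best$r ||
                      (r == best$r && tau > best$tau))) {
      best <- list(tau = tau, r = r, fdr = fdr)
    }
  }
  best
}

# small random Gaussian dataset with optional mean shifts in group 2
rand_dataset <- function(M, n1, n2, shift = rep(0, M), seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(M * (n1 + n2)), M)
    x[, n1 + seq_len(n2)] <- x[, n1 + seq_len(n2)] + shift
    expression_dataset(x, paste0("f", seq_len(M)),
                       paste0("s", seq_len(n1 + n2)),
                       rep(c("A", "B"), c(n1, n2)))
  })
}

# random count dataset from independent NB draws
rand_count_dataset <- function(M, n1, n2, mu = 100, disp = 0.1, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnbinom(M * (n1 + n2), mu = mu, size = 1 / disp), M)
    expression_dataset(x, paste0("f", seq_len(M)),
                       paste0("s", seq_len(n1 + n2)),
                       rep(c("A", "B"), c(n1, n2)))
  })
}

swap_labels <- function(data) {
  lv <- levels(data$labels)
  data$labels <- factor(ifelse(data$labels == lv[1L], lv[2L], lv[1L]),
                        levels = lv)
  data
}
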