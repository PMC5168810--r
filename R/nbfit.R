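# Vectorised negative-binomial GLM machinery for the two-group design with
# log size-factor offsets. All features are fitted simultaneously with
# matrix operations: the design [1, group] is saturated for two groups, so
# each IRLS step reduces to two weighted means of the working response.
# The per-feature profile-ML dispersion search runs in compiled code
# (cpp_alpha_ml).
#
# Parameterisation: Var(y) = mu + alpha * mu^2 (alpha = dispersion, 1/theta).

ALPHA_ML_MIN <- 1e-4   # below this the fit is declared Poisson
ALPHA_ML_MAX <- 50
ALPHA_EPS <- 1e-12     # clamp for externally supplied dispersion 0

# One block of IRLS iterations for fixed per-feature dispersion alpha
# (compiled kernel). counts: M x N; g2: logical length N; off: length N
# (log size factors). Returns list(beta0, beta1, mu).
nb_irls <- function(counts, g2, off, alpha, beta0, beta1, iter = 4L) {
  cpp_nb_irls(counts, g2, off, rep_len(alpha, nrow(counts)),
              beta0, beta1, as.integer(iter))
}

# Profile score dl/d(alpha) at fixed mu (pure-R mirror of the compiled
# kernel, kept for cross-checking in the test suite).
nb_alpha_score <- function(counts, mu, alpha) {
  a <- matrix(alpha, nrow(counts), ncol(counts))
  ia <- 1 / a
  rowSums(ia^2 * (digamma(ia) - digamma(counts + ia) + log1p(a * mu)) +
            (counts - mu) / (a * (1 + a * mu)))
}

# NB log-likelihood per feature at given mu / alpha.
nb_loglik <- function(counts, mu, alpha) {
  a <- matrix(alpha, nrow(counts), ncol(counts))
  ia <- 1 / a
  rowSums(lgamma(counts + ia) - lgamma(ia) - lgamma(counts + 1) +
            counts * log(a * mu / (1 + a * mu)) - ia * log1p(a * mu))
}

# Full per-matrix NB Wald fit. Returns the statistic vector with attributes.
nb_wald_matrix <- function(counts, g2, sf, shrink = TRUE, dispersion = NULL) {
  M <- nrow(counts); N <- ncol(counts)
  off <- log(sf)
  all_zero <- rowSums(counts) == 0
  norm <- sweep(counts, 2L, sf, "/")
  m1 <- rowMeans(norm[, !g2, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  beta0 <- log(pmax(m1, 1e-8))
  beta1 <- log(pmax(m2, 1e-8)) - beta0

  if (!is.null(dispersion)) {
    alpha <- pmax(rep_len(dispersion, M), 0)
    alpha_use <- pmax(alpha, ALPHA_EPS)
    pois <- alpha <= ALPHA_EPS
    fit <- nb_irls(counts, g2, off, alpha_use, beta0, beta1, iter = 8L)
  } else {
    # moment init, then alternate beta-IRLS and profile-ML dispersion
    v <- row_vars(norm)
    mbar <- (m1 + m2) / 2
    alpha_use <- pmin(pmax((v - mbar) / pmax(mbar^2, 1e-8), ALPHA_ML_MIN),
                      ALPHA_ML_MAX)
    pois <- rep(FALSE, M)
    fit <- NULL
    for (round in 1:2) {
      fit <- nb_irls(counts, g2, off, alpha_use, beta0, beta1, iter = 4L)
      beta0 <- fit$beta0; beta1 <- fit$beta1
      ml <- cpp_alpha_ml(counts, fit$mu, ALPHA_ML_MIN, ALPHA_ML_MAX, 16L)
      alpha_use <- ml$alpha
      pois <- ml$at_min
    }
    if (shrink && M >= 10L) {
      # trend: ML dispersion regressed on 1/mean (+ intercept); shrink each
      # log-dispersion halfway toward the trend
      base_mean <- pmax((m1 + m2) / 2, 1e-8)
      dfit <- stats::lm.fit(cbind(1, 1 / base_mean), alpha_use)
      trend <- pmin(pmax(dfit$fitted.values, ALPHA_ML_MIN), ALPHA_ML_MAX)
      alpha_use <- exp(0.5 * log(alpha_use) + 0.5 * log(trend))
    }
    alpha <- alpha_use
    fit <- nb_irls(counts, g2, off, alpha_use, fit$beta0, fit$beta1, iter = 6L)
  }

  bad <- !is.finite(fit$beta0) | !is.finite(fit$beta1)
  if (any(bad)) {
    # Poisson fallback: closed-form group means under offsets
    s1 <- sum(sf[!g2]); s2 <- sum(sf[g2])
    y1 <- rowSums(counts[, !g2, drop = FALSE]); y2 <- rowSums(counts[, g2, drop = FALSE])
    fit$beta0[bad] <- log(pmax(y1[bad] / s1, 1e-8))
    fit$beta1[bad] <- log(pmax(y2[bad] / s2, 1e-8)) - fit$beta0[bad]
    alpha_use[bad] <- ALPHA_EPS
    pois[bad] <- TRUE
    xind <- as.numeric(g2)
    eta <- fit$beta0 + outer(fit$beta1, xind) + matrix(off, M, N, byrow = TRUE)
    fit$mu <- exp(pmin(pmax(eta, -30), 30))
  }

  # Wald SE from the observed information of the saturated two-group design
  mu <- fit$mu
  w_obs <- mu * (1 + alpha_use * counts) / (1 + alpha_use * mu)^2
  sw1 <- rowSums(w_obs[, !g2, drop = FALSE])
  sw2 <- rowSums(w_obs[, g2, drop = FALSE])
  se <- sqrt(1 / pmax(sw1, 1e-12) + 1 / pmax(sw2, 1e-12))
  stat <- fit$beta1 / se
  stat[all_zero] <- 0
  stat[!is.finite(stat)] <- 0
  attr(stat, "dispersion") <- alpha_use
  attr(stat, "beta") <- fit$beta1
  attr(stat, "se") <- se
  attr(stat, "all_zero") <- which(all_zero)
  attr(stat, "poisson_fallback") <- which(pois & !all_zero)
  stat
}
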