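#' Basic attributes: per-feature test statistics
#'
#' Each extractor maps an [expression_dataset()] to one signed statistic per
#' feature, oriented group 2 minus group 1 (larger = stronger evidence of
#' up-regulation in group 2). These statistics are the coordinates of the
#' multi-dimensional space in which the discriminant boundary is learned.
#'
#' @name basic-attributes
NULL

group_counts <- function(labels) {
  g2 <- group2_mask(labels)
  c(n1 = sum(!g2), n2 = sum(g2))
}

check_two_per_group <- function(labels) {
  n <- group_counts(labels)
  if (any(n < 2L)) stop("both groups need at least 2 samples")
  n
}

check_integerish <- function(values, what) {
  if (any(values < 0)) stop(what, " requires non-negative values")
  if (max(abs(values - round(values))) > 1e-6)
    stop(what, " requires integer counts; use scale_round() for continuous data")
  round(values)
}

#' SAM-style corrected t-statistic
#'
#' Two-sample t-statistic with a data-wide fudge constant s0 added to the
#' per-feature pooled standard error, stabilising features with tiny
#' variances: \eqn{(\bar x_2 - \bar x_1) / (s_g + s_0)}.
#'
#' @param data an [expression_dataset()]; any real values.
#' @param s0_mode fudge-constant policy: \code{"median"} (s0 = median of the
#'   per-feature standard errors, the default), \code{"quantile"} (use
#'   \code{s0_quantile}), or \code{"fixed"} (use \code{s0} as given).
#' @param s0_quantile quantile of the standard errors used when
#'   \code{s0_mode = "quantile"}.
#' @param s0 fixed fudge value for \code{s0_mode = "fixed"} (0 gives the
#'   ordinary pooled-variance t).
#' @param log_transform if TRUE, apply log2(x + 0.5) before testing.
#' @return numeric vector of M statistics; features with zero variance in
#'   both groups and s0 = 0 are set to 0 and flagged in
#'   \code{attr(, "zero_variance")}.
#' @export
compute_sam_t <- function(data, s0_mode = c("median", "quantile", "fixed"),
                          s0_quantile = 0.5, s0 = 0, log_transform = FALSE) {
  s0_mode <- match.arg(s0_mode)
  check_two_per_group(data$labels)
  x <- data$values
  if (log_transform) {
    if (any(x < -0.5)) stop("log transform requires values >= -0.5")
    x <- log2(x + 0.5)
  }
  g2 <- group2_mask(data$labels)
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(x[, !g2, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- row_vars(x[, !g2, drop = FALSE])
  v2 <- row_vars(x[, g2, drop = FALSE])
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  s0_val <- switch(s0_mode,
                   median = stats::median(se),
                   quantile = unname(stats::quantile(se, s0_quantile, type = 7)),
                   fixed = s0)
  denom <- se + s0_val
  zv <- denom == 0
  stat <- ifelse(zv, 0, (m2 - m1) / ifelse(zv, 1, denom))
  attr(stat, "s0") <- s0_val
  attr(stat, "zero_variance") <- which(zv)
  stat
}

#' SAM-style centered rank-sum statistic
#'
#' Per feature, samples receive mid-ranks (ties averaged); the statistic is
#' the group-2 rank sum minus its null expectation,
#' \eqn{W - n_2 (n_1 + n_2 + 1)/2}.
#'
#' @inheritParams compute_sam_t
#' @return numeric vector of M statistics.
#' @export
compute_sam_ranksum <- function(data) {
  check_two_per_group(data$labels)
  g2 <- group2_mask(data$labels)
  N <- ncol(data$values)
  n2 <- sum(g2)
  e0 <- n2 * (N + 1) / 2
  rk <- row_mid_ranks(data$values)
  rowSums(rk[, g2, drop = FALSE]) - e0
}

# row-wise mid-ranks; pairwise column comparison is much faster than
# apply(rank) for the short sample vectors typical here
row_mid_ranks <- function(x) {
  N <- ncol(x)
  if (N > 30L) {
    rk <- t(apply(x, 1L, rank, ties.method = "average"))
    if (nrow(x) == 1L) rk <- matrix(rk, nrow = 1L)
    return(rk)
  }
  r <- matrix(1, nrow(x), N)
  for (j in seq_len(N)) {
    xj <- x[, j]
    for (k in seq_len(N)) {
      if (k == j) next
      xk <- x[, k]
      r[, j] <- r[, j] + (xk < xj) + 0.5 * (xk == xj)
    }
  }
  r
}

# rowwise sample variance (denominator n-1)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Smyth-style moment matching of a scaled inverse-chi-square prior to the
# per-feature sample variances: returns list(d0, s02). d0 is capped so that
# "effectively infinite" moderation stays finite.
fit_variance_prior <- function(s2, df, d0_cap = 1e6) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3L)
    stop("need at least 3 features with positive variance to estimate the variance prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- d0_cap
  } else {
    d0 <- min(2 * trigamma_inverse(evar), d0_cap)
  }
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated t-statistic (empirical-Bayes shrunken variance)
#'
#' Two-group (optionally precision-weighted) t-statistic whose residual
#' variance is replaced by the posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}. The prior
#' hyperparameters \eqn{(d_0, s_0^2)} are estimated by moment-matching the
#' log sample variances across features (digamma/trigamma equations).
#'
#' @param data an [expression_dataset()]; any real values.
#' @param weights optional M x N matrix of positive precision weights.
#' @param d0,s02 optional hyperparameter overrides; \code{d0 = 0} gives the
#'   ordinary t-statistic, large \code{d0} shrinks every variance to
#'   \code{s02}.
#' @return numeric vector of M statistics with attributes \code{d0},
#'   \code{s02} and \code{df_total}.
#' @export
compute_moderated_t <- function(data, weights = NULL, d0 = NULL, s02 = NULL) {
  check_two_per_group(data$labels)
  x <- data$values
  M <- nrow(x); N <- ncol(x)
  g2 <- group2_mask(data$labels)
  if (is.null(weights)) weights <- matrix(1, M, N)
  if (!all(dim(weights) == dim(x))) stop("weights must match the data matrix")
  if (any(weights <= 0)) stop("weights must be positive")
  w1 <- weights[, !g2, drop = FALSE]; w2 <- weights[, g2, drop = FALSE]
  x1 <- x[, !g2, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  sw1 <- rowSums(w1); sw2 <- rowSums(w2)
  m1 <- rowSums(w1 * x1) / sw1
  m2 <- rowSums(w2 * x2) / sw2
  df <- N - 2
  rss <- rowSums(w1 * (x1 - m1)^2) + rowSums(w2 * (x2 - m2)^2)
  s2 <- rss / df
  vunsc <- 1 / sw1 + 1 / sw2  # unscaled variance of the group contrast
  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  stat <- (m2 - m1) / sqrt(s2_post * vunsc)
  stat[!is.finite(stat)] <- 0
  attr(stat, "d0") <- d0
  attr(stat, "s02") <- s02
  attr(stat, "df_total") <- df + d0
  stat
}

#' Moderated t on log-CPM with mean-variance precision weights
#'
#' Count-data analogue of the moderated t: counts are transformed to
#' log2 counts-per-million with a half-count offset,
#' \eqn{\log_2((y + 0.5) / (lib + 1) \cdot 10^6)}; the square-root residual
#' standard deviation is smoothed against average log-CPM with lowess; each
#' observation receives the precision weight
#' \eqn{(\widehat{\mathrm{sqrt\mbox{-}SD}})^{-4}} (inverse predicted
#' variance) at its fitted log-CPM; transformed values and weights feed
#' [compute_moderated_t()].
#'
#' @param data an [expression_dataset()] of non-negative integer counts.
#' @param use_weights if FALSE, skip the mean-variance trend and use unit
#'   weights (the statistic is then exactly [compute_moderated_t()] on the
#'   log-CPM values).
#' @param span lowess span for the mean-variance trend.
#' @return numeric vector of M statistics; the fitted trend is attached as
#'   \code{attr(, "trend")} (list with knots \code{x}, \code{y}).
#' @export
compute_voom_t <- function(data, use_weights = TRUE, span = 0.5) {
  counts <- check_integerish(data$values, "compute_voom_t")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all library sizes (column sums) must be positive")
  M <- nrow(counts); N <- ncol(counts)
  logcpm <- log2(sweep(counts + 0.5, 2L, lib + 1, "/") * 1e6)
  ldat <- expression_dataset(logcpm, data$feature_ids, data$sample_ids, data$labels)
  if (!use_weights) return(compute_moderated_t(ldat))
  if (M < 50L) {
    warning("fewer than 50 features: mean-variance trend unreliable, using unit weights")
    return(compute_moderated_t(ldat))
  }
  g2 <- group2_mask(data$labels)
  m1 <- rowMeans(logcpm[, !g2, drop = FALSE])
  m2 <- rowMeans(logcpm[, g2, drop = FALSE])
  fitted <- matrix(m1, M, N)
  fitted[, g2] <- m2
  resid_sd <- sqrt(rowSums((logcpm - fitted)^2) / (N - 2))
  avg <- rowMeans(logcpm)
  lo <- stats::lowess(avg, sqrt(resid_sd), f = span)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2, ties = "ordered")$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(pred^-4, M, N)
  stat <- compute_moderated_t(ldat, weights = w)
  attr(stat, "trend") <- list(x = lo$x, y = lo$y)
  stat
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: for each sample, the median across
#' all-positive features of the ratio of its count to the feature's
#' geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts non-negative M x N matrix.
#' @return numeric vector of N positive factors. Falls back to library-size
#'   factors (with a warning) when no feature is positive in every sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with all-positive counts: using library-size factors")
    sf <- colSums(counts)
    if (any(sf <= 0)) stop("cannot normalize: a sample has zero total count")
  } else {
    lx <- log(counts[pos, , drop = FALSE])
    geo <- rowMeans(lx)
    sf <- exp(apply(lx - geo, 2L, stats::median))
  }
  unname(sf / exp(mean(log(sf))))
}

#' Negative-binomial Wald statistic
#'
#' Per feature, a negative-binomial log-link GLM with intercept, group
#' indicator and log size-factor offsets is fitted; the dispersion is
#' estimated by maximum likelihood and (optionally) shrunk toward a
#' mean-dispersion trend; the statistic is
#' \eqn{\hat\beta_{group} / SE(\hat\beta_{group})} with the standard error
#' taken from the observed information.
#'
#' @param data an [expression_dataset()] of non-negative integer counts.
#' @param size_factors optional vector of N positive normalisation factors;
#'   computed by [size_factors()] when NULL.
#' @param shrink if TRUE (default), per-feature log-dispersions are shrunk
#'   halfway toward a trend obtained by regressing the ML dispersions on
#'   1/mean; disabled automatically when fewer than 10 features are present.
#' @param dispersion optional fixed dispersion (scalar or length-M);
#'   \code{dispersion = 0} gives the Poisson Wald statistic.
#' @return numeric vector of M statistics with attributes \code{dispersion}
#'   (values used), \code{all_zero} (indices of all-zero features, statistic
#'   0) and \code{poisson_fallback} (indices fitted at the Poisson boundary).
#' @export
compute_nb_wald <- function(data, size_factors = NULL, shrink = TRUE,
                            dispersion = NULL) {
  counts <- check_integerish(data$values, "compute_nb_wald")
  if (is.null(size_factors)) size_factors <- discut::size_factors(counts)
  if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
    stop("size_factors must be ", ncol(counts), " positive values")
  nb_wald_matrix(counts, group2_mask(data$labels), size_factors,
                 shrink = shrink, dispersion = dispersion)
}

attribute_registry <- function() {
  list(
    sam_t = function(data, settings) do.call(compute_sam_t, c(list(data), settings)),
    sam_log_t = function(data, settings)
      do.call(compute_sam_t, c(list(data, log_transform = TRUE), settings)),
    sam_ranksum = function(data, settings) compute_sam_ranksum(data),
    moderated_t = function(data, settings) do.call(compute_moderated_t, c(list(data), settings)),
    voom_t = function(data, settings) do.call(compute_voom_t, c(list(data), settings)),
    nb_wald = function(data, settings) do.call(compute_nb_wald, c(list(data), settings))
  )
}

#' Supported basic-attribute names
#' @return character vector of attribute names accepted by
#'   [build_attribute_matrix()].
#' @export
attribute_names <- function() names(attribute_registry())

#' Build the M x K attribute matrix
#'
#' Computes the requested basic attributes column by column, in order, with
#' the uniform group-2-minus-group-1 orientation. The same spec (names plus
#' settings) is reused verbatim when attributes are recomputed on permuted
#' labels, so data-dependent tuning constants (SAM s0, variance prior,
#' mean-variance trend, dispersions) are re-estimated under each label
#' assignment by the identical policy.
#'
#' @param data an [expression_dataset()].
#' @param spec character vector of attribute names (see [attribute_names()]),
#'   or a named list mapping attribute names to lists of extractor settings.
#' @return object of class \code{"attribute_matrix"}: list with \code{stats}
#'   (M x K matrix, all finite), \code{attribute_names}, \code{settings}.
#' @export
build_attribute_matrix <- function(data, spec) {
  if (is.character(spec)) {
    spec <- stats::setNames(rep(list(list()), length(spec)), spec)
  }
  if (length(spec) == 0L) stop("attribute spec must not be empty")
  reg <- attribute_registry()
  unknown <- setdiff(names(spec), names(reg))
  if (length(unknown) > 0L)
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(reg), collapse = ", "))
  if (anyDuplicated(names(spec)))
    warning("duplicate attribute names in spec produce identical columns")
  cols <- lapply(seq_along(spec), function(k) {
    st <- as.numeric(reg[[names(spec)[k]]](data, spec[[k]]))
    if (any(!is.finite(st)))
      stop("non-finite statistic from '", names(spec)[k], "' at feature ",
           data$feature_ids[which(!is.finite(st))[1L]])
    st
  })
  stats_mat <- do.call(cbind, cols)
  dimnames(stats_mat) <- list(data$feature_ids, names(spec))
  structure(list(stats = stats_mat, attribute_names = names(spec),
                 settings = spec),
            class = "attribute_matrix")
}

#' @export
print.attribute_matrix <- function(x, ...) {
  cat(sprintf("attribute_matrix: %d features x %d attributes (%s)\n",
              nrow(x$stats), ncol(x$stats),
              paste(x$attribute_names, collapse = ", ")))
  invisible(x)
}

#' Write an attribute matrix as TSV
#' @param am an [build_attribute_matrix()] result.
#' @param path output path.
#' @export
write_attributes <- function(am, path) {
  write_matrix(am$stats, path)
}
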