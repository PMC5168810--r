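#' Linear discriminant model
#'
#' The discriminant function \eqn{f(s_1, \dots, s_K) = \sum_k w_k s_k - \tau}
#' with L1-normalised weights (\eqn{\sum_k |w_k| = 1}). All weights are
#' non-negative when detecting up-regulation and non-positive for
#' down-regulation; a feature is called when its discriminant value is
#' strictly positive.
#'
#' @param weights numeric length-K weight vector, single-signed, absolute
#'   values summing to 1.
#' @param tau cutoff.
#' @param direction \code{"up"} or \code{"down"}.
#' @return object of class \code{"discriminant_model"}.
#' @export
discriminant_model <- function(weights, tau = 0, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (abs(sum(abs(weights)) - 1) > 1e-9)
    stop("weights must satisfy sum(|w|) = 1")
  if (direction == "up" && any(weights < 0))
    stop("up-direction weights must be non-negative")
  if (direction == "down" && any(weights > 0))
    stop("down-direction weights must be non-positive")
  structure(list(weights = as.numeric(weights), tau = as.numeric(tau),
                 direction = direction),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("discriminant_model (%s): w = (%s), tau = %.6g\n", x$direction,
              paste(sprintf("%.3f", x$weights), collapse = ", "), x$tau))
  invisible(x)
}

#' Discriminant values of all features
#'
#' \eqn{d_i = \sum_k w_k s_i^{(k)} - \tau}; features with \eqn{d_i > 0}
#' (strictly) are called.
#'
#' @param stats M x K attribute matrix (or an \code{attribute_matrix}).
#' @param model a [discriminant_model()].
#' @return numeric vector of M discriminant values.
#' @export
discriminant_values <- function(stats, model) {
  if (inherits(stats, "attribute_matrix")) stats <- stats$stats
  stats <- as.matrix(stats)
  if (ncol(stats) != length(model$weights))
    stop("model has ", length(model$weights), " weights but stats has ",
         ncol(stats), " columns")
  if (any(!is.finite(stats))) {
    bad <- which(rowSums(!is.finite(stats)) > 0)[1L]
    stop("non-finite statistic at feature ",
         if (!is.null(rownames(stats))) rownames(stats)[bad] else bad)
  }
  drop(stats %*% model$weights) - model$tau
}

#' Estimated tail probability of the null discriminant
#'
#' \eqn{\hat P(D_f > 0 \mid NULL)}: the median (or mean) over permutations
#' of the count of positive permutation discriminant values, divided by M.
#'
#' @param perm_d list of B numeric vectors (discriminant values on each
#'   permutation), or a B x M / M x B matrix split by permutation.
#' @param e_b_mode \code{"median"} (default) or \code{"mean"} aggregation
#'   over permutations.
#' @return scalar estimate.
#' @export
estimate_p_pos_null <- function(perm_d, e_b_mode = c("median", "mean")) {
  e_b_mode <- match.arg(e_b_mode)
  if (!is.list(perm_d)) perm_d <- list(perm_d)
  M <- length(perm_d[[1L]])
  cnt <- vapply(perm_d, function(v) sum(v > 0), 0)
  agg <- if (e_b_mode == "median") stats::median(cnt) else mean(cnt)
  agg / M
}

#' Null-quantile pivot of the pooled permutation discriminants
#'
#' The lower-interpolation \eqn{\lambda}-quantile of the pooled permutation
#' discriminant values: with the pooled values sorted, element
#' \eqn{\max(1, \lceil \lambda n \rceil)}.
#'
#' @param perm_d pooled permutation discriminant values (vector or list of
#'   per-permutation vectors).
#' @param lambda quantile in (0, 1).
#' @return scalar \eqn{d_\lambda}.
#' @export
estimate_d_lambda <- function(perm_d, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  pooled <- if (is.list(perm_d)) unlist(perm_d, use.names = FALSE) else perm_d
  if (length(pooled) == 0L) stop("pooled permutation set is empty")
  s <- sort(pooled)
  s[max(1L, ceiling(lambda * length(s)))]
}

#' Estimated proportion of null features
#'
#' \eqn{\hat P(NULL) = |\{d_i \le d_\lambda\}| / ((1-\lambda) M)}, truncated
#' at 1 (a probability must not exceed 1). A degenerate zero count (all
#' observed discriminants above the pivot) is returned as 0 with attribute
#' \code{degenerate = TRUE}; [estimate_fdr()] floors it to one count so the
#' estimate cannot certify a zero FDR from a vacuous numerator.
#'
#' @param d observed discriminant values (length M).
#' @param d_lambda pivot from [estimate_d_lambda()].
#' @param lambda the quantile used for the pivot.
#' @return scalar in [0, 1].
#' @export
estimate_p_null <- function(d, d_lambda, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  M <- length(d)
  cnt <- sum(d <= d_lambda)
  p <- min(cnt / ((1 - lambda) * M), 1)
  if (cnt == 0L) attr(p, "degenerate") <- TRUE
  p
}

#' Permutation-based FDR estimate of a discriminant boundary
#'
#' Composes the null tail probability, null proportion and observed
#' positive-call rate into
#' \deqn{\widehat{FDR}_\lambda = \frac{|\{d_i \le d_\lambda\}| \cdot
#'   \hat E_b(|\{d^*_{i,b} > 0\}|)}{(1-\lambda)\,(r \vee 1)\, M}}
#' with \eqn{r = |\{d_i > 0\}|}; the result is clipped to [0, 1]. When no
#' feature is called and no permutation produces a positive value the
#' estimate is exactly 0. A degenerate zero numerator count is floored at 1
#' (flagged).
#'
#' @param d observed discriminant values (length M).
#' @param perm_d list of B per-permutation discriminant vectors.
#' @param lambda null-quantile tuning parameter (default 0.5).
#' @param e_b_mode \code{"median"} or \code{"mean"}.
#' @return object of class \code{"fdr_estimate"}: list with \code{fdr_hat},
#'   \code{r}, \code{p_null_hat}, \code{p_pos_null_hat}, \code{d_lambda},
#'   \code{lambda}, \code{e_b_mode}, \code{degenerate}.
#' @export
estimate_fdr <- function(d, perm_d, lambda = 0.5,
                         e_b_mode = c("median", "mean")) {
  e_b_mode <- match.arg(e_b_mode)
  if (!is.list(perm_d)) perm_d <- list(perm_d)
  M <- length(d)
  d_lambda <- estimate_d_lambda(perm_d, lambda)
  n0 <- sum(d <= d_lambda)
  degenerate <- n0 == 0L
  n0_use <- max(n0, 1L)
  cnt <- vapply(perm_d, function(v) sum(v > 0), 0)
  eb <- if (e_b_mode == "median") stats::median(cnt) else mean(cnt)
  r <- sum(d > 0)
  fdr <- min(n0_use * eb / ((1 - lambda) * max(r, 1L) * M), 1)
  p_pos <- eb / M
  structure(list(fdr_hat = fdr, r = r,
                 p_null_hat = min(n0_use / ((1 - lambda) * M), 1),
                 p_pos_null_hat = p_pos, d_lambda = d_lambda,
                 lambda = lambda, e_b_mode = e_b_mode,
                 degenerate = degenerate),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("fdr_estimate: FDR^ = %.4f (r = %d, P^(NULL) = %.3f, lambda = %.2f, E_b = %s)\n",
              x$fdr_hat, x$r, x$p_null_hat, x$lambda, x$e_b_mode))
  invisible(x)
}
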