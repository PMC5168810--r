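#' Search configuration for Discriminant-Cut
#'
#' @param psi target FDR bound in (0, 1); the learned boundary must satisfy
#'   estimated FDR < psi.
#' @param resolution weight-grid step (a unit fraction); NULL selects 0.05
#'   for K <= 3 and 0.1 for larger K at search time.
#' @param lambda null-quantile tuning parameter of the FDR estimator.
#' @param e_b_mode \code{"median"} or \code{"mean"} aggregation over
#'   permutations.
#' @param B number of search-phase permutations.
#' @param B_cal number of calibration-phase permutations (an independent
#'   set used to recalibrate the cutoff of the selected boundary).
#' @param seed integer seed driving both permutation sets (the calibration
#'   set uses a disjoint stream derived from it).
#' @param direction \code{"up"}, \code{"down"} or \code{"both"}.
#' @return object of class \code{"search_config"}.
#' @export
search_config <- function(psi = 0.05, resolution = NULL, lambda = 0.5,
                          e_b_mode = c("median", "mean"), B = 100L,
                          B_cal = 500L, seed = 1L,
                          direction = c("both", "up", "down")) {
  e_b_mode <- match.arg(e_b_mode)
  direction <- match.arg(direction)
  if (psi <= 0 || psi >= 1) stop("psi must be in (0, 1)")
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  if (!is.null(resolution)) check_unit_fraction(resolution)
  if (B <= 0 || B_cal <= 0) stop("B and B_cal must be positive")
  structure(list(psi = psi, resolution = resolution, lambda = lambda,
                 e_b_mode = e_b_mode, B = as.integer(B),
                 B_cal = as.integer(B_cal), seed = as.integer(seed),
                 direction = direction),
            class = "search_config")
}

check_unit_fraction <- function(resolution) {
  if (resolution <= 0 || resolution > 1) stop("resolution must be in (0, 1]")
  m <- round(1 / resolution)
  if (abs(1 / resolution - m) > 1e-8)
    stop("resolution must be a unit fraction (1/integer)")
  as.integer(m)
}

default_resolution <- function(K) if (K <= 3L) 0.05 else 0.1

# row-wise median of a matrix (compiled fast path for tune_tau)
row_medians <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  cpp_row_medians(m)
}

# all non-negative integer K-tuples summing to m, rows in lexicographic order
compositions <- function(m, K) {
  if (K == 1L) return(matrix(m, 1L, 1L))
  do.call(rbind, lapply(0:m, function(a) cbind(a, compositions(m - a, K - 1L))))
}

#' Candidate weight vectors on the L1 simplex grid
#'
#' All length-K vectors whose entries are non-negative multiples of
#' \code{resolution} summing to 1 (up direction), negated for the down
#' direction. The count is \eqn{\binom{1/\delta + K - 1}{K - 1}}.
#'
#' @param K number of attributes.
#' @param resolution grid step (unit fraction).
#' @param direction \code{"up"} or \code{"down"}.
#' @return matrix with one weight vector per row, in lexicographic order.
#' @export
weight_grid <- function(K, resolution, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (K < 1L) stop("K must be >= 1")
  m <- check_unit_fraction(resolution)
  W <- unname(compositions(m, K)) / m
  if (direction == "down") W <- -W
  W
}

#' Tune the cutoff of a fixed weight vector
#'
#' Given the tau = 0 discriminant values of the original data and of each
#' permutation, evaluates every candidate cutoff (the sorted distinct
#' observed values, plus one below the minimum) and returns the cutoff
#' maximizing the number of calls subject to estimated FDR < psi, ties
#' broken toward the larger (more conservative) cutoff. Counts above each
#' candidate are obtained from sorted arrays by binary search, so the
#' estimator is never recomputed from scratch per candidate.
#'
#' @param d0 observed discriminant values at tau = 0 (length M).
#' @param perm_d0 permutation discriminant values at tau = 0: a list of B
#'   vectors or an M x B matrix.
#' @param psi target FDR bound.
#' @param lambda,e_b_mode FDR-estimator settings (see [estimate_fdr()]).
#' @return list with \code{feasible}; when feasible also \code{tau},
#'   \code{r}, \code{fdr} (an \code{fdr_estimate} at the chosen cutoff).
#' @export
tune_tau <- function(d0, perm_d0, psi, lambda = 0.5,
                     e_b_mode = c("median", "mean")) {
  e_b_mode <- match.arg(e_b_mode)
  Q <- if (is.list(perm_d0)) do.call(cbind, perm_d0) else as.matrix(perm_d0)
  M <- length(d0)
  B <- ncol(Q)
  tau_cand <- c(min(d0) - 1, sort(unique(d0)))
  C <- length(tau_cand)
  sp <- sort(d0)
  r <- M - findInterval(tau_cand, sp)
  # pivot count is invariant to tau: both d and d_lambda shift by -tau;
  # partial sort suffices for the single pooled order statistic
  pooled <- as.vector(Q)
  k <- max(1L, ceiling(lambda * length(pooled)))
  d_lambda0 <- sort(pooled, partial = k)[k]
  n0 <- sum(d0 <= d_lambda0)
  n0_use <- max(n0, 1L)
  cnt <- matrix(0, C, B)
  for (b in seq_len(B)) {
    cnt[, b] <- M - findInterval(tau_cand, sort(Q[, b]))
  }
  eb <- if (e_b_mode == "median") row_medians(cnt) else rowMeans(cnt)
  fdr <- pmin(n0_use * eb / ((1 - lambda) * pmax(r, 1L) * M), 1)
  ok <- which(fdr < psi & r > 0L)
  if (length(ok) == 0L) return(list(feasible = FALSE))
  best <- ok[which.max(r[ok])]          # r strictly decreases over candidates
  best <- max(ok[r[ok] == r[best]])     # ties -> larger tau
  tau <- tau_cand[best]
  est <- structure(list(fdr_hat = fdr[best], r = r[best],
                        p_null_hat = min(n0_use / ((1 - lambda) * M), 1),
                        p_pos_null_hat = eb[best] / M,
                        d_lambda = d_lambda0 - tau, lambda = lambda,
                        e_b_mode = e_b_mode, degenerate = n0 == 0L),
                   class = "fdr_estimate")
  list(feasible = TRUE, tau = tau, r = r[best], fdr = est)
}

#' Precompute attributes and permutation nulls for Discriminant-Cut
#'
#' Splitting preparation from fitting lets several boundary searches (e.g.
#' a psi sweep, or single-attribute comparisons via [subset_prepared()])
#' share one expensive attribute/permutation computation.
#'
#' @param data an [expression_dataset()].
#' @param spec attribute spec (see [build_attribute_matrix()]).
#' @param cfg a [search_config()].
#' @return object of class \code{"dc_prepared"} holding the attribute
#'   matrix and the search- and calibration-phase permutation nulls.
#' @export
dc_prepare <- function(data, spec, cfg = search_config()) {
  am <- build_attribute_matrix(data, spec)
  perms_search <- generate_permutations(data$labels, cfg$B, seed = cfg$seed)
  perms_cal <- generate_permutations(data$labels, cfg$B_cal,
                                     seed = cfg$seed + 500009L,
                                     exclude = perms_search$perms)
  null_search <- attributes_on_permutations(data, perms_search, am$settings,
                                            purpose = "search")
  null_cal <- attributes_on_permutations(data, perms_cal, am$settings,
                                         purpose = "calibration")
  structure(list(data = data, attributes = am, null_search = null_search,
                 null_calib = null_cal,
                 effective_B = c(search = perms_search$B_effective,
                                 calibration = perms_cal$B_effective)),
            class = "dc_prepared")
}

#' Restrict a prepared object to a subset of attributes
#'
#' @param prep a [dc_prepare()] result.
#' @param attributes character vector of attribute names to keep.
#' @return a \code{"dc_prepared"} object over the selected columns.
#' @export
subset_prepared <- function(prep, attributes) {
  keep <- match(attributes, prep$attributes$attribute_names)
  if (anyNA(attributes) || anyNA(keep))
    stop("unknown attribute(s): ",
         paste(attributes[is.na(keep)], collapse = ", "))
  sub_am <- prep$attributes
  sub_am$stats <- sub_am$stats[, keep, drop = FALSE]
  sub_am$attribute_names <- attributes
  sub_am$settings <- sub_am$settings[keep]
  sub_null <- function(nl) {
    nl$perm_stats <- lapply(nl$perm_stats, function(m) m[, keep, drop = FALSE])
    nl
  }
  out <- prep
  out$attributes <- sub_am
  out$null_search <- sub_null(prep$null_search)
  out$null_calib <- sub_null(prep$null_calib)
  out
}

# stack a permutation null into an (M*B) x K matrix for fast projection
stack_null <- function(nl) do.call(rbind, nl$perm_stats)

#' Fit one direction of the discriminant boundary
#'
#' Exhaustive search over the weight grid: each candidate weight vector's
#' cutoff is tuned on the search-phase null ([tune_tau()]); the candidate
#' maximizing detections wins (ties broken by smaller search-phase FDR,
#' fewer nonzero weights, then lexicographically smallest weights); its
#' cutoff is then recalibrated on the independent calibration null, and the
#' recalibrated boundary produces the final calls.
#'
#' @param prep a [dc_prepare()] result (or subset).
#' @param cfg a [search_config()].
#' @param direction \code{"up"} or \code{"down"}.
#' @return list with \code{status} (\code{"ok"} or
#'   \code{"no detections at psi"}), \code{model}, \code{d} (recalibrated
#'   discriminant values), \code{calls} (logical), \code{fdr_search},
#'   \code{fdr_calib}, \code{search_table} (per-grid-point audit).
#' @export
fit_direction <- function(prep, cfg, direction = c("up", "down")) {
  direction <- match.arg(direction)
  S <- prep$attributes$stats
  K <- ncol(S)
  resolution <- if (is.null(cfg$resolution)) default_resolution(K) else cfg$resolution
  W <- weight_grid(K, resolution, direction)
  Qs <- stack_null(prep$null_search)
  M <- nrow(S)
  B <- prep$null_search$B
  empty <- list(status = "no detections at psi", model = NULL,
                d = rep(NA_real_, M), calls = rep(FALSE, M),
                fdr_search = NULL, fdr_calib = NULL)
  best <- NULL
  audit <- data.frame(r = integer(nrow(W)), fdr = NA_real_, tau = NA_real_)
  for (g in seq_len(nrow(W))) {
    w <- W[g, ]
    p <- drop(S %*% w)
    q <- matrix(Qs %*% w, M, B)
    tt <- tune_tau(p, q, cfg$psi, cfg$lambda, cfg$e_b_mode)
    if (!tt$feasible) next
    audit$r[g] <- tt$r
    audit$fdr[g] <- tt$fdr$fdr_hat
    audit$tau[g] <- tt$tau
    nz <- sum(w != 0)
    if (is.null(best) ||
        tt$r > best$r ||
        (tt$r == best$r && tt$fdr$fdr_hat < best$fdr$fdr_hat) ||
        (tt$r == best$r && tt$fdr$fdr_hat == best$fdr$fdr_hat && nz < best$nz)) {
      best <- list(w = w, tau = tt$tau, r = tt$r, fdr = tt$fdr, nz = nz)
    }
  }
  audit <- cbind(as.data.frame(W), audit)
  names(audit)[seq_len(K)] <- prep$attributes$attribute_names
  empty$search_table <- audit
  if (is.null(best)) return(empty)
  # recalibrate tau on the independent permutation set, weights fixed
  p <- drop(S %*% best$w)
  Qc <- stack_null(prep$null_calib)
  qc <- matrix(Qc %*% best$w, M, prep$null_calib$B)
  tc <- tune_tau(p, qc, cfg$psi, cfg$lambda, cfg$e_b_mode)
  if (!tc$feasible) {
    empty$fdr_search <- best$fdr
    return(empty)
  }
  model <- discriminant_model(best$w, tc$tau, direction)
  d <- p - tc$tau
  list(status = "ok", model = model, d = d, calls = d > 0,
       fdr_search = best$fdr, fdr_calib = tc$fdr, search_table = audit)
}

#' Detect differentially expressed features with Discriminant-Cut
#'
#' Runs the full pipeline: attribute extraction, permutation nulls, grid
#' search per direction, independent cutoff recalibration, final calls.
#' Up- and down-regulation are treated asymmetrically with separate,
#' sign-constrained discriminant functions; in \code{direction = "both"}
#' mode the union of the two call sets is reported with per-direction
#' models and FDR estimates. A feature falling on the positive side of both
#' boundaries is assigned the direction with the larger discriminant value.
#'
#' @param data an [expression_dataset()].
#' @param spec attribute spec (see [build_attribute_matrix()]), or a
#'   \code{"dc_prepared"} object to reuse precomputed nulls.
#' @param cfg a [search_config()].
#' @return object of class \code{"detection_result"}: list with
#'   \code{calls} (data.frame: feature_id, attribute columns, d_up, d_down,
#'   called), \code{model_up}, \code{model_down}, \code{fdr_estimates},
#'   \code{status}, \code{effective_B}, \code{config}, \code{audit}.
#' @export
detect <- function(data, spec, cfg = search_config()) {
  prep <- if (inherits(spec, "dc_prepared")) spec else dc_prepare(data, spec, cfg)
  M <- nrow(prep$attributes$stats)
  dirs <- if (cfg$direction == "both") c("up", "down") else cfg$direction
  fits <- lapply(dirs, function(dd) fit_direction(prep, cfg, dd))
  names(fits) <- dirs
  d_up <- if ("up" %in% dirs) fits$up$d else rep(NA_real_, M)
  d_down <- if ("down" %in% dirs) fits$down$d else rep(NA_real_, M)
  call_up <- if ("up" %in% dirs) fits$up$calls else rep(FALSE, M)
  call_down <- if ("down" %in% dirs) fits$down$calls else rep(FALSE, M)
  called <- rep("none", M)
  called[call_up] <- "up"
  called[call_down] <- "down"
  both <- call_up & call_down
  if (any(both)) called[both] <- ifelse(d_up[both] >= d_down[both], "up", "down")
  calls <- data.frame(feature_id = prep$data$feature_ids,
                      as.data.frame(prep$attributes$stats),
                      d_up = d_up, d_down = d_down, called = called,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 model_up = if ("up" %in% dirs) fits$up$model else NULL,
                 model_down = if ("down" %in% dirs) fits$down$model else NULL,
                 fdr_estimates = lapply(fits, function(f)
                   list(search = f$fdr_search, calibration = f$fdr_calib)),
                 status = vapply(fits, function(f) f$status, ""),
                 effective_B = prep$effective_B,
                 config = cfg,
                 audit = lapply(fits, function(f) f$search_table)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  tab <- table(factor(x$calls$called, levels = c("up", "down", "none")))
  cat(sprintf("detection_result: %d up, %d down, %d not called (psi = %g)\n",
              tab[["up"]], tab[["down"]], tab[["none"]], x$config$psi))
  for (dd in names(x$fdr_estimates)) {
    est <- x$fdr_estimates[[dd]]$calibration
    if (!is.null(est))
      cat(sprintf("  %s: calibrated FDR^ = %.4f (r = %d)\n", dd, est$fdr_hat, est$r))
    else
      cat(sprintf("  %s: %s\n", dd, x$status[[dd]]))
  }
  invisible(x)
}
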