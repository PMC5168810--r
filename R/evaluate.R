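#' True FDR of a call set against ground truth
#'
#' A call is false when the truth is "none" or the called direction
#' disagrees with the true direction. Returns false calls / max(calls, 1).
#'
#' @param calls data.frame with columns \code{feature_id} and \code{called}
#'   ("up"/"down"/"none"), as in a [detect()] result, or a character vector
#'   of called directions aligned with \code{truth}.
#' @param truth data.frame with \code{feature_id} and \code{truth}
#'   ("up"/"down"/"none"), as in a [simulate_dataset()] result.
#' @return list with \code{true_fdr}, \code{calls}, \code{true_positives},
#'   \code{false_positives}.
#' @export
true_fdr <- function(calls, truth) {
  if (is.data.frame(calls)) {
    idx <- match(calls$feature_id, truth$feature_id)
    if (anyNA(idx)) stop("truth table does not cover all called features")
    called <- calls$called
    tr <- truth$truth[idx]
  } else {
    called <- calls
    tr <- truth$truth
    if (length(called) != length(tr)) stop("calls/truth length mismatch")
  }
  is_call <- called != "none"
  tp <- sum(is_call & called == tr)
  fp <- sum(is_call) - tp
  list(true_fdr = fp / max(sum(is_call), 1L), calls = sum(is_call),
       true_positives = tp, false_positives = fp)
}

#' Sweep the target FDR and tabulate detections
#'
#' Runs one boundary search per target FDR on shared attribute matrices and
#' permutation nulls, reporting calls, true FDR and true positives per
#' target. Reordering the table by calls gives the false discovery curve
#' (true FDR vs number of detections).
#'
#' @param data an [expression_dataset()] or a \code{"dc_prepared"} object.
#' @param spec attribute spec (ignored when \code{data} is prepared).
#' @param cfg a [search_config()]; its \code{psi} is overridden by the grid.
#' @param psi_grid target FDR values (default 0.01..0.10 by 0.01).
#' @param truth optional truth table for true-FDR columns.
#' @return data.frame with one row per target FDR: \code{psi},
#'   \code{calls}, \code{fdr_hat_up}, \code{fdr_hat_down}, and when truth
#'   is supplied \code{true_fdr}, \code{true_positives}.
#' @export
sweep_psi <- function(data, spec = NULL, cfg = search_config(),
                      psi_grid = seq(0.01, 0.10, by = 0.01), truth = NULL) {
  prep <- if (inherits(data, "dc_prepared")) data else dc_prepare(data, spec, cfg)
  rows <- lapply(psi_grid, function(psi) {
    cfg_i <- cfg
    cfg_i$psi <- psi
    res <- detect(prep$data, prep, cfg_i)
    est_up <- res$fdr_estimates$up$calibration
    est_dn <- res$fdr_estimates$down$calibration
    row <- data.frame(psi = psi, calls = sum(res$calls$called != "none"),
                      fdr_hat_up = if (is.null(est_up)) NA_real_ else est_up$fdr_hat,
                      fdr_hat_down = if (is.null(est_dn)) NA_real_ else est_dn$fdr_hat)
    if (!is.null(truth)) {
      ev <- true_fdr(res$calls[, c("feature_id", "called")], truth)
      row$true_fdr <- ev$true_fdr
      row$true_positives <- ev$true_positives
    }
    row
  })
  do.call(rbind, rows)
}

#' Aggregate replicate evaluation reports
#'
#' Means across replicates per configuration, plus paired comparisons of
#' true-positive counts between configurations (replicate-matched mean
#' difference and paired t-statistic).
#'
#' @param reports a named list of configurations, each a list of per-
#'   replicate results as returned by [true_fdr()] (all configurations must
#'   cover the same replicates, in the same order).
#' @return list with \code{means} (data.frame: configuration, mean true
#'   FDR, mean true positives, mean calls, n) and \code{paired}
#'   (data.frame of pairwise mean differences in true positives with
#'   paired t-statistics).
#' @export
aggregate_replicates <- function(reports) {
  if (length(reports) < 1L) stop("no reports")
  nrep <- vapply(reports, length, 0L)
  if (length(unique(nrep)) != 1L || nrep[1L] < 2L)
    stop("all configurations need the same number (>= 2) of replicates")
  get <- function(cfg, field) vapply(reports[[cfg]], function(r) r[[field]], 0)
  cfgs <- names(reports)
  means <- data.frame(
    configuration = cfgs,
    mean_true_fdr = vapply(cfgs, function(cc) mean(get(cc, "true_fdr")), 0),
    mean_true_positives = vapply(cfgs, function(cc) mean(get(cc, "true_positives")), 0),
    mean_calls = vapply(cfgs, function(cc) mean(get(cc, "calls")), 0),
    n = nrep[1L], row.names = NULL, stringsAsFactors = FALSE)
  paired <- NULL
  if (length(cfgs) >= 2L) {
    combs <- utils::combn(cfgs, 2L)
    paired <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- get(combs[1L, j], "true_positives")
      b <- get(combs[2L, j], "true_positives")
      dif <- a - b
      tstat <- if (stats::sd(dif) == 0) {
        if (mean(dif) == 0) 0 else Inf * sign(mean(dif))
      } else mean(dif) / (stats::sd(dif) / sqrt(length(dif)))
      data.frame(config_a = combs[1L, j], config_b = combs[2L, j],
                 mean_diff = mean(dif), paired_t = tstat,
                 stringsAsFactors = FALSE)
    }))
  }
  list(means = means, paired = paired)
}
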