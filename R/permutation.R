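#' Generate group-size-preserving label permutations
#'
#' Produces B permuted condition-label vectors, each with the same group
#' sizes as the original and none equal to the original assignment. When the
#' number of distinct non-identity assignments is at most B, all of them are
#' returned (exhaustive mode) and the effective B is reported. The
#' complementary assignment (group swap) counts as a distinct vector.
#'
#' @param labels two-level factor (or vector) of length N.
#' @param B requested number of permutations (positive).
#' @param seed integer RNG seed; identical inputs give identical output.
#' @param exclude optional list of label vectors (e.g. a search-phase
#'   permutation set) that the new set must not overlap with; honoured only
#'   when enough distinct assignments remain.
#' @return object of class \code{"label_permutations"}: list with
#'   \code{perms} (list of factors), \code{B_effective}, \code{exhaustive},
#'   \code{seed}.
#' @export
generate_permutations <- function(labels, B, seed = 1L, exclude = NULL) {
  if (B <= 0) stop("B must be positive")
  labels <- as.factor(labels)
  N <- length(labels)
  n2 <- sum(group2_mask(labels))
  if (n2 == 0L || n2 == N) stop("both groups must be non-empty")
  total <- choose(N, n2)
  if (total - 1 < 2) stop("too few distinct label assignments for a permutation null")
  key <- function(lab) paste(as.integer(lab), collapse = "")
  id_key <- key(labels)
  excl_keys <- if (is.null(exclude)) character(0) else vapply(exclude, key, "")
  lev <- levels(labels)
  make_lab <- function(g2idx) {
    v <- rep(lev[1L], N)
    v[g2idx] <- lev[2L]
    factor(v, levels = lev)
  }
  exhaustive <- (total - 1) <= B
  if (exhaustive) {
    combs <- utils::combn(N, n2)
    perms <- lapply(seq_len(ncol(combs)), function(j) make_lab(combs[, j]))
    keys <- vapply(perms, key, "")
    perms <- perms[keys != id_key]
    B_eff <- length(perms)
  } else {
    perms <- vector("list", B)
    seen <- c(id_key, excl_keys)
    withr::with_seed(seed, {
      got <- 0L
      tries <- 0L
      while (got < B) {
        tries <- tries + 1L
        if (tries > 1000L * B) {
          # not enough assignments remain outside the excluded set
          seen <- id_key
          tries <- 0L
        }
        cand <- sort(sample.int(N, n2))
        lab <- make_lab(cand)
        k <- key(lab)
        if (k %in% seen) next
        got <- got + 1L
        perms[[got]] <- lab
        seen <- c(seen, k)
      }
    })
    B_eff <- B
  }
  structure(list(perms = perms, B_effective = B_eff,
                 exhaustive = exhaustive, seed = seed),
            class = "label_permutations")
}

#' @export
print.label_permutations <- function(x, ...) {
  cat(sprintf("label_permutations: B = %d%s\n", x$B_effective,
              if (x$exhaustive) " (exhaustive)" else ""))
  invisible(x)
}

#' Recompute attribute matrices on permuted labels
#'
#' For every permuted label vector the full attribute pipeline is re-run —
#' including re-estimation of data-dependent constants (SAM s0, variance
#' prior, mean-variance weights, NB dispersions) under the permuted labels.
#' Permutation statistics are never obtained by shuffling the original
#' statistic vector.
#'
#' @param data an [expression_dataset()].
#' @param perms a [generate_permutations()] result (or list of label
#'   vectors).
#' @param spec attribute spec, identical to the one used on the original
#'   labels (see [build_attribute_matrix()]).
#' @param purpose \code{"search"} or \code{"calibration"} (bookkeeping).
#' @return object of class \code{"permutation_null"}: list with
#'   \code{perm_stats} (list of M x K matrices), \code{permuted_labels},
#'   \code{B}, \code{purpose}, \code{spec}.
#' @export
attributes_on_permutations <- function(data, perms, spec, purpose = "search") {
  labs <- if (inherits(perms, "label_permutations")) perms$perms else perms
  perm_stats <- lapply(labs, function(lab) {
    pd <- data
    pd$labels <- factor(lab, levels = levels(data$labels))
    suppressWarnings(build_attribute_matrix(pd, spec)$stats)
  })
  structure(list(perm_stats = perm_stats, permuted_labels = labs,
                 B = length(labs), purpose = purpose, spec = spec),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null (%s): B = %d, %d x %d per permutation\n",
              x$purpose, x$B, nrow(x$perm_stats[[1L]]), ncol(x$perm_stats[[1L]])))
  invisible(x)
}
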