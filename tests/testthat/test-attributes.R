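test_that("SAM corrected t: degenerate and reduction cases", {
  # identical groups -> numerator exactly zero
  x <- matrix(rep(c(5, 7, 9), 4), 3, 4)
  d <- expression_dataset(x, labels = c("A", "A", "B", "B"))
  expect_equal(as.numeric(compute_sam_t(d, s0_mode = "fixed", s0 = 1)), c(0, 0, 0))

  # s0 = 0 reduces to the ordinary pooled-variance t
  dd <- rand_dataset(30, 4, 4, seed = 2)
  got <- compute_sam_t(dd, s0_mode = "fixed", s0 = 0)
  want <- apply(dd$values, 1, function(v) {
    tt <- t.test(v[5:8], v[1:4], var.equal = TRUE)
    unname(tt$statistic)
  })
  expect_equal(as.numeric(got), unname(want), tolerance = 1e-10)
})

test_that("SAM corrected t matches a per-feature reference computation", {
  dd <- rand_dataset(50, 3, 3, seed = 11)
  got <- compute_sam_t(dd)  # default: s0 = median of standard errors
  # one-feature-at-a-time oracle
  se <- apply(dd$values, 1, function(v) {
    sp2 <- ((2) * var(v[1:3]) + (2) * var(v[4:6])) / 4
    sqrt(sp2 * (1 / 3 + 1 / 3))
  })
  s0 <- median(se)
  want <- apply(dd$values, 1, function(v) mean(v[4:6]) - mean(v[1:3])) / (se + s0)
  expect_equal(unname(as.numeric(got)), unname(want), tolerance = 1e-10)
  expect_equal(attr(got, "s0"), s0)
})

test_that("centered rank-sum statistic: exact values and symmetry", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  d <- expression_dataset(x, "f1", paste0("s", 1:6), rep(c("A", "B"), each = 3))
  # W = 4+5+6 = 15, E0 = 3*7/2 = 10.5
  expect_equal(unname(compute_sam_ranksum(d)), 4.5)

  # all values equal -> mid-ranks force W = E0
  xe <- matrix(3, 2, 6)
  de <- expression_dataset(xe, labels = rep(c("A", "B"), each = 3))
  expect_equal(unname(compute_sam_ranksum(de)), c(0, 0))

  # swapping labels flips the sign for balanced groups
  dd <- rand_dataset(40, 4, 4, seed = 3)
  expect_equal(compute_sam_ranksum(swap_labels(dd)), -compute_sam_ranksum(dd))
})

test_that("rank-sum ties receive mid-ranks", {
  x <- matrix(c(1, 1, 2, 2, 2, 3), 1, 6)
  d <- expression_dataset(x, "f1", paste0("s", 1:6), rep(c("A", "B"), each = 3))
  # mid-ranks: 1.5 1.5 4 4 4 6; W = 4+4+6 = 14; E0 = 10.5
  expect_equal(unname(compute_sam_ranksum(d)), 3.5)
})

test_that("moderated t reduces correctly at the d0 extremes", {
  dd <- rand_dataset(40, 4, 4, seed = 5)
  # d0 = 0: ordinary t
  got0 <- compute_moderated_t(dd, d0 = 0, s02 = 1)
  want <- apply(dd$values, 1, function(v)
    unname(t.test(v[5:8], v[1:4], var.equal = TRUE)$statistic))
  expect_equal(as.numeric(got0), unname(want), tolerance = 1e-10)

  # huge d0: every denominator uses the common prior variance
  gotI <- compute_moderated_t(dd, d0 = 1e12, s02 = 2)
  m1 <- rowMeans(dd$values[, 1:4]); m2 <- rowMeans(dd$values[, 5:8])
  expect_equal(unname(as.numeric(gotI)), unname((m2 - m1) / sqrt(2 * (1 / 4 + 1 / 4))),
               tolerance = 1e-6)
})

test_that("moderated-t hyperparameters recover a known variance prior", {
  # features with variances from a scaled inverse-chi-square with known
  # (d0, s02); the moment-matching estimates must land within 15%
  M <- 2000; n <- 8; d0 <- 4; s02 <- 2
  dd <- withr::with_seed(77, {
    sigma2 <- d0 * s02 / rchisq(M, d0)
    x <- matrix(rnorm(M * n, sd = sqrt(rep(sigma2, n))), M, n)
    expression_dataset(x, labels = rep(c("A", "B"), each = 4))
  })
  st <- compute_moderated_t(dd)
  expect_lt(abs(attr(st, "d0") - d0) / d0, 0.15)
  expect_lt(abs(attr(st, "s02") - s02) / s02, 0.15)
})

test_that("moderated t needs enough informative features", {
  d <- expression_dataset(matrix(5, 2, 4), labels = c("A", "A", "B", "B"))
  expect_error(compute_moderated_t(d), "positive variance")
})

test_that("log-CPM transform and unit-weight equivalence", {
  # count 0 in a library of ~1e6 reads maps near -1 on the log2-CPM scale
  dd <- withr::with_seed(8, {
    x <- matrix(rpois(200 * 4, 50), 200, 4)
    x <- rbind(x, c(0, 0, 0, 0))
    sums <- colSums(x)
    x[1, ] <- x[1, ] + (1e6 - sums)  # force libraries to exactly 1e6
    expression_dataset(x, labels = c("A", "A", "B", "B"))
  })
  logcpm <- log2(sweep(dd$values + 0.5, 2, colSums(dd$values) + 1, "/") * 1e6)
  expect_equal(logcpm[201, 1], log2(0.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)
  expect_equal(unname(logcpm[201, 1]), -1, tolerance = 1e-3)

  # unit weights: voom-style statistic == moderated t on log-CPM exactly
  ldat <- expression_dataset(logcpm, dd$feature_ids, dd$sample_ids, dd$labels)
  expect_equal(as.numeric(compute_voom_t(dd, use_weights = FALSE)),
               as.numeric(compute_moderated_t(ldat)))

  # fewer than 50 features: falls back to unit weights with a warning
  small <- expression_dataset(dd$values[1:20, ], labels = dd$labels)
  lcs <- log2(sweep(small$values + 0.5, 2, colSums(small$values) + 1, "/") * 1e6)
  lsmall <- expression_dataset(lcs, labels = dd$labels)
  expect_warning(st <- compute_voom_t(small), "unit weights")
  expect_equal(as.numeric(st), as.numeric(compute_moderated_t(lsmall)))
})

test_that("mean-variance trend matches an independently coded lowess", {
  dd <- withr::with_seed(9, {
    mu <- 10^runif(300, 1, 3.5)
    x <- matrix(rnbinom(300 * 8, mu = rep(mu, 8), size = 5), 300, 8)
    expression_dataset(x, labels = rep(c("A", "B"), each = 4))
  })
  st <- compute_voom_t(dd)
  trend <- attr(st, "trend")
  # oracle: recompute the knots from the stated definition
  lib <- colSums(dd$values)
  logcpm <- log2(sweep(dd$values + 0.5, 2, lib + 1, "/") * 1e6)
  m1 <- rowMeans(logcpm[, 1:4]); m2 <- rowMeans(logcpm[, 5:8])
  fitted <- cbind(m1, m1, m1, m1, m2, m2, m2, m2)
  s <- sqrt(rowSums((logcpm - fitted)^2) / 6)
  lo <- lowess(rowMeans(logcpm), sqrt(s), f = 0.5)
  expect_equal(trend$x, lo$x)
  expect_equal(trend$y, lo$y, tolerance = 1e-12)
})

test_that("size factors: equivariance and brute-force agreement", {
  # identical samples -> all factors 1
  x <- matrix(rep(c(10, 20, 30), 4), 3, 4)
  expect_equal(size_factors(x), rep(1, 4))

  # doubling one sample doubles its factor relative to the others
  x2 <- x; x2[, 2] <- 2 * x2[, 2]
  sf <- size_factors(x2)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)

  # random Poisson matrix vs direct implementation
  cm <- withr::with_seed(4, matrix(rpois(100 * 6, 80), 100, 6))
  got <- size_factors(cm)
  pos <- apply(cm, 1, function(v) all(v > 0))
  loggeo <- rowMeans(log(cm[pos, ]))
  raw <- apply(cm[pos, ], 2, function(col) exp(median(log(col) - loggeo)))
  expect_equal(got, unname(raw / exp(mean(log(raw)))))
})

test_that("NB Wald statistic: symmetry, Poisson limit, likelihood oracle", {
  # identical counts in both groups -> coefficient and statistic exactly 0
  x <- matrix(rep(c(10, 25, 40), 4), 3, 4)
  d <- expression_dataset(x, labels = c("A", "A", "B", "B"))
  expect_equal(unname(as.numeric(compute_nb_wald(d, size_factors = rep(1, 4)))),
               c(0, 0, 0))

  # dispersion fixed at 0 -> Poisson GLM Wald statistic
  dd <- rand_count_dataset(20, 4, 4, mu = 60, disp = 0.05, seed = 21)
  st <- compute_nb_wald(dd, size_factors = rep(1, 8), dispersion = 0)
  grp <- rep(0:1, each = 4)
  want <- apply(dd$values, 1, function(v)
    summary(glm(v ~ grp, family = poisson()))$coefficients[2, 3])
  expect_equal(unname(as.numeric(st)), unname(want), tolerance = 1e-6)

  # single gene: coefficient and SE against brute-force ML maximisation
  y <- withr::with_seed(31, c(rnbinom(6, mu = 100, size = 10),
                              rnbinom(6, mu = 200, size = 10)))
  dg <- expression_dataset(matrix(rep(y, 10), 10, 12, byrow = TRUE),
                           labels = rep(c("A", "B"), each = 6))
  st <- compute_nb_wald(dg, size_factors = rep(1, 12), shrink = FALSE)
  nll <- function(p) {
    mu <- exp(p[1] + p[2] * rep(0:1, each = 6))
    -sum(dnbinom(y, mu = mu, size = exp(-p[3]), log = TRUE))
  }
  opt <- optim(c(log(100), log(2), log(0.1)), nll, method = "BFGS", hessian = TRUE)
  expect_equal(unname(attr(st, "beta")[1]), opt$par[2], tolerance = 1e-4)
  se_oracle <- sqrt(solve(opt$hessian)[2, 2])
  expect_equal(unname(attr(st, "se")[1]), se_oracle, tolerance = 1e-3)

  # all-zero feature: statistic 0 and flagged
  xz <- rbind(dd$values[1:3, ], 0)
  dz <- expression_dataset(xz, labels = rep(c("A", "B"), each = 4))
  stz <- compute_nb_wald(dz, size_factors = rep(1, 8))
  expect_equal(unname(stz[4]), 0)
  expect_equal(unname(attr(stz, "all_zero")), 4L)
})

test_that("dispersion ML agrees with an independent NB fit", {
  skip_if_not_installed("MASS")
  dd <- rand_count_dataset(30, 6, 6, mu = 150, disp = 0.15, seed = 41)
  st <- compute_nb_wald(dd, size_factors = rep(1, 12), shrink = FALSE)
  grp <- rep(0:1, each = 6)
  theta <- apply(dd$values, 1, function(v)
    suppressWarnings(MASS::glm.nb(v ~ grp))$theta)
  expect_equal(unname(attr(st, "dispersion")), unname(1 / theta),
               tolerance = 0.02)
})

test_that("count-only statistics refuse continuous input", {
  dd <- rand_dataset(60, 3, 3, seed = 6)
  dd$values <- abs(dd$values)
  expect_error(compute_voom_t(dd), "integer")
  expect_error(compute_nb_wald(dd), "integer")
})

test_that("all extractors are antisymmetric under group exchange", {
  dd <- rand_count_dataset(80, 5, 5, mu = 120, disp = 0.1, seed = 51)
  sw <- swap_labels(dd)
  for (fn in list(function(d) compute_sam_t(d),
                  compute_sam_ranksum,
                  function(d) compute_moderated_t(d),
                  function(d) suppressWarnings(compute_voom_t(d)),
                  function(d) compute_nb_wald(d))) {
    a <- as.numeric(fn(dd))
    b <- as.numeric(fn(sw))
    expect_equal(b, -a, tolerance = 1e-8)
  }
})

test_that("statistics are symmetric about zero under the null", {
  dd <- rand_dataset(5000, 4, 4, seed = 61)
  for (st in list(compute_sam_t(dd), compute_moderated_t(dd))) {
    nz <- st[st != 0]
    p <- binom.test(sum(nz > 0), length(nz))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("build_attribute_matrix assembles columns in spec order", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  d <- expression_dataset(x, "f1", paste0("s", 1:6), rep(c("A", "B"), each = 3))
  am <- build_attribute_matrix(d, "sam_ranksum")
  expect_equal(unname(am$stats), matrix(4.5, 1, 1))

  dd <- rand_dataset(30, 3, 3, seed = 71)
  expect_warning(am2 <- build_attribute_matrix(dd, c("sam_t", "sam_t")),
                 "duplicate")
  expect_equal(am2$stats[, 1], am2$stats[, 2])
  expect_error(build_attribute_matrix(dd, character(0)), "empty")
  expect_error(build_attribute_matrix(dd, "bogus"), "bogus")
})
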