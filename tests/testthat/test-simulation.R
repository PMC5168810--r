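test_that("low-count filter applies the strict more-than-half rule", {
  # low in exactly half the samples -> retained
  x <- rbind(c(1, 2, 50, 60), c(50, 60, 70, 80), c(0, 0, 0, 0),
             c(1, 2, 3, 60))
  keep <- filter_low_counts(x, threshold = 10)
  expect_true(1 %in% keep)   # 2 of 4 low: kept
  expect_true(2 %in% keep)
  expect_false(3 %in% keep)  # all-zero: removed
  expect_false(4 %in% keep)  # 3 of 4 low: removed

  cm <- withr::with_seed(2, matrix(rpois(200 * 6, 12), 200, 6))
  want <- which(sapply(1:200, function(i) sum(cm[i, ] < 10) <= 3))
  expect_equal(filter_low_counts(cm, 10), want)
})

test_that("NB fitting recovers parameters and clamps underdispersion", {
  f <- withr::with_seed(3, fit_nb(rpois(500, 50)))
  expect_lt(f$dispersion, 0.01)

  fc <- fit_nb(rep(7, 10))
  expect_equal(fc$mean, 7)
  expect_equal(fc$dispersion, 0)
  expect_true(fc$clamped)

  f2 <- withr::with_seed(4, fit_nb(rnbinom(1000, mu = 100, size = 5)))
  expect_lt(abs(f2$dispersion - 0.2) / 0.2, 0.25)
})

test_that("GMM fitting selects component counts by BIC", {
  x1 <- withr::with_seed(5, rnorm(500, 100, 10))
  g1 <- fit_gmm(x1)
  expect_equal(g1$k, 1L)

  x2 <- withr::with_seed(6, c(rnorm(250, 50, 5), rnorm(250, 150, 10)))
  g2 <- fit_gmm(x2)
  expect_equal(g2$k, 2L)
  expect_equal(sum(g2$weights), 1, tolerance = 1e-8)

  gc <- fit_gmm(rep(4, 10))
  expect_equal(gc$k, 1L)
  expect_gt(gc$sds, 0)
})

test_that("histogram correlation agrees with a from-scratch binning oracle", {
  # density mass proportional to histogram counts -> exactly 1
  x <- c(rep(1, 10), rep(2, 20), rep(3, 30), rep(4, 40))
  # piecewise cdf putting mass 0.1/0.2/0.3/0.4 into the 4 spanned quarters
  # of [1,4]; with bins = 4 the per-bin masses mirror the counts
  cdf <- approxfun(c(1 - 1e-9, 1.75, 2.5, 3.25, 4), c(0, 0.1, 0.3, 0.6, 1),
                   yleft = 0, yright = 1)
  expect_equal(histogram_correlation(x, cdf, bins = 4), 1)

  # constant fitted mass -> undefined, read as no preference
  flat_cdf <- function(q) punif(q, 0, 10)
  xx <- c(rep(1, 5), rep(9, 1), 2, 2, 2, 5)
  expect_true(is.na(histogram_correlation(xx, flat_cdf, bins = 2)))

  # random data vs independently coded binning
  withr::with_seed(7, {
    for (i in 1:5) {
      y <- rnbinom(200, mu = 80, size = 3)
      cdf_nb <- function(q) pnbinom(q, mu = 80, size = 3)
      got <- histogram_correlation(y, cdf_nb, bins = 20)
      br <- seq(min(y), max(y), length.out = 21)
      idx <- pmin(pmax(findInterval(y, br, rightmost.closed = TRUE,
                                    left.open = TRUE), 1L), 20L)
      obs <- tabulate(idx, 20) / length(y)
      lo <- br[-21]; hi <- br[-1]; lo[1] <- lo[1] - 1e-9
      mass <- cdf_nb(hi) - cdf_nb(lo)
      expect_equal(got, cor(obs, mass), tolerance = 1e-12)
    }
  })
})

test_that("family choice tracks the generating distribution", {
  # large NB samples: NB preferred in a majority of seeds
  picks <- vapply(1:7, function(s) {
    x <- withr::with_seed(400 + s, rnbinom(300, mu = 200, size = 2))
    choose_family(x)$family
  }, "")
  expect_gt(mean(picks == "NB"), 0.5)

  # strongly bimodal: GMM wins
  xb <- withr::with_seed(8, round(c(rnorm(150, 50, 5), rnorm(150, 400, 20))))
  expect_equal(choose_family(xb)$family, "GMM")

  # degenerate constant vector: forced NB with flag
  cf <- choose_family(rep(5L, 10))
  expect_equal(cf$family, "NB")
  expect_true(cf$forced)
})

test_that("sigma_N estimation: degenerate, deterministic, scale-stable", {
  ref <- matrix(rep(c(100, 200, 300), 10), 3, 10)
  expect_equal(estimate_sigma_N(ref, 6, n_draws = 50, seed = 1), 0)

  cm <- withr::with_seed(9, matrix(rnbinom(300 * 20, mu = 500, size = 5), 300, 20))
  s1 <- estimate_sigma_N(cm, 8, n_draws = 100, seed = 2)
  s2 <- estimate_sigma_N(cm, 8, n_draws = 100, seed = 2)
  expect_identical(s1, s2)
  s_scaled <- estimate_sigma_N(2 * cm, 8, n_draws = 100, seed = 2)
  expect_equal(s_scaled, s1, tolerance = 0.02)
  expect_error(estimate_sigma_N(cm, 30, seed = 1), "exceeds")
})

test_that("null genes respect the fold-change guard; GMM draws stay non-negative", {
  fit <- list(family = "GMM",
              gmm = list(weights = c(0.5, 0.5), means = c(-20, 50),
                         sds = c(10, 10), k = 2L))
  y <- withr::with_seed(10, simulate_null_gene(fit, 12, sigma_N = Inf))
  expect_true(all(y >= 0))
  expect_equal(y, round(y))

  # an impossible guard errors after max_tries
  fit2 <- list(family = "NB", nb = list(mean = 100, dispersion = 0.5))
  expect_error(withr::with_seed(11,
    simulate_null_gene(fit2, 6, sigma_N = 1e-9, max_tries = 5, gene_id = "g9")),
    "g9")
})

test_that("signal injection uses the documented factor range and groups", {
  g2 <- rep(c(FALSE, TRUE), each = 6)
  base <- rep(100L, 12)
  withr::with_seed(12, {
    for (i in 1:50) {
      inj <- inject_def(base, "up", g2)
      expect_gte(inj$factor, 1.5)
      expect_lte(inj$factor, 3.0)
      if (inj$scaled_group == 2L) {
        expect_equal(inj$pre_round[g2], base[g2] * inj$factor)
        expect_equal(inj$pre_round[!g2], as.numeric(base[!g2]))
      } else {
        expect_equal(inj$pre_round[!g2], base[!g2] / inj$factor)
      }
      expect_equal(inj$counts, round(inj$pre_round))
    }
    # dividing zeros leaves zeros
    injz <- inject_def(rep(0L, 12), "down", g2)
    expect_equal(injz$counts, rep(0, 12))
  })
})

test_that("simulated datasets honour configuration and determinism", {
  lib <- synthetic_reference(300, seed = 20)
  s0 <- simulate_dataset(lib, N = 8, n_up = 0, n_down = 0, seed = 21)
  expect_true(all(s0$truth$truth == "none"))
  expect_true(all(s0$data$values >= 0))
  expect_true(all(s0$data$values == round(s0$data$values)))

  s1 <- simulate_dataset(lib, N = 8, n_up = 50, n_down = 30, seed = 22)
  expect_equal(sum(s1$truth$truth == "up"), 50)
  expect_equal(sum(s1$truth$truth == "down"), 30)

  s1b <- simulate_dataset(lib, N = 8, n_up = 50, n_down = 30, seed = 22)
  expect_identical(s1$data$values, s1b$data$values)
  expect_identical(s1$truth, s1b$truth)

  # truth-null genes satisfy the generation-time fold-change bound
  nulls <- which(s1$truth$truth == "none")
  g2 <- s1$data$labels == "B"
  lfc <- log2((rowMeans(s1$data$values[nulls, g2]) + 0.5) /
                (rowMeans(s1$data$values[nulls, !g2]) + 0.5))
  expect_true(all(abs(lfc) <= 4.5 * s1$sigma_N + 1e-12))
})

test_that("synthetic library matches its target mixture proportions", {
  lib <- synthetic_reference(10000, seed = 30)
  fam <- vapply(lib$genes, function(g) g$family, "")
  expect_lt(abs(mean(fam == "GMM") - 0.635), 0.03)
  ks <- vapply(lib$genes[fam == "GMM"], function(g) g$gmm$k, 0L)
  expect_lt(abs(mean(ks == 1) - 0.44), 0.03)
  expect_lt(abs(mean(ks == 2) - 0.50), 0.03)
  expect_lt(abs(mean(ks == 3) - 0.06), 0.03)

  lib2 <- synthetic_reference(10000, seed = 30)
  expect_identical(lib$genes[[17]], lib2$genes[[17]])

  ref <- simulate_reference_matrix(synthetic_reference(150, seed = 31),
                                   n_samples = 10, seed = 32)
  expect_true(all(ref >= 0))
  expect_true(all(ref == round(ref)))
})

test_that("a fitted reference library can drive the simulator", {
  cm <- withr::with_seed(40, matrix(rnbinom(120 * 30, mu = 300, size = 2), 120, 30))
  lib <- fit_gene_library(cm, threshold = 10)
  expect_s3_class(lib, "gene_library")
  expect_gt(lib$M, 50)
  sim <- simulate_dataset(lib, N = 8, n_up = 5, n_down = 5, seed = 41,
                          sigma_N = 1)
  expect_equal(dim(sim$data$values), c(lib$M, 8))
})
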