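test_that("bin-width rules reproduce their defining formulas", {
  x <- rnorm(100)
  expect_equal(bin_width(x, "sturges")$n_bins, 8L)  # ceiling(log2(100)) + 1

  set.seed(1)
  y <- rnorm(1000)
  y <- y / sd(y)  # unit standard deviation
  expect_equal(bin_width(y, "scott")$width, 3.49 * 1000^(-1 / 3),
               tolerance = 1e-12)
  z <- y / IQR(y)  # unit interquartile range
  expect_equal(bin_width(z, "fd")$width, 2 * 1000^(-1 / 3), tolerance = 1e-12)

  expect_error(bin_width(rep(1, 50), "scott"), "zero range")
  expect_error(bin_width(c(rep(0, 48), 1, 2), "fd"), "zero IQR")
})

test_that("grids are per-dimension, deterministic, and cover the range", {
  set.seed(2)
  xy <- cbind(rnorm(500), 10 * rnorm(500))
  g <- build_grid(xy, "scott")
  expect_gt(g$widths[2] / g$widths[1], 5)  # widths estimated independently
  expect_identical(g, build_grid(xy, "scott"))
  for (j in 1:2) {
    expect_lte(g$edges[[j]][1], min(xy[, j]))
    expect_gte(g$edges[[j]][length(g$edges[[j]])], max(xy[, j]))
  }
  expect_error(build_grid(matrix(rep(2, 10)), "scott"), "zero range")
})

test_that("hist_density counts into sparse bins with the c/(n*width) density", {
  g <- structure(list(edges = list(c(0, 2, 4)), widths = 2, n_bins = 2L,
                      rule = "scott", dim = 1L), class = "bin_grid")
  hd <- hist_density(matrix(c(0.5, 1.5, 2.5, 3.5)), g)
  expect_equal(hd$counts, c(2, 2))
  expect_equal(hist_density_at(hd, matrix(c(0.1, 3.9))), c(0.25, 0.25))
  expect_equal(sum(hd$counts) / hd$n, 1)
  expect_equal(hist_density_at(hd, matrix(5)), 0)  # outside the grid

  # all mass in one bin: entropy of the histogram is log(width)
  g1 <- structure(list(edges = list(c(0, 4)), widths = 4, n_bins = 1L,
                       rule = "scott", dim = 1L), class = "bin_grid")
  hd1 <- hist_density(matrix(c(1, 2, 3)), g1)
  p <- hd1$counts / hd1$n
  expect_equal(-sum(p * log(p)) + log(4), log(4))

  set.seed(3)
  big <- matrix(rnorm(2000), ncol = 2)
  hdb <- hist_density(big, build_grid(big, "fd"))
  expect_lte(length(hdb$codes), min(nrow(big), prod(hdb$grid$n_bins)))
})

test_that("bin_entropy equals a first-principles per-point recomputation", {
  set.seed(4)
  samples <- list(runif(40), rnorm(211), rexp(500), rt(123, df = 3))
  for (x in samples) {
    for (rule in c("sturges", "scott", "fd")) {
      expect_equal(bin_entropy(matrix(x), rule), brute_bin_entropy_1d(x, rule),
                   tolerance = 1e-12,
                   label = sprintf("oracle parity (%s, n=%d)", rule, length(x)))
    }
  }
})

test_that("bin_entropy converges to the uniform closed form and scales covariantly", {
  est <- vapply(1:3, function(s)
    bin_entropy(draw_sample(dist_uniform(0.5, 2), 100000, seed = s), "scott"),
    numeric(1))
  expect_lt(abs(mean(est) - log(1.5)) / abs(log(1.5)), 0.01)

  set.seed(5)
  xy <- matrix(rnorm(600), ncol = 2)
  s <- 4.2
  for (rule in c("sturges", "scott", "fd"))
    expect_equal(bin_entropy(s * xy, rule),
                 bin_entropy(xy, rule) + 2 * log(s), tolerance = 1e-8)
})

test_that("bin_kl is zero on itself, accurate on uniforms, and handles empty q-bins", {
  x <- draw_sample(dist_normal(), 500, seed = 6)
  self <- bin_kl(x, x, "scott")
  expect_equal(as.numeric(self), 0)
  expect_equal(attr(self, "n_excluded"), 0L)

  cs <- builtin_cases()
  kl <- bin_kl(draw_sample(cs[[1]]$p, 10000, seed = 7),
               draw_sample(cs[[1]]$q, 10000, seed = 8), "scott")
  expect_lt(abs(as.numeric(kl) - log(4 / 3)), 0.05)

  # disjoint occupied bins: every p point excluded -> error
  expect_error(bin_kl(matrix(seq(0, 1, length.out = 20)),
                      matrix(seq(100, 101, length.out = 20)), "scott"),
               "support mismatch")

  # strict mode surfaces the divergence instead of excluding
  xp <- matrix(c(seq(0, 1, length.out = 30), 50))
  xq <- matrix(seq(0, 1.05, length.out = 40))
  lenient <- bin_kl(xp, xq, "sturges", empty_q = "exclude")
  expect_true(is.finite(as.numeric(lenient)))
  expect_gt(attr(lenient, "n_excluded"), 0L)
  expect_identical(as.numeric(bin_kl(xp, xq, "sturges",
                                     empty_q = "infinity")), Inf)
})

test_that("bin_mi is a non-negative discrete MI and matches hand values", {
  xy <- cbind(c(0.1, 0.2, 0.8, 0.9), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(bin_mi(xy, 1, "sturges"), log(2), tolerance = 1e-12)

  ind <- cbind(draw_sample(dist_uniform(0, 1), 10000, seed = 9),
               draw_sample(dist_uniform(0, 1), 10000, seed = 10))
  expect_lt(bin_mi(ind, 1, "sturges"), 0.02)

  set.seed(11)
  for (i in 1:10) {
    z <- matrix(rnorm(2 * sample(20:80, 1)), ncol = 2)
    expect_gte(bin_mi(z, 1, sample(c("sturges", "scott", "fd"), 1)), -1e-12)
  }

  mi_ref <- -0.5 * log(1 - 0.25)
  xy4 <- draw_sample(builtin_cases()[[4]]$p, 100000, seed = 12)
  expect_lt(abs(bin_mi(xy4, 1, "sturges") - mi_ref), 0.05)
})

test_that("quantile partitions average sorted subsamples with fixed endpoints", {
  set.seed(13)
  x <- runif(50)
  # a single repetition of size NZ-1 is just that sorted subsample
  qp <- qs_quantiles(x, NZ = 11, Nk = 1, seed = 3)
  sub <- infoest:::with_seed(3, sort(x[sample.int(50, 10)]))
  expect_equal(qp$Z, c(min(x), sub, max(x)))
  expect_identical(qs_quantiles(x, 11, 5, seed = 4),
                   qs_quantiles(x, 11, 5, seed = 4))
  expect_error(qs_quantiles(x, NZ = 60, Nk = 1, seed = 1), "exceeds")

  # interior quantiles of a large uniform sample are nearly equally spaced
  xu <- draw_sample(dist_uniform(0, 1), 10000, seed = 14)
  qp2 <- qs_quantiles(as.numeric(xu), NZ = 2500, Nk = 500, seed = 15)
  j <- seq_len(2499)
  expect_lt(max(abs(qp2$Z[j + 1] - j / 2500)), 0.02)
})

test_that("QS entropy follows its closed form and slightly underestimates", {
  # equal spacings of width 1/NZ give exactly zero
  qp <- structure(list(Z = seq(0, 1, length.out = 101), NZ = 100L, Nk = 1L),
                  class = "quantile_partition")
  expect_equal(qs_entropy(runif(10), partition = qp), 0, tolerance = 1e-12)

  x <- draw_sample(dist_uniform(0, 1), 10000, seed = 16)
  h <- qs_entropy(x, seed = 17)
  expect_lt(abs(h - 0), 0.03)

  # scaling the sample by s adds log(s); pipeline equals the closed form
  s <- 5
  expect_equal(qs_entropy(s * as.numeric(x), seed = 17),
               qs_entropy(x, seed = 17) + log(s), tolerance = 1e-10)
  NZ <- max(2L, as.integer(infoest:::round_half_up(0.25 * 10000)))
  qp2 <- qs_quantiles(as.numeric(x), NZ, 500, seed = 17)
  expect_equal(h, mean(log(NZ * diff(qp2$Z))), tolerance = 1e-12)

  expect_error(qs_entropy(matrix(rnorm(20), ncol = 2)), "one-dimensional")
})
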