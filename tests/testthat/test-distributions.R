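test_that("specification invariants are validated at construction", {
  expect_error(dist_uniform(2, 0.5), "b > a")
  expect_error(dist_normal(0, 0), "sd > 0")
  expect_error(dist_normal_mixture(c(0.7, 0.2),
                                   list(dist_normal(), dist_normal(1))),
               "sum to 1")
  expect_error(dist_normal_mixture(c(0.5, -0.5, 1),
                                   list(dist_normal(), dist_normal(),
                                        dist_normal())),
               "non-negative")
  expect_error(dist_mvnormal(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(dist_gamma_exponential(-1), "theta > 0")
})

test_that("sampling is support-contained, deterministic, and seeded", {
  x <- draw_sample(dist_uniform(0.5, 2.0), 5, seed = 1)
  expect_equal(dim(x), c(5L, 1L))
  expect_true(all(x >= 0.5 & x <= 2.0))
  expect_identical(x, draw_sample(dist_uniform(0.5, 2.0), 5, seed = 1))
  expect_false(identical(x, draw_sample(dist_uniform(0.5, 2.0), 5, seed = 2)))

  ge <- draw_sample(dist_gamma_exponential(3), 100, seed = 4)
  expect_true(all(ge > 0))

  # the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(draw_sample(dist_normal(), 10, seed = 1))
  expect_identical(runif(1), before)
})

test_that("large-sample moments match the specification", {
  cs <- builtin_cases()
  x <- draw_sample(cs[[7]]$p, 200000, seed = 7)
  expect_lt(max(abs(cov(x) - cs[[7]]$p$sigma)), 0.02)

  ge <- draw_sample(dist_gamma_exponential(3), 100000, seed = 11)
  expect_lt(abs(mean(ge[, 1]) - 3), 0.03)  # Gamma(theta, 1) marginal mean
})

test_that("gamma-exponential sample prefers the joint density over independence", {
  spec <- dist_gamma_exponential(3)
  x <- draw_sample(spec, 5000, seed = 2)
  ll_joint <- sum(log(dist_pdf(spec, x)))
  ll_indep <- sum(log(infoest:::dist_marginal_pdf(spec, 1)(x[, 1]))) +
    sum(log(infoest:::dist_marginal_pdf(spec, 2)(x[, 2])))
  expect_gt(ll_joint, ll_indep)
})

test_that("exact densities match hand evaluations and are normalized", {
  expect_equal(dist_pdf(dist_uniform(0.5, 2.0), 1.0), 1 / 1.5)
  expect_equal(dist_pdf(dist_uniform(0.5, 2.0), 3.0), 0)
  expect_equal(dist_pdf(dist_gamma_exponential(3), cbind(1, 1)),
               exp(-2) / gamma(3), tolerance = 1e-12)
  spec4 <- builtin_cases()[[7]]$p
  expect_equal(dist_pdf(spec4, matrix(spec4$mean, 1)),
               1 / sqrt((2 * pi)^4 * det(spec4$sigma)), tolerance = 1e-12)

  # integrates to 1 over the true support (d <= 2)
  for (spec in list(dist_uniform(0.5, 2), dist_normal(-2.5, 2.5),
                    builtin_cases()[[3]]$p)) {
    mass <- integrate(function(v) dist_pdf(spec, v),
                      -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  mass2 <- infoest:::quad2(function(x1, x2)
    dist_pdf(dist_gamma_exponential(3), cbind(x1, x2)),
    c(0, Inf), c(0, Inf), tol = 1e-8)$value
  expect_equal(mass2, 1, tolerance = 1e-6)
})

test_that("closed-form references reproduce hand and printed values", {
  expect_equal(analytic_reference("entropy", dist_uniform(0, 1))$value, 0)
  expect_equal(analytic_reference("entropy", dist_normal(-2.5, 2.5))$value,
               0.5 * log(2 * pi * exp(1) * 6.25), tolerance = 1e-12)
  expect_equal(analytic_reference("kl", dist_uniform(0.5, 2),
                                  dist_uniform(0, 2))$value,
               log(4 / 3), tolerance = 1e-12)
  # gamma-exponential entropy: 1 + theta - theta*psi(theta) + lgamma(theta)
  expect_equal(analytic_reference("entropy", dist_gamma_exponential(3))$value,
               4 - 3 * digamma(3) + lgamma(3), tolerance = 1e-12)

  cs <- builtin_cases()
  expect_equal(round(case_reference(cs[[7]], "entropy")$value, 2), 5.09)
  expect_equal(round(case_reference(cs[[8]], "mi")$value, 2), 1.10)

  # no closed form: mixtures (all quantities) and gamma-exponential KL
  mx <- cs[[3]]$p
  expect_identical(analytic_reference("entropy", mx), "unavailable")
  expect_identical(analytic_reference("kl", mx, dist_normal()), "unavailable")
  expect_identical(analytic_reference("kl", dist_gamma_exponential(3),
                                      dist_gamma_exponential(4)),
                   "unavailable")

  # KL support rule for uniforms: q narrower than p is rejected
  expect_error(analytic_reference("kl", dist_uniform(0, 2),
                                  dist_uniform(0.5, 2)),
               "support")
})

test_that("quadrature references agree with closed forms (cases 1, 2, 4, 6)", {
  cs <- builtin_cases()
  for (case in cs[c(1, 2, 4, 6)]) {
    for (quantity in case$quantities) {
      an <- analytic_reference(quantity, case$p, case$q, split = case$mi_split)
      if (identical(an, "unavailable")) next  # gamma-exponential KL
      nu <- numeric_reference(quantity, case$p, case$q)
      expect_equal(nu$value, an$value, tolerance = 1e-6,
                   label = sprintf("case %d %s quadrature", case$id, quantity))
    }
  }
  # KL of a spec against itself is 0 within tolerance
  expect_equal(numeric_reference("kl", cs[[2]]$p, cs[[2]]$p)$value, 0,
               tolerance = 1e-8)
})

test_that("references respect non-negativity of KL and MI", {
  cs <- builtin_cases()
  for (case in cs) {
    for (quantity in intersect(c("kl", "mi"), case$quantities)) {
      if (case$p$dim > 2) {
        ref <- analytic_reference(quantity, case$p, case$q,
                                  split = case$mi_split)
      } else {
        ref <- case_reference(case, quantity)
      }
      expect_gte(ref$value, 0)
    }
  }
})

test_that("the case registry carries the printed benchmark parameters", {
  cs <- builtin_cases()
  expect_length(cs, 8)
  expect_equal(c(cs[[1]]$p$a, cs[[1]]$p$b), c(0.5, 2.0))
  expect_equal(c(cs[[1]]$q$a, cs[[1]]$q$b), c(0.0, 2.0))
  expect_equal(cs[[6]]$p$theta, 3)
  expect_equal(cs[[6]]$q$theta, 4)
  expect_equal(unique(cs[[8]]$p$sigma[upper.tri(cs[[8]]$p$sigma)]), 0.9)
  expect_equal(unique(cs[[8]]$q$sigma[upper.tri(cs[[8]]$q$sigma)]), 0.1)
  for (i in 1:3) expect_false("mi" %in% cs[[i]]$quantities)
  for (i in 4:8) expect_true("mi" %in% cs[[i]]$quantities)
  expect_equal(cs[[7]]$mi_split, 3L)
  expect_equal(cs[[8]]$mi_split, 9L)
})

test_that("samples round-trip through delimited text and the registry serializes", {
  x <- draw_sample(dist_normal(), 25, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_sample(x, f)
  expect_equal(read_sample(f), x, tolerance = 1e-14,
               ignore_attr = TRUE)
  f2 <- tempfile(fileext = ".yml")
  write_cases_config(f2)
  cfg <- yaml::read_yaml(f2)
  expect_length(cfg, 8)
  expect_equal(cfg[[6]]$p$params$theta, 3)
})
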