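#' Benchmark distribution specifications
#'
#' Constructors for the distribution families used throughout the package:
#' the 1-D uniform and normal, weighted normal mixtures (1-D or multivariate
#' components), the d-dimensional multivariate normal, and the 2-D
#' gamma-exponential. A specification validates its parameters on
#' construction and is the single source of samples ([draw_sample()]), exact
#' densities ([dist_pdf()]), and reference values ([analytic_reference()],
#' [numeric_reference()]).
#'
#' @param a,b lower and upper bound of the uniform distribution (`b > a`).
#' @param mean mean (scalar for `dist_normal`, length-d vector for
#'   `dist_mvnormal`).
#' @param sd standard deviation, `sd > 0`.
#' @param sigma d x d symmetric positive-definite covariance matrix.
#' @param weights non-negative mixture weights summing to 1.
#' @param components list of component specifications (all `dist_normal`, or
#'   all `dist_mvnormal` of a common dimension).
#' @param theta scale parameter of the gamma-exponential distribution,
#'   `theta > 0`; the support is `x1, x2 > 0` and the density is
#'   `x1^theta * exp(-x1 - x1*x2) / gamma(theta)`.
#'
#' @return An object of class `dist_spec` with fields `family`, `dim`, and the
#'   family-specific parameters.
#' @examples
#' p <- dist_uniform(0.5, 2)
#' x <- draw_sample(p, 100, seed = 1)
#' range(x)
#' @name dist_spec
NULL

new_dist_spec <- function(family, dim, params) {
  structure(c(list(family = family, dim = as.integer(dim)), params),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1 || length(b) != 1)
    stop("`a` and `b` must be scalars")
  if (!(b > a)) stop("uniform bounds require b > a")
  new_dist_spec("uniform", 1L, list(a = a, b = b))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean = 0, sd = 1) {
  if (!(sd > 0)) stop("normal requires sd > 0")
  new_dist_spec("normal", 1L, list(mean = mean, sd = sd))
}

#' @rdname dist_spec
#' @export
dist_mvnormal <- function(mean, sigma) {
  sigma <- as.matrix(sigma)
  d <- length(mean)
  if (!all(dim(sigma) == d)) stop("`sigma` must be d x d with d = length(mean)")
  if (max(abs(sigma - t(sigma))) > 1e-12) stop("`sigma` must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`sigma` must be positive-definite")
  new_dist_spec("mv_normal", d, list(mean = as.numeric(mean), sigma = sigma))
}

#' @rdname dist_spec
#' @export
dist_normal_mixture <- function(weights, components) {
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (length(weights) != length(components))
    stop("one weight per component is required")
  fams <- vapply(components, function(s) s$family, character(1))
  if (!all(fams %in% c("normal", "mv_normal")))
    stop("mixture components must be normal or mv_normal specifications")
  dims <- vapply(components, function(s) s$dim, integer(1))
  if (length(unique(dims)) != 1) stop("mixture components must share a dimension")
  new_dist_spec("normal_mixture", dims[1],
                list(weights = as.numeric(weights), components = components))
}

#' @rdname dist_spec
#' @export
dist_gamma_exponential <- function(theta) {
  if (!(theta > 0)) stop("gamma-exponential requires theta > 0")
  new_dist_spec("gamma_exponential", 2L, list(theta = theta))
}

#' @export
print.dist_spec <- function(x, ...) {
  par_str <- switch(x$family,
    uniform = sprintf("a=%g, b=%g", x$a, x$b),
    normal = sprintf("mean=%g, sd=%g", x$mean, x$sd),
    mv_normal = sprintf("d=%d", x$dim),
    normal_mixture = sprintf("%d components", length(x$components)),
    gamma_exponential = sprintf("theta=%g", x$theta))
  cat(sprintf("<dist_spec %s (%s), dim %d>\n", x$family, par_str, x$dim))
  invisible(x)
}

#' Draw a seeded sample from a distribution specification
#'
#' Returns an `n x d` matrix of observations. The seed fixes the entire random
#' stream, so identical `(spec, n, seed)` calls are bit-identical; the caller's
#' RNG state is left untouched. Mixtures draw the categorical component labels
#' first and then each component's rows in component order, so the stream is
#' consumed in a fixed, reproducible order. The gamma-exponential factorizes as
#' `x1 ~ Gamma(theta, 1)` and `x2 | x1 ~ Exponential(rate = x1)`, which
#' reproduces its joint density exactly.
#'
#' @param spec a [dist_spec] object.
#' @param n number of observations, `n >= 1`.
#' @param seed integer seed.
#' @return numeric matrix with `n` rows and `spec$dim` columns.
#' @export
draw_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!(n >= 1)) stop("`n` must be at least 1")
  n <- as.integer(n)
  with_seed(seed, draw_sample_impl(spec, n))
}

draw_sample_impl <- function(spec, n) {
  switch(spec$family,
    uniform = matrix(stats::runif(n, spec$a, spec$b), ncol = 1),
    normal = matrix(stats::rnorm(n, spec$mean, spec$sd), ncol = 1),
    mv_normal = {
      d <- spec$dim
      z <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
      sweep(z %*% chol(spec$sigma), 2, spec$mean, "+")
    },
    normal_mixture = {
      k <- length(spec$components)
      lab <- sample.int(k, n, replace = TRUE, prob = spec$weights)
      out <- matrix(NA_real_, nrow = n, ncol = spec$dim)
      for (j in seq_len(k)) {
        rows <- which(lab == j)
        if (length(rows))
          out[rows, ] <- draw_sample_impl(spec$components[[j]], length(rows))
      }
      out
    },
    gamma_exponential = {
      x1 <- stats::rgamma(n, shape = spec$theta, scale = 1)
      x2 <- stats::rexp(n, rate = x1)
      cbind(x1, x2, deparse.level = 0)
    },
    stop("unknown family: ", spec$family))
}

#' Evaluate the exact probability density of a specification
#'
#' @param spec a [dist_spec] object.
#' @param x points at which to evaluate, an `m x d` matrix (a vector is taken
#'   as a one-column matrix when `d = 1`).
#' @return numeric vector of densities; zero outside the support.
#' @export
dist_pdf <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  x <- as_sample_matrix(x, d = spec$dim)
  switch(spec$family,
    uniform = ifelse(x[, 1] >= spec$a & x[, 1] <= spec$b,
                     1 / (spec$b - spec$a), 0),
    normal = stats::dnorm(x[, 1], spec$mean, spec$sd),
    mv_normal = {
      u <- chol(spec$sigma)
      z <- forwardsolve(t(u), t(x) - spec$mean)
      q <- colSums(z^2)
      logdet <- 2 * sum(log(diag(u)))
      exp(-0.5 * (spec$dim * log(2 * pi) + logdet + q))
    },
    normal_mixture = {
      dens <- numeric(nrow(x))
      for (j in seq_along(spec$components))
        dens <- dens + spec$weights[j] * dist_pdf(spec$components[[j]], x)
      dens
    },
    gamma_exponential = {
      x1 <- x[, 1]; x2 <- x[, 2]
      ifelse(x1 > 0 & x2 > 0,
             exp(spec$theta * log(pmax(x1, .Machine$double.xmin)) -
                   x1 - x1 * x2 - lgamma(spec$theta)),
             0)
    })
}

# true support, per dimension, as a list of c(lo, hi)
dist_support <- function(spec) {
  switch(spec$family,
    uniform = list(c(spec$a, spec$b)),
    gamma_exponential = list(c(0, Inf), c(0, Inf)),
    rep(list(c(-Inf, Inf)), spec$dim))
}

# exact 1-D marginal density of dimension `j`, as a function of a vector
dist_marginal_pdf <- function(spec, j) {
  switch(spec$family,
    normal = ,
    uniform = function(v) dist_pdf(spec, v),
    mv_normal = {
      m <- spec$mean[j]; s <- sqrt(spec$sigma[j, j])
      function(v) stats::dnorm(v, m, s)
    },
    normal_mixture = {
      margs <- lapply(spec$components, dist_marginal_pdf, j = j)
      w <- spec$weights
      function(v) {
        dens <- numeric(length(v))
        for (i in seq_along(w)) dens <- dens + w[i] * margs[[i]](v)
        dens
      }
    },
    gamma_exponential = {
      th <- spec$theta
      if (j == 1) function(v) stats::dgamma(v, shape = th, scale = 1)
      else function(v) ifelse(v > 0, th / (1 + v)^(th + 1), 0)
    },
    stop("no marginal density for family ", spec$family))
}

unavailable <- function() "unavailable"

is_unavailable <- function(x) identical(x, "unavailable")

new_reference <- function(quantity, value, method, tolerance = NULL) {
  structure(list(quantity = quantity, value = value, method = method,
                 tolerance = tolerance),
            class = "reference_value")
}

#' @export
print.reference_value <- function(x, ...) {
  cat(sprintf("<reference %s = %.6f nats (%s)>\n", x$quantity, x$value,
              x$method))
  invisible(x)
}

#' Closed-form reference values
#'
#' Exact entropy, KL divergence, or mutual information where a closed form
#' exists: uniform and (multivariate) normal entropy and KL, the Gaussian
#' mutual information from a block partition of the covariance, and the
#' gamma-exponential entropy `1 + theta - theta*digamma(theta) + lgamma(theta)`
#' and mutual information `digamma(theta) - log(theta) + 1/theta`. Returns the
#' string `"unavailable"` exactly for the combinations with no closed form:
#' all three quantities for normal mixtures, and the KL divergence between two
#' gamma-exponential distributions (use [numeric_reference()] there).
#'
#' @param quantity one of `"entropy"`, `"kl"`, `"mi"`.
#' @param spec_p distribution of interest.
#' @param spec_q approximating distribution (KL only).
#' @param split for multivariate-normal mutual information: X is the leading
#'   `split` dimensions and Y the trailing `d - split`.
#' @return a `reference_value` (value in nats) or `"unavailable"`.
#' @export
analytic_reference <- function(quantity = c("entropy", "kl", "mi"),
                               spec_p, spec_q = NULL, split = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(spec_p, "dist_spec"))
  if (quantity == "entropy") {
    val <- switch(spec_p$family,
      uniform = log(spec_p$b - spec_p$a),
      normal = 0.5 * log(2 * pi * exp(1) * spec_p$sd^2),
      mv_normal = 0.5 * (spec_p$dim * log(2 * pi * exp(1)) +
                           determinant(spec_p$sigma)$modulus[1]),
      gamma_exponential = 1 + spec_p$theta -
        spec_p$theta * digamma(spec_p$theta) + lgamma(spec_p$theta),
      normal_mixture = return(unavailable()))
    return(new_reference("entropy", val, "analytic"))
  }
  if (quantity == "kl") {
    stopifnot(inherits(spec_q, "dist_spec"))
    if (spec_p$dim != spec_q$dim) stop("KL requires equal dimensions")
    if (spec_p$family == "normal_mixture" || spec_q$family == "normal_mixture")
      return(unavailable())
    if (spec_p$family == "gamma_exponential") return(unavailable())
    if (spec_p$family == "uniform" && spec_q$family == "uniform") {
      if (spec_q$a > spec_p$a || spec_q$b < spec_p$b)
        stop("KL divergence requires support(q) to cover support(p); ",
             "uniform q = [", spec_q$a, ", ", spec_q$b,
             "] does not cover p = [", spec_p$a, ", ", spec_p$b, "]")
      return(new_reference("kl",
        log((spec_q$b - spec_q$a) / (spec_p$b - spec_p$a)), "analytic"))
    }
    if (spec_p$family == "normal" && spec_q$family == "normal") {
      v <- 0.5 * ((spec_p$sd / spec_q$sd)^2 +
                    (spec_q$mean - spec_p$mean)^2 / spec_q$sd^2 - 1 +
                    log(spec_q$sd^2 / spec_p$sd^2))
      return(new_reference("kl", v, "analytic"))
    }
    if (spec_p$family == "mv_normal" && spec_q$family == "mv_normal") {
      d <- spec_p$dim
      sq_inv <- solve(spec_q$sigma)
      dm <- spec_q$mean - spec_p$mean
      v <- 0.5 * (determinant(spec_q$sigma)$modulus[1] -
                    determinant(spec_p$sigma)$modulus[1] +
                    sum(diag(sq_inv %*% spec_p$sigma)) +
                    drop(t(dm) %*% sq_inv %*% dm) - d)
      return(new_reference("kl", v, "analytic"))
    }
    return(unavailable())
  }
  # mutual information
  if (spec_p$family == "normal_mixture") return(unavailable())
  if (spec_p$dim < 2)
    stop("mutual information needs at least two dimensions to split")
  if (spec_p$family == "gamma_exponential") {
    th <- spec_p$theta
    return(new_reference("mi", digamma(th) - log(th) + 1 / th, "analytic"))
  }
  if (spec_p$family == "mv_normal") {
    if (is.null(split)) split <- spec_p$dim - 1L
    if (!(split >= 1 && split < spec_p$dim))
      stop("`split` must partition the dimensions")
    ix <- seq_len(split); iy <- (split + 1):spec_p$dim
    s <- spec_p$sigma
    v <- 0.5 * (determinant(s[ix, ix, drop = FALSE])$modulus[1] +
                  determinant(s[iy, iy, drop = FALSE])$modulus[1] -
                  determinant(s)$modulus[1])
    return(new_reference("mi", v, "analytic"))
  }
  stop("no mutual-information reference for family ", spec_p$family)
}

#' Adaptive-quadrature reference values
#'
#' Numerically integrates the defining integrals of entropy, KL divergence, or
#' mutual information over the true support of the distribution, for
#' specifications of dimension one or two. One-dimensional integrals use
#' QUADPACK directly; two-dimensional ones use iterated adaptive quadrature,
#' which handles the infinite supports of the normal and gamma-exponential
#' families. Both absolute and relative tolerances default to `1.49e-8`.
#'
#' @inheritParams analytic_reference
#' @param tol absolute and relative quadrature tolerance.
#' @return a `reference_value` with `method = "quadrature"` and the achieved
#'   error estimate as `tolerance`.
#' @export
numeric_reference <- function(quantity = c("entropy", "kl", "mi"),
                              spec_p, spec_q = NULL, tol = 1.49e-8) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(spec_p, "dist_spec"))
  d <- spec_p$dim
  if (d > 2) stop("quadrature references are implemented for d <= 2 only")
  sup <- dist_support(spec_p)
  if (quantity == "entropy") {
    if (d == 1) {
      r <- quad1(function(v) -xlogx(dist_pdf(spec_p, v)),
                 sup[[1]][1], sup[[1]][2], tol)
    } else {
      r <- quad2(function(x1, x2)
        -xlogx(dist_pdf(spec_p, cbind(x1, x2))), sup[[1]], sup[[2]], tol)
    }
    return(new_reference("entropy", r$value, "quadrature", r$error))
  }
  if (quantity == "kl") {
    stopifnot(inherits(spec_q, "dist_spec"))
    if (spec_q$dim != d) stop("KL requires equal dimensions")
    f <- function(x) {
      p <- dist_pdf(spec_p, x)
      q <- dist_pdf(spec_q, x)
      ifelse(p > 0, p * (log(pmax(p, .Machine$double.xmin)) -
                           log(pmax(q, .Machine$double.xmin))), 0)
    }
    if (d == 1) r <- quad1(function(v) f(matrix(v, ncol = 1)),
                           sup[[1]][1], sup[[1]][2], tol)
    else r <- quad2(function(x1, x2) f(cbind(x1, x2)), sup[[1]], sup[[2]], tol)
    return(new_reference("kl", r$value, "quadrature", r$error))
  }
  if (d != 2) stop("mutual information requires a two-dimensional specification")
  px <- dist_marginal_pdf(spec_p, 1)
  py <- dist_marginal_pdf(spec_p, 2)
  f <- function(x1, x2) {
    p <- dist_pdf(spec_p, cbind(x1, x2))
    m <- px(x1) * py(x2)
    ifelse(p > 0, p * (log(pmax(p, .Machine$double.xmin)) -
                         log(pmax(m, .Machine$double.xmin))), 0)
  }
  r <- quad2(f, sup[[1]], sup[[2]], tol)
  new_reference("mi", r$value, "quadrature", r$error)
}

#' The eight built-in benchmark cases
#'
#' Returns the registry of test cases used throughout the benchmark: 1-D
#' uniform, normal, and normal mixture (entropy and KL only), 2-D normal,
#' 2-D normal mixture, and 2-D gamma-exponential, and 4-D and 10-D
#' multivariate normals. Each entry carries the sampled distribution `p`, the
#' approximating distribution `q` (for KL), the applicable quantities, and the
#' dimension split used for mutual information (X = leading `mi_split`
#' dimensions, Y = the rest).
#'
#' @return a list of 8 `benchmark_case` objects.
#' @export
builtin_cases <- function() {
  sigma_p2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  sigma_q2 <- diag(c(5, 1))
  sigma_m2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  sig4 <- function(off) {
    s <- matrix(off, 4, 4); diag(s) <- 1; s
  }
  sig10 <- function(off) {
    s <- matrix(off, 10, 10); diag(s) <- 1; s
  }
  cases <- list(
    list(id = 1L, label = "1D uniform",
         p = dist_uniform(0.5, 2.0), q = dist_uniform(0.0, 2.0),
         quantities = c("entropy", "kl"), mi_split = NA_integer_),
    list(id = 2L, label = "1D normal",
         p = dist_normal(-2.5, 2.5), q = dist_normal(0, 3.15),
         quantities = c("entropy", "kl"), mi_split = NA_integer_),
    list(id = 3L, label = "1D normal mixture",
         p = dist_normal_mixture(c(0.5, 0.5),
                                 list(dist_normal(-2.5, 2.5),
                                      dist_normal(2.5, 1))),
         q = dist_normal(0, 3.15),
         quantities = c("entropy", "kl"), mi_split = NA_integer_),
    list(id = 4L, label = "2D normal",
         p = dist_mvnormal(c(-2, 0), sigma_p2),
         q = dist_mvnormal(c(0, 0), sigma_q2),
         quantities = c("entropy", "kl", "mi"), mi_split = 1L),
    list(id = 5L, label = "2D normal mixture",
         p = dist_normal_mixture(c(0.5, 0.5),
                                 list(dist_mvnormal(c(-2, 0), sigma_p2),
                                      dist_mvnormal(c(2, 0), sigma_m2))),
         q = dist_mvnormal(c(0, 0), sigma_q2),
         quantities = c("entropy", "kl", "mi"), mi_split = 1L),
    list(id = 6L, label = "2D gamma-exponential",
         p = dist_gamma_exponential(3), q = dist_gamma_exponential(4),
         quantities = c("entropy", "kl", "mi"), mi_split = 1L),
    list(id = 7L, label = "4D normal",
         p = dist_mvnormal(c(0.1, 0.3, 0.6, 0.9), sig4(0.5)),
         q = dist_mvnormal(rep(0, 4), sig4(0.1)),
         quantities = c("entropy", "kl", "mi"), mi_split = 3L),
    list(id = 8L, label = "10D normal",
         p = dist_mvnormal(rep(0, 10), sig10(0.9)),
         q = dist_mvnormal(rep(0, 10), sig10(0.1)),
         quantities = c("entropy", "kl", "mi"), mi_split = 9L))
  lapply(cases, function(x) structure(x, class = "benchmark_case"))
}

#' @export
print.benchmark_case <- function(x, ...) {
  cat(sprintf("<case %d: %s, d=%d, quantities: %s>\n", x$id, x$label,
              x$p$dim, paste(x$quantities, collapse = ", ")))
  invisible(x)
}

#' Reference value for a benchmark case and quantity
#'
#' Uses the closed form when one exists and falls back to adaptive quadrature
#' otherwise (the mixture cases, and the gamma-exponential KL divergence).
#'
#' @param case a `benchmark_case` from [builtin_cases()].
#' @param quantity one of the case's applicable quantities.
#' @param tol quadrature tolerance for the numeric fallback.
#' @return a `reference_value`.
#' @export
case_reference <- function(case, quantity, tol = 1.49e-8) {
  stopifnot(inherits(case, "benchmark_case"))
  if (!quantity %in% case$quantities)
    stop("quantity ", quantity, " does not apply to case ", case$id)
  ref <- analytic_reference(quantity, case$p, case$q, split = case$mi_split)
  if (is_unavailable(ref))
    ref <- numeric_reference(quantity, case$p, case$q, tol = tol)
  ref
}

#' Read and write delimited sample matrices
#'
#' Samples are stored as plain delimited text, one row per observation and one
#' column per dimension, `.` as the decimal mark, no header by default.
#'
#' @param x sample matrix.
#' @param file path.
#' @param header whether to write/expect a `V1..Vd` header line.
#' @param sep field separator.
#' @return `read_sample` returns a numeric matrix.
#' @export
write_sample <- function(x, file, header = FALSE, sep = "\t") {
  x <- as_sample_matrix(x)
  utils::write.table(x, file = file, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(file)
}

#' @rdname write_sample
#' @export
read_sample <- function(file, header = FALSE, sep = "\t") {
  as_sample_matrix(utils::read.table(file, header = header, sep = sep))
}

#' Serialize the case registry to a structured config file
#'
#' Writes the built-in case registry as YAML (keys: `family`, `params`, `dim`,
#' `quantities`, `mi_split`), so the benchmark configuration is inspectable and
#' portable outside R.
#'
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_cases_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to write the case registry")
  spec_to_list <- function(s) {
    params <- switch(s$family,
      uniform = list(a = s$a, b = s$b),
      normal = list(mean = s$mean, sd = s$sd),
      mv_normal = list(mean = s$mean, sigma = as.vector(s$sigma)),
      normal_mixture = list(weights = s$weights,
                            components = lapply(s$components, spec_to_list)),
      gamma_exponential = list(theta = s$theta))
    list(family = s$family, dim = s$dim, params = params)
  }
  out <- lapply(builtin_cases(), function(cs) {
    list(id = cs$id, label = cs$label, p = spec_to_list(cs$p),
         q = spec_to_list(cs$q), quantities = as.list(cs$quantities),
         mi_split = if (is.na(cs$mi_split)) NULL else cs$mi_split)
  })
  yaml::write_yaml(out, file)
  invisible(file)
}
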