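#' Silverman's rule-of-thumb bandwidth
#'
#' The scalar smoothing multiplier `h = (n (d + 2) / 4)^(-1 / (d + 4))` applied
#' to the full sample covariance in the multivariate Gaussian kernel. It is
#' strictly decreasing in the sample size for a fixed dimension.
#'
#' @param n sample size.
#' @param d dimension.
#' @return bandwidth `h > 0`.
#' @export
silverman_bandwidth <- function(n, d) {
  stopifnot(n >= 1, d >= 1)
  (n * (d + 2) / 4)^(-1 / (d + 4))
}

#' Fit a Gaussian kernel density model
#'
#' Stores the sample, its unbiased (`n - 1` divisor) covariance, and the
#' Silverman bandwidth. The kernel is the multivariate Gaussian
#' `K(u) = (2*pi)^(-d/2) h^(-d) det(Sigma)^(-1/2) exp(-u/2)` with the
#' Mahalanobis argument `u = (x - x_i)' Sigma^(-1) (x - x_i) / h^2`, i.e. a
#' Gaussian with covariance `h^2 Sigma` centered at each sample point.
#'
#' @param x sample matrix, `n x d` with `n >= 2` and non-singular covariance.
#' @return an object of class `kde_model`.
#' @export
kde_fit <- function(x) {
  x <- as_sample_matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("KDE requires at least 2 observations")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0))
    stop("singular sample covariance: dimension(s) ",
         paste(which(vars == 0), collapse = ", "), " are constant")
  sigma <- stats::cov(x)
  u <- tryCatch(chol(sigma),
                error = function(e) stop("singular sample covariance"))
  h <- silverman_bandwidth(n, d)
  structure(list(points = x, cov = sigma, chol = u, bandwidth = h,
                 dim = d, n = n,
                 log_norm = -(d / 2) * log(2 * pi) - d * log(h) -
                   sum(log(diag(u)))),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("<kde_model: n=%d, d=%d, h=%.5f>\n", x$n, x$dim, x$bandwidth))
  invisible(x)
}

#' Evaluate a fitted kernel density
#'
#' @param model a `kde_model` from [kde_fit()].
#' @param x query points, `m x d`.
#' @param chunk number of query rows per evaluation block (memory control).
#' @return density vector, strictly positive everywhere.
#' @export
kde_eval <- function(model, x, chunk = 1024L) {
  stopifnot(inherits(model, "kde_model"))
  x <- as_sample_matrix(x, d = model$dim)
  # whiten so Mahalanobis distance becomes Euclidean distance
  zr <- t(forwardsolve(t(model$chol), t(model$points)))
  zq <- t(forwardsolve(t(model$chol), t(x)))
  h2 <- model$bandwidth^2
  rn <- rowSums(zr^2)
  out <- numeric(nrow(x))
  for (start in seq(1, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    qn <- rowSums(zq[idx, , drop = FALSE]^2)
    d2 <- outer(qn, rn, "+") -
      2 * tcrossprod(zq[idx, , drop = FALSE], zr)
    d2[d2 < 0] <- 0
    out[idx] <- rowMeans(exp(model$log_norm - d2 / (2 * h2)))
  }
  out
}

#' Integration box for KDE integral estimates
#'
#' Per-dimension limits for the numerical integration of a kernel density:
#' the sample minimum and maximum, widened by the bandwidth on each side.
#'
#' @param x sample matrix.
#' @param h bandwidth.
#' @return a list with one `c(lo, hi)` per dimension.
#' @export
integration_box <- function(x, h) {
  x <- as_sample_matrix(x)
  lapply(seq_len(ncol(x)), function(j) c(min(x[, j]) - h, max(x[, j]) + h))
}

check_kde_budget <- function(n, mode, n_max) {
  if (mode == "resubstitution" && n > n_max)
    stop("KDE resubstitution at n = ", n, " exceeds the configured ceiling of ",
         n_max, " points; raise `n_max` explicitly to override")
}

check_integral_dim <- function(d) {
  if (d > 2)
    stop("KDE integral estimates are limited to d <= 2; numerical ",
         "integration of a kernel density is prohibitively expensive beyond")
}

kde_integrate <- function(f, box, tol) {
  if (length(box) == 1) quad1(f, box[[1]][1], box[[1]][2], tol)$value
  else quad2(f, box[[1]], box[[2]], tol)$value
}

#' KDE plug-in estimators of entropy, KL divergence, and mutual information
#'
#' Resubstitution estimates replace the defining integral with the mean
#' log-density over the sample points; integral estimates numerically
#' integrate the fitted kernel density over the sample-derived
#' [integration_box()] (not the true support, so bounded-support targets keep
#' a deliberate boundary bias). Integral mode is limited to `d <= 2`;
#' resubstitution refuses samples beyond `n_max` points so quadratic-cost
#' evaluations fail loudly rather than stall.
#'
#' `kde_kl` fits separate models to the two samples and averages
#' `log(p_hat/q_hat)` over the `p` sample; `kde_mi` fits the joint model and
#' the two marginal models (columns `1:dx` vs the rest) and averages
#' `log(p_joint / (p_x * p_y))`. No clipping is applied to `kde_mi`, which may
#' be slightly negative by construction.
#'
#' @param x,x_p,x_q,xy sample matrices (`xy` holds X and Y blocks side by
#'   side).
#' @param mode `"resubstitution"` or `"integral"`.
#' @param dx number of leading columns forming the X block.
#' @param tol quadrature tolerance for integral mode.
#' @param n_max resubstitution sample-size ceiling.
#' @return estimate in nats.
#' @export
kde_entropy <- function(x, mode = c("resubstitution", "integral"),
                        tol = 1.49e-8, n_max = 25000L) {
  mode <- match.arg(mode)
  x <- as_sample_matrix(x)
  model <- kde_fit(x)
  if (mode == "resubstitution") {
    check_kde_budget(nrow(x), mode, n_max)
    return(-mean(log(kde_eval(model, x))))
  }
  check_integral_dim(ncol(x))
  box <- integration_box(x, model$bandwidth)
  f <- if (ncol(x) == 1) {
    function(v) -xlogx(kde_eval(model, matrix(v, ncol = 1)))
  } else {
    function(x1, x2) -xlogx(kde_eval(model, cbind(x1, x2)))
  }
  kde_integrate(f, box, tol)
}

#' @rdname kde_entropy
#' @export
kde_kl <- function(x_p, x_q, mode = c("resubstitution", "integral"),
                   tol = 1.49e-8, n_max = 25000L) {
  mode <- match.arg(mode)
  x_p <- as_sample_matrix(x_p)
  x_q <- as_sample_matrix(x_q, d = ncol(x_p))
  mp <- kde_fit(x_p)
  mq <- kde_fit(x_q)
  if (mode == "resubstitution") {
    check_kde_budget(max(nrow(x_p), nrow(x_q)), mode, n_max)
    return(mean(log(kde_eval(mp, x_p)) - log(kde_eval(mq, x_p))))
  }
  check_integral_dim(ncol(x_p))
  box <- integration_box(x_p, mp$bandwidth)
  f <- if (ncol(x_p) == 1) {
    function(v) {
      pts <- matrix(v, ncol = 1)
      p <- kde_eval(mp, pts)
      p * (log(p) - log(kde_eval(mq, pts)))
    }
  } else {
    function(x1, x2) {
      pts <- cbind(x1, x2)
      p <- kde_eval(mp, pts)
      p * (log(p) - log(kde_eval(mq, pts)))
    }
  }
  kde_integrate(f, box, tol)
}

#' @rdname kde_entropy
#' @export
kde_mi <- function(xy, dx, mode = c("resubstitution", "integral"),
                   tol = 1.49e-8, n_max = 25000L) {
  mode <- match.arg(mode)
  xy <- as_sample_matrix(xy)
  d <- ncol(xy)
  if (!(dx >= 1 && dx < d)) stop("`dx` must satisfy 1 <= dx < d")
  xs <- xy[, seq_len(dx), drop = FALSE]
  ys <- xy[, (dx + 1):d, drop = FALSE]
  mj <- kde_fit(xy)
  mx <- kde_fit(xs)
  my <- kde_fit(ys)
  if (mode == "resubstitution") {
    check_kde_budget(nrow(xy), mode, n_max)
    return(mean(log(kde_eval(mj, xy)) - log(kde_eval(mx, xs)) -
                  log(kde_eval(my, ys))))
  }
  check_integral_dim(d)  # implies dx = 1, d = 2
  box <- integration_box(xy, mj$bandwidth)  # joint box; marginals use its projections
  f <- function(x1, x2) {
    p <- kde_eval(mj, cbind(x1, x2))
    p * (log(p) - log(kde_eval(mx, matrix(x1, ncol = 1))) -
           log(kde_eval(my, matrix(x2, ncol = 1))))
  }
  kde_integrate(f, box, tol)
}
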