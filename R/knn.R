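#' Volume of the d-dimensional Euclidean unit ball
#'
#' `pi^(d/2) / gamma(d/2 + 1)`: 2 for `d = 1`, `pi` for `d = 2`,
#' `4*pi/3` for `d = 3`.
#'
#' @param d dimension, `d >= 1`.
#' @return the Lebesgue volume of the unit ball.
#' @export
unit_ball_volume <- function(d) {
  stopifnot(d >= 1)
  pi^(d / 2) / gamma(d / 2 + 1)
}

#' Exact k-nearest-neighbor distances
#'
#' Distances from each query point to its k nearest points in the reference
#' set, computed exactly with a kd-tree, under the Euclidean (`p = 2`) or
#' maximum (Chebyshev, `p = Inf`) norm. In `"self-excluded"` mode the query
#' set must be the reference set itself and point `i` is never its own
#' neighbor (requires `k <= n - 1`); in `"cross"` mode the sets are
#' independent (requires `k <= m`). Distance ties at the k-th neighbor do not
#' affect the returned k-th distance value.
#'
#' @param query query points, `m x d`.
#' @param reference reference points, `n x d`; defaults to `query`.
#' @param k number of neighbors.
#' @param norm `"euclidean"` or `"maximum"`.
#' @param mode `"self-excluded"` or `"cross"`.
#' @return an `m x k` matrix of distances, columns sorted ascending (column
#'   `k` is the k-th neighbor distance).
#' @export
knn_distances <- function(query, reference = query, k,
                          norm = c("euclidean", "maximum"),
                          mode = c("self-excluded", "cross")) {
  norm <- match.arg(norm)
  mode <- match.arg(mode)
  query <- as_sample_matrix(query)
  reference <- as_sample_matrix(reference, d = ncol(query))
  self <- mode == "self-excluded"
  if (self && !identical(dim(query), dim(reference)))
    stop("self-excluded mode queries the reference set against itself")
  cpp_knn_dist(reference, query, as.integer(k), norm == "maximum", self)
}

# strict/non-strict neighbor counts within per-point radii (internal)
count_within <- function(query, reference, radius,
                         norm = c("euclidean", "maximum"),
                         mode = c("self-excluded", "cross"), strict = TRUE) {
  norm <- match.arg(norm)
  mode <- match.arg(mode)
  query <- as_sample_matrix(query)
  reference <- as_sample_matrix(reference, d = ncol(query))
  cpp_count_within(reference, query, as.numeric(radius), norm == "maximum",
                   mode == "self-excluded", strict)
}

check_positive_distances <- function(rho, what, jitter_allowed = TRUE) {
  if (any(rho == 0)) {
    idx <- which(rho == 0)
    stop(what, ": zero ", if (jitter_allowed) "k-th neighbor " else "",
         "distance at point(s) ",
         paste(utils::head(idx, 5), collapse = ", "),
         if (length(idx) > 5) ", ..." else "",
         " (duplicate points); remove duplicates or enable ",
         "`jitter_duplicates`")
  }
}

apply_jitter <- function(x) {
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  x + matrix(stats::runif(length(x), -1, 1), nrow(x), ncol(x)) *
    rep(1e-10 * rng, each = nrow(x))
}

#' Kozachenko-Leonenko k-NN entropy estimator
#'
#' `H_hat = digamma(N) - digamma(k) + log(c1(d)) + (d/N) * sum(log(rho_k(i)))`
#' where `rho_k(i)` is the Euclidean distance from point `i` to its k-th
#' nearest neighbor (self excluded) and `c1(d)` the unit-ball volume. Exactly
#' translation invariant, and scaling the sample by `s` adds `d * log(s)`.
#' Duplicate points make a k-th distance zero; by default this is an error,
#' or an explicit tiny uniform jitter (amplitude `1e-10` of the per-dimension
#' range, drawn from the current RNG stream) can be requested.
#'
#' @param x sample matrix, `n >= k + 1`.
#' @param k number of neighbors.
#' @param jitter_duplicates perturb duplicates instead of failing.
#' @return entropy estimate in nats.
#' @export
knn_entropy <- function(x, k = 1L, jitter_duplicates = FALSE) {
  x <- as_sample_matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (jitter_duplicates) x <- apply_jitter(x)
  rho <- knn_distances(x, k = k, norm = "euclidean", mode = "self-excluded")[, k]
  check_positive_distances(rho, "knn_entropy")
  digamma(n) - digamma(k) + log(unit_ball_volume(d)) + (d / n) * sum(log(rho))
}

#' Wang et al. k-NN Kullback-Leibler divergence estimator
#'
#' `D_hat = (d/n) * sum(log(nu_k(i) / rho_k(i))) + log(m / (n - 1))` where
#' `rho_k(i)` is the k-th neighbor distance of `p`-point `i` within the `p`
#' sample (self excluded) and `nu_k(i)` its k-th neighbor distance into the
#' `q` sample, both Euclidean. Invariant under a common affine map of both
#' samples; may be negative (the estimator is unbounded below).
#'
#' @param x_p sample from the distribution of interest, `n >= k + 1`.
#' @param x_q sample from the approximating distribution, `m >= k`.
#' @param k number of neighbors.
#' @param jitter_duplicates perturb duplicates instead of failing.
#' @return KL divergence estimate in nats.
#' @export
knn_kl <- function(x_p, x_q, k = 1L, jitter_duplicates = FALSE) {
  x_p <- as_sample_matrix(x_p)
  x_q <- as_sample_matrix(x_q, d = ncol(x_p))
  if (jitter_duplicates) {
    x_p <- apply_jitter(x_p)
    x_q <- apply_jitter(x_q)
  }
  n <- nrow(x_p); m <- nrow(x_q); d <- ncol(x_p)
  rho <- knn_distances(x_p, k = k, norm = "euclidean",
                       mode = "self-excluded")[, k]
  nu <- knn_distances(x_p, x_q, k = k, norm = "euclidean", mode = "cross")[, k]
  check_positive_distances(rho, "knn_kl (within-p distances)")
  check_positive_distances(nu, "knn_kl (p-to-q distances)")
  (d / n) * sum(log(nu) - log(rho)) + log(m / (n - 1))
}

#' Kraskov et al. k-NN mutual information estimator
#'
#' Algorithm 1 of the Kraskov-Stoegbauer-Grassberger estimator:
#' `I_hat = digamma(k) + digamma(N) - mean(digamma(n_x + 1) + digamma(n_y + 1))`
#' where, for each point, `rho_k` is the maximum-norm distance to its k-th
#' neighbor in the joint space and `n_x`, `n_y` count the other points whose
#' marginal maximum-norm distance is *strictly* smaller than `rho_k`. Raw
#' negative values (common for independent data at small `n` and `k = 1`) are
#' clipped to 0 in the returned value; the unclipped estimate is attached as
#' attribute `"raw"`.
#'
#' @param xy sample matrix with the X block in the leading `dx` columns and
#'   the Y block in the rest.
#' @param dx number of leading columns forming X.
#' @param k number of neighbors (`k = 15` is a robust default for mutual
#'   information).
#' @param jitter_duplicates perturb duplicates instead of failing.
#' @return mutual information estimate in nats (clipped at 0), with the raw
#'   value as attribute `"raw"`.
#' @export
kraskov_mi <- function(xy, dx, k = 15L, jitter_duplicates = FALSE) {
  xy <- as_sample_matrix(xy)
  d <- ncol(xy)
  if (!(dx >= 1 && dx < d)) stop("`dx` must satisfy 1 <= dx < d")
  if (jitter_duplicates) xy <- apply_jitter(xy)
  n <- nrow(xy)
  xs <- xy[, seq_len(dx), drop = FALSE]
  ys <- xy[, (dx + 1):d, drop = FALSE]
  rho <- knn_distances(xy, k = k, norm = "maximum", mode = "self-excluded")[, k]
  check_positive_distances(rho, "kraskov_mi (joint-space distances)")
  nx <- count_within(xs, xs, rho, norm = "maximum", mode = "self-excluded",
                     strict = TRUE)
  ny <- count_within(ys, ys, rho, norm = "maximum", mode = "self-excluded",
                     strict = TRUE)
  raw <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' k-NN density estimate
#'
#' `p_hat(x) = k / (N - 1) / (c1(d) * rho_k(x)^d)`, the density implied by the
#' k-th neighbor distance. Included for completeness and illustration: its
#' variance is large and it is not recommended as a plug-in for entropy.
#'
#' @param x sample matrix.
#' @param query query points; `NULL` (default) evaluates at the sample points
#'   themselves with self-exclusion.
#' @param k number of neighbors.
#' @return strictly positive density vector.
#' @export
knn_density <- function(x, query = NULL, k = 1L) {
  x <- as_sample_matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (is.null(query)) {
    rho <- knn_distances(x, k = k, norm = "euclidean",
                         mode = "self-excluded")[, k]
  } else {
    query <- as_sample_matrix(query, d = d)
    rho <- knn_distances(query, x, k = k, norm = "euclidean",
                         mode = "cross")[, k]
  }
  check_positive_distances(rho, "knn_density", jitter_allowed = FALSE)
  (k / (n - 1)) / (unit_ball_volume(d) * rho^d)
}
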