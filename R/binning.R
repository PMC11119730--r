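#' Bin-width rules of thumb
#'
#' One-dimensional histogram sizing rules. Sturges' rule is a bin *count*,
#' `ceiling(log2(n)) + 1`, converted to a width as `range/count`; Scott's rule
#' gives the width `3.49 * sd(x) * n^(-1/3)` and Freedman-Diaconis the width
#' `2 * IQR(x) * n^(-1/3)`, with the implied count `ceiling(range/width)`.
#'
#' @param x one-dimensional sample (`n >= 2`, non-constant).
#' @param rule `"sturges"`, `"scott"`, or `"fd"`.
#' @return a list with `width` and `n_bins`.
#' @export
bin_width <- function(x, rule = c("sturges", "scott", "fd")) {
  rule <- match.arg(rule)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("bin-width rules require n >= 2")
  rng <- diff(range(x))
  if (rng == 0) stop("cannot bin a constant sample (zero range)")
  if (rule == "sturges") {
    n_bins <- ceiling(log2(n)) + 1
    return(list(width = rng / n_bins, n_bins = as.integer(n_bins)))
  }
  if (rule == "scott") {
    s <- stats::sd(x)
    if (s == 0) stop("Scott's rule is undefined for zero standard deviation")
    w <- 3.49 * s * n^(-1 / 3)
  } else {
    iqr <- stats::IQR(x)
    if (iqr == 0) stop("Freedman-Diaconis rule is undefined for zero IQR")
    w <- 2 * iqr * n^(-1 / 3)
  }
  list(width = w, n_bins = as.integer(ceiling(rng / w)))
}

#' Build a per-dimension uniform binning grid
#'
#' The bin width is estimated independently for each dimension with the chosen
#' rule, so binning is uniform within but not across dimensions. Edges start
#' at each column's minimum; bins are half-open `[e_j, e_{j+1})` with the last
#' bin closed so the maximum is counted.
#'
#' @param x sample matrix.
#' @param rule bin-width rule, see [bin_width()].
#' @return an object of class `bin_grid` with per-dimension `edges`, `widths`,
#'   and `n_bins`.
#' @export
build_grid <- function(x, rule = c("sturges", "scott", "fd")) {
  rule <- match.arg(rule)
  x <- as_sample_matrix(x)
  edges <- vector("list", ncol(x))
  widths <- numeric(ncol(x))
  nb <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    bw <- bin_width(x[, j], rule)
    lo <- min(x[, j])
    if (rule == "sturges") {
      # exact cover of the range with the implied count
      edges[[j]] <- seq(lo, max(x[, j]), length.out = bw$n_bins + 1L)
    } else {
      edges[[j]] <- lo + bw$width * (0:bw$n_bins)
    }
    widths[j] <- bw$width
    nb[j] <- bw$n_bins
  }
  structure(list(edges = edges, widths = widths, n_bins = nb, rule = rule,
                 dim = ncol(x)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid (%s): %s bins, widths %s>\n", x$rule,
              paste(x$n_bins, collapse = "x"),
              paste(signif(x$widths, 4), collapse = ", ")))
  invisible(x)
}

# Per-point bin index tuple encoded as a single numeric code (products of bin
# counts stay well below 2^53 for the sizes used here); NA for points outside
# the grid range.
bin_codes <- function(x, grid) {
  x <- as_sample_matrix(x, d = grid$dim)
  code <- numeric(nrow(x))
  oob <- logical(nrow(x))
  for (j in seq_len(grid$dim)) {
    idx <- findInterval(x[, j], grid$edges[[j]], rightmost.closed = TRUE)
    oob <- oob | idx < 1L | idx > grid$n_bins[j]
    code <- code * grid$n_bins[j] + (idx - 1)
  }
  code[oob] <- NA_real_
  code
}

#' Sparse histogram density
#'
#' Counts the sample into the grid, storing only occupied bins (required for
#' high-dimensional grids, where the full cell array would be astronomically
#' large). The frequency estimate in a bin with count `c` is
#' `c / (n * prod(widths))`.
#'
#' @param x sample matrix.
#' @param grid a `bin_grid` (typically built from the same sample).
#' @return an object of class `hist_density` with `codes` (occupied bin
#'   codes), `counts`, total `n`, and the `grid`.
#' @export
hist_density <- function(x, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  x <- as_sample_matrix(x, d = grid$dim)
  code <- bin_codes(x, grid)
  inb <- code[!is.na(code)]
  r <- rle(sort(inb))
  structure(list(codes = r$values, counts = r$lengths, n = nrow(x),
                 n_in_grid = length(inb), grid = grid),
            class = "hist_density")
}

#' @export
print.hist_density <- function(x, ...) {
  cat(sprintf("<hist_density: %d occupied bins, n=%d>\n",
              length(x$codes), x$n))
  invisible(x)
}

#' Density of a histogram at query points
#'
#' @param hd a `hist_density`.
#' @param x query points.
#' @return density vector, `count / (n * bin volume)`; 0 in empty bins and
#'   outside the grid.
#' @export
hist_density_at <- function(hd, x) {
  stopifnot(inherits(hd, "hist_density"))
  code <- bin_codes(x, hd$grid)
  pos <- match(code, hd$codes)
  cnt <- ifelse(is.na(pos), 0, hd$counts[pos])
  cnt / (hd$n * prod(hd$grid$widths))
}

#' Histogram estimators of entropy, KL divergence, and mutual information
#'
#' `bin_entropy` computes the differential-entropy form of the quantized
#' entropy, `-sum(p_b log p_b) + log(prod(widths))` with `p_b = c_b / n` over
#' occupied bins (empty bins are excluded before summation; the bin-volume
#' term is the quantization correction that makes the estimate converge to
#' differential entropy as the widths shrink).
#'
#' `bin_kl` builds the grid from the `p` sample, maps the `q` sample onto the
#' same grid, and averages `log(f_hat/g_hat)` over the `p` points; bin-volume
#' factors cancel. Points of `p` whose bin holds no `q` mass are excluded from
#' the mean by default (their number is attached as attribute `n_excluded`);
#' with `empty_q = "infinity"` any such point makes the estimate `+Inf`,
#' reproducing the divergence seen on sparse high-dimensional grids.
#'
#' `bin_mi` bins the X block (leading `dx` columns) and the Y block on their
#' own marginal grids; the joint grid is their Cartesian product, which
#' guarantees the contingency-table marginals match the marginal histograms,
#' so the estimate is a discrete mutual information and is non-negative up to
#' floating error.
#'
#' @param x,x_p,x_q,xy sample matrices.
#' @param rule bin-width rule, see [bin_width()].
#' @param dx number of leading columns forming the X block.
#' @param empty_q handling of `p` points falling in `q`-empty bins.
#' @return estimate in nats.
#' @export
bin_entropy <- function(x, rule = c("sturges", "scott", "fd")) {
  rule <- match.arg(rule)
  x <- as_sample_matrix(x)
  grid <- build_grid(x, rule)
  hd <- hist_density(x, grid)
  p <- hd$counts / hd$n
  -sum(p * log(p)) + sum(log(grid$widths))
}

#' @rdname bin_entropy
#' @export
bin_kl <- function(x_p, x_q, rule = c("sturges", "scott", "fd"),
                   empty_q = c("exclude", "infinity")) {
  rule <- match.arg(rule)
  empty_q <- match.arg(empty_q)
  x_p <- as_sample_matrix(x_p)
  x_q <- as_sample_matrix(x_q, d = ncol(x_p))
  grid <- build_grid(x_p, rule)
  hp <- hist_density(x_p, grid)
  hq <- hist_density(x_q, grid)
  n <- nrow(x_p); m <- nrow(x_q)
  # per p-point counts in its own bin, under both histograms
  code <- bin_codes(x_p, grid)
  cp <- hp$counts[match(code, hp$codes)]
  posq <- match(code, hq$codes)
  cq <- ifelse(is.na(posq), 0, hq$counts[posq])
  bad <- cq == 0
  if (all(bad))
    stop("all ", n, " points of the p-sample fall in bins with no q mass: ",
         "total support mismatch between the samples")
  if (empty_q == "infinity" && any(bad)) {
    out <- Inf
    attr(out, "n_excluded") <- sum(bad)
    return(out)
  }
  vals <- log(cp[!bad] / n) - log(cq[!bad] / m)
  out <- mean(vals)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' @rdname bin_entropy
#' @export
bin_mi <- function(xy, dx, rule = c("sturges", "scott", "fd")) {
  rule <- match.arg(rule)
  xy <- as_sample_matrix(xy)
  d <- ncol(xy)
  if (!(dx >= 1 && dx < d)) stop("`dx` must satisfy 1 <= dx < d")
  xs <- xy[, seq_len(dx), drop = FALSE]
  ys <- xy[, (dx + 1):d, drop = FALSE]
  gx <- build_grid(xs, rule)
  gy <- build_grid(ys, rule)
  n <- nrow(xy)
  cx_code <- bin_codes(xs, gx)
  cy_code <- bin_codes(ys, gy)
  joint_code <- cx_code * prod(gy$n_bins) + cy_code
  count_of <- function(code) {
    r <- rle(sort(code))
    r$lengths[match(code, r$values)]
  }
  cxy <- count_of(joint_code)
  cx <- count_of(cx_code)
  cy <- count_of(cy_code)
  mean(log(cxy / n) - log(cx / n) - log(cy / n))
}

#' Averaged empirical quantile partition
#'
#' Draws `Nk` subsamples of size `NZ - 1` without replacement from the sample,
#' sorts each, and averages the sorted values across subsamples to estimate
#' the interior quantile locations; the endpoints are the full-sample minimum
#' and maximum.
#'
#' @param x one-dimensional sample.
#' @param NZ number of quantile intervals (`NZ >= 2`, `NZ - 1 <= n`).
#' @param Nk number of subsample repetitions.
#' @param seed integer seed for the subsampling.
#' @return an object of class `quantile_partition` with the ordered locations
#'   `Z` (length `NZ + 1`), `NZ`, and `Nk`.
#' @export
qs_quantiles <- function(x, NZ, Nk, seed) {
  x <- as.numeric(x)
  n <- length(x)
  if (NZ < 2) stop("`NZ` must be at least 2")
  if (NZ - 1 > n) stop("`NZ` - 1 exceeds the sample size")
  interior <- with_seed(seed, {
    acc <- numeric(NZ - 1)
    for (r in seq_len(Nk))
      acc <- acc + sort.int(x[sample.int(n, NZ - 1)])
    acc / Nk
  })
  structure(list(Z = c(min(x), interior, max(x)), NZ = as.integer(NZ),
                 Nk = as.integer(Nk)),
            class = "quantile_partition")
}

#' @export
print.quantile_partition <- function(x, ...) {
  cat(sprintf("<quantile_partition: NZ=%d, Nk=%d, range [%.4g, %.4g]>\n",
              x$NZ, x$Nk, x$Z[1], x$Z[length(x$Z)]))
  invisible(x)
}

#' Quantile Spacing entropy estimator
#'
#' One-dimensional entropy from the average log spacing between averaged
#' empirical quantiles: with the partition `Z` of [qs_quantiles()] and
#' spacings `Delta_j = z_j - z_{j-1}`, the estimate is
#' `mean(log(NZ * Delta_j))`, the entropy of the piecewise-constant density
#' that puts mass `1/NZ` on each interval. `NZ` defaults to 25% of the sample
#' size (rounded half away from zero, floored at 2) and `Nk` to 500.
#'
#' @param x one-dimensional sample (a one-column matrix is accepted).
#' @param alpha fraction of the sample size used as the quantile count.
#' @param Nk number of subsample repetitions.
#' @param seed integer seed for the subsampling.
#' @param partition optionally, a precomputed `quantile_partition` (then
#'   `alpha`, `Nk`, and `seed` are ignored).
#' @return entropy estimate in nats.
#' @export
qs_entropy <- function(x, alpha = 0.25, Nk = 500L, seed = 1L,
                       partition = NULL) {
  if (!is.null(dim(x)) && ncol(x) > 1)
    stop("the Quantile Spacing estimator is defined for one-dimensional ",
         "samples only")
  x <- as.numeric(x)
  if (is.null(partition)) {
    NZ <- max(2L, as.integer(round_half_up(alpha * length(x))))
    partition <- qs_quantiles(x, NZ, Nk, seed)
  }
  stopifnot(inherits(partition, "quantile_partition"))
  spac <- diff(partition$Z)
  mean(log(partition$NZ * spac))
}
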