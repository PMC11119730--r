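# Independent brute-force oracles used to validate the fast implementations.

# all-pairs k-th nearest neighbor distances
brute_knn <- function(query, reference, k, norm = "euclidean",
                      self_excluded = FALSE) {
  method <- if (norm == "euclidean") "euclidean" else "maximum"
  out <- matrix(NA_real_, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    if (norm == "euclidean") {
      d <- sqrt(colSums((t(reference) - query[i, ])^2))
    } else {
      d <- apply(abs(t(reference) - query[i, ]), 2, max)
    }
    if (self_excluded) d <- d[-i]
    out[i, ] <- sort(d)[seq_len(k)]
  }
  out
}

# first-principles 1-D histogram entropy: per-point frequency estimate, then
# the mean log plus the quantization correction (a per-point loop, a different
# computational path from the per-bin sum in bin_entropy)
brute_bin_entropy_1d <- function(x, rule) {
  bw <- bin_width(x, rule)
  edges <- if (rule == "sturges") {
    seq(min(x), max(x), length.out = bw$n_bins + 1L)
  } else {
    min(x) + bw$width * (0:bw$n_bins)
  }
  width <- if (rule == "sturges") diff(range(x)) / bw$n_bins else bw$width
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  acc <- 0
  for (i in seq_along(x)) {
    ci <- sum(idx == idx[i])
    acc <- acc + log(ci / length(x))
  }
  -acc / length(x) + log(width)
}
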