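# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# coerce input to an n x d numeric matrix and validate finiteness
as_sample_matrix <- function(x, d = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("sample contains non-finite entries")
  if (!is.null(d) && ncol(x) != d)
    stop(sprintf("sample has %d column(s), expected %d", ncol(x), d))
  x
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Adaptive 1-D quadrature over the true support via QUADPACK.
quad1 <- function(f, lower, upper, tol = 1.49e-8) {
  r <- stats::integrate(f, lower, upper, rel.tol = tol, abs.tol = tol,
                        subdivisions = 500L, stop.on.error = FALSE)
  if (!r$message %in% c("OK", "roundoff error was detected"))
    warning("quadrature did not fully converge: ", r$message,
            " (error estimate ", format(r$abs.error), ")")
  list(value = r$value, error = r$abs.error)
}

# Iterated adaptive 2-D quadrature; handles infinite limits in both
# coordinates. `f` takes (x1, x2) with x2 vectorized.
quad2 <- function(f, xlim, ylim, tol = 1.49e-8) {
  inner_tol <- tol
  outer <- function(xs) {
    vapply(xs, function(x1) {
      stats::integrate(function(x2) f(x1, x2), ylim[1], ylim[2],
                       rel.tol = inner_tol, abs.tol = inner_tol,
                       subdivisions = 500L, stop.on.error = FALSE)$value
    }, numeric(1))
  }
  r <- stats::integrate(outer, xlim[1], xlim[2], rel.tol = tol, abs.tol = tol,
                        subdivisions = 500L, stop.on.error = FALSE)
  if (!r$message %in% c("OK", "roundoff error was detected"))
    warning("quadrature did not fully converge: ", r$message,
            " (error estimate ", format(r$abs.error), ")")
  list(value = r$value, error = r$abs.error)
}

# x * log(x) with the 0 log 0 = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
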