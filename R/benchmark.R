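#' Estimator specifications for the sweep engine
#'
#' Lightweight descriptors pairing an estimator family with its
#' hyperparameters, used by [sweep_config()] and [run_sweep()].
#'
#' @param k number of neighbors (k-NN family).
#' @param rule bin-width rule (binning family).
#' @param mode `"resubstitution"` or `"integral"` (KDE family).
#' @param alpha,Nk Quantile Spacing hyperparameters.
#' @param n_max sample-size ceiling for KDE resubstitution.
#' @return an `estimator_spec` object.
#' @name estimator_spec
NULL

new_estimator_spec <- function(name, variant, params) {
  structure(list(name = name, variant = variant, params = params),
            class = "estimator_spec")
}

#' @rdname estimator_spec
#' @export
est_knn <- function(k = 1L)
  new_estimator_spec("knn", sprintf("k=%d", k), list(k = as.integer(k)))

#' @rdname estimator_spec
#' @export
est_binning <- function(rule = "scott")
  new_estimator_spec("binning", sprintf("rule=%s", rule), list(rule = rule))

#' @rdname estimator_spec
#' @export
est_kde <- function(mode = "resubstitution", n_max = 25000L)
  new_estimator_spec("kde", sprintf("mode=%s", mode),
                     list(mode = mode, n_max = as.integer(n_max)))

#' @rdname estimator_spec
#' @export
est_qs <- function(alpha = 0.25, Nk = 500L)
  new_estimator_spec("qs", sprintf("alpha=%g,Nk=%d", alpha, Nk),
                     list(alpha = alpha, Nk = as.integer(Nk)))

#' @export
print.estimator_spec <- function(x, ...) {
  cat(sprintf("<estimator %s (%s)>\n", x$name, x$variant))
  invisible(x)
}

#' Configure an estimation sweep
#'
#' A sweep evaluates each requested estimator on repeated seeded samples of
#' each size, for each requested quantity of one benchmark case. Within a
#' `(size, seed)` cell every estimator sees the same sample, so estimator
#' comparisons are paired. The default size ladder spans 100 to 100,000
#' observations; the seed count is freely reducible from the 300 used for
#' full confidence bands.
#'
#' @param case a `benchmark_case` from [builtin_cases()], or its integer id.
#' @param quantities subset of the case's quantities.
#' @param estimators list of [estimator_spec] objects.
#' @param sizes sample sizes.
#' @param seeds integer seeds (one replicate per seed).
#' @return a `sweep_config` object.
#' @export
sweep_config <- function(case, quantities = NULL, estimators,
                         sizes = c(100, 500, 1000, 5000, 10000, 50000, 100000),
                         seeds = 1:20) {
  if (is.numeric(case)) case <- builtin_cases()[[case]]
  stopifnot(inherits(case, "benchmark_case"))
  if (is.null(quantities)) quantities <- case$quantities
  bad <- setdiff(quantities, case$quantities)
  if (length(bad))
    stop("quantity ", paste(bad, collapse = ", "), " does not apply to case ",
         case$id, " (", case$label, ")")
  if (inherits(estimators, "estimator_spec")) estimators <- list(estimators)
  stopifnot(all(vapply(estimators, inherits, logical(1), "estimator_spec")))
  for (est in estimators) {
    if (est$name == "qs" &&
        (case$p$dim > 1 || !all(quantities == "entropy")))
      stop("the Quantile Spacing estimator supports 1-D entropy only")
  }
  if (length(seeds) < 1) stop("at least one seed is required")
  structure(list(case = case, quantities = quantities,
                 estimators = estimators, sizes = as.integer(sizes),
                 seeds = as.integer(seeds)),
            class = "sweep_config")
}

# dispatch one estimator on one cell; returns list(value, raw, excluded)
run_estimator <- function(est, quantity, xp, xq, dx, seed) {
  p <- est$params
  val <- switch(paste(est$name, quantity, sep = "."),
    knn.entropy = knn_entropy(xp, k = p$k),
    knn.kl = knn_kl(xp, xq, k = p$k),
    knn.mi = kraskov_mi(xp, dx, k = p$k),
    binning.entropy = bin_entropy(xp, rule = p$rule),
    binning.kl = bin_kl(xp, xq, rule = p$rule),
    binning.mi = bin_mi(xp, dx, rule = p$rule),
    kde.entropy = kde_entropy(xp, mode = p$mode, n_max = p$n_max),
    kde.kl = kde_kl(xp, xq, mode = p$mode, n_max = p$n_max),
    kde.mi = kde_mi(xp, dx, mode = p$mode, n_max = p$n_max),
    qs.entropy = qs_entropy(xp, alpha = p$alpha, Nk = p$Nk,
                            seed = seed + 900000L),
    stop("estimator ", est$name, " does not support quantity ", quantity))
  list(value = as.numeric(val),
       raw = if (!is.null(attr(val, "raw"))) attr(val, "raw") else
         as.numeric(val),
       excluded = if (!is.null(attr(val, "n_excluded")))
         attr(val, "n_excluded") else NA_integer_)
}

#' Run an estimation sweep
#'
#' Draws one `p` sample per `(size, seed)` cell (and one `q` sample, from the
#' stream `seed + 500000`, when KL divergence is requested), applies every
#' estimator to the same data, and returns one record per
#' `estimator x quantity x size x seed`. Estimator failures are recorded with
#' their message (`status = "error"`) and the sweep continues. The output is
#' deterministic given the configuration.
#'
#' @param config a [sweep_config()].
#' @param verbose print per-cell progress to stderr.
#' @return a data.frame of estimate records with columns `case`, `quantity`,
#'   `estimator`, `variant`, `n`, `seed`, `value`, `raw`, `excluded`,
#'   `status`, `message`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  case <- config$case
  need_q <- "kl" %in% config$quantities
  rows <- list()
  for (n in config$sizes) {
    for (seed in config$seeds) {
      xp <- draw_sample(case$p, n, seed)
      xq <- if (need_q) draw_sample(case$q, n, seed + 500000L) else NULL
      for (quantity in config$quantities) {
        for (est in config$estimators) {
          res <- tryCatch(
            c(run_estimator(est, quantity, xp, xq, case$mi_split, seed),
              list(status = "ok", message = "")),
            error = function(e)
              list(value = NA_real_, raw = NA_real_, excluded = NA_integer_,
                   status = "error", message = conditionMessage(e)))
          rows[[length(rows) + 1L]] <- data.frame(
            case = case$id, quantity = quantity, estimator = est$name,
            variant = est$variant, n = n, seed = seed,
            value = res$value, raw = res$raw, excluded = res$excluded,
            status = res$status, message = res$message,
            stringsAsFactors = FALSE)
          if (verbose)
            message(sprintf("case %d %s %s/%s n=%d seed=%d: %s", case$id,
                            quantity, est$name, est$variant, n, seed,
                            res$status))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate sweep records into an evaluation table
#'
#' Groups records by `(case, quantity, estimator, variant, n)` and reports the
#' mean estimate, the 2.5th and 97.5th percentiles across seeds, the reference
#' value, and the signed relative error of the mean,
#' `(mean - reference) / |reference|`. Cells whose reference is 0 report the
#' absolute error of the mean instead and are flagged in `error_type`.
#'
#' @param records a record data.frame from [run_sweep()].
#' @param references named numeric vector of reference values keyed by
#'   `"case.quantity"` (e.g. `"2.entropy"`); computed from the built-in case
#'   registry via [case_reference()] when omitted.
#' @return a data.frame with one row per cell.
#' @export
summarize_records <- function(records, references = NULL) {
  records <- records[records$status == "ok" & is.finite(records$value), ,
                     drop = FALSE]
  if (!nrow(records)) stop("no successful records to summarize")
  if (is.null(references)) {
    keys <- unique(paste(records$case, records$quantity, sep = "."))
    cases <- builtin_cases()
    references <- vapply(keys, function(k) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      case_reference(cases[[as.integer(parts[1])]], parts[2])$value
    }, numeric(1))
  }
  grp <- interaction(records$case, records$quantity, records$estimator,
                     records$variant, records$n, drop = TRUE)
  out <- lapply(split(records, grp), function(g) {
    key <- paste(g$case[1], g$quantity[1], sep = ".")
    ref <- unname(references[key])
    if (is.na(ref)) stop("missing reference for cell ", key)
    m <- mean(g$value)
    zero_ref <- ref == 0
    data.frame(case = g$case[1], quantity = g$quantity[1],
               estimator = g$estimator[1], variant = g$variant[1],
               n = g$n[1], n_seeds = nrow(g), mean = m,
               p2.5 = unname(stats::quantile(g$value, 0.025)),
               p97.5 = unname(stats::quantile(g$value, 0.975)),
               reference = ref,
               rel_error = if (zero_ref) m - ref else (m - ref) / abs(ref),
               error_type = if (zero_ref) "absolute" else "relative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$case, out$quantity, out$estimator, out$variant, out$n), ]
  rownames(out) <- NULL
  out
}

#' Full-precision CSV round-trip for sweep records
#'
#' Doubles are written with 17 significant digits so that
#' write-read-summarize reproduces the in-memory summary bit for bit.
#'
#' @param records record data.frame.
#' @param file path.
#' @return `read_records` returns the record data.frame.
#' @export
write_records <- function(records, file) {
  out <- records
  for (col in c("value", "raw"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname write_records
#' @export
read_records <- function(file) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(value = "character",
                                        raw = "character"))
  rec$value <- as.numeric(rec$value)
  rec$raw <- as.numeric(rec$raw)
  rec$message <- as.character(rec$message)
  rec$message[is.na(rec$message)] <- ""
  rec
}
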