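# GC-matched null model. Control windows are drawn from the unbroken pool,
# one per reference (broken) window, each matched on GC content; repeating
# the draw builds an empirical null distribution for any per-window-set
# summary.

.check_pool <- function(pool) {
  if (any(pool$n_breaks != 0L)) .stopf("pool must contain only unbroken windows")
  if (any(!pool$full)) .stopf("pool must contain only full-length windows")
  if (any(is.na(pool$gc))) .stopf("pool must not contain all-N (undefined GC) windows")
  invisible(TRUE)
}

#' Draw one GC-matched control window set
#'
#' For every reference window, one control is drawn uniformly at random —
#' without replacement within the sample — from the pool members whose GC
#' fraction lies within `tolerance` of that reference window's GC.
#' Deterministic given `seed`.
#'
#' @param pool candidate control windows (unbroken, full-length, defined
#'   GC), a data frame from [count_features_in_windows()].
#' @param reference the windows to match (e.g. the broken class).
#' @param tolerance absolute GC difference allowed.
#' @param seed integer seed for this draw.
#' @return an object of class `null_sample`: pool row indices, the selected
#'   windows, target and achieved GC, seed and tolerance.
#' @export
sample_gc_matched <- function(pool, reference, tolerance = 0.02, seed = 1L) {
  .check_pool(pool)
  if (nrow(reference) == 0L) .stopf("empty reference set")
  if (nrow(pool) < nrow(reference)) {
    .stopf("pool (%d) smaller than reference (%d)", nrow(pool), nrow(reference))
  }
  ref_gc <- reference$gc
  if (any(is.na(ref_gc))) .stopf("reference windows must have defined GC")
  picked <- integer(nrow(reference))
  used <- logical(nrow(pool))
  with_seed(seed, {
    for (i in seq_along(ref_gc)) {
      elig <- which(!used & abs(pool$gc - ref_gc[i]) <= tolerance + 1e-12)
      if (length(elig) == 0L) {
        .stopf("no unbroken window within GC tolerance %.3f of reference %s:%d (GC %.3f)",
               tolerance, reference$chrom[i], reference$start[i], ref_gc[i])
      }
      sel <- elig[sample.int(length(elig), 1L)]
      picked[i] <- sel
      used[sel] <- TRUE
    }
  })
  achieved <- pool$gc[picked]
  stopifnot(all(abs(achieved - ref_gc) <= tolerance + 1e-12))
  structure(list(
    index = picked,
    windows = pool[picked, , drop = FALSE],
    reference_gc = ref_gc,
    achieved_gc = achieved,
    tolerance = tolerance,
    seed = as.integer(seed)
  ), class = "null_sample")
}

#' Default null-model summarizer
#'
#' Percentage of windows containing a CpG, percentage containing a
#' CpG-nonamer pair, and the mean nonamer count per window.
#'
#' @param w a window-stats data frame.
#' @return named numeric vector.
#' @export
null_summary_default <- function(w) {
  c(pct_with_cpg = 100 * mean(w$has_cpg),
    pct_with_pair = 100 * mean(w$has_pair),
    mean_nonamers = mean(w$n_nonamers))
}

#' Iterated GC-matched null distribution
#'
#' Repeats [sample_gc_matched()] `iterations` times — sampling without
#' replacement within an iteration, independently across iterations — and
#' applies `summarizer` to each sampled window set. Iteration `i` uses the
#' child seed `child_seed(seed, i)`, so the whole run is bit-reproducible
#' from the master seed and iterations could be regenerated independently.
#'
#' @param pool,reference,tolerance as in [sample_gc_matched()].
#' @param iterations number of iterations (>= 1).
#' @param seed master seed.
#' @param summarizer function mapping a window data frame to a named
#'   numeric vector.
#' @return an object of class `null_distribution`: the iterations-by-summary
#'   `values` matrix plus per-summary min/max/percentiles.
#' @export
iterate_null <- function(pool, reference, iterations = 1000L, seed = 1L,
                         summarizer = null_summary_default,
                         tolerance = 0.02) {
  if (!.is_count(iterations) || iterations < 1) .stopf("`iterations` must be >= 1")
  .check_pool(pool)
  first <- summarizer(pool[0, , drop = FALSE])
  k <- length(first)
  values <- matrix(NA_real_, nrow = iterations, ncol = k,
                   dimnames = list(NULL, names(first)))
  for (i in seq_len(iterations)) {
    s <- sample_gc_matched(pool, reference, tolerance = tolerance,
                           seed = child_seed(seed, i))
    values[i, ] <- summarizer(s$windows)
  }
  qs <- apply(values, 2L, quantile,
              probs = c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1), na.rm = TRUE)
  structure(list(values = values, iterations = as.integer(iterations),
                 seed = as.integer(seed), tolerance = tolerance,
                 quantiles = qs),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d iterations (seed %d)\n",
              x$iterations, x$seed))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' Empirical p-value against a null distribution
#'
#' Add-one convention: `(1 + #{null at least as extreme}) / (1 + B)`, which
#' can never return zero. Two-sided doubles the smaller tail, capped at 1.
#'
#' @param observed observed summary value.
#' @param null numeric vector of null values, or a [iterate_null()] result
#'   (then `column` selects the summary).
#' @param side `"upper"`, `"lower"` or `"two_sided"`.
#' @param column summary column when `null` is a `null_distribution`.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' empirical_p(10, rnorm(99), side = "upper")
empirical_p <- function(observed, null, side = c("upper", "lower", "two_sided"),
                        column = 1L) {
  side <- match.arg(side)
  if (inherits(null, "null_distribution")) null <- null$values[, column]
  b <- length(null)
  if (b == 0L) .stopf("empty null distribution")
  up <- (1 + sum(null >= observed)) / (1 + b)
  lo <- (1 + sum(null <= observed)) / (1 + b)
  switch(side,
         upper = up,
         lower = lo,
         two_sided = min(1, 2 * min(up, lo)))
}

#' Export a null distribution as TSV
#' @param null a `null_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_tsv <- function(null, path) {
  df <- data.frame(iteration = seq_len(nrow(null$values)), null$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
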