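# Stratification of breakpoints and their co-occurrence signature by
# promoter regions, Giemsa-derived chromatin class, and patient cohort.

.STAIN_MAP <- c(gneg = "euchromatin",
                gpos25 = "heterochromatin", gpos50 = "heterochromatin",
                gpos75 = "heterochromatin", gpos100 = "heterochromatin",
                gvar = "heterochromatin",
                acen = "excluded", stalk = "excluded")

#' Map gieStain labels to chromatin classes
#'
#' `gneg` is euchromatin; `gpos25/50/75/100` and `gvar` are
#' heterochromatin; `acen` and `stalk` (centromeres, rDNA stalks) are
#' excluded from either class.
#'
#' @param label character vector of gieStain values.
#' @return character vector of `"euchromatin"`, `"heterochromatin"`,
#'   `"excluded"`.
#' @export
#' @examples
#' stain_to_class(c("gneg", "gpos100"))
stain_to_class <- function(label) {
  out <- .STAIN_MAP[label]
  if (any(is.na(out))) {
    .stopf("unrecognized gieStain label: '%s'", label[is.na(out)][1])
  }
  unname(out)
}

# per-break minimal pair gap <= pair_gap_max within the standard radius
.break_has_pair <- function(breaks, hits, cpgs, config) {
  n <- nrow(breaks)
  out <- logical(n)
  hs_by <- split(hits$start, hits$chrom)
  cs_by <- split(cpgs$start, cpgs$chrom)
  for (i in seq_len(n)) {
    g <- .pair_gaps_at(breaks$position[i],
                       hs_by[[breaks$chrom[i]]] %||% integer(0),
                       cs_by[[breaks$chrom[i]]] %||% integer(0),
                       config$breakpoint_radius)
    out[i] <- !is.null(g) && min(g) <= config$pair_gap_max
  }
  out
}

#' Breakpoint distribution across chromatin classes
#'
#' Each breakpoint is assigned to euchromatin or heterochromatin via the
#' cytoband it falls in ([stain_to_class()]); breaks in excluded bands
#' (`acen`, `stalk`) or outside any band are counted separately and do not
#' enter the contrast. Per class the function reports the break count, its
#' fraction of classified breaks, and the fraction of breaks carrying a
#' CpG-nonamer pair (gap at most `pair_gap_max` within the proximity
#' radius), plus the class-by-pair chi-square.
#'
#' @param breaks a [breakpoint_table()].
#' @param hits,cpgs feature tables.
#' @param cytobands a [read_cytoband()] region set.
#' @param config an [analysis_config()].
#' @return an object of class `chromatin_breakdown`.
#' @export
chromatin_breakdown <- function(breaks, hits, cpgs, cytobands,
                                config = analysis_config()) {
  stopifnot(inherits(cytobands, "region_set"))
  if (nrow(cytobands) == 0L) .stopf("empty cytoband set")
  if (nrow(breaks) == 0L) .stopf("no breakpoints")
  cls <- rep("uncovered", nrow(breaks))
  band_class <- stain_to_class(cytobands$label)
  for (wanted in c("euchromatin", "heterochromatin", "excluded")) {
    sub <- cytobands[band_class == wanted, , drop = FALSE]
    if (nrow(sub) == 0L) next
    inside <- .positions_in_regions(sub, breaks$chrom, breaks$position)
    cls[inside] <- wanted
  }
  has_pair <- .break_has_pair(breaks, hits, cpgs, config)
  classified <- cls %in% c("euchromatin", "heterochromatin")
  n_classified <- sum(classified)
  strata <- lapply(c(euchromatin = "euchromatin",
                     heterochromatin = "heterochromatin"), function(k) {
    sel <- cls == k
    list(n_breaks = sum(sel),
         fraction = if (n_classified) sum(sel) / n_classified else NA_real_,
         n_with_pair = sum(has_pair & sel),
         fraction_with_pair = if (sum(sel)) mean(has_pair[sel]) else NA_real_)
  })
  tab <- matrix(c(strata$euchromatin$n_with_pair,
                  strata$euchromatin$n_breaks - strata$euchromatin$n_with_pair,
                  strata$heterochromatin$n_with_pair,
                  strata$heterochromatin$n_breaks - strata$heterochromatin$n_with_pair),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("euchromatin", "heterochromatin"),
                                c("pair", "no_pair")))
  chisq <- tryCatch(chi_square_2x2(tab), error = function(e) {
    list(statistic = NA_real_, p.value = NA_real_, df = 1L, table = tab,
         yates = FALSE, note = conditionMessage(e))
  })
  structure(list(
    strata = strata,
    n_classified = n_classified,
    n_excluded = sum(cls == "excluded"),
    n_uncovered = sum(cls == "uncovered"),
    pair_table = tab,
    chisq = chisq,
    per_break = data.frame(chrom = breaks$chrom, position = breaks$position,
                           class = cls, has_pair = has_pair)
  ), class = "chromatin_breakdown")
}

#' @export
print.chromatin_breakdown <- function(x, ...) {
  e <- x$strata$euchromatin; h <- x$strata$heterochromatin
  cat(sprintf(
    "<chromatin_breakdown> %d classified breaks (%d excluded, %d uncovered)\n  euchromatin:     %d (%.0f%%), pair fraction %.2f\n  heterochromatin: %d (%.0f%%), pair fraction %.2f\n",
    x$n_classified, x$n_excluded, x$n_uncovered,
    e$n_breaks, 100 * e$fraction, e$fraction_with_pair,
    h$n_breaks, 100 * h$fraction, h$fraction_with_pair))
  invisible(x)
}

#' Breakpoint distribution across promoter regions
#'
#' A break is "in promoter" when its position lies inside a promoter
#' interval; among those, the fraction carrying CpG-nonamer clustering
#' (pair gap at most `pair_gap_max` within the radius) is reported.
#'
#' @param breaks a [breakpoint_table()].
#' @param promoters a promoter [region_set()].
#' @param hits,cpgs feature tables.
#' @param config an [analysis_config()].
#' @return list with `n_breaks`, `n_in_promoters`, `fraction`,
#'   `n_in_promoters_with_pair`, `fraction_with_pair`.
#' @export
promoter_breakdown <- function(breaks, promoters, hits, cpgs,
                               config = analysis_config()) {
  stopifnot(inherits(promoters, "region_set"))
  inside <- .positions_in_regions(promoters, breaks$chrom, breaks$position)
  n_in <- sum(inside)
  with_pair <- if (n_in) {
    .break_has_pair(breaks[inside, , drop = FALSE], hits, cpgs, config)
  } else logical(0)
  list(n_breaks = nrow(breaks),
       n_in_promoters = n_in,
       fraction = if (nrow(breaks)) n_in / nrow(breaks) else NA_real_,
       n_in_promoters_with_pair = sum(with_pair),
       fraction_with_pair = if (n_in) mean(with_pair) else NA_real_)
}

#' Compare broken-window feature densities between cohorts
#'
#' Takes the broken windows of each cohort (windows counted against that
#' cohort's breakpoints alone) and reports per-cohort means and totals of
#' nonamers, CpGs and breaks per window, pairwise ratios relative to the
#' first cohort, and a chi-square test on the pooled count table
#' (cohort x feature totals).
#'
#' @param stats_by_cohort named list of window-stats data frames, one per
#'   cohort, each containing that cohort's broken windows.
#' @return an object of class `cohort_comparison`.
#' @export
cohort_compare <- function(stats_by_cohort) {
  if (length(stats_by_cohort) < 2L) .stopf("need at least two cohorts")
  empty <- vapply(stats_by_cohort, function(w) nrow(w) == 0L, logical(1))
  if (any(empty)) {
    .stopf("cohort '%s' has zero broken windows", names(stats_by_cohort)[empty][1])
  }
  means <- t(vapply(stats_by_cohort, function(w) {
    c(n_windows = nrow(w),
      mean_nonamers = mean(w$n_nonamers),
      mean_cpgs = mean(w$n_cpgs),
      mean_breaks = mean(w$n_breaks),
      total_nonamers = sum(w$n_nonamers),
      total_cpgs = sum(w$n_cpgs),
      total_breaks = sum(w$n_breaks))
  }, numeric(7)))
  ref <- means[1L, ]
  ratios <- sweep(means[, c("mean_nonamers", "mean_cpgs", "mean_breaks"),
                        drop = FALSE], 2L,
                  ref[c("mean_nonamers", "mean_cpgs", "mean_breaks")], "/")
  counts <- means[, c("total_nonamers", "total_cpgs", "total_breaks"),
                  drop = FALSE]
  chisq <- tryCatch(suppressWarnings(chisq.test(counts)),
                    error = function(e) NULL)
  structure(list(
    summary = as.data.frame(means),
    ratios_vs_first = as.data.frame(ratios),
    pooled_counts = counts,
    chisq_statistic = if (is.null(chisq)) NA_real_ else unname(chisq$statistic),
    chisq_p = if (is.null(chisq)) NA_real_ else chisq$p.value
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  print(round(x$summary, 2))
  cat("ratios vs first cohort:\n")
  print(round(x$ratios_vs_first, 2))
  invisible(x)
}
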