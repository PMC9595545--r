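# Co-occurrence statistics: proximity fractions around breakpoints,
# CpG-to-nonamer distance distributions, and the contingency/rank/means
# contrasts between broken and control windows.

# Count features with interval [s, s+w) overlapping [p - r, p + r + 1)
# for each break position p. Features and breaks restricted to one chrom.
.n_near <- function(pos, feat_starts, width, radius) {
  if (length(feat_starts) == 0L) return(integer(length(pos)))
  fs <- sort(feat_starts)
  # overlap iff s > p - radius - width and s <= p + radius
  findInterval(pos + radius, fs) - findInterval(pos - radius - width, fs)
}

#' Proximity of nonamers and CpGs to breakpoints
#'
#' For each breakpoint `p`, a feature counts as adjacent when its interval
#' overlaps the symmetric window `[p - radius, p + radius + 1)`. Reports
#' how many breakpoints have at least one adjacent nonamer, at least one
#' adjacent CpG, and both.
#'
#' @param breaks a [breakpoint_table()] (typically deduplicated).
#' @param hits nonamer hits from [scan_cryptic_nonamers()].
#' @param cpgs CpG sites from [scan_cpg()].
#' @param radius proximity radius in bases.
#' @return an object of class `proximity_summary`: counts, fractions and
#'   the per-break indicator table.
#' @export
proximity_summary <- function(breaks, hits, cpgs, radius = 100L) {
  stopifnot(inherits(breaks, "breakpoint_table"), radius > 0)
  n <- nrow(breaks)
  near_hit <- logical(n)
  near_cpg <- logical(n)
  for (ch in unique(breaks$chrom)) {
    sel <- breaks$chrom == ch
    p <- breaks$position[sel]
    near_hit[sel] <- .n_near(p, hits$start[hits$chrom == ch], 9L, radius) > 0L
    near_cpg[sel] <- .n_near(p, cpgs$start[cpgs$chrom == ch], 2L, radius) > 0L
  }
  per_break <- data.frame(chrom = breaks$chrom, position = breaks$position,
                          near_nonamer = near_hit, near_cpg = near_cpg,
                          near_both = near_hit & near_cpg)
  structure(list(
    n_breakpoints = n,
    n_with_nonamer = sum(near_hit),
    n_with_cpg = sum(near_cpg),
    n_with_both = sum(near_hit & near_cpg),
    fraction_with_nonamer = if (n) mean(near_hit) else NA_real_,
    fraction_with_cpg = if (n) mean(near_cpg) else NA_real_,
    fraction_with_both = if (n) mean(near_hit & near_cpg) else NA_real_,
    radius = as.integer(radius),
    per_break = per_break
  ), class = "proximity_summary")
}

#' @export
print.proximity_summary <- function(x, ...) {
  cat(sprintf(
    "<proximity_summary> %d breakpoints, radius %d bp\n  with nonamer: %d (%.1f%%)\n  with CpG:     %d (%.1f%%)\n  with both:    %d (%.1f%%)\n",
    x$n_breakpoints, x$radius,
    x$n_with_nonamer, 100 * x$fraction_with_nonamer,
    x$n_with_cpg, 100 * x$fraction_with_cpg,
    x$n_with_both, 100 * x$fraction_with_both))
  invisible(x)
}

# All (CpG, hit) pair gaps near one breakpoint; NULL if no pair.
.pair_gaps_at <- function(position, hit_starts, cpg_starts, radius) {
  hs <- hit_starts[hit_starts > position - radius - 9L &
                     hit_starts <= position + radius]
  cs <- cpg_starts[cpg_starts > position - radius - 2L &
                     cpg_starts <= position + radius]
  if (length(hs) == 0L || length(cs) == 0L) return(NULL)
  g <- outer(cs, hs, function(c, h) pmax(0L, pmax(c, h) - pmin(c + 2L, h + 9L)))
  as.vector(g)
}

#' Minimal CpG-to-nonamer gap near a breakpoint
#'
#' Over all (CpG, nonamer) pairs in which both features overlap the
#' breakpoint's proximity window, returns the minimal edge-to-edge gap in
#' bases; overlapping features have gap 0. The gap is symmetric in feature
#' order. `NA` when no such pair exists.
#'
#' @param chrom,position breakpoint coordinate (0-based).
#' @param hits,cpgs feature tables.
#' @param radius proximity radius in bases.
#' @return integer gap or `NA`.
#' @export
#' @examples
#' hits <- data.frame(chrom = "c", start = 20L, end = 29L,
#'                    strand = "+", mismatches = 0L, observed = "ACAAAAACC")
#' cpgs <- data.frame(chrom = "c", start = 10L, end = 12L)
#' nearest_pair_gap("c", 15L, hits, cpgs, radius = 100)
nearest_pair_gap <- function(chrom, position, hits, cpgs, radius = 100L) {
  stopifnot(radius > 0)
  g <- .pair_gaps_at(position, hits$start[hits$chrom == chrom],
                     cpgs$start[cpgs$chrom == chrom], radius)
  if (is.null(g)) NA_integer_ else as.integer(min(g))
}

#' CpG-to-nonamer distance distribution around breakpoints
#'
#' Computes the minimal pair gap per breakpoint (see [nearest_pair_gap()]),
#' overall and restricted to nonamers of mismatch class 2, 3 and 4, plus
#' summary fractions. Because "73% of pairs under 50 bp" can be read per
#' breakpoint or per pair, both denominators are reported.
#'
#' @param breaks a [breakpoint_table()].
#' @param hits,cpgs feature tables.
#' @param config an [analysis_config()]; supplies `pair_gap_max`.
#' @param radius proximity radius (defaults to the config's
#'   `breakpoint_radius`; widen it to measure distant control pairs).
#' @return an object of class `distance_summary`.
#' @export
distance_distribution <- function(breaks, hits, cpgs,
                                  config = analysis_config(),
                                  radius = NULL) {
  radius <- radius %||% config$breakpoint_radius
  n <- nrow(breaks)
  gap <- rep(NA_integer_, n)
  gap_by_mm <- matrix(NA_integer_, nrow = n, ncol = 3,
                      dimnames = list(NULL, c("mm2", "mm3", "mm4")))
  all_pair_gaps <- integer(0)
  hs_by_chrom <- split(hits$start, hits$chrom)
  hs_mm_by_chrom <- split(hits[, c("start", "mismatches")], hits$chrom)
  cs_by_chrom <- split(cpgs$start, cpgs$chrom)
  for (i in seq_len(n)) {
    ch <- breaks$chrom[i]
    p <- breaks$position[i]
    cs <- cs_by_chrom[[ch]] %||% integer(0)
    hs_all <- hs_by_chrom[[ch]] %||% integer(0)
    g <- .pair_gaps_at(p, hs_all, cs, radius)
    if (!is.null(g)) {
      gap[i] <- min(g)
      all_pair_gaps <- c(all_pair_gaps, g)
    }
    hmm <- hs_mm_by_chrom[[ch]]
    for (k in 2:4) {
      hk <- if (is.null(hmm)) integer(0) else hmm$start[hmm$mismatches == k]
      gk <- .pair_gaps_at(p, hk, cs, radius)
      if (!is.null(gk)) gap_by_mm[i, k - 1L] <- min(gk)
    }
  }
  per_break <- data.frame(chrom = breaks$chrom, position = breaks$position,
                          gap = gap, gap_by_mm)
  got <- gap[!is.na(gap)]
  structure(list(
    per_break = per_break,
    n_breakpoints = n,
    n_with_pair = length(got),
    median_gap = if (length(got)) median(got) else NA_real_,
    frac_breaks_lt50 = if (length(got)) mean(got < 50) else NA_real_,
    frac_pairs_lt50 = if (length(all_pair_gaps)) {
      mean(all_pair_gaps < 50)
    } else NA_real_,
    frac_le_pair_gap_max = if (length(got)) {
      mean(got <= config$pair_gap_max)
    } else NA_real_,
    by_mismatch = vapply(colnames(gap_by_mm), function(cn) {
      v <- gap_by_mm[, cn]
      median(v[!is.na(v)])
    }, numeric(1)),
    radius = as.integer(radius),
    pair_gap_max = config$pair_gap_max,
    empty = length(got) == 0L
  ), class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  if (x$empty) {
    cat("<distance_summary> no CpG-nonamer pair near any breakpoint\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<distance_summary> %d/%d breakpoints with a pair (radius %d bp)\n  median gap %.0f bp; %.0f%% of breaks < 50 bp; %.0f%% <= %d bp\n",
    x$n_with_pair, x$n_breakpoints, x$radius, x$median_gap,
    100 * x$frac_breaks_lt50, 100 * x$frac_le_pair_gap_max, x$pair_gap_max))
  invisible(x)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson statistic in closed form,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with 1 degree of freedom.
#' With `yates = TRUE` the absolute difference `|ad - bc|` is reduced by
#' `N/2` (clamped at zero) before squaring. The default applies no
#' correction.
#'
#' @param x a 2x2 matrix, or a length-4 vector `(a, b, c, d)` read
#'   row-wise.
#' @param yates apply Yates continuity correction.
#' @return list with `statistic`, `p.value`, `df` (always 1), `table`,
#'   `yates`.
#' @export
#' @examples
#' chi_square_2x2(c(20, 10, 10, 20))
chi_square_2x2 <- function(x, yates = FALSE) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    tab <- x
  } else {
    stopifnot(length(x) == 4L)
    tab <- matrix(x, nrow = 2L, byrow = TRUE)
  }
  if (any(tab < 0) || any(is.na(tab))) .stopf("cells must be non-negative")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) .stopf("zero marginal: chi-square undefined")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / prod(marg)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, table = tab, yates = yates)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-sided
#' p-value uses the exact distribution (via the null Wilcoxon distribution)
#' when both samples have at most 8 observations and no ties are present,
#' and otherwise a normal approximation with tie correction (no continuity
#' correction). When the tie-corrected variance is zero the samples are
#' indistinguishable and p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (for `x`), `p.value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) .stopf("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && nx <= 8L && ny <= 8L) {
    p <- if (u > nx * ny / 2) {
      1 - pwilcox(u - 1, nx, ny)
    } else {
      pwilcox(u, nx, ny)
    }
    p <- min(2 * p, 1)
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = u, p.value = p, method = method)
}

#' Two-sample t test
#'
#' Welch by default (the pooled-variance Student variant via
#' `welch = FALSE`). Errors when both samples have zero variance, since no
#' statistic is defined there.
#'
#' @param x,y numeric samples of size at least 2.
#' @param welch use the Welch unequal-variance statistic.
#' @return list with `t`, `p.value`, `df`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  if (length(x) < 2L || length(y) < 2L) .stopf("each sample needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    .stopf("zero variance in both samples: t statistic undefined")
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}

.class_summary <- function(w) {
  list(n = nrow(w),
       mean_nonamers = mean(w$n_nonamers),
       median_nonamers = median(w$n_nonamers),
       total_nonamers = sum(w$n_nonamers),
       mean_cpgs = mean(w$n_cpgs),
       median_cpgs = median(w$n_cpgs),
       total_cpgs = sum(w$n_cpgs),
       mean_breaks = mean(w$n_breaks),
       total_breaks = sum(w$n_breaks),
       pct_with_cpg = 100 * mean(w$has_cpg),
       pct_with_pair = 100 * mean(w$has_pair))
}

#' Contrast broken windows against control windows
#'
#' Reports per-class means, medians and totals of nonamer, CpG and break
#' counts, the percentage of windows containing CpGs and containing
#' CpG-nonamer pairs, a chi-square test on the pair-presence by class 2x2
#' table, a Mann-Whitney test on per-window nonamer counts, and a Welch t
#' test on the same counts. Raw p-values are primary; Benjamini-Hochberg
#' adjusted values are attached since three contrasts are emitted.
#'
#' @param classification a [classify_windows()] result; its `broken` class
#'   is contrasted.
#' @param controls a data frame of control windows (e.g. the GC-matched
#'   sample from [sample_gc_matched()], or all unbroken windows).
#' @return an object of class `window_contrast`.
#' @export
summarize_window_contrast <- function(classification, controls) {
  stopifnot(inherits(classification, "window_classification"))
  broken <- classification$broken
  if (nrow(broken) == 0L) .stopf("no broken windows to contrast")
  if (is.null(controls) || nrow(controls) == 0L) .stopf("no control windows")
  tab <- matrix(c(sum(broken$has_pair), sum(!broken$has_pair),
                  sum(controls$has_pair), sum(!controls$has_pair)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("broken", "control"),
                                c("pair", "no_pair")))
  chisq <- tryCatch(chi_square_2x2(tab),
                    error = function(e) {
                      list(statistic = NA_real_, p.value = NA_real_,
                           df = 1L, table = tab, yates = FALSE,
                           note = conditionMessage(e))
                    })
  mw <- mann_whitney_u(broken$n_nonamers, controls$n_nonamers)
  tt <- tryCatch(two_sample_t(broken$n_nonamers, controls$n_nonamers),
                 error = function(e) {
                   list(t = NA_real_, p.value = NA_real_, df = NA_real_,
                        note = conditionMessage(e))
                 })
  raw <- c(chisq_pair = chisq$p.value, mann_whitney = mw$p.value,
           t_test = tt$p.value)
  structure(list(
    broken = .class_summary(broken),
    control = .class_summary(controls),
    pair_table = tab,
    chisq = chisq,
    mann_whitney = mw,
    t_test = tt,
    p_raw = raw,
    p_adjusted = p.adjust(raw, method = "BH")
  ), class = "window_contrast")
}

#' @export
print.window_contrast <- function(x, ...) {
  cat(sprintf(
    "<window_contrast> %d broken vs %d control windows\n  nonamers/window: %.2f vs %.2f (MW p = %.3g)\n  %%windows with pair: %.1f vs %.1f (chi-square %.2f, p = %.3g)\n",
    x$broken$n, x$control$n, x$broken$mean_nonamers, x$control$mean_nonamers,
    x$mann_whitney$p.value, x$broken$pct_with_pair, x$control$pct_with_pair,
    x$chisq$statistic, x$chisq$p.value))
  invisible(x)
}
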