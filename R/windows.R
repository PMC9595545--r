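# Genome tiling and per-window feature counting. Windows are the unit of
# every enrichment statistic: breaks, nonamers and CpGs are assigned to
# exactly one window by their start coordinate, so window totals always sum
# to the genome-wide totals.

#' Tile a genome into fixed-size windows
#'
#' Non-overlapping tiling from position 0 in steps of `size`; the final
#' window of each chromosome is truncated at the chromosome end and flagged
#' `full = FALSE` when shorter than `size`.
#'
#' @param genome a [genome_sequence()].
#' @param size window size in bases.
#' @return data frame `chrom, start, end, full` with attribute `size`.
#' @export
#' @examples
#' tile_windows(genome_sequence(c(chr1 = strrep("A", 250))), 100)
tile_windows <- function(genome, size) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!.is_count(size) || size <= 0) .stopf("window `size` must be >= 1")
  size <- as.integer(size)
  len <- genome_lengths(genome)
  pieces <- lapply(names(len), function(ch) {
    n <- len[[ch]]
    if (n == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), full = logical(0)))
    }
    starts <- seq.int(0L, n - 1L, by = size)
    ends <- pmin(starts + size, n)
    data.frame(chrom = rep(ch, length(starts)), start = starts, end = ends,
               full = (ends - starts) == size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "size") <- size
  out
}

#' GC fraction of DNA strings
#'
#' `(#G + #C) / (#non-N bases)`; a string consisting entirely of `N`
#' (or empty) has undefined GC and returns `NA`.
#'
#' @param seq character vector over `{A,C,G,T,N}`.
#' @return numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @export
#' @examples
#' gc_fraction(c("ACGT", "AAAA", "ACGN"))
gc_fraction <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) .stopf("sequences must be over {A,C,G,T,N}")
  rg <- charToRaw("G"); rc <- charToRaw("C"); rn <- charToRaw("N")
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return(NA_real_)
    x <- charToRaw(s)
    non_n <- sum(x != rn)
    if (non_n == 0L) return(NA_real_)
    sum(x == rg | x == rc) / non_n
  }, numeric(1), USE.NAMES = FALSE)
}

# For one chromosome, find CpG-nonamer pairs with edge gap <= pair_gap_max.
# For each CpG only its nearest qualifying hit on each side needs checking:
# if any pair on that side fits a window, the nearest-side pair fits too.
# Returns a data.frame of pair spans [start, end) plus the gap.
.chrom_pairs <- function(hit_starts, cpg_starts, pair_gap_max) {
  if (length(hit_starts) == 0L || length(cpg_starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), gap = integer(0)))
  }
  hs <- sort(hit_starts)
  res_s <- integer(0); res_e <- integer(0); res_g <- integer(0)
  idx <- findInterval(cpg_starts, hs)
  for (side in c("left", "right")) {
    j <- if (side == "left") idx else idx + 1L
    ok <- j >= 1L & j <= length(hs)
    cs <- cpg_starts[ok]
    h <- hs[j[ok]]
    gap <- pmax(0L, pmax(cs, h) - pmin(cs + 2L, h + 9L))
    keep <- gap <= pair_gap_max
    res_s <- c(res_s, pmin(cs, h)[keep])
    res_e <- c(res_e, pmax(cs + 2L, h + 9L)[keep])
    res_g <- c(res_g, gap[keep])
  }
  data.frame(start = res_s, end = res_e, gap = res_g)
}

#' Count breaks, nonamers and CpGs in genome windows
#'
#' Each feature is assigned to exactly one window by its start coordinate
#' (a nonamer straddling a boundary belongs to the left window), so the
#' column sums equal the genome-wide totals for every window size. Each
#' window also gets its GC fraction (over non-N bases; `NA` for all-N
#' windows), a `has_cpg` flag, and a `has_pair` flag marking windows that
#' contain at least one CpG-nonamer pair with edge gap at most
#' `config$pair_gap_max`; the pair must lie fully inside the window
#' extended by `config$window_context` bases on each side.
#'
#' @param windows a tiling from [tile_windows()].
#' @param breaks a (deduplicated) [breakpoint_table()].
#' @param hits nonamer hits from [scan_cryptic_nonamers()].
#' @param cpgs CpG sites from [scan_cpg()].
#' @param genome the [genome_sequence()] the windows tile.
#' @param config an [analysis_config()].
#' @return the `windows` data frame extended with `n_breaks, n_nonamers,
#'   n_cpgs, gc, has_cpg, has_pair`.
#' @export
count_features_in_windows <- function(windows, breaks, hits, cpgs, genome,
                                      config = analysis_config()) {
  stopifnot(inherits(genome, "genome_sequence"))
  size <- attr(windows, "size")
  if (is.null(size)) .stopf("`windows` must come from tile_windows()")
  len <- genome_lengths(genome)
  out <- windows
  out$n_breaks <- 0L
  out$n_nonamers <- 0L
  out$n_cpgs <- 0L
  out$gc <- NA_real_
  out$has_pair <- FALSE
  ctx <- config$window_context

  count_in <- function(pos, ch, nwin, what) {
    if (length(pos) == 0L) return(integer(nwin))
    if (any(pos < 0L) || any(pos >= len[[ch]])) {
      .stopf("%s coordinate outside chromosome %s", what, ch)
    }
    tabulate(pos %/% size + 1L, nbins = nwin)
  }

  for (ch in unique(windows$chrom)) {
    sel <- which(out$chrom == ch)
    nwin <- length(sel)
    bp <- breaks$position[breaks$chrom == ch]
    hp <- hits$start[hits$chrom == ch]
    cp <- cpgs$start[cpgs$chrom == ch]
    out$n_breaks[sel] <- count_in(bp, ch, nwin, "breakpoint")
    out$n_nonamers[sel] <- count_in(hp, ch, nwin, "nonamer hit")
    out$n_cpgs[sel] <- count_in(cp, ch, nwin, "CpG")

    s <- unclass(genome)[[ch]]
    x <- charToRaw(s)
    cum_gc <- c(0, cumsum(x == charToRaw("G") | x == charToRaw("C")))
    cum_n <- c(0, cumsum(x == charToRaw("N")))
    st <- out$start[sel]; en <- out$end[sel]
    gc_ct <- cum_gc[en + 1L] - cum_gc[st + 1L]
    nn_ct <- cum_n[en + 1L] - cum_n[st + 1L]
    denom <- (en - st) - nn_ct
    out$gc[sel] <- ifelse(denom > 0L, gc_ct / denom, NA_real_)

    pairs <- .chrom_pairs(hp, cp, config$pair_gap_max)
    if (nrow(pairs)) {
      klo <- pmax(0L, as.integer(ceiling((pairs$end - ctx) / size)) - 1L)
      khi <- pmin(nwin - 1L, (pairs$start + ctx) %/% size)
      keep <- klo <= khi
      if (any(keep)) {
        wins <- unique(unlist(mapply(seq.int, klo[keep], khi[keep],
                                     SIMPLIFY = FALSE)))
        out$has_pair[sel[wins + 1L]] <- TRUE
      }
    }
  }
  out$has_cpg <- out$n_cpgs > 0L
  attr(out, "size") <- size
  attr(out, "pair_gap_max") <- config$pair_gap_max
  attr(out, "window_context") <- ctx
  out
}

#' Partition windows by break-cluster status
#'
#' `broken`: at least `min_breaks` breaks; `unbroken`: exactly zero;
#' `intermediate`: in between (excluded from broken-vs-unbroken contrasts
#' rather than pooled into either side).
#'
#' @param stats windows with counts from [count_features_in_windows()].
#' @param min_breaks break-cluster threshold (>= 1).
#' @return an object of class `window_classification`: a list with elements
#'   `broken`, `unbroken`, `intermediate` (data frames), `threshold`, `sizes`.
#' @export
classify_windows <- function(stats, min_breaks = 3L) {
  if (!.is_count(min_breaks) || min_breaks < 1) .stopf("`min_breaks` must be >= 1")
  broken <- stats[stats$n_breaks >= min_breaks, , drop = FALSE]
  unbroken <- stats[stats$n_breaks == 0L, , drop = FALSE]
  inter <- stats[stats$n_breaks > 0L & stats$n_breaks < min_breaks, ,
                 drop = FALSE]
  structure(list(
    broken = broken, unbroken = unbroken, intermediate = inter,
    threshold = as.integer(min_breaks),
    sizes = c(broken = nrow(broken), unbroken = nrow(unbroken),
              intermediate = nrow(inter))
  ), class = "window_classification")
}

#' @export
print.window_classification <- function(x, ...) {
  cat(sprintf(
    "<window_classification> threshold >= %d breaks: %d broken, %d unbroken, %d intermediate\n",
    x$threshold, x$sizes[["broken"]], x$sizes[["unbroken"]],
    x$sizes[["intermediate"]]))
  invisible(x)
}

#' Genome-wide break density and its chromosome-length correlation
#'
#' @param breaks a [breakpoint_table()] (deduplicated internally).
#' @param genome a [genome_sequence()].
#' @return list with `breaks_per_mb` (unique breaks per megabase of
#'   genome), `per_chromosome` (chrom, length, n_breaks), and `correlation`
#'   (Pearson r between per-chromosome break count and chromosome length;
#'   `NA` with a reason in `correlation_note` when fewer than two
#'   chromosomes or no breaks).
#' @export
breaks_per_mb <- function(breaks, genome) {
  stopifnot(inherits(breaks, "breakpoint_table"),
            inherits(genome, "genome_sequence"))
  len <- genome_lengths(genome)
  total <- sum(as.numeric(len))
  if (total == 0) .stopf("zero-length genome")
  uniq <- dedupe_breakpoints(breaks)
  .check_breaks_in_genome(uniq, genome)
  per <- data.frame(chrom = names(len), length = as.numeric(len),
                    n_breaks = vapply(names(len), function(ch) {
                      sum(uniq$chrom == ch)
                    }, numeric(1)), row.names = NULL)
  note <- NULL
  r <- NA_real_
  if (nrow(uniq) == 0L) {
    note <- "no breaks: correlation undefined"
  } else if (length(len) < 2L) {
    note <- "fewer than two chromosomes: correlation undefined"
  } else if (sd(per$length) == 0 || sd(per$n_breaks) == 0) {
    note <- "constant lengths or counts: correlation undefined"
  } else {
    r <- cor(per$length, per$n_breaks)
  }
  list(breaks_per_mb = nrow(uniq) / (total / 1e6),
       n_unique_breaks = nrow(uniq),
       per_chromosome = per,
       correlation = r,
       correlation_note = note)
}

#' Export window statistics as TSV
#' @param stats windows with counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
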