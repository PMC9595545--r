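#' Analysis configuration
#'
#' One object holds every numeric threshold of the pipeline so a run can be
#' reproduced from its echoed configuration alone. Defaults follow the
#' fragility analysis this package implements: the canonical RSS nonamer
#' `ACAAAAACC`; up to 4 mismatches for a "cryptic" nonamer (equivalently at
#' least 5 of 9 positions conserved); a 100 bp proximity radius around point
#' breakpoints; an 80 bp maximum CpG-to-nonamer edge gap for a fragility
#' pair; 100 bp and 1 kb window tilings; break clusters of at least 3 breaks
#' per window; 1000 null-model iterations with GC matched to within 0.02.
#'
#' @param motif reference nonamer, a 9-character string over `A,C,G,T`.
#' @param max_mismatch maximum Hamming distance for a cryptic nonamer (0-9).
#' @param breakpoint_radius bases scanned either side of a breakpoint; the
#'   proximity window around break `p` is `[p - radius, p + radius + 1)`.
#' @param pair_gap_max maximum edge-to-edge gap (bases) between a CpG and a
#'   nonamer for the two to count as a fragility pair.
#' @param window_sizes genome tiling sizes in bases.
#' @param min_breaks_per_window break-cluster threshold: windows with at
#'   least this many deduplicated breaks are "broken".
#' @param null_iterations iterations for the GC-matched null model.
#' @param gc_tolerance absolute GC-fraction tolerance for control matching.
#' @param random_seed master seed; all child streams derive from it.
#' @param require_positions optional integer vector of 1-based motif
#'   positions that must match exactly (a stricter scan mode; empty by
#'   default because genome-wide bound regions conserve even the central
#'   adenines only partially).
#' @param window_context bases of context either side of a window when
#'   deciding whether it contains a CpG-nonamer pair (`has_pair`). The
#'   default 0 evaluates pairs inside the window itself, matching how
#'   per-window co-occurrence percentages are defined in this analysis.
#' @return an object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$max_mismatch
analysis_config <- function(motif = "ACAAAAACC",
                            max_mismatch = 4L,
                            breakpoint_radius = 100L,
                            pair_gap_max = 80L,
                            window_sizes = c(100L, 1000L),
                            min_breaks_per_window = 3L,
                            null_iterations = 1000L,
                            gc_tolerance = 0.02,
                            random_seed = 1L,
                            require_positions = integer(0),
                            window_context = 0L) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) != 9L ||
      grepl("[^ACGT]", motif)) {
    .stopf("`motif` must be a 9-mer over {A,C,G,T}, got %s", deparse(motif))
  }
  if (!.is_count(max_mismatch) || max_mismatch < 0 || max_mismatch > 9) {
    .stopf("`max_mismatch` must be an integer in [0, 9]")
  }
  if (!.is_count(breakpoint_radius) || breakpoint_radius <= 0) {
    .stopf("`breakpoint_radius` must be a positive integer")
  }
  if (!.is_count(pair_gap_max) || pair_gap_max < 0) {
    .stopf("`pair_gap_max` must be a non-negative integer")
  }
  if (length(window_sizes) < 1L || any(window_sizes <= 0) ||
      any(window_sizes != as.integer(window_sizes))) {
    .stopf("`window_sizes` must be positive integers")
  }
  if (!.is_count(min_breaks_per_window) || min_breaks_per_window < 1) {
    .stopf("`min_breaks_per_window` must be >= 1")
  }
  if (!.is_count(null_iterations) || null_iterations < 1) {
    .stopf("`null_iterations` must be >= 1")
  }
  if (!is.numeric(gc_tolerance) || gc_tolerance <= 0 || gc_tolerance > 1) {
    .stopf("`gc_tolerance` must be in (0, 1]")
  }
  if (length(require_positions) &&
      (any(require_positions < 1) || any(require_positions > 9) ||
       anyDuplicated(require_positions))) {
    .stopf("`require_positions` must be distinct 1-based motif positions")
  }
  if (!.is_count(window_context) || window_context < 0) {
    .stopf("`window_context` must be a non-negative integer")
  }
  structure(list(
    motif = motif,
    max_mismatch = as.integer(max_mismatch),
    breakpoint_radius = as.integer(breakpoint_radius),
    pair_gap_max = as.integer(pair_gap_max),
    window_sizes = as.integer(window_sizes),
    min_breaks_per_window = as.integer(min_breaks_per_window),
    null_iterations = as.integer(null_iterations),
    gc_tolerance = as.numeric(gc_tolerance),
    random_seed = as.integer(random_seed),
    require_positions = as.integer(sort(require_positions)),
    window_context = as.integer(window_context)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
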