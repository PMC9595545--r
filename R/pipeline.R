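# End-to-end orchestration: load -> dedupe -> scan -> tile/count ->
# classify -> contrasts -> distances -> null model -> stratifications ->
# PWM -> report. Optional annotation inputs are skipped with a logged
# notice rather than failing the run.

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ragfrag] ", fmt), ...))
  invisible(NULL)
}

#' Run the full fragility analysis
#'
#' Executes every stage of the pipeline on a genome plus breakpoint table
#' and returns one self-contained report. All thresholds come from the
#' configuration; all randomness (GC-matched sampling, null iterations)
#' derives from `config$random_seed`, so two runs on the same inputs are
#' identical.
#'
#' @param genome a [genome_sequence()] or a FASTA path.
#' @param breaks a [breakpoint_table()] or a BED path.
#' @param config an [analysis_config()].
#' @param promoters optional promoter [region_set()] or BED path.
#' @param cytobands optional cytoband [region_set()] or TSV path.
#' @param run_null run the iterated GC-matched null model (the slowest
#'   stage; disable for quick looks).
#' @param verbose log stage progress.
#' @return an object of class `run_report`.
#' @export
run_full_analysis <- function(genome, breaks, config = analysis_config(),
                              promoters = NULL, cytobands = NULL,
                              run_null = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(genome) && !inherits(genome, "genome_sequence")) {
    genome <- read_genome_fasta(genome)
  }
  if (is.character(breaks)) breaks <- read_breakpoints(breaks, "bed")
  if (is.character(promoters)) promoters <- read_bed_regions(promoters, "promoters")
  if (is.character(cytobands)) cytobands <- read_cytoband(cytobands)
  notes <- character(0)
  seed <- config$random_seed

  n_raw <- nrow(breaks)
  breaks <- dedupe_breakpoints(breaks)
  .check_breaks_in_genome(breaks, genome)
  .log_stage(verbose, "breakpoints: %d raw, %d unique", n_raw, nrow(breaks))

  hits <- scan_cryptic_nonamers(genome, config)
  cpgs <- scan_cpg(genome)
  .log_stage(verbose, "scan: %d nonamer hits, %d CpGs", nrow(hits), nrow(cpgs))

  density <- breaks_per_mb(breaks, genome)

  windows <- list()
  for (size in config$window_sizes) {
    tiles <- tile_windows(genome, size)
    stats <- count_features_in_windows(tiles, breaks, hits, cpgs, genome,
                                       config)
    cls <- classify_windows(stats, config$min_breaks_per_window)
    # conservation audit: per-window counts must sum to genome-wide totals
    stopifnot(sum(stats$n_breaks) == nrow(breaks),
              sum(stats$n_nonamers) == nrow(hits),
              sum(stats$n_cpgs) == nrow(cpgs))
    windows[[as.character(size)]] <- list(stats = stats,
                                          classification = cls)
    .log_stage(verbose, "windows %d bp: %d broken / %d unbroken / %d intermediate",
               size, cls$sizes[["broken"]], cls$sizes[["unbroken"]],
               cls$sizes[["intermediate"]])
  }

  primary_size <- if ("100" %in% names(windows)) "100" else names(windows)[1]
  prim <- windows[[primary_size]]
  pool <- prim$classification$unbroken
  pool <- pool[pool$full & !is.na(pool$gc), , drop = FALSE]

  contrast <- NULL
  matched <- NULL
  if (nrow(prim$classification$broken) > 0L && nrow(pool) > 0L) {
    matched <- tryCatch(
      sample_gc_matched(pool, prim$classification$broken,
                        tolerance = config$gc_tolerance,
                        seed = child_seed(seed, 101)),
      error = function(e) {
        notes <<- c(notes, paste("GC matching fell back to all unbroken windows:",
                                 conditionMessage(e)))
        NULL
      })
    controls <- if (is.null(matched)) pool else matched$windows
    contrast <- summarize_window_contrast(prim$classification, controls)
  } else {
    notes <- c(notes, "window contrast skipped: no broken or no eligible unbroken windows")
  }

  proximity <- proximity_summary(breaks, hits, cpgs, config$breakpoint_radius)
  distances <- distance_distribution(breaks, hits, cpgs, config)

  null <- NULL
  null_p <- NULL
  if (run_null && !is.null(contrast) &&
      nrow(pool) >= nrow(prim$classification$broken)) {
    null <- iterate_null(pool, prim$classification$broken,
                         iterations = config$null_iterations,
                         seed = child_seed(seed, 102),
                         tolerance = config$gc_tolerance)
    observed <- null_summary_default(prim$classification$broken)
    null_p <- vapply(seq_along(observed), function(j) {
      empirical_p(observed[j], null$values[, j], side = "upper")
    }, numeric(1))
    names(null_p) <- names(observed)
    .log_stage(verbose, "null model: %d iterations", null$iterations)
  } else if (run_null) {
    notes <- c(notes, "null model skipped: insufficient windows")
  }

  promoter <- NULL
  if (!is.null(promoters)) {
    promoter <- promoter_breakdown(breaks, promoters, hits, cpgs, config)
  } else {
    notes <- c(notes, "promoter stratification skipped: no promoter regions supplied")
  }

  chromatin <- NULL
  if (!is.null(cytobands)) {
    chromatin <- chromatin_breakdown(breaks, hits, cpgs, cytobands, config)
  } else {
    notes <- c(notes, "chromatin stratification skipped: no cytoband file supplied")
  }

  cohorts <- NULL
  present <- setdiff(unique(breaks$cohort), "unlabeled")
  if (length(present) >= 2L) {
    by_cohort <- lapply(present, function(co) {
      sub <- breaks[breaks$cohort == co, , drop = FALSE]
      tiles <- tile_windows(genome, as.integer(primary_size))
      stats <- count_features_in_windows(tiles, sub, hits, cpgs, genome, config)
      classify_windows(stats, config$min_breaks_per_window)$broken
    })
    names(by_cohort) <- present
    cohorts <- tryCatch(cohort_compare(by_cohort), error = function(e) {
      notes <<- c(notes, paste("cohort comparison skipped:", conditionMessage(e)))
      NULL
    })
  } else {
    notes <- c(notes, "cohort comparison skipped: fewer than two labelled cohorts")
  }

  # PWM over breakpoint-proximal hits (falls back to all hits)
  prox_hits <- hits[.hits_near_breaks(hits, breaks, config$breakpoint_radius), ,
                    drop = FALSE]
  if (nrow(prox_hits) == 0L) {
    notes <- c(notes, "no breakpoint-proximal hits: PWM built from all hits")
    prox_hits <- hits
  }
  pwm <- if (nrow(prox_hits)) build_pwm(prox_hits) else NULL
  conservation <- if (!is.null(pwm)) pwm_conservation(pwm, 0.6) else NULL

  structure(list(
    version = as.character(packageVersion("ragfrag")),
    config = config,
    seed = seed,
    inputs = list(n_chromosomes = length(genome),
                  genome_bases = sum(as.numeric(genome_lengths(genome))),
                  n_breaks_raw = n_raw,
                  n_breaks_unique = nrow(breaks)),
    totals = list(n_nonamer_hits = nrow(hits), n_cpgs = nrow(cpgs)),
    density = density,
    windows = windows,
    primary_size = as.integer(primary_size),
    gc_matched = matched,
    contrast = contrast,
    proximity = proximity,
    distances = distances,
    null = null,
    null_p = null_p,
    promoter = promoter,
    chromatin = chromatin,
    cohorts = cohorts,
    pwm = pwm,
    conservation = conservation,
    hits = hits,
    cpgs = cpgs,
    breaks = breaks,
    notes = notes
  ), class = "run_report")
}

.hits_near_breaks <- function(hits, breaks, radius) {
  out <- logical(nrow(hits))
  for (ch in unique(hits$chrom)) {
    sel <- hits$chrom == ch
    bp <- sort(breaks$position[breaks$chrom == ch])
    if (length(bp) == 0L) next
    s <- hits$start[sel]
    # overlap of [s, s+9) with [p - radius, p + radius + 1)
    out[sel] <- (findInterval(s + radius + 8L, bp) -
                   findInterval(s - radius - 1L, bp)) > 0L
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> ragfrag %s, seed %d\n", x$version, x$seed))
  cat(sprintf("  genome: %d chromosome(s), %s bases\n",
              x$inputs$n_chromosomes,
              format(x$inputs$genome_bases, big.mark = ",")))
  cat(sprintf("  breaks: %d unique (%d raw); %.2f per Mb\n",
              x$inputs$n_breaks_unique, x$inputs$n_breaks_raw,
              x$density$breaks_per_mb))
  cat(sprintf("  features: %d nonamer hits, %d CpGs\n",
              x$totals$n_nonamer_hits, x$totals$n_cpgs))
  if (!is.null(x$contrast)) print(x$contrast)
  if (!is.null(x$proximity)) print(x$proximity)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Reduce a report to plain lists for JSON serialisation.
.report_json <- function(report) {
  win_summaries <- lapply(report$windows, function(w) {
    list(sizes = as.list(w$classification$sizes),
         threshold = w$classification$threshold)
  })
  list(
    version = report$version,
    seed = report$seed,
    config = unclass(report$config),
    inputs = report$inputs,
    totals = report$totals,
    density = list(breaks_per_mb = report$density$breaks_per_mb,
                   correlation = report$density$correlation),
    windows = win_summaries,
    primary_size = report$primary_size,
    contrast = if (!is.null(report$contrast)) {
      list(broken = report$contrast$broken,
           control = report$contrast$control,
           pair_table = as.vector(report$contrast$pair_table),
           chisq_statistic = report$contrast$chisq$statistic,
           chisq_p = report$contrast$chisq$p.value,
           mann_whitney_U = report$contrast$mann_whitney$U,
           mann_whitney_p = report$contrast$mann_whitney$p.value,
           t = report$contrast$t_test$t,
           t_p = report$contrast$t_test$p.value,
           p_adjusted = as.list(report$contrast$p_adjusted))
    },
    proximity = report$proximity[c("n_breakpoints", "n_with_nonamer",
                                   "n_with_cpg", "n_with_both",
                                   "fraction_with_nonamer",
                                   "fraction_with_cpg",
                                   "fraction_with_both", "radius")],
    distances = report$distances[c("n_breakpoints", "n_with_pair",
                                   "median_gap", "frac_breaks_lt50",
                                   "frac_pairs_lt50",
                                   "frac_le_pair_gap_max", "radius")],
    null_p = as.list(report$null_p),
    promoter = report$promoter,
    chromatin = if (!is.null(report$chromatin)) {
      list(strata = report$chromatin$strata,
           n_classified = report$chromatin$n_classified,
           chisq_p = report$chromatin$chisq$p.value)
    },
    cohorts = if (!is.null(report$cohorts)) {
      list(summary = report$cohorts$summary,
           ratios_vs_first = report$cohorts$ratios_vs_first,
           chisq_p = report$cohorts$chisq_p)
    },
    pwm = if (!is.null(report$pwm)) {
      list(n = attr(report$pwm, "n"), matrix = unclass(report$pwm))
    },
    notes = report$notes
  )
}

#' Write a run report and its tabular outputs to a directory
#'
#' Emits `report.json` plus `windows_<size>.tsv`, `hits.bed`, `cpgs.bed`,
#' `distances.tsv`, `null.tsv` and `pwm.tsv` (stages that did not run are
#' simply absent).
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (size in names(report$windows)) {
    write_windows_tsv(report$windows[[size]]$stats,
                      file.path(dir, sprintf("windows_%s.tsv", size)))
  }
  write_hits_bed(report$hits, file.path(dir, "hits.bed"))
  write_cpg_bed(report$cpgs, file.path(dir, "cpgs.bed"))
  write.table(report$distances$per_break, file.path(dir, "distances.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$null)) {
    write_null_tsv(report$null, file.path(dir, "null.tsv"))
  }
  if (!is.null(report$pwm)) {
    write_pwm_tsv(report$pwm, file.path(dir, "pwm.tsv"))
  }
  invisible(dir)
}
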