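# Breakpoint table: one genomic point per record, with optional cohort,
# gene and source labels. Positions are 0-based.

.COHORTS <- c("lymphoid", "nonlymphoid", "unlabeled")

#' Construct a breakpoint table
#'
#' A breakpoint is a single base position (translocation junction
#' coordinates are treated as points). Duplicate `(chrom, position,
#' source_id)` triples are rejected; the same position reported by
#' different sources is retained — collapsing to unique positions is the
#' explicit [dedupe_breakpoints()] step, never implicit.
#'
#' @param chrom chromosome names.
#' @param position 0-based base offsets.
#' @param cohort per-record cohort, one of `"lymphoid"`, `"nonlymphoid"`,
#'   `"unlabeled"` (recycled).
#' @param gene optional gene symbols.
#' @param source_id optional record identifiers (e.g. database accession).
#' @return a `breakpoint_table` (a data frame).
#' @export
#' @examples
#' breakpoint_table("chr1", c(10, 20), cohort = "lymphoid")
breakpoint_table <- function(chrom, position, cohort = "unlabeled",
                             gene = NA_character_, source_id = NA_character_) {
  n <- length(position)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n)
  if (n && (any(is.na(position)) || any(position < 0))) {
    .stopf("breakpoint positions must be non-negative")
  }
  if (any(position != as.integer(position))) {
    .stopf("breakpoint positions must be integers")
  }
  cohort <- rep_len(as.character(cohort), n)
  bad <- setdiff(unique(cohort), .COHORTS)
  if (length(bad)) .stopf("unknown cohort label: '%s'", bad[1])
  gene <- rep_len(as.character(gene), n)
  source_id <- rep_len(as.character(source_id), n)
  key <- paste(chrom, position, source_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    .stopf("duplicate breakpoint record: %s:%d (source %s)",
           chrom[i], as.integer(position[i]), source_id[i])
  }
  structure(
    data.frame(chrom = as.character(chrom), position = as.integer(position),
               cohort = cohort, gene = gene, source_id = source_id,
               stringsAsFactors = FALSE),
    class = c("breakpoint_table", "data.frame")
  )
}

#' Read breakpoints from BED or TSV
#'
#' BED dialect: 0-based half-open intervals; the breakpoint is the
#' interval's *start* (intervals wider than one base still contribute a
#' single point). Column 4, when present, is kept as `source_id`.
#' TSV dialect: tab-separated columns `chrom, position, cohort, gene,
#' source_id`, the last three optional, no header; `position` is 0-based.
#'
#' @param path input file.
#' @param dialect `"bed"` or `"tsv"`.
#' @return a [breakpoint_table()].
#' @export
read_breakpoints <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "", fill = TRUE)
  if (dialect == "bed") {
    if (ncol(df) < 3L) .stopf("BED needs at least 3 columns, got %d", ncol(df))
    start <- df[[2]]; end <- df[[3]]
    if (any(start < 0)) .stopf("negative coordinate in %s", path)
    if (any(end <= start)) {
      i <- which(end <= start)[1]
      .stopf("empty or inverted BED interval at line %d: %s\t%d\t%d",
             i, df[[1]][i], start[i], end[i])
    }
    src <- if (ncol(df) >= 4L) as.character(df[[4]]) else NA_character_
    breakpoint_table(df[[1]], start, source_id = src)
  } else {
    if (ncol(df) < 2L) .stopf("TSV needs at least chrom and position columns")
    pos <- df[[2]]
    if (any(pos < 0)) .stopf("negative coordinate in %s", path)
    grab <- function(k, default) {
      if (ncol(df) >= k) {
        v <- as.character(df[[k]]); v[is.na(v) | v == ""] <- default; v
      } else default
    }
    breakpoint_table(df[[1]], pos,
                     cohort = grab(3L, "unlabeled"),
                     gene = grab(4L, NA_character_),
                     source_id = grab(5L, NA_character_))
  }
}

#' Write breakpoints as BED
#'
#' Emits one width-1 interval per record (`chrom, position, position + 1`),
#' plus a name column when any `source_id` is set, so reading the file back
#' with [read_breakpoints()] reproduces the coordinates exactly.
#'
#' @param breaks a `breakpoint_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(breaks, path) {
  stopifnot(inherits(breaks, "breakpoint_table"))
  out <- data.frame(breaks$chrom, breaks$position, breaks$position + 1L)
  if (any(!is.na(breaks$source_id))) {
    nm <- breaks$source_id
    nm[is.na(nm)] <- "."
    out[[4]] <- nm
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse breakpoints to unique genomic positions
#'
#' One record is kept per `(chrom, position)`. The cohort survives when all
#' merged records agree, otherwise it becomes `"unlabeled"`; likewise the
#' gene label. Source ids of merged records are joined with `;`. The number
#' of removed duplicates is attached as attribute `n_removed`.
#'
#' @param breaks a `breakpoint_table`.
#' @return a deduplicated `breakpoint_table`.
#' @export
dedupe_breakpoints <- function(breaks) {
  stopifnot(inherits(breaks, "breakpoint_table"))
  if (nrow(breaks) == 0L) {
    out <- breaks
    attr(out, "n_removed") <- 0L
    return(out)
  }
  key <- paste(breaks$chrom, breaks$position, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  consistent <- function(v) {
    u <- vapply(split(v, grp), function(z) {
      z <- unique(z)
      if (length(z) == 1L) z else NA_character_
    }, character(1))
    u[order(unique(grp))]
  }
  cohort <- consistent(breaks$cohort)
  cohort[is.na(cohort)] <- "unlabeled"
  gene <- consistent(breaks$gene)
  src <- vapply(split(breaks$source_id, grp), function(z) {
    z <- unique(z[!is.na(z)])
    if (length(z)) paste(z, collapse = ";") else NA_character_
  }, character(1))[order(unique(grp))]
  out <- breakpoint_table(breaks$chrom[first], breaks$position[first],
                          cohort = cohort, gene = gene, source_id = src)
  attr(out, "n_removed") <- nrow(breaks) - nrow(out)
  out
}

# Error unless every breakpoint falls inside the attached genome.
.check_breaks_in_genome <- function(breaks, genome) {
  len <- genome_lengths(genome)
  miss <- setdiff(unique(breaks$chrom), names(len))
  if (length(miss)) .stopf("breakpoint chromosome '%s' not in genome", miss[1])
  bad <- breaks$position >= len[breaks$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    .stopf("breakpoint %s:%d lies outside the chromosome (length %d)",
           breaks$chrom[i], breaks$position[i], len[[breaks$chrom[i]]])
  }
  invisible(TRUE)
}
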