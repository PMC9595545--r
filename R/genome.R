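# Genome container and FASTA IO. Sequences live as uppercase character
# strings over {A,C,G,T,N}; every coordinate downstream is 0-based half-open.

.check_alphabet <- function(seqs) {
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad != -1L) {
      .stopf("illegal character '%s' in record '%s' at offset %d (0-based)",
             substr(seqs[[i]], bad, bad), names(seqs)[i], bad - 1L)
    }
  }
  invisible(TRUE)
}

#' Construct a genome from named sequences
#'
#' @param seqs named character vector of chromosome sequences. Lowercase is
#'   accepted and normalised; any character outside `{A,C,G,T,N}` is an
#'   error reporting the record and offset.
#' @return an object of class `genome_sequence`: a named character vector.
#' @export
#' @examples
#' g <- genome_sequence(c(chr1 = "acgtN"))
#' genome_lengths(g)
genome_sequence <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0L) {
    .stopf("`seqs` must be a non-empty character vector")
  }
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) .stopf("all chromosomes must be named")
  if (anyDuplicated(nm)) {
    .stopf("duplicate chromosome name: '%s'", nm[anyDuplicated(nm)])
  }
  if (any(nchar(seqs) == 0L)) {
    .stopf("empty sequence for record '%s'", nm[which(nchar(seqs) == 0L)[1]])
  }
  seqs <- toupper(seqs)
  .check_alphabet(seqs)
  structure(seqs, class = "genome_sequence")
}

#' Chromosome lengths of a genome
#' @param genome a `genome_sequence`.
#' @return named integer vector of lengths in bases.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  vapply(unclass(genome), nchar, integer(1))
}

#' @export
print.genome_sequence <- function(x, ...) {
  len <- genome_lengths(x)
  cat(sprintf("<genome_sequence> %d chromosome(s), %s bases total\n",
              length(x), format(sum(as.numeric(len)), big.mark = ",")))
  for (nm in names(len)) cat(sprintf("  %s: %d bp\n", nm, len[[nm]]))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Multi-record and line-wrapped FASTA are accepted (parsing is delegated to
#' Biostrings). Sequences are uppercased; any residue outside `{A,C,G,T,N}`
#' is rejected with the record name and 0-based offset. Record names are the
#' first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return a [genome_sequence()].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("no FASTA records in %s", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) .stopf("malformed FASTA header (empty name) in %s", path)
  if (any(Biostrings::width(set) == 0L)) {
    .stopf("empty sequence for record '%s' in %s",
           nm[which(Biostrings::width(set) == 0L)[1]], path)
  }
  seqs <- as.character(set)
  names(seqs) <- nm
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
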