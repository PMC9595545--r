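# Mismatch-tolerant nonamer scanning, CpG detection and PWM construction.
#
# The scanner is the computational core of the package: every start on every
# chromosome is tested on both strands against the reference nonamer, and a
# window is a hit when its Hamming distance is at most `max_mismatch`. N
# matches nothing (it always contributes a mismatch), so windows buried in
# assembly gaps cannot pass. The implementation is vectorized over the
# chromosome (one pass per motif position); an independent brute-force
# scanner in the test suite guards its correctness.

.raw_base <- function(ch) charToRaw(ch)

#' Hamming distance between equal-length DNA strings
#'
#' Positions differ when the characters differ or when either is `N`
#' (ambiguity is treated conservatively as a mismatch).
#'
#' @param a,b character vectors of equal-length DNA strings over
#'   `{A,C,G,T,N}`; recycled pairwise.
#' @return integer vector of distances.
#' @export
#' @examples
#' hamming_distance("ACAAAAACC", "ACAAAAACG")
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(grepl("[^ACGTN]", c(a, b)))) .stopf("sequences must be over {A,C,G,T,N}")
  mapply(function(x, y) {
    if (nchar(x) != nchar(y)) {
      .stopf("unequal lengths: %d vs %d", nchar(x), nchar(y))
    }
    rx <- charToRaw(x)
    ry <- charToRaw(y)
    nn <- charToRaw("N")
    sum(rx != ry | rx == nn | ry == nn)
  }, a, b, USE.NAMES = FALSE)
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorized; the
#' empty string returns itself.
#'
#' @param x character vector over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACAAAAACC")
reverse_complement <- function(x) {
  if (any(grepl("[^ACGTN]", x))) .stopf("sequences must be over {A,C,G,T,N}")
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(z) {
    paste(rev(z), collapse = "")
  }, character(1))
}

# reverse-complement a vector of fixed-width 9-mers without per-element loops
.revcomp9 <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  paste0(substr(comp, 9, 9), substr(comp, 8, 8), substr(comp, 7, 7),
         substr(comp, 6, 6), substr(comp, 5, 5), substr(comp, 4, 4),
         substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
}

# Scan one chromosome string; returns data.frame(start, strand, mismatches).
.scan_chrom <- function(seq, motif, max_mismatch, require_positions) {
  n <- nchar(seq)
  if (n < 9L) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  m <- n - 8L
  x <- charToRaw(seq)
  mf <- charToRaw(motif)                      # plus strand reference
  mr <- charToRaw(reverse_complement(motif))  # minus strand: window vs rc(motif)
  mc <- charToRaw(chartr("ACGTN", "TGCAN", motif)) # per-position complement
  mm_p <- integer(m)
  mm_m <- integer(m)
  for (j in 0:8) {
    w <- x[(1L + j):(m + j)]
    mm_p <- mm_p + (w != mf[j + 1L])
    mm_m <- mm_m + (w != mr[j + 1L])
  }
  ok_p <- mm_p <= max_mismatch
  ok_m <- mm_m <= max_mismatch
  for (p in require_positions) {
    # plus strand: window position p must equal motif position p;
    # minus strand: motif position p reads from window position 10 - p and
    # must equal the complement of the motif base.
    ok_p <- ok_p & (x[p:(m + p - 1L)] == mf[p])
    q <- 10L - p
    ok_m <- ok_m & (x[q:(m + q - 1L)] == mc[p])
  }
  ip <- which(ok_p)
  im <- which(ok_m)
  df <- data.frame(
    start = c(ip, im) - 1L,
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    mismatches = c(mm_p[ip], mm_m[im]),
    stringsAsFactors = FALSE
  )
  df[order(df$start, df$strand), , drop = FALSE]
}

#' Scan a genome for cryptic nonamers
#'
#' Every start `i` with `i + 9 <= length` is tested on the plus strand
#' (window vs motif) and on the minus strand (reverse complement of the
#' window vs motif). Windows within `max_mismatch` Hamming distance — and
#' matching every `require_positions` position exactly, if any — are
#' reported. Overlapping hits are all kept, and one window may hit on both
#' strands. Output ordering is (chromosome order of the genome, start,
#' `+` before `-`).
#'
#' @param genome a [genome_sequence()].
#' @param config an [analysis_config()]; uses `motif`, `max_mismatch`,
#'   `require_positions`.
#' @return data frame with columns `chrom, start, end, strand, mismatches,
#'   observed` (the 9-mer read 5'→3' on the hit strand), 0-based half-open.
#' @export
#' @examples
#' g <- genome_sequence(c(chr1 = "ACAAAAACCC"))
#' scan_cryptic_nonamers(g, analysis_config())
scan_cryptic_nonamers <- function(genome, config = analysis_config()) {
  stopifnot(inherits(genome, "genome_sequence"),
            inherits(config, "analysis_config"))
  pieces <- lapply(names(genome), function(ch) {
    df <- .scan_chrom(unclass(genome)[[ch]], config$motif,
                      config$max_mismatch, config$require_positions)
    if (nrow(df) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        mismatches = integer(0), observed = character(0)))
    }
    obs <- substring(unclass(genome)[[ch]], df$start + 1L, df$start + 9L)
    minus <- df$strand == "-"
    if (any(minus)) obs[minus] <- .revcomp9(obs[minus])
    data.frame(chrom = ch, start = df$start, end = df$start + 9L,
               strand = df$strand, mismatches = df$mismatches,
               observed = obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "motif") <- config$motif
  attr(out, "max_mismatch") <- config$max_mismatch
  out
}

#' Locate CpG dinucleotides
#'
#' Reports every position `i` with `genome[i:i+2] == "CG"`, sorted. The CG
#' dinucleotide is its own reverse complement, so one strand suffices;
#' adjacent occurrences (`CGCG`) are both reported.
#'
#' @param genome a [genome_sequence()].
#' @return data frame `chrom, start, end` (0-based half-open; `start` is
#'   the C on the plus strand).
#' @export
#' @examples
#' scan_cpg(genome_sequence(c(chr1 = "ACGT")))
scan_cpg <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  rc <- charToRaw("C")
  rg <- charToRaw("G")
  pieces <- lapply(names(genome), function(ch) {
    s <- unclass(genome)[[ch]]
    n <- nchar(s)
    if (n < 2L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    x <- charToRaw(s)
    w <- which(x[-n] == rc & x[-1L] == rg)
    data.frame(chrom = rep(ch, length(w)), start = w - 1L, end = w + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Number of distinct 9-mers accepted as cryptic nonamers
#'
#' Closed form: the Hamming ball of radius `max_mismatch` around a fixed
#' word of length `motif_length` over a 4-letter alphabet contains
#' `sum_k C(L, k) * 3^k` words.
#'
#' @param max_mismatch mismatch tolerance.
#' @param motif_length word length (default 9).
#' @return numeric count.
#' @export
#' @examples
#' motif_space_size(4)
motif_space_size <- function(max_mismatch, motif_length = 9L) {
  stopifnot(max_mismatch >= 0, max_mismatch <= motif_length)
  sum(choose(motif_length, 0:max_mismatch) * 3^(0:max_mismatch))
}

#' Build a position weight matrix from nonamer hits
#'
#' Column `j`, row `b` holds the frequency of base `b` at position `j`
#' across the contributing 9-mers (minus-strand hits are already in
#' hit-strand orientation, so no further transformation is applied). A
#' sequence with `N` at a position contributes no mass there; the column is
#' renormalized over the sequences that do contribute.
#'
#' @param hits a hit data frame from [scan_cryptic_nonamers()] (its
#'   `observed` column is used) or a character vector of 9-mers.
#' @return a 4 x 9 matrix of class `pwm` (rows `A,C,G,T`, columns summing
#'   to 1) with attribute `n` = number of contributing sequences.
#' @export
#' @examples
#' build_pwm(c("ACAAAAACC", "GCAAAAACC"))
build_pwm <- function(hits) {
  obs <- if (is.data.frame(hits)) hits$observed else hits
  if (is.null(obs) || length(obs) == 0L) .stopf("no hits to build a PWM from")
  if (any(nchar(obs) != 9L)) .stopf("all contributing sequences must be 9-mers")
  if (any(grepl("[^ACGTN]", obs))) .stopf("sequences must be over {A,C,G,T,N}")
  chars <- matrix(unlist(strsplit(obs, "", fixed = TRUE), use.names = FALSE),
                  ncol = 9L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(9L), function(j) {
    tab <- table(factor(chars[, j], levels = bases))
    as.integer(tab)
  }, integer(4))
  denom <- colSums(counts)
  if (any(denom == 0L)) {
    .stopf("position %d has no non-N contributions", which(denom == 0L)[1])
  }
  pwm <- sweep(counts, 2L, denom, "/")
  dimnames(pwm) <- list(bases, paste0("pos", 1:9))
  structure(pwm, n = length(obs), class = c("pwm", "matrix", "array"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> built from %d sequence(s)\n", attr(x, "n")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-position conservation of a PWM
#'
#' @param pwm a [build_pwm()] matrix.
#' @param threshold a position is flagged conserved when its maximal base
#'   frequency reaches this fraction; must lie in (0, 1].
#' @return data frame `position, consensus, frequency, conserved`. Ties on
#'   the maximal frequency resolve to the first base in A,C,G,T order.
#' @export
pwm_conservation <- function(pwm, threshold = 0.6) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    .stopf("`threshold` must lie in (0, 1]")
  }
  idx <- apply(unclass(pwm), 2L, which.max)
  freq <- vapply(seq_len(ncol(pwm)), function(j) pwm[idx[j], j], numeric(1))
  data.frame(position = seq_len(ncol(pwm)),
             consensus = rownames(pwm)[idx],
             frequency = freq,
             conserved = freq >= threshold)
}

#' Export nonamer hits as BED6
#'
#' Score is `9 - mismatches`, so exact matches score highest.
#' @param hits hit data frame from [scan_cryptic_nonamers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  out <- data.frame(hits$chrom, hits$start, hits$end,
                    hits$observed, 9L - hits$mismatches, hits$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export CpG sites as BED
#' @param cpgs CpG data frame from [scan_cpg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_bed <- function(cpgs, path) {
  write.table(cpgs[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a PWM as a tab-separated matrix
#'
#' Rows `A,C,G,T`, nine columns; the layout logo tools accept.
#' @param pwm a `pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_tsv <- function(pwm, path) {
  write.table(format(unclass(pwm), digits = 6), path, sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(path)
}
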