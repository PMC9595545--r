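# Independent brute-force oracle for the nonamer scanner, written in a
# deliberately different style (per-position character comparison, explicit
# loops) so it shares no code path with the vectorized implementation.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  sum(x != y | x == "N" | y == "N")
}

# data.frame(start, strand, mismatches), 0-based starts
oracle_scan <- function(seq, motif = "ACAAAAACC", max_mm = 4L) {
  n <- nchar(seq)
  rows <- list()
  if (n >= 9L) {
    for (i in 1:(n - 8L)) {
      w <- substr(seq, i, i + 8L)
      dp <- oracle_hamming(w, motif)
      if (dp <= max_mm) rows[[length(rows) + 1L]] <- list(i - 1L, "+", dp)
      dm <- oracle_hamming(oracle_revcomp(w), motif)
      if (dm <= max_mm) rows[[length(rows) + 1L]] <- list(i - 1L, "-", dm)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  data.frame(start = vapply(rows, function(r) r[[1]], integer(1)),
             strand = vapply(rows, function(r) r[[2]], character(1)),
             mismatches = vapply(rows, function(r) as.integer(r[[3]]), integer(1)))
}

hit_key <- function(df) {
  sort(paste(df$start, df$strand, df$mismatches, sep = ":"))
}

random_seq <- function(n, gc = 0.5, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# minimal window-stats frame for null-model unit tests
make_winstats <- function(gc, n_breaks = 0L, has_cpg = TRUE, has_pair = TRUE,
                          n_nonamers = 5L, n_cpgs = 1L, full = TRUE) {
  n <- length(gc)
  data.frame(chrom = "chr1",
             start = seq.int(0L, by = 100L, length.out = n),
             end = seq.int(100L, by = 100L, length.out = n),
             full = rep_len(full, n),
             n_breaks = rep_len(as.integer(n_breaks), n),
             n_nonamers = rep_len(as.integer(n_nonamers), n),
             n_cpgs = rep_len(as.integer(n_cpgs), n),
             gc = gc,
             has_pair = rep_len(has_pair, n),
             has_cpg = rep_len(has_cpg, n))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
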