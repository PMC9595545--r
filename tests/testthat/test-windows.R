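test_that("tiling covers every base once, truncating the last window", {
  g <- genome_sequence(c(chr1 = strrep("A", 250)))
  w <- tile_windows(g, 100)
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(100L, 200L, 250L))
  expect_identical(w$full, c(TRUE, TRUE, FALSE))

  w1 <- tile_windows(genome_sequence(c(c = strrep("A", 100))), 100)
  expect_equal(nrow(w1), 1L)
  expect_true(w1$full)

  short <- tile_windows(genome_sequence(c(c = "ACGT")), 100)
  expect_equal(nrow(short), 1L)
  expect_false(short$full)
  expect_error(tile_windows(g, 0), "size")
})

test_that("GC fraction excludes N from the denominator", {
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("ACGN"), 2 / 3)
  expect_true(is.na(gc_fraction("NNNN")))
  expect_error(gc_fraction("ACGX"), "A,C,G,T,N")
})

test_that("features land in exactly one window by start coordinate", {
  g <- genome_sequence(c(chr1 = random_seq(300, 0.5, seed = 4)))
  cfg <- analysis_config()
  w <- tile_windows(g, 100)
  breaks <- breakpoint_table("chr1", 150)
  hits <- data.frame(chrom = "chr1", start = 98L, end = 107L, strand = "+",
                     mismatches = 2L, observed = strrep("A", 9))
  cpgs <- data.frame(chrom = "chr1", start = 99L, end = 101L)
  st <- count_features_in_windows(w, breaks, hits, cpgs, g, cfg)
  expect_equal(st$n_breaks, c(0L, 1L, 0L))
  # boundary-straddling features belong to the left window
  expect_equal(st$n_nonamers, c(1L, 0L, 0L))
  expect_equal(st$n_cpgs, c(1L, 0L, 0L))
  expect_error(
    count_features_in_windows(w, breakpoint_table("chr1", 400), hits, cpgs,
                              g, cfg),
    "outside")
})

test_that("window counts conserve genome-wide totals at every size", {
  g <- genome_sequence(c(chr1 = random_seq(3001, 0.5, seed = 8),
                         chr2 = random_seq(1203, 0.3, seed = 9)))
  cfg <- analysis_config()
  hits <- scan_cryptic_nonamers(g, cfg)
  cpgs <- scan_cpg(g)
  set.seed(2)
  breaks <- dedupe_breakpoints(breakpoint_table(
    sample(c("chr1", "chr2"), 80, TRUE), sample(0:1100, 80),
    source_id = sprintf("s%d", 1:80)))
  for (size in c(100L, 1000L)) {
    st <- count_features_in_windows(tile_windows(g, size), breaks, hits,
                                    cpgs, g, cfg)
    expect_equal(sum(st$n_breaks), nrow(breaks))
    expect_equal(sum(st$n_nonamers), nrow(hits))
    expect_equal(sum(st$n_cpgs), nrow(cpgs))
    # disjoint cover
    expect_equal(sum(st$end - st$start), sum(genome_lengths(g)))
  }
})

test_that("a window holding the literal motif counts at least one nonamer", {
  g <- genome_sequence(c(c = paste0(strrep("C", 50), "ACAAAAACC",
                                    strrep("C", 41))))
  st <- count_features_in_windows(tile_windows(g, 100),
                                  breakpoint_table(character(0), integer(0)),
                                  scan_cryptic_nonamers(g, analysis_config()),
                                  scan_cpg(g), g, analysis_config())
  expect_gte(st$n_nonamers[1], 1L)
})

test_that("classification partitions windows at the break threshold", {
  st <- make_winstats(gc = rep(0.5, 6))
  st$n_breaks <- c(3L, 0L, 2L, 5L, 1L, 0L)
  cl <- classify_windows(st, 3)
  expect_equal(cl$sizes, c(broken = 2L, unbroken = 2L, intermediate = 2L))
  expect_equal(sum(cl$sizes), nrow(st))
  expect_equal(cl$broken$n_breaks, c(3L, 5L))
  # with no breaks anywhere, threshold 1 leaves broken and intermediate empty
  st0 <- make_winstats(gc = rep(0.5, 4), n_breaks = 0L)
  cl0 <- classify_windows(st0, 1)
  expect_equal(cl0$sizes[["broken"]] + cl0$sizes[["intermediate"]], 0L)
  expect_error(classify_windows(st, 0), "min_breaks")
})

test_that("break density is unique breaks per megabase", {
  g <- genome_sequence(c(chr1 = strrep("A", 6e6), chr2 = strrep("A", 4e6)))
  # counts proportional to length: 10 + 6 = 16 on 10 Mb -> 1.6/Mb, r = 1
  bp <- breakpoint_table(c(rep("chr1", 9), rep("chr2", 6), "chr1"),
                         c(seq(0, 8e5, by = 1e5), seq(0, 5e5, by = 1e5), 99))
  d <- breaks_per_mb(bp, g)
  expect_equal(d$breaks_per_mb, 1.6)
  expect_equal(d$correlation, 1)
  expect_equal(d$per_chromosome$n_breaks, c(10, 6))

  d0 <- breaks_per_mb(breakpoint_table(character(0), integer(0)), g)
  expect_equal(d0$breaks_per_mb, 0)
  expect_true(is.na(d0$correlation))
  expect_match(d0$correlation_note, "no breaks")
})
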