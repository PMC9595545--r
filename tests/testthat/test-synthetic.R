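test_that("generated genomes hit the target GC and are seed-deterministic", {
  g <- generate_genome(c(chr1 = 100000), gc = 0.5, seed = 2)
  expect_equal(gc_fraction(unclass(g)[["chr1"]]), 0.5, tolerance = 0.01)
  g2 <- generate_genome(c(chr1 = 100000), gc = 0.5, seed = 2)
  expect_identical(unclass(g), unclass(g2))
  at_only <- generate_genome(c(c = 5000), gc = 0, seed = 1)
  expect_false(grepl("[GC]", unclass(at_only)[["c"]]))
})

test_that("background CpG density matches the i.i.d. expectation and thins", {
  g <- generate_genome(c(c = 200000), gc = 0.5, seed = 3)
  dens <- nrow(scan_cpg(g)) / 200000
  expect_equal(dens, 1 / 16, tolerance = 0.08) # (gc/2)^2 per dinucleotide
  gt <- generate_genome(c(c = 200000), gc = 0.5, seed = 3, cpg_retention = 0.2)
  dens_t <- nrow(scan_cpg(gt)) / 200000
  expect_equal(dens_t / dens, 0.2, tolerance = 0.1)
  none <- generate_genome(c(c = 50000), gc = 0.5, seed = 4, cpg_retention = 0)
  expect_equal(nrow(scan_cpg(none)), 0L)
})

test_that("planted motifs carry their exact mismatch count and strand", {
  base <- genome_sequence(c(c = strrep("C", 400)))
  cfg4 <- analysis_config(max_mismatch = 4)
  cfg3 <- analysis_config(max_mismatch = 3)
  for (mm in 0:4) {
    pl <- plant_motif(base, "c", 100, mismatches = mm, seed = 50 + mm)
    expect_equal(hamming_distance(pl$truth$planted, "ACAAAAACC"), mm)
    hits <- scan_cryptic_nonamers(pl$genome, cfg4)
    at_plant <- hits[hits$start == 100 & hits$strand == pl$truth$strand, ]
    expect_equal(nrow(at_plant), 1L)
    expect_equal(at_plant$mismatches, mm)
    expect_identical(at_plant$observed, pl$truth$planted)
    if (mm == 4) {
      h3 <- scan_cryptic_nonamers(pl$genome, cfg3)
      expect_false(any(h3$start == 100 & h3$strand == pl$truth$strand))
    }
  }
  expect_error(plant_motif(base, "c", 100, mismatches = 5), "\\[0, 4\\]")
  expect_error(plant_motif(base, "c", 395, mismatches = 0), "does not fit")
})

test_that("planted pairs read back their exact gap", {
  base <- genome_sequence(c(c = random_seq(3000, 0.41, seed = 6)))
  for (gap in c(0L, 8L, 80L)) {
    pl <- plant_pair(base, "c", 1000, gap = gap, seed = gap + 1,
                     inert_radius = 115L)
    hits <- scan_cryptic_nonamers(pl$genome, analysis_config())
    cpgs <- scan_cpg(pl$genome)
    got <- nearest_pair_gap("c", pl$truth$cpg_start, hits, cpgs, radius = 100)
    expect_equal(got, gap)
  }
  # a distant pair leaves the covering window without a qualifying pair
  far <- plant_pair(genome_sequence(c(c = strrep("C", 2000))), "c", 500,
                    gap = 500, seed = 9)
  st <- count_features_in_windows(
    tile_windows(far$genome, 100),
    breakpoint_table(character(0), integer(0)),
    scan_cryptic_nonamers(far$genome, analysis_config()),
    scan_cpg(far$genome), far$genome, analysis_config())
  expect_false(any(st$has_pair))
  expect_error(plant_pair(base, "c", 2995, gap = 20, seed = 1), "does not fit")
})

test_that("breakpoint simulation follows the footprint break model", {
  g <- genome_sequence(c(c = strrep("A", 100000)))
  fp <- region_set("c", c(1000, 5000), c(1200, 5200), name = "fp")
  only_fp <- simulate_breakpoints(g, fp, lambda_bg = 0, lambda_frag = 0.05,
                                  seed = 21)
  expect_true(all(only_fp$provenance == "footprint"))
  expect_true(all(only_fp$breaks$position %in% c(1000:1199, 5000:5199)))

  pois <- simulate_breakpoints(g, NULL, lambda_bg = 1e-3, lambda_frag = 1e-3,
                               seed = 22)
  expect_lt(abs(nrow(pois$breaks) - 100), 3 * sqrt(100) + 1)

  none <- simulate_breakpoints(g, NULL, lambda_bg = 0, lambda_frag = 0, seed = 1)
  expect_equal(nrow(none$breaks), 0L)
  expect_error(simulate_breakpoints(g, NULL, lambda_bg = 10, lambda_frag = 0,
                                    seed = 1), "exceeds cap")
})

test_that("scenarios are byte-reproducible for a fixed (name, seed)", {
  a <- make_scenario("null", seed = 77)
  b <- make_scenario("null", seed = 77)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(a$breaks$position, b$breaks$position)
  expect_equal(a$truth$lambda_bg, a$truth$lambda_frag) # no enrichment by design

  c1 <- make_scenario("paper_like", seed = 5)
  c2 <- make_scenario("paper_like", seed = 5)
  expect_identical(unclass(c1$genome), unclass(c2$genome))
  expect_identical(c1$breaks$position, c2$breaks$position)
  f <- tempfile(); f2 <- tempfile()
  write_scenario(c1, f); write_scenario(c2, f2)
  expect_identical(readLines(file.path(f, "genome.fa")),
                   readLines(file.path(f2, "genome.fa")))
  expect_identical(readLines(file.path(f, "breaks.bed")),
                   readLines(file.path(f2, "breaks.bed")))
})

test_that("break provenance fractions match the footprint rate model", {
  sc <- make_scenario("paper_like", seed = 31)
  foot_len <- region_bases(sc$truth$footprints)
  genome_len <- sum(genome_lengths(sc$genome))
  exp_foot <- sc$truth$lambda_frag * foot_len
  exp_bg <- sc$truth$lambda_bg * (genome_len - foot_len)
  frac <- mean(sc$provenance == "footprint")
  expected <- exp_foot / (exp_foot + exp_bg)
  se <- sqrt(expected * (1 - expected) / nrow(sc$breaks))
  expect_lt(abs(frac - expected), 3 * se + 0.01)
})

test_that("planted scenario CpGs and footprint pairs are recoverable", {
  sc <- make_scenario("paper_like", seed = 13)
  cpgs <- scan_cpg(sc$genome)
  key <- paste(cpgs$chrom, cpgs$start)
  planted <- paste(sc$truth$footprints$chrom, sc$truth$cpg_starts)
  expect_true(all(planted %in% key))
})
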