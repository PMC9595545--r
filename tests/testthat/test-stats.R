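mk_hits <- function(chrom, start, mismatches = 0L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + 9L, strand = "+",
             mismatches = as.integer(mismatches),
             observed = strrep("A", 9), stringsAsFactors = FALSE)
}
mk_cpgs <- function(chrom, start) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + 2L, stringsAsFactors = FALSE)
}

test_that("proximity counts features overlapping the symmetric radius", {
  bp <- breakpoint_table("c", 500)
  ps <- proximity_summary(bp, mk_hits("c", 450), mk_cpgs("c", 520), radius = 100)
  expect_equal(ps$n_with_nonamer, 1L)
  expect_equal(ps$n_with_cpg, 1L)
  expect_equal(ps$n_with_both, 1L)

  far <- proximity_summary(bp, mk_hits("c", 650), mk_cpgs("c", 520), 100)
  expect_equal(far$n_with_nonamer, 0L)
  # inclusive edge: a nonamer starting exactly radius away still overlaps
  edge <- proximity_summary(bp, mk_hits("c", 600), mk_cpgs("c", 520), 100)
  expect_equal(edge$n_with_nonamer, 1L)
})

test_that("proximity fractions are translation invariant", {
  set.seed(5)
  pos <- sample(1000:9000, 50)
  bp <- breakpoint_table("c", pos)
  hits <- mk_hits("c", sample(1000:9000, 200))
  cpgs <- mk_cpgs("c", sample(1000:9000, 100))
  a <- proximity_summary(bp, hits, cpgs, 100)
  shift <- 12345L
  b <- proximity_summary(breakpoint_table("c", pos + shift),
                         mk_hits("c", hits$start + shift),
                         mk_cpgs("c", cpgs$start + shift), 100)
  expect_equal(a$fraction_with_nonamer, b$fraction_with_nonamer)
  expect_equal(a$fraction_with_both, b$fraction_with_both)
})

test_that("nearest pair gap is the minimal edge distance, 0 on overlap", {
  expect_equal(nearest_pair_gap("c", 15, mk_hits("c", 20), mk_cpgs("c", 10), 100), 8L)
  expect_equal(nearest_pair_gap("c", 8, mk_hits("c", 5), mk_cpgs("c", 10), 100), 0L)
  expect_true(is.na(nearest_pair_gap("c", 15, mk_hits("c", 20),
                                     mk_cpgs(character(0), integer(0)), 100)))
  # symmetric in feature order: CpG left or right of the nonamer
  left <- nearest_pair_gap("c", 50, mk_hits("c", 60), mk_cpgs("c", 40), 100)
  right <- nearest_pair_gap("c", 50, mk_hits("c", 31), mk_cpgs("c", 58), 100)
  expect_equal(left, 60L - 42L)
  expect_equal(right, 58L - 40L)
})

test_that("chi-square matches the closed form and base R", {
  expect_equal(chi_square_2x2(c(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi_square_2x2(c(10, 10, 10, 10))$p.value, 1)
  expect_equal(chi_square_2x2(c(20, 10, 10, 20))$statistic, 20 / 3)
  expect_equal(chi_square_2x2(c(5, 0, 0, 5))$statistic, 10)
  expect_error(chi_square_2x2(c(5, 5, 0, 0)), "zero marginal")

  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rbinom(4, 60, 0.5) + 1L, 2)
    mine <- chi_square_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(chi_square_2x2(tab, yates = TRUE)$statistic,
                 unname(refy$statistic), tolerance = 1e-12)
  }
})

test_that("chi-square p decreases as the statistic grows", {
  stats <- vapply(1:20, function(k) {
    chi_square_2x2(c(10 + k, 10, 10, 10 + k))$statistic
  }, numeric(1))
  ps <- pchisq(stats, 1, lower.tail = FALSE)
  expect_true(all(diff(stats) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("Mann-Whitney U comes from midranks, p exact or tie-corrected", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$p.value, ref$p.value)

  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$U, 9 / 2) # n^2 / 2 under complete ties
  single <- mann_whitney_u(5, 5)
  expect_equal(single$U, 0.5)
  expect_equal(single$p.value, 1)

  set.seed(7)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mine <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("t test handles identical and degenerate samples", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p.value, 1)
  expect_error(two_sample_t(c(1, 1, 1, 1), c(2, 2, 2, 2)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
  ok <- two_sample_t(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.finite(ok$t))
})

test_that("t test has near-full power at a one-sigma shift, n = 50", {
  set.seed(31)
  rej <- 0L
  for (i in 1:1000) {
    p <- two_sample_t(rnorm(50), rnorm(50, 1))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 1000, 0.99)
})

test_that("window contrast reports class sizes and behaves under the null", {
  st <- make_winstats(gc = rep(0.5, 78), n_nonamers = 5L)
  st$n_breaks <- rep(c(3L, 0L), each = 39)
  st$has_pair <- rep(rep(c(TRUE, FALSE), c(20, 19)), 2) # same mix per class
  cl <- classify_windows(st, 3)
  ctr <- summarize_window_contrast(cl, cl$unbroken)
  expect_equal(ctr$broken$n, 39L)
  expect_equal(ctr$control$n, 39L)
  # identical count distributions: no mean difference, U = n^2/2
  expect_equal(ctr$broken$mean_nonamers, ctr$control$mean_nonamers)
  expect_equal(ctr$mann_whitney$U, 39^2 / 2)
  expect_equal(ctr$chisq$statistic, 0, tolerance = 1e-9)
  expect_error(summarize_window_contrast(cl, cl$unbroken[0, ]), "control")
})

test_that("distance distribution recovers planted gaps per mismatch class", {
  g <- genome_sequence(c(c = strrep("C", 3000)))
  p1 <- plant_pair(g, "c", 500, gap = 8, seed = 1)
  p2 <- plant_pair(p1$genome, "c", 1500, gap = 20, seed = 2)
  p3 <- plant_pair(p2$genome, "c", 2500, gap = 90, seed = 3)
  truth <- rbind(p1$truth, p2$truth, p3$truth)
  cfg <- analysis_config()
  hits <- scan_cryptic_nonamers(p3$genome, cfg)
  cpgs <- scan_cpg(p3$genome)
  bp <- breakpoint_table("c", truth$cpg_start)
  d <- distance_distribution(bp, hits, cpgs, cfg)
  expect_equal(d$per_break$gap, c(8L, 20L, 90L))
  expect_equal(d$frac_le_pair_gap_max, 2 / 3)
  expect_equal(d$median_gap, 20)
  # the planted variant carries 2 mismatches: class-2 gaps match, class-3 absent
  expect_equal(d$per_break$mm2, c(8L, 20L, 90L))
  expect_true(all(is.na(d$per_break$mm3)))

  none <- distance_distribution(breakpoint_table("c", 10),
                                hits[0, ], cpgs[0, ], cfg)
  expect_true(none$empty)
})
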