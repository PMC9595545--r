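test_that("region intersection is half-open and idempotent", {
  a <- region_set("chr1", 0, 10)
  b <- region_set("chr1", 5, 15)
  ab <- intersect_regions(a, b)
  expect_equal(ab$start, 5L)
  expect_equal(ab$end, 10L)

  abut <- intersect_regions(region_set("chr1", 0, 10),
                            region_set("chr1", 10, 20))
  expect_equal(nrow(abut), 0L)

  aa <- intersect_regions(a, a)
  fa <- flatten_regions(a)
  expect_equal(aa$start, fa$start)
  expect_equal(aa$end, fa$end)

  # commutative, and never longer than either operand
  x <- region_set("chr1", c(0, 30, 100), c(20, 60, 150))
  y <- region_set("chr1", c(10, 50, 90), c(40, 55, 200))
  xy <- intersect_regions(x, y)
  yx <- intersect_regions(y, x)
  expect_equal(xy[, 1:3], yx[, 1:3])
  expect_lte(region_bases(xy), min(region_bases(x), region_bases(y)))
})

test_that("gieStain labels map to chromatin classes", {
  expect_identical(stain_to_class("gneg"), "euchromatin")
  expect_identical(stain_to_class(c("gpos25", "gpos100", "gvar")),
                   rep("heterochromatin", 3))
  expect_identical(stain_to_class(c("acen", "stalk")), rep("excluded", 2))
  expect_error(stain_to_class("gpos33"), "unrecognized")
})

test_that("chromatin breakdown assigns each break to one class", {
  cb <- region_set("c", c(0, 500, 800), c(500, 800, 1000),
                   label = c("gneg", "gpos50", "acen"), name = "cytoband")
  bp <- breakpoint_table("c", c(10, 100, 600, 850, 1500))
  hits <- data.frame(chrom = "c", start = c(20L, 610L), end = c(29L, 619L),
                     strand = "+", mismatches = 0L, observed = strrep("A", 9))
  cpgs <- data.frame(chrom = "c", start = c(40L, 630L), end = c(42L, 632L))
  br <- chromatin_breakdown(bp, hits, cpgs, cb, analysis_config())
  expect_equal(br$strata$euchromatin$n_breaks, 2L)
  expect_equal(br$strata$heterochromatin$n_breaks, 1L)
  expect_equal(br$n_excluded, 1L)
  expect_equal(br$n_uncovered, 1L)
  expect_equal(br$n_classified +
                 br$n_excluded + br$n_uncovered, nrow(bp))
  expect_equal(br$strata$euchromatin$fraction, 2 / 3)
  # all breaks in gneg bands -> euchromatin fraction 1
  all_eu <- chromatin_breakdown(breakpoint_table("c", c(10, 20)),
                                hits, cpgs,
                                region_set("c", 0, 1000, label = "gneg"),
                                analysis_config())
  expect_equal(all_eu$strata$euchromatin$fraction, 1)
  expect_error(chromatin_breakdown(bp, hits, cpgs,
                                   region_set(character(0), integer(0),
                                              integer(0)),
                                   analysis_config()),
               "empty cytoband")
})

test_that("promoter breakdown is membership-based and order invariant", {
  prom <- region_set("c", c(50, 300), c(150, 400), name = "promoters")
  bp <- breakpoint_table("c", c(100, 200, 350, 500))
  hits <- data.frame(chrom = "c", start = 90L, end = 99L, strand = "+",
                     mismatches = 0L, observed = strrep("A", 9))
  cpgs <- data.frame(chrom = "c", start = 105L, end = 107L)
  pb <- promoter_breakdown(bp, prom, hits, cpgs, analysis_config())
  expect_equal(pb$n_in_promoters, 2L)
  expect_equal(pb$fraction, 0.5)
  expect_equal(pb$n_in_promoters_with_pair, 1L)

  shuffled <- region_set("c", c(300, 50), c(400, 150), name = "promoters")
  pb2 <- promoter_breakdown(bp, shuffled, hits, cpgs, analysis_config())
  expect_equal(pb2$fraction, pb$fraction)
  # half-open boundaries: a break exactly at an interval end is outside
  edge <- promoter_breakdown(breakpoint_table("c", c(150, 149)), prom,
                             hits, cpgs, analysis_config())
  expect_equal(edge$n_in_promoters, 1L)
})

test_that("cohort comparison reports unit ratios for identical cohorts", {
  w <- make_winstats(gc = rep(0.4, 10), n_nonamers = 7L, n_cpgs = 2L,
                     n_breaks = 4L)
  cc <- cohort_compare(list(lymphoid = w, nonlymphoid = w))
  expect_true(all(cc$ratios_vs_first == 1))
  expect_error(cohort_compare(list(a = w, b = w[0, ])), "zero broken")
  expect_error(cohort_compare(list(a = w)), "two cohorts")
})
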