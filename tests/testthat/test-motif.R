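test_that("hamming distance counts differing positions, N always mismatches", {
  expect_equal(hamming_distance("ACAAAAACC", "ACAAAAACC"), 0L)
  expect_equal(hamming_distance("ACAAAAACC", "ACAAAAACG"), 1L)
  expect_equal(hamming_distance("ACAAAAACC", "ACANAAACC"), 1L)
  expect_equal(hamming_distance("NNN", "NNN"), 3L)
  expect_error(hamming_distance("ACGT", "ACG"), "unequal lengths")
  expect_error(hamming_distance("ACGU", "ACGT"), "A,C,G,T,N")
})

test_that("reverse complement is the reversed Watson-Crick complement", {
  expect_identical(reverse_complement("ACAAAAACC"), "GGTTTTTGT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("N"), "N")
  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(sample(1:40, 1), gc = 0.5, seed = i)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("scanner finds canonical nonamers on both strands", {
  cfg <- analysis_config()
  h <- scan_cryptic_nonamers(genome_sequence(c(c1 = "ACAAAAACC")), cfg)
  expect_equal(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_equal(h$mismatches, 0L)
  expect_identical(h$observed, "ACAAAAACC")

  h <- scan_cryptic_nonamers(genome_sequence(c(c1 = "GGTTTTTGT")), cfg)
  expect_equal(nrow(h), 1L)
  expect_identical(h$strand, "-")
  expect_equal(h$mismatches, 0L)
  expect_identical(h$observed, "ACAAAAACC") # read 5'->3' on the hit strand

  h <- scan_cryptic_nonamers(genome_sequence(c(c1 = "ACAAAAACCC")), cfg)
  expect_equal(nrow(h), 2L)
  expect_identical(h$strand, c("+", "+"))
  expect_equal(h$start, c(0L, 1L))
  expect_equal(h$mismatches, c(0L, 3L))

  h <- scan_cryptic_nonamers(genome_sequence(c(c1 = "CCCCCCCCC")), cfg)
  expect_equal(nrow(h), 0L)
})

test_that("scanner matches the brute-force oracle on random sequences", {
  cfg <- analysis_config()
  for (gc in c(0.3, 0.5, 0.7)) {
    for (i in 1:3) {
      s <- random_seq(300, gc = gc, seed = 100 * gc + i)
      got <- scan_cryptic_nonamers(genome_sequence(c(z = s)), cfg)
      expect_identical(hit_key(got), hit_key(oracle_scan(s)))
    }
  }
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  s <- random_seq(400, gc = 0.45, seed = 99)
  cfg <- analysis_config()
  fwd <- scan_cryptic_nonamers(genome_sequence(c(g = s)), cfg)
  rev <- scan_cryptic_nonamers(genome_sequence(c(g = reverse_complement(s))), cfg)
  mapped <- data.frame(start = nchar(s) - (rev$start + 9L),
                       strand = ifelse(rev$strand == "+", "-", "+"),
                       mismatches = rev$mismatches)
  expect_identical(hit_key(fwd), hit_key(mapped))
})

test_that("windows drowned in N cannot pass; few Ns count as mismatches", {
  cfg <- analysis_config()
  expect_equal(nrow(scan_cryptic_nonamers(
    genome_sequence(c(c1 = "NNNNNNNNN")), cfg)), 0L)
  # four Ns in an otherwise exact motif: exactly at the tolerance
  h <- scan_cryptic_nonamers(genome_sequence(c(c1 = "NNNNAAACC")), cfg)
  expect_equal(h$mismatches[h$strand == "+"], 4L)
})

test_that("require_positions enforces exact conservation where asked", {
  # position 5 mutated: a 1-mismatch hit by default, gone under the filter
  g <- genome_sequence(c(c1 = "ACAATAACC"))
  expect_equal(nrow(scan_cryptic_nonamers(g, analysis_config())), 1L)
  strict <- analysis_config(require_positions = c(5, 6))
  expect_equal(nrow(scan_cryptic_nonamers(g, strict)), 0L)
  # minus-strand hits honour the same positions through the complement
  gm <- genome_sequence(c(c1 = reverse_complement("ACAATAACC")))
  expect_equal(nrow(scan_cryptic_nonamers(gm, strict)), 0L)
  gm2 <- genome_sequence(c(c1 = "GGTTTTTGT"))
  expect_equal(nrow(scan_cryptic_nonamers(gm2, strict)), 1L)
})

test_that("CpG scan reports every CG, including adjacent ones", {
  expect_equal(scan_cpg(genome_sequence(c(c = "ACGT")))$start, 1L)
  expect_equal(scan_cpg(genome_sequence(c(c = "CGCG")))$start, c(0L, 2L))
  expect_equal(scan_cpg(genome_sequence(c(c = "GCGC")))$start, 1L)
  expect_equal(nrow(scan_cpg(genome_sequence(c(c = "A")))), 0L)
})

test_that("CpG counts are strand-invariant", {
  for (i in 1:10) {
    s <- random_seq(500, gc = 0.6, seed = 300 + i)
    a <- nrow(scan_cpg(genome_sequence(c(x = s))))
    b <- nrow(scan_cpg(genome_sequence(c(x = reverse_complement(s)))))
    expect_equal(a, b)
  }
})

test_that("PWM frequencies follow base counts and renormalise around N", {
  p1 <- build_pwm("ACAAAAACC")
  expect_equal(unname(p1["A", 1]), 1)
  expect_equal(unname(colSums(p1)), rep(1, 9))

  p2 <- build_pwm(c("ACAAAAACC", "GCAAAAACC"))
  expect_equal(unname(p2["A", 1]), 0.5)
  expect_equal(unname(p2["G", 1]), 0.5)
  expect_equal(unname(p2["C", 2]), 1)

  expect_error(build_pwm(character(0)), "no hits")

  pN <- build_pwm(c("NCAAAAACC", "GCAAAAACC"))
  expect_equal(unname(pN["G", 1]), 1) # N contributes no mass at position 1
  expect_equal(unname(colSums(pN)), rep(1, 9))
  expect_equal(attr(pN, "n"), 2L)
})

test_that("conservation flags positions by maximal frequency", {
  one_hot <- build_pwm("ACAAAAACC")
  cons <- pwm_conservation(one_hot, 0.6)
  expect_true(all(cons$conserved))
  expect_equal(cons$frequency, rep(1, 9))
  expect_identical(paste(cons$consensus, collapse = ""), "ACAAAAACC")

  uniform <- build_pwm(c(strrep("A", 9), strrep("C", 9),
                         strrep("G", 9), strrep("T", 9)))
  expect_false(any(pwm_conservation(uniform, 0.6)$conserved))
  expect_error(pwm_conservation(one_hot, 0), "threshold")
  expect_error(pwm_conservation(one_hot, 1.2), "threshold")
})

test_that("motif space size follows the Hamming-ball closed form", {
  expect_equal(motif_space_size(0), 1)
  expect_equal(motif_space_size(1), 1 + 9 * 3)
  expect_equal(motif_space_size(9), 4^9)
})
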