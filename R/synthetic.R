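# Synthetic genomes with planted ground truth. This module stands in for
# the patient breakpoint compilations and the reference genome: it emits
# i.i.d. genomes with a controllable GC content and (optionally) human-like
# CpG depletion, plants nonamer variants and CpG-nonamer pairs at known
# coordinates, and simulates breakpoints whose per-base rate is elevated
# inside "fragile footprints". Every random component draws from its own
# child stream of the master seed, so parts can be regenerated
# independently and whole scenarios are byte-reproducible.

.CANONICAL_NONAMER <- "ACAAAAACC"

# A distance-2 nonamer variant whose embeddings in a poly-C inert filler
# produce exactly one scanner hit: the canonical nonamer overlaps itself at
# shift 1 with Hamming distance 3, so an *exact* plant always drags in
# shifted hits 1-2 bp to each side; this variant does not (verified over
# all shifts, both strands, with a CpG at any gap and order). Used for
# fixtures that must recover planted pair gaps exactly.
.SHIFT_RESISTANT_VARIANT <- "ACAAGTACC"

#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`. With `cpg_retention < 1` the genome is then
#' depleted of CpGs the way mammalian genomes are: each CG dinucleotide is
#' kept with the given probability and otherwise its C is deaminated to T.
#' The default retention 0.2 reproduces the roughly five-fold CpG depletion
#' of the human genome, under which about 57% of 100 bp windows contain a
#' CpG at GC 0.41.
#'
#' @param lengths named vector of chromosome lengths.
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed master seed (one child stream per chromosome).
#' @param cpg_retention probability that a CpG survives thinning.
#' @return a [genome_sequence()].
#' @export
#' @examples
#' generate_genome(c(chr1 = 1000), gc = 0.5, seed = 1)
generate_genome <- function(lengths, gc = 0.41, seed = 1L,
                            cpg_retention = 1) {
  stopifnot(is.numeric(lengths), length(lengths) >= 1L,
            !is.null(names(lengths)), all(lengths >= 1))
  if (gc < 0 || gc > 1) .stopf("`gc` must lie in [0, 1]")
  if (cpg_retention < 0 || cpg_retention > 1) {
    .stopf("`cpg_retention` must lie in [0, 1]")
  }
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  seqs <- vapply(seq_along(lengths), function(k) {
    with_seed(child_seed(seed, k), {
      b <- codes[sample.int(4L, lengths[[k]], replace = TRUE, prob = prob)]
      if (cpg_retention < 1 && lengths[[k]] >= 2L) {
        n <- length(b)
        cg <- which(b[-n] == codes[2L] & b[-1L] == codes[3L])
        if (length(cg)) {
          drop <- cg[runif(length(cg)) >= cpg_retention]
          b[drop] <- codes[4L] # C -> T, deamination-style
        }
      }
      intToUtf8(b)
    })
  }, character(1))
  names(seqs) <- names(lengths)
  genome_sequence(seqs)
}

.write_at <- function(seq, position, insert) {
  # overwrite (not insert) `insert` at 0-based `position`
  paste0(substr(seq, 1L, position),
         insert,
         substr(seq, position + nchar(insert) + 1L, nchar(seq)))
}

#' Plant a cryptic nonamer variant in a genome
#'
#' Writes a 9-mer at exactly `mismatches` Hamming distance from the
#' canonical nonamer (mutated positions chosen uniformly, substituted
#' bases uniform over the three alternatives) at the given position, on a
#' uniformly chosen strand: a minus-strand plant writes the reverse
#' complement of the variant, and the scanner reports it as a minus-strand
#' hit.
#'
#' @param genome a [genome_sequence()].
#' @param chrom chromosome name.
#' @param position 0-based start; `position + 9` must fit the chromosome.
#' @param mismatches intended Hamming distance, 0 to 4.
#' @param seed seed for variant and strand choice.
#' @param motif reference nonamer.
#' @return list with the modified `genome` and a one-row `truth` data frame
#'   (`chrom, start, strand, mismatches, planted` — the variant in
#'   hit-strand orientation).
#' @export
plant_motif <- function(genome, chrom, position, mismatches, seed = 1L,
                        motif = .CANONICAL_NONAMER) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!.is_count(mismatches) || mismatches < 0 || mismatches > 4) {
    .stopf("`mismatches` must be an integer in [0, 4]")
  }
  len <- genome_lengths(genome)[[chrom]]
  if (position < 0 || position + 9L > len) {
    .stopf("plant at %s:%d does not fit (length %d)", chrom, position, len)
  }
  res <- with_seed(seed, {
    v <- strsplit(motif, "")[[1]]
    if (mismatches > 0) {
      at <- sample.int(9L, mismatches)
      for (j in at) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1L)
    }
    list(variant = paste(v, collapse = ""),
         strand = sample(c("+", "-"), 1L))
  })
  written <- if (res$strand == "+") res$variant else reverse_complement(res$variant)
  g <- unclass(genome)
  g[[chrom]] <- .write_at(g[[chrom]], position, written)
  list(genome = genome_sequence(g),
       truth = data.frame(chrom = chrom, start = as.integer(position),
                          strand = res$strand,
                          mismatches = as.integer(mismatches),
                          planted = res$variant, stringsAsFactors = FALSE))
}

#' Plant a CpG-nonamer pair at an exact edge gap
#'
#' Writes a CG dinucleotide and a plus-strand nonamer variant separated by
#' exactly `gap` intervening bases (the edge-to-edge distance the
#' co-occurrence statistics measure); whether the CpG or the nonamer comes
#' first is chosen by the seed. With `inert_radius > 0` the surrounding
#' `[anchor - inert_radius, anchor + block + inert_radius)` is first
#' overwritten with poly-C inert filler, which carries no CpG and no
#' cryptic nonamer on either strand, so the planted pair is the only
#' feature in the neighbourhood and its gap is recovered exactly. For that
#' reason the default planted variant is the shift-resistant
#' `ACAAGTACC` (2 mismatches) rather than the canonical nonamer, whose
#' self-overlap would scatter extra hits 1-2 bp around the plant.
#'
#' @param genome a [genome_sequence()].
#' @param chrom chromosome name.
#' @param anchor 0-based start of the planted block.
#' @param gap exact edge gap in bases (>= 0).
#' @param seed seed deciding the feature order.
#' @param variant the 9-mer written (must be within 4 mismatches of the
#'   canonical nonamer).
#' @param inert_radius bases of inert filler written either side of the
#'   block (0 = plant into the background as-is).
#' @return list with the modified `genome` and a one-row `truth` data frame
#'   (`chrom, cpg_start, nonamer_start, strand, mismatches, gap, order`).
#' @export
plant_pair <- function(genome, chrom, anchor, gap, seed = 1L,
                       variant = .SHIFT_RESISTANT_VARIANT,
                       inert_radius = 0L) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!.is_count(gap) || gap < 0) .stopf("`gap` must be a non-negative integer")
  mm <- hamming_distance(variant, .CANONICAL_NONAMER)
  if (mm > 4) .stopf("`variant` must be within 4 mismatches of the canonical nonamer")
  block <- 2L + gap + 9L
  len <- genome_lengths(genome)[[chrom]]
  lo <- anchor - inert_radius
  hi <- anchor + block + inert_radius
  if (lo < 0 || hi > len) {
    .stopf("pair block [%d, %d) does not fit chromosome %s (length %d)",
           lo, hi, chrom, len)
  }
  cpg_first <- with_seed(seed, sample(c(TRUE, FALSE), 1L))
  g <- unclass(genome)
  if (inert_radius > 0L) {
    g[[chrom]] <- .write_at(g[[chrom]], lo, strrep("C", hi - lo))
  }
  if (cpg_first) {
    cpg_start <- anchor
    nona_start <- anchor + 2L + gap
  } else {
    nona_start <- anchor
    cpg_start <- anchor + 9L + gap
  }
  g[[chrom]] <- .write_at(g[[chrom]], cpg_start, "CG")
  g[[chrom]] <- .write_at(g[[chrom]], nona_start, variant)
  list(genome = genome_sequence(g),
       truth = data.frame(chrom = chrom,
                          cpg_start = as.integer(cpg_start),
                          nonamer_start = as.integer(nona_start),
                          strand = "+",
                          mismatches = as.integer(mm),
                          gap = as.integer(gap),
                          order = if (cpg_first) "cpg_first" else "nonamer_first",
                          stringsAsFactors = FALSE))
}

#' Simulate breakpoints from a footprint break model
#'
#' Per-base independent break probability `lambda_frag` inside the fragile
#' footprints and `lambda_bg` outside (Bernoulli thinning; at most one
#' break per base by construction). Provenance of every break is recorded.
#'
#' @param genome a [genome_sequence()].
#' @param footprints a [region_set()] of fragile footprints, or `NULL`.
#' @param lambda_bg,lambda_frag per-base break probabilities.
#' @param seed seed (one child stream per chromosome).
#' @param cohort cohort label for the simulated breaks.
#' @param id_prefix prefix for generated source ids.
#' @param max_expected guard against runaway rates: error when the expected
#'   break count exceeds this cap.
#' @return list with `breaks` (a [breakpoint_table()]) and `provenance`
#'   (character, `"footprint"` or `"background"`, one per break).
#' @export
simulate_breakpoints <- function(genome, footprints = NULL,
                                 lambda_bg = 1e-5, lambda_frag = 0.05,
                                 seed = 1L, cohort = "unlabeled",
                                 id_prefix = "sim", max_expected = 5e5) {
  stopifnot(inherits(genome, "genome_sequence"),
            lambda_bg >= 0, lambda_frag >= 0)
  len <- genome_lengths(genome)
  foot_len <- if (is.null(footprints)) 0 else region_bases(footprints)
  expected <- lambda_bg * (sum(as.numeric(len)) - foot_len) +
    lambda_frag * foot_len
  if (expected > max_expected) {
    .stopf("expected break count %.0f exceeds cap %.0f; lower the rates",
           expected, max_expected)
  }
  chroms <- character(0); pos <- integer(0); prov <- character(0)
  for (k in seq_along(len)) {
    ch <- names(len)[k]
    n <- len[[k]]
    rate <- rep(lambda_bg, n)
    in_foot <- rep(FALSE, n)
    if (!is.null(footprints)) {
      fp <- footprints[footprints$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(fp))) {
        idx <- (fp$start[j] + 1L):fp$end[j]
        rate[idx] <- lambda_frag
        in_foot[idx] <- TRUE
      }
    }
    hit <- with_seed(child_seed(seed, k), which(runif(n) < rate))
    chroms <- c(chroms, rep(ch, length(hit)))
    pos <- c(pos, hit - 1L)
    prov <- c(prov, ifelse(in_foot[hit], "footprint", "background"))
  }
  ids <- if (length(pos)) sprintf("%s_%05d", id_prefix, seq_along(pos)) else character(0)
  breaks <- breakpoint_table(chroms, pos, cohort = cohort, source_id = ids)
  list(breaks = breaks, provenance = prov)
}

# evenly spaced candidate anchors, at least `stride` apart, inside margins
.anchor_grid <- function(len, margin, stride) {
  seq.int(margin, len - margin, by = stride)
}

#' Build a complete synthetic scenario
#'
#' Self-consistent (genome, breakpoints, annotations, ground truth)
#' bundles for end-to-end runs:
#'
#' * `"paper_like"`: 500 kb over two chromosomes at GC 0.41 with human-like
#'   CpG depletion; 39 fragile footprint windows of 100 bp, each carrying a
#'   planted CpG followed (gap uniform on 10-80 bp) by a tandem array of
#'   canonical nonamers filling the window, so broken windows carry several
#'   times the background nonamer density; breaks at 0.08/base inside
#'   footprints vs 2e-5 outside (about 8 per broken window); alternating
#'   gneg/gpos cytobands and a sparse promoter track.
#' * `"null"`: 100 kb, same genome model; footprints are laid out but not
#'   planted and `lambda_frag == lambda_bg == 0.01`, so break-cluster
#'   windows arise by Poisson chance alone and feature co-occurrence is
#'   independent of class (type-I calibration).
#' * `"promoter_fixture"`: 200 kb with 20 promoters of 2.5 kb (a TSS
#'   -2000..+500 layout); 1000 breaks placed with probability 0.02 inside
#'   promoters, uniform elsewhere.
#' * `"cohort_fixture"`: 200 kb with a CpG-free background; 20 lymphoid
#'   footprint windows planted with 2 CpGs each and 20 nonlymphoid windows
#'   with 1 CpG each (equal nonamer arrays), breaks only inside footprints,
#'   labelled by cohort — the designed lymphoid/nonlymphoid CpG ratio is
#'   exactly 2.
#'
#' @param name scenario name.
#' @param seed master seed; identical `(name, seed)` pairs reproduce the
#'   scenario byte for byte.
#' @return list with `name`, `seed`, `genome`, `breaks`
#'   (a [breakpoint_table()]), `provenance`, `config`, `annotations`
#'   (list of `promoters`, `cytobands`, possibly `NULL`) and `truth`.
#' @export
make_scenario <- function(name = c("paper_like", "null", "promoter_fixture",
                                   "cohort_fixture"),
                          seed = 1L) {
  name <- match.arg(name)
  switch(name,
         paper_like = .scenario_paper_like(seed),
         null = .scenario_null(seed),
         promoter_fixture = .scenario_promoter(seed),
         cohort_fixture = .scenario_cohort(seed))
}

.scenario_paper_like <- function(seed) {
  lengths <- c(chr1 = 300000L, chr2 = 200000L)
  genome <- generate_genome(lengths, gc = 0.41, seed = child_seed(seed, 1),
                            cpg_retention = 0.2)
  # 39 footprint windows of 100 bp on a 1 kb grid (no two adjacent)
  grid <- rbind(
    data.frame(chrom = "chr1", start = .anchor_grid(300000L, 1000L, 1000L)),
    data.frame(chrom = "chr2", start = .anchor_grid(200000L, 1000L, 1000L))
  )
  grid$start <- (grid$start %/% 100L) * 100L
  picked <- with_seed(child_seed(seed, 2), {
    grid[sample.int(nrow(grid), 39L), , drop = FALSE]
  })
  g <- unclass(genome)
  gaps <- integer(39)
  cpg_starts <- integer(39)
  with_seed(child_seed(seed, 3), {
    for (i in seq_len(39L)) {
      w <- picked$start[i]
      ch <- picked$chrom[i]
      gap <- sample(10:80, 1L)
      gaps[i] <- gap
      cpg <- w + 3L
      cpg_starts[i] <- cpg
      array_start <- cpg + 2L + gap
      n_copies <- max(1L, (w + 97L - array_start) %/% 9L)
      g[[ch]] <- .write_at(g[[ch]], cpg, "CG")
      g[[ch]] <- .write_at(g[[ch]], array_start,
                           strrep(.CANONICAL_NONAMER, n_copies))
    }
  })
  genome <- genome_sequence(g)
  footprints <- region_set(picked$chrom, picked$start, picked$start + 100L,
                           name = "footprints")
  sim <- simulate_breakpoints(genome, footprints,
                              lambda_bg = 2e-5, lambda_frag = 0.08,
                              seed = child_seed(seed, 4), cohort = "lymphoid")
  cytobands <- .alternating_cytobands(lengths, band = 25000L)
  promoters <- with_seed(child_seed(seed, 5), {
    st <- sort(sample(.anchor_grid(300000L, 5000L, 5000L), 20L))
    region_set("chr1", st, st + 2500L, name = "promoters")
  })
  list(name = "paper_like", seed = as.integer(seed), genome = genome,
       breaks = sim$breaks, provenance = sim$provenance,
       config = analysis_config(random_seed = seed),
       annotations = list(promoters = promoters, cytobands = cytobands),
       truth = list(footprints = footprints, pair_gaps = gaps,
                    cpg_starts = cpg_starts,
                    lambda_bg = 2e-5, lambda_frag = 0.08))
}

.scenario_null <- function(seed) {
  lengths <- c(chr1 = 100000L)
  genome <- generate_genome(lengths, gc = 0.41, seed = child_seed(seed, 1),
                            cpg_retention = 0.2)
  starts <- with_seed(child_seed(seed, 2), {
    sort(sample(.anchor_grid(100000L, 1000L, 1000L), 20L))
  })
  starts <- (starts %/% 100L) * 100L
  footprints <- region_set("chr1", starts, starts + 100L, name = "footprints")
  rate <- 0.01
  sim <- simulate_breakpoints(genome, footprints,
                              lambda_bg = rate, lambda_frag = rate,
                              seed = child_seed(seed, 3))
  list(name = "null", seed = as.integer(seed), genome = genome,
       breaks = sim$breaks, provenance = sim$provenance,
       config = analysis_config(random_seed = seed),
       annotations = list(promoters = NULL, cytobands = NULL),
       truth = list(footprints = footprints, lambda_bg = rate,
                    lambda_frag = rate))
}

.scenario_promoter <- function(seed) {
  lengths <- c(chr1 = 200000L)
  genome <- generate_genome(lengths, gc = 0.41, seed = child_seed(seed, 1),
                            cpg_retention = 0.2)
  tss <- .anchor_grid(200000L, 10000L, 9000L)[1:20]
  promoters <- region_set("chr1", tss - 2000L, tss + 500L, name = "promoters")
  prom_pos <- unlist(mapply(seq.int, promoters$start, promoters$end - 1L,
                            SIMPLIFY = FALSE))
  n_breaks <- 1000L
  placed <- with_seed(child_seed(seed, 2), {
    in_prom <- runif(n_breaks) < 0.02
    pos <- integer(n_breaks)
    pos[in_prom] <- sample(prom_pos, sum(in_prom))
    outside <- setdiff(0:(200000L - 1L), prom_pos)
    pos[!in_prom] <- sample(outside, sum(!in_prom))
    list(pos = pos, in_prom = in_prom)
  })
  breaks <- breakpoint_table("chr1", placed$pos,
                             source_id = sprintf("p_%04d", seq_len(n_breaks)))
  list(name = "promoter_fixture", seed = as.integer(seed), genome = genome,
       breaks = breaks, provenance = ifelse(placed$in_prom, "promoter",
                                            "background"),
       config = analysis_config(random_seed = seed),
       annotations = list(promoters = promoters, cytobands = NULL),
       truth = list(in_promoter = placed$in_prom, target_fraction = 0.02))
}

.scenario_cohort <- function(seed) {
  lengths <- c(chr1 = 200000L)
  genome <- generate_genome(lengths, gc = 0.41, seed = child_seed(seed, 1),
                            cpg_retention = 0)
  grid <- .anchor_grid(200000L, 2000L, 2000L)
  grid <- (grid %/% 100L) * 100L
  picked <- with_seed(child_seed(seed, 2), sample(grid, 40L))
  lym <- sort(picked[1:20])
  non <- sort(picked[21:40])
  g <- unclass(genome)
  plant_window <- function(w, n_cpg) {
    g[["chr1"]] <<- .write_at(g[["chr1"]], w + 10L, "CG")
    if (n_cpg > 1L) g[["chr1"]] <<- .write_at(g[["chr1"]], w + 40L, "CG")
    g[["chr1"]] <<- .write_at(g[["chr1"]], w + 60L,
                              strrep(.CANONICAL_NONAMER, 3L))
  }
  for (w in lym) plant_window(w, 2L)
  for (w in non) plant_window(w, 1L)
  genome <- genome_sequence(g)
  fp_lym <- region_set("chr1", lym, lym + 100L, name = "lymphoid_footprints")
  fp_non <- region_set("chr1", non, non + 100L, name = "nonlymphoid_footprints")
  sim_l <- simulate_breakpoints(genome, fp_lym, lambda_bg = 0,
                                lambda_frag = 0.08,
                                seed = child_seed(seed, 3),
                                cohort = "lymphoid", id_prefix = "lym")
  sim_n <- simulate_breakpoints(genome, fp_non, lambda_bg = 0,
                                lambda_frag = 0.08,
                                seed = child_seed(seed, 4),
                                cohort = "nonlymphoid", id_prefix = "non")
  breaks <- breakpoint_table(
    c(sim_l$breaks$chrom, sim_n$breaks$chrom),
    c(sim_l$breaks$position, sim_n$breaks$position),
    cohort = c(sim_l$breaks$cohort, sim_n$breaks$cohort),
    source_id = c(sim_l$breaks$source_id, sim_n$breaks$source_id))
  list(name = "cohort_fixture", seed = as.integer(seed), genome = genome,
       breaks = breaks,
       provenance = c(sim_l$provenance, sim_n$provenance),
       config = analysis_config(random_seed = seed),
       annotations = list(promoters = NULL, cytobands = NULL),
       truth = list(lymphoid_footprints = fp_lym,
                    nonlymphoid_footprints = fp_non,
                    designed_cpg_ratio = 2))
}

.alternating_cytobands <- function(lengths, band = 25000L) {
  stains <- c("gneg", "gpos50", "gneg", "gpos100", "gneg", "gvar")
  pieces <- lapply(names(lengths), function(ch) {
    starts <- seq.int(0L, lengths[[ch]] - 1L, by = band)
    ends <- pmin(starts + band, lengths[[ch]])
    data.frame(chrom = ch, start = starts, end = ends,
               label = rep_len(stains, length(starts)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  region_set(df$chrom, df$start, df$end, label = df$label, name = "cytoband")
}

#' Write a scenario's fixtures to standard files
#'
#' Emits FASTA (genome), BED (breakpoints, promoters), cytoband TSV and a
#' JSON ground-truth file into a directory; the test-suite inputs are
#' exactly these formats.
#'
#' @param scenario a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(scenario$genome, file.path(dir, "genome.fa"))
  write_breakpoints_bed(scenario$breaks, file.path(dir, "breaks.bed"))
  if (!is.null(scenario$annotations$promoters)) {
    write_regions_bed(scenario$annotations$promoters,
                      file.path(dir, "promoters.bed"))
  }
  if (!is.null(scenario$annotations$cytobands)) {
    cb <- scenario$annotations$cytobands
    write.table(data.frame(cb$chrom, cb$start, cb$end,
                           paste0("band", seq_len(nrow(cb))), cb$label),
                file.path(dir, "cytoband.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  truth <- scenario$truth
  truth$footprints <- NULL
  truth$lymphoid_footprints <- NULL
  truth$nonlymphoid_footprints <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
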