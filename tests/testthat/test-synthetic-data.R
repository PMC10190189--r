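test_that("background CpG density matches the i.i.d. expectation", {
  g <- simulate_genome(n_chrom = 1L, chrom_length_bp = 1e5, gc_fraction = 0.5,
                       island_density = 0, site_density = 0, seed = 42)
  n_pairs <- g$lengths[[1]] - 1
  expected <- n_pairs / 16
  se <- sqrt(n_pairs * (1 / 16) * (15 / 16))
  expect_lt(abs(genome_cpg_count(g) - expected), 3 * se)
})

test_that("genome simulation is deterministic and islands are CpG-dense", {
  g1 <- simulate_genome(1L, 5e4, 0.5, island_density = 0.01, seed = 7)
  g2 <- simulate_genome(1L, 5e4, 0.5, island_density = 0.01, seed = 7)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$cpg_index, g2$cpg_index)

  g <- simulate_genome(1L, 2e5, 0.5, island_density = 0.01,
                       site_density = 0, seed = 3)
  expect_gt(length(g$islands), 0)
  inside_cpg <- sum(count_cpgs_in_oracle(g, g$islands))
  inside_bp <- sum(GenomicRanges::width(g$islands))
  outside_cpg <- genome_cpg_count(g) - inside_cpg
  outside_bp <- sum(g$lengths) - inside_bp
  expect_gte((inside_cpg / inside_bp) / (outside_cpg / outside_bp), 5)
})

test_that("digestion cuts at the offset inside each site", {
  g <- genome_from_seq(c(chr1 = "TTCTGCAGAA"))
  fr <- digest_genome(g, size_min = 2, size_max = 8)
  ## site at 1-based 3; cut after base 7 -> fragments 1-7 and 8-10
  expect_equal(GenomicRanges::start(fr), c(1L, 8L))
  expect_equal(GenomicRanges::end(fr), c(7L, 10L))
  expect_equal(fr$selected, c(TRUE, TRUE))

  g0 <- genome_from_seq(c(chr1 = strrep("AT", 200)))
  fr0 <- digest_genome(g0)
  expect_equal(length(fr0), 1L)
  expect_equal(GenomicRanges::width(fr0), 400L)
  expect_true(fr0$selected)  # 400 bp is inside 200-500
})

test_that("regularly spaced sites select all internal fragments", {
  ## 50 sites 300 bp apart: internal fragments 300 bp (selected); the two
  ## terminal fragments selected iff their length is in [200, 500]
  unit <- paste0(strrep("A", 294), "CTGCAG")
  seqs <- paste0(strrep("T", 150), strrep(unit, 50), strrep("T", 700))
  g <- genome_from_seq(c(chr1 = seqs))
  fr <- digest_genome(g)
  internal <- fr[-c(1, length(fr))]
  expect_true(all(GenomicRanges::width(internal) == 300L))
  expect_true(all(internal$selected))
  expect_equal(fr$selected[1], GenomicRanges::width(fr)[1] >= 200 &
                 GenomicRanges::width(fr)[1] <= 500)
  expect_false(fr$selected[length(fr)])  # 700 + remnant tail > 500
})

test_that("fragment boundaries abut and cpg counts match a direct scan", {
  g <- simulate_genome(1L, 5e4, 0.5, island_density = 0.01, seed = 11)
  fr <- digest_genome(g)
  expect_equal(GenomicRanges::start(fr)[1], 1L)
  expect_equal(GenomicRanges::end(fr)[length(fr)], g$lengths[[1]])
  expect_true(all(GenomicRanges::start(fr)[-1] ==
                    GenomicRanges::end(fr)[-length(fr)] + 1L))
  expect_equal(fr$cpg_count, as.integer(count_cpgs_in_oracle(g, fr)))
})

test_that("capture probability follows the saturating law", {
  expect_equal(capture_probability(0, kappa = 1, epsilon = 0), 0)
  expect_equal(capture_probability(1, kappa = 1, epsilon = 0), 0.5)
  expect_equal(capture_probability(0, kappa = 1, epsilon = 0.01), 0.01)
  m <- 0:50
  for (kappa in c(0.5, 1, 4)) {
    for (eps in c(0, 0.01, 0.3)) {
      p <- capture_probability(m, kappa, eps)
      expect_true(all(diff(p) >= 0))
      expect_true(all(p >= 0 & p <= 1))
    }
  }
  expect_error(capture_probability(1, kappa = 0), "kappa")
})

test_that("methylome planting records truth and respects islands", {
  g <- simulate_genome(1L, 2e5, 0.5, island_density = 0.02, seed = 5)
  fr <- digest_genome(g)
  me <- plant_methylome(g, fr, groups = c("E", "B"), n_dmrs = 20L,
                        delta = 0.5, seed = 9)
  expect_equal(length(me$truth_dmrs), 20L)
  ov <- GenomicRanges::findOverlaps(me$truth_dmrs, fr[fr$selected],
                                    type = "equal")
  expect_equal(length(ov), 20L)  # every truth record is a selected fragment
  expect_true(all(abs(me$truth_dmrs$delta) == 0.5))

  ## the untouched group keeps the plain island/baseline structure
  me2 <- plant_methylome(g, fr, baseline_meth = 0.8, island_meth = 0.2)
  cpg <- g$cpg_index[["chr1"]]
  p <- me2$prob[["E"]][["chr1"]]
  isl <- g$islands
  inside <- rep(FALSE, length(cpg))
  for (k in seq_along(isl)) {
    inside <- inside | (cpg >= GenomicRanges::start(isl)[k] &
                          cpg <= GenomicRanges::end(isl)[k])
  }
  expect_lt(mean(p[inside]), mean(p[!inside]))
  expect_error(plant_methylome(g, fr, baseline_meth = 0.8, n_dmrs = 5,
                               delta = 0.9, seed = 1), "infeasible")
})

test_that("null methylome leaves groups identical", {
  g <- simulate_genome(1L, 5e4, 0.5, seed = 2)
  fr <- digest_genome(g)
  me <- plant_methylome(g, fr, groups = c("E", "B"), n_dmrs = 0L)
  expect_identical(me$prob[["E"]], me$prob[["B"]])
})

test_that("read simulation is deterministic and reads match their truth", {
  g <- simulate_genome(1L, 1e5, 0.5, island_density = 0.01, seed = 21)
  fr <- digest_genome(g)
  me <- plant_methylome(g, fr, groups = c("E", "B"), seed = 1)
  sheet <- make_sample_sheet(c(E = 2L, B = 2L), barcode_len = 6L, seed = 4)
  sim1 <- simulate_medip_reads(fr, me, sheet, g, 300, seed = 8, gzip = FALSE)
  sim2 <- simulate_medip_reads(fr, me, sheet, g, 300, seed = 8, gzip = FALSE)
  expect_identical(readLines(sim1$r1), readLines(sim2$r1))
  expect_identical(readLines(sim1$r2), readLines(sim2$r2))

  r1 <- read_fastq(sim1$r1)
  r2 <- read_fastq(sim1$r2)
  truth <- sim1$truth
  expect_equal(nrow(r1), length(truth))  # one truth record per pair
  seq1 <- as.character(g$sequences[[1]])
  bc <- stats::setNames(sheet$barcode, sheet$sample)
  idx <- sample(length(truth), 25)
  for (i in idx) {
    exp_bc <- bc[[truth$sample[i]]]
    expect_equal(substr(r1$seq[i], 1, 6), exp_bc)
    expect_equal(substr(r1$seq[i], 7, 11), "CTGCA")
    ins <- substr(r1$seq[i], 12, nchar(r1$seq[i]))
    expect_equal(ins, substr(seq1, GenomicRanges::start(truth)[i],
                             GenomicRanges::start(truth)[i] + nchar(ins) - 1L))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r2$seq[i])))
    expect_equal(rc, substr(seq1, GenomicRanges::end(truth)[i] - 99L,
                            GenomicRanges::end(truth)[i]))
  }
})

test_that("a fully unmethylated genome with no background capture emits nothing", {
  g <- simulate_genome(1L, 5e4, 0.5, island_density = 0, seed = 13)
  fr <- digest_genome(g)
  me <- plant_methylome(g, fr, groups = c("E", "B"), baseline_meth = 0,
                        island_meth = 0, epsilon = 0)
  sheet <- make_sample_sheet(c(E = 2L, B = 2L), seed = 1)
  out <- simulate_medip_fragments(fr, me, sheet, g, 200, seed = 2)
  expect_equal(length(out), 0L)
})
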