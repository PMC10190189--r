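test_that("TSS distances follow the strand-aware midpoint rule", {
  ## + strand gene with TSS at 0-based 10,000 (1-based 10,001);
  ## region [7500, 7600) 0-based -> 1-based 7501..7600, midpoint0 7550
  expect_equal(tss_distance(7501L, 7600L, 10001L, "+"), -2450)
  ## midpoint on the TSS itself
  expect_equal(tss_distance(9001L, 11000L, 10001L, "+"), 0)
  ## - strand gene [1000, 2000) 0-based: TSS 1-based 2000; midpoint0 1899
  expect_equal(tss_distance(1850L, 1950L, 2000L, "-"), 100)
})

test_that("magnitude bins use leading digit times power of ten", {
  expect_equal(magnitude_bin(-2450), "-2 Kbps")
  expect_equal(magnitude_bin(0), "0")
  expect_equal(magnitude_bin(19999), "+10 Kbps")
  expect_equal(magnitude_bin(20000), "+20 Kbps")
  expect_equal(magnitude_bin(-10000), "-10 Kbps")
  expect_equal(magnitude_bin(c(7, -340, 1.2e6)),
               c("+7 bps", "-300 bps", "+1 Mbps"))
})

test_that("the promoter worked example classifies as Promoter (2-3kb)", {
  gm <- make_gene_models(data.frame(
    gene_id = "g1", symbol = "G1", chrom = "chr1", strand = "+",
    start = 10001L, end = 15000L))
  ann <- annotate_dmrs(gr("chr1", 7501L, 7600L), gm)
  expect_equal(as.character(ann$feature), "Promoter (2-3kb)")
  expect_equal(ann$tss_distance, -2450)
  expect_equal(ann$gene_id, "g1")
  expect_equal(ann$magnitude_bin, "-2 Kbps")
})

test_that("feature precedence and fallbacks behave as specified", {
  gm <- make_gene_models(
    data.frame(gene_id = c("g1", "g2"), symbol = c("G1", "G2"),
               chrom = "chr1", strand = c("+", "-"),
               start = c(10001L, 40001L), end = c(15000L, 45000L)),
    exons = data.frame(gene_id = c("g1", "g1", "g2"),
                       start = c(10001L, 14001L, 40001L),
                       end = c(11000L, 15000L, 45000L)))
  ## midpoint inside g1 between exons -> Intron
  ann_in <- annotate_dmrs(gr("chr1", 12001L, 12200L), gm)
  expect_equal(as.character(ann_in$feature), "Intron")
  ## midpoint inside an exon
  ann_ex <- annotate_dmrs(gr("chr1", 10101L, 10300L), gm)
  expect_equal(as.character(ann_ex$feature), "Exon")
  ## just after the + gene end -> Downstream
  ann_dn <- annotate_dmrs(gr("chr1", 15051L, 15150L), gm)
  expect_equal(as.character(ann_dn$feature), "Downstream (<=300bp)")
  ## upstream of the - strand gene TSS (right edge) -> Promoter
  ann_pm <- annotate_dmrs(gr("chr1", 45501L, 45700L), gm)
  expect_equal(as.character(ann_pm$feature), "Promoter (<=1kb)")
  expect_lt(ann_pm$tss_distance, 0)
  ## far from everything -> Distal Intergenic with the nearest gene
  ann_di <- annotate_dmrs(gr("chr1", 99001L, 99100L), gm)
  expect_equal(as.character(ann_di$feature), "Distal Intergenic")
  expect_equal(ann_di$gene_id, "g2")
})

test_that("an empty gene set yields Distal Intergenic with NA gene", {
  gm0 <- simulate_gene_models(simulate_genome(1L, 1e4, 0.5, seed = 1), 0L)
  ann <- annotate_dmrs(gr("chr1", 501L, 700L), gm0)
  expect_equal(as.character(ann$feature), "Distal Intergenic")
  expect_true(is.na(ann$gene_id))
  expect_true(is.na(ann$tss_distance))
})

test_that("TSS distance is antisymmetric under strand mirroring", {
  L <- 100000L
  gm_f <- make_gene_models(data.frame(
    gene_id = "g", symbol = "G", chrom = "chr1", strand = "+",
    start = 30001L, end = 40000L))
  ## mirror the gene: coordinates x -> L - x + 1, strand flipped
  gm_r <- make_gene_models(data.frame(
    gene_id = "g", symbol = "G", chrom = "chr1", strand = "-",
    start = L - 40000L + 1L, end = L - 30001L + 1L))
  for (reg in list(c(20001L, 20200L), c(35001L, 35100L), c(50001L, 50400L))) {
    d_f <- tss_distance(reg[1], reg[2], gm_f$genes$tss, "+")
    d_r <- tss_distance(L - reg[2] + 1L, L - reg[1] + 1L, gm_r$genes$tss, "-")
    expect_lte(abs(d_f - d_r), 1)  # midpoint rounding may differ by one bp
  }
})

test_that("classification agrees with the brute-force precedence oracle", {
  g <- simulate_genome(2L, 5e5, 0.5, seed = 41)
  gm <- simulate_gene_models(g, 60L, seed = 42)
  set.seed(43)
  dmrs <- uniform_fragments(g, 300L, width = 150L)
  ann <- annotate_dmrs(dmrs, gm)
  for (i in seq_along(dmrs)) {
    orc <- oracle_annotate_one(
      as.character(GenomicRanges::seqnames(dmrs))[i],
      GenomicRanges::start(dmrs)[i], GenomicRanges::end(dmrs)[i],
      gm$genes, gm$exons)
    expect_equal(as.character(ann$feature[i]), orc$feature)
    expect_equal(ann$gene_id[i], orc$gene_id)
    if (!is.na(orc$d)) expect_equal(ann$tss_distance[i], orc$d)
  }
})

test_that("feature fractions sum to one and count correctly", {
  gm <- make_gene_models(data.frame(
    gene_id = "g1", symbol = "G1", chrom = "chr1", strand = "+",
    start = 50001L, end = 60000L),
    exons = data.frame(gene_id = "g1", start = c(50001L, 59001L),
                       end = c(50200L, 60000L)))
  regs <- gr("chr1",
             c(48001L, 48501L, 49001L, 55001L),
             c(48200L, 48700L, 49200L, 55200L))
  ann <- annotate_dmrs(regs, gm)  # three promoter bins + one intron
  fd <- feature_distribution(ann)
  expect_equal(sum(fd$fraction), 1, tolerance = 1e-12)
  expect_equal(fd$fraction[grepl("Intron", fd$feature)], 0.25)
  expect_equal(sum(fd$n[grepl("Promoter", fd$feature)]), 3L)

  shuffled <- annotate_dmrs(regs[c(3, 1, 4, 2)], gm)
  expect_equal(feature_distribution(shuffled)[order(feature_distribution(shuffled)$feature), ],
               fd[order(fd$feature), ], ignore_attr = TRUE)
  expect_error(feature_distribution(ann[0, ]), "empty")
})

test_that("TSS-distance histogram orders bins by signed distance", {
  ann <- data.frame(tss_distance = c(-2450, -2450, 120, 19999, 20000, 0))
  h <- tss_distance_histogram(ann)
  expect_equal(h$bin, c("-2 Kbps", "0", "+100 bps", "+10 Kbps", "+20 Kbps"))
  expect_equal(h$n, c(2L, 1L, 1L, 1L, 1L))
})
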