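## fixture builders and independent oracles used across the suite

## gbs_genome from literal chromosome sequences (via the FASTA reader, so the
## container is built exactly as user data would be)
genome_from_seq <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fa)
  load_genome_fasta(fa)
}

## GRanges helper on arbitrary chromosomes (1-based closed)
gr <- function(chrom, start, end, strand = "*", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(g) <- S4Vectors::DataFrame(mc)
  g
}

## roi_counts object around a plain count matrix (dummy disjoint ROIs)
make_cm <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(samples)) colnames(counts) <- samples
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  n <- nrow(counts)
  rois <- gr("chr1", seq_len(n) * 1000L, seq_len(n) * 1000L + 200L)
  rownames(counts) <- sprintf("ROI_%06d", seq_len(n))
  structure(list(rois = rois, samples = colnames(counts),
                 counts = counts,
                 library_sizes = colSums(counts)),
            class = "roi_counts")
}

## gene_models from a plain gene table (one exon spanning the gene unless
## given); mirrors the package constructor without reusing its code paths
make_gene_models <- function(genes, exons = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end)
  structure(list(genes = genes[, c("gene_id", "symbol", "chrom", "strand",
                                   "start", "end", "tss", "tts")],
                 exons = exons), class = "gene_models")
}

## independent oracle: conditional split distribution as a product of
## stats::dnbinom masses (equal per-sample size factors), normalized over all
## splits; p = total mass of splits no more probable than observed
oracle_nb_exact <- function(t1, t2, n1, n2, phi, mu = 1) {
  total <- t1 + t2
  t <- 0:total
  w <- if (phi == 0) {
    stats::dbinom(t, total, n1 / (n1 + n2))
  } else {
    p <- 1 / (1 + phi * mu)  # NB prob parameter, equal across groups
    stats::dnbinom(t, size = n1 / phi, prob = p) *
      stats::dnbinom(total - t, size = n2 / phi, prob = p)
  }
  w <- w / sum(w)
  sum(w[w <= w[t1 + 1] * (1 + 1e-9)])
}

## independent oracle: upper-tail hypergeometric by direct combinatorial sum
oracle_hyper_upper <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## independent oracle: midpoint feature classification by exhaustive scan
## over every gene's feature intervals with explicit precedence
oracle_annotate_one <- function(chrom, start, end, genes, exons,
                                promoter_bp = 3000, downstream_bp = 300) {
  mid0 <- floor((start - 1 + end) / 2)
  mid1 <- mid0 + 1
  cand <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(feature = "Distal Intergenic", gene_id = NA, d = NA))
  }
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    g <- cand[k, ]
    tss0 <- g$tss - 1
    d <- if (g$strand == "+") mid0 - tss0 else tss0 - mid0
    feat <- NA_character_
    if (d <= -1 && d >= -promoter_bp) {
      kb <- ceiling(-d / 1000)
      feat <- if (kb <= 1) "Promoter (<=1kb)"
              else sprintf("Promoter (%d-%dkb)", kb - 1, kb)
    } else if (mid1 >= g$start && mid1 <= g$end) {
      ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
      feat <- if (any(ex$start <= mid1 & ex$end >= mid1)) "Exon" else "Intron"
    } else if (g$strand == "+" && mid1 > g$end &&
               mid1 <= g$end + downstream_bp) {
      feat <- "Downstream (<=300bp)"
    } else if (g$strand == "-" && mid1 < g$start &&
               mid1 >= g$start - downstream_bp) {
      feat <- "Downstream (<=300bp)"
    }
    data.frame(gene_id = g$gene_id, feature = feat, d = d)
  })
  tab <- do.call(rbind, rows)
  prec <- c("Promoter (<=1kb)" = 1, "Promoter (1-2kb)" = 2,
            "Promoter (2-3kb)" = 3, "Exon" = 4, "Intron" = 5,
            "Downstream (<=300bp)" = 6)
  hit <- tab[!is.na(tab$feature), , drop = FALSE]
  if (!nrow(hit)) {
    o <- order(abs(tab$d), tab$gene_id)
    return(list(feature = "Distal Intergenic",
                gene_id = tab$gene_id[o[1]], d = tab$d[o[1]]))
  }
  ## promoter sub-bins share the Promoter precedence tier
  tier <- ifelse(grepl("^Promoter", hit$feature), 1,
                 prec[hit$feature] - 2)
  o <- order(tier, abs(hit$d), hit$gene_id)
  list(feature = hit$feature[o[1]], gene_id = hit$gene_id[o[1]],
       d = hit$d[o[1]])
}

## brute-force CpG counter: substring scan, independent of the package's
## sorted-index arithmetic
count_cpgs_in_oracle <- function(genome, regions) {
  vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    s <- GenomicRanges::start(regions)[i]
    e <- GenomicRanges::end(regions)[i]
    seq <- as.character(genome$sequences[[chrom]])
    sub <- substr(seq, s, min(e + 1L, nchar(seq)))
    m <- gregexpr("CG", sub, fixed = TRUE)[[1]]
    sum(m > 0)
  }, numeric(1))
}

## random fragments uniform over a genome (length-fixed, capture-unbiased)
uniform_fragments <- function(genome, n, width = 300L) {
  chrom <- sample(genome$chrom_names, n, replace = TRUE,
                  prob = genome$lengths / sum(genome$lengths))
  start <- vapply(chrom, function(cn) {
    sample.int(genome$lengths[[cn]] - width, 1L)
  }, integer(1))
  gr(chrom, start, start + width - 1L)
}
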