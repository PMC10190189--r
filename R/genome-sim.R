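#' Simulate a reference genome with CpG islands
#'
#' Generates i.i.d. background sequence at a given GC content and plants
#' CpG-dense islands, returning the chromosome sequences together with a
#' precomputed index of CpG dinucleotide positions. The object plays the role
#' of the reference genome for the rest of the pipeline (in-silico digestion,
#' coupling analysis, annotation).
#'
#' Background bases are drawn independently with P(G) = P(C) = `gc_fraction`/2,
#' so the expected background CpG density is `(gc_fraction/2)^2` per bp.
#' Islands are non-overlapping intervals whose sequence is generated by a token
#' process that emits the dinucleotide "CG" with probability
#' `island_cpg_rate`, giving a CpG density of roughly
#' `island_cpg_rate / (1 + island_cpg_rate)` per bp (about 6x the background
#' at the defaults).
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length_bp length of every chromosome in bp (>= 10000).
#' @param gc_fraction background GC content, strictly inside (0, 1).
#' @param island_density fraction of each chromosome covered by CpG islands
#'   (0 disables islands).
#' @param island_length_bp length of each planted island.
#' @param island_cpg_rate probability that the island token process emits a
#'   "CG" dinucleotide at each step.
#' @param site_density per-bp density of planted restriction sites (PstI,
#'   "CTGCAG"); the default mean spacing of 350 bp makes a sizeable share of
#'   digestion fragments fall in the 200-500 bp selection window, emulating
#'   the reduced-representation design at desk scale. 0 disables planting
#'   (only chance occurrences of the site remain, roughly one per 4 kb).
#' @param seed integer seed; the same seed yields a byte-identical genome.
#'
#' @return An object of class `gbs_genome`: a list with `chrom_names`,
#'   `sequences` (a [Biostrings::DNAStringSet]), `lengths`, `cpg_index`
#'   (per-chromosome sorted 1-based start positions of "CG") and `islands`
#'   (a [GenomicRanges::GRanges] of the planted island intervals).
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length_bp = 1e6,
                            gc_fraction = 0.41, island_density = 0.01,
                            island_length_bp = 500L, island_cpg_rate = 0.6,
                            site_density = 1 / 350, seed = NULL) {
  if (n_chrom < 1) stop_param("'n_chrom' must be >= 1")
  if (chrom_length_bp < 10000) stop_param("'chrom_length_bp' must be >= 10000")
  check_prob(gc_fraction, "gc_fraction", open = TRUE)
  if (island_density < 0 || island_density >= 1)
    stop_param("'island_density' must be in [0, 1)")
  check_prob(island_cpg_rate, "island_cpg_rate")

  len <- as.integer(chrom_length_bp)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  base_prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                 G = gc_fraction / 2, T = (1 - gc_fraction) / 2)

  with_seed(seed, {
    island_tbl <- list()
    seqs <- character(n_chrom)
    for (ci in seq_len(n_chrom)) {
      chars <- sample(names(base_prob), len, replace = TRUE, prob = base_prob)
      starts <- integer(0)
      n_isl <- floor(island_density * len / island_length_bp)
      if (n_isl > 0) {
        ## place non-overlapping islands by rejection, bounded retries
        tries <- 0L
        while (length(starts) < n_isl && tries < 50L * n_isl) {
          cand <- sample.int(len - island_length_bp, 1L)
          if (!length(starts) ||
              all(abs(cand - starts) >= island_length_bp)) {
            starts <- c(starts, cand)
          }
          tries <- tries + 1L
        }
        starts <- sort(starts)
        for (s in starts) {
          isl <- island_sequence(island_length_bp, island_cpg_rate, base_prob)
          chars[s:(s + island_length_bp - 1L)] <- isl
        }
      }
      if (site_density > 0) {
        ## plant PstI sites at exponential spacing (the site has no CpG,
        ## so CpG statistics are untouched)
        site <- c("C", "T", "G", "C", "A", "G")
        pos <- 1L
        repeat {
          pos <- pos + max(6L, as.integer(stats::rexp(1, site_density)))
          if (pos + 5L > len) break
          chars[pos:(pos + 5L)] <- site
        }
      }
      seqs[ci] <- paste(chars, collapse = "")
      island_tbl[[ci]] <- if (length(starts)) {
        data.frame(chrom = chrom_names[ci], start = starts,
                   end = starts + island_length_bp - 1L)
      } else NULL
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- chrom_names
    isl_df <- do.call(rbind, island_tbl)
    genome <- structure(
      list(chrom_names = chrom_names,
           sequences = sequences,
           lengths = stats::setNames(rep(len, n_chrom), chrom_names),
           cpg_index = cpg_positions(sequences),
           islands = NULL),
      class = "gbs_genome")
    genome$islands <- if (is.null(isl_df)) {
      granges_on(genome, character(0), integer(0), integer(0))
    } else {
      granges_on(genome, isl_df$chrom, isl_df$start, isl_df$end)
    }
    genome
  })
}

## island token stream: "CG" with prob rate, else one background base
island_sequence <- function(n, rate, base_prob) {
  out <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < rate && i < n) {
      out[i] <- "C"; out[i + 1L] <- "G"
      i <- i + 2L
    } else {
      out[i] <- sample(names(base_prob), 1L, prob = base_prob)
      i <- i + 1L
    }
  }
  out
}

## 1-based start positions of every "CG" dinucleotide, per chromosome
cpg_positions <- function(sequences) {
  lapply(seq_along(sequences), function(i) {
    Biostrings::start(Biostrings::matchPattern("CG", sequences[[i]]))
  }) |> stats::setNames(names(sequences))
}

#' @export
print.gbs_genome <- function(x, ...) {
  cat(sprintf("gbs_genome: %d chromosome(s), %s bp total, %s CpGs\n",
              length(x$chrom_names),
              format(sum(x$lengths), big.mark = ","),
              format(sum(lengths(x$cpg_index)), big.mark = ",")))
  invisible(x)
}

#' Count of CpG dinucleotides in the whole genome
#' @param genome a `gbs_genome`.
#' @return integer count.
#' @export
genome_cpg_count <- function(genome) sum(lengths(genome$cpg_index))

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` non-overlapping transcripts on the genome, on random
#' strands, each with a random number of exons. The first exon starts at the
#' transcript start and the last ends at the transcript end; exons are sorted
#' and non-overlapping. Gene models provide the targets for feature annotation
#' (promoter / exon / intron / downstream / distal intergenic).
#'
#' @param genome a `gbs_genome`.
#' @param n_genes number of genes to place (0 is allowed).
#' @param exon_count_range integer range for the exon count per gene.
#' @param gene_length_range bp range for transcript lengths.
#' @param seed integer seed.
#' @param max_tries placement retries per gene before giving up.
#'
#' @return An object of class `gene_models`: a list with `genes` (data.frame:
#'   gene_id, symbol, chrom, strand, start, end, tss, tts; 1-based closed
#'   coordinates, tss/tts strand-aware) and `exons` (data.frame: gene_id,
#'   start, end).
#' @export
simulate_gene_models <- function(genome, n_genes = 50L,
                                 exon_count_range = c(2L, 8L),
                                 gene_length_range = c(2000L, 10000L),
                                 seed = NULL, max_tries = 200L) {
  stopifnot(inherits(genome, "gbs_genome"))
  if (n_genes == 0) return(empty_gene_models())
  if (max(gene_length_range) + 1 > max(genome$lengths))
    stop_param("genes cannot fit on the chromosomes")

  with_seed(seed, {
    placed <- vector("list", n_genes)
    occupied <- list()  # per chrom: matrix of (start,end)
    for (gi in seq_len(n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        chrom <- sample(genome$chrom_names, 1L,
                        prob = genome$lengths / sum(genome$lengths))
        glen <- sample(seq(gene_length_range[1], gene_length_range[2]), 1L)
        if (glen + 1 > genome$lengths[[chrom]]) next
        start <- sample.int(genome$lengths[[chrom]] - glen, 1L)
        end <- start + glen - 1L
        occ <- occupied[[chrom]]
        if (!is.null(occ) && any(start <= occ[, 2] & end >= occ[, 1])) next
        occupied[[chrom]] <- rbind(occ, c(start, end))
        placed[[gi]] <- data.frame(
          chrom = chrom, start = start, end = end,
          strand = sample(c("+", "-"), 1L))
        ok <- TRUE
        break
      }
      if (!ok) stop_param(
        "could not place %d non-overlapping genes after %d retries each",
        n_genes, max_tries)
    }
    genes <- do.call(rbind, placed)
    genes$gene_id <- sprintf("G%04d", seq_len(n_genes))
    genes$symbol <- sprintf("SYM%04d", seq_len(n_genes))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)

    exon_rows <- lapply(seq_len(n_genes), function(gi) {
      g <- genes[gi, ]
      k <- sample(seq(exon_count_range[1], exon_count_range[2]), 1L)
      data.frame(gene_id = g$gene_id, partition_exons(g$start, g$end, k))
    })
    exons <- do.call(rbind, exon_rows)
    structure(list(
      genes = genes[, c("gene_id", "symbol", "chrom", "strand",
                        "start", "end", "tss", "tts")],
      exons = exons), class = "gene_models")
  })
}

## split [start, end] into k exons: exon i lives in block i of k equal blocks;
## first exon anchored at start, last at end
partition_exons <- function(start, end, k) {
  len <- end - start + 1L
  k <- max(1L, min(k, len %/% 60L))  # need room for introns
  edges <- round(seq(start, end + 1L, length.out = k + 1L))
  ex <- lapply(seq_len(k), function(i) {
    lo <- edges[i]
    hi <- edges[i + 1L] - 1L
    blen <- hi - lo + 1L
    elen <- max(20L, floor(blen / 3L))
    es <- if (i == 1L) lo else lo + sample.int(blen - elen, 1L)
    ee <- if (i == k) hi else min(es + elen - 1L, hi)
    if (i == k && k > 1L) es <- max(lo + 1L, hi - elen + 1L)
    c(start = es, end = if (i == k) hi else ee)
  })
  out <- as.data.frame(do.call(rbind, ex))
  out[order(out$start), ]
}

empty_gene_models <- function() {
  structure(list(
    genes = data.frame(gene_id = character(0), symbol = character(0),
                       chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0),
                       tss = integer(0), tts = integer(0)),
    exons = data.frame(gene_id = character(0), start = integer(0),
                       end = integer(0))), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}
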