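#' Saturating MeDIP capture probability
#'
#' Probability that a molecule carrying `m` methylated CpGs is captured by the
#' antibody enrichment step. A saturating law reproduces the qualitative MeDIP
#' property that enrichment grows with methyl-CpG load and then plateaus:
#' `(1 - epsilon) * m / (m + kappa) + epsilon`.
#'
#' @param m methylated CpG count(s) on the molecule (>= 0, vectorized).
#' @param kappa half-saturation constant: methylated CpGs at which capture
#'   reaches 50% of its ceiling (> 0).
#' @param epsilon non-specific background capture rate, in `[0, 1)`.
#' @return capture probabilities in `[0, 1]`, same length as `m`.
#' @export
capture_probability <- function(m, kappa = 1, epsilon = 0.01) {
  if (any(m < 0)) stop_param("'m' must be >= 0")
  if (kappa <= 0) stop_param("'kappa' must be > 0")
  if (epsilon < 0 || epsilon >= 1) stop_param("'epsilon' must be in [0, 1)")
  (1 - epsilon) * m / (m + kappa) + epsilon
}

#' Plant a group-structured methylome on a digested genome
#'
#' Assigns every CpG a methylation probability per group: `island_meth` inside
#' CpG islands, `baseline_meth` elsewhere, identical across groups; then plants
#' `n_dmrs` truly differential fragments by shifting the CpG probabilities of
#' one group by +/- `delta` within each chosen fragment. Only size-selected
#' fragments with at least 3 CpGs are eligible. The planted truth is recorded
#' so downstream sensitivity/false-discovery checks have a gold standard.
#'
#' @param genome a `gbs_genome`.
#' @param fragments digestion fragments from [digest_genome()].
#' @param groups character vector of group labels (>= 2 for planted DMRs).
#' @param baseline_meth methylation probability outside islands.
#' @param island_meth methylation probability inside islands.
#' @param n_dmrs number of truly differential fragments to plant.
#' @param delta absolute probability shift for planted DMRs; the shifted
#'   probabilities must stay in `[0, 1]` or an error is raised.
#' @param dmr_group group whose probabilities are shifted. The default
#'   (`NULL`) assigns each planted DMR to a uniformly drawn group, so the
#'   contrast sees both hypermethylation directions, as real studies do, and
#'   the planted signal stays balanced across samples.
#' @param kappa,epsilon capture model parameters stored with the methylome.
#' @param seed integer seed.
#'
#' @return An object of class `methylome_model`: list with `groups`, `prob`
#'   (per group, per chromosome numeric vectors aligned with the genome CpG
#'   index), `kappa`, `epsilon` and `truth_dmrs` (GRanges with signed `delta`
#'   and the shifted `group`).
#' @export
plant_methylome <- function(genome, fragments, groups = c("E", "B"),
                            baseline_meth = 0.2, island_meth = 0.8,
                            n_dmrs = 0L, delta = 0.5,
                            dmr_group = NULL,
                            kappa = 1, epsilon = 0.01, seed = NULL) {
  stopifnot(inherits(genome, "gbs_genome"))
  check_prob(baseline_meth, "baseline_meth")
  check_prob(island_meth, "island_meth")
  if (n_dmrs > 0 && (delta <= 0 || delta > 1))
    stop_param("'delta' must be in (0, 1]")
  if (!is.null(dmr_group) && !dmr_group %in% groups)
    stop_param("'dmr_group' must be one of 'groups'")

  base_prob <- lapply(genome$chrom_names, function(chrom) {
    p <- rep(baseline_meth, length(genome$cpg_index[[chrom]]))
    isl <- genome$islands[
      as.character(GenomicRanges::seqnames(genome$islands)) == chrom]
    if (length(isl)) {
      cpg <- genome$cpg_index[[chrom]]
      inside <- rep(FALSE, length(cpg))
      for (k in seq_along(isl)) {
        inside <- inside |
          (cpg >= GenomicRanges::start(isl)[k] &
             cpg <= GenomicRanges::end(isl)[k])
      }
      p[inside] <- island_meth
    }
    p
  })
  names(base_prob) <- genome$chrom_names
  prob <- stats::setNames(rep(list(base_prob), length(groups)), groups)

  truth <- granges_on(genome, character(0), integer(0), integer(0))
  if (n_dmrs > 0) {
    eligible <- which(S4Vectors::mcols(fragments)$selected &
                        S4Vectors::mcols(fragments)$cpg_count >= 3L)
    ## a fragment is plantable only if the whole +/- delta shift keeps every
    ## one of its CpG probabilities inside [0, 1] (fragments straddling an
    ## island boundary mix baseline and island levels and may support
    ## neither direction)
    ## feasibility is group-independent: all groups share the same
    ## probabilities before planting, and each fragment is planted once
    frag_shift_ok <- function(idx, dir) {
      fr <- fragments[idx]
      chrom <- as.character(GenomicRanges::seqnames(fr))
      cpg <- genome$cpg_index[[chrom]]
      sel <- cpg >= GenomicRanges::start(fr) & cpg <= GenomicRanges::end(fr)
      p <- prob[[groups[1]]][[chrom]][sel]
      if (dir > 0) all(p + delta <= 1) else all(p - delta >= 0)
    }
    up_ok <- vapply(eligible, frag_shift_ok, logical(1), dir = 1)
    dn_ok <- vapply(eligible, frag_shift_ok, logical(1), dir = -1)
    feasible <- eligible[up_ok | dn_ok]
    if (n_dmrs > length(feasible))
      stop_param(
        "delta = %g infeasible: only %d plantable fragments for n_dmrs = %d",
        delta, length(feasible), n_dmrs)
    truth <- with_seed(seed, {
      pick <- sort(sample(seq_along(feasible), n_dmrs))
      chosen <- feasible[pick]
      can_up <- up_ok[up_ok | dn_ok][pick]
      can_dn <- dn_ok[up_ok | dn_ok][pick]
      deltas <- numeric(n_dmrs)
      grp <- character(n_dmrs)
      for (j in seq_along(chosen)) {
        fr <- fragments[chosen[j]]
        chrom <- as.character(GenomicRanges::seqnames(fr))
        cpg <- genome$cpg_index[[chrom]]
        sel <- cpg >= GenomicRanges::start(fr) & cpg <= GenomicRanges::end(fr)
        sgn <- if (can_up[j] && can_dn[j]) sample(c(1, -1), 1L)
               else if (can_up[j]) 1 else -1
        grp[j] <- if (is.null(dmr_group)) sample(groups, 1L) else dmr_group
        prob[[grp[j]]][[chrom]][sel] <-
          prob[[grp[j]]][[chrom]][sel] + sgn * delta
        deltas[j] <- sgn * delta
      }
      tr <- fragments[chosen]
      S4Vectors::mcols(tr) <- S4Vectors::DataFrame(delta = deltas,
                                                   group = grp)
      tr
    })
  }
  structure(list(groups = groups, prob = prob, kappa = kappa,
                 epsilon = epsilon, truth_dmrs = truth),
            class = "methylome_model")
}

#' @export
print.methylome_model <- function(x, ...) {
  cat(sprintf("methylome_model: %d group(s), %d planted DMR(s), kappa=%g, epsilon=%g\n",
              length(x$groups), length(x$truth_dmrs), x$kappa, x$epsilon))
  invisible(x)
}

## expected methylated-CpG count per fragment for one group:
## sum of that group's CpG methylation probabilities inside each fragment
fragment_meth_sum <- function(fragments, methylome, genome, group) {
  out <- numeric(length(fragments))
  chroms <- as.character(GenomicRanges::seqnames(fragments))
  st <- GenomicRanges::start(fragments)
  en <- GenomicRanges::end(fragments)
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    cpg <- genome$cpg_index[[chrom]]
    p <- methylome$prob[[group]][[chrom]]
    cs <- c(0, cumsum(p))
    out[idx] <- cs[findInterval(en[idx], cpg) + 1L] -
      cs[findInterval(st[idx] - 1L, cpg) + 1L]
  }
  out
}

#' Simulate MeDIP-captured fragments (truth alignments)
#'
#' Samples sequenced molecules for every sample in the sheet: molecules are
#' drawn multinomially over the size-selected fragments with weights equal to
#' the capture probability of each fragment's expected methylated-CpG count
#' under the sample's group methylome. Per-sample depth is Poisson with mean
#' `mean_fragments_per_sample` scaled by the sample's total capture yield
#' relative to the across-sample average: in a pooled barcoded library the
#' immunoprecipitation is performed on the pool, so a sample whose methylome
#' captures more material contributes proportionally more read pairs, and the
#' per-fragment sequencing rate of unaffected fragments stays equal across
#' groups. This is the simulator's truth-alignment output: the read generator
#' ([simulate_medip_reads()]) serializes these molecules to FASTQ.
#'
#' @param fragments digestion fragments from [digest_genome()].
#' @param methylome a `methylome_model`.
#' @param sample_sheet data.frame with columns `sample` and `group` (see
#'   [make_sample_sheet()]).
#' @param genome the `gbs_genome` the fragments came from.
#' @param mean_fragments_per_sample expected molecules per sample.
#' @param seed integer seed.
#' @return A [GenomicRanges::GRanges] of sample-tagged molecules with random
#'   library strand, metadata columns `sample` and `group`.
#' @export
simulate_medip_fragments <- function(fragments, methylome, sample_sheet,
                                     genome, mean_fragments_per_sample = 5000,
                                     seed = NULL) {
  stopifnot(inherits(methylome, "methylome_model"))
  if (!all(c("sample", "group") %in% names(sample_sheet)))
    stop_param("sample_sheet needs 'sample' and 'group' columns")
  if (!all(sample_sheet$group %in% methylome$groups))
    stop_param("sample sheet groups absent from the methylome model")
  sel <- fragments[S4Vectors::mcols(fragments)$selected]
  if (!length(sel)) stop_param("no size-selected fragments to sample from")

  weights <- lapply(methylome$groups, function(g) {
    capture_probability(fragment_meth_sum(sel, methylome, genome, g),
                        methylome$kappa, methylome$epsilon)
  })
  names(weights) <- methylome$groups

  ## pooled-library depth: reads per sample scale with its capture yield
  yields <- vapply(sample_sheet$group, function(g) sum(weights[[g]]),
                   numeric(1))
  mean_yield <- mean(yields)
  depth_mean <- if (mean_yield > 0)
    mean_fragments_per_sample * yields / mean_yield else rep(0, length(yields))

  with_seed(seed, {
    per_sample <- lapply(seq_len(nrow(sample_sheet)), function(i) {
      smp <- sample_sheet$sample[i]
      grp <- sample_sheet$group[i]
      w <- weights[[grp]]
      n <- stats::rpois(1L, depth_mean[i])
      if (n == 0L || sum(w) == 0) return(NULL)
      idx <- sample.int(length(sel), n, replace = TRUE, prob = w)
      mol <- sel[idx]
      S4Vectors::mcols(mol) <- S4Vectors::DataFrame(sample = smp, group = grp)
      GenomicRanges::strand(mol) <- sample(c("+", "-"), n, replace = TRUE)
      mol
    })
    per_sample <- per_sample[!vapply(per_sample, is.null, logical(1))]
    if (!length(per_sample))
      return(granges_on(genome, character(0), integer(0), integer(0),
                        sample = character(0), group = character(0)))
    out <- do.call(c, per_sample)
    names(out) <- NULL
    out
  })
}

#' Build a sample sheet with per-sample barcodes
#'
#' @param n_per_group named integer vector: samples per group label.
#' @param tissue single tissue label for all samples (default "A").
#' @param barcode_len barcode length in bp.
#' @param seed integer seed for barcode generation.
#' @return data.frame with columns `sample`, `barcode`, `group`, `tissue`.
#' @export
make_sample_sheet <- function(n_per_group = c(E = 9L, B = 9L), tissue = "A",
                              barcode_len = 6L, seed = NULL) {
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  with_seed(seed, {
    barcodes <- character(0)
    while (length(barcodes) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), barcode_len, replace = TRUE),
                    collapse = "")
      if (!cand %in% barcodes) barcodes <- c(barcodes, cand)
    }
    data.frame(sample = sprintf("%s%02d_%s", groups,
                                stats::ave(seq_len(n), groups,
                                           FUN = seq_along), tissue),
               barcode = barcodes, group = groups, tissue = tissue,
               stringsAsFactors = FALSE)
  })
}

#' Simulate multiplexed paired-end GBS-MeDIP reads
#'
#' Serializes molecules drawn by [simulate_medip_fragments()] to a multiplexed
#' FASTQ pair. Read 1 is `barcode + "CTGCA" + fragment 5' sequence`, read 2 is
#' the reverse complement of the fragment 3' end; both are `read_len` bases.
#' Base qualities are fixed at "I" (Phred+33, Q40); substitution errors are
#' injected uniformly at rate `seq_error` over all read bases.
#'
#' @inheritParams simulate_medip_fragments
#' @param read_len total read length (must not exceed the shortest selected
#'   fragment).
#' @param seq_error per-base substitution error rate.
#' @param out_dir directory for FASTQ/BED/TSV outputs; created if missing.
#' @param gzip write gzipped FASTQ.
#' @return list with `truth` (the molecule GRanges, with `read_id` added),
#'   `r1`, `r2` (FASTQ paths), `truth_bed`, `truth_dmr_bed`, `sample_sheet_tsv`.
#' @export
simulate_medip_reads <- function(fragments, methylome, sample_sheet, genome,
                                 mean_fragments_per_sample = 2000,
                                 read_len = 100L, seq_error = 0,
                                 out_dir = tempfile("gbsmedip_sim_"),
                                 gzip = TRUE, seed = NULL) {
  check_prob(seq_error, "seq_error")
  if (anyDuplicated(sample_sheet$barcode))
    stop_param("barcodes must be unique per sample")
  blen <- unique(nchar(sample_sheet$barcode))
  if (length(blen) != 1L) stop_param("all barcodes must have equal length")
  sel_w <- GenomicRanges::width(
    fragments[S4Vectors::mcols(fragments)$selected])
  if (!length(sel_w)) stop_param("no size-selected fragments")
  if (read_len > min(sel_w))
    stop_param("read_len (%d) exceeds shortest selected fragment (%d)",
               read_len, min(sel_w))

  seed2 <- if (is.null(seed)) NULL else seed + 1L
  truth <- simulate_medip_fragments(fragments, methylome, sample_sheet,
                                    genome, mean_fragments_per_sample,
                                    seed = seed)
  if (length(truth))
    S4Vectors::mcols(truth)$read_id <- sprintf("rd%07d", seq_along(truth))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1_path <- file.path(out_dir, paste0("pool_R1", ext))
  r2_path <- file.path(out_dir, paste0("pool_R2", ext))

  bc <- stats::setNames(sample_sheet$barcode, sample_sheet$sample)
  gseq <- genome$sequences
  chroms <- as.character(GenomicRanges::seqnames(truth))
  st <- GenomicRanges::start(truth)
  en <- GenomicRanges::end(truth)
  ins1 <- read_len - blen - 5L
  r1 <- r2 <- character(length(truth))
  for (chrom in unique(chroms)) {
    i <- which(chroms == chrom)
    s1 <- Biostrings::extractAt(
      gseq[[chrom]], IRanges::IRanges(st[i], st[i] + ins1 - 1L))
    s2 <- Biostrings::extractAt(
      gseq[[chrom]], IRanges::IRanges(en[i] - read_len + 1L, en[i]))
    r1[i] <- paste0(bc[S4Vectors::mcols(truth)$sample[i]], "CTGCA",
                    as.character(s1))
    r2[i] <- as.character(Biostrings::reverseComplement(s2))
  }
  if (seq_error > 0 && length(truth)) {
    r1 <- with_seed(seed2, inject_errors(r1, seq_error))
    r2 <- with_seed(if (is.null(seed2)) NULL else seed2 + 1L,
                    inject_errors(r2, seq_error))
  }

  ids <- if (length(truth)) S4Vectors::mcols(truth)$read_id else character(0)
  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)

  truth_bed <- file.path(out_dir, "truth_alignments.bed")
  write_bed6(truth, truth_bed,
             name = if (length(truth))
               paste(ids, S4Vectors::mcols(truth)$sample, sep = "|")
             else character(0))
  dmr_bed <- file.path(out_dir, "truth_dmrs.bed")
  write_bed4(methylome$truth_dmrs, dmr_bed,
             name = if (length(methylome$truth_dmrs))
               sprintf("%+g", S4Vectors::mcols(methylome$truth_dmrs)$delta)
             else character(0))
  sheet_tsv <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sample_sheet, sheet_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(truth = truth, r1 = r1_path, r2 = r2_path, truth_bed = truth_bed,
       truth_dmr_bed = dmr_bed, sample_sheet_tsv = sheet_tsv)
}

## uniform substitution errors at per-base rate
inject_errors <- function(reads, rate) {
  if (!length(reads)) return(reads)
  mat <- strsplit(reads, "", fixed = TRUE)
  vapply(mat, function(ch) {
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      for (h in hit) {
        ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
      }
    }
    paste(ch, collapse = "")
  }, character(1))
}
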