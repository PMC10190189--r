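#' In-silico restriction digestion of a genome
#'
#' Cuts every chromosome at each exact forward-strand occurrence of the
#' recognition site, at a fixed offset inside the site (for PstI, CTGCAG cut
#' after the 5th base, which leaves the CTGCA remnant at the start of each
#' downstream fragment). Fragments are the intervals between consecutive cuts
#' plus the chromosome ends; a fragment is flagged `selected` when its length
#' falls inside the size-selection window.
#'
#' @param genome a `gbs_genome`.
#' @param recognition_site recognition sequence (default PstI, "CTGCAG").
#' @param cut_offset cut position within the site, 0..nchar(site); the cut
#'   falls after `cut_offset` bases of the site.
#' @param size_min,size_max size-selection window in bp (default 200-500).
#'
#' @return A [GenomicRanges::GRanges] of fragments (1-based closed) with
#'   metadata columns `cpg_count` (CpG start positions inside the fragment)
#'   and `selected`.
#' @export
digest_genome <- function(genome, recognition_site = "CTGCAG",
                          cut_offset = 5L, size_min = 200L, size_max = 500L) {
  stopifnot(inherits(genome, "gbs_genome"))
  if (!grepl("^[ACGT]+$", recognition_site))
    stop_param("'recognition_site' must be over {A,C,G,T}")
  if (cut_offset < 0 || cut_offset > nchar(recognition_site))
    stop_param("'cut_offset' must be within 0..nchar(recognition_site)")

  per_chrom <- lapply(seq_along(genome$chrom_names), function(ci) {
    chrom <- genome$chrom_names[ci]
    len <- genome$lengths[[ci]]
    sites <- Biostrings::start(
      Biostrings::matchPattern(recognition_site, genome$sequences[[ci]]))
    ## cut after 1-based position (site + cut_offset - 1)
    cuts <- sites + cut_offset - 1L
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < len]))
    bounds <- c(0L, cuts, len)
    data.frame(chrom = chrom,
               start = utils::head(bounds, -1L) + 1L,
               end = utils::tail(bounds, -1L))
  })
  df <- do.call(rbind, per_chrom)
  fr <- granges_on(genome, df$chrom, df$start, df$end)
  S4Vectors::mcols(fr)$cpg_count <- count_cpgs_in(fr, genome)
  width <- GenomicRanges::width(fr)
  S4Vectors::mcols(fr)$selected <- width >= size_min & width <= size_max
  fr
}

## number of CpG start positions falling inside each range
count_cpgs_in <- function(gr, genome) {
  out <- integer(length(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    cpg <- genome$cpg_index[[chrom]]
    ## counts of sorted cpg positions within [start, end]
    out[idx] <- findInterval(en[idx], cpg) - findInterval(st[idx] - 1L, cpg)
  }
  out
}
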