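## Interval and annotation formats. In-memory intervals are GRanges (1-based
## closed); BED files are 0-based half-open, GFF3 and SAM are 1-based — all
## conversions happen here, at the file boundary. Writers emit deterministic
## column order and (chrom, start) sort order.

sort_by_coord <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Write intervals as BED6
#'
#' @param gr a GRanges.
#' @param path output path.
#' @param name,score name and score columns (recycled).
#' @return the path, invisibly.
#' @export
write_bed6 <- function(gr, path, name = NULL, score = 0L) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr2 <- gr[o]
  name <- if (is.null(name)) sprintf("region_%06d", seq_along(gr2))
          else rep(name, length.out = length(gr))[o]
  score <- rep(score, length.out = length(gr))[o]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr2)),
                   start = GenomicRanges::start(gr2) - 1L,
                   end = GenomicRanges::end(gr2),
                   name = name,
                   score = score,
                   strand = sub("\\*", ".",
                                as.character(GenomicRanges::strand(gr2))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_bed4 <- function(gr, path, name = NULL) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr2 <- gr[o]
  name <- if (is.null(name)) sprintf("region_%06d", seq_along(gr2))
          else rep(name, length.out = length(gr))[o]
  df <- data.frame(as.character(GenomicRanges::seqnames(gr2)),
                   GenomicRanges::start(gr2) - 1L,
                   GenomicRanges::end(gr2), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4/BED6 file into GRanges
#'
#' @param path BED path (0-based half-open; converted to 1-based closed).
#' @return GRanges with `name` and `score` metadata when present.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || !nrow(df))
    return(GenomicRanges::GRanges())
  if (ncol(df) < 3L) stop_param("BED file needs >= 3 columns: %s", path)
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
    strand = if (ncol(df) >= 6L) sub("\\.", "*", df[[6]]) else "*")
  if (ncol(df) >= 4L) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5L) S4Vectors::mcols(gr)$score <- df[[5]]
  gr
}

#' Load aligned fragments from BED, SAM or BAM
#'
#' Normalizes one sequenced fragment per record/pair to a sample-tagged
#' GRanges. For BED, each line is one fragment and the sample is taken from
#' the name column (the part after the last "|" when present, so the
#' simulator's `readid|sample` truth names resolve). For SAM/BAM, proper
#' pairs are collapsed to the leftmost mate's `[POS, POS + TLEN - 1]` span;
#' unmapped, secondary and supplementary records are dropped and counted.
#'
#' @param path file path, or for SAM/BAM a named character vector of paths
#'   (names = sample labels).
#' @param format one of "BED", "SAM", "BAM".
#' @param sample sample label for a single SAM/BAM file.
#' @return GRanges with metadata column `sample` and attribute `dropped`
#'   (count of discarded records).
#' @export
load_alignments <- function(path, format = c("BED", "SAM", "BAM"),
                            sample = NULL) {
  format <- match.arg(format)
  if (format == "BED") {
    gr <- read_bed(path)
    nm <- S4Vectors::mcols(gr)$name %||% rep(NA_character_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      sample = sub("^.*\\|", "", nm))
    attr(gr, "dropped") <- 0L
    return(gr)
  }
  paths <- if (is.null(names(path)) && !is.null(sample))
    stats::setNames(path, sample) else path
  if (is.null(names(paths)))
    stop_param("SAM/BAM input needs sample names (named paths or 'sample=')")
  parts <- lapply(names(paths), function(smp) {
    if (format == "SAM") parse_sam(paths[[smp]], smp)
    else parse_bam(paths[[smp]], smp)
  })
  out <- do.call(c, lapply(parts, `[[`, "gr"))
  attr(out, "dropped") <- sum(vapply(parts, `[[`, integer(1), "dropped"))
  out
}

parse_sam <- function(path, sample) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(list(gr = GenomicRanges::GRanges(sample = character(0)),
                dropped = 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad))
    stop_param("unparseable SAM record at line %d of %s", bad[1], path)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  rname <- vapply(f, `[[`, character(1), 3L)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  tlen <- vapply(f, function(x) as.integer(x[9]), integer(1))
  drop <- bitwAnd(flag, 0x4L) > 0L | bitwAnd(flag, 0x100L) > 0L |
    bitwAnd(flag, 0x800L) > 0L | rname == "*"
  keep <- !drop & tlen > 0L  # leftmost mate of each proper pair
  gr <- GenomicRanges::GRanges(
    rname[keep],
    IRanges::IRanges(pos[keep], pos[keep] + tlen[keep] - 1L),
    strand = ifelse(bitwAnd(flag[keep], 0x10L) > 0L, "-", "+"),
    sample = sample)
  list(gr = gr, dropped = sum(drop))
}

parse_bam <- function(path, sample) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_param("BAM input requires the Rsamtools package")
  prm <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "isize"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = prm)[[1]]
  keep <- !is.na(b$isize) & b$isize > 0L
  gr <- GenomicRanges::GRanges(
    as.character(b$rname[keep]),
    IRanges::IRanges(b$pos[keep], b$pos[keep] + b$isize[keep] - 1L),
    strand = ifelse(bitwAnd(b$flag[keep], 0x10L) > 0L, "-", "+"),
    sample = sample)
  cnt <- Rsamtools::countBam(path)$records
  list(gr = gr, dropped = cnt - sum(keep) - sum(!is.na(b$isize) & b$isize < 0L))
}

#' Write gene models as GFF3
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- gm$genes[order(gm$genes$chrom, gm$genes$start), ]
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tgbsmedip\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i],
                       g$gene_id[i], g$symbol[i]), con)
    ex <- gm$exons[gm$exons$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tgbsmedip\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom[i], ex$start[j], ex$end[j], g$strand[i],
                         g$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Write gene models as BED12
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_models_bed12 <- function(gm, path) {
  g <- gm$genes[order(gm$genes$chrom, gm$genes$start), ]
  rows <- vapply(seq_len(nrow(g)), function(i) {
    ex <- gm$exons[gm$exons$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    start0 <- g$start[i] - 1L
    paste(g$chrom[i], start0, g$end[i], g$gene_id[i], 0L, g$strand[i],
          start0, g$end[i], "0", nrow(ex),
          paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
          paste0(paste(ex$start - 1L - start0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Load gene models from GFF3 or BED12
#'
#' GFF3 coordinates are 1-based inclusive; BED12 is 0-based half-open. Both
#' are unified into the package's `gene_models` representation (1-based
#' closed, strand-aware TSS/TTS). Records whose exons fall outside the
#' transcript are rejected with a warning.
#'
#' @param path annotation path.
#' @param format "GFF3" or "BED12".
#' @return a `gene_models` object.
#' @export
load_gene_models <- function(path, format = c("GFF3", "BED12")) {
  format <- match.arg(format)
  if (format == "GFF3") {
    gff <- rtracklayer::import(path, format = "gff3")
    is_gene <- tolower(as.character(gff$type)) == "gene"
    is_exon <- tolower(as.character(gff$type)) == "exon"
    gg <- gff[is_gene]
    genes <- data.frame(
      gene_id = as.character(gg$ID),
      symbol = if (!is.null(gg$Name)) as.character(gg$Name)
               else as.character(gg$ID),
      chrom = as.character(GenomicRanges::seqnames(gg)),
      strand = as.character(GenomicRanges::strand(gg)),
      start = GenomicRanges::start(gg),
      end = GenomicRanges::end(gg),
      stringsAsFactors = FALSE)
    ge <- gff[is_exon]
    parent <- vapply(ge$Parent, function(p) as.character(p)[1], character(1))
    exons <- data.frame(gene_id = parent,
                        start = GenomicRanges::start(ge),
                        end = GenomicRanges::end(ge),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 12L) stop_param("BED12 needs 12 columns: %s", path)
    genes <- data.frame(gene_id = as.character(df[[4]]),
                        symbol = as.character(df[[4]]),
                        chrom = as.character(df[[1]]),
                        strand = df[[6]],
                        start = df[[2]] + 1L, end = df[[3]],
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      sizes <- as.integer(strsplit(df[[11]][i], ",")[[1]])
      offs <- as.integer(strsplit(df[[12]][i], ",")[[1]])
      data.frame(gene_id = genes$gene_id[i],
                 start = genes$start[i] + offs,
                 end = genes$start[i] + offs + sizes - 1L)
    }))
  }
  ## reject genes with exons outside the transcript
  bad <- unique(exons$gene_id[
    exons$start < genes$start[match(exons$gene_id, genes$gene_id)] |
      exons$end > genes$end[match(exons$gene_id, genes$gene_id)]])
  if (length(bad)) {
    warning(sprintf("rejecting %d gene(s) with exons outside the transcript",
                    length(bad)), call. = FALSE)
    genes <- genes[!genes$gene_id %in% bad, ]
    exons <- exons[!exons$gene_id %in% bad, ]
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  structure(list(genes = genes[, c("gene_id", "symbol", "chrom", "strand",
                                   "start", "end", "tss", "tts")],
                 exons = exons), class = "gene_models")
}

#' Load gene sets from a GMT file
#' @param path GMT path (set name, description, then gene ids, tab-separated).
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop_param("GMT rows need at least 3 fields (name, description, genes)")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set descriptions.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  rows <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write the genome as FASTA
#' @param genome a `gbs_genome`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

#' Load a genome from FASTA into the pipeline's genome container
#' @param path FASTA path.
#' @return a `gbs_genome` (with CpG index built; no island annotation).
#' @export
load_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub(" .*$", "", names(seqs))
  genome <- structure(
    list(chrom_names = names(seqs), sequences = seqs,
         lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
         cpg_index = cpg_positions(seqs), islands = NULL),
    class = "gbs_genome")
  genome$islands <- granges_on(genome, character(0), integer(0), integer(0))
  genome
}

#' Read a sample sheet TSV
#' @param path TSV with header: sample, barcode, group, tissue (extra columns
#'   kept).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
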