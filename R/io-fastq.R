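## FASTQ records are written with a fixed "I" quality line (Phred+33, Q40);
## the simulator injects substitution errors in the base calls, not realistic
## quality strings.

write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (!length(ids)) {
    # an empty file is a valid FASTQ
    return(invisible(path))
  }
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal 4-line-record FASTQ reader (plain or gzipped).
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(gzfile(path))
  if (!length(lines))
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  if (length(lines) %% 4L != 0L)
    stop_param("malformed FASTQ (%d lines is not a multiple of 4): %s",
               length(lines), path)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", sub(" .*$", "", lines[idx])),
             seq = lines[idx + 1L], qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' Demultiplex a pooled GBS-MeDIP FASTQ pair
#'
#' A read pair is assigned to a sample when read 1 starts with that sample's
#' barcode immediately followed by the PstI cut-site remnant ("CTGCA" by
#' default); matching is exact, with no mismatch rescue. Assigned pairs are
#' written per sample with barcode + remnant trimmed from read 1; everything
#' else goes to a reject pair. Assignment partitions the input: per-sample
#' counts plus rejects always sum to the input pair count.
#'
#' @param fastq_r1,fastq_r2 pooled FASTQ paths (plain or gzipped).
#' @param barcode_table data.frame with columns `sample` and `barcode`
#'   (all barcodes equal length, unique) — e.g. a sample sheet.
#' @param remnant cut-site remnant expected right after the barcode.
#' @param out_dir output directory for per-sample FASTQ files.
#' @param gzip write gzipped outputs.
#' @return list with `stats` (data.frame sample/n plus a `.rejected` row),
#'   `files` (data.frame sample/r1/r2) and `rejects` (r1/r2 paths).
#' @export
demultiplex <- function(fastq_r1, fastq_r2, barcode_table, remnant = "CTGCA",
                        out_dir = tempfile("demux_"), gzip = TRUE) {
  if (!nchar(remnant)) stop_param("'remnant' must be non-empty")
  if (anyDuplicated(barcode_table$barcode)) stop_param("barcodes not unique")
  blen <- unique(nchar(barcode_table$barcode))
  if (length(blen) != 1L) stop_param("barcodes must all have equal length")

  r1 <- read_fastq(fastq_r1)
  r2 <- read_fastq(fastq_r2)
  if (nrow(r1) != nrow(r2))
    stop_param("R1/R2 record counts differ (%d vs %d)", nrow(r1), nrow(r2))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  prefix <- substr(r1$seq, 1L, blen)
  rem <- substr(r1$seq, blen + 1L, blen + nchar(remnant))
  assign_to <- barcode_table$sample[match(prefix, barcode_table$barcode)]
  assign_to[rem != remnant] <- NA_character_

  files <- data.frame(sample = barcode_table$sample,
                      r1 = file.path(out_dir, paste0(barcode_table$sample,
                                                     "_R1", ext)),
                      r2 = file.path(out_dir, paste0(barcode_table$sample,
                                                     "_R2", ext)),
                      stringsAsFactors = FALSE)
  counts <- integer(nrow(barcode_table))
  for (i in seq_len(nrow(barcode_table))) {
    hit <- which(assign_to == barcode_table$sample[i])
    counts[i] <- length(hit)
    write_fastq(r1$id[hit],
                substr(r1$seq[hit], blen + nchar(remnant) + 1L,
                       nchar(r1$seq[hit])),
                files$r1[i])
    write_fastq(r2$id[hit], r2$seq[hit], files$r2[i])
  }
  rej <- which(is.na(assign_to))
  rej_r1 <- file.path(out_dir, paste0("rejected_R1", ext))
  rej_r2 <- file.path(out_dir, paste0("rejected_R2", ext))
  write_fastq(r1$id[rej], r1$seq[rej], rej_r1)
  write_fastq(r2$id[rej], r2$seq[rej], rej_r2)

  stats <- rbind(
    data.frame(sample = barcode_table$sample, n = counts,
               stringsAsFactors = FALSE),
    data.frame(sample = ".rejected", n = length(rej)))
  list(stats = stats, files = files, rejects = c(r1 = rej_r1, r2 = rej_r2))
}
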