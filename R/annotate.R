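## Feature annotation of DMRs: each region is classified by its midpoint
## against strand-aware gene features with the precedence
## Promoter > Exon > Intron > Downstream > Distal Intergenic.
## Promoter = promoter_bp upstream of the TSS (sub-binned at 1 kb);
## Downstream = downstream_bp after the TTS. Intergenic regions are assigned
## to the nearest gene by absolute TSS distance.

FEATURE_LEVELS <- c("Promoter (<=1kb)", "Promoter (1-2kb)", "Promoter (2-3kb)",
                    "Exon", "Intron", "Downstream (<=300bp)",
                    "Distal Intergenic")

#' Signed distance from a region midpoint to a gene TSS
#'
#' The midpoint is `floor((start0 + end0) / 2)` in 0-based half-open
#' coordinates (equivalently `floor((start - 1 + end) / 2)` of the 1-based
#' closed range). The distance is strand-signed: negative values are upstream
#' of the TSS in the gene's reading direction.
#'
#' @param start,end region coordinates (1-based closed, vectorized).
#' @param tss gene TSS position (1-based).
#' @param strand gene strand, "+" or "-".
#' @return signed distance in bp.
#' @export
tss_distance <- function(start, end, tss, strand) {
  mid0 <- floor((start - 1 + end) / 2)
  tss0 <- tss - 1
  ifelse(strand == "+", mid0 - tss0, tss0 - mid0)
}

#' Magnitude bin label for a TSS distance
#'
#' Bins a signed distance to its leading digit times its power of ten:
#' -2450 becomes "-2 Kbps", +19999 "+10 Kbps", +20000 "+20 Kbps"; zero maps
#' to "0". This mirrors reporting TSS-distance peaks by order of magnitude.
#'
#' @param d signed distance(s) in bp.
#' @return character label(s).
#' @export
magnitude_bin <- function(d) {
  vapply(d, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x == 0) return("0")
    mag <- 10^floor(log10(abs(x)))
    lead <- floor(abs(x) / mag) * mag
    unit <- if (lead >= 1e6) c(1e6, "Mbps") else if (lead >= 1e3) c(1e3, "Kbps")
            else c(1, "bps")
    sprintf("%s%g %s", if (x > 0) "+" else "-",
            lead / as.numeric(unit[1]), unit[2])
  }, character(1))
}

## candidate features of one region midpoint against one gene; returns the
## highest-precedence feature or NA when the gene does not cover the midpoint
classify_against_gene <- function(mid0, gene, promoter_bp, downstream_bp,
                                  exons) {
  tss0 <- gene$tss - 1
  d <- if (gene$strand == "+") mid0 - tss0 else tss0 - mid0
  if (d >= -promoter_bp && d <= -1) {
    kb <- ceiling(-d / 1000)
    feat <- if (kb <= 1) "Promoter (<=1kb)" else
      sprintf("Promoter (%d-%dkb)", kb - 1, kb)
    if (feat == "Promoter (0-1kb)") feat <- "Promoter (<=1kb)"
    return(list(feature = feat, d = d))
  }
  mid1 <- mid0 + 1  # 1-based position of the midpoint
  if (mid1 >= gene$start && mid1 <= gene$end) {
    in_exon <- any(exons$start <= mid1 & exons$end >= mid1)
    return(list(feature = if (in_exon) "Exon" else "Intron", d = d))
  }
  down <- if (gene$strand == "+") {
    mid1 > gene$end && mid1 <= gene$end + downstream_bp
  } else {
    mid1 < gene$start && mid1 >= gene$start - downstream_bp
  }
  if (down) return(list(feature = "Downstream (<=300bp)", d = d))
  list(feature = NA_character_, d = d)
}

#' Annotate regions with genomic features, nearest genes and TSS distances
#'
#' Classifies each region by its midpoint with the precedence
#' Promoter > Exon > Intron > Downstream > Distal Intergenic; the promoter is
#' `promoter_bp` before the TSS (sub-binned at 1 kb) and the downstream
#' region `downstream_bp` after the TTS, both strand-aware. Among genes
#' offering the same feature class, ties break by smaller absolute TSS
#' distance, then lexicographic gene id. Regions hitting no feature are
#' Distal Intergenic and take the nearest gene by absolute TSS distance.
#' With an empty gene set everything is Distal Intergenic with NA gene and
#' distance.
#'
#' @param regions GRanges (or a `test_dmrs()` data.frame with chrom/start/end).
#' @param gene_models a `gene_models` object.
#' @param promoter_bp promoter extent upstream of the TSS (default 3000).
#' @param downstream_bp downstream extent after the TTS (default 300).
#' @return data.frame: chrom, start, end, feature, gene_id, symbol,
#'   tss_distance, magnitude_bin (plus the input columns when a data.frame
#'   was supplied).
#' @export
annotate_dmrs <- function(regions, gene_models, promoter_bp = 3000L,
                          downstream_bp = 300L) {
  df <- if (inherits(regions, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
               start = GenomicRanges::start(regions),
               end = GenomicRanges::end(regions),
               stringsAsFactors = FALSE)
  } else as.data.frame(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  genes <- gene_models$genes
  exons_by_gene <- split(gene_models$exons, gene_models$exons$gene_id)

  n <- nrow(df)
  feature <- rep("Distal Intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  if (nrow(genes)) {
    prec <- stats::setNames(seq_along(FEATURE_LEVELS), FEATURE_LEVELS)
    for (i in seq_len(n)) {
      mid0 <- floor((df$start[i] - 1 + df$end[i]) / 2)
      cand <- genes[genes$chrom == df$chrom[i], , drop = FALSE]
      if (!nrow(cand)) {
        ## nearest gene falls back to any chromosome? no gene on this one:
        ## keep NA gene but still Distal Intergenic
        next
      }
      best_feat <- NA_character_
      best_d <- NA_real_
      best_gene <- NA_character_
      all_d <- tss_distance(df$start[i], df$end[i], cand$tss, cand$strand)
      for (k in seq_len(nrow(cand))) {
        res <- classify_against_gene(mid0, cand[k, ], promoter_bp,
                                     downstream_bp,
                                     exons_by_gene[[cand$gene_id[k]]])
        if (is.na(res$feature)) next
        better <- is.na(best_feat) ||
          prec[[res$feature]] < prec[[best_feat]] ||
          (prec[[res$feature]] == prec[[best_feat]] &&
             (abs(res$d) < abs(best_d) ||
                (abs(res$d) == abs(best_d) &&
                   cand$gene_id[k] < best_gene)))
        if (better) {
          best_feat <- res$feature
          best_d <- res$d
          best_gene <- cand$gene_id[k]
        }
      }
      if (is.na(best_feat)) {
        ## Distal Intergenic: nearest gene by |TSS distance|, ties by gene id
        o <- order(abs(all_d), cand$gene_id)
        gene_id[i] <- cand$gene_id[o[1]]
        dist[i] <- all_d[o[1]]
      } else {
        feature[i] <- best_feat
        gene_id[i] <- best_gene
        dist[i] <- best_d
      }
    }
  }
  out <- df
  out$feature <- factor(feature, levels = FEATURE_LEVELS)
  out$gene_id <- gene_id
  out$symbol <- genes$symbol[match(gene_id, genes$gene_id)]
  out$tss_distance <- dist
  out$magnitude_bin <- magnitude_bin(dist)
  out
}

#' Feature-class fractions of an annotated set
#'
#' @param annotated output of [annotate_dmrs()] (non-empty).
#' @return data.frame: feature, n, fraction (fractions sum to 1).
#' @export
feature_distribution <- function(annotated) {
  if (!nrow(annotated)) stop_param("empty annotated set")
  tab <- table(annotated$feature)
  data.frame(feature = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' TSS-distance magnitude histogram
#'
#' Counts annotated regions per signed magnitude bin, ordered by the signed
#' distance each label represents.
#'
#' @param annotated output of [annotate_dmrs()].
#' @return data.frame: bin, n.
#' @export
tss_distance_histogram <- function(annotated) {
  d <- annotated$tss_distance
  bins <- magnitude_bin(d)
  tab <- table(bins)
  rep_d <- vapply(names(tab), function(b) {
    if (b == "0") return(0)
    sgn <- if (startsWith(b, "-")) -1 else 1
    v <- as.numeric(sub("^[+-]([0-9.]+) .*$", "\\1", b))
    unit <- if (grepl("Mbps", b)) 1e6 else if (grepl("Kbps", b)) 1e3 else 1
    sgn * v * unit
  }, numeric(1))
  data.frame(bin = names(tab)[order(rep_d)],
             n = as.integer(tab)[order(rep_d)],
             stringsAsFactors = FALSE)
}
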