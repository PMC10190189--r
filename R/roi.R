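#' Poisson background for stacked-read filtering
#'
#' PCR amplification can stack many identical fragments on one genomic
#' position. The per-position read count is modelled as Poisson with rate
#' `lambda_pos` (total fragments over distinct (chrom, start, strand)
#' positions); `n_star` is the smallest stack count whose upper tail
#' probability falls below `p_stack` (default 0.001), i.e. the first count
#' regarded as amplification excess.
#'
#' @param fragments a sample's aligned fragments (GRanges).
#' @param p_stack Poisson tail threshold for declaring a stack excessive.
#' @return list with `lambda_pos`, `n_star`, `p_stack` (class
#'   `poisson_background`).
#' @export
estimate_stack_threshold <- function(fragments, p_stack = 0.001) {
  if (!length(fragments)) stop_param("no fragments")
  key <- paste(as.character(GenomicRanges::seqnames(fragments)),
               GenomicRanges::start(fragments),
               as.character(GenomicRanges::strand(fragments)))
  lambda_pos <- length(fragments) / length(unique(key))
  structure(list(lambda_pos = lambda_pos,
                 n_star = poisson_stack_threshold(lambda_pos, p_stack),
                 p_stack = p_stack),
            class = "poisson_background")
}

#' Poisson stack threshold for a given per-position rate
#'
#' Smallest stack count `n` whose Poisson upper tail `P(X >= n | lambda)`
#' falls below `p` — the first count regarded as amplification excess.
#' At `lambda = 0.1` the tails are P(X>=1) = 0.0952, P(X>=2) = 4.68e-3,
#' P(X>=3) = 1.55e-4, so the threshold is 3.
#'
#' @param lambda mean reads per position.
#' @param p tail threshold (default 0.001).
#' @return integer threshold `n_star >= 1`.
#' @export
poisson_stack_threshold <- function(lambda, p = 0.001) {
  n <- 1L
  while (stats::ppois(n - 1L, lambda, lower.tail = FALSE) >= p) {
    n <- n + 1L
    if (n > 1e6) stop_param("stack threshold did not converge")
  }
  n
}

#' Remove stacked reads above the Poisson threshold
#'
#' For each (chrom, start, strand) key, retains at most `max(1, n_star - 1)`
#' fragments (the first by position-sorted input order) and reports the
#' number removed. Run per sample, before pooling groups: amplification
#' stacks are per-library artifacts.
#'
#' @param fragments a sample's aligned fragments (GRanges).
#' @param background a `poisson_background` from the same sample.
#' @return list with `fragments` (filtered GRanges) and `removed` (count).
#' @export
filter_stacked_reads <- function(fragments, background) {
  stopifnot(inherits(background, "poisson_background"))
  keep_max <- max(1L, background$n_star - 1L)
  o <- order(as.character(GenomicRanges::seqnames(fragments)),
             GenomicRanges::start(fragments),
             as.character(GenomicRanges::strand(fragments)))
  fr <- fragments[o]
  key <- paste(as.character(GenomicRanges::seqnames(fr)),
               GenomicRanges::start(fr),
               as.character(GenomicRanges::strand(fr)))
  rank_in_key <- stats::ave(seq_along(key), key, FUN = seq_along)
  keep <- rank_in_key <= keep_max
  list(fragments = fr[keep], removed = sum(!keep))
}

#' Call regions of interest from two merged coverage pools
#'
#' Slides windows along the genome and scores each window in both directions
#' (each group's merged pool as "treatment" against the other as "control").
#' The window p-value is the Poisson upper tail `P(X >= x_t)` at rate
#' `lambda = max(x_c * N_t / N_c, global_rate * window_bp)` where `N` are the
#' pool sizes and the global rate is the treatment pool's fragments per bp —
#' a scaled-control estimate with a genome-background floor. Window p-values
#' are BH-adjusted per direction; windows at `q <= roi_fdr` from either
#' direction are merged (union; overlapping or bookended windows joined) into
#' the final ROIs, each carrying the best contributing p and q. The procedure
#' is symmetric: swapping the pools yields the same ROI set.
#'
#' @param pool1,pool2 merged fragment GRanges for the two groups (non-empty).
#' @param genome a `gbs_genome`.
#' @param window_bp,step_bp sliding-window width and step.
#' @param roi_fdr BH threshold for retaining windows (default 0.1).
#' @return GRanges of disjoint ROIs with metadata `p` and `q` (best window
#'   values), sorted by (chrom, start).
#' @export
call_rois <- function(pool1, pool2, genome, window_bp = 300L, step_bp = 100L,
                      roi_fdr = 0.1) {
  stopifnot(inherits(genome, "gbs_genome"))
  if (!length(pool1) || !length(pool2)) stop_param("both pools must be non-empty")
  if (sum(genome$lengths) == 0) stop_param("zero-length genome")
  windows <- sliding_windows(genome, window_bp, step_bp)
  x1 <- GenomicRanges::countOverlaps(windows, pool1)
  x2 <- GenomicRanges::countOverlaps(windows, pool2)
  n1 <- length(pool1)
  n2 <- length(pool2)
  gbp <- sum(genome$lengths)

  score_dir <- function(xt, xc, nt, nc) {
    lambda <- pmax(xc * nt / nc, (nt / gbp) * window_bp)
    stats::ppois(xt - 1L, lambda, lower.tail = FALSE)
  }
  p_fwd <- score_dir(x1, x2, n1, n2)
  p_rev <- score_dir(x2, x1, n2, n1)
  q_fwd <- bh_adjust(p_fwd)
  q_rev <- bh_adjust(p_rev)

  hit <- q_fwd <= roi_fdr | q_rev <= roi_fdr
  if (!any(hit)) {
    out <- granges_on(genome, character(0), integer(0), integer(0))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(p = numeric(0),
                                                  q = numeric(0))
    return(out)
  }
  hw <- windows[hit]
  best_p <- pmin(p_fwd, p_rev)[hit]
  best_q <- pmin(q_fwd, q_rev)[hit]
  merged <- GenomicRanges::reduce(hw)  # joins overlapping + bookended windows
  ov <- GenomicRanges::findOverlaps(merged, hw)
  S4Vectors::mcols(merged)$p <- as.numeric(tapply(
    best_p[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), min))
  S4Vectors::mcols(merged)$q <- as.numeric(tapply(
    best_q[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), min))
  sort_by_coord(merged)
}

sliding_windows <- function(genome, window_bp, step_bp) {
  if (window_bp <= 0 || step_bp <= 0) stop_param("windows must be positive")
  per <- lapply(seq_along(genome$chrom_names), function(ci) {
    len <- genome$lengths[[ci]]
    starts <- seq(1L, max(1L, len - window_bp + 1L), by = step_bp)
    data.frame(chrom = genome$chrom_names[ci], start = starts,
               end = pmin(starts + window_bp - 1L, len))
  })
  df <- do.call(rbind, per)
  granges_on(genome, df$chrom, df$start, df$end)
}

#' Count fragments per ROI per sample
#'
#' A fragment is counted for an ROI when they share at least one bp.
#' Library sizes are the per-sample fragment totals after stack filtering.
#'
#' @param rois disjoint ROI GRanges.
#' @param fragments_by_sample named list of per-sample fragment GRanges
#'   (post stack filter).
#' @return An object of class `roi_counts`: list with `rois`, `samples`,
#'   `counts` (integer matrix, ROI x sample) and `library_sizes`.
#' @export
count_matrix <- function(rois, fragments_by_sample) {
  if (is.null(names(fragments_by_sample)))
    stop_param("'fragments_by_sample' must be a named list")
  if (length(rois) > 1 &&
      !all(GenomicRanges::countOverlaps(rois, rois) == 1L))
    stop_param("ROIs must be non-overlapping")
  counts <- vapply(fragments_by_sample, function(fr) {
    GenomicRanges::countOverlaps(rois, fr)
  }, integer(length(rois)))
  counts <- matrix(counts, nrow = length(rois),
                   dimnames = list(
                     sprintf("ROI_%06d", seq_along(rois)),
                     names(fragments_by_sample)))
  structure(list(rois = rois, samples = names(fragments_by_sample),
                 counts = counts,
                 library_sizes = vapply(fragments_by_sample, length,
                                        integer(1))),
            class = "roi_counts")
}

#' @export
print.roi_counts <- function(x, ...) {
  cat(sprintf("roi_counts: %d ROIs x %d samples (median library %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' Write ROIs as BED6 (score = -10 log10 q, truncated)
#' @param rois ROI GRanges with `q` metadata.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rois_bed <- function(rois, path) {
  q <- S4Vectors::mcols(rois)$q %||% rep(1, length(rois))
  score <- pmin(1000L, as.integer(floor(-10 * log10(pmax(q, 1e-100)))))
  write_bed6(rois, path, name = sprintf("ROI_%06d", seq_along(rois)),
             score = score)
}
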