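#' Venn-style overlap counts across region sets
#'
#' Two regions overlap when they share at least one bp. The Venn cells are
#' computed on the connected components of the overlap graph across all sets
#' (touching-but-not-overlapping regions stay separate): each component is
#' counted once under the membership signature of the sets contributing to
#' it.
#'
#' @param region_sets named list of GRanges, each internally disjoint.
#' @return An object of class `overlap_result`: list with `set_sizes`,
#'   `cells` (data.frame: signature, n), `pairwise` (matrix of component
#'   counts shared by each set pair).
#' @export
find_overlaps <- function(region_sets) {
  if (is.null(names(region_sets)) || any(!nzchar(names(region_sets))))
    stop_param("'region_sets' must be a named list")
  for (nm in names(region_sets)) {
    gr <- region_sets[[nm]]
    if (any(GenomicRanges::width(gr) < 1L))
      stop_param("malformed interval in set '%s'", nm)
    if (length(gr) > 1 && !all(GenomicRanges::countOverlaps(gr, gr) == 1L))
      stop_param("set '%s' is not internally disjoint", nm)
  }
  all_gr <- unlist(GenomicRanges::GRangesList(lapply(region_sets, function(g) {
    GenomicRanges::granges(g)
  })), use.names = FALSE)
  ## min.gapwidth = 0: merge only genuinely overlapping ranges, never bookends
  comps <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
  member <- vapply(region_sets, function(g) {
    GenomicRanges::countOverlaps(comps, g, ignore.strand = TRUE) > 0L
  }, logical(length(comps)))
  member <- matrix(member, nrow = length(comps),
                   dimnames = list(NULL, names(region_sets)))
  sig <- apply(member, 1L, function(row) {
    paste(names(region_sets)[row], collapse = "&")
  })
  cells <- as.data.frame(table(sig), stringsAsFactors = FALSE)
  names(cells) <- c("signature", "n")
  k <- length(region_sets)
  pairwise <- matrix(0L, k, k,
                     dimnames = list(names(region_sets), names(region_sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- sum(member[, i] & member[, j])
  }
  structure(list(set_sizes = vapply(region_sets, length, integer(1)),
                 cells = cells, pairwise = pairwise,
                 components = comps, membership = member),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result\nset sizes:\n")
  print(x$set_sizes)
  cat("Venn cells (overlap-graph components):\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Permutation test for overlap between two region sets
#'
#' Null model: every region of `set_b` is relocated uniformly at random,
#' chromosome-matched and length-preserving, within the placement universe
#' (the whole genome, or a supplied interval universe such as the ROI space).
#' The statistic is the number of `set_a` regions overlapped by (the permuted)
#' `set_b`; the empirical p-value uses the add-one estimator
#' `(1 + #(perm >= observed)) / (n_perm + 1)`, which can never return 0.
#'
#' @param set_a,set_b GRanges.
#' @param universe either a `gbs_genome` (whole-genome placement) or a GRanges
#'   of allowed placement intervals.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return list of class `permutation_overlap`: observed, null_mean, null_sd,
#'   p, n_perm, seed.
#' @export
permutation_overlap_test <- function(set_a, set_b, universe, n_perm = 100L,
                                     seed = NULL) {
  uni <- if (inherits(universe, "gbs_genome")) {
    GenomicRanges::GRanges(universe$chrom_names,
                           IRanges::IRanges(1L, universe$lengths))
  } else universe
  uni_chrom <- as.character(GenomicRanges::seqnames(uni))
  b_chrom <- as.character(GenomicRanges::seqnames(set_b))
  b_width <- GenomicRanges::width(set_b)
  ## per set_b region: universe intervals on its chromosome that can hold it
  slots <- lapply(seq_along(set_b), function(i) {
    u <- uni[uni_chrom == b_chrom[i]]
    u <- u[GenomicRanges::width(u) >= b_width[i]]
    if (!length(u))
      stop_param("region %d (%d bp) does not fit in the universe on %s",
                 i, b_width[i], b_chrom[i])
    data.frame(start = GenomicRanges::start(u),
               room = GenomicRanges::width(u) - b_width[i] + 1L)
  })
  observed <- sum(GenomicRanges::countOverlaps(
    set_a, set_b, ignore.strand = TRUE) > 0L)
  stats_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      starts <- vapply(seq_along(set_b), function(i) {
        sl <- slots[[i]]
        j <- sample.int(nrow(sl), 1L, prob = sl$room)
        sl$start[j] + sample.int(sl$room[j], 1L) - 1L
      }, integer(1))
      perm_b <- GenomicRanges::GRanges(
        b_chrom, IRanges::IRanges(starts, width = b_width))
      sum(GenomicRanges::countOverlaps(set_a, perm_b,
                                       ignore.strand = TRUE) > 0L)
    }, integer(1))
  })
  structure(list(observed = observed,
                 null_mean = mean(stats_null),
                 null_sd = stats::sd(stats_null),
                 p = (1 + sum(stats_null >= observed)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "permutation_overlap")
}

#' @export
print.permutation_overlap <- function(x, ...) {
  cat(sprintf(
    "permutation_overlap: observed %d, null %.2f +/- %.2f, p = %.4g (N = %d)\n",
    x$observed, x$null_mean, x$null_sd, x$p, x$n_perm))
  invisible(x)
}
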