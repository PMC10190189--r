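#' CpG coupling values for a set of regions
#'
#' The coupling value of a region is its CpG count: the number of CpG
#' dinucleotide start positions inside the region. MeDIP coverage depends on
#' local CpG density, and the coupling value is the covariate of that
#' dependency.
#'
#' @param rois region GRanges.
#' @param genome a `gbs_genome` (regions must lie on its chromosomes).
#' @return integer vector of coupling values, one per region.
#' @export
compute_coupling <- function(rois, genome) {
  stopifnot(inherits(genome, "gbs_genome"))
  chroms <- as.character(GenomicRanges::seqnames(rois))
  if (!all(chroms %in% genome$chrom_names))
    stop_param("region on unknown chromosome")
  if (any(GenomicRanges::end(rois) >
          genome$lengths[chroms]))
    stop_param("region beyond chromosome end")
  count_cpgs_in(rois, genome)
}

#' Fit the coverage-vs-CpG-density calibration line
#'
#' Bins regions by integer coupling value, computes the mean raw count per
#' bin, and fits an ordinary least-squares line through the bin means on the
#' ascending low-coupling portion — bins from 0 up to the bin with the maximum
#' mean (beyond it, antibody saturation flattens and bends the relationship).
#' The calibration plot of MeDIP data is this bin-mean curve with the fitted
#' line.
#'
#' @param counts one sample's raw counts, aligned with `coupling`.
#' @param coupling coupling values from [compute_coupling()].
#' @return An object of class `calibration_fit`: list with `intercept`,
#'   `slope`, `c_max_fit` (last coupling bin used), `bins` (data.frame:
#'   coupling, mean_count, n, residual).
#' @export
fit_calibration <- function(counts, coupling) {
  if (length(counts) != length(coupling))
    stop_param("'counts' and 'coupling' lengths differ")
  mean_by <- tapply(counts, coupling, mean)
  cvals <- as.integer(names(mean_by))
  if (length(cvals) < 2L)
    stop_param("calibration needs >= 2 distinct coupling bins")
  c_max_fit <- cvals[which.max(mean_by)]
  use <- cvals <= c_max_fit
  if (sum(use) < 2L) {
    ## max-mean bin is the first bin; fall back to the full range
    use <- rep(TRUE, length(cvals))
    c_max_fit <- max(cvals)
  }
  fit <- stats::lm.fit(cbind(1, cvals[use]), as.numeric(mean_by[use]))
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  bins <- data.frame(coupling = cvals,
                     mean_count = as.numeric(mean_by),
                     n = as.integer(table(coupling)),
                     residual = as.numeric(mean_by) - (a + b * cvals))
  structure(list(intercept = unname(a), slope = unname(b),
                 c_max_fit = c_max_fit, bins = bins),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration_fit: count = %.4g + %.4g * coupling (fit up to c = %d)\n",
              x$intercept, x$slope, x$c_max_fit))
  invisible(x)
}

#' Relative methylation scores
#'
#' Divides each raw count by its coupling-predicted expectation under the
#' sample's calibration line, flooring the prediction at its value for one
#' CpG so CpG-free regions do not blow up the ratio. The rms matrix is a
#' descriptive, display-level normalization; differential testing runs on raw
#' counts with size factors.
#'
#' @param cm a `roi_counts` object.
#' @param calibrations named list of `calibration_fit`, one per sample.
#' @param coupling coupling values for the ROIs of `cm`.
#' @return numeric matrix of rms values, same shape as `cm$counts`.
#' @export
rms_transform <- function(cm, calibrations, coupling) {
  stopifnot(inherits(cm, "roi_counts"))
  if (!all(cm$samples %in% names(calibrations)))
    stop_param("missing calibration for some samples")
  out <- cm$counts * 0
  for (smp in cm$samples) {
    cal <- calibrations[[smp]]
    floor_val <- cal$intercept + cal$slope * 1
    pred <- pmax(cal$intercept + cal$slope * coupling, floor_val)
    out[, smp] <- cm$counts[, smp] / pred
  }
  out
}

#' CpG enrichment score of a fragment set
#'
#' Density-ratio ("relH"-style) enrichment: CpG density within the union of
#' the covered intervals divided by the genome-wide CpG density. Scores above
#' 1 indicate methylation-biased capture, the signature of a working MeDIP
#' enrichment.
#'
#' @param fragments covered fragments (GRanges, non-empty).
#' @param genome a `gbs_genome`.
#' @return single numeric enrichment score.
#' @export
cpg_enrichment_score <- function(fragments, genome) {
  stopifnot(inherits(genome, "gbs_genome"))
  if (!length(fragments)) stop_param("empty coverage")
  un <- GenomicRanges::reduce(fragments, ignore.strand = TRUE)
  covered_cpg <- sum(count_cpgs_in(un, genome))
  covered_bp <- sum(GenomicRanges::width(un))
  genome_cpg <- genome_cpg_count(genome)
  genome_bp <- sum(genome$lengths)
  (covered_cpg / covered_bp) / (genome_cpg / genome_bp)
}

#' Distinct CpG positions under a fragment set
#'
#' @param fragments covered fragments (GRanges).
#' @param genome a `gbs_genome`.
#' @return integer count of distinct CpG start positions covered.
#' @export
covered_cpg_count <- function(fragments, genome) {
  un <- GenomicRanges::reduce(fragments, ignore.strand = TRUE)
  sum(count_cpgs_in(un, genome))
}
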