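#' Default pipeline parameters
#'
#' Every tunable of the pipeline with its default: stacked-read Poisson
#' threshold `p_stack = 0.001`; ROI window FDR `roi_fdr = 0.1`; window
#' geometry 300/100 bp; `min_row_sum = 10`; DMR tiers `dmr_p = 0.05` and
#' `dmr_fdr = 0.6`; promoter/downstream extents 3000/300 bp; `n_perm = 100`
#' permutations; ORA report threshold `ora_fdr = 0.1`; capture model
#' `kappa = 1`, `epsilon = 0.01`; size selection 200-500 bp; `read_len = 100`.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(p_stack = 0.001, roi_fdr = 0.1, window_bp = 300L, step_bp = 100L,
            min_row_sum = 10L, dmr_p = 0.05, dmr_fdr = 0.6,
            promoter_bp = 3000L, downstream_bp = 300L, n_perm = 100L,
            ora_fdr = 0.1, kappa = 1, epsilon = 0.01,
            size_min = 200L, size_max = 500L, read_len = 100L)
  o <- list(...)
  bad <- setdiff(names(o), names(p))
  if (length(bad)) stop_param("unknown parameter(s): %s",
                              paste(bad, collapse = ", "))
  utils::modifyList(p, o)
}

#' Auto-generate contrasts from a sample sheet
#'
#' With group labels E, BS and BN present in a tissue, builds the four
#' standard contrasts E/B (B being the union of BS and BN), E/BS, E/BN and
#' BS/BN; with exactly two labels, the single two-group contrast. Contrasts
#' with fewer than 2 samples on either side are skipped with a message.
#' A 3-tissue sheet with the full label set therefore yields 12 contrasts.
#'
#' @param sample_sheet data.frame with `sample`, `group`, `tissue` columns.
#' @return list of `contrast_spec` objects.
#' @export
make_contrasts <- function(sample_sheet) {
  stopifnot(all(c("sample", "group", "tissue") %in% names(sample_sheet)))
  out <- list()
  for (tis in unique(sample_sheet$tissue)) {
    sub <- sample_sheet[sample_sheet$tissue == tis, ]
    byg <- split(sub$sample, sub$group)
    byg <- byg[unique(sub$group)]  # keep sheet order, not alphabetical
    pairs <- if (all(c("E", "BS", "BN") %in% names(byg))) {
      b_all <- byg$B %||% c(byg$BS, byg$BN)
      list(list("E/B", byg$E, b_all),
           list("E/BS", byg$E, byg$BS),
           list("E/BN", byg$E, byg$BN),
           list("BS/BN", byg$BS, byg$BN))
    } else if (length(byg) == 2L) {
      list(list(paste(names(byg)[1], names(byg)[2], sep = "/"),
                byg[[1]], byg[[2]]))
    } else {
      ## all pairwise comparisons for other label layouts
      cmb <- utils::combn(names(byg), 2L, simplify = FALSE)
      lapply(cmb, function(pr) {
        list(paste(pr[1], pr[2], sep = "/"), byg[[pr[1]]], byg[[pr[2]]])
      })
    }
    for (pr in pairs) {
      if (length(pr[[2]]) < 2L || length(pr[[3]]) < 2L) {
        message(sprintf("skipping contrast %s-%s: < 2 samples per side",
                        tis, pr[[1]]))
        next
      }
      out[[paste(tis, pr[[1]], sep = "-")]] <-
        contrast_spec(paste(tis, pr[[1]], sep = "-"), pr[[2]], pr[[3]],
                      tissue = tis)
    }
  }
  out
}

#' Run the full per-contrast analysis
#'
#' End-to-end driver over aligned fragments: per-sample stacked-read
#' filtering, per-contrast group-merged ROI calling, ROI counting, coupling
#' calibration and rms, NB exact DMR testing with the two significance tiers,
#' feature annotation, TSS-distance histograms, cross-contrast overlap
#' counting with permutation tests (within tissue, on the pooled ROI
#' universe), and per-contrast gene-set over-representation against the
#' universe of genes carrying at least one tested ROI.
#'
#' @param fragments_by_sample named list of per-sample aligned fragment
#'   GRanges.
#' @param sample_sheet data.frame with `sample`, `group`, `tissue`.
#' @param genome a `gbs_genome`.
#' @param gene_models optional `gene_models` (annotation/ORA skipped if NULL).
#' @param gene_sets optional named list of gene sets for ORA.
#' @param params list from [pipeline_params()].
#' @param contrasts optional explicit list of `contrast_spec` (defaults to
#'   [make_contrasts()]).
#' @param out_dir optional directory; when given, per-contrast TSV/BED files
#'   and a manifest TSV are written.
#' @param seed integer seed for the permutation tests.
#' @return list with `contrasts` (per-contrast results: rois, counts, dmr
#'   table, annotation, feature fractions, tss histogram, ora), `overlaps`,
#'   `permutation_tests`, `manifest` (data.frame), `filter_stats`.
#' @export
run_contrasts <- function(fragments_by_sample, sample_sheet, genome,
                          gene_models = NULL, gene_sets = NULL,
                          params = pipeline_params(), contrasts = NULL,
                          out_dir = NULL, seed = 1L) {
  stopifnot(inherits(genome, "gbs_genome"))
  if (!all(sample_sheet$sample %in% names(fragments_by_sample)))
    stop_param("sample sheet lists samples without fragments")

  ## stage 0: per-sample stack filtering
  filtered <- list()
  filter_stats <- data.frame(sample = character(0), input = integer(0),
                             removed = integer(0), n_star = integer(0))
  for (smp in sample_sheet$sample) {
    fr <- fragments_by_sample[[smp]]
    bg <- estimate_stack_threshold(fr, params$p_stack)
    fl <- filter_stacked_reads(fr, bg)
    filtered[[smp]] <- fl$fragments
    filter_stats <- rbind(filter_stats, data.frame(
      sample = smp, input = length(fr), removed = fl$removed,
      n_star = bg$n_star))
  }

  contrasts <- contrasts %||% make_contrasts(sample_sheet)
  res <- list()
  manifest <- list()
  have_genes <- !is.null(gene_models) && nrow(gene_models$genes) > 0
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    pool1 <- do.call(c, unname(filtered[ct$group1]))
    pool2 <- do.call(c, unname(filtered[ct$group2]))
    rois <- call_rois(pool1, pool2, genome, params$window_bp, params$step_bp,
                      params$roi_fdr)
    entry <- list(contrast = ct, rois = rois)
    if (length(rois)) {
      cm <- count_matrix(rois, filtered[c(ct$group1, ct$group2)])
      coupling <- compute_coupling(rois, genome)
      calib <- lapply(cm$samples, function(s) {
        tryCatch(fit_calibration(cm$counts[, s], coupling),
                 error = function(e) NULL)
      })
      names(calib) <- cm$samples
      rms <- if (!any(vapply(calib, is.null, logical(1))))
        rms_transform(cm, calib, coupling) else NULL
      dmr <- test_dmrs(cm, ct, min_row_sum = params$min_row_sum,
                       p_thr = params$dmr_p, fdr_thr = params$dmr_fdr)
      entry <- c(entry, list(counts = cm, coupling = coupling,
                             calibration = calib, rms = rms, dmr = dmr))
      if (have_genes && nrow(dmr)) {
        ann <- annotate_dmrs(dmr, gene_models, params$promoter_bp,
                             params$downstream_bp)
        expl <- ann[ann$exploratory, , drop = FALSE]
        entry$annotation <- ann
        if (nrow(expl)) {
          entry$feature_fractions <- feature_distribution(expl)
          entry$tss_histogram <- tss_distance_histogram(expl)
        }
        if (!is.null(gene_sets) && nrow(expl)) {
          universe <- map_dmrs_to_genes(ann)
          query <- map_dmrs_to_genes(expl)
          if (length(universe) && length(query))
            entry$ora <- ora_test(query, universe, gene_sets,
                                  params$ora_fdr)
        }
      }
      manifest[[cn]] <- data.frame(
        contrast = cn, tissue = ct$tissue,
        n_samples = length(c(ct$group1, ct$group2)),
        n_roi = length(rois), n_tested = nrow(dmr),
        n_dmr_p = sum(dmr$exploratory), n_dmr_fdr = sum(dmr$top))
    } else {
      manifest[[cn]] <- data.frame(
        contrast = cn, tissue = ct$tissue,
        n_samples = length(c(ct$group1, ct$group2)),
        n_roi = 0L, n_tested = 0L, n_dmr_p = 0L, n_dmr_fdr = 0L)
    }
    res[[cn]] <- entry
  }

  ## cross-contrast overlap and permutation tests within each tissue
  dmr_sets <- lapply(res, function(e) {
    if (is.null(e$dmr) || !nrow(e$dmr)) return(GenomicRanges::GRanges())
    d <- e$dmr[e$dmr$exploratory, , drop = FALSE]
    GenomicRanges::reduce(GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start, d$end)), min.gapwidth = 0L)
  })
  nonempty <- names(dmr_sets)[vapply(dmr_sets, length, integer(1)) > 0]
  overlaps <- if (length(nonempty) >= 2L)
    find_overlaps(dmr_sets[nonempty]) else NULL
  perm_tests <- list()
  tissues <- vapply(res, function(e) e$contrast$tissue, character(1))
  for (tis in unique(tissues)) {
    members <- intersect(nonempty, names(tissues)[tissues == tis])
    if (length(members) < 2L) next
    roi_universe <- GenomicRanges::reduce(do.call(c, unname(
      lapply(res[members], function(e) GenomicRanges::granges(e$rois)))))
    cmb <- utils::combn(members, 2L, simplify = FALSE)
    for (pr in cmb) {
      key <- paste(pr, collapse = " vs ")
      perm_tests[[key]] <- permutation_overlap_test(
        dmr_sets[[pr[1]]], dmr_sets[[pr[2]]], roi_universe,
        n_perm = params$n_perm, seed = seed)
    }
  }

  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  out <- list(contrasts = res, overlaps = overlaps,
              permutation_tests = perm_tests, manifest = manifest,
              filter_stats = filter_stats, params = params, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

## plain-file output tree: one subdirectory per contrast plus shared reports
write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$filter_stats, file.path(out_dir, "filter_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cn in names(run$contrasts)) {
    e <- run$contrasts[[cn]]
    cdir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", cn))
    dir.create(cdir, showWarnings = FALSE)
    if (!is.null(e$rois) && length(e$rois))
      write_rois_bed(e$rois, file.path(cdir, "rois.bed"))
    if (!is.null(e$counts))
      utils::write.table(e$counts$counts, file.path(cdir, "counts.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    for (tbl in c("dmr", "annotation", "feature_fractions",
                  "tss_histogram", "ora")) {
      if (!is.null(e[[tbl]]))
        utils::write.table(e[[tbl]], file.path(cdir, paste0(tbl, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(run$overlaps))
    utils::write.table(run$overlaps$cells,
                       file.path(out_dir, "overlap_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(run$permutation_tests)) {
    pt <- do.call(rbind, lapply(names(run$permutation_tests), function(k) {
      x <- run$permutation_tests[[k]]
      data.frame(comparison = k, observed = x$observed,
                 null_mean = x$null_mean, null_sd = x$null_sd, p = x$p,
                 n_perm = x$n_perm)
    }))
    utils::write.table(pt, file.path(out_dir, "permutation_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
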