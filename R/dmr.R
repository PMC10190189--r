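#' Median-of-ratios size factors
#'
#' Library-size normalization factors: for each sample, the median over ROIs
#' of the count divided by the ROI's geometric mean across samples, computed
#' over ROIs where every sample has a positive count. When fewer than 10 such
#' ROIs exist, falls back to total-count ratios. Factors are rescaled to
#' geometric mean 1.
#'
#' @param cm a `roi_counts` object or a plain count matrix.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
size_factors <- function(cm) {
  x <- if (inherits(cm, "roi_counts")) cm$counts else as.matrix(cm)
  if (all(x == 0)) stop_param("all-zero count matrix")
  log_gm <- rowMeans(log(x))
  use <- is.finite(log_gm)  # rows with all-positive counts
  if (sum(use) >= 10L) {
    f <- apply(x[use, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - log_gm[use]))
    })
  } else {
    f <- colSums(x) / mean(colSums(x))
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

#' Contrast specification
#'
#' @param name contrast label, e.g. "A-E/B".
#' @param group1,group2 disjoint non-empty sample-name vectors.
#' @param tissue optional tissue label.
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group1, group2, tissue = NA_character_) {
  if (!length(group1) || !length(group2))
    stop_param("both groups must be non-empty")
  if (length(intersect(group1, group2)))
    stop_param("groups must be disjoint")
  structure(list(name = name, group1 = group1, group2 = group2,
                 tissue = tissue), class = "contrast_spec")
}

#' Estimate negative-binomial dispersion with shrinkage
#'
#' Per ROI, a method-of-moments estimate on size-factor-normalized counts
#' pooled across the two groups after centering group means:
#' `phi_hat = max(0, (s2 - mu) / mu^2)` with `s2` the pooled within-group
#' variance and `mu` the overall normalized mean. The common dispersion
#' `phi_common` is a 20% trimmed mean of the per-ROI estimates, and each ROI
#' is shrunk towards it with prior weight `n0`:
#' `phi_i = (d_i * phi_hat_i + n0 * phi_common) / (d_i + n0)`, `d_i` the
#' residual degrees of freedom.
#'
#' @param cm a `roi_counts` object.
#' @param contrast a `contrast_spec`.
#' @param n0 shrinkage prior weight (default 10).
#' @param sf optional precomputed size factors.
#' @return list of class `dispersion_model` with `phi_common`, `phi`
#'   (per ROI), `phi_raw`, `n0`, `df_resid`.
#' @export
estimate_dispersion <- function(cm, contrast, n0 = 10, sf = NULL) {
  stopifnot(inherits(cm, "roi_counts"), inherits(contrast, "contrast_spec"))
  smp <- c(contrast$group1, contrast$group2)
  if (!all(smp %in% cm$samples))
    stop_param("contrast samples absent from the count matrix")
  if (length(contrast$group1) < 2L || length(contrast$group2) < 2L)
    stop_param("dispersion estimation needs >= 2 samples per group")
  sf <- sf %||% size_factors(cm)
  y <- sweep(cm$counts[, smp, drop = FALSE], 2L, sf[smp], "/")
  g <- rep(c(1L, 2L), c(length(contrast$group1), length(contrast$group2)))
  n <- length(smp)
  d <- n - 2L
  mu1 <- rowMeans(y[, g == 1L, drop = FALSE])
  mu2 <- rowMeans(y[, g == 2L, drop = FALSE])
  centered <- y
  centered[, g == 1L] <- y[, g == 1L, drop = FALSE] - mu1
  centered[, g == 2L] <- y[, g == 2L, drop = FALSE] - mu2
  s2 <- rowSums(centered^2) / d
  mu <- rowMeans(y)
  phi_raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  phi_common <- mean(phi_raw, trim = 0.2)
  phi <- (d * phi_raw + n0 * phi_common) / (d + n0)
  structure(list(phi_common = phi_common, phi = phi, phi_raw = phi_raw,
                 n0 = n0, df_resid = d),
            class = "dispersion_model")
}

#' Two-sided conditional negative-binomial exact test
#'
#' Conditions on the ROI total `T = t1 + t2` under equal per-sample-adjusted
#' means. The conditional split distribution is a Dirichlet-multinomial
#' kernel with sizes `r_g = n_g / phi`, tilted by the relative group rates
#' (group rate proportional to the sum of its size factors):
#' `w(t1) = DM(t1; r1, r2) * rho^t1`, `rho = (S1 n2) / (S2 n1)`. The p-value
#' sums the normalized probabilities of all splits no more probable than the
#' observed one. At `phi = 0` the kernel reduces exactly to the conditional
#' binomial with success probability `S1 / (S1 + S2)`. Totals above
#' `max_enum` use a normal approximation of the conditional distribution.
#'
#' @param t1,t2 group total counts.
#' @param n1,n2 samples per group.
#' @param phi negative-binomial dispersion (>= 0).
#' @param s1,s2 summed size factors per group (default `n1`, `n2`: equal
#'   factors).
#' @param max_enum largest total enumerated exactly (default 5000).
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(t1, t2, n1, n2, phi = 0, s1 = n1, s2 = n2,
                          max_enum = 5000L) {
  total <- t1 + t2
  if (total == 0L) return(1)
  pi1 <- s1 / (s1 + s2)
  if (total > max_enum) return(nb_test_normal_approx(t1, total, n1, n2,
                                                     phi, pi1))
  t <- 0:total
  lw <- if (phi <= 1e-12) {
    stats::dbinom(t, total, pi1, log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    rho <- (s1 * n2) / (s2 * n1)
    lgamma(t + r1) - lgamma(t + 1) - lgamma(r1) +
      lgamma(total - t + r2) - lgamma(total - t + 1) - lgamma(r2) +
      t * log(rho)
  }
  lw <- lw - logsumexp(lw)
  lobs <- lw[t1 + 1L]
  min(1, sum(exp(lw[lw <= lobs + 1e-7])))
}

## moment-matched normal approximation of the conditional split distribution:
## mean T*pi1; Dirichlet-multinomial variance inflation (a0 + T)/(a0 + 1)
## with a0 = (n1 + n2)/phi, collapsing to the binomial variance at phi = 0
nb_test_normal_approx <- function(t1, total, n1, n2, phi, pi1) {
  mu <- total * pi1
  v <- total * pi1 * (1 - pi1)
  if (phi > 1e-12) {
    a0 <- (n1 + n2) / phi
    v <- v * (a0 + total) / (a0 + 1)
  }
  min(1, 2 * stats::pnorm(-abs(t1 - mu) / sqrt(v)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, clipped to 1,
#' invariant to input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values aligned with the input.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_param("p-values must be within [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Test ROIs for differential methylation
#'
#' Stage-2 statistics: drops ROIs whose count sum over the contrast samples is
#' below `min_row_sum`, runs the conditional NB exact test per remaining ROI
#' (dispersion from `dispersion`), BH-adjusts across tested ROIs, and flags
#' the two significance tiers — exploratory (`p <= p_thr`) and top
#' (`q <= fdr_thr`), computed independently. The log2 fold change uses
#' 0.5-shifted normalized group means; the hypermethylated label names the
#' group with the larger normalized mean ("E>B" style).
#'
#' @param cm a `roi_counts` object.
#' @param contrast a `contrast_spec`.
#' @param dispersion a `dispersion_model` for the same matrix/contrast, or a
#'   single numeric dispersion recycled over ROIs.
#' @param min_row_sum minimum count sum over contrast samples (default 10).
#' @param p_thr exploratory-tier p threshold (default 0.05).
#' @param fdr_thr top-tier BH threshold (default 0.6).
#' @param sf optional precomputed size factors.
#' @return data.frame (one row per tested ROI): roi, chrom, start, end,
#'   mean1, mean2, log2fc, phi, p, q, logical `exploratory` and `top` tier
#'   flags, a display `tier` label, and the `hyper` direction label.
#' @export
test_dmrs <- function(cm, contrast, dispersion = NULL, min_row_sum = 10L,
                      p_thr = 0.05, fdr_thr = 0.6, sf = NULL) {
  stopifnot(inherits(cm, "roi_counts"), inherits(contrast, "contrast_spec"))
  smp <- c(contrast$group1, contrast$group2)
  if (!all(smp %in% cm$samples))
    stop_param("contrast samples absent from the count matrix")
  sf <- sf %||% size_factors(cm)
  dispersion <- dispersion %||% estimate_dispersion(cm, contrast, sf = sf)
  phi_all <- if (inherits(dispersion, "dispersion_model")) dispersion$phi
             else rep(dispersion, nrow(cm$counts))

  x <- cm$counts[, smp, drop = FALSE]
  keep <- rowSums(x) >= min_row_sum
  if (!any(keep)) {
    return(data.frame(roi = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      mean1 = numeric(0), mean2 = numeric(0),
                      log2fc = numeric(0), phi = numeric(0),
                      p = numeric(0), q = numeric(0),
                      exploratory = logical(0), top = logical(0),
                      tier = character(0), hyper = character(0)))
  }
  idx <- which(keep)
  g1 <- contrast$group1
  g2 <- contrast$group2
  s1 <- sum(sf[g1])
  s2 <- sum(sf[g2])
  t1 <- rowSums(x[idx, g1, drop = FALSE])
  t2 <- rowSums(x[idx, g2, drop = FALSE])
  phi <- phi_all[idx]
  p <- vapply(seq_along(idx), function(i) {
    nb_exact_test(t1[i], t2[i], length(g1), length(g2), phi[i], s1, s2)
  }, numeric(1))
  q <- bh_adjust(p)

  y <- sweep(x[idx, , drop = FALSE], 2L, sf[smp], "/")
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  log2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  lbl1 <- unique(sub("[0-9_].*$", "", g1))[1]
  lbl2 <- unique(sub("[0-9_].*$", "", g2))[1]
  hyper <- ifelse(m1 >= m2, paste0(lbl1, ">", lbl2), paste0(lbl2, ">", lbl1))
  ## the two tiers are defined independently; `tier` is a display label
  exploratory <- p <= p_thr
  top <- q <= fdr_thr
  tier <- ifelse(top, "top", ifelse(exploratory, "exploratory", "none"))

  rois <- cm$rois[idx]
  data.frame(roi = rownames(cm$counts)[idx],
             chrom = as.character(GenomicRanges::seqnames(rois)),
             start = GenomicRanges::start(rois),
             end = GenomicRanges::end(rois),
             mean1 = m1, mean2 = m2, log2fc = log2fc, phi = phi,
             p = p, q = q, exploratory = exploratory, top = top,
             tier = tier, hyper = hyper,
             row.names = NULL, stringsAsFactors = FALSE)
}
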