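test_that("stack threshold matches closed-form and brute-force Poisson tails", {
  expect_equal(poisson_stack_threshold(0.1), 3L)

  ## brute-force tail: sum of dpois masses from n upward
  brute <- function(lambda, p) {
    n <- 1L
    repeat {
      tail <- sum(stats::dpois(n:(n + 2000L), lambda))
      if (tail < p) return(n)
      n <- n + 1L
    }
  }
  for (lambda in c(0.05, 0.5, 2, 10)) {
    expect_equal(poisson_stack_threshold(lambda),
                 brute(lambda, 0.001))
  }
})

test_that("the estimated background reflects position multiplicity", {
  fr <- gr("chr1", c(10L, 10L, 50L, 90L), c(110L, 110L, 150L, 190L),
           strand = "+")
  bg <- estimate_stack_threshold(fr)
  expect_equal(bg$lambda_pos, 4 / 3)
  expect_s3_class(bg, "poisson_background")
  expect_error(estimate_stack_threshold(fr[0]), "no fragments")
})

test_that("stack filtering keeps at most n_star - 1 per position", {
  bg <- structure(list(lambda_pos = 0.1, n_star = 3L, p_stack = 0.001),
                  class = "poisson_background")
  five <- gr("chr1", rep(100L, 5), rep(400L, 5), strand = "+")
  out <- filter_stacked_reads(five, bg)
  expect_equal(length(out$fragments), 2L)
  expect_equal(out$removed, 3L)

  distinct <- gr("chr1", c(1L, 100L, 200L), c(50L, 150L, 260L), strand = "+")
  out2 <- filter_stacked_reads(distinct, bg)
  expect_equal(out2$removed, 0L)

  ## opposite strands are different positions
  two_strands <- gr("chr1", rep(100L, 2), rep(400L, 2), strand = c("+", "-"))
  bg1 <- structure(list(lambda_pos = 0, n_star = 1L, p_stack = 0.001),
                   class = "poisson_background")
  out3 <- filter_stacked_reads(two_strands, bg1)
  expect_equal(length(out3$fragments), 2L)  # n_star = 1 still keeps the first
})

test_that("Poisson-null data loses under 0.5% of reads to the stack filter", {
  set.seed(404)
  counts <- stats::rpois(20000L, 0.1)
  pos <- rep(seq_len(20000L) * 10L, counts)
  fr <- gr("chr1", pos, pos + 99L, strand = "+")
  bg <- estimate_stack_threshold(fr)
  out <- filter_stacked_reads(fr, bg)
  expect_lt(out$removed / length(fr), 0.005)
})

test_that("a coverage spike yields exactly one ROI containing it", {
  ## identical base coverage in both pools, plus a 10x spike in pool 1:
  ## only the spike windows can differ between directions
  g <- simulate_genome(1L, 5e4, 0.5, site_density = 0, seed = 77)
  set.seed(101)
  pool1 <- uniform_fragments(g, 3000L)
  pool2 <- pool1
  spike <- gr("chr1", rep(20000L, 250) + sample(0:50, 250, replace = TRUE),
              rep(20300L, 250))
  pool1b <- c(pool1, spike)
  rois <- call_rois(pool1b, pool2, g)
  expect_equal(length(rois), 1L)
  expect_lte(GenomicRanges::start(rois), 20000L)
  expect_gte(GenomicRanges::end(rois), 20300L)
  expect_lte(rois$q, 0.1)

  ## symmetric under label swap
  rois_swap <- call_rois(pool2, pool1b, g)
  expect_equal(GenomicRanges::start(rois_swap), GenomicRanges::start(rois))
  expect_equal(GenomicRanges::end(rois_swap), GenomicRanges::end(rois))
  expect_equal(rois_swap$p, rois$p)

  ## ROIs are disjoint and merging is idempotent
  expect_true(all(GenomicRanges::countOverlaps(rois, rois) == 1L))
  expect_equal(length(GenomicRanges::reduce(rois)), length(rois))
})

test_that("identical pools yield no ROI", {
  g <- simulate_genome(1L, 5e4, 0.5, site_density = 0, seed = 78)
  set.seed(11)
  pool <- uniform_fragments(g, 2000L)
  rois <- call_rois(pool, pool, g)
  expect_equal(length(rois), 0L)
})

test_that("count matrix counts >= 1 bp overlaps with half-open boundaries", {
  rois <- gr("chr1", c(151L, 201L), c(250L, 300L))
  ## 0-based [100,200) -> 1-based 101..200: overlaps ROI 151..250 only
  frag <- gr("chr1", 101L, 200L)
  cm <- count_matrix(rois[1], list(s1 = frag))
  expect_equal(unname(cm$counts[1, 1]), 1L)
  cm2 <- count_matrix(rois[2], list(s1 = frag))
  expect_equal(unname(cm2$counts[1, 1]), 0L)
})

test_that("count matrix equals a quadratic interval-intersection oracle", {
  g <- simulate_genome(1L, 1e5, 0.5, site_density = 0, seed = 55)
  set.seed(56)
  frags <- uniform_fragments(g, 1000L, width = 250L)
  starts <- seq(1000L, 99000L, by = 2000L)[1:50]
  rois <- gr("chr1", starts, starts + 400L)
  cm <- count_matrix(rois, list(s1 = frags))
  oracle <- vapply(seq_along(rois), function(i) {
    sum(GenomicRanges::start(frags) <= GenomicRanges::end(rois)[i] &
          GenomicRanges::end(frags) >= GenomicRanges::start(rois)[i])
  }, numeric(1))
  expect_equal(unname(cm$counts[, 1]), as.integer(oracle))
  expect_equal(unname(cm$library_sizes), 1000L)
  expect_error(count_matrix(gr("chr1", c(1L, 50L), c(100L, 140L)),
                            list(s1 = frags)), "non-overlapping")
})
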