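test_that("size factors follow median-of-ratios with geometric-mean scaling", {
  set.seed(14)
  base <- matrix(stats::rpois(400, 20), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  same <- base
  same[, 2] <- same[, 1]
  expect_equal(unname(size_factors(make_cm(same))), c(1, 1))

  doubled <- base
  doubled[, 2] <- doubled[, 1] * 2L
  sf <- size_factors(make_cm(doubled))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  perm <- doubled[sample(nrow(doubled)), ]
  expect_equal(size_factors(make_cm(perm)), sf)
  expect_error(size_factors(make_cm(matrix(0, 5, 2))), "all-zero")
})

test_that("dispersion estimation recovers known regimes", {
  ct <- contrast_spec("E/B", paste0("E", 1:9), paste0("B", 1:9))
  smp <- c(ct$group1, ct$group2)

  set.seed(21)
  pois <- matrix(stats::rpois(200 * 18, 50), ncol = 18,
                 dimnames = list(NULL, smp))
  dp <- estimate_dispersion(make_cm(pois), ct)
  expect_lt(dp$phi_common, 0.02)

  nb <- matrix(stats::rnbinom(200 * 18, mu = 50, size = 1 / 0.2), ncol = 18,
               dimnames = list(NULL, smp))
  dn <- estimate_dispersion(make_cm(nb), ct)
  expect_gt(dn$phi_common, 0.1)
  expect_lt(dn$phi_common, 0.3)

  const <- matrix(7L, nrow = 50, ncol = 18, dimnames = list(NULL, smp))
  dc <- estimate_dispersion(make_cm(const), ct)
  expect_true(all(dc$phi_raw == 0))

  expect_error(estimate_dispersion(
    make_cm(pois[, 1:3], samples = c("E1", "E2", "B1")),
    contrast_spec("x", c("E1", "E2"), "B1")), "2 samples")
})

test_that("exact test reproduces hand-enumerated and symmetric cases", {
  ## phi = 0, 1 vs 1, counts (0, 10): both tails of Binomial(10, 1/2)
  expect_equal(nb_exact_test(0L, 10L, 1L, 1L, phi = 0), 2 / 1024,
               tolerance = 1e-14)
  ## the most probable split has p = 1
  expect_equal(nb_exact_test(5L, 5L, 1L, 1L, phi = 0), 1)
  expect_equal(nb_exact_test(12L, 12L, 3L, 3L, phi = 0.3), 1)
  ## symmetry under group swap
  for (phi in c(0, 0.15)) {
    expect_equal(nb_exact_test(3L, 14L, 2L, 2L, phi = phi),
                 nb_exact_test(14L, 3L, 2L, 2L, phi = phi))
  }
  ## zero total is untestable
  expect_equal(nb_exact_test(0L, 0L, 2L, 2L, phi = 0.1), 1)
})

test_that("exact test matches the dnbinom-product oracle over a grid", {
  set.seed(33)
  cases <- expand.grid(total = c(1L, 5L, 17L, 30L),
                       n1 = 1:4, n2 = 1:4,
                       phi = c(0, 0.1, 0.5, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    t1 <- sample(0:cs$total, 1L)
    p_pkg <- nb_exact_test(t1, cs$total - t1, cs$n1, cs$n2, phi = cs$phi)
    p_orc <- oracle_nb_exact(t1, cs$total - t1, cs$n1, cs$n2, cs$phi,
                             mu = 3.3)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12,
                 info = sprintf("total=%d t1=%d n1=%d n2=%d phi=%g",
                                cs$total, t1, cs$n1, cs$n2, cs$phi))
  }
})

test_that("vanishing dispersion converges to the conditional binomial", {
  for (total in c(6L, 21L, 30L)) {
    for (t1 in c(0L, 2L, total %/% 2L)) {
      expect_equal(nb_exact_test(t1, total - t1, 3L, 2L, phi = 1e-13),
                   oracle_nb_exact(t1, total - t1, 3L, 2L, phi = 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("unequal size factors tilt the conditional distribution", {
  ## one sample per group, factor ratio 3: under the null t1 ~ Bin(T, 3/4)
  p <- nb_exact_test(9L, 3L, 1L, 1L, phi = 0, s1 = 3, s2 = 1)
  w <- stats::dbinom(0:12, 12, 0.75)
  expect_equal(p, sum(w[w <= w[10] * (1 + 1e-9)]), tolerance = 1e-12)
})

test_that("normal approximation agrees with enumeration at the switch point", {
  for (phi in c(0, 0.05)) {
    t1 <- 2550L; t2 <- 2450L
    exact <- nb_exact_test(t1, t2, 9L, 9L, phi = phi, max_enum = 10000L)
    approx <- nb_exact_test(t1, t2, 9L, 9L, phi = phi, max_enum = 100L)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("BH adjustment reproduces the step-up worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  expect_equal(bh_adjust(p)[order(p)], sort(bh_adjust(p)))
  shuffle <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[shuffle]), bh_adjust(p)[shuffle])
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("minRowSum gates ROIs before testing and BH", {
  counts <- rbind(c(1L, 2L, 3L, 4L),   # row sum 10: retained
                  c(1L, 2L, 3L, 3L),   # row sum 9: dropped
                  c(20L, 22L, 1L, 2L)) # clearly differential
  cm <- make_cm(counts, samples = c("E1", "E2", "B1", "B2"))
  ct <- contrast_spec("E/B", c("E1", "E2"), c("B1", "B2"))
  res <- test_dmrs(cm, ct, dispersion = 0)
  expect_equal(nrow(res), 2L)
  expect_false("ROI_000002" %in% res$roi)
  expect_equal(res$hyper[res$roi == "ROI_000003"], "E>B")
  expect_true(res$exploratory[res$roi == "ROI_000003"])
})

test_that("DMR testing is symmetric under group swap", {
  set.seed(61)
  counts <- matrix(stats::rpois(40 * 6, 30), ncol = 6,
                   dimnames = list(NULL, c(paste0("E", 1:3), paste0("B", 1:3))))
  counts[5, 1:3] <- counts[5, 1:3] + 60L
  cm <- make_cm(counts)
  fwd <- test_dmrs(cm, contrast_spec("E/B", paste0("E", 1:3), paste0("B", 1:3)),
                   dispersion = 0.05)
  rev <- test_dmrs(cm, contrast_spec("B/E", paste0("B", 1:3), paste0("E", 1:3)),
                   dispersion = 0.05)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$hyper, rev$hyper)  # direction label names the same group
})

test_that("the two significance tiers are computed independently", {
  set.seed(62)
  counts <- matrix(stats::rpois(30 * 4, 15), ncol = 4,
                   dimnames = list(NULL, c("E1", "E2", "B1", "B2")))
  cm <- make_cm(counts)
  ct <- contrast_spec("E/B", c("E1", "E2"), c("B1", "B2"))
  res <- test_dmrs(cm, ct, dispersion = 0)
  expect_equal(res$exploratory, res$p <= 0.05)
  expect_equal(res$top, res$q <= 0.6)
})
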