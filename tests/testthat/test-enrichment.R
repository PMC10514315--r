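test_that("BH adjustment matches hand-derived step-up values", {
  # thresholds i/m * 0.05 = 0.0125, 0.025, 0.0375, 0.05: all four significant
  q <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(q <= 0.05))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "domain")
  expect_error(bh_adjust(c(0.5, -0.1)), "domain")

  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("UV-enrichment calls behave at the limits", {
  set.seed(42)
  n_null <- 60
  ncl <- matrix(rlnorm(3 * n_null, 12, 0.2), n_null)
  cl <- matrix(rlnorm(3 * n_null, 12, 0.2), n_null)
  # one strongly enriched protein with tiny jitter
  cl <- rbind(1e6 * 2^1 * (1 + c(1e-6, -1e-6, 0)), cl)
  ncl <- rbind(rep(1e6, 3) * (1 + c(1e-6, 0, -1e-6)), ncl)
  x <- make_silac_table(cl, ncl)
  res <- test_uv_enrichment(x)
  expect_true(res$enriched[1])
  expect_lt(res$p_value[1], 1e-6)
  expect_equal(res$mean_log2_ratio[1], 1, tolerance = 1e-5)
  # q-values never undercut p-values and respect the BH ordering
  tested <- !res$pseudo
  expect_true(all(res$q_value[tested] >= res$p_value[tested]))

  # symmetric ratios around zero: one-sample form gives p = 0.5 exactly
  y <- make_silac_table(rbind(1e6 * 2^c(-1, 0, 1)), rbind(rep(1e6, 3)))
  r <- test_uv_enrichment(y, form = "ratio")
  expect_equal(r$t_stat[1], 0)
  expect_equal(r$p_value[1], 0.5)

  # CL-only proteins get the pseudo-values and are scored enriched
  z <- replace_ncl_zeros(make_silac_table(
    rbind(c(5, 5, 5), c(7, 7, 7)), rbind(c(1, 1, 1), c(0, 0, 0))))
  rz <- test_uv_enrichment(z)
  expect_true(rz$pseudo[2])
  expect_true(rz$enriched[2])
  expect_equal(rz$mean_log2_ratio[2], 10)
  expect_equal(rz$neg_log10_p[2], 10)

  # zero within-protein variance: sign of the mean decides
  w <- make_silac_table(rbind(c(4, 4, 4), c(1, 1, 1)),
                        rbind(c(1, 1, 1), c(4, 4, 4)))
  rw <- test_uv_enrichment(w)
  expect_true(all(rw$zero_variance))
  expect_equal(rw$p_value, c(0, 1))

  # fewer than two CL replicates is a statistics error
  one_rep <- make_silac_table(matrix(1:3, 3, 1), matrix(1, 3, 1))
  expect_error(test_uv_enrichment(one_rep), "2 CL replicates")
})

test_that("all three test forms agree on direction and differ as expected", {
  set.seed(43)
  n <- 2000
  cl <- matrix(rlnorm(3 * n, 12, 0.28), n)
  ncl <- matrix(rlnorm(3 * n, 12, 0.28), n)
  x <- make_silac_table(cl, ncl)
  r_w <- test_uv_enrichment(x, form = "welch")
  p_w <- r_w$p_value
  p_r <- test_uv_enrichment(x, form = "ratio")$p_value
  p_p <- test_uv_enrichment(x, form = "pooled")$p_value
  # under a null, the shared-nCL-mean ratio form is anti-conservative
  # relative to both two-sample forms
  expect_gt(mean(p_r <= 0.05), mean(p_w <= 0.05))
  # pooled and Welch share the same statistic at equal n; for enrichment
  # candidates (t >= 0) Welch's smaller df makes it the more conservative
  pos <- r_w$t_stat >= 0
  expect_true(all(p_w[pos] >= p_p[pos] - 1e-12))
})

test_that("detectable changes in O follow the t-quantile formula", {
  # n = 3, sd = 0.10: qt(0.95, 2) * 0.10 / sqrt(3)
  v <- c(0, 0.1, 0.2)  # sd is exactly 0.1
  expect_equal(detectable_delta_O(v), 0.1685854, tolerance = 1e-6)
  expect_equal(detectable_delta_O(rep(1, 3)), 0)
  expect_equal(detectable_delta_O(v * 2), 2 * detectable_delta_O(v))
  expect_error(detectable_delta_O(1), "2 replicates")
})

test_that("detectable changes in S invert exactly and respect feasibility", {
  # pure signal: the detectable change in S equals the change in O
  expect_equal(detectable_delta_S(0.25, S = 10, N = 0), 0.25)

  # worked value: d = 0.169 at S/O = 0.5
  expect_equal(detectable_delta_S(0.169, S = 5, N = 5),
               log2(2^0.169 - 0.5) + 1, tolerance = 1e-12)
  # independent numerical oracle: solve 2^d * O = S * 2^x + N for x
  f <- function(x) 5 * 2^x + 5 - 2^0.169 * 10
  x_num <- uniroot(f, c(0, 2), tol = 1e-12)$root
  expect_equal(detectable_delta_S(0.169, 5, 5), x_num, tolerance = 1e-9)

  # round trip: applying the detectable S fold-change moves log2(O) by d
  set.seed(44)
  for (i in 1:25) {
    S <- runif(1, 0.1, 10); N <- runif(1, 0, 10); d <- runif(1, 0.05, 1)
    if (2^d - N / (S + N) <= 0) next
    ds <- detectable_delta_S(d, S, N)
    expect_equal(log2((S * 2^ds + N) / (S + N)), d, tolerance = 1e-9)
  }

  # strictly decreasing in S/O at fixed d
  dS <- vapply(seq(0.1, 0.9, by = 0.1),
               function(so) detectable_delta_S(0.169, so, 1 - so), numeric(1))
  expect_true(all(diff(dS) < 0))

  # a large free fraction still leaves any increase attainable (2^d > N/O)
  expect_equal(detectable_delta_S(0.1, S = 0.01, N = 0.99),
               log2(2^0.1 - 0.99) - log2(0.01), tolerance = 1e-12)
  expect_equal(detectable_delta_S(0.1, S = 0.01, N = 0.99), 3.03,
               tolerance = 1e-2)
  # but a decrease below log2(N/O) is unattainable: removing all S leaves N
  expect_warning(out <- detectable_delta_S(-0.1, S = 0.001, N = 0.999),
                 "unattainable")
  expect_identical(out, -Inf)
  expect_error(detectable_delta_S(0.1, S = 0, N = 1), "positive")
})

test_that("per-protein sensitivity estimates track S/N", {
  set.seed(45)
  s2n <- c(9, 3, 1, 0.25)
  p <- profiles_from_s2n(s2n)
  x <- make_silac_table(
    matrix(rep((2 * s2n + 1) * 1e6, 3), ncol = 3) * rlnorm(12, 0, 0.05),
    matrix(rep(1e6, 12), ncol = 3) * rlnorm(12, 0, 0.05))
  sens <- estimate_sensitivity(x, p)
  expect_equal(sens$n_reps, rep(3, 4))
  expect_equal(sens$t_crit, rep(qt(0.95, 2), 4))
  expect_true(all(sens$detectable_dlog2_S >= sens$detectable_dlog2_O - 1e-12,
                  na.rm = TRUE))
})
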