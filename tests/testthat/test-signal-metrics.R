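test_that("signal decomposition reproduces the analytic identities", {
  x <- make_silac_table(matrix(rep(c(3, 7, 5, 0.5), 3), ncol = 3),
                        matrix(rep(c(1, 1, 5, 1), 3), ncol = 3))
  p <- compute_signal_profiles(x)

  # CL/nCL = 3  =>  S/N = 1, 50% RNA-bound
  expect_equal(p$cl_ncl[1], 3)
  expect_equal(p$S[1] / p$N[1], 1)
  expect_equal(p$log2_sn[1], 0)
  expect_equal(p$pct_bound[1], 50)

  # S/N = 3  =>  75% RNA-bound
  expect_equal(p$S[2], 6); expect_equal(p$N[2], 2)
  expect_equal(p$log2_sn[2], log2(3))
  expect_equal(p$pct_bound[2], 75)

  # S = 0: all abundance is background (N = B)
  expect_equal(p$S[3], 0)
  expect_equal(p$pct_bound[3], 0)
  expect_true(is.na(p$log2_sn[3]))
  expect_equal(p$pct_tp_s[3], 0)
  expect_equal(p$pct_tp_n[3], p$pct_tp[3])

  # S < 0 is clamped for percentage quantities
  expect_lt(p$S[4], 0)
  expect_equal(p$pct_bound[4], 0)
  expect_equal(p$pct_tp_s[4], 0)
})

test_that("conservation and abundance-partition invariants hold", {
  set.seed(21)
  x <- make_silac_table(matrix(rlnorm(300, 12), 100), matrix(rlnorm(300, 11), 100))
  p <- compute_signal_profiles(x)
  expect_equal(p$O, p$spi_cl + p$spi_ncl)
  expect_equal(p$S + p$N, p$O)
  expect_equal(sum(p$pct_tp), 100, tolerance = 1e-9)
  expect_equal(p$pct_tp_s + p$pct_tp_n, p$pct_tp, tolerance = 1e-9)
  expect_equal(sum(p$pct_tp_s + p$pct_tp_n), 100, tolerance = 1e-9)
  expect_true(all(p$pct_bound >= 0 & p$pct_bound <= 100))
})

test_that("percent bound is the stated function of CL/nCL and monotone in it", {
  set.seed(22)
  ratios <- sort(runif(50, 1, 50))
  ncl <- rlnorm(50, 10)
  x <- make_silac_table(matrix(rep(ratios * ncl, 3), ncol = 3),
                        matrix(rep(ncl, 3), ncol = 3))
  p <- compute_signal_profiles(x)
  expect_equal(p$pct_bound, 100 * (ratios - 1) / (ratios + 1), tolerance = 1e-9)
  expect_true(all(diff(p$pct_bound) > 0))
})

test_that("naive noise partitioning always overestimates the bound fraction", {
  set.seed(23)
  ncl <- rlnorm(200, 10)
  cl <- ncl * runif(200, 1.01, 30)  # S > 0 everywhere
  x <- make_silac_table(matrix(rep(cl, 3), ncol = 3),
                        matrix(rep(ncl, 3), ncol = 3))
  eq <- compute_signal_profiles(x, "equal_noise")
  nv <- compute_signal_profiles(x, "naive")
  expect_true(all(nv$pct_bound > eq$pct_bound))
})

test_that("RNase-dependent fold-change is a guarded log2 ratio", {
  expect_equal(rnase_fold_change(4, 1), 2)
  expect_equal(rnase_fold_change(7.3, 7.3), 0)
  expect_equal(rnase_fold_change(1, 4), -2)
  expect_error(rnase_fold_change(0, 1), "positive")
  expect_error(rnase_fold_change(1, -2), "positive")
})

test_that("RCS scores follow the product formula and the two-tier ranking", {
  p <- profiles_from_s2n(c(4, 1, 0.25))
  # force known %TP by overriding (hand-built profile rows)
  p$pct_tp <- c(10, 5, 85)
  p <- compute_rcs(p)
  expect_equal(p$rcs[1], log2(4) * log10(10))
  expect_equal(p$rcs[2], 0)          # log2(S/N) = 0 regardless of %TP

  # S/N above 1 with tiny abundance still outranks S/N below 1 with high abundance
  q <- profiles_from_s2n(c(8, 0.5))
  q$pct_tp <- c(0.1, 10)
  q <- compute_rcs(q)
  expect_lt(q$rcs_rank[1], q$rcs_rank[2])

  # ranks are a permutation and order-independent
  set.seed(31)
  r <- profiles_from_s2n(runif(40, 0.1, 20))
  r <- compute_rcs(r)
  expect_permutation(r$rcs_rank, 40)
  shuffled <- compute_rcs(r[sample(nrow(r)), ])
  expect_equal(shuffled$rcs_rank[match(r$protein_id, shuffled$protein_id)],
               r$rcs_rank)

  # CL-only proteins head the ranking, ordered by abundance
  cl <- matrix(5, 3, 3); ncl <- rbind(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  x <- replace_ncl_zeros(make_silac_table(cl * c(1, 1, 2), ncl))
  pr <- compute_rcs(compute_signal_profiles(x))
  expect_true(all(pr$rcs_rank[pr$cl_only] < pr$rcs_rank[!pr$cl_only]))
  expect_lt(pr$rcs_rank[3], pr$rcs_rank[2])  # higher %TP first among CL-only
})

test_that("category summaries partition the RNA-bound signal", {
  p <- profiles_from_s2n(c(2, 2, 0, 1))
  ids <- p$protein_id

  one <- summarize_categories(p, list(all = ids))
  expect_equal(one$share_of_signal[one$category == "all"], 100)

  # two proteins with equal S split across two categories -> 50/50
  p2 <- profiles_from_s2n(c(3, 3))
  two <- summarize_categories(p2, list(a = p2$protein_id[1], b = p2$protein_id[2]))
  expect_equal(two$share_of_signal[two$category %in% c("a", "b")], c(50, 50))

  # a category of S = 0 proteins contributes noise but no signal
  z <- summarize_categories(p, list(zero = ids[3], rest = ids[c(1, 2, 4)]))
  zrow <- z[z$category == "zero", ]
  expect_equal(zrow$share_of_signal, 0)
  expect_gt(zrow$sum_pct_tp_n, 0)
  expect_equal(sum(z$share_of_signal), 100, tolerance = 1e-9)

  # overlap is an error in partition mode, allowed otherwise
  expect_error(summarize_categories(p, list(a = ids[1:2], b = ids[2:3])),
               "overlap")
  ov <- summarize_categories(p, list(a = ids[1:2], b = ids[2:3]),
                             partition = FALSE)
  expect_equal(nrow(ov), 2)

  # uncovered proteins fall into the complement category
  cmp <- summarize_categories(p, list(a = ids[1]))
  expect_true("(other)" %in% cmp$category)
  expect_equal(sum(cmp$n_proteins), nrow(p))
})

test_that("cumulative curves are monotone empirical distributions", {
  p <- profiles_from_s2n(c(1, 2, 4, 8, 0.5))
  ann <- annotation_set("RBP", p$protein_id[1:3])
  cc <- cumulative_curves(p, "log2_sn", ann)
  for (s in unique(cc$stratum)) {
    q <- cc$quantile[cc$stratum == s]
    v <- cc$value[cc$stratum == s]
    expect_true(all(diff(q) >= 0))
    expect_true(all(diff(v) >= 0))
    expect_equal(max(q), 1)
  }
  # three distinct values -> quantiles 1/3, 2/3, 1
  rbp <- cc[cc$stratum == "RBP", ]
  expect_equal(rbp$quantile, c(1, 2, 3) / 3)

  # duplicated values appear as repeated steps of 1/n
  pd <- profiles_from_s2n(c(2, 2, 4))
  ccd <- suppressWarnings(
    cumulative_curves(pd, "log2_sn", annotation_set("RBP", pd$protein_id)))
  d <- ccd[ccd$stratum == "RBP", ]
  expect_equal(sum(d$value == 1), 2)

  # an empty stratum is skipped with a warning
  expect_warning(
    cumulative_curves(pd, "log2_sn", annotation_set("RBP", pd$protein_id)),
    "non-RBP"
  )
})
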