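test_that("rank bins are contiguous and summarize the ranking", {
  set.seed(61)
  sim <- generate_silac(generator_config(n_proteins = 260, seed = 12,
                                         detection_floor = 0,
                                         n_contaminants = 0))
  x <- preprocess_silac(sim$table)
  p <- compute_rcs(compute_signal_profiles(x))
  ann <- annotation_set("GO:RBP",
                        sim$truth$protein_id[sim$truth$is_rbp])
  sens <- estimate_sensitivity(x, p)
  bins <- rank_bin_analysis(p, sens, ann, bin_size = 100)
  expect_equal(bins$bin_size, c(100, 100, nrow(p) - 200))
  expect_equal(sum(bins$bin_size), nrow(p))
  expect_equal(sum(bins$sum_pct_tp), 100, tolerance = 1e-9)
  # RBPs have uniformly higher S/N in the generator, so annotated counts
  # concentrate in the top bins
  expect_true(all(diff(bins$n_annotated_rbps) <= 0))

  all_ann <- annotation_set("all", p$protein_id)
  bins2 <- rank_bin_analysis(p, annotations = all_ann, bin_size = 100)
  expect_equal(bins2$n_annotated_rbps[1:2], c(100L, 100L))

  expect_error(rank_bin_analysis(p, bin_size = 0), "bin_size")
  expect_error(rank_bin_analysis(compute_signal_profiles(x)), "compute_rcs")
})

test_that("benchmark summaries rank methods by specificity", {
  ann <- NULL
  make_method <- function(background, seed) {
    cfg <- generator_config(n_proteins = 400, seed = seed,
                            background_free_protein = background,
                            detection_floor = 0, n_contaminants = 0)
    sim <- generate_silac(cfg)
    x <- preprocess_silac(sim$table)
    list(profiles = compute_rcs(compute_signal_profiles(x)),
         enrichment = test_uv_enrichment(x),
         truth = sim$truth)
  }
  hi <- make_method(background = 0.02, seed = 13)  # high-specificity capture
  lo <- make_method(background = 1.0, seed = 13)   # noisy capture
  ann <- annotation_set("GO:RBP", hi$truth$protein_id[hi$truth$is_rbp])

  bench <- benchmark_summary(
    list(clean = hi$profiles, noisy = lo$profiles), ann,
    list(clean = hi$enrichment, noisy = lo$enrichment))
  s <- bench$summary
  expect_equal(nrow(s), 2)
  expect_gt(s$pct_tp_s_total[s$method == "clean"],
            s$pct_tp_s_total[s$method == "noisy"])
  expect_equal(nrow(bench$overlap), 1)

  # a single method: one row, no overlap section
  solo <- benchmark_summary(list(only = hi$profiles), ann,
                            list(only = hi$enrichment))
  expect_equal(nrow(solo$summary), 1)
  expect_equal(nrow(solo$overlap), 0)

  # identical methods overlap completely
  twin <- benchmark_summary(list(a = hi$profiles, b = hi$profiles), ann,
                            list(a = hi$enrichment, b = hi$enrichment))
  expect_equal(twin$overlap$n_shared_enriched,
               sum(hi$enrichment$enriched))
})

test_that("pseudo-replicates and sample aggregation follow the averaging rules", {
  x <- make_silac_table(rbind(c(4, 0), c(2, 6)), rbind(c(1, 3), c(0, 0)))
  aug <- add_pseudo_replicate(x)
  expect_equal(unname(spi_matrix(aug, "CL")[, 3]), c(4, 4))  # non-zero mean
  expect_equal(unname(spi_matrix(aug, "nCL")[, 3]), c(2, NA_real_))

  y <- make_comparative_table(rbind(c(10, 20), c(30, 0)),
                              rbind(c(1, 2), c(3, 4)), groups = c("A", "B"))
  agg <- aggregate_samples(y)
  expect_equal(dim(agg$intensities), c(2L, 2L))
  expect_equal(table_groups(agg), c("A", "B"))
})

test_that("run_pipeline wires the modes together and validates config", {
  out1 <- withr::local_tempdir()
  sim_res <- run_pipeline(list(mode = "simulate", out_dir = out1,
                               generator = list(n_proteins = 250)), seed = 14)
  expect_true(file.exists(file.path(out1, "silac_table.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  # simulate -> silac on the emitted file completes and recovers parameters
  out2 <- withr::local_tempdir()
  truth <- readr::read_tsv(file.path(out1, "truth.tsv"), show_col_types = FALSE)
  res <- run_pipeline(list(
    mode = "silac", out_dir = out2, dialect = "generic",
    input = file.path(out1, "silac_table.tsv"),
    annotations = list("GO:RBP" = truth$protein_id[truth$is_rbp])
  ), seed = 14)
  expect_true(file.exists(file.path(out2, "signal_profiles.tsv")))
  expect_true(file.exists(file.path(out2, "uv_enrichment.tsv")))
  expect_true(file.exists(file.path(out2, "rank_bins.tsv")))
  expect_s3_class(res$profiles, "signal_profiles")
  est <- res$profiles$pct_bound[match(truth$protein_id,
                                      res$profiles$protein_id)]
  err <- abs(est - 100 * truth$true_bound_fraction)
  expect_lte(median(err[truth$true_bound_fraction >= 0.5], na.rm = TRUE), 10)

  # rerunning the same configuration reproduces outputs byte-identically
  out3 <- withr::local_tempdir()
  run_pipeline(list(mode = "silac", out_dir = out3, dialect = "generic",
                    input = file.path(out1, "silac_table.tsv"),
                    annotations = list("GO:RBP" = truth$protein_id[truth$is_rbp])),
               seed = 14)
  for (f in c("signal_profiles.tsv", "uv_enrichment.tsv")) {
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out3, f)))
  }

  # comparative mode end to end on simulated tables
  out4 <- withr::local_tempdir()
  cres <- suppressWarnings(run_pipeline(list(
    mode = "comparative", out_dir = out4,
    generator = list(n_proteins = 250, replicate_cv = 0.05),
    shifted_fraction = 0.1, shift_log2 = 2
  ), seed = 15))
  expect_true(file.exists(file.path(out4, "occupancy_clrnp.tsv")))
  expect_true(all(c("purple", "gold", "teal", "none") %in%
                    names(cres$hit_counts)))

  expect_error(run_pipeline(list(out_dir = "x")), "mode")
  expect_error(run_pipeline(list(mode = "silac")), "out_dir")
  expect_error(run_pipeline(list(mode = "benchmark", out_dir = out1,
                                 annotations = list(a = "P1"))),
               "methods")
})
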