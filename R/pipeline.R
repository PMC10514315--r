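#' Run a configured analysis pipeline
#'
#' Orchestrates the package's stages from a YAML (or list) configuration and
#' writes all outputs as TSV plus a machine-readable JSON run manifest
#' (inputs, seed, thresholds, stage log, package version) sufficient to re-run
#' the analysis identically.
#'
#' Modes:
#' * `simulate`: draw a synthetic SILAC experiment and write the
#'   generic-dialect table plus the truth table.
#' * `silac`: read (or take) a CL/nCL table, preprocess, compute signal
#'   profiles, RCS ranks, UV-enrichment* calls, sensitivity estimates and,
#'   given annotations, category summaries and rank bins.
#' * `comparative`: read input and clRNP two-condition tables, preprocess,
#'   run both occupancy-test BH passes gated by a companion SILAC profile
#'   table, and join the fractions.
#' * `benchmark`: run the `silac` stages for several methods and summarize.
#'
#' Config keys (YAML): `mode`; `seed`; `out_dir`; per mode: `input`
#' (paths or omitted when simulating), `dialect`, `channel_map`,
#' `annotations` (named paths), `alpha_fdr`, `sn_threshold`, `test_form`,
#' `generator` (arguments of [generator_config()]), `shifted_fraction`,
#' `shift_log2`, `bin_size`, `contaminant_patterns`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @param seed Integer seed; overrides the config's `seed`.
#' @return Invisibly, a named list of result objects (also written to
#'   `out_dir`). Errors in any stage propagate with the stage name.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$mode)) stop("validation error: config key \"mode\" is missing")
  mode <- match.arg(cfg$mode, c("simulate", "silac", "comparative", "benchmark"))
  out_dir <- out_dir %||% cfg$out_dir %||% stop(
    "validation error: config key \"out_dir\" is missing")
  seed <- seed %||% cfg$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- switch(mode,
    simulate = stage("simulate", run_simulate(cfg, seed, out_dir)),
    silac = stage("silac", run_silac(cfg, seed, out_dir)),
    comparative = stage("comparative", run_comparative(cfg, seed, out_dir)),
    benchmark = stage("benchmark", run_benchmark(cfg, seed, out_dir))
  )
  manifest <- list(
    package = "rbpsignal",
    version = as.character(utils::packageVersion("rbpsignal")),
    mode = mode, seed = seed,
    config = cfg,
    outputs = names(results$files),
    stage_log = results$log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(results)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage \"", name, "\" failed: ", conditionMessage(e), call. = FALSE)
  })
}

cfg_generator <- function(cfg, seed) {
  args <- cfg$generator %||% list()
  args$seed <- seed
  do.call(generator_config, args)
}

run_simulate <- function(cfg, seed, out_dir) {
  sim <- generate_silac(cfg_generator(cfg, seed))
  files <- list(
    silac_table = file.path(out_dir, "silac_table.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_table(as_generic_frame(sim$table), files$silac_table)
  write_table(sim$truth, files$truth)
  list(table = sim$table, truth = sim$truth, files = files,
       log = list("simulate: wrote generic-dialect SILAC table and truth"))
}

load_table <- function(cfg, entry) {
  if (inherits(entry, "intensity_table")) return(entry)
  read_protein_groups(entry, dialect = cfg$dialect %||% "generic",
                      channel_map = cfg$channel_map)
}

load_annotations <- function(cfg) {
  if (is.null(cfg$annotations)) return(NULL)
  sets <- lapply(names(cfg$annotations), function(nm) {
    a <- cfg$annotations[[nm]]
    if (inherits(a, "annotation_set")) a
    else if (is.character(a) && length(a) == 1 && file.exists(a)) {
      suppressMessages(read_annotation_set(a, nm))
    } else annotation_set(nm, a)
  })
  names(sets) <- names(cfg$annotations)
  sets
}

run_silac <- function(cfg, seed, out_dir, prefix = "") {
  log <- list()
  if (is.null(cfg$input)) {
    sim <- generate_silac(cfg_generator(cfg, seed))
    raw <- sim$table
    log <- c(log, "silac: simulated input table")
  } else {
    raw <- load_table(cfg, cfg$input)
    log <- c(log, sprintf("silac: read %d proteins", nrow(raw$intensities)))
  }
  x <- preprocess_silac(raw, patterns = cfg$contaminant_patterns %||%
                          contaminant_patterns())
  rep <- preprocess_report(x)
  log <- c(log, sprintf(
    "preprocess: %d in, %d contaminants, %d detection-filtered, %d peptide-filtered, %d retained (%d CL-only)",
    rep$n_input, rep$n_contaminants_removed, rep$n_filtered_detection,
    rep$n_filtered_peptides, rep$n_retained, rep$n_cl_only))

  profiles <- compute_rcs(compute_signal_profiles(x))
  enrichment <- test_uv_enrichment(x, alpha_fdr = cfg$alpha_fdr %||% 0.05,
                                   form = cfg$test_form %||% "welch")
  sensitivity <- estimate_sensitivity(x, profiles)
  log <- c(log, sprintf("enrichment: %d of %d UV-enriched*",
                        sum(enrichment$enriched), nrow(enrichment)))

  annotations <- load_annotations(cfg)
  categories <- NULL; bins <- NULL
  if (!is.null(annotations)) {
    categories <- summarize_categories(profiles, annotations[1],
                                       partition = TRUE)
    bins <- rank_bin_analysis(profiles, sensitivity, annotations[[1]],
                              bin_size = cfg$bin_size %||% 100)
  }
  files <- list()
  wt <- function(obj, name) {
    if (is.null(obj)) return()
    path <- file.path(out_dir, paste0(prefix, name, ".tsv"))
    write_table(obj, path)
    files[[paste0(prefix, name)]] <<- path
  }
  wt(profiles, "signal_profiles")
  wt(enrichment, "uv_enrichment")
  wt(sensitivity, "sensitivity")
  wt(categories, "category_summary")
  wt(bins, "rank_bins")
  list(table = x, profiles = profiles, enrichment = enrichment,
       sensitivity = sensitivity, categories = categories, bins = bins,
       files = files, log = log)
}

run_comparative <- function(cfg, seed, out_dir) {
  log <- list()
  if (is.null(cfg$input)) {
    sim <- generate_comparative(cfg_generator(cfg, seed),
                                shifted_fraction = cfg$shifted_fraction %||% 0.05,
                                shift_log2 = cfg$shift_log2 %||% 1)
    input_raw <- sim$input; clrnp_raw <- sim$clrnp; silac_raw <- sim$silac
    log <- c(log, "comparative: simulated input/clRNP/companion-SILAC tables")
  } else {
    input_raw <- load_table(cfg, cfg$input$input)
    clrnp_raw <- load_table(cfg, cfg$input$clrnp)
    silac_raw <- load_table(cfg, cfg$input$silac)
  }
  input <- preprocess_comparative(input_raw)
  clrnp <- preprocess_comparative(clrnp_raw)
  silac <- preprocess_silac(silac_raw)
  sn_profiles <- compute_signal_profiles(silac)

  alpha <- cfg$alpha_fdr %||% 0.05
  thr <- cfg$sn_threshold %||% 3
  res_in <- test_occupancy_change(input, "input", sn_profiles, thr, alpha)
  res_cl <- test_occupancy_change(clrnp, "clRNP", sn_profiles, thr, alpha)
  joined <- compare_fractions(res_in, res_cl)
  counts <- table(factor(res_cl$hit_class,
                         levels = c("purple", "gold", "teal", "none")))
  log <- c(log, sprintf(
    "occupancy (clRNP): %d purple, %d gold, %d teal hits of %d tested",
    counts["purple"], counts["gold"], counts["teal"], nrow(res_cl)))

  files <- list(
    occupancy_input = file.path(out_dir, "occupancy_input.tsv"),
    occupancy_clrnp = file.path(out_dir, "occupancy_clrnp.tsv"),
    fraction_comparison = file.path(out_dir, "fraction_comparison.tsv")
  )
  write_table(res_in, files$occupancy_input)
  write_table(res_cl, files$occupancy_clrnp)
  write_table(joined, files$fraction_comparison)
  list(input = res_in, clrnp = res_cl, comparison = joined,
       hit_counts = counts, files = files, log = log)
}

run_benchmark <- function(cfg, seed, out_dir) {
  if (is.null(cfg$methods)) {
    stop("validation error: config key \"methods\" is missing")
  }
  annotations <- load_annotations(cfg)
  if (is.null(annotations)) {
    stop("validation error: benchmark mode needs an \"annotations\" entry")
  }
  per_profiles <- list(); per_enrichment <- list()
  log <- list(); files <- list()
  for (m in names(cfg$methods)) {
    sub <- utils::modifyList(cfg, cfg$methods[[m]])
    res <- run_silac(sub, seed, out_dir, prefix = paste0(m, "_"))
    per_profiles[[m]] <- res$profiles
    per_enrichment[[m]] <- res$enrichment
    files <- c(files, res$files)
    log <- c(log, paste0(m, ": ", unlist(res$log)))
  }
  bench <- benchmark_summary(per_profiles, annotations[[1]], per_enrichment)
  files$benchmark_summary <- file.path(out_dir, "benchmark_summary.tsv")
  files$benchmark_overlap <- file.path(out_dir, "benchmark_overlap.tsv")
  write_table(bench$summary, files$benchmark_summary)
  write_table(bench$overlap, files$benchmark_overlap)
  list(summary = bench$summary, overlap = bench$overlap,
       methods = per_profiles, files = files, log = log)
}
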