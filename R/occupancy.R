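#' Differential RNA-occupancy test between two conditions
#'
#' Compares log2-normalized SPI between two condition groups (e.g. DMSO vs
#' harringtonine) within one fraction (input or clRNP) using independent
#' two-tailed pooled-variance (homoscedastic) t-tests, and applies two
#' Benjamini-Hochberg passes: over all tested proteins (`q_no_limit`) and over
#' only the proteins whose signal-to-noise ratio from a companion SILAC
#' experiment exceeds `sn_threshold` (`q_sn_limit`; missing for proteins
#' outside the subset). Restricting the multiplicity to high-S/N proteins
#' limits detection of free-protein changes and increases statistical power.
#'
#' Hit classes at `alpha_fdr`: `"purple"` significant in both passes,
#' `"gold"` only with the S/N limit, `"teal"` only without, `"none"`
#' otherwise.
#'
#' @param x A comparative [intensity_table()] preprocessed with
#'   [preprocess_comparative()] (two condition groups, full detection, >= 2
#'   unique peptides).
#' @param fraction Label stored in the output (`"input"` or `"clRNP"`).
#' @param sn_profiles `signal_profiles` from a companion SILAC experiment
#'   supplying per-protein `log2_sn`; proteins absent from it are ungateable
#'   and excluded from the gated pass with a warning.
#' @param sn_threshold S/N gate (default 3, i.e. 75% RNA-bound); strict
#'   inequality `S/N > sn_threshold`.
#' @param alpha_fdr BH false-discovery rate (default 0.05).
#' @param conditions Optional length-2 character vector ordering the groups as
#'   (reference, treatment); defaults to the table's group order. The reported
#'   `log2_fc` is treatment minus reference.
#' @return A tibble with `protein_id`, `fraction`, `log2_fc`, `t_stat`,
#'   `p_value`, `q_no_limit`, `q_sn_limit`, `hit_class`, `log2_sn`,
#'   `pct_bound`.
#' @export
test_occupancy_change <- function(x, fraction = c("clRNP", "input"),
                                  sn_profiles = NULL, sn_threshold = 3,
                                  alpha_fdr = 0.05, conditions = NULL) {
  fraction <- match.arg(fraction)
  groups <- table_groups(x)
  if (is.null(conditions)) conditions <- groups
  if (length(conditions) != 2 || !all(conditions %in% groups)) {
    stop("configuration error: need exactly two condition groups; table has ",
         paste(groups, collapse = ", "))
  }
  a <- spi_matrix(x, conditions[1])
  b <- spi_matrix(x, conditions[2])
  if (anyNA(a) || anyNA(b) || any(a <= 0) || any(b <= 0)) {
    stop("data error: missing or non-positive SPI; run preprocess_comparative() first")
  }
  la <- log2(a); lb <- log2(b)
  n1 <- ncol(la); n2 <- ncol(lb)
  if (n1 < 2 || n2 < 2) stop("statistics error: need >= 2 replicates per condition")
  sp2 <- ((n1 - 1) * row_var(la) + (n2 - 1) * row_var(lb)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  fc <- unname(rowMeans(lb) - rowMeans(la))
  se <- unname(se)
  tt <- fc / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se == 0] <- ifelse(fc[se == 0] == 0, 1, 0)
  q_all <- bh_adjust(p)

  log2_sn <- rep(NA_real_, nrow(a))
  pct_bound <- rep(NA_real_, nrow(a))
  if (!is.null(sn_profiles)) {
    idx <- match(x$proteins$protein_id, sn_profiles$protein_id)
    log2_sn <- sn_profiles$log2_sn[idx]
    pct_bound <- sn_profiles$pct_bound[idx]
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " protein(s) lack a companion S/N profile and ",
              "are excluded from the gated pass")
    }
  }
  gated <- !is.na(log2_sn) & log2_sn > log2(sn_threshold)
  q_sn <- rep(NA_real_, length(p))
  if (any(gated)) q_sn[gated] <- bh_adjust(p[gated])

  sig_all <- q_all <= alpha_fdr
  sig_sn <- !is.na(q_sn) & q_sn <= alpha_fdr
  hit_class <- ifelse(sig_all & sig_sn, "purple",
                      ifelse(sig_sn, "gold",
                             ifelse(sig_all, "teal", "none")))
  out <- tibble::tibble(
    protein_id = x$proteins$protein_id,
    fraction = fraction,
    log2_fc = fc, t_stat = tt, p_value = p,
    q_no_limit = q_all, q_sn_limit = q_sn,
    hit_class = hit_class,
    log2_sn = log2_sn, pct_bound = pct_bound
  )
  attr(out, "alpha_fdr") <- alpha_fdr
  attr(out, "sn_threshold") <- sn_threshold
  attr(out, "conditions") <- conditions
  out
}

#' Join input- and clRNP-fraction occupancy results
#'
#' Inner-joins the two result sets on `protein_id` and classifies each shared
#' protein: `"occupancy_specific"` if its RNA-bound (clRNP) abundance changes
#' significantly while its total (input) abundance does not,
#' `"abundance_driven"` if both change, `"input_only"` if only the input
#' changes, `"none"` otherwise. A clRNP change counts as significant if either
#' BH pass calls it at its recorded `alpha_fdr`.
#'
#' @param input_results,clrnp_results Tibbles from [test_occupancy_change()].
#' @return A tibble with per-fraction `log2_fc`, q-values, and `change_class`.
#' @export
compare_fractions <- function(input_results, clrnp_results) {
  shared <- intersect(input_results$protein_id, clrnp_results$protein_id)
  if (length(shared) == 0) {
    warning("no shared proteins between fractions; empty join")
  }
  ii <- match(shared, input_results$protein_id)
  ci <- match(shared, clrnp_results$protein_id)
  alpha_in <- attr(input_results, "alpha_fdr") %||% 0.05
  alpha_cl <- attr(clrnp_results, "alpha_fdr") %||% 0.05
  in_hit <- input_results$q_no_limit[ii] <= alpha_in
  cl_hit <- clrnp_results$q_no_limit[ci] <= alpha_cl |
    (!is.na(clrnp_results$q_sn_limit[ci]) &
       clrnp_results$q_sn_limit[ci] <= alpha_cl)
  change_class <- ifelse(cl_hit & !in_hit, "occupancy_specific",
                         ifelse(cl_hit & in_hit, "abundance_driven",
                                ifelse(in_hit, "input_only", "none")))
  tibble::tibble(
    protein_id = shared,
    log2_fc_input = input_results$log2_fc[ii],
    log2_fc_clrnp = clrnp_results$log2_fc[ci],
    q_input = input_results$q_no_limit[ii],
    q_clrnp_no_limit = clrnp_results$q_no_limit[ci],
    q_clrnp_sn_limit = clrnp_results$q_sn_limit[ci],
    hit_class_clrnp = clrnp_results$hit_class[ci],
    change_class = change_class
  )
}
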