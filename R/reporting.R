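#' RCS rank-bin analysis
#'
#' Ranks proteins by RBP-confidence score and summarizes contiguous rank bins
#' (default 100 proteins per bin; the last bin may be short): number of
#' annotated RBPs, mean RCS, summed %TP, mean log2(S/N) (finite values only),
#' mean unique peptide count, and mean detectable change in log2(S).
#'
#' @param profiles `signal_profiles` with `rcs_rank` (see [compute_rcs()]).
#' @param sensitivity Optional tibble from [estimate_sensitivity()].
#' @param annotations Optional [annotation_set()] of known RBPs.
#' @param bin_size Proteins per bin (default 100).
#' @return A tibble with one row per rank bin.
#' @export
rank_bin_analysis <- function(profiles, sensitivity = NULL, annotations = NULL,
                              bin_size = 100) {
  if (bin_size < 1) stop("configuration error: bin_size must be >= 1")
  if (!"rcs_rank" %in% names(profiles)) stop("run compute_rcs() first")
  p <- profiles[order(profiles$rcs_rank), ]
  bin <- ceiling(seq_len(nrow(p)) / bin_size)
  is_rbp <- if (!is.null(annotations)) {
    p$protein_id %in% annotations$members
  } else rep(NA, nrow(p))
  d_s <- if (!is.null(sensitivity)) {
    sensitivity$detectable_dlog2_S[match(p$protein_id, sensitivity$protein_id)]
  } else rep(NA_real_, nrow(p))
  rows <- lapply(unique(bin), function(b) {
    k <- bin == b
    tibble::tibble(
      bin_index = b,
      bin_size = sum(k),
      n_annotated_rbps = if (all(is.na(is_rbp))) NA_integer_ else sum(is_rbp[k]),
      mean_rcs = mean(p$rcs[k], na.rm = TRUE),
      sum_pct_tp = sum(p$pct_tp[k]),
      mean_log2_sn = mean(p$log2_sn[k][is.finite(p$log2_sn[k])]),
      mean_unique_peptides = mean(p$unique_peptides[k]),
      mean_detectable_dlog2_S = mean(d_s[k][is.finite(d_s[k])])
    )
  })
  do.call(rbind, rows)
}

#' Cross-method benchmark summary
#'
#' Summarizes, per method, the quantities used to compare RNA-centric capture
#' methods: protein counts, UV-enriched* counts (overall and among annotated
#' RBPs), total RNA-bound abundance (%TP_S summed over proteins), and the RBP
#' share of total RNA-bound intensity. Also reports pairwise overlaps of the
#' methods' UV-enriched* sets.
#'
#' @param per_method_profiles Named list of `signal_profiles`, one per method.
#' @param annotations An [annotation_set()] of known RBPs.
#' @param per_method_enrichment Optional named list of [test_uv_enrichment()]
#'   results aligned with `per_method_profiles`; without it, enriched counts
#'   are `NA`.
#' @return A list with `summary` (one row per method) and `overlap` (pairwise
#'   intersection counts of enriched sets; empty for a single method).
#' @export
benchmark_summary <- function(per_method_profiles, annotations,
                              per_method_enrichment = NULL) {
  methods <- names(per_method_profiles)
  if (is.null(methods)) stop("per_method_profiles must be a named list")
  enriched_sets <- list()
  rows <- lapply(methods, function(m) {
    prof <- per_method_profiles[[m]]
    is_rbp <- prof$protein_id %in% annotations$members
    enr <- per_method_enrichment[[m]]
    enriched <- if (!is.null(enr)) {
      enr$protein_id[enr$enriched]
    } else NULL
    enriched_sets[[m]] <<- enriched
    total_s <- sum(pmax(prof$S, 0))
    tibble::tibble(
      method = m,
      n_proteins = nrow(prof),
      n_enriched = if (is.null(enriched)) NA_integer_ else length(enriched),
      n_enriched_rbps = if (is.null(enriched)) NA_integer_ else
        sum(enriched %in% annotations$members),
      pct_tp_s_total = sum(prof$pct_tp_s),
      rbp_share_of_signal = if (total_s > 0)
        100 * sum(pmax(prof$S[is_rbp], 0)) / total_s else 0
    )
  })
  overlap <- tibble::tibble(method_a = character(), method_b = character(),
                            n_shared_enriched = integer())
  if (length(methods) > 1 && !is.null(per_method_enrichment)) {
    pairs <- utils::combn(methods, 2)
    overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      tibble::tibble(
        method_a = a, method_b = b,
        n_shared_enriched = length(intersect(enriched_sets[[a]],
                                             enriched_sets[[b]]))
      )
    }))
  }
  list(summary = do.call(rbind, rows), overlap = overlap)
}

#' Add a pseudo-replicate by averaging two replicates
#'
#' For external two-replicate datasets: appends, per group, a third replicate
#' equal to the mean of the non-zero values of replicates 1 and 2. Logged as
#' an explicit transform; off by default in all pipelines.
#'
#' @param x An [intensity_table()] whose groups have exactly 2 replicates.
#' @return The augmented `intensity_table`.
#' @export
add_pseudo_replicate <- function(x) {
  new_cols <- list(); new_samples <- list()
  for (g in table_groups(x)) {
    m <- spi_matrix(x, g)
    if (ncol(m) != 2) stop("group ", g, " does not have exactly 2 replicates")
    v <- ifelse(is.na(m) | m == 0, NA, m)
    avg <- rowMeans(v, na.rm = TRUE)
    avg[is.nan(avg)] <- NA_real_
    new_cols[[g]] <- avg
    new_samples[[g]] <- data.frame(sample_id = sprintf("%s_3", g), group = g,
                                   replicate = 3L, stringsAsFactors = FALSE)
  }
  x$intensities <- cbind(x$intensities, do.call(cbind, new_cols))
  x$samples <- rbind(x$samples, do.call(rbind, new_samples))
  colnames(x$intensities) <- x$samples$sample_id
  it_log(x, "add_pseudo_replicate", list())
}

#' Aggregate replicate-free samples into one average profile
#'
#' For external datasets recorded as many single samples: mean-normalizes all
#' samples, then replaces each group's columns by the per-protein average of
#' the non-zero values across its samples (one aggregate replicate per group).
#'
#' @param x An [intensity_table()].
#' @return An `intensity_table` with one column per group.
#' @export
aggregate_samples <- function(x) {
  x <- mean_normalize(x)
  groups <- table_groups(x)
  cols <- lapply(groups, function(g) {
    m <- spi_matrix(x, g)
    v <- ifelse(is.na(m) | m == 0, NA, m)
    avg <- rowMeans(v, na.rm = TRUE)
    avg[is.nan(avg)] <- NA_real_
    avg
  })
  samples <- data.frame(sample_id = sprintf("%s_1", groups), group = groups,
                        replicate = 1L, stringsAsFactors = FALSE)
  out <- x
  out$intensities <- do.call(cbind, cols)
  colnames(out$intensities) <- samples$sample_id
  out$samples <- samples
  it_log(out, "aggregate_samples", list())
}
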