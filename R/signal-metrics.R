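#' Per-protein signal/noise decomposition
#'
#' Decomposes mean crosslinked (CL) and non-crosslinked (nCL) channel
#' intensities into RNA-bound signal `S` and free-protein noise `N`. Under the
#' equal noise-partitioning model, free protein distributes 1:1 between the
#' pooled SILAC channels, so
#' \deqn{S = \overline{SPI}_{CL} - \overline{SPI}_{nCL}, \qquad
#'       N = 2\,\overline{SPI}_{nCL},}
#' and the observed total is `O = S + N = spi_cl + spi_ncl`. The naive model
#' (`partition_model = "naive"`) instead attributes the whole nCL channel to
#' noise once (`N = spi_ncl`), which systematically overestimates the
#' RNA-bound fraction and is provided for comparison only.
#'
#' Derived per-protein quantities:
#' * `cl_ncl`, `log2_sn`: enrichment ratio and log2 signal-to-noise
#'   (`log2_sn` is `NA` when `S <= 0`, `Inf` for CL-only proteins);
#' * `pct_bound`: percent RNA-bound, `100 * S/(S+N)`, clamped to `[0, 100]`
#'   (CL-only proteins: 100);
#' * `pct_tp`: Total Protein Approach abundance `100 * O / sum(O)` over the
#'   retained protein set;
#' * `pct_tp_s`, `pct_tp_n`: its RNA-bound and free components
#'   (`pct_tp_s = max(S, 0)/O * pct_tp`; for proteins with `S <= 0` all
#'   abundance is background, `pct_tp_n = pct_tp`).
#'
#' @param x A preprocessed [intensity_table()] with `CL` and `nCL` groups.
#' @param partition_model `"equal_noise"` (default) or `"naive"`.
#' @param per_replicate If `TRUE`, also return per-replicate `S/N` columns
#'   (`log2_sn_1`, ...) computed from each CL replicate against the nCL mean.
#' @return A tibble of class `signal_profiles`, one row per protein, with the
#'   fields above plus `S`, `N`, `O`, `spi_cl`, `spi_ncl`, `cl_only`; RCS
#'   columns are added by [compute_rcs()].
#' @export
compute_signal_profiles <- function(x, partition_model = c("equal_noise", "naive"),
                                    per_replicate = FALSE) {
  partition_model <- match.arg(partition_model)
  cl <- spi_matrix(x, "CL")
  ncl <- spi_matrix(x, "nCL")
  if (any(cl[is.finite(cl)] < 0) || any(ncl[is.finite(ncl)] < 0)) {
    stop("data error: negative SPI")
  }
  spi_cl <- unname(rowMeans(cl, na.rm = TRUE))
  spi_ncl <- unname(rowMeans(ncl))
  spi_ncl[is.na(spi_ncl)] <- 0
  cl_only <- x$proteins$cl_only | spi_ncl == 0

  S <- spi_cl - spi_ncl
  N <- switch(partition_model, equal_noise = 2 * spi_ncl, naive = spi_ncl)
  O <- S + N
  S_pos <- pmax(S, 0)
  cl_ncl <- ifelse(cl_only, Inf, spi_cl / spi_ncl)
  log2_sn <- rep(NA_real_, length(S))
  pos <- !cl_only & S > 0 & N > 0
  log2_sn[pos] <- log2(S[pos] / N[pos])
  log2_sn[cl_only] <- Inf
  pct_bound <- ifelse(cl_only, 100, 100 * S_pos / (S_pos + N))
  pct_tp <- 100 * O / sum(O)
  pct_tp_s <- ifelse(O > 0, S_pos / O, 0) * pct_tp
  pct_tp_n <- pct_tp - pct_tp_s

  out <- tibble::tibble(
    protein_id = x$proteins$protein_id,
    gene_name = x$proteins$gene_name,
    unique_peptides = x$proteins$unique_peptides,
    spi_cl = spi_cl, spi_ncl = spi_ncl,
    S = S, N = N, O = O,
    cl_ncl = cl_ncl, log2_sn = log2_sn,
    pct_bound = pct_bound,
    pct_tp = pct_tp, pct_tp_s = pct_tp_s, pct_tp_n = pct_tp_n,
    cl_only = cl_only
  )
  if (per_replicate) {
    for (j in seq_len(ncol(cl))) {
      sj <- cl[, j] - spi_ncl
      out[[sprintf("log2_sn_%d", j)]] <-
        ifelse(sj > 0 & spi_ncl > 0, log2(sj / (2 * spi_ncl)), NA_real_)
    }
  }
  attr(out, "partition_model") <- partition_model
  class(out) <- c("signal_profiles", class(out))
  out
}

#' RNase-dependent fold-change of observed protein
#'
#' Log2 fold-change of the observed (e.g. densitometric band) quantity between
#' an RNase-treated sample, where liberated RNA-bound protein contributes
#' `|S| + N`, and an untreated control showing only free protein `N`.
#'
#' @param observed_rnase Positive intensity of the RNase-treated sample.
#' @param observed_untreated Positive intensity of the untreated control.
#' @return `log2(observed_rnase) - log2(observed_untreated)`.
#' @export
rnase_fold_change <- function(observed_rnase, observed_untreated) {
  if (any(observed_rnase <= 0) || any(observed_untreated <= 0)) {
    stop("domain error: band intensities must be positive")
  }
  log2(observed_rnase) - log2(observed_untreated)
}

#' RBP-confidence scores and ordinal ranks
#'
#' The RBP-confidence score combines enrichment efficiency and abundance:
#' `RCS = log2(S/N) * log10(%TP)`. Ranking prioritizes S/N over abundance with
#' a two-tier rule: proteins detected only in the CL channel come first
#' (ordered by `pct_tp`), then proteins with `log2(S/N) >= 0` ordered by RCS
#' descending, then proteins with `S/N < 1` (including `S <= 0`) ordered by
#' `log2(S/N)` descending. Ties break by `pct_tp` descending, then accession.
#'
#' @param profiles A `signal_profiles` tibble from [compute_signal_profiles()].
#' @return The same tibble with `rcs` and `rcs_rank` columns filled;
#'   `rcs_rank` is a permutation of `1..n` with 1 = most confident.
#' @export
compute_rcs <- function(profiles) {
  p <- profiles
  finite_sn <- is.finite(p$log2_sn)
  p$rcs <- ifelse(finite_sn & p$S > 0, p$log2_sn * log10(p$pct_tp), NA_real_)

  tier <- ifelse(p$cl_only, 1L, ifelse(finite_sn & p$log2_sn >= 0, 2L, 3L))
  key1 <- ifelse(tier == 1L, -p$pct_tp, ifelse(tier == 2L, -p$rcs, 0))
  # tier 3: sort by log2_sn descending, S <= 0 (undefined S/N) last
  key1[tier == 3L] <- -ifelse(is.na(p$log2_sn[tier == 3L]), -Inf,
                              p$log2_sn[tier == 3L])
  ord <- order(tier, key1, -p$pct_tp, p$protein_id)
  p$rcs_rank <- integer(nrow(p))
  p$rcs_rank[ord] <- seq_len(nrow(p))
  p
}

#' Annotation-level signal summaries
#'
#' Sums the Total Protein Approach components over annotation categories. In
#' partition mode the categories must be disjoint; proteins not covered by any
#' set fall into an implicit complement category. `share_of_signal` is
#' `%TP_(S)`: the category's RNA-bound intensity as a percentage of total
#' RNA-bound intensity.
#'
#' @param profiles A `signal_profiles` tibble.
#' @param annotations A list of [annotation_set()] objects (or a named list of
#'   accession vectors).
#' @param partition If `TRUE` (default), categories must not overlap and a
#'   complement category `"(other)"` completes the partition.
#' @param complement Label of the complement category.
#' @return A tibble with `category`, `n_proteins`, `sum_pct_tp_s`,
#'   `sum_pct_tp_n`, `share_of_signal`.
#' @export
summarize_categories <- function(profiles, annotations, partition = TRUE,
                                 complement = "(other)") {
  sets <- normalize_annotations(annotations)
  member <- lapply(sets, function(s) profiles$protein_id %in% s$members)
  if (partition && length(sets) > 1) {
    cover <- Reduce(`+`, member)
    if (any(cover > 1)) {
      stop("categories overlap; use partition = FALSE for overlapping sets")
    }
  }
  if (partition) {
    covered <- Reduce(`|`, member)
    if (any(!covered)) {
      member <- c(member, list(!covered))
      sets <- c(sets, list(annotation_set(complement, character())))
    }
  }
  total_s <- sum(pmax(profiles$S, 0))
  rows <- lapply(seq_along(sets), function(i) {
    m <- member[[i]]
    tibble::tibble(
      category = sets[[i]]$name,
      n_proteins = sum(m),
      sum_pct_tp_s = sum(profiles$pct_tp_s[m]),
      sum_pct_tp_n = sum(profiles$pct_tp_n[m]),
      share_of_signal = if (total_s > 0) {
        100 * sum(pmax(profiles$S[m], 0)) / total_s
      } else 0
    )
  })
  do.call(rbind, rows)
}

normalize_annotations <- function(annotations) {
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    if (inherits(a, "annotation_set")) return(a)
    nm <- names(annotations)[i]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- paste0("set", i)
    annotation_set(nm, a)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Empirical cumulative distributions by annotation stratum
#'
#' Splits proteins into members and non-members of an annotation set and
#' returns, per stratum, the sorted values of the chosen metric with their
#' empirical cumulative quantiles (suitable for cumulative-frequency plots).
#'
#' @param profiles A `signal_profiles` tibble.
#' @param by `"log2_sn"` or `"log10_pct_tp"`.
#' @param strata An [annotation_set()] defining the two strata.
#' @return A tibble with `stratum`, `value`, `quantile`; `quantile` is
#'   monotone non-decreasing within each stratum. Non-finite values are
#'   dropped; empty strata are skipped with a warning.
#' @export
cumulative_curves <- function(profiles, by = c("log2_sn", "log10_pct_tp"),
                              strata) {
  by <- match.arg(by)
  values <- switch(by, log2_sn = profiles$log2_sn,
                   log10_pct_tp = log10(profiles$pct_tp))
  member <- profiles$protein_id %in% strata$members
  groups <- list(member, !member)
  labels <- c(strata$name, paste0("non-", strata$name))
  out <- list()
  for (i in 1:2) {
    v <- sort(values[groups[[i]] & is.finite(values)])
    if (length(v) == 0) {
      warning("stratum \"", labels[i], "\" has no finite values; skipped")
      next
    }
    out[[length(out) + 1]] <- tibble::tibble(
      stratum = labels[i], value = v,
      quantile = seq_along(v) / length(v)
    )
  }
  if (!length(out)) stop("no stratum has finite values")
  do.call(rbind, out)
}
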