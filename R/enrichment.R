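#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: on sorted p-values,
#' `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("domain error: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Identify UV-enriched* proteins
#'
#' Tests, per protein, whether recovery from the crosslinked (CL) channel
#' exceeds the non-crosslinked (nCL) channel. The reported effect size is the
#' mean log2(CL/nCL) ratio formed from each CL replicate against the protein's
#' mean nCL SPI. Three test forms are available:
#'
#' * `"welch"` (default): unpaired, upper-tailed, unequal-variance t-test of
#'   the log2 CL replicate values against the log2 nCL replicate values
#'   (Satterthwaite degrees of freedom). This is the only form whose null
#'   hypothesis matches the mean log2 ratio while keeping the nCL sampling
#'   noise in the standard error.
#' * `"ratio"`: one-sample upper-tailed t-test of the per-replicate ratios
#'   against 0 (`df = n - 1`). Because all ratios share the protein's nCL
#'   mean, this form understates the variance of the mean ratio and is
#'   anti-conservative; it is kept for sensitivity analysis.
#' * `"pooled"`: two-sample pooled-variance form.
#'
#' Proteins detected only in the CL channel (`cl_only`) bypass testing, are
#' scored UV-enriched*, and receive the pseudo-values
#' `mean_log2_ratio = 10`, `-log10(p) = 10`; they are excluded from the BH
#' multiplicity `m`. Proteins with zero variance in both channels get `p = 0`
#' if the mean ratio is positive and `p = 1` otherwise, and are flagged.
#'
#' @param x A preprocessed [intensity_table()] with `CL` and `nCL` groups and
#'   at least 2 CL replicates.
#' @param alpha_fdr BH false-discovery rate (default 0.05).
#' @param form Test form, see above.
#' @return A tibble with `protein_id`, `mean_log2_ratio`, `t_stat`, `p_value`,
#'   `q_value`, `neg_log10_p` (capped at 10), `enriched`, `pseudo`,
#'   `zero_variance`.
#' @export
test_uv_enrichment <- function(x, alpha_fdr = 0.05,
                               form = c("welch", "ratio", "pooled")) {
  form <- match.arg(form)
  cl <- spi_matrix(x, "CL")
  ncl <- spi_matrix(x, "nCL")
  n1 <- ncol(cl); n2 <- ncol(ncl)
  if (n1 < 2) stop("statistics error: need at least 2 CL replicates")
  pseudo <- x$proteins$cl_only | rowSums(ncl > 0, na.rm = TRUE) == 0

  tested <- which(!pseudo)
  cl_t <- cl[tested, , drop = FALSE]
  if (anyNA(cl_t) || any(cl_t <= 0, na.rm = TRUE)) {
    stop("data error: non-positive or missing CL intensity in a tested protein; ",
         "run the detection filter first")
  }
  lcl <- log2(cl[tested, , drop = FALSE])
  lncl <- log2(ncl[tested, , drop = FALSE])
  mean_ncl <- rowMeans(ncl[tested, , drop = FALSE])
  ratios <- log2(cl[tested, , drop = FALSE] / mean_ncl)
  mean_ratio <- rowMeans(ratios)

  m1 <- rowMeans(lcl); m2 <- rowMeans(lncl)
  v1 <- row_var(lcl); v2 <- row_var(lncl)
  if (form == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- (m1 - m2) / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else if (form == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- (m1 - m2) / se
    df <- rep(n1 + n2 - 2, length(tt))
  } else {
    vr <- row_var(ratios)
    se <- sqrt(vr / n1)
    tt <- mean_ratio / se
    df <- rep(n1 - 1, length(tt))
  }
  zero_var <- !is.na(se) & se == 0
  p <- stats::pt(tt, df, lower.tail = FALSE)
  eff <- if (form == "ratio") mean_ratio else m1 - m2
  p[zero_var] <- ifelse(eff[zero_var] > 0, 0, 1)
  tt[zero_var] <- ifelse(eff[zero_var] > 0, Inf, 0)
  q <- bh_adjust(p)

  out <- tibble::tibble(
    protein_id = x$proteins$protein_id,
    mean_log2_ratio = NA_real_, t_stat = NA_real_,
    p_value = NA_real_, q_value = NA_real_,
    neg_log10_p = NA_real_,
    enriched = FALSE, pseudo = pseudo, zero_variance = FALSE
  )
  out$mean_log2_ratio[tested] <- mean_ratio
  out$t_stat[tested] <- tt
  out$p_value[tested] <- p
  out$q_value[tested] <- q
  out$neg_log10_p[tested] <- pmin(-log10(pmax(p, 1e-300)), 10)
  out$zero_variance[tested] <- zero_var
  out$enriched[tested] <- q <= alpha_fdr & mean_ratio > 0
  # CL-only proteins: scored UV-enriched*, omitted from statistics
  out$mean_log2_ratio[pseudo] <- 10
  out$p_value[pseudo] <- 1e-10
  out$q_value[pseudo] <- 1e-10
  out$neg_log10_p[pseudo] <- 10
  out$enriched[pseudo] <- TRUE
  attr(out, "alpha_fdr") <- alpha_fdr
  attr(out, "form") <- form
  out
}

row_var <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Smallest detectable change in observed quantity
#'
#' The detectable change in log2 observed protein quantity at the given
#' one-sided confidence level: `t_conf(df = n - 1) * SEM of log2(O)`.
#'
#' @param log2_O_values Per-replicate log2 observed quantities (n >= 2).
#' @param confidence One-sided confidence level (default 0.95).
#' @return The detectable `dlog2(O)` (>= 0).
#' @export
detectable_delta_O <- function(log2_O_values, confidence = 0.95) {
  n <- length(log2_O_values)
  if (n < 2) stop("statistics error: need at least 2 replicates")
  stats::qt(confidence, df = n - 1) * stats::sd(log2_O_values) / sqrt(n)
}

#' Smallest detectable change in RNA-bound quantity
#'
#' Converts a detectable change in observed quantity `O = S + N` into the
#' fold-change in RNA-bound quantity `S` that produces it, assuming the free
#' component `N` is unchanged:
#' \deqn{\Delta\log_2(S) = \log_2(2^{\Delta\log_2(O)} - N/O) - \log_2(S/O).}
#' As `N/O` approaches 0 this reduces to `detectable_dlog2_O`. Any positive
#' change in `O` is attainable by increasing `S` (since `2^d > 1 >= N/O`), but
#' a requested *decrease* below `log2(N/O)` is not: removing all signal still
#' leaves `N`. In that case the unattainable sentinel `-Inf` is returned with
#' a warning.
#'
#' @param detectable_dlog2_O Detectable change in log2(O), from
#'   [detectable_delta_O()].
#' @param S RNA-bound intensity (> 0).
#' @param N Free-protein intensity (>= 0).
#' @return The detectable `dlog2(S)`, or `-Inf` if unattainable.
#' @export
detectable_delta_S <- function(detectable_dlog2_O, S, N) {
  if (S <= 0) stop("S must be positive")
  O <- S + N
  margin <- 2^detectable_dlog2_O - N / O
  if (margin <= 0) {
    warning(sprintf(
      "unattainable: 2^dlog2(O) = %.4g does not exceed N/O = %.4g; no change in S achieves it",
      2^detectable_dlog2_O, N / O))
    return(-Inf)
  }
  log2(margin) - log2(S / O)
}

#' Per-protein sensitivity estimates
#'
#' Computes, for every protein of a SILAC table, the standard deviation of
#' log2 observed quantity across replicates, the detectable change in
#' log2(O), and the corresponding detectable change in log2(S) given the
#' protein's signal decomposition.
#'
#' @param x A preprocessed [intensity_table()] with `CL` and `nCL` groups.
#' @param profiles Matching `signal_profiles` from [compute_signal_profiles()].
#' @param confidence One-sided confidence level (default 0.95).
#' @return A tibble with `protein_id`, `sd_log2_O`, `detectable_dlog2_O`,
#'   `detectable_dlog2_S`, `n_reps`, `t_crit`. `detectable_dlog2_S` is `NA`
#'   for proteins with `S <= 0` and `Inf` where unattainable.
#' @export
estimate_sensitivity <- function(x, profiles, confidence = 0.95) {
  cl <- spi_matrix(x, "CL")
  ncl <- spi_matrix(x, "nCL")
  O_rep <- cl + ncl
  n <- ncol(O_rep)
  if (n < 2) stop("statistics error: need at least 2 replicates")
  valid <- rowSums(is.na(O_rep) | O_rep <= 0) == 0
  sd_o <- rep(NA_real_, nrow(O_rep))
  sd_o[valid] <- sqrt(row_var(log2(O_rep[valid, , drop = FALSE])))
  t_crit <- stats::qt(confidence, df = n - 1)
  d_o <- t_crit * sd_o / sqrt(n)

  idx <- match(x$proteins$protein_id, profiles$protein_id)
  S <- profiles$S[idx]; N <- profiles$N[idx]
  d_s <- rep(NA_real_, length(d_o))
  ok <- !is.na(d_o) & !is.na(S) & S > 0
  margin <- 2^d_o[ok] - N[ok] / (S[ok] + N[ok])
  d_s[ok] <- ifelse(margin > 0,
                    log2(pmax(margin, .Machine$double.xmin)) -
                      log2(S[ok] / (S[ok] + N[ok])),
                    Inf)
  tibble::tibble(
    protein_id = x$proteins$protein_id,
    sd_log2_O = sd_o,
    detectable_dlog2_O = d_o,
    detectable_dlog2_S = d_s,
    n_reps = n,
    t_crit = t_crit
  )
}
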