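#' Default contaminant patterns
#'
#' Regular expressions matched (case-insensitively) against protein accessions
#' and gene names to curate common contaminants and spike-ins: human keratins,
#' bovine serum albumin, porcine trypsin, yeast alcohol dehydrogenase and
#' bovine casein.
#'
#' @return Character vector of regular expressions.
#' @export
contaminant_patterns <- function() {
  c(
    "^KRT[0-9]",  "K1C[0-9]+_HUMAN", "K2C[0-9]+_HUMAN", "KRT_",  # keratins
    "ALBU_BOVIN", "^P02769",                                     # BSA
    "TRYP_PIG",   "^P00761",                                     # trypsin
    "ADH1_YEAST", "^P00330",                                     # yeast ADH
    "CAS[AB12]*_BOVIN", "^P02662", "^P02663", "^P02666", "^P02668" # casein
  )
}

#' Remove contaminant protein groups
#'
#' Drops rows flagged as potential contaminants at read time and rows whose
#' accession or gene name matches a contaminant pattern.
#'
#' @param x An [intensity_table()].
#' @param patterns Character vector of regular expressions; defaults to
#'   [contaminant_patterns()].
#' @return The filtered `intensity_table` (removal is recorded in the log).
#' @export
remove_contaminants <- function(x, patterns = contaminant_patterns()) {
  p <- x$proteins
  hit <- p$contaminant_flag
  if (length(patterns)) {
    pat <- paste(patterns, collapse = "|")
    hit <- hit |
      grepl(pat, p$protein_id, ignore.case = TRUE) |
      (!is.na(p$gene_name) & grepl(pat, p$gene_name, ignore.case = TRUE))
  }
  out <- it_subset(x, !hit)
  if (nrow(out$intensities) == 0) {
    warning("all proteins were flagged as contaminants; table is empty")
  }
  it_log(out, "remove_contaminants", list(patterns = patterns),
         n_before = nrow(x$intensities), n_removed = sum(hit))
}

#' Detection and peptide-evidence filter
#'
#' Retains proteins with a non-missing SPI in every replicate of every
#' required group and at least `min_unique_peptides` unique peptide matches.
#' SILAC designs require full detection in the crosslinked (`CL`) channel only
#' (proteins not detected in all CL replicates are excluded); comparative
#' designs require full detection in both condition groups and two unique
#' peptides. When an `nCL` group is present, proteins whose nCL measurements
#' are all missing or zero are retained but flagged `cl_only`: they are scored
#' UV-enriched* downstream via pseudo-values rather than tested.
#'
#' @param x An [intensity_table()].
#' @param required_groups Character vector of group labels that must be fully
#'   detected.
#' @param min_unique_peptides Minimum unique peptide count (default 1).
#' @return The filtered `intensity_table`, with `cl_only` flags updated.
#' @export
filter_detection <- function(x, required_groups, min_unique_peptides = 1L) {
  unknown <- setdiff(required_groups, table_groups(x))
  if (length(unknown)) {
    stop("configuration error: unknown group label ", paste(unknown, collapse = ", "))
  }
  detected <- rep(TRUE, nrow(x$intensities))
  for (g in required_groups) {
    detected <- detected & rowSums(is.na(spi_matrix(x, g))) == 0
  }
  enough <- x$proteins$unique_peptides >= min_unique_peptides
  n_det <- sum(!detected)
  n_pep <- sum(detected & !enough)
  out <- it_subset(x, detected & enough)
  if ("nCL" %in% table_groups(out)) {
    ncl <- spi_matrix(out, "nCL")
    out$proteins$cl_only <- rowSums(!is.na(ncl) & ncl > 0) == 0
  }
  it_log(out, "filter_detection",
         list(required_groups = required_groups,
              min_unique_peptides = min_unique_peptides),
         n_before = nrow(x$intensities),
         n_filtered_detection = n_det, n_filtered_peptides = n_pep)
}

#' Mean-normalize replicate samples to total SPI
#'
#' Each replicate sample is scaled by (mean of per-sample totals) / (that
#' sample's total), so all per-sample totals become equal to the
#' pre-normalization mean and the grand total SPI is conserved. Totals are
#' computed over non-missing cells.
#'
#' What constitutes one "sample" depends on the design. In a pooled-channel
#' SILAC experiment one LC-MS/MS run carries both channels, so `by =
#' "replicate"` totals the CL and nCL columns of the same replicate index and
#' scales them jointly, preserving within-run CL/nCL ratios. In label-free
#' comparative designs every column is its own run (`by = "sample"`).
#'
#' @param x An [intensity_table()].
#' @param by `"sample"` (each column normalized on its own total) or
#'   `"replicate"` (columns sharing a replicate index are scaled jointly).
#' @param within Optional character vector of group labels defining a block to
#'   normalize within (e.g. normalize input-fraction samples separately from
#'   clRNP samples); default normalizes across all samples of the table.
#' @return The normalized `intensity_table`; scale factors are recorded in the
#'   log and surfaced by [preprocess_report()].
#' @export
mean_normalize <- function(x, by = c("sample", "replicate"), within = NULL) {
  by <- match.arg(by)
  if (nrow(x$intensities) == 0) stop("cannot normalize an empty table")
  cols <- if (is.null(within)) seq_len(ncol(x$intensities)) else
    which(x$samples$group %in% within)
  unit <- switch(by,
                 sample = x$samples$sample_id[cols],
                 replicate = as.character(x$samples$replicate[cols]))
  totals_col <- colSums(x$intensities[, cols, drop = FALSE], na.rm = TRUE)
  totals <- tapply(totals_col, unit, sum)
  if (any(totals == 0)) {
    stop("normalization error: zero total SPI in ", by, " ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  factors <- mean(totals) / totals
  col_factors <- as.numeric(factors[unit])
  x$intensities[, cols] <- sweep(x$intensities[, cols, drop = FALSE], 2,
                                 col_factors, `*`)
  sf <- stats::setNames(col_factors, x$samples$sample_id[cols])
  it_log(x, "mean_normalize", list(by = by, within = within),
         scale_factors = sf)
}

#' Replace zero or missing nCL values by the protein's non-zero nCL mean
#'
#' For each protein, nCL replicate values that are zero or missing are
#' replaced with the mean of that protein's non-zero nCL values. Proteins with
#' no non-zero nCL value are left at zero and flagged `cl_only`. Crosslinked
#' (CL) values are never imputed.
#'
#' @param x An [intensity_table()] containing an `nCL` group.
#' @return The imputed `intensity_table`.
#' @export
replace_ncl_zeros <- function(x) {
  if (!"nCL" %in% table_groups(x)) stop("table has no nCL group")
  idx <- which(x$samples$group == "nCL")
  m <- x$intensities[, idx, drop = FALSE]
  bad <- is.na(m) | m == 0
  means <- rowSums(ifelse(bad, 0, m)) / pmax(rowSums(!bad), 1L)
  n_imputed <- 0L
  for (j in seq_along(idx)) {
    rep_rows <- bad[, j] & means > 0
    m[rep_rows, j] <- means[rep_rows]
    n_imputed <- n_imputed + sum(rep_rows)
  }
  m[is.na(m)] <- 0
  x$intensities[, idx] <- m
  x$proteins$cl_only <- rowSums(m > 0) == 0
  it_log(x, "replace_ncl_zeros", list(),
         n_imputed = n_imputed, n_cl_only = sum(x$proteins$cl_only))
}

#' Standard preprocessing pipelines
#'
#' `preprocess_silac()` applies, in order: contaminant removal, the SILAC
#' detection filter (full detection in CL, `min_unique_peptides = 1`),
#' mean normalization, and nCL zero replacement. `preprocess_comparative()`
#' applies contaminant removal, the comparative detection filter (full
#' detection in both condition groups, `min_unique_peptides = 2`), and mean
#' normalization.
#'
#' @param x An [intensity_table()].
#' @param patterns Contaminant patterns, see [remove_contaminants()].
#' @param min_unique_peptides Peptide-evidence threshold.
#' @return A preprocessed `intensity_table` with a complete operation log.
#' @export
preprocess_silac <- function(x, patterns = contaminant_patterns(),
                             min_unique_peptides = 1L) {
  x <- remove_contaminants(x, patterns)
  x <- filter_detection(x, "CL", min_unique_peptides)
  x <- mean_normalize(x, by = "replicate")
  replace_ncl_zeros(x)
}

#' @rdname preprocess_silac
#' @param groups The two condition group labels (defaults to all groups).
#' @param within_groups Passed to [mean_normalize()] as the normalization
#'   block; default normalizes across all samples of both conditions.
#' @export
preprocess_comparative <- function(x, groups = table_groups(x),
                                   patterns = contaminant_patterns(),
                                   min_unique_peptides = 2L,
                                   within_groups = NULL) {
  x <- remove_contaminants(x, patterns)
  x <- filter_detection(x, groups, min_unique_peptides)
  mean_normalize(x, within = within_groups)
}

#' Summarize the preprocessing applied to a table
#'
#' Collates the operation log into the counts of the preprocessing funnel.
#'
#' @param x A preprocessed [intensity_table()].
#' @return A list with `n_input`, `n_retained`, `n_contaminants_removed`,
#'   `n_filtered_detection`, `n_filtered_peptides`, `n_cl_only` and the
#'   per-sample `scale_factors`.
#' @export
preprocess_report <- function(x) {
  rep <- list(n_input = NA_integer_, n_retained = nrow(x$intensities),
              n_contaminants_removed = 0L, n_filtered_detection = 0L,
              n_filtered_peptides = 0L, n_cl_only = sum(x$proteins$cl_only),
              scale_factors = NULL)
  for (entry in x$log) {
    if (is.na(rep$n_input) && !is.null(entry$n_before)) {
      rep$n_input <- entry$n_before
    }
    if (entry$op == "remove_contaminants") {
      rep$n_contaminants_removed <- rep$n_contaminants_removed + entry$n_removed
    }
    if (entry$op == "filter_detection") {
      rep$n_filtered_detection <- rep$n_filtered_detection + entry$n_filtered_detection
      rep$n_filtered_peptides <- rep$n_filtered_peptides + entry$n_filtered_peptides
    }
    if (entry$op == "mean_normalize") rep$scale_factors <- entry$scale_factors
    if (entry$op == "replace_ncl_zeros") rep$n_cl_only <- entry$n_cl_only
  }
  if (is.na(rep$n_input)) rep$n_input <- rep$n_retained
  rep
}

#' Replay a recorded preprocessing sequence on a raw table
#'
#' Re-applies the operations in `log` (as recorded in a processed table) to a
#' raw table, reproducing the processed table exactly.
#'
#' @param raw An unprocessed [intensity_table()].
#' @param log The `$log` element of a processed table.
#' @return The reprocessed `intensity_table`.
#' @export
replay_log <- function(raw, log) {
  funs <- list(remove_contaminants = remove_contaminants,
               filter_detection = filter_detection,
               mean_normalize = mean_normalize,
               replace_ncl_zeros = replace_ncl_zeros)
  x <- raw
  for (entry in log) {
    f <- funs[[entry$op]]
    if (is.null(f)) stop("cannot replay unknown operation: ", entry$op)
    x <- do.call(f, c(list(x), entry$args))
  }
  x
}
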