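#' Protein-group intensity tables
#'
#' An `intensity_table` holds a rectangular protein x sample matrix of sum
#' peptide intensities (SPI) together with per-protein metadata and a sample
#' sheet mapping each column to a `(group, replicate)` pair. Groups are
#' condition or channel labels such as `"CL"`/`"nCL"` for SILAC designs or
#' `"DMSO"`/`"HT"` for comparative designs. Missing measurements are stored as
#' `NA` and are distinct from a measured intensity of 0.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames = protein
#'   accessions), samples in columns. All finite values must be >= 0; `NA`
#'   marks a missing measurement.
#' @param proteins Data frame with one row per protein:
#'   `protein_id`, `gene_name`, `unique_peptides`, `contaminant_flag`,
#'   and (optionally) `cl_only`. Rows must align with `intensities`.
#' @param samples Data frame with one row per column of `intensities`:
#'   `sample_id`, `group`, `replicate`.
#'
#' @return An object of class `intensity_table`: a list with elements
#'   `intensities`, `proteins`, `samples` and an operation `log`.
#' @export
intensity_table <- function(intensities, proteins, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(proteins$gene_name)) proteins$gene_name <- NA_character_
  if (is.null(proteins$unique_peptides)) proteins$unique_peptides <- 1L
  if (is.null(proteins$contaminant_flag)) proteins$contaminant_flag <- FALSE
  if (is.null(proteins$cl_only)) proteins$cl_only <- FALSE
  rownames(intensities) <- proteins$protein_id
  colnames(intensities) <- samples$sample_id
  x <- structure(
    list(intensities = intensities, proteins = proteins, samples = samples,
         log = list()),
    class = "intensity_table"
  )
  validate_intensity_table(x)
  x
}

validate_intensity_table <- function(x) {
  p <- x$proteins
  if (anyDuplicated(p$protein_id)) {
    dup <- unique(p$protein_id[duplicated(p$protein_id)])
    stop("duplicate protein_id values: ", paste(dup, collapse = ", "))
  }
  if (nrow(p) != nrow(x$intensities)) {
    stop("protein metadata and intensity matrix disagree on the number of proteins")
  }
  if (nrow(x$samples) != ncol(x$intensities)) {
    stop("sample sheet and intensity matrix disagree on the number of samples")
  }
  v <- x$intensities
  if (any(v[is.finite(v)] < 0)) stop("negative SPI values are not allowed")
  if (any(p$unique_peptides < 0, na.rm = TRUE)) {
    stop("unique_peptides must be non-negative")
  }
  invisible(x)
}

#' @export
print.intensity_table <- function(x, ...) {
  g <- table(x$samples$group)
  cat(sprintf(
    "intensity_table: %d proteins x %d samples (%s)\n",
    nrow(x$intensities), ncol(x$intensities),
    paste(sprintf("%s: %d reps", names(g), as.integer(g)), collapse = ", ")
  ))
  if (length(x$log)) {
    cat("processing log:",
        paste(vapply(x$log, `[[`, "", "op"), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$intensities)

#' Group labels of an intensity table
#' @param x An `intensity_table`.
#' @return Character vector of unique group labels, in sample-sheet order.
#' @export
table_groups <- function(x) unique(x$samples$group)

#' Extract the SPI sub-matrix of one group
#'
#' @param x An `intensity_table`.
#' @param group A group label present in `table_groups(x)`.
#' @return Numeric matrix (proteins x replicates of `group`), replicate order.
#' @export
spi_matrix <- function(x, group) {
  keep <- x$samples$group == group
  if (!any(keep)) stop("unknown group label: ", group)
  m <- x$intensities[, keep, drop = FALSE]
  m[, order(x$samples$replicate[keep]), drop = FALSE]
}

#' @rdname intensity_table
#' @param x An `intensity_table`.
#' @export
protein_info <- function(x) tibble::as_tibble(x$proteins)

#' @rdname intensity_table
#' @export
sample_info <- function(x) tibble::as_tibble(x$samples)

# subset rows, keeping metadata aligned and the log intact
it_subset <- function(x, keep) {
  x$intensities <- x$intensities[keep, , drop = FALSE]
  x$proteins <- x$proteins[keep, , drop = FALSE]
  rownames(x$proteins) <- NULL
  x
}

# append an operation record to the audit log
it_log <- function(x, op, args = list(), ...) {
  x$log <- c(x$log, list(c(list(op = op, args = args), list(...))))
  x
}

#' Convert a generic-dialect wide data frame to an intensity table
#'
#' The generic dialect has columns `protein_id`, optionally `gene_name` and
#' `unique_peptides`, then one `<group>_<replicate>` column per sample (e.g.
#' `CL_1`, `CL_2`, `nCL_1`, ...). `NA` cells are missing; literal 0 is a
#' measured zero.
#'
#' @param df A data frame in the generic wide layout.
#' @return An `intensity_table`.
#' @export
as_intensity_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("protein_id", "gene_name", "unique_peptides",
                           "contaminant_flag", "cl_only"), names(df))
  if (!"protein_id" %in% meta_cols) stop("missing mandatory column: protein_id")
  int_cols <- setdiff(names(df), meta_cols)
  parsed <- regmatches(int_cols, regexec("^(.+)_([0-9]+)$", int_cols))
  bad <- int_cols[lengths(parsed) == 0]
  if (length(bad)) {
    stop("intensity columns must be named <group>_<replicate>; offending: ",
         paste(bad, collapse = ", "))
  }
  samples <- data.frame(
    sample_id = int_cols,
    group = vapply(parsed, `[`, "", 2),
    replicate = as.integer(vapply(parsed, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  check_replicate_layout(samples)
  proteins <- df[meta_cols]
  if (!is.null(proteins$unique_peptides)) {
    proteins$unique_peptides <- as.integer(proteins$unique_peptides)
  }
  intensity_table(as.matrix(df[int_cols]), proteins, samples)
}

# every group must carry replicates 1..k with no gaps, so that a missing
# column (e.g. CL_2 among CL_1, CL_3) is a format error naming the column
check_replicate_layout <- function(samples) {
  for (g in unique(samples$group)) {
    reps <- sort(samples$replicate[samples$group == g])
    expected <- seq_len(max(reps))
    gap <- setdiff(expected, reps)
    if (length(gap)) {
      stop("format error: missing intensity column ",
           paste(sprintf("%s_%d", g, gap), collapse = ", "))
    }
  }
  invisible(samples)
}

#' Flatten an intensity table to the generic wide layout
#'
#' Inverse of [as_intensity_table()]; used for writing generic-dialect TSVs.
#'
#' @param x An `intensity_table`.
#' @return A tibble in the generic wide layout.
#' @export
as_generic_frame <- function(x) {
  out <- x$proteins[c("protein_id", "gene_name", "unique_peptides")]
  m <- x$intensities
  colnames(m) <- sprintf("%s_%d", x$samples$group, x$samples$replicate)
  tibble::as_tibble(cbind(out, as.data.frame(m, optional = TRUE)))
}
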