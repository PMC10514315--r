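#' Read a protein-groups intensity table
#'
#' Reads per-protein sum peptide intensities (SPI) from a tab-separated
#' protein-groups file in either the MaxQuant `proteinGroups.txt` dialect or
#' the package's generic dialect.
#'
#' For the MaxQuant dialect the first accession of the semicolon-delimited
#' `Majority protein IDs` field becomes the primary `protein_id`, rows marked
#' `+` in `Potential contaminant` get `contaminant_flag = TRUE` (they are kept;
#' removal is a preprocessing step), and intensity cells equal to 0 are mapped
#' to missing, since MaxQuant writes 0 for "not detected". The generic dialect
#' keeps literal zeros and uses the `NA` token for missing cells.
#'
#' @param path Path to a TSV file.
#' @param dialect `"generic"` or `"maxquant"`.
#' @param channel_map For the MaxQuant dialect (and optionally for the generic
#'   one), a named list mapping a column-name regular expression to a
#'   `c(group, replicate)` pair, e.g.
#'   `list("^Intensity H 1$" = c("CL", 1), ...)`. Each pattern must match
#'   exactly one column.
#' @return An [intensity_table()].
#' @export
read_protein_groups <- function(path, dialect = c("generic", "maxquant"),
                                channel_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_guess()),
    na = c("NA", ""), progress = FALSE, show_col_types = FALSE
  ))
  if (dialect == "generic") {
    if (!is.null(channel_map)) check_channel_map_columns(df, channel_map)
    as_intensity_table(df)
  } else {
    read_maxquant(df, channel_map)
  }
}

check_channel_map_columns <- function(df, channel_map) {
  for (pat in names(channel_map)) {
    hits <- grep(pat, names(df), value = TRUE)
    if (length(hits) == 0) stop("format error: no column matches \"", pat, "\"")
    if (length(hits) > 1) {
      stop("channel_map pattern \"", pat, "\" matches several columns: ",
           paste(hits, collapse = ", "))
    }
  }
  invisible(df)
}

read_maxquant <- function(df, channel_map) {
  mandatory <- c("Majority protein IDs", "Unique peptides", "Potential contaminant")
  absent <- setdiff(mandatory, names(df))
  if (length(absent)) {
    stop("format error: missing mandatory column ", paste(absent, collapse = ", "))
  }
  if (is.null(channel_map)) {
    stop("the maxquant dialect requires a channel_map naming the intensity columns")
  }
  check_channel_map_columns(df, channel_map)
  ids <- sub(";.*$", "", df[["Majority protein IDs"]])
  if (anyDuplicated(ids)) {
    dup <- sort(unique(ids[duplicated(ids)]))
    stop("aggregation error: duplicate primary IDs after extraction: ",
         paste(dup, collapse = ", "))
  }
  cols <- vapply(names(channel_map),
                 function(pat) grep(pat, names(df), value = TRUE), "")
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  m[!is.na(m) & m == 0] <- NA_real_  # MaxQuant: 0 means not detected
  samples <- data.frame(
    sample_id = sprintf("%s_%s",
                        vapply(channel_map, `[`, "", 1),
                        vapply(channel_map, `[`, "", 2)),
    group = vapply(channel_map, `[`, "", 1),
    replicate = as.integer(vapply(channel_map, `[`, "", 2)),
    stringsAsFactors = FALSE
  )
  contam <- !is.na(df[["Potential contaminant"]]) &
    df[["Potential contaminant"]] == "+"
  proteins <- data.frame(
    protein_id = ids,
    gene_name = if ("Gene names" %in% names(df)) {
      sub(";.*$", "", df[["Gene names"]])
    } else NA_character_,
    unique_peptides = as.integer(df[["Unique peptides"]]),
    contaminant_flag = contam,
    stringsAsFactors = FALSE
  )
  intensity_table(m, proteins, samples)
}

#' Read an annotation membership list
#'
#' One accession per line; blank lines are ignored and surrounding whitespace
#' is stripped. Membership lookups are case-exact.
#'
#' @param path Path to a plain-text file.
#' @param name Name of the annotation set (e.g. `"GO:RBP"`).
#' @return An object of class `annotation_set`: a list with `name` and the
#'   deduplicated character vector `members`.
#' @export
read_annotation_set <- function(path, name) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  members <- unique(lines)
  if (length(members) == 0) {
    warning("annotation set \"", name, "\" is empty")
  }
  message(sprintf("annotation set \"%s\": %d lines read, %d unique accessions",
                  name, length(lines), length(members)))
  annotation_set(name, members)
}

#' @rdname read_annotation_set
#' @param members Character vector of accessions.
#' @export
annotation_set <- function(name, members) {
  structure(list(name = name, members = unique(as.character(members))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set \"%s\": %d accessions\n", x$name, length(x$members)))
  invisible(x)
}

#' Write a per-protein result table as TSV
#'
#' Writes a single-header tab-separated UTF-8 file. Strings and integers
#' round-trip bit-identically through [readr::read_tsv()]; doubles round-trip
#' to full precision. A list of records must share one field schema.
#'
#' @param records A data frame, or a list of named lists/rows with identical
#'   names.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!is.list(records)) stop("records must be a data frame or list of records")
    if (length(records)) {
      schemas <- lapply(records, names)
      if (length(unique(vapply(schemas, paste, "", collapse = "\r"))) > 1) {
        stop("schema error: records have heterogeneous fields")
      }
      records <- do.call(rbind, lapply(records, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    } else {
      stop("cannot infer a schema from an empty list; pass a data frame")
    }
  }
  ok <- tryCatch({
    readr::write_tsv(records, path, na = "NA", progress = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e)))
  invisible(records)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, na = "NA", progress = FALSE, show_col_types = FALSE)
}
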