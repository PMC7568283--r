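#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
NULL

# Required columns and column types per on-disk table schema. Unknown
# columns are preserved as read.
table_schemas <- list(
  sample_metadata = list(
    required = c("sample_id", "condition"),
    types = c(sample_id = "character", condition = "character",
              age_years = "numeric", sex = "character",
              postmortem_delay_hours = "numeric", braak_stage = "integer")
  ),
  de_table = list(
    required = c("gene", "cell_type", "log2fc", "raw_p", "adjusted_p",
                 "direction", "significant"),
    types = c(gene = "character", cell_type = "character",
              log2fc = "numeric", raw_p = "numeric", adjusted_p = "numeric",
              direction = "character", significant = "logical")
  ),
  external_de = list(
    required = c("gene"),
    types = c(gene = "character", effect = "numeric", adjusted_p = "numeric")
  )
)

#' Validate a sample metadata table
#'
#' Checks the condition labels and their consistency with Braak staging
#' when given: cases must have Braak stage >= 4 and controls <= 2, the
#' selection rule used when assembling the cohort.
#'
#' @param samples Data frame with at least `sample_id` and `condition`
#'   (`"AD"`/`"NC"`); optional `braak_stage` (integer 0-6).
#' @return The table, invisibly, or an error.
#' @export
validate_sample_metadata <- function(samples) {
  bad <- setdiff(unique(samples$condition), c("AD", "NC"))
  if (length(bad))
    stop("sample_metadata: condition must be AD or NC, found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample_metadata: duplicate sample_id", call. = FALSE)
  if ("braak_stage" %in% names(samples)) {
    b <- samples$braak_stage
    ok <- is.na(b) |
      (samples$condition == "AD" & b >= 4) |
      (samples$condition == "NC" & b <= 2)
    if (!all(ok))
      stop("sample_metadata: condition inconsistent with braak_stage ",
           "(AD requires Braak >= 4, NC requires Braak <= 2) for sample(s) ",
           paste(samples$sample_id[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

# Map common external-DE column aliases onto the canonical names.
normalize_external_columns <- function(df) {
  alias <- list(effect = c("effect", "log2fc", "logfc", "t", "t_statistic"),
                adjusted_p = c("adjusted_p", "adj_p", "padj", "adj_p_val"))
  for (canon in names(alias)) {
    if (canon %in% names(df)) next
    hit <- intersect(alias[[canon]], names(df))
    if (length(hit)) names(df)[match(hit[1], names(df))] <- canon
  }
  df
}

#' Read a typed pipeline table
#'
#' Reads a CSV/TSV with header (delimiter inferred from the extension) and
#' validates it against one of the pipeline's schemas. Unknown columns are
#' preserved; required columns are type-coerced and checked.
#'
#' @param path File path (`.csv` or `.tsv`, optionally `.gz`).
#' @param schema_name One of `"sample_metadata"`, `"de_table"`,
#'   `"external_de"`.
#' @return A tibble.
#' @export
read_table <- function(path, schema_name = c("sample_metadata", "de_table",
                                             "external_de")) {
  schema_name <- match.arg(schema_name)
  schema <- table_schemas[[schema_name]]
  delim <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (schema_name == "external_de") df <- normalize_external_columns(df)
  missing <- setdiff(schema$required, names(df))
  if (length(missing))
    stop("schema '", schema_name, "': missing required column(s) ",
         paste(missing, collapse = ", "), " in ", path, call. = FALSE)
  for (col in intersect(names(schema$types), names(df))) {
    df[[col]] <- switch(schema$types[[col]],
                        character = as.character(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        integer = as.integer(df[[col]]),
                        logical = as.logical(df[[col]]))
  }
  if (schema_name == "sample_metadata") validate_sample_metadata(df)
  if (schema_name == "external_de" && !all(c("effect", "adjusted_p") %in%
                                           names(df)))
    stop("schema 'external_de': need an effect column (effect/log2fc/t) ",
         "and an adjusted p column (adjusted_p/adj_p/padj)", call. = FALSE)
  df
}

#' Write a pipeline table
#'
#' CSV with header; numeric columns are printed with full (round-trip
#' faithful) precision so write-then-read is the identity.
#'
#' @param df Data frame.
#' @param path Output `.csv` (or `.tsv`) path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
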