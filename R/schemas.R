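## Declared TSV schemas for every tabular artifact the pipeline reads or
## writes.  Types: c = character, i = integer, d = double, l = logical.

edit_schemas <- list(
  mature_annotation = c(
    mature_id = "c", hairpin_id = "c", start = "i", end = "i", arm = "c"
  ),
  design = c(sample_id = "c", group = "c"),
  position_counts = c(
    sample_id = "c", mature_id = "c", position = "i", ref_base = "c",
    A = "i", C = "i", G = "i", U = "i"
  ),
  sites = c(
    mature_id = "c", position = "i", ref_base = "c", alt_base = "c",
    sample_id = "c", k = "i", n = "i", level = "d", p_error = "d",
    is_adar = "l", retained = "l"
  ),
  matrix_long = c(
    mature_id = "c", position = "i", sample_id = "c",
    k = "i", n = "i", level = "d"
  ),
  differential = c(
    mature_id = "c", position = "i", mean_group1 = "d", mean_group2 = "d",
    delta = "d", welch_t = "d", welch_df = "d", p_raw = "d", p_bh = "d",
    significant = "l", untestable = "l"
  ),
  residuals = c(
    sample_id = "c", edited_t = "d", total_t = "d",
    fitted = "d", residual = "d"
  ),
  site_matches = c(
    isomir = "c", utr_id = "c", start = "i", site_type = "c"
  ),
  pool_comparison = c(
    n_targets_a = "i", n_targets_b = "i", n_shared = "i", n_union = "i",
    shared_fraction = "d", shared_pct_a = "d", shared_pct_b = "d"
  ),
  motif_counts = c(
    trinucleotide = "c", n_edited = "i", n_background = "i"
  ),
  ground_truth_sites = c(
    sample_id = "c", mature_id = "c", position = "i",
    true_fraction = "d", true_edited = "i", total = "i"
  ),
  ground_truth_reads = c(
    sample_id = "c", mature_id = "c", n_reads = "i"
  )
)

schema_cols <- function(schema) {
  sch <- edit_schemas[[schema]]
  if (is.null(sch)) {
    abort(sprintf(
      "unknown schema '%s'; available: %s",
      schema, paste(names(edit_schemas), collapse = ", ")
    ))
  }
  sch
}

#' Write a pipeline table with schema validation
#'
#' Writes a tab-separated UTF-8 file with a header row.  The data frame must
#' carry every column the named schema declares, with compatible types;
#' columns are reordered to the schema and floats are written at full
#' precision so a write/read round trip reproduces values.
#'
#' @param x Data frame conforming to the schema.
#' @param path Output path.
#' @param schema One of `names(miredit:::edit_schemas)`, e.g.
#'   `"position_counts"`, `"sites"`, `"differential"`.
#' @return `path`, invisibly.
#' @seealso [read_table_checked()]
#' @export
write_table_checked <- function(x, path, schema) {
  sch <- schema_cols(schema)
  missing_cols <- setdiff(names(sch), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "table does not conform to schema '%s': missing column(s) %s",
      schema, paste(missing_cols, collapse = ", ")
    ))
  }
  x <- dplyr::select(tibble::as_tibble(x), dplyr::all_of(names(sch)))
  for (col in names(sch)) {
    ok <- switch(sch[[col]],
      c = is.character(x[[col]]) || all(is.na(x[[col]])),
      i = is.numeric(x[[col]]),
      d = is.numeric(x[[col]]),
      l = is.logical(x[[col]])
    )
    if (!ok) {
      abort(sprintf("column '%s' has the wrong type for schema '%s'", col, schema))
    }
    if (sch[[col]] == "i") x[[col]] <- as.integer(round(x[[col]]))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline table written by [write_table_checked()]
#'
#' @param path Path to a TSV file.
#' @param schema Schema name, as for [write_table_checked()].
#' @return A tibble with the schema's columns and types.
#' @export
read_table_checked <- function(path, schema) {
  sch <- schema_cols(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- do.call(readr::cols, as.list(sch))
  x <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  missing_cols <- setdiff(names(sch), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "'%s' does not conform to schema '%s': missing column(s) %s",
      path, schema, paste(missing_cols, collapse = ", ")
    ))
  }
  dplyr::select(x, dplyr::all_of(names(sch)))
}
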