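## FASTA/FASTQ readers and writers.  Parsing is delegated to Biostrings;
## this layer normalizes to the RNA alphabet and enforces the pipeline's
## validity rules (unique ids, non-empty records, restricted alphabet for
## references).

#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased and `T` is converted to `U`; record ids are the
#' first whitespace-delimited token of the header.  Reference sequences
#' (hairpins, UTRs) must be strictly `{A,C,G,U}`; set `allow_ambiguous` when
#' reading read sets that may carry `N`s.
#'
#' @param path Path to a FASTA file (gzip accepted).
#' @param allow_ambiguous Permit IUPAC ambiguity codes (e.g. `N`) in the
#'   sequences.  Default `FALSE`: ambiguity codes are rejected, the behaviour
#'   wanted for references.
#' @return A tibble with columns `id`, `sequence`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">h1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)))
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_rna(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    abort(sprintf(
      "empty FASTA record '%s' (record %d) in '%s'",
      ids[empty[1]], empty[1], path
    ))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated FASTA id(s) in '%s': %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  allow <- if (allow_ambiguous) "ACGUNRYSWKMBDHV" else "ACGU"
  check_rna(seqs, sprintf("FASTA sequence in '%s'", path), allow = allow)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Read a FASTQ file into a tibble
#'
#' Four-line FASTQ records, plain or gzip.  Sequences are normalized as in
#' [read_fasta()] (RNA alphabet, `N` tolerated); per-base quality strings are
#' carried verbatim but never used by the pipeline.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ## structural pre-validation: Biostrings silently repairs some malformed
  ## records (e.g. a quality string shorter than its sequence), so the
  ## 4-line structure is checked here first
  con <- gzfile(path) # reads plain files too
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ in '%s': %d lines, not a multiple of 4",
                  path, length(lines)))
  }
  rec <- seq.int(1L, length(lines), by = 4L)
  if (any(substr(lines[rec], 1, 1) != "@") ||
      any(substr(lines[rec + 2L], 1, 1) != "+")) {
    abort(sprintf("malformed FASTQ in '%s': header lines out of place", path))
  }
  len_mismatch <- which(nchar(lines[rec + 1L]) != nchar(lines[rec + 3L]))
  if (length(len_mismatch) > 0) {
    i <- len_mismatch[1]
    abort(sprintf(
      "FASTQ record %d ('%s') in '%s': sequence length %d != quality length %d",
      i, sub("^@", "", sub("\\s.*$", "", lines[rec[i]])), path,
      nchar(lines[rec[i] + 1L]), nchar(lines[rec[i] + 3L])
    ))
  }
  parsed <- tryCatch(
    {
      set <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      list(ids = names(set), seqs = as.character(set),
           qual = as.character(S4Vectors::mcols(set)$qualities))
    },
    error = function(e) {
      abort(sprintf("malformed FASTQ in '%s': %s", path, conditionMessage(e)))
    }
  )
  seqs <- parsed$seqs
  qual <- parsed$qual
  if (any(!nzchar(seqs))) abort(sprintf("empty FASTQ record in '%s'", path))
  tibble::tibble(
    id = sub("\\s.*$", "", parsed$ids),
    sequence = unname(normalize_rna(seqs)),
    quality = unname(qual)
  )
}

#' Read and validate a mature-arm annotation table
#'
#' The table locates each mature miRNA on its parent hairpin, with 1-based
#' inclusive coordinates on the hairpin's 5'-to-3' axis.  Required columns:
#' `mature_id`, `hairpin_id`, `start`, `end`, `arm` (`5p` or `3p`).
#'
#' @param path Path to a TSV file with the columns above.
#' @param hairpins Optional hairpin tibble from [read_fasta()]; when given,
#'   coordinates are validated against hairpin lengths and `hairpin_id`s
#'   must exist.
#' @return A validated tibble of annotations.
#' @export
read_mature_table <- function(path, hairpins = NULL) {
  ann <- read_table_checked(path, "mature_annotation")
  validate_mature(ann, hairpins)
}

#' Validate mature-arm annotations against a hairpin reference
#'
#' @param ann Annotation tibble (`mature_id`, `hairpin_id`, `start`, `end`,
#'   `arm`).
#' @param hairpins Optional tibble with `id`, `sequence`.
#' @return `ann`, invisibly usable, after validation.
#' @export
validate_mature <- function(ann, hairpins = NULL) {
  ann <- tibble::as_tibble(ann)
  dup <- ann$mature_id[duplicated(ann$mature_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated mature_id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(ann$start)) || any(is.na(ann$end)) ||
      any(ann$start < 1L) || any(ann$start > ann$end)) {
    bad <- ann$mature_id[which(is.na(ann$start) | is.na(ann$end) |
                                 ann$start < 1L | ann$start > ann$end)[1]]
    abort(sprintf(
      "invalid coordinates for '%s': need 1 <= start <= end (1-based inclusive)",
      bad
    ))
  }
  if (!all(ann$arm %in% c("5p", "3p"))) {
    abort("column 'arm' must be '5p' or '3p'")
  }
  if (!is.null(hairpins)) {
    unknown <- setdiff(ann$hairpin_id, hairpins$id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown hairpin_id(s): %s", paste(unknown, collapse = ", ")))
    }
    len <- setNames(nchar(hairpins$sequence), hairpins$id)
    over <- ann$end > len[ann$hairpin_id]
    if (any(over)) {
      i <- which(over)[1]
      abort(sprintf(
        "'%s': end %d exceeds hairpin '%s' length %d",
        ann$mature_id[i], ann$end[i], ann$hairpin_id[i], len[[ann$hairpin_id[i]]]
      ))
    }
  }
  ann
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `id`, `sequence`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  lines <- as.vector(rbind(paste0(">", x$id), x$sequence))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Sequences are emitted in the DNA alphabet (`U` back-converted to `T`),
#' matching what sequencers produce; [read_fastq()] restores the RNA
#' alphabet on the way back in.
#'
#' @param x Tibble with columns `id`, `sequence` and optionally `quality`
#'   (defaults to a constant `I` string).
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x)) x$quality else strrep("I", nchar(x$sequence))
  lines <- as.vector(rbind(
    paste0("@", x$id), chartr("U", "T", x$sequence), "+", qual
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
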