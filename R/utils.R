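## Sequence utilities shared across the pipeline.  Everything internal works
## on the RNA alphabet {A,C,G,U}; DNA input is converted on the way in.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases the sequence and converts `T` to `U` (miRBase convention:
#' references and reads are handled internally as RNA).  Idempotent.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over the RNA alphabet (plus any ambiguity codes
#'   present in the input, which downstream steps treat as never-matching).
#' @examples
#' normalize_rna("acgt")
#' @export
normalize_rna <- function(x) {
  chartr("T", "U", toupper(as.character(x)))
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of sequences over `{A,C,G,U}` (DNA input is
#'   normalized first).
#' @return Character vector of reverse complements, RNA alphabet.
#' @examples
#' rna_revcomp("UCAUGGA")
#' @export
rna_revcomp <- function(x) {
  x <- normalize_rna(x)
  check_rna(x, "sequence")
  stringi::stri_reverse(chartr("ACGU", "UGCA", x))
}

## error unless all characters of x are within `allow`
check_rna <- function(x, what = "sequence", allow = "ACGU") {
  bad <- grepl(paste0("[^", allow, "]"), x)
  if (any(bad)) {
    offend <- unique(unlist(strsplit(gsub(paste0("[", allow, "]"), "", x[bad]), "")))
    abort(sprintf(
      "%s contains characters outside {%s}: %s",
      what, paste(strsplit(allow, "")[[1]], collapse = ","),
      paste(offend, collapse = ", ")
    ))
  }
  invisible(x)
}

## Per-position mismatch count between equal-length string vectors a and b.
## All elements must share one common length L (callers group by length).
str_mismatches <- function(a, b, L = nchar(a[1])) {
  out <- integer(length(a))
  for (j in seq_len(L)) {
    out <- out + (substr(a, j, j) != substr(b, j, j))
  }
  out
}

## single-base substitution, 1-based
sub_base_at <- function(sequence, position, base) {
  substr(sequence, position, position) <- base
  sequence
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

#' mature miR-376a-3p sequences
#'
#' The miRBase mature sequence of hsa-miR-376a-3p and its seed-edited form,
#' in which the adenosine at mature position +6 has been deaminated to
#' inosine (read as guanosine).  Useful as a worked example for the edit
#' localization and target-switch operations.
#'
#' @param edited If `TRUE`, return the +6 A-to-I edited form.
#' @return A length-1 character RNA sequence (21 nt).
#' @examples
#' infer_edit_site(mir376a_3p(), mir376a_3p(edited = TRUE))
#' @export
mir376a_3p <- function(edited = FALSE) {
  if (edited) "AUCAUGGAGGAAAAUCCACGU" else "AUCAUAGAGGAAAAUCCACGU"
}
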