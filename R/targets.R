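## Seed-edit target switching: edited vs non-edited isomiR sequences,
## canonical seed-match site patterns (8mer / 7mer-m8 / 7mer-A1, TargetScan
## conventions), 3'UTR scanning and target-pool comparison.

#' Apply an A-to-I edit to a mature sequence
#'
#' Replaces the adenosine at `position` with `G` (inosine is read as
#' guanosine); errors if the base at that position is not `A`.
#'
#' @param sequence Mature miRNA sequence (RNA or DNA alphabet).
#' @param position 1-based position of the edited adenosine.
#' @return The edited sequence.
#' @examples
#' apply_edit(mir376a_3p(), 6)
#' @export
apply_edit <- function(sequence, position) {
  s <- normalize_rna(sequence)
  if (!is_count(position) || position < 1 || position > nchar(s)) {
    abort("position must be inside the sequence")
  }
  b <- substr(s, position, position)
  if (b != "A") {
    abort(sprintf("base at position %d is '%s', not 'A'; cannot apply an A-to-I edit",
                  position, b))
  }
  sub_base_at(s, position, "G")
}

#' Locate the single A-to-G difference between two isomiRs
#'
#' @param unedited,edited Equal-length mature sequences expected to differ
#'   at exactly one position, with `A` in `unedited` and `G` in `edited`.
#' @return The 1-based edit position.
#' @examples
#' infer_edit_site(mir376a_3p(), mir376a_3p(edited = TRUE))
#' @export
infer_edit_site <- function(unedited, edited) {
  a <- normalize_rna(unedited)
  b <- normalize_rna(edited)
  if (nchar(a) != nchar(b)) abort("sequences differ in length")
  diff <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diff) != 1) {
    abort(sprintf("sequences differ at %d positions; expected exactly 1", length(diff)))
  }
  if (substr(a, diff, diff) != "A" || substr(b, diff, diff) != "G") {
    abort(sprintf("difference at position %d is %s->%s, not A->G",
                  diff, substr(a, diff, diff), substr(b, diff, diff)))
  }
  diff
}

#' Seed region of a mature miRNA
#'
#' Positions 2-8, the primary determinant of target recognition.
#'
#' @param sequence Mature sequence of length at least 8.
#' @return The 7-nt seed.
#' @examples
#' seed_of(mir376a_3p(edited = TRUE))
#' @export
seed_of <- function(sequence) {
  s <- normalize_rna(sequence)
  if (nchar(s) < 8) abort("sequence must be at least 8 nt to have a seed")
  substr(s, 2, 8)
}

#' Canonical seed-match site patterns
#'
#' Target-site strings a UTR must contain, per TargetScan conventions:
#' `7mer-m8` is the reverse complement of miRNA positions 2-8; `8mer` is
#' the 7mer-m8 followed by `A`; `7mer-A1` is the reverse complement of
#' positions 2-7 followed by `A`.  The `A` opposite miRNA position 1 is a
#' literal adenosine in the UTR regardless of the miRNA's first base.
#'
#' @param seed 7-nt seed from [seed_of()].
#' @return Tibble with columns `site_type` (ordered strongest first:
#'   `8mer`, `7mer-m8`, `7mer-A1`) and `pattern`.
#' @examples
#' site_patterns(seed_of(mir376a_3p(edited = TRUE)))
#' @export
site_patterns <- function(seed) {
  seed <- normalize_rna(seed)
  if (nchar(seed) != 7) abort("seed must be exactly 7 nt")
  check_rna(seed, "seed")
  rc <- rna_revcomp(seed)
  tibble::tibble(
    site_type = c("8mer", "7mer-m8", "7mer-A1"),
    pattern = c(paste0(rc, "A"), rc, paste0(substr(rc, 2, 7), "A"))
  )
}

## all (possibly overlapping) occurrence starts of a fixed pattern
fixed_match_starts <- function(subject, pattern) {
  m <- stringi::stri_locate_all_fixed(subject, pattern, overlap = TRUE)[[1]]
  if (all(is.na(m[, 1]))) integer() else as.integer(m[, 1])
}

#' Scan 3'UTRs for canonical seed-match sites
#'
#' Finds every occurrence of the 8mer / 7mer-m8 / 7mer-A1 patterns in each
#' UTR.  Overlapping classifications at the same seed-match location are
#' resolved by the hierarchy 8mer > 7mer-m8 > 7mer-A1, so each location is
#' reported once with the strongest type (a 7mer-m8 that is part of an
#' 8mer, or a 7mer-A1 completing an 8mer, is not additionally reported).
#'
#' @param utrs Tibble with columns `id`, `sequence` (from [read_fasta()]),
#'   RNA or DNA alphabet.
#' @param patterns Pattern tibble from [site_patterns()].
#' @return Tibble with columns `utr_id`, `start` (1-based position of the
#'   reported pattern in the UTR) and `site_type`.
#' @export
scan_utr <- function(utrs, patterns) {
  utrs <- tibble::as_tibble(utrs)
  seqs <- normalize_rna(utrs$sequence)
  pat <- setNames(patterns$pattern, patterns$site_type)
  res <- purrr::map_dfr(seq_len(nrow(utrs)), function(i) {
    s <- seqs[i]
    hits <- purrr::map_dfr(names(pat), function(ty) {
      st <- fixed_match_starts(s, pat[[ty]])
      if (length(st) == 0) return(NULL)
      ## anchor = start of the seed 2-8 complementary core, shared across
      ## types so the hierarchy can deduplicate one physical location:
      ## 8mer and 7mer-m8 start at the core; the 7mer-A1 core sits one
      ## base to the left of its match start.
      anchor <- if (ty == "7mer-A1") st - 1L else st
      tibble::tibble(utr_id = utrs$id[i], start = st,
                     site_type = ty, anchor = anchor)
    })
    if (nrow(hits) == 0) return(NULL)
    hits$rank <- match(hits$site_type, c("8mer", "7mer-m8", "7mer-A1"))
    hits <- hits[order(hits$anchor, hits$rank), ]
    hits <- hits[!duplicated(hits$anchor), ]
    hits[, c("utr_id", "start", "site_type")]
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(utr_id = character(), start = integer(),
                          site_type = character()))
  }
  dplyr::arrange(res, .data$utr_id, .data$start)
}

#' Compare the target pools of two isomiRs
#'
#' A UTR is a target of an isomiR if it carries at least one accepted site
#' of any type.  Overlap is reported as the Jaccard shared fraction
#' (intersection over union) plus per-pool percentages, since either
#' denominator may be of interest.
#'
#' @param matches_a,matches_b Match tibbles from [scan_utr()] for the two
#'   isomiRs over the same UTR set.
#' @return Object of class `target_pool_comparison`: list with the two
#'   target-id sets, the shared ids, and a one-row `summary` tibble
#'   (`n_targets_a`, `n_targets_b`, `n_shared`, `n_union`,
#'   `shared_fraction`, `shared_pct_a`, `shared_pct_b`).
#' @export
compare_target_pools <- function(matches_a, matches_b) {
  ta <- unique(matches_a$utr_id)
  tb <- unique(matches_b$utr_id)
  shared <- intersect(ta, tb)
  un <- union(ta, tb)
  summary <- tibble::tibble(
    n_targets_a = length(ta),
    n_targets_b = length(tb),
    n_shared = length(shared),
    n_union = length(un),
    shared_fraction = if (length(un) > 0) length(shared) / length(un) else NA_real_,
    shared_pct_a = if (length(ta) > 0) 100 * length(shared) / length(ta) else NA_real_,
    shared_pct_b = if (length(tb) > 0) 100 * length(shared) / length(tb) else NA_real_
  )
  structure(
    list(targets_a = ta, targets_b = tb, shared = shared, summary = summary),
    class = "target_pool_comparison"
  )
}

#' @export
print.target_pool_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<target_pool_comparison> %d vs %d targets, %d shared (Jaccard %.1f%%; %.1f%% of A, %.1f%% of B)\n",
    s$n_targets_a, s$n_targets_b, s$n_shared, 100 * s$shared_fraction,
    s$shared_pct_a, s$shared_pct_b
  ))
  invisible(x)
}

#' @describeIn compare_target_pools `tidy()`: the one-row summary tibble.
#' @param x A `target_pool_comparison`.
#' @param ... Unused.
#' @export
tidy.target_pool_comparison <- function(x, ...) {
  x$summary
}

#' Quantify the target-pool switch caused by a seed edit
#'
#' Derives the edited isomiR from the non-edited mature sequence, builds
#' both sets of canonical site patterns, scans the UTR set with each, and
#' compares the target pools.
#'
#' @param mature_seq Non-edited mature sequence.
#' @param edit_pos 1-based position of the edited adenosine (must be inside
#'   the seed, positions 2-8, to change the seed match).
#' @param utrs UTR tibble (`id`, `sequence`).
#' @return A list of class `target_switch`: `isomirs` (tibble with the two
#'   sequences and their seeds), `patterns` (per-isomiR site patterns),
#'   `matches` (per-isomiR [scan_utr()] results) and `comparison`
#'   (a [compare_target_pools()] object, non-edited = pool A, edited =
#'   pool B).
#' @export
target_switch <- function(mature_seq, edit_pos, utrs) {
  non <- normalize_rna(mature_seq)
  ed <- apply_edit(non, edit_pos)
  isomirs <- tibble::tibble(
    isomir = c("non_edited", "edited"),
    sequence = c(non, ed),
    seed = c(seed_of(non), seed_of(ed))
  )
  pats <- dplyr::bind_rows(
    dplyr::mutate(site_patterns(isomirs$seed[1]), isomir = "non_edited"),
    dplyr::mutate(site_patterns(isomirs$seed[2]), isomir = "edited")
  )
  m_non <- scan_utr(utrs, dplyr::filter(pats, .data$isomir == "non_edited"))
  m_ed <- scan_utr(utrs, dplyr::filter(pats, .data$isomir == "edited"))
  structure(
    list(
      isomirs = isomirs,
      patterns = pats[, c("isomir", "site_type", "pattern")],
      matches = list(non_edited = m_non, edited = m_ed),
      comparison = compare_target_pools(m_non, m_ed)
    ),
    class = "target_switch"
  )
}

#' @export
print.target_switch <- function(x, ...) {
  cat(sprintf("<target_switch> edit at position %d: seed %s -> %s\n",
              infer_edit_site(x$isomirs$sequence[1], x$isomirs$sequence[2]),
              x$isomirs$seed[1], x$isomirs$seed[2]))
  print(x$comparison)
  invisible(x)
}
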