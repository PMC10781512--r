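## Adapter trimming, bounded-mismatch ungapped alignment of reads to
## hairpins, mature-arm assignment, and per-position base tallies.
##
## The aligner considers every ungapped placement of a read on the sense
## strand of every hairpin and keeps the placement(s) with the fewest
## mismatches, up to max_mismatch.  Candidate placements are found by a
## pigeonhole band lookup: a read split into (max_mismatch + 1) bands must
## match at least one band exactly at any placement within the mismatch
## budget, so exact band joins enumerate all admissible placements.

#' Alignment parameters
#'
#' @param max_mismatch Maximum mismatches allowed per read placement.
#' @param adapter Optional 3' adapter to trim before alignment.
#' @param min_overlap_adapter Minimum adapter prefix length that must match
#'   a read suffix for trimming to fire.
#' @param mature_5p_tolerance Maximum distance (nt) between a read's hairpin
#'   offset and the annotated mature start for mature-arm assignment.
#' @param min_read_length Reads shorter than this after trimming are
#'   discarded.
#' @return An `align_params` list.
#' @export
align_params <- function(max_mismatch = 2L,
                         adapter = NULL,
                         min_overlap_adapter = 6L,
                         mature_5p_tolerance = 2L,
                         min_read_length = 15L) {
  if (!is_count(max_mismatch)) abort("max_mismatch must be a non-negative integer")
  if (!is_count(min_overlap_adapter) || min_overlap_adapter < 1) {
    abort("min_overlap_adapter must be a positive integer")
  }
  if (!is_count(mature_5p_tolerance)) abort("mature_5p_tolerance must be non-negative")
  if (!is_count(min_read_length) || min_read_length < 1) {
    abort("min_read_length must be a positive integer")
  }
  if (!is.null(adapter)) {
    adapter <- normalize_rna(adapter)
    check_rna(adapter, "adapter")
  }
  structure(
    list(
      max_mismatch = as.integer(max_mismatch),
      adapter = adapter,
      min_overlap_adapter = as.integer(min_overlap_adapter),
      mature_5p_tolerance = as.integer(mature_5p_tolerance),
      min_read_length = as.integer(min_read_length)
    ),
    class = "align_params"
  )
}

#' Trim a 3' adapter from read sequences
#'
#' Removes the longest read suffix that exactly equals a prefix of the
#' adapter of length at least `min_overlap`; reads without such a suffix are
#' returned unchanged.
#'
#' @param sequence Character vector of read sequences.
#' @param adapter Adapter sequence (`NULL` returns the input, normalized).
#' @param min_overlap Minimum matching prefix length.
#' @return Character vector of trimmed sequences (RNA alphabet).
#' @examples
#' trim_adapter("AUCAUGGAGGUGGAAUUC", "UGGAAUUCUCGG")
#' @export
trim_adapter <- function(sequence, adapter, min_overlap = 6L) {
  x <- normalize_rna(sequence)
  if (is.null(adapter) || !nzchar(adapter)) return(x)
  adapter <- normalize_rna(adapter)
  nc <- nchar(x)
  best <- integer(length(x))
  for (k in seq.int(min_overlap, nchar(adapter))) {
    hit <- nc >= k & substr(x, nc - k + 1L, nc) == substr(adapter, 1L, k)
    best[hit] <- k
  }
  ifelse(best > 0L, substr(x, 1L, nc - best), x)
}

## split 1..L into nb near-equal bands -> tibble(s, e)
band_bounds <- function(L, nb) {
  cut <- floor(seq(0, L, length.out = nb + 1L))
  tibble::tibble(s = cut[-(nb + 1L)] + 1L, e = cut[-1L])
}

## Core: unique sequences of one common length -> best placements.
## Returns tibble(seq, status, hairpin_id, offset, n_mismatch).
align_unique_length <- function(useq, hairpins, max_mismatch) {
  L <- nchar(useq[1])
  hp <- dplyr::filter(hairpins, nchar(.data$sequence) >= L)
  none <- tibble::tibble(
    seq = useq, status = "unaligned",
    hairpin_id = NA_character_, offset = NA_integer_, n_mismatch = NA_integer_
  )
  if (nrow(hp) == 0) return(none)
  windows <- tidyr::unnest(
    tibble::tibble(
      hairpin_id = hp$id,
      hseq = hp$sequence,
      offset = lapply(nchar(hp$sequence), function(H) seq_len(H - L + 1L))
    ),
    cols = "offset"
  )
  bands <- band_bounds(L, max_mismatch + 1L)
  reads <- tibble::tibble(ui = seq_along(useq), seq = useq)
  cand <- dplyr::bind_rows(lapply(seq_len(nrow(bands)), function(b) {
    s <- bands$s[b]; e <- bands$e[b]
    wk <- dplyr::mutate(windows,
                        key = substr(.data$hseq, .data$offset + s - 1L,
                                     .data$offset + e - 1L))
    rk <- dplyr::mutate(reads, key = substr(.data$seq, s, e))
    dplyr::inner_join(rk, wk, by = "key", relationship = "many-to-many")
  }))
  if (nrow(cand) == 0) return(none)
  cand <- dplyr::distinct(cand, .data$ui, .data$hairpin_id, .data$offset,
                          .keep_all = TRUE)
  cand$n_mismatch <- str_mismatches(
    cand$seq, substr(cand$hseq, cand$offset, cand$offset + L - 1L), L
  )
  cand <- dplyr::filter(cand, .data$n_mismatch <= max_mismatch)
  if (nrow(cand) == 0) return(none)
  best <- cand |>
    dplyr::group_by(.data$ui) |>
    dplyr::filter(.data$n_mismatch == min(.data$n_mismatch)) |>
    dplyr::summarise(
      n_hp = dplyr::n_distinct(.data$hairpin_id),
      hairpin_id = .data$hairpin_id[which.min(.data$offset)],
      offset = min(.data$offset),
      n_mismatch = .data$n_mismatch[1],
      .groups = "drop"
    )
  out <- none
  out$status[best$ui] <- ifelse(best$n_hp > 1L, "ambiguous", "aligned")
  hit <- best$ui[best$n_hp == 1L]
  sel <- best$n_hp == 1L
  out$hairpin_id[hit] <- best$hairpin_id[sel]
  out$offset[hit] <- best$offset[sel]
  out$n_mismatch[hit] <- best$n_mismatch[sel]
  out
}

#' Align reads to hairpins (ungapped, bounded mismatches)
#'
#' Adapter-trims each read, discards reads shorter than
#' `params$min_read_length`, and assigns each remaining read to the ungapped
#' sense-strand placement with the fewest mismatches over all hairpins.
#' Ties across distinct hairpins make the read `ambiguous` (discarded
#' downstream); ties within one hairpin resolve to the smallest offset.
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally
#'   `sample_id`, `quality` (carried through; quality is trimmed with the
#'   sequence).
#' @param hairpins Reference tibble (`id`, `sequence`) from [read_fasta()].
#' @param params An [align_params()].
#' @return The input tibble plus columns `status` (`aligned`, `unaligned`,
#'   `ambiguous`, `too_short`), `hairpin_id`, `offset` (1-based hairpin
#'   coordinate of the read's first base) and `n_mismatch`; `sequence` is
#'   the trimmed sequence.
#' @export
align_reads <- function(reads, hairpins, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  reads <- tibble::as_tibble(reads)
  if (!all(c("id", "sequence") %in% names(reads))) {
    abort("reads need columns 'id' and 'sequence'")
  }
  check_rna(hairpins$sequence, "hairpin sequence")
  raw_len <- nchar(reads$sequence)
  seqs <- trim_adapter(reads$sequence, params$adapter, params$min_overlap_adapter)
  if ("quality" %in% names(reads)) {
    reads$quality <- substr(reads$quality, 1L, nchar(seqs))
  }
  reads$sequence <- seqs
  reads$status <- "unaligned"
  reads$hairpin_id <- NA_character_
  reads$offset <- NA_integer_
  reads$n_mismatch <- NA_integer_
  short <- nchar(seqs) < params$min_read_length
  reads$status[short] <- "too_short"
  todo <- which(!short)
  if (length(todo) == 0) return(reads)
  by_len <- split(todo, nchar(seqs[todo]))
  for (idx in by_len) {
    useq <- unique(seqs[idx])
    res <- align_unique_length(useq, hairpins, params$max_mismatch)
    m <- match(seqs[idx], res$seq)
    reads$status[idx] <- res$status[m]
    reads$hairpin_id[idx] <- res$hairpin_id[m]
    reads$offset[idx] <- res$offset[m]
    reads$n_mismatch[idx] <- res$n_mismatch[m]
  }
  reads
}

#' Assign aligned reads to mature arms
#'
#' A read is assigned to the mature arm whose annotated start lies within
#' `mature_5p_tolerance` of the read's hairpin offset and whose span covers
#' at least 90% of the read; reads matching no arm (e.g. loop-region reads)
#' get `mature_id` `NA`.
#'
#' @param alignments Output of [align_reads()].
#' @param mature Mature annotation tibble ([read_mature_table()]).
#' @param params An [align_params()].
#' @return `alignments` plus a `mature_id` column.
#' @export
assign_mature <- function(alignments, mature, params = align_params()) {
  alignments$mature_id <- NA_character_
  al <- which(alignments$status == "aligned")
  if (length(al) == 0) return(alignments)
  x <- alignments[al, c("hairpin_id", "offset", "sequence")]
  x$row <- al
  x$L <- nchar(x$sequence)
  cand <- dplyr::inner_join(x, mature, by = "hairpin_id",
                            relationship = "many-to-many")
  cand <- dplyr::mutate(
    cand,
    overlap = pmin(cand$end, cand$offset + cand$L - 1L) -
      pmax(cand$start, cand$offset) + 1L
  )
  cand <- dplyr::filter(
    cand,
    abs(.data$offset - .data$start) <= params$mature_5p_tolerance,
    .data$overlap >= 0.9 * .data$L
  )
  if (nrow(cand) == 0) return(alignments)
  best <- cand |>
    dplyr::group_by(.data$row) |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  alignments$mature_id[best$row] <- best$mature_id
  alignments
}

#' Tally observed bases per mature position
#'
#' Accumulates, for every (sample, mature miRNA, mature position), the
#' number of assigned reads showing each of A/C/G/U at that position.
#' Positions are 1-based mature coordinates (+1 = the mature 5' base).
#' Ambiguity codes in reads are never counted.
#'
#' @param assigned Output of [assign_mature()] (rows with `mature_id` `NA`
#'   are ignored).
#' @param hairpins Reference tibble (`id`, `sequence`).
#' @param mature Mature annotation tibble.
#' @return A tibble in the `position_counts` schema: `sample_id`,
#'   `mature_id`, `position`, `ref_base`, `A`, `C`, `G`, `U`.
#' @export
tally_positions <- function(assigned, hairpins, mature) {
  x <- dplyr::filter(assigned, !is.na(.data$mature_id))
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample1"
  if (nrow(x) == 0) return(edit_schema_tibble("position_counts"))
  x <- dplyr::inner_join(
    x, mature[, c("mature_id", "start", "end")], by = "mature_id"
  )
  L <- nchar(x$sequence)
  p1 <- pmax(1L, x$offset - x$start + 1L)
  p2 <- pmin(x$end - x$start + 1L, x$offset + L - 1L - x$start + 1L)
  npos <- pmax(0L, p2 - p1 + 1L)
  rows <- rep(seq_len(nrow(x)), npos)
  pos <- unlist(lapply(seq_len(nrow(x)), function(i) {
    if (npos[i] > 0) seq.int(p1[i], p2[i]) else integer()
  }))
  j <- (x$start[rows] + pos - 1L) - x$offset[rows] + 1L
  base <- substr(x$sequence[rows], j, j)
  long <- tibble::tibble(
    sample_id = x$sample_id[rows],
    mature_id = x$mature_id[rows],
    position = as.integer(pos),
    base = base
  )
  long <- dplyr::filter(long, .data$base %in% RNA_BASES)
  wide <- long |>
    dplyr::count(.data$sample_id, .data$mature_id, .data$position, .data$base) |>
    tidyr::pivot_wider(
      names_from = "base", values_from = "n", values_fill = 0L
    )
  for (b in RNA_BASES) if (!b %in% names(wide)) wide[[b]] <- 0L
  hp_seq <- setNames(hairpins$sequence, hairpins$id)
  ann <- mature[, c("mature_id", "hairpin_id", "start")]
  wide <- dplyr::left_join(wide, ann, by = "mature_id")
  wide$ref_base <- unname(substr(
    hp_seq[wide$hairpin_id],
    wide$start + wide$position - 1L, wide$start + wide$position - 1L
  ))
  dplyr::arrange(
    dplyr::select(
      wide, dplyr::all_of(names(schema_cols("position_counts")))
    ),
    .data$sample_id, .data$mature_id, .data$position
  )
}

#' Trim, align, assign and tally in one call
#'
#' Convenience wrapper running [trim_adapter()] (via [align_reads()]),
#' [assign_mature()] and [tally_positions()] over a read table that may
#' span several samples.
#'
#' @inheritParams align_reads
#' @inheritParams tally_positions
#' @param mature Mature annotation tibble.
#' @return A `position_counts` tibble.
#' @export
count_positions <- function(reads, hairpins, mature, params = align_params()) {
  al <- align_reads(reads, hairpins, params)
  al <- assign_mature(al, mature, params)
  tally_positions(al, hairpins, mature)
}
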