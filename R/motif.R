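## Trinucleotide context of edited adenosines vs the background of all
## adenosines in expressed mature miRNAs (ADAR substrate preference is for
## a U 5' and a G 3' of the edited A, i.e. the UAG triplet).

#' Trinucleotide context of a mature position
#'
#' Returns the bases flanking an adenosine in the *unedited* reference
#' (the ADAR substrate, not the edited read).  Terminal mature positions
#' are padded with the flanking hairpin base when hairpin context is
#' supplied, else with `-`.
#'
#' @param sequence Mature sequence.
#' @param position 1-based mature position; the base there must be `A`.
#' @param hairpin Optional hairpin sequence providing flanking context.
#' @param mature_start 1-based start of the mature on the hairpin
#'   (required with `hairpin`).
#' @return Three-character context string, e.g. `"UAG"`.
#' @examples
#' site_context(mir376a_3p(), 6)
#' @export
site_context <- function(sequence, position, hairpin = NULL, mature_start = NULL) {
  s <- normalize_rna(sequence)
  if (!is_count(position) || position < 1 || position > nchar(s)) {
    abort("position must be inside the mature sequence")
  }
  if (substr(s, position, position) != "A") {
    abort(sprintf("base at position %d is '%s', not 'A'",
                  position, substr(s, position, position)))
  }
  pad <- function(mature_pos) {
    if (mature_pos >= 1 && mature_pos <= nchar(s)) {
      return(substr(s, mature_pos, mature_pos))
    }
    if (!is.null(hairpin)) {
      if (is.null(mature_start)) abort("mature_start is required with hairpin context")
      hp <- normalize_rna(hairpin)
      hpos <- mature_start + mature_pos - 1L
      if (hpos >= 1 && hpos <= nchar(hp)) return(substr(hp, hpos, hpos))
    }
    "-"
  }
  paste0(pad(position - 1L), "A", pad(position + 1L))
}

#' Trinucleotide context table for edited sites
#'
#' Counts the X-A-Z context of every edited adenosine (using the unedited
#' reference base at the centre) against the background of all adenosines
#' in the expressed mature miRNAs, with hairpin bases padding mature
#' boundaries.  Optionally adds a per-motif two-sided Fisher exact
#' enrichment test (edited vs background membership), BH-adjusted - an
#' extra beyond the plain count ranking, off by default.
#'
#' @param sites Tibble of called sites; rows with `is_adar` and `retained`
#'   columns are filtered to retained A-to-G sites, otherwise all
#'   (`mature_id`, `position`) rows are used.  Deduplicated across samples.
#' @param hairpins Reference tibble (`id`, `sequence`).
#' @param mature Mature annotation tibble defining the expressed background
#'   set.
#' @param enrichment Add Fisher exact enrichment columns.
#' @return Tibble of class `motif_table`, sorted by edited count:
#'   `trinucleotide`, `n_edited`, `n_background`, and with
#'   `enrichment = TRUE` also `odds_ratio`, `p_fisher`, `p_bh`.
#' @export
motif_table <- function(sites, hairpins, mature, enrichment = FALSE) {
  x <- tibble::as_tibble(sites)
  if (all(c("is_adar", "retained") %in% names(x))) {
    x <- dplyr::filter(x, .data$is_adar, .data$retained)
  }
  x <- dplyr::distinct(x, .data$mature_id, .data$position)
  hp_seq <- setNames(hairpins$sequence, hairpins$id)
  ann <- mature
  ann$hp <- unname(hp_seq[ann$hairpin_id])

  context_at <- function(mature_id, position) {
    i <- match(mature_id, ann$mature_id)
    hpos <- ann$start[i] + position - 1L
    left <- ifelse(hpos - 1L >= 1L, substr(ann$hp[i], hpos - 1L, hpos - 1L), "-")
    right <- ifelse(hpos + 1L <= nchar(ann$hp[i]),
                    substr(ann$hp[i], hpos + 1L, hpos + 1L), "-")
    centre <- substr(ann$hp[i], hpos, hpos)
    bad <- centre != "A"
    if (any(bad)) {
      abort(sprintf("site %s:%d has reference base '%s', not 'A'",
                    mature_id[bad][1], position[bad][1], centre[bad][1]))
    }
    paste0(left, "A", right)
  }

  edited_ctx <- if (nrow(x) > 0) context_at(x$mature_id, x$position) else character()

  ## background: every adenosine in every expressed mature
  bg <- purrr::map_dfr(seq_len(nrow(ann)), function(i) {
    mseq <- substr(ann$hp[i], ann$start[i], ann$end[i])
    pos <- which(strsplit(mseq, "")[[1]] == "A")
    if (length(pos) == 0) return(NULL)
    tibble::tibble(mature_id = ann$mature_id[i], position = pos)
  })
  bg_ctx <- if (nrow(bg) > 0) context_at(bg$mature_id, bg$position) else character()

  tab <- dplyr::full_join(
    dplyr::count(tibble::tibble(trinucleotide = edited_ctx),
                 .data$trinucleotide, name = "n_edited"),
    dplyr::count(tibble::tibble(trinucleotide = bg_ctx),
                 .data$trinucleotide, name = "n_background"),
    by = "trinucleotide"
  )
  tab$n_edited[is.na(tab$n_edited)] <- 0L
  tab$n_background[is.na(tab$n_background)] <- 0L
  tab <- dplyr::arrange(tab, dplyr::desc(.data$n_edited),
                        dplyr::desc(.data$n_background), .data$trinucleotide)
  if (enrichment && nrow(tab) > 0) {
    tot_e <- sum(tab$n_edited)
    tot_b <- sum(tab$n_background)
    ft <- lapply(seq_len(nrow(tab)), function(i) {
      fisher.test(matrix(c(
        tab$n_edited[i], tot_e - tab$n_edited[i],
        tab$n_background[i], tot_b - tab$n_background[i]
      ), nrow = 2))
    })
    tab$odds_ratio <- vapply(ft, function(f) unname(f$estimate), numeric(1))
    tab$p_fisher <- vapply(ft, function(f) f$p.value, numeric(1))
    tab$p_bh <- bh_adjust(tab$p_fisher)
  }
  tibble::new_tibble(tab, class = "motif_table")
}
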