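## A-to-G editing-site calling from per-position base tallies: the editing
## level ratio, the binomial sequencing-error filter, the minimum
## edited-read and minimum mean-level filters, and the cross-sample
## editing-level matrix.

#' Site-calling filter parameters
#'
#' @param error_rate Assumed uniform per-base sequencing error rate `p`
#'   of the binomial error model.
#' @param error_alpha Upper-tail probability threshold: a sample supports a
#'   site when `P(X >= k) < error_alpha` for `X ~ Binomial(n, p)`.
#' @param min_edited_reads Minimum edited (A-to-G) read count; summed across
#'   samples by default, required per sample when
#'   `per_sample_min_edited = TRUE`.
#' @param min_mean_level Minimum mean editing level across all samples
#'   (groups pooled); sites below this are treated as biologically
#'   irrelevant low-level editing and dropped.
#' @param min_samples_pass Number of samples in which the binomial error
#'   filter must pass.
#' @param per_sample_min_edited Apply `min_edited_reads` within every
#'   covered sample instead of to the cross-sample sum.
#' @return A `site_filter_params` list.
#' @export
site_filter_params <- function(error_rate = 0.01,
                               error_alpha = 0.05,
                               min_edited_reads = 10L,
                               min_mean_level = 0.10,
                               min_samples_pass = 1L,
                               per_sample_min_edited = FALSE) {
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1) {
    abort("error_rate must be in (0, 1)")
  }
  if (!is.numeric(error_alpha) || error_alpha <= 0 || error_alpha > 1) {
    abort("error_alpha must be in (0, 1]")
  }
  if (!is_count(min_edited_reads)) abort("min_edited_reads must be a non-negative integer")
  if (!is.numeric(min_mean_level) || min_mean_level < 0 || min_mean_level > 1) {
    abort("min_mean_level must be in [0, 1]")
  }
  if (!is_count(min_samples_pass) || min_samples_pass < 1) {
    abort("min_samples_pass must be a positive integer")
  }
  structure(
    list(
      error_rate = error_rate,
      error_alpha = error_alpha,
      min_edited_reads = as.integer(min_edited_reads),
      min_mean_level = min_mean_level,
      min_samples_pass = as.integer(min_samples_pass),
      per_sample_min_edited = isTRUE(per_sample_min_edited)
    ),
    class = "site_filter_params"
  )
}

#' Editing level: edited reads over total coverage
#'
#' @param k Edited read counts.
#' @param n Total read counts covering the position.
#' @return `k / n`, with `NA` where `n == 0` (no information, not zero
#'   editing).  Errors if any `k > n`.
#' @examples
#' compute_editing_level(80, 100)
#' @export
compute_editing_level <- function(k, n) {
  if (any(k < 0 | n < 0, na.rm = TRUE)) abort("k and n must be non-negative")
  if (any(k > n, na.rm = TRUE)) abort("k must not exceed n")
  ifelse(n > 0, k / n, NA_real_)
}

#' Upper-tail binomial probability of the sequencing-error model
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`: the probability that sequencing
#' errors alone produce at least the observed number of mismatching reads.
#' Evaluated through the survival function, numerically stable for large
#' `n`.
#'
#' @param k Observed mismatching read counts.
#' @param n Total read counts.
#' @param p Per-base error rate, in (0, 1).
#' @return Vector of upper-tail probabilities.
#' @examples
#' binomial_error_pvalue(10, 100, 0.01)
#' @export
binomial_error_pvalue <- function(k, n, p = 0.01) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) abort("p must be in (0, 1)")
  if (any(k < 0 | n < 0, na.rm = TRUE)) abort("k and n must be non-negative")
  if (any(k > n, na.rm = TRUE)) abort("k must not exceed n")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Call A-to-G editing sites from position counts
#'
#' Emits one row per (candidate site, sample).  A candidate site is a
#' position whose reference base within the mature span is `A` (alternate
#' `G`); other mismatches with non-zero counts are reported too but flagged
#' `is_adar = FALSE` and never retained.  A candidate is `retained` when all
#' three filters hold: (i) the edited-read count reaches
#' `min_edited_reads` (summed across samples, or per sample if configured),
#' (ii) the binomial error tail probability is below `error_alpha` in at
#' least `min_samples_pass` samples, and (iii) the mean editing level
#' across all samples is at least `min_mean_level`.  The filters commute:
#' retention does not depend on the order they are applied in.
#'
#' @param counts `position_counts` tibble from [tally_positions()] or
#'   [simulate_position_counts()].
#' @param params A [site_filter_params()].
#' @param samples Optional character vector of all sample ids in the
#'   experiment; defaults to the samples present in `counts`.  Samples with
#'   no coverage at a site get `n = 0`, `level = NA`.
#' @return A tibble in the `sites` schema with per-site filter columns
#'   `pass_min_edited`, `pass_error`, `pass_level` as attributes-free
#'   ordinary columns.
#' @export
call_sites <- function(counts, params = site_filter_params(), samples = NULL) {
  stopifnot(inherits(params, "site_filter_params"))
  counts <- tibble::as_tibble(counts)
  samples <- samples %||% unique(counts$sample_id)

  long <- tidyr::pivot_longer(
    counts, cols = dplyr::all_of(RNA_BASES),
    names_to = "alt_base", values_to = "k"
  )
  long <- long |>
    dplyr::group_by(.data$sample_id, .data$mature_id, .data$position) |>
    dplyr::mutate(n = sum(.data$k)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$alt_base != .data$ref_base)

  ## A->G candidates: keep every sample row (even k = 0) so the matrix is
  ## complete; other substitutions only where observed (diagnostics).
  ag <- dplyr::filter(long, .data$ref_base == "A", .data$alt_base == "G")
  other <- dplyr::filter(long,
                         !(.data$ref_base == "A" & .data$alt_base == "G"),
                         .data$k > 0)

  ag <- tidyr::complete(
    ag,
    tidyr::nesting(!!!rlang::syms(c("mature_id", "position", "ref_base", "alt_base"))),
    sample_id = samples,
    fill = list(k = 0L, n = 0L)
  )

  x <- dplyr::bind_rows(
    dplyr::mutate(ag, is_adar = TRUE),
    dplyr::mutate(other, is_adar = FALSE)
  )
  x$level <- compute_editing_level(x$k, x$n)
  x$p_error <- ifelse(
    x$n > 0, binomial_error_pvalue(x$k, x$n, params$error_rate), 1
  )

  flags <- x |>
    dplyr::group_by(.data$mature_id, .data$position, .data$alt_base) |>
    dplyr::summarise(
      pass_min_edited = if (params$per_sample_min_edited) {
        all(.data$k[.data$n > 0] >= params$min_edited_reads) && any(.data$n > 0)
      } else {
        sum(.data$k) >= params$min_edited_reads
      },
      pass_error = sum(.data$p_error < params$error_alpha & .data$n > 0) >=
        params$min_samples_pass,
      pass_level = isTRUE(mean(.data$level, na.rm = TRUE) >= params$min_mean_level),
      .groups = "drop"
    )
  x <- dplyr::left_join(x, flags, by = c("mature_id", "position", "alt_base"))
  x$retained <- x$is_adar & x$pass_min_edited & x$pass_error & x$pass_level
  dplyr::arrange(
    dplyr::select(
      x, dplyr::all_of(names(schema_cols("sites"))),
      dplyr::all_of(c("pass_min_edited", "pass_error", "pass_level"))
    ),
    dplyr::desc(.data$is_adar), .data$mature_id, .data$position, .data$sample_id
  )
}

#' Assemble the cross-sample editing-level matrix
#'
#' Rows are retained A-to-G sites, columns are samples in design order;
#' cells are editing levels, with `NA` (not 0) where a sample has no
#' coverage.  The edited-read (`k`) and coverage (`n`) matrices are carried
#' alongside.
#'
#' @param sites Output of [call_sites()].
#' @param design Design tibble (`sample_id`, `group`), fixing column order.
#' @return An object of class `editing_matrix`: list with matrices `level`,
#'   `k`, `n` (rownames `"mature_id:position"`), the site metadata tibble
#'   `sites`, and `design`.
#' @export
build_matrix <- function(sites, design) {
  design <- tibble::as_tibble(design)
  if (!all(c("sample_id", "group") %in% names(design))) {
    abort("design needs columns 'sample_id' and 'group'")
  }
  x <- dplyr::filter(sites, .data$is_adar, .data$retained)
  extra <- setdiff(unique(x$sample_id), design$sample_id)
  if (length(extra) > 0) {
    abort(sprintf("sample(s) in sites but not in design: %s",
                  paste(extra, collapse = ", ")))
  }
  if (any(duplicated(x[, c("mature_id", "position", "sample_id")]))) {
    abort("duplicated (site, sample) rows in sites table")
  }
  site_meta <- dplyr::distinct(
    x, .data$mature_id, .data$position, .data$ref_base, .data$alt_base
  )
  site_meta <- dplyr::arrange(site_meta, .data$mature_id, .data$position)
  key <- function(m, p) paste0(m, ":", p)
  rn <- key(site_meta$mature_id, site_meta$position)
  mk <- function(values, fill) {
    out <- matrix(fill, nrow(site_meta), nrow(design),
                  dimnames = list(rn, design$sample_id))
    out[cbind(match(key(x$mature_id, x$position), rn),
              match(x$sample_id, design$sample_id))] <- values
    out
  }
  lev <- mk(x$level, NA_real_)
  kk <- mk(as.integer(x$k), 0L)
  nn <- mk(as.integer(x$n), 0L)
  structure(
    list(level = lev, k = kk, n = nn, sites = site_meta, design = design),
    class = "editing_matrix"
  )
}

#' Construct an editing matrix from count matrices
#'
#' Lower-level companion to [build_matrix()] for workflows that already
#' hold edited-read and coverage matrices (e.g. matrix-level simulation
#' studies): levels are computed as `k / n` with `NA` where `n = 0`.
#'
#' @param k,n Integer matrices (sites x samples) of edited-read counts and
#'   coverages; identical dimensions, rownames `"mature_id:position"`
#'   (generated when absent), colnames = sample ids.
#' @param design Design tibble (`sample_id`, `group`) covering all columns.
#' @return An `editing_matrix`.
#' @export
as_editing_matrix <- function(k, n, design) {
  k <- as.matrix(k)
  n <- as.matrix(n)
  if (!all(dim(k) == dim(n))) abort("k and n must have identical dimensions")
  if (any(k > n)) abort("k must not exceed n")
  if (is.null(rownames(k))) {
    rownames(k) <- sprintf("site-%03d:1", seq_len(nrow(k)))
  }
  rownames(n) <- rownames(k)
  design <- tibble::as_tibble(design)
  if (is.null(colnames(k))) {
    colnames(k) <- colnames(n) <- design$sample_id
  }
  if (!setequal(colnames(k), design$sample_id)) {
    abort("matrix columns must match design$sample_id")
  }
  key <- strsplit(rownames(k), ":", fixed = TRUE)
  sites <- tibble::tibble(
    mature_id = vapply(key, `[`, character(1), 1),
    position = as.integer(vapply(key, `[`, character(1), 2)),
    ref_base = "A", alt_base = "G"
  )
  lev <- ifelse(n > 0, k / n, NA_real_)
  dimnames(lev) <- dimnames(k)
  structure(
    list(level = lev, k = k, n = n, sites = sites, design = design),
    class = "editing_matrix"
  )
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf(
    "<editing_matrix> %d retained A-to-G site(s) x %d sample(s) [groups: %s]\n",
    nrow(x$level), ncol(x$level),
    paste(sprintf("%s=%d", names(table(x$design$group)),
                  as.integer(table(x$design$group))), collapse = ", ")
  ))
  if (nrow(x$level) > 0) {
    print(utils::head(round(x$level, 3), 5))
  }
  invisible(x)
}

#' @describeIn build_matrix `tidy()` method: the matrix in long form
#'   (`mature_id`, `position`, `sample_id`, `group`, `k`, `n`, `level`).
#' @param x An `editing_matrix`.
#' @param ... Unused.
#' @export
tidy.editing_matrix <- function(x, ...) {
  long <- tidyr::expand_grid(
    site = rownames(x$level), sample_id = colnames(x$level)
  )
  idx <- cbind(match(long$site, rownames(x$level)),
               match(long$sample_id, colnames(x$level)))
  meta <- x$sites[match(long$site, paste0(x$sites$mature_id, ":", x$sites$position)), ]
  tibble::tibble(
    mature_id = meta$mature_id,
    position = meta$position,
    sample_id = long$sample_id,
    group = x$design$group[match(long$sample_id, x$design$sample_id)],
    k = x$k[idx],
    n = x$n[idx],
    level = x$level[idx]
  )
}
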