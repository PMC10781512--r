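## Differential editing between two groups (Welch t + BH), abundance
## correlation residual diagnostics, median-of-ratios normalization and
## Spearman correlation utilities.

welch_core <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Welch two-sample t-test (unpaired, two-tailed)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom.  Degenerate inputs are resolved deterministically: when both
#' groups have zero variance and equal means the result is `t = 0, p = 1`;
#' zero variance in both groups with unequal means, or fewer than two
#' non-missing values in a group, is flagged `untestable` (no p-value)
#' rather than reported as an infinite statistic.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @return One-row tibble: `mean_x`, `mean_y`, `delta` (`mean_y - mean_x`),
#'   `welch_t`, `welch_df`, `p_value`, `n_x`, `n_y`, `untestable`.
#' @examples
#' welch_t_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  out <- tibble::tibble(
    mean_x = if (length(x)) mean(x) else NA_real_,
    mean_y = if (length(y)) mean(y) else NA_real_,
    delta = mean_y - mean_x,
    welch_t = NA_real_, welch_df = NA_real_, p_value = NA_real_,
    n_x = length(x), n_y = length(y), untestable = TRUE
  )
  if (length(x) < 2 || length(y) < 2) return(out)
  v1 <- var(x)
  v2 <- var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) {
      out$welch_t <- 0
      out$welch_df <- length(x) + length(y) - 2
      out$p_value <- 1
      out$untestable <- FALSE
    }
    return(out)
  }
  w <- welch_core(mean(x), mean(y), v1, v2, length(x), length(y))
  out$welch_t <- w$t
  out$welch_df <- w$df
  out$p_value <- w$p
  out$untestable <- FALSE
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Raw p-values in `(0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

## Row-wise Welch over a level matrix; groups is a logical vector (TRUE =
## group 1).  Returns a tibble aligned with rows of X.
welch_rows <- function(X, g1, g2) {
  X1 <- X[, g1, drop = FALSE]
  X2 <- X[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE)
  m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  untestable <- n1 < 2 | n2 < 2
  zerovar <- !untestable & v1 == 0 & v2 == 0
  degenerate_eq <- zerovar & m1 == m2
  untestable <- untestable | (zerovar & m1 != m2)
  ok <- !untestable & !zerovar
  t <- df <- p <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    w <- welch_core(m1[ok], m2[ok], v1[ok], v2[ok], n1[ok], n2[ok])
    t[ok] <- w$t
    df[ok] <- w$df
    p[ok] <- w$p
  }
  t[degenerate_eq] <- 0
  df[degenerate_eq] <- (n1 + n2 - 2)[degenerate_eq]
  p[degenerate_eq] <- 1
  tibble::tibble(
    mean_group1 = ifelse(n1 > 0, m1, NA_real_),
    mean_group2 = ifelse(n2 > 0, m2, NA_real_),
    delta = mean_group2 - mean_group1,
    welch_t = t, welch_df = df, p_raw = p,
    untestable = untestable
  )
}

#' Differential editing between two groups
#'
#' Runs a Welch t-test per retained site on the editing-level matrix and
#' applies Benjamini-Hochberg correction jointly across all testable sites
#' (sites flagged untestable are excluded from the BH family).
#'
#' @param x An `editing_matrix` from [build_matrix()].
#' @param design Two-group design tibble; defaults to the design stored in
#'   `x`.  Group 1 is the first group in design order.
#' @param alpha FDR threshold for the `significant` flag.
#' @return A tibble of class `edit_diff`, one row per site: `mature_id`,
#'   `position`, `mean_group1`, `mean_group2`, `delta`
#'   (group2 minus group1), `welch_t` (group1 minus group2 in the
#'   numerator), `welch_df`, `p_raw`, `p_bh`, `significant`, `untestable`.
#'   Attributes `groups` and `alpha` record the design.
#' @export
differential_editing <- function(x, design = x$design, alpha = 0.05) {
  stopifnot(inherits(x, "editing_matrix"))
  design <- tibble::as_tibble(design)
  missing_s <- setdiff(design$sample_id, colnames(x$level))
  if (length(missing_s) > 0) {
    abort(sprintf("design sample(s) not in matrix: %s",
                  paste(missing_s, collapse = ", ")))
  }
  groups <- unique(design$group)
  if (length(groups) != 2) abort("design must define exactly two groups")
  if (any(table(design$group) < 2)) abort("each group needs at least 2 samples")
  X <- x$level[, design$sample_id, drop = FALSE]
  res <- welch_rows(X, design$group == groups[1], design$group == groups[2])
  res <- dplyr::bind_cols(
    x$sites[, c("mature_id", "position")],
    res
  )
  res$p_bh <- NA_real_
  testable <- !res$untestable
  if (any(testable)) res$p_bh[testable] <- bh_adjust(res$p_raw[testable])
  res$significant <- !is.na(res$p_bh) & res$p_bh < alpha
  res <- res[, c("mature_id", "position", "mean_group1", "mean_group2",
                 "delta", "welch_t", "welch_df", "p_raw", "p_bh",
                 "significant", "untestable")]
  structure(
    tibble::new_tibble(res, class = "edit_diff"),
    groups = groups, alpha = alpha
  )
}

#' @describeIn differential_editing `tidy()`: the result as a plain tibble.
#' @param ... Unused.
#' @export
tidy.edit_diff <- function(x, ...) {
  tibble::as_tibble(unclass2tbl(x))
}

unclass2tbl <- function(x) {
  attr(x, "groups") <- NULL
  attr(x, "alpha") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @describeIn differential_editing `glance()`: one-row summary with the
#'   number of sites tested, number significant, and alpha.
#' @export
glance.edit_diff <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_tested = sum(!x$untestable),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    group1 = attr(x, "groups")[1],
    group2 = attr(x, "groups")[2]
  )
}

#' Abundance-correlation residual diagnostics
#'
#' Checks whether changes in a site's edited-form abundance merely track
#' the miRNA's overall abundance: fits an ordinary least-squares line of
#' edited abundance on total abundance (optionally on a log2(CPM + 1)
#' scale), reports the Pearson correlation and per-sample residuals.  A
#' perfectly proportional relationship gives residuals of exactly zero;
#' samples sitting away from the line carry editing changes not explained
#' by abundance.
#'
#' @param data Per-sample tibble.
#' @param edited,total Columns (tidy-eval) holding the edited-form and
#'   overall abundances.
#' @param transform `"log2_cpm_plus1"` (default) or `"linear"`.  CPM uses
#'   the `lib_size` column when given, otherwise values are taken as
#'   already library-normalized.
#' @param lib_size Optional column of per-sample library sizes.
#' @return An object of class `abundance_fit`: tibble with per-sample
#'   transformed values, fitted values and residuals (plus `sample_id` and
#'   `group` when present in `data`), with attributes `slope`, `intercept`,
#'   `pearson_r`, `transform`, `degenerate`.
#' @export
abundance_residuals <- function(data, edited, total,
                                transform = c("log2_cpm_plus1", "linear"),
                                lib_size = NULL) {
  transform <- match.arg(transform)
  e <- dplyr::pull(data, {{ edited }})
  t_ <- dplyr::pull(data, {{ total }})
  ls_quo <- rlang::enquo(lib_size)
  ls <- if (rlang::quo_is_null(ls_quo)) NULL else dplyr::pull(data, {{ lib_size }})
  keep <- !is.na(e) & !is.na(t_)
  if (sum(keep) < 3) abort("abundance_residuals needs at least 3 complete pairs")
  f <- switch(transform,
    linear = function(v) v,
    log2_cpm_plus1 = function(v) {
      cpm <- if (is.null(ls)) v else v / ls * 1e6
      log2(cpm + 1)
    }
  )
  xe <- f(e[keep])
  xt <- f(t_[keep])
  degenerate <- var(xt) == 0 || var(xe) == 0
  if (degenerate) {
    slope <- intercept <- r <- NA_real_
    fit_vals <- rep(mean(xe), length(xe))
  } else {
    fit <- lm(xe ~ xt)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r <- cor(xt, xe)
    fit_vals <- unname(fitted(fit))
  }
  out <- tibble::tibble(
    edited_t = xe, total_t = xt,
    fitted = fit_vals, residual = xe - fit_vals
  )
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id[keep]), out)
  }
  if ("group" %in% names(data)) out$group <- data$group[keep]
  structure(
    tibble::new_tibble(out, class = "abundance_fit"),
    slope = slope, intercept = intercept, pearson_r = r,
    transform = transform, degenerate = degenerate
  )
}

#' @describeIn abundance_residuals `tidy()`: per-sample table as a plain
#'   tibble.
#' @param x An `abundance_fit`.
#' @param ... Unused.
#' @export
tidy.abundance_fit <- function(x, ...) {
  out <- x
  for (a in c("slope", "intercept", "pearson_r", "transform", "degenerate")) {
    attr(out, a) <- NULL
  }
  class(out) <- c("tbl_df", "tbl", "data.frame")
  tibble::as_tibble(out)
}

#' @describeIn abundance_residuals `glance()`: slope, intercept, Pearson r,
#'   transform and degeneracy flag.
#' @export
glance.abundance_fit <- function(x, ...) {
  tibble::tibble(
    slope = attr(x, "slope"),
    intercept = attr(x, "intercept"),
    pearson_r = attr(x, "pearson_r"),
    n = nrow(x),
    transform = attr(x, "transform"),
    degenerate = attr(x, "degenerate")
  )
}

#' Median-of-ratios normalization
#'
#' Per-sample size factor = median, over genes with all-positive counts, of
#' the gene's count divided by the gene's geometric mean across samples;
#' normalized counts are the raw counts divided by the sample's factor.
#'
#' @param counts Numeric matrix (or all-numeric data frame), genes in rows,
#'   samples in columns, non-negative counts.
#' @return List with `normalized` (matrix) and `size_factors` (named
#'   vector).  Errors when no gene has all-positive counts.
#' @examples
#' m <- rbind(c(2, 4), c(4, 8), c(6, 12))
#' median_of_ratios_normalize(m)$size_factors
#' @export
median_of_ratios_normalize <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0, na.rm = TRUE)) {
    abort("counts must be a non-negative numeric matrix")
  }
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    abort("no gene has all-positive counts; size factors are undefined")
  }
  logm <- log(m[allpos, , drop = FALSE])
  geo <- exp(rowMeans(logm))
  sf <- apply(m[allpos, , drop = FALSE] / geo, 2, median)
  normalized <- sweep(m, 2, sf, "/")
  list(normalized = normalized, size_factors = sf)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y Paired numeric vectors with at least 3 complete pairs.
#' @return The rank correlation, or `NA` with a warning when either vector
#'   is constant (undefined).
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) abort("spearman_correlation needs at least 3 complete pairs")
  x <- x[keep]
  y <- y[keep]
  if (var(x) == 0 || var(y) == 0) {
    warning("rank correlation undefined: constant input")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
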