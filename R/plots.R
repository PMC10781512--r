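## ggplot2 displays for the pipeline's result types.

#' Plot per-sample editing levels of one site by group
#'
#' Points per sample with group mean and SEM bars - the standard display
#' for a differentially edited site.
#'
#' @param x An `editing_matrix`.
#' @param mature_id,position Site to plot; defaults to the first site in
#'   the matrix.
#' @return A ggplot object.
#' @export
plot_editing_levels <- function(x, mature_id = NULL, position = NULL) {
  stopifnot(inherits(x, "editing_matrix"))
  long <- tidy(x)
  if (is.null(mature_id)) {
    mature_id <- x$sites$mature_id[1]
    position <- x$sites$position[1]
  }
  d <- dplyr::filter(long, .data$mature_id == !!mature_id,
                     .data$position == !!position)
  if (nrow(d) == 0) abort("site not found in matrix")
  sm <- d |>
    dplyr::filter(!is.na(.data$level)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$level),
      sem = stats::sd(.data$level) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$level)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_errorbar(
      data = sm,
      ggplot2::aes(x = .data$group, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      inherit.aes = FALSE, width = 0.25
    ) +
    ggplot2::geom_point(
      data = sm, ggplot2::aes(x = .data$group, y = .data$mean),
      inherit.aes = FALSE, shape = 95, size = 8
    ) +
    ggplot2::labs(
      title = sprintf("%s (+%d)", mature_id, position),
      x = NULL, y = "editing level (edited / total reads)"
    ) +
    ggplot2::ylim(0, 1)
}

#' @describeIn differential_editing `autoplot()`: group-difference vs
#'   significance plot, coloured by the BH-significance flag.
#' @param object An `edit_diff`.
#' @export
autoplot.edit_diff <- function(object, ...) {
  d <- tidy(object)
  d <- dplyr::filter(d, !d$untestable)
  groups <- attr(object, "groups")
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$delta, y = -log10(.data$p_bh),
                    colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#C23B22")) +
    ggplot2::labs(
      x = sprintf("editing-level difference (%s - %s)", groups[2], groups[1]),
      y = expression(-log[10] ~ "BH-adjusted p"),
      colour = "significant"
    )
}

#' @describeIn abundance_residuals `autoplot()`: edited vs total abundance
#'   scatter with the least-squares line; residuals are vertical distances
#'   from the line.
#' @param object An `abundance_fit`.
#' @export
autoplot.abundance_fit <- function(object, ...) {
  d <- tidy(object)
  has_group <- "group" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$total_t, y = .data$edited_t))
  p <- if (has_group) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  lab <- if (attr(object, "transform") == "log2_cpm_plus1") {
    "log2(CPM + 1)"
  } else {
    "abundance"
  }
  p +
    ggplot2::geom_abline(slope = attr(object, "slope"),
                         intercept = attr(object, "intercept"),
                         linetype = "dashed", na.rm = TRUE) +
    ggplot2::labs(
      x = paste("total", lab), y = paste("edited-form", lab),
      subtitle = sprintf("Pearson r = %.3f", attr(object, "pearson_r"))
    )
}

#' Plot the trinucleotide context ranking of edited sites
#'
#' @param x A `motif_table`.
#' @param top Number of contexts to show.
#' @return A ggplot object.
#' @export
plot_motif_counts <- function(x, top = 10) {
  d <- utils::head(tibble::as_tibble(x), top)
  d$trinucleotide <- factor(d$trinucleotide, levels = rev(d$trinucleotide))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_edited, y = .data$trinucleotide)) +
    ggplot2::geom_col(fill = "#4A6FA5") +
    ggplot2::labs(x = "edited sites", y = "context (5'-XAZ-3')")
}
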