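#' Plot time-activity curves
#'
#' @param curves A `tac` table.
#' @param log_y Log-scale the activity axis?
#' @return A ggplot.
#' @export
plot_tac <- function(curves, log_y = FALSE) {
  p <- ggplot2::ggplot(as_tac(curves),
                       ggplot2::aes(.data$time_h, .data$activity_bq,
                                    colour = .data$organ)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after injection (h)", y = "organ activity (Bq)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.tac <- function(object, ...) plot_tac(object, ...)

#' Diverging bar chart of regulation counts
#'
#' Up counts plotted positive and down counts negative per condition — the
#' standard view of total transcript regulation across exposure conditions.
#'
#' @param summary Tibble from [de_summary()].
#' @return A ggplot.
#' @export
plot_de_counts <- function(summary) {
  long <- summary |>
    mutate(condition = factor(.data$condition, levels = .data$condition)) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    mutate(n = ifelse(.data$direction == "n_down", -.data$n, .data$n))
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(n_up = "#b2182b", n_down = "#2166ac"),
                               labels = c(n_up = "up", n_down = "down")) +
    ggplot2::labs(x = NULL, y = "significantly regulated transcripts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.de_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(sign(.data$fold_change) * log2(abs(.data$fold_change)),
                                  -log10(.data$p_adj), colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60")) +
    ggplot2::labs(title = attr(object, "condition"),
                  x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Fold-change trajectories of biomarker candidates
#'
#' @param screen A `biomarker_screen`.
#' @return A ggplot (empty panel if no candidates).
#' @export
plot_biomarker_trajectories <- function(screen) {
  traj <- attr(screen, "trajectories")
  if (is.null(traj) || !nrow(traj)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "no all-condition biomarker candidates"))
  }
  traj <- mutate(traj, condition = factor(.data$condition,
                                          levels = unique(.data$condition)))
  ggplot2::ggplot(traj, ggplot2::aes(.data$condition, .data$fold_change,
                                     group = .data$probe, colour = .data$gene)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "signed fold change", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.biomarker_screen <- function(object, ...) plot_biomarker_trajectories(object)

#' Heatmap of cellular-function response profiles
#'
#' Subcategory-by-condition tiles coloured by binned response intensity —
#' the categorized cellular-function profile view.
#'
#' @param pm Result of [profile_matrix()] (or its `long` component).
#' @return A ggplot.
#' @export
plot_profile_heatmap <- function(pm) {
  long <- if (is.data.frame(pm)) pm else pm$long
  pal <- c(none = "grey95", very_low = "#d4e6f1", low = "#a9cce3",
           medium = "#5499c7", high = "#2471a3", very_high = "#1a5276")
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$subcategory,
                                     fill = .data$bin)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::facet_grid(category ~ ., scales = "free_y", space = "free_y",
                        switch = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
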