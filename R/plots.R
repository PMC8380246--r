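#' Plot mean MADRS trajectories by response label
#'
#' Spaghetti plot of individual MADRS panels with class mean curves overlaid,
#' grouped by the rule-based response label.
#'
#' @param madrs MADRS tibble (as for [classify_response()]).
#' @param labels Output of [classify_response()] (computed if omitted).
#' @return A ggplot object.
#' @export
plot_madrs_trajectories <- function(madrs, labels = classify_response(madrs)) {
  long <- tidyr::pivot_longer(
    dplyr::left_join(madrs, labels[, c("subject_id", "label")],
                     by = "subject_id"),
    dplyr::starts_with("madrs_w"), names_to = "week", values_to = "madrs")
  long$week <- as.integer(sub("madrs_w", "", long$week))
  means <- dplyr::summarise(dplyr::group_by(long, .data$label, .data$week),
                            madrs = mean(.data$madrs), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$madrs,
                                     colour = .data$label)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.15) +
    ggplot2::geom_line(data = means, linewidth = 1.2) +
    ggplot2::geom_point(data = means, size = 2) +
    ggplot2::labs(x = "Week", y = "MADRS", colour = "Response") +
    ggplot2::theme_minimal()
}

#' @method autoplot kml_result
#' @export
autoplot.kml_result <- function(object, ...) {
  cen <- tibble::as_tibble(object$centroids, .name_repair = "minimal")
  names(cen) <- as.character(madrs_weeks)
  cen$cluster <- factor(seq_len(nrow(cen)))
  long <- tidyr::pivot_longer(cen, -"cluster", names_to = "week",
                              values_to = "madrs")
  long$week <- as.integer(long$week)
  ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$madrs,
                                     colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 1) + ggplot2::geom_point() +
    ggplot2::labs(title = paste0("Trajectory centroids (k = ",
                                 object$selected_k, ")"),
                  x = "Week", y = "MADRS") +
    ggplot2::theme_minimal()
}

#' @method autoplot screen_funnel
#' @export
autoplot.screen_funnel <- function(object, ...) {
  cts <- object$counts
  cts$stage <- factor(cts$stage, levels = cts$stage)
  ggplot2::ggplot(cts, ggplot2::aes(.data$stage, .data$n_remaining)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "RNAs remaining",
                  title = "Three-criterion selection funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot association_result
#' @export
autoplot.association_result <- function(object, ...) {
  tab <- object$table
  if (!nrow(tab)) stop("empty association table", call. = FALSE)
  ggplot2::ggplot(tab, ggplot2::aes(.data$rr, .data$gene)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$fdr < 0.05)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "Risk ratio per 1 SD of slope (log scale)", y = NULL,
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
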