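# ggplot2 graphics for profiles, diagrams, speciation and kinetics.

#' Plot a 1D SAXS profile
#'
#' Log-intensity versus q, optionally overlaying detected peak positions.
#'
#' @param object A `saxs_profile`.
#' @param peaks Optional `peak_list` from [detect_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saxs_profile
#' @export
autoplot.saxs_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$q, y = .data$intensity)) +
    geom_line() +
    scale_y_log10() +
    labs(x = expression(q ~ (nm^-1)), y = "intensity (a.u.)",
         title = attr(object, "label")) +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + geom_vline(xintercept = peaks$q, linetype = "dashed",
                        colour = "grey50")
  }
  p
}

#' Plot a phase diagram
#'
#' Buffer x pH tiles labelled by the assigned phase(s); coexisting phases in
#' one cell are joined with "+".
#'
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  cells <- object |>
    as_tibble() |>
    group_by(.data$buffer, .data$ph) |>
    summarise(phases = paste(sort(unique(.data$group_id)), collapse = "+"),
              .groups = "drop")
  ggplot(cells, aes(x = .data$buffer, y = .data$ph, fill = .data$phases)) +
    geom_tile(colour = "white") +
    labs(x = NULL, y = "pH", fill = "phase") +
    theme_minimal()
}

#' Plot buffer valency versus pH
#'
#' @param buffers Buffer names or definitions (default the three presets).
#' @param ph Grid of pH values.
#' @return A ggplot of mean valency curves.
#' @export
plot_mean_valency <- function(buffers = c("citrate", "phosphate", "acetate"),
                              ph = seq(2, 10, by = 0.05)) {
  data <- list_rbind(map(buffers, mean_valency, ph = ph))
  ggplot(data, aes(x = .data$ph, y = .data$valency,
                   colour = .data$buffer)) +
    geom_line() +
    labs(x = "pH", y = "mean valency |z|", colour = NULL) +
    theme_minimal()
}

#' Plot nearest-neighbor distance versus pH
#'
#' The analogue of a d_NN-vs-pH figure: one panel per buffer, point shape by
#' phase.
#'
#' @param diagram A `phase_diagram` or [dnn_vs_ph()] table.
#' @return A ggplot.
#' @export
plot_dnn_vs_ph <- function(diagram) {
  data <- dnn_vs_ph(diagram)
  ggplot(data, aes(x = .data$ph, y = .data$d_nn,
                   colour = .data$group_id, shape = .data$group_id)) +
    geom_point(size = 2) +
    facet_wrap(~buffer) +
    labs(x = "pH", y = expression(d[NN] ~ (nm)), colour = "phase",
         shape = "phase") +
    theme_minimal()
}

#' Plot single-cell expression trajectories
#'
#' Grey single-cell traces with the per-condition mean overlaid.
#'
#' @param data Trajectory tibble (`cell_id`, `condition`, `time_h`,
#'   `fluorescence`).
#' @param max_cells Cap on plotted single-cell traces per condition
#'   (default 50).
#' @return A ggplot.
#' @export
plot_trajectories <- function(data, max_cells = 50) {
  check_columns(data, c("cell_id", "time_h", "fluorescence"), "data")
  if (!"condition" %in% names(data)) data$condition <- "all"
  keep_cells <- data |>
    distinct(.data$condition, .data$cell_id) |>
    group_by(.data$condition) |>
    dplyr::slice_head(n = max_cells) |>
    ungroup()
  traces <- dplyr::semi_join(data, keep_cells,
                             by = c("condition", "cell_id"))
  means <- data |>
    group_by(.data$condition, .data$time_h) |>
    summarise(fluorescence = mean(.data$fluorescence), .groups = "drop")
  ggplot(traces, aes(x = .data$time_h, y = .data$fluorescence)) +
    geom_line(aes(group = .data$cell_id), colour = "grey70",
              linewidth = 0.2) +
    geom_line(data = means, aes(colour = .data$condition),
              linewidth = 1) +
    facet_wrap(~condition) +
    labs(x = "time (h)", y = "fluorescence (a.u.)", colour = NULL) +
    theme_minimal()
}

#' Plot per-condition efficiency summaries
#'
#' Relative efficiency (AUC, normalised to the reference) against mean onset
#' time with standard-error bars.
#'
#' @param summaries Output of [relative_efficiency()].
#' @return A ggplot.
#' @export
plot_condition_summary <- function(summaries) {
  check_columns(summaries,
                c("condition", "mean_onset", "relative_efficiency"),
                "summaries")
  ggplot(summaries, aes(x = .data$mean_onset,
                        y = .data$relative_efficiency,
                        colour = .data$condition)) +
    geom_point(size = 3) +
    geom_errorbar(aes(ymin = .data$relative_efficiency -
                        .data$sem_auc / .data$mean_auc *
                        .data$relative_efficiency,
                      ymax = .data$relative_efficiency +
                        .data$sem_auc / .data$mean_auc *
                        .data$relative_efficiency),
                  width = 0.05) +
    labs(x = "mean onset (h)", y = "relative efficiency (AUC)",
         colour = NULL) +
    theme_minimal()
}
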