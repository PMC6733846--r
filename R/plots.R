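#' Plot a peri-event time histogram
#'
#' @param object A [build_peth()] object.
#' @param limits Optional [baseline_limits()] drawn as horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.peth <- function(object, limits = NULL, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$time_ms, y = .data$count)) +
    geom_col(width = object$bin_width, fill = "grey30") +
    labs(x = "Time from stimulus (ms)", y = "Spikes per bin") +
    theme_minimal()
  if (!is.null(limits)) {
    p <- p + geom_hline(yintercept = c(limits$lower, limits$upper),
                        linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot PCA population trajectories
#'
#' Trajectories are drawn in the plane of the first two components, by
#' convention from 50 ms before to 2 s after the first stimulus; optional
#' stimulus states are overlaid as coloured points.
#'
#' @param object A pooled [pca_trajectories()] object.
#' @param states Optional [extract_stimulus_states()] tibble.
#' @param trim Window (s) of trajectory shown.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_trajectories <- function(object, states = NULL,
                                      trim = c(-0.05, 2), ...) {
  d <- tidy(object) |>
    filter(.data$time_s >= trim[1], .data$time_s <= trim[2])
  p <- ggplot(d, aes(x = .data$pc1, y = .data$pc2, group = .data$train_id)) +
    geom_path(alpha = 0.3, colour = "grey40") +
    labs(x = "PC1", y = "PC2") +
    theme_minimal()
  if (!is.null(states)) {
    p <- p + geom_point(data = states,
                        aes(x = .data$pc1, y = .data$pc2,
                            colour = factor(.data$stim_index)),
                        inherit.aes = FALSE, size = 1.5) +
      labs(colour = "Stimulus")
  }
  p
}

#' Plot observed vs randomised silhouette coefficients
#'
#' @param object A [silhouette_analysis()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.silhouette_analysis <- function(object, ...) {
  ggplot(object$random, aes(x = factor(.data$k), y = .data$mean_sc)) +
    geom_boxplot(fill = "grey85") +
    geom_hline(yintercept = object$observed_mean, colour = "firebrick") +
    annotate("text", x = 1, y = object$observed_mean, vjust = -0.5, hjust = 0,
             label = sprintf("observed (k = %d)", object$k_observed),
             colour = "firebrick", size = 3) +
    labs(x = "Random clusters (k)", y = "Mean silhouette coefficient") +
    theme_minimal()
}

#' Plot decoding accuracy against population size
#'
#' @param curve A [population_size_curve()] tibble (one or more conditions).
#' @param chance Chance accuracy drawn as a dashed line (1/60 by default).
#' @return A ggplot of medians with interquartile ribbons.
#' @export
plot_size_curve <- function(curve, chance = 1 / 60) {
  s <- summarise_size_curve(curve)
  ggplot(s, aes(x = .data$n_cells, y = .data$median,
                colour = .data$condition, fill = .data$condition)) +
    geom_ribbon(aes(ymin = .data$q25, ymax = .data$q75), alpha = 0.2,
                colour = NA) +
    geom_line() + geom_point(size = 1) +
    geom_hline(yintercept = chance, linetype = "dashed", colour = "grey40") +
    labs(x = "Number of cells", y = "Mean decoding accuracy") +
    theme_minimal()
}

#' Plot aligned trial trajectories of a session
#'
#' @param trials A `behavior_session` or long trace tibble.
#' @param goal_area,goal_time Entrance parameters (drawn as reference lines).
#' @return A ggplot of position traces with the goal area shaded.
#' @export
plot_session_trajectories <- function(trials, goal_area = 10, goal_time = 7) {
  trace <- as_behavior_trace(trials)
  ggplot(trace, aes(x = .data$time_s, y = .data$position_cm,
                    group = .data$trial_id)) +
    annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = goal_area,
             alpha = 0.15, fill = "seagreen") +
    geom_line(alpha = 0.25) +
    geom_vline(xintercept = goal_time, linetype = "dashed") +
    labs(x = "Time from treadmill onset (s)", y = "Position (cm from front wall)") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
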