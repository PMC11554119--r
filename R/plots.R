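#' @export
autoplot.design_matrix <- function(object, ...) {
  df <- as_tibble(unclass(object)) |>
    dplyr::mutate(frame = dplyr::row_number()) |>
    tidyr::pivot_longer(-"frame", names_to = "regressor")
  df$regressor <- factor(df$regressor, colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~regressor, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL)
}

#' @export
autoplot.behavior_summary <- function(object, measure = "mean_rt", ...) {
  cis <- within_subject_ci(object, measure)
  lev <- c("expected", "unexpected_same", "unexpected_diff")
  cis$condition3 <- factor(cis$condition3, intersect(lev, cis$condition3))
  ggplot2::ggplot(cis, ggplot2::aes(.data$condition3, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci_half,
                                        ymax = .data$mean + .data$ci_half),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = measure,
                  caption = "error bars: 95% within-subject CI")
}

#' Scatter of single-trial responses against surprise with the fitted slope
#'
#' @param betas A `trial_betas` stack.
#' @param surprise A `surprise` tibble.
#' @param voxels ROI voxel columns.
#' @return A ggplot.
#' @export
plot_surprise_scaling <- function(betas, surprise, voxels) {
  un <- betas$meta$condition == "unexpected"
  y <- rowMeans(betas$betas[un, voxels, drop = FALSE])
  z <- surprise$z[match(betas$meta$trial[un], surprise$trial)]
  ggplot2::ggplot(tibble(z = z, beta = y), ggplot2::aes(.data$z, .data$beta)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = sprintf("surprise (z, %s)", surprise$model_id[1]),
                  y = "single-trial response (ROI mean)")
}
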