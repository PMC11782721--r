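# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' Tidy a transfer table
#'
#' @param x A `transfer_table`.
#' @param ... Unused.
#' @return A plain tibble with columns `r1`, `uni`, `dsr`.
#' @export
tidy.transfer_table <- function(x, ...) {
  tibble::tibble(r1 = x$r1, uni = x$uni, dsr = x$dsr)
}

#' Summarize a transfer table
#'
#' @param x A `transfer_table`.
#' @param window R1 window used for the fold scan.
#' @param ... Unused.
#' @return One-row tibble: grid extent and step, B1 scale, fold count and
#'   bijectivity over `window`.
#' @export
glance.transfer_table <- function(x, window = c(0.2, 5), ...) {
  window <- c(max(window[1], min(x$r1)), min(window[2], max(x$r1)))
  fr <- find_folds(x, window)
  p <- attr(x, "protocol")
  tibble::tibble(
    n = nrow(x),
    r1_min = min(x$r1),
    r1_max = max(x$r1),
    dr1 = if (nrow(x) > 1) x$r1[2] - x$r1[1] else NA_real_,
    b1_scale = p$b1_scale,
    n_folds = length(fr$folds),
    bijective = fr$bijective
  )
}

#' Plot a transfer table
#'
#' Draws the UNI and DSR transfer curves against R1.
#'
#' @param object A `transfer_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transfer_table <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("uni", "dsr"), names_to = "contrast",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r1, y = .data$value,
                                   colour = .data$contrast)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(R[1] ~ (s^-1)), y = "contrast value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a fold report
#'
#' @param x A `fold_report`.
#' @param ... Unused.
#' @return Tibble with columns `fold_r1` and `grid_index` (empty if
#'   bijective).
#' @export
tidy.fold_report <- function(x, ...) {
  tibble::tibble(fold_r1 = x$folds, grid_index = x$grid_index)
}

#' Tidy a mapping result
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return Tibble with one row per voxel: `voxel`, `r1`, `distance`,
#'   `truncated`, `invalid`.
#' @export
tidy.mapping_result <- function(x, ...) {
  tibble::tibble(
    voxel = seq_along(x$r1),
    r1 = as.numeric(x$r1),
    distance = as.numeric(x$distance),
    truncated = as.logical(x$truncated),
    invalid = as.logical(x$invalid)
  )
}

#' Summarize a mapping result
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return One-row tibble of counts and R1 quantiles.
#' @export
glance.mapping_result <- function(x, ...) {
  r1 <- as.numeric(x$r1)
  tibble::tibble(
    method = x$method,
    n_voxels = length(r1),
    n_invalid = sum(x$invalid),
    n_truncated = sum(x$truncated, na.rm = TRUE),
    median_r1 = stats::median(r1, na.rm = TRUE),
    q25_r1 = stats::quantile(r1, 0.25, na.rm = TRUE, names = FALSE),
    q75_r1 = stats::quantile(r1, 0.75, na.rm = TRUE, names = FALSE)
  )
}

#' Summarize a bias curve
#'
#' @param x A `bias_curve`.
#' @param ... Unused.
#' @return Per-scale tibble with the maximum and root-mean-square absolute
#'   bias.
#' @export
glance.bias_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$b1_scale) |>
    dplyr::summarise(
      max_abs_bias = max(abs(.data$bias)),
      rms_bias = sqrt(mean(.data$bias^2)),
      .groups = "drop"
    )
}

#' Plot a bias curve
#'
#' @param object A `bias_curve`.
#' @param ... Unused.
#' @return A ggplot of bias against true R1, one line per transmit scale.
#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r1_true, y = .data$bias,
                               colour = factor(.data$b1_scale))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(true ~ R[1] ~ (s^-1)),
                  y = expression(R[1] ~ bias ~ (s^-1)),
                  colour = "B1+ scale") +
    ggplot2::theme_minimal()
}

#' Tidy cross-scaling statistics
#'
#' @param x A `cross_scaling_stats`.
#' @param ... Unused.
#' @return The per-tissue summary tibble.
#' @export
tidy.cross_scaling_stats <- function(x, ...) x$tissue

#' Tidy a variance study
#'
#' @param x A `variance_study`.
#' @param ... Unused.
#' @return Tibble with columns `manipulation_pct`, `tissue`, `mean_sd`.
#' @export
tidy.variance_study <- function(x, ...) x$tissue

#' Plot a variance study
#'
#' @param object A `variance_study`.
#' @param ... Unused.
#' @return A ggplot of tissue-mean R1 standard deviation against the
#'   flip-angle manipulation.
#' @export
autoplot.variance_study <- function(object, ...) {
  ggplot2::ggplot(object$tissue,
                  ggplot2::aes(x = .data$manipulation_pct, y = .data$mean_sd,
                               colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "flip-angle manipulation (%)",
                  y = expression(mean ~ R[1] ~ SD ~ (s^-1)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
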