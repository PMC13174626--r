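#' Tidy an evaluation into its per-threshold curve
#'
#' @param x A `funbench_eval`.
#' @param ... Unused.
#' @return The `eval_curve` tibble (`tau`, `pr_macro`, `rc_macro`,
#'   `pr_micro`, `rc_micro`, `ru`, `mi`, `m`) with identifying columns
#'   `method_id`, `aspect`, `setting`, `mode` prepended.
#' @exportS3Method generics::tidy
tidy.funbench_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method_id = x$method_id %||% NA_character_,
                   aspect = x$aspect, setting = x$setting, mode = x$mode),
    tibble::as_tibble(x$curve)
  )
}

#' One-row summary of an evaluation
#'
#' @param x A `funbench_eval`.
#' @param ... Unused.
#' @return One-row tibble: `team`, `model`, `method_id`, `aspect`,
#'   `setting`, `mode`, `n`, `fmax_macro`, `tau_macro`, `fmax_micro`,
#'   `tau_micro`, `smin`, `tau_smin`, `coverage`.
#' @exportS3Method generics::glance
glance.funbench_eval <- function(x, ...) {
  tibble::tibble(
    team = x$team %||% NA_character_, model = x$model %||% NA_integer_,
    method_id = x$method_id %||% NA_character_,
    aspect = x$aspect, setting = x$setting, mode = x$mode, n = x$n,
    fmax_macro = x$fmax_macro, tau_macro = x$tau_macro,
    fmax_micro = x$fmax_micro, tau_micro = x$tau_micro,
    smin = x$smin, tau_smin = x$tau_smin,
    coverage = x$coverage
  )
}

#' Plot precision-recall and ru-mi curves
#'
#' For an `eval_curve`: the macro and micro precision-recall curves (and,
#' when ia weights were supplied, the ru-mi curve) as two panels. For a
#' `funbench_eval` the same plot titled with the method and benchmark.
#'
#' @param object An `eval_curve` or `funbench_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_curve <- function(object, ...) {
  curve <- tibble::as_tibble(object)
  pr <- curve %>%
    tidyr::pivot_longer(
      c("pr_macro", "rc_macro", "pr_micro", "rc_micro"),
      names_to = c("quantity", "flavor"), names_sep = "_"
    ) %>%
    tidyr::pivot_wider(names_from = "quantity", values_from = "value")
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$rc, y = .data$pr,
                                   colour = .data$flavor)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eval_curve
#' @exportS3Method ggplot2::autoplot
autoplot.funbench_eval <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::labs(title = paste0(object$method_id %||% "method", " on ",
                                 object$aspect, "/", object$setting),
                  subtitle = sprintf("Fmax(M) %.3f | Fmax(u) %.3f%s",
                                     object$fmax_macro, object$fmax_micro,
                                     if (is.na(object$smin)) "" else
                                       sprintf(" | Smin %.3f", object$smin)))
}

#' Plot the ru-mi trade-off curve
#'
#' @param curve An `eval_curve` computed with ia weights.
#' @return A ggplot object; the dashed circle arc marks the Smin norm.
#' @export
plot_rumi <- function(curve) {
  tbl <- tibble::as_tibble(curve)
  s <- smin(curve)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$ru, y = .data$mi)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = tbl$ru[tbl$tau == s$tau][1],
                      y = tbl$mi[tbl$tau == s$tau][1],
                      shape = 1, size = 3) +
    ggplot2::labs(x = "remaining uncertainty (bits)",
                  y = "misinformation (bits)",
                  subtitle = sprintf("Smin = %.3f at tau = %.3g",
                                     s$smin, s$tau)) +
    ggplot2::theme_minimal()
}

#' Plot a leaderboard
#'
#' Dot-and-interval plot of a [rank_methods()] leaderboard; baselines are
#' drawn as open triangles.
#'
#' @param board Tibble from [rank_methods()].
#' @param metric Name of the metric column plotted (guessed from the board
#'   when `NULL`).
#' @return A ggplot object.
#' @export
plot_leaderboard <- function(board, metric = NULL) {
  metric <- metric %||%
    intersect(c("fmax_macro", "fmax_micro", "smin"), names(board))[1]
  board <- dplyr::mutate(
    board, label = paste0(.data$team, " (m", .data$model, ")")
  )
  ggplot2::ggplot(board, ggplot2::aes(
    x = .data[[metric]],
    y = stats::reorder(.data$label, .data[[metric]] *
                         if (metric == "smin") -1 else 1),
    shape = .data$is_baseline
  )) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                guide = "none") +
    ggplot2::labs(x = metric, y = NULL) +
    ggplot2::theme_minimal()
}
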