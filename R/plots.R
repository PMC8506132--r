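# ggplot2 figures for each result type.

#' Plot a Michaelis-Menten fit
#'
#' Observed initial velocities with the fitted saturation curve overlaid.
#'
#' @param object An `mm_fit`.
#' @param n_curve Points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, n_curve = 200, ...) {
  grid <- tibble(s_mM = seq(0, max(object$data$s_mM), length.out = n_curve))
  grid$v <- predict(object, grid$s_mM)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$s_mM, .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[S] (mM)", y = "v",
                  title = sprintf("Vmax = %.3g, KM = %.3g mM",
                                  object$Vmax, object$KM)) +
    ggplot2::theme_minimal()
}

#' Plot a coupled-assay progress curve
#'
#' Intermediate accumulation and the approach of the observed velocity ratio
#' v2/v1 to its steady state.
#'
#' @param curve Tibble from [simulate_coupled_assay()] or
#'   [gen_progress_curve()].
#' @param v1 Target velocity used to draw the v2/v1 ratio; when `NULL` only
#'   the intermediate is drawn.
#' @return A ggplot.
#' @export
plot_progress_curve <- function(curve, v1 = NULL) {
  check_columns(curve, c("t_min", "B_mM", "v2_mM_min"), "curve")
  if (is.null(v1)) {
    return(ggplot2::ggplot(curve, ggplot2::aes(.data$t_min, .data$B_mM)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "time (min)", y = "[B] (mM)") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(curve, ggplot2::aes(.data$t_min, .data$v2_mM_min / v1)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time (min)", y = "v2 / v1") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param rmsf_tbl Tibble from [rmsf()].
#' @return A ggplot, one panel per chain.
#' @export
plot_rmsf <- function(rmsf_tbl) {
  check_columns(rmsf_tbl, c("residue_seq", "rmsf"), "rmsf_tbl")
  p <- ggplot2::ggplot(rmsf_tbl,
                       ggplot2::aes(.data$residue_seq, .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
  if ("chain_id" %in% names(rmsf_tbl)) {
    p <- p + ggplot2::facet_wrap(~chain_id)
  }
  p
}

#' Plot an RMSD or Rg time series
#'
#' @param series Tibble with a `frame` column and one of `rmsd` / `rg`.
#' @return A ggplot.
#' @export
plot_series <- function(series) {
  ycol <- intersect(c("rmsd", "rg"), names(series))[1]
  if (is.na(ycol)) {
    abort("Expected an `rmsd` or `rg` column.",
          class = "halokin_invalid_parameter")
  }
  ggplot2::ggplot(series, ggplot2::aes(.data$frame, .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = paste0(toupper(ycol), " (Å)")) +
    ggplot2::theme_minimal()
}

#' Plot shell composition percentages
#'
#' Residue-type percentages per shell, the at-a-glance haloadaptation
#' comparison.
#'
#' @param composition A `shell_composition` from [shell_composition()].
#' @return A ggplot.
#' @export
plot_shell_composition <- function(composition) {
  stopifnot(inherits(composition, "shell_composition"))
  ggplot2::ggplot(composition$by_type,
                  ggplot2::aes(.data$residue_name, .data$pct,
                               fill = .data$shell)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue", y = "% of shell", fill = "shell") +
    ggplot2::theme_minimal()
}
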