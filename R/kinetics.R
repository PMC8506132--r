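# Michaelis-Menten kinetics: rate conversion, nonlinear fitting, efficiencies.

#' Convert an absorbance slope to a reaction velocity
#'
#' Converts the linear slope of an NADH absorbance trace at 340 nm into a
#' velocity via Beer-Lambert: `v = slope / (extinction * path)`. When the
#' enzyme mass concentration is supplied the specific activity is reported as
#' well (1 U = 1 umol product per minute, so a velocity of 1 mM/min in the
#' cuvette equals 1 U/ml).
#'
#' @param slope Absorbance change per minute (delta A340 / min). Vectorised.
#' @param extinction_mM_cm Molar extinction coefficient in mM^-1 cm^-1;
#'   defaults to 6.22 for NADH at 340 nm.
#' @param path_cm Optical path length in cm (default 1).
#' @param enzyme_mg_ml Optional enzyme mass concentration in mg/ml; when given
#'   specific activity in U/mg is included in the output.
#' @return A tibble with columns `slope`, `v_mM_min` (velocity, mM/min, equal
#'   to U/ml) and, when `enzyme_mg_ml` is supplied, `specific_activity_U_mg`.
#' @examples
#' rate_from_absorbance(0.0622)                      # 0.01 mM/min
#' rate_from_absorbance(0.622, enzyme_mg_ml = 0.001) # 100 U/mg
#' @export
rate_from_absorbance <- function(slope, extinction_mM_cm = 6.22, path_cm = 1,
                                 enzyme_mg_ml = NULL) {
  if (!is.numeric(slope) || any(!is.finite(slope))) {
    abort("`slope` must be finite numeric.", class = "halokin_invalid_parameter")
  }
  check_number(extinction_mM_cm, "extinction_mM_cm", positive = TRUE)
  check_number(path_cm, "path_cm", positive = TRUE)
  v <- slope / (extinction_mM_cm * path_cm)
  out <- tibble(slope = slope, v_mM_min = v)
  if (!is.null(enzyme_mg_ml)) {
    check_number(enzyme_mg_ml, "enzyme_mg_ml", positive = TRUE)
    # v [mM/min] == U/ml in the cuvette; dividing by mg/ml gives U/mg
    out$specific_activity_U_mg <- v / enzyme_mg_ml
  }
  out
}

#' Read a kinetics CSV
#'
#' Expects the header `condition,substrate,s_mM,v,replicate`; lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return A tibble with those five columns.
#' @export
read_kinetics_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  check_columns(df, c("condition", "substrate", "s_mM", "v", "replicate"),
                "kinetics csv")
  as_tibble(df)
}

mm_model <- function(s, Vmax, KM) Vmax * s / (KM + s)

validate_mm_data <- function(data) {
  check_columns(data, c("s_mM", "v"), "data")
  s <- data$s_mM
  v <- data$v
  if (any(!is.finite(s)) || any(!is.finite(v))) {
    abort("Concentrations and velocities must be finite.",
          class = "halokin_invalid_parameter")
  }
  if (any(s < 0)) {
    abort("Substrate concentrations must be >= 0.",
          class = "halokin_invalid_parameter")
  }
  if (any(v < 0)) {
    abort("Initial velocities must be >= 0 for saturation fitting.",
          class = "halokin_invalid_parameter")
  }
  if (length(unique(s)) < 3) {
    abort("At least 3 distinct substrate concentrations are required.",
          class = "halokin_invalid_parameter")
  }
  invisible(data)
}

#' Fit the Michaelis-Menten equation to initial velocities
#'
#' Unweighted nonlinear least squares of `v = Vmax * s / (KM + s)` by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]), initialised deterministically
#' at `Vmax0 = 1.2 * max(v)` and `KM0 =` the substrate concentration whose
#' velocity is closest to `Vmax0 / 2`, so fits are reproducible without random
#' restarts. Standard errors come from the linearised covariance at the
#' optimum; when a `replicate` column is present, per-replicate fits provide
#' an additional replicate-level SD of the estimates.
#'
#' @param data Data frame with columns `s_mM` (substrate concentration, mM)
#'   and `v` (initial velocity); optional `replicate`.
#' @param enzyme_M Optional enzyme molar concentration. When supplied,
#'   `kcat = Vmax / enzyme_M` is reported in s^-1, with `v` interpreted in
#'   mM/min (the assay's native unit).
#' @param v_unit Unit of `v`: `"mM_min"` (default) or `"per_s"` (already
#'   normalised per second). Only affects the kcat conversion.
#' @return An object of class `mm_fit`; see [tidy.mm_fit()], [glance.mm_fit()],
#'   [autoplot.mm_fit()].
#' @examples
#' d <- gen_mm_dataset(Vmax = 49.1, KM = 2.34,
#'                     s_values = c(0.5, 1, 2, 4, 8, 16, 30))
#' fit <- fit_michaelis_menten(d)
#' glance(fit)
#' @export
fit_michaelis_menten <- function(data, enzyme_M = NULL,
                                 v_unit = c("mM_min", "per_s")) {
  v_unit <- match.arg(v_unit)
  validate_mm_data(data)
  s <- data$s_mM
  v <- data$v
  if (all(v == 0)) {
    abort("Degenerate data: all velocities are zero; Vmax is unidentifiable.",
          class = "halokin_nonconvergence")
  }
  start <- mm_start(s, v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * s / (KM + s),
                      data = data.frame(s = s, v = v),
                      start = start,
                      lower = c(Vmax = 1e-12, KM = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("Michaelis-Menten fit did not converge: ",
                   conditionMessage(e)),
            class = "halokin_nonconvergence")
    }
  )
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, KM = NA_real_))
  # an essentially flat KM direction means the data carry no curvature
  if (!is.finite(est[["KM"]]) ||
      (is.finite(se[["KM"]]) && se[["KM"]] > 100 * abs(est[["KM"]]))) {
    abort(sprintf(
      "KM is unbounded by the data (KM = %.3g, SE = %.3g): no curvature in the design.",
      est[["KM"]], se[["KM"]]), class = "halokin_nonconvergence")
  }
  kcat <- NA_real_
  if (!is.null(enzyme_M)) {
    check_number(enzyme_M, "enzyme_M", positive = TRUE)
    vmax_M_s <- if (v_unit == "mM_min") est[["Vmax"]] * 1e-3 / 60 else est[["Vmax"]]
    kcat <- vmax_M_s / enzyme_M
  }
  rep_sd <- NULL
  if ("replicate" %in% names(data) &&
      length(unique(data$replicate)) > 1) {
    rep_sd <- replicate_fit_sd(data)
  }
  structure(
    list(fit = fit, data = as_tibble(data),
         Vmax = unname(est[["Vmax"]]), KM = unname(est[["KM"]]),
         se_Vmax = unname(se[["Vmax"]]), se_KM = unname(se[["KM"]]),
         kcat = kcat, enzyme_M = enzyme_M, v_unit = v_unit,
         replicate_sd = rep_sd, n_points = length(v)),
    class = "mm_fit")
}

mm_start <- function(s, v) {
  vmax0 <- 1.2 * max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- max(min(s[s > 0], na.rm = TRUE), 1e-3)
  list(Vmax = vmax0, KM = km0)
}

replicate_fit_sd <- function(data) {
  fits <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(d, key) {
      tryCatch({
        f <- minpack.lm::nlsLM(v ~ Vmax * s / (KM + s),
                               data = data.frame(s = d$s_mM, v = d$v),
                               start = mm_start(d$s_mM, d$v),
                               lower = c(Vmax = 1e-12, KM = 1e-12))
        as.list(stats::coef(f))
      }, error = function(e) NULL)
    })
  fits <- purrr::compact(fits)
  if (length(fits) < 2) return(NULL)
  tibble(term = c("Vmax", "KM"),
         replicate_sd = c(sd(purrr::map_dbl(fits, "Vmax")),
                          sd(purrr::map_dbl(fits, "KM"))),
         n_replicates = length(fits))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  Vmax = %.4g (SE %.3g)\n  KM   = %.4g mM (SE %.3g)\n",
              x$Vmax, x$se_Vmax, x$KM, x$se_KM))
  if (is.finite(x$kcat)) cat(sprintf("  kcat = %.4g s^-1\n", x$kcat))
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error` and,
#'   when replicates were fitted individually, `replicate_sd`.
#' @export
tidy.mm_fit <- function(x, ...) {
  out <- tibble(term = c("Vmax", "KM"),
                estimate = c(x$Vmax, x$KM),
                std.error = c(x$se_Vmax, x$se_KM))
  if (!is.null(x$replicate_sd)) {
    out <- dplyr::left_join(out, x$replicate_sd, by = "term")
  }
  out
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `Vmax`, `KM_mM`, `kcat_s`, their SEs,
#'   residual `sigma` and `n_points`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(Vmax = x$Vmax, se_Vmax = x$se_Vmax,
         KM_mM = x$KM, se_KM = x$se_KM,
         kcat_s = x$kcat,
         sigma = tryCatch(summary(x$fit)$sigma, error = function(e) NA_real_),
         n_points = x$n_points)
}

#' Fitted velocities on the observed grid
#'
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @return The input data with a `.fitted` column.
#' @export
augment.mm_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = mm_model(.data$s_mM, x$Vmax, x$KM))
}

#' Predicted Michaelis-Menten velocity
#'
#' @param object An `mm_fit` object.
#' @param s_mM Substrate concentrations (mM).
#' @param ... Unused.
#' @return Numeric velocities on the fitted curve.
#' @export
predict.mm_fit <- function(object, s_mM, ...) {
  mm_model(s_mM, object$Vmax, object$KM)
}

#' Catalytic efficiency kcat/KM
#'
#' The apparent second-order rate constant of the enzyme at sub-saturating
#' substrate, in M^-1 s^-1. Full precision is kept unless `sig_figs` is given;
#' published tables conventionally round to 2 significant figures.
#'
#' @param kcat Turnover number in s^-1 (vectorised).
#' @param KM_mM Michaelis constant in mM (vectorised).
#' @param sig_figs Optional number of significant figures for reporting.
#' @return Efficiency in M^-1 s^-1.
#' @examples
#' catalytic_efficiency(14.8, 3.31, sig_figs = 2) # 4500
#' @export
catalytic_efficiency <- function(kcat, KM_mM, sig_figs = NULL) {
  if (!is.numeric(kcat) || !is.numeric(KM_mM)) {
    abort("`kcat` and `KM_mM` must be numeric.",
          class = "halokin_invalid_parameter")
  }
  if (any(KM_mM <= 0)) {
    abort("`KM_mM` must be > 0.", class = "halokin_invalid_parameter")
  }
  eff <- kcat / (KM_mM * 1e-3)
  if (!is.null(sig_figs)) eff <- signif(eff, sig_figs)
  eff
}

#' Normalize activities to a reference condition
#'
#' Expresses activities as a percentage of a chosen reference condition, the
#' convention used for salt-activity profiles (e.g. the activity at 2.0 M KCl
#' taken as 100%).
#'
#' @param data Data frame with columns `condition` and `activity`.
#' @param reference_condition The condition whose activity defines 100%.
#' @return The input with an added `percent` column.
#' @examples
#' normalize_activity(
#'   data.frame(condition = c("A", "B"), activity = c(10, 20)), "B")
#' @export
normalize_activity <- function(data, reference_condition) {
  check_columns(data, c("condition", "activity"), "data")
  ref <- data$activity[data$condition == reference_condition]
  if (length(ref) == 0) {
    abort(sprintf("Reference condition '%s' not found.", reference_condition),
          class = "halokin_invalid_parameter")
  }
  ref <- mean(ref)
  if (!is.finite(ref) || ref <= 0) {
    abort("Reference activity must be > 0.",
          class = "halokin_invalid_parameter")
  }
  dplyr::mutate(as_tibble(data), percent = 100 * .data$activity / ref)
}

#' Fit Michaelis-Menten parameters for every condition in a dataset
#'
#' Groups a kinetics table by `condition` (and `substrate` when present),
#' fits each group and assembles a per-condition report.
#'
#' @param data Kinetics tibble as from [read_kinetics_csv()] or
#'   [gen_mm_dataset()].
#' @param enzyme_M Optional enzyme molar concentration for kcat.
#' @param sig_figs Significant figures for the reported efficiency (default 2,
#'   the usual table convention); estimates themselves are not rounded.
#' @return A tibble with one row per condition: `Vmax`, `se_Vmax`, `KM_mM`,
#'   `se_KM`, `kcat_s`, `efficiency_M_s`, `n_points`.
#' @export
fit_mm_by_condition <- function(data, enzyme_M = NULL, sig_figs = 2) {
  check_columns(data, c("condition", "s_mM", "v"), "data")
  keys <- intersect(c("condition", "substrate"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_michaelis_menten(d, enzyme_M = enzyme_M)
      g <- glance(f)
      g$efficiency_M_s <- if (is.finite(g$kcat_s)) {
        catalytic_efficiency(g$kcat_s, g$KM_mM, sig_figs = sig_figs)
      } else NA_real_
      g
    }) |>
    dplyr::ungroup()
}

#' Write a per-condition fit report as TSV
#'
#' @param report Tibble from [fit_mm_by_condition()].
#' @param path Output file.
#' @return `report`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(report)
}
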