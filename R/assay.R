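# Two-enzyme coupled assay: progress-curve simulation, lag time, and
# auxiliary-enzyme sizing after Storer & Cornish-Bowden.
#
# The enzyme of interest produces the intermediate B at constant velocity v1;
# the auxiliary (indicator) enzyme consumes it with Michaelis-Menten kinetics:
#
#   d[B]/dt = v1 - V2 [B] / (KM2 + [B]),   [B](0) = 0
#
# The observable velocity is v2(t) = V2 [B]/(KM2+[B]); the assay is valid once
# v2/v1 is close to 1, which happens after a lag governed by KM2/V2.

#' Specify a coupled assay
#'
#' @param v1 Steady velocity of the enzyme of interest, mM/min.
#' @param V2 Maximal velocity of the auxiliary enzyme, mM/min (numerically
#'   equal to U/ml in the cuvette).
#' @param KM2 Michaelis constant of the auxiliary enzyme for the intermediate,
#'   mM.
#' @param rho Required v2/v1 ratio at the end of the lag, in (0, 1).
#' @param t_max Allowed lag time, min.
#' @return A list of class `assay_spec`.
#' @examples
#' assay_spec(v1 = 0.01, V2 = 2, KM2 = 2.34)
#' @export
assay_spec <- function(v1, V2 = NULL, KM2, rho = 0.99, t_max = 5) {
  check_number(v1, "v1", non_negative = TRUE)
  check_number(KM2, "KM2", positive = TRUE)
  check_number(rho, "rho", positive = TRUE)
  if (rho >= 1) {
    abort("`rho` must be in (0, 1).", class = "halokin_invalid_parameter")
  }
  check_number(t_max, "t_max", positive = TRUE)
  if (!is.null(V2)) check_number(V2, "V2", positive = TRUE)
  structure(list(v1 = v1, V2 = V2, KM2 = KM2, rho = rho, t_max = t_max),
            class = "assay_spec")
}

as_assay_spec <- function(spec) {
  if (inherits(spec, "assay_spec")) return(spec)
  if (is.list(spec)) {
    return(assay_spec(v1 = spec$v1, V2 = spec$V2, KM2 = spec$KM2,
                      rho = spec$rho %||% 0.99, t_max = spec$t_max %||% 5))
  }
  abort("`spec` must be an assay_spec or a named list.",
        class = "halokin_invalid_parameter")
}

#' Read an assay configuration JSON
#'
#' Accepts the keys `v1_mM_min`, `KM2_mM`, `rho`, `t_max_min` and optional
#' `V2_U_ml`.
#'
#' @param path JSON file.
#' @return An `assay_spec`.
#' @export
read_assay_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  assay_spec(v1 = cfg$v1_mM_min, V2 = cfg$V2_U_ml,
             KM2 = cfg$KM2_mM, rho = cfg$rho %||% 0.99,
             t_max = cfg$t_max_min %||% 5)
}

# RK4 right-hand side for the state (B, P): P accumulates the product flux.
coupled_rhs <- function(state, v1, V2, KM2) {
  v2 <- V2 * state[1] / (KM2 + state[1])
  c(v1 - v2, v2)
}

rk4_integrate <- function(v1, V2, KM2, t_end, n_steps, state0 = c(0, 0),
                          t0 = 0, keep = TRUE) {
  h <- (t_end - t0) / n_steps
  state <- state0
  if (keep) {
    out <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3)
    out[1, ] <- c(t0, state)
  }
  for (i in seq_len(n_steps)) {
    k1 <- coupled_rhs(state, v1, V2, KM2)
    k2 <- coupled_rhs(state + h / 2 * k1, v1, V2, KM2)
    k3 <- coupled_rhs(state + h / 2 * k2, v1, V2, KM2)
    k4 <- coupled_rhs(state + h * k3, v1, V2, KM2)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state))) {
      abort(sprintf(
        "Non-finite state at step %d (t = %.6g min, h = %.3g): [B] = %g.",
        i, t0 + i * h, h, state[1]), class = "halokin_numerical_error")
    }
    if (keep) out[i + 1, ] <- c(t0 + i * h, state)
  }
  if (keep) out else state
}

#' Simulate a coupled-assay progress curve
#'
#' Integrates the intermediate balance `d[B]/dt = v1 - V2 [B]/(KM2 + [B])`
#' from `[B](0) = 0` with fixed-step 4th-order Runge-Kutta. The step is halved
#' until the largest change in `[B]` on the shared grid is below `tol`
#' (default 1e-9 mM), so the returned curve is integrator-converged.
#'
#' @param spec An [assay_spec()] with `V2` set.
#' @param t_end End time, min.
#' @param dt Initial output step, min (default `t_end / 500`).
#' @param tol Convergence tolerance on `[B]`, mM.
#' @return A tibble `t_min`, `B_mM`, `v2_mM_min`, `product_mM` (cumulative
#'   integral of v2).
#' @examples
#' curve <- simulate_coupled_assay(assay_spec(0.01, 2, 2.34), t_end = 10)
#' tail(curve, 1)  # [B] near v1*KM2/(V2-v1)
#' @export
simulate_coupled_assay <- function(spec, t_end, dt = NULL, tol = 1e-9) {
  spec <- as_assay_spec(spec)
  if (is.null(spec$V2)) {
    abort("`spec$V2` must be set to simulate.",
          class = "halokin_invalid_parameter")
  }
  check_number(t_end, "t_end", positive = TRUE)
  dt <- dt %||% (t_end / 500)
  check_number(dt, "dt", positive = TRUE)
  n <- max(2L, as.integer(ceiling(t_end / dt)))
  out <- rk4_integrate(spec$v1, spec$V2, spec$KM2, t_end, n)
  repeat {
    out2 <- rk4_integrate(spec$v1, spec$V2, spec$KM2, t_end, 2L * n)
    delta <- max(abs(out2[seq(1, 2 * n + 1, by = 2), 2] - out[, 2]))
    out <- out2
    n <- 2L * n
    if (delta < tol || n > 2^22) break
  }
  # report on the original output grid to keep curves a manageable size
  idx <- unique(c(seq(1, n + 1, by = max(1L, n %/% 1000L)), n + 1L))
  B <- out[idx, 2]
  tibble(t_min = out[idx, 1],
         B_mM = B,
         v2_mM_min = spec$V2 * B / (spec$KM2 + B),
         product_mM = out[idx, 3])
}

# B(t) at time t by RK4 from a known state, used for bisection refinement.
b_at <- function(spec, t, t0 = 0, B0 = 0, n_steps = 64L) {
  if (t <= t0) return(B0)
  rk4_integrate(spec$v1, spec$V2, spec$KM2, t, n_steps,
                state0 = c(B0, 0), t0 = t0, keep = FALSE)[1]
}

#' Lag time of a coupled assay
#'
#' The smallest time at which the auxiliary velocity reaches the required
#' fraction of the target velocity, `v2(t)/v1 >= rho`. Found on the simulated
#' progress curve and refined by bisection to `tol` minutes.
#'
#' @param spec An [assay_spec()] with `V2` set.
#' @param tol Time tolerance, min.
#' @return Lag time in minutes.
#' @examples
#' lag_time(assay_spec(0.01, 2, 2.34, rho = 0.99)) # about 5.4 min
#' @export
lag_time <- function(spec, tol = 1e-4) {
  spec <- as_assay_spec(spec)
  if (is.null(spec$V2)) {
    abort("`spec$V2` must be set.", class = "halokin_invalid_parameter")
  }
  if (spec$v1 == 0) return(0)
  # the steady ratio is min(1, V2/v1): if it never exceeds rho the lag
  # does not exist
  if (min(1, spec$V2 / spec$v1) <= spec$rho) {
    abort(sprintf(
      "Infeasible: limiting v2/v1 ratio %.4g never exceeds rho = %.4g.",
      min(1, spec$V2 / spec$v1), spec$rho), class = "halokin_infeasible")
  }
  # B level at which v2/v1 = rho
  B_star <- spec$rho * spec$v1 * spec$KM2 / (spec$V2 - spec$rho * spec$v1)
  tau <- spec$KM2 / spec$V2  # first-order time constant
  t_hi <- max(4 * tau * -log1p(-spec$rho), 8 * tau)
  while (b_at(spec, t_hi, n_steps = 512L) < B_star) {
    t_hi <- 2 * t_hi
    if (t_hi > 1e9 * tau) {
      abort("Lag time did not converge below the search cap.",
            class = "halokin_infeasible")
    }
  }
  t_lo <- 0
  B_lo <- 0
  while (t_hi - t_lo > tol) {
    t_mid <- (t_lo + t_hi) / 2
    B_mid <- b_at(spec, t_mid, t0 = t_lo, B0 = B_lo, n_steps = 64L)
    if (B_mid >= B_star) {
      t_hi <- t_mid
    } else {
      t_lo <- t_mid
      B_lo <- B_mid
    }
  }
  (t_lo + t_hi) / 2
}

#' Minimal auxiliary-enzyme activity for a coupled assay
#'
#' The smallest auxiliary maximal velocity `V2` (U/ml) for which the lag time
#' at ratio `rho` does not exceed `t_max`. Found by bisection on `V2`, with
#' the upper bracket doubled until feasible. The recommendation is reported at
#' `report_sig_figs` significant figures, the precision at which such
#' prescriptions are quoted.
#'
#' @param v1 Target-enzyme velocity, mM/min.
#' @param KM2 Auxiliary-enzyme Michaelis constant for the intermediate, mM.
#' @param rho Required v2/v1 ratio, in (0, 1).
#' @param t_max Allowed lag, min.
#' @param report_sig_figs Significant figures for the reported value.
#' @param tol Relative bisection tolerance on V2.
#' @return A one-row tibble: inputs plus `V2_U_ml` (unrounded bisection
#'   result), `V2_reported` and the achieved `lag_min`.
#' @examples
#' minimal_auxiliary_activity(0.01, 2.34, rho = 0.99, t_max = 5)
#' @export
minimal_auxiliary_activity <- function(v1, KM2, rho = 0.99, t_max = 5,
                                       report_sig_figs = 1, tol = 1e-6) {
  check_number(v1, "v1", positive = TRUE)
  check_number(KM2, "KM2", positive = TRUE)
  check_number(rho, "rho", positive = TRUE)
  if (rho >= 1) {
    abort("`rho` must be in (0, 1).", class = "halokin_invalid_parameter")
  }
  check_number(t_max, "t_max", positive = TRUE)
  lag_ok <- function(V2) {
    lag_time(assay_spec(v1, V2, KM2, rho = rho, t_max = t_max)) <= t_max
  }
  lo <- v1            # below v1 the steady ratio cannot reach 1
  hi <- max(2 * v1, KM2 * -log1p(-rho) / t_max)
  while (!lag_ok(hi)) {
    hi <- 2 * hi
    if (hi > 1e6) {
      abort("No feasible auxiliary activity below 1e6 U/ml.",
            class = "halokin_infeasible")
    }
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (lag_ok(mid)) hi <- mid else lo <- mid
  }
  V2 <- hi
  tibble(v1_mM_min = v1, KM2_mM = KM2, rho = rho, t_max_min = t_max,
         V2_U_ml = V2,
         V2_reported = signif(V2, report_sig_figs),
         lag_min = lag_time(assay_spec(v1, V2, KM2, rho = rho)))
}

#' Promiscuous background rate of the auxiliary enzyme
#'
#' First-order rate of a side reaction far below its KM (e.g. glucose
#' oxidation by a G6P dehydrogenase): `rate = efficiency * [E] * [S]`.
#'
#' @param efficiency_M_s Catalytic efficiency kcat/KM of the side activity,
#'   M^-1 s^-1.
#' @param enzyme_M Enzyme concentration, M.
#' @param substrate_M Substrate concentration, M.
#' @return Rate in M/s (vectorised).
#' @examples
#' promiscuous_rate(23, 12e-9, 5e-3) # 1.38e-9 M/s
#' @export
promiscuous_rate <- function(efficiency_M_s, enzyme_M, substrate_M) {
  for (arg in list(efficiency_M_s, enzyme_M, substrate_M)) {
    if (!is.numeric(arg) || any(arg < 0) || any(!is.finite(arg))) {
      abort("All inputs must be finite and >= 0.",
            class = "halokin_invalid_parameter")
    }
  }
  efficiency_M_s * enzyme_M * substrate_M
}

#' Correct a measured rate for background activity
#'
#' Subtracts the auxiliary enzyme's own (promiscuous) velocity from the total
#' observed velocity. A warning is raised when the background exceeds half of
#' the total, i.e. the measurement is dominated by background.
#'
#' @param v_total Total observed velocity.
#' @param v_background Background velocity measured without the enzyme of
#'   interest.
#' @return `v_total - v_background` (vectorised).
#' @examples
#' background_corrected_rate(0.05, 0.02) # 0.03
#' @export
background_corrected_rate <- function(v_total, v_background) {
  if (any(!is.finite(v_total)) || any(!is.finite(v_background))) {
    abort("Velocities must be finite.", class = "halokin_invalid_parameter")
  }
  dominated <- v_total != 0 & (v_background / v_total > 0.5)
  if (any(dominated)) {
    warn(sprintf(
      "Background exceeds 50%% of the total signal for %d value(s); the measurement is background-dominated.",
      sum(dominated)), class = "halokin_background_dominated")
  }
  v_total - v_background
}

#' Write a progress curve as CSV
#'
#' Columns `t_min,B_mM,v2_mM_min,product_mM`, the dialect the assay
#' simulation produces.
#'
#' @param curve Tibble from [simulate_coupled_assay()].
#' @param path Output file.
#' @return `curve`, invisibly.
#' @export
write_progress_csv <- function(curve, path) {
  check_columns(curve, c("t_min", "B_mM", "v2_mM_min", "product_mM"), "curve")
  readr::write_csv(curve, path)
  invisible(curve)
}
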