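# Kabsch superposition and the fluctuation observables built on it:
# RMSD time series, per-residue RMSF, radius of gyration, replicate stats.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two matched coordinate sets, via SVD of the covariance matrix with
#' the reflection corrected through the sign of the smallest singular value,
#' so the returned rotation always has determinant +1.
#'
#' @param mobile,reference `n x 3` coordinate matrices, equal `n >= 3`.
#' @param weights Optional non-negative per-atom weights (e.g. masses).
#' @return A list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (the minimised value) and `transformed` (mobile mapped onto the
#'   reference: `mobile %*% t(rotation) + translation`).
#' @examples
#' a <- matrix(rnorm(12), ncol = 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3) {
    abort("`mobile` and `reference` must be n x 3 matrices of equal size.",
          class = "halokin_invalid_parameter")
  }
  n <- nrow(mobile)
  if (n < 3) {
    abort("At least 3 atoms are required for superposition.",
          class = "halokin_invalid_parameter")
  }
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("`weights` must be non-negative with positive sum.",
          class = "halokin_invalid_parameter")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  m <- sweep(mobile, 2, cm)
  r <- sweep(reference, 2, cr)
  h <- t(m * w) %*% r
  s <- svd(h)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300)) {
    abort("Degenerate geometry: covariance rank < 2 (collinear or coincident points).",
          class = "halokin_degenerate")
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- m %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((transformed - r)^2)))
  translation <- as.numeric(cr - rot %*% cm)
  list(rotation = rot, translation = translation, rmsd = rmsd,
       transformed = sweep(transformed, 2, cr, "+"))
}

superposed_rmsd <- function(mobile, reference, weights = NULL) {
  kabsch_superpose(mobile, reference, weights)$rmsd
}

#' RMSD time series of a trajectory
#'
#' Superposes every frame onto a reference frame over the selected atoms
#' (Kabsch) and records the minimised RMSD, the standard conformational-
#' integrity observable of an MD production run.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Index of the reference frame (default 1).
#' @param selection [atom_selection()], indices or `NULL` (all atoms);
#'   C-alpha only is the common choice for proteins:
#'   `atom_selection(atom_name = "CA")`.
#' @param mass_weighted Weight atoms by mass? Default `FALSE`.
#' @return A tibble `frame`, `time` (if the trajectory has times), `rmsd`
#'   in Angstrom.
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = NULL,
                        mass_weighted = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- select_atoms(traj$topology, selection)
  w <- if (mass_weighted) traj$topology$mass[idx] else NULL
  ref <- traj$frames[[reference_frame]][idx, , drop = FALSE]
  rmsd <- vapply(traj$frames, function(f) {
    superposed_rmsd(f[idx, , drop = FALSE], ref, w)
  }, numeric(1))
  out <- tibble(frame = seq_along(traj$frames), rmsd = rmsd)
  if (!is.null(traj$times)) out <- dplyr::mutate(out, time = traj$times,
                                                 .after = "frame")
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Fluctuation of each selected atom about its mean position,
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`, averaged per residue. When `align`
#' is on, frames are first superposed onto the mean structure, iterated
#' twice (align to the first frame, take the mean, re-align to that mean)
#' so the fluctuations are measured in the molecule frame, free of rigid
#' drift.
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param selection [atom_selection()], indices or `NULL`.
#' @param align Remove global rigid motion first? Default `TRUE`.
#' @param per `"residue"` (default) averages atom RMSF within each residue;
#'   `"atom"` returns one row per atom.
#' @return A tibble with `rmsf` in Angstrom per residue (or atom).
#' @export
rmsf <- function(traj, selection = NULL, align = TRUE,
                 per = c("residue", "atom")) {
  per <- match.arg(per)
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2) {
    abort("RMSF needs at least two frames.",
          class = "halokin_invalid_parameter")
  }
  idx <- select_atoms(traj$topology, selection)
  coords <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  if (align) {
    ref <- coords[[1]]
    for (pass in 1:2) {
      coords <- lapply(coords, function(f) {
        kabsch_superpose(f, ref)$transformed
      })
      ref <- Reduce(`+`, coords) / length(coords)
    }
  }
  mean_coords <- Reduce(`+`, coords) / length(coords)
  msf <- Reduce(`+`, lapply(coords, function(f) {
    rowSums((f - mean_coords)^2)
  })) / length(coords)
  atom_tbl <- dplyr::mutate(traj$topology[idx, ], rmsf = sqrt(msf))
  if (per == "atom") {
    return(dplyr::select(atom_tbl, dplyr::any_of(
      c("serial", "atom_name", "chain_id", "residue_seq", "residue_name",
        "rmsf"))))
  }
  atom_tbl |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
    dplyr::summarise(rmsf = mean(.data$rmsf), .groups = "drop")
}

rg_frame <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / sum(masses))
}

#' Radius of gyration
#'
#' Mass-weighted spread of a selection about its centre of mass,
#' `Rg = sqrt(sum m_i |r_i - r_com|^2 / sum m_i)`, per frame — the standard
#' compaction metric of an MD trajectory.
#'
#' @param traj A [trajectory()] (or a single `n x 3` matrix, in which case a
#'   plain number is returned and `masses` must be supplied for
#'   mass-weighting).
#' @param selection [atom_selection()], indices or `NULL`.
#' @param mass_weighted Use atomic masses (default) or unit weights.
#' @param masses Optional explicit masses when `traj` is a bare matrix.
#' @return A tibble `frame`, `rg` (Angstrom), or a single number for a bare
#'   coordinate matrix.
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = TRUE,
                               masses = NULL) {
  if (is.matrix(traj)) {
    m <- if (mass_weighted) {
      if (is.null(masses)) {
        abort("Supply `masses` for a bare coordinate matrix.",
              class = "halokin_invalid_parameter")
      }
      masses
    } else rep(1, nrow(traj))
    if (sum(m) <= 0) {
      abort("Total mass must be > 0.", class = "halokin_invalid_parameter")
    }
    return(rg_frame(traj, m))
  }
  stopifnot(inherits(traj, "trajectory"))
  idx <- select_atoms(traj$topology, selection)
  m <- if (mass_weighted) traj$topology$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) {
    abort("Total mass must be > 0.", class = "halokin_invalid_parameter")
  }
  tibble(frame = seq_along(traj$frames),
         rg = vapply(traj$frames, function(f) {
           rg_frame(f[idx, , drop = FALSE], m)
         }, numeric(1)))
}

#' Pointwise replicate statistics of series
#'
#' Mean and sample SD across replicate series at each time point, plus the
#' mean +/- SD over a stated window (e.g. the last 10% of frames, the usual
#' "last 10 ns" convention for a 100 ns run).
#'
#' @param series_list List of equal-length numeric vectors (one per
#'   replicate), or a data frame whose columns are replicates.
#' @param window Frame indices for the window summary; `NULL` uses the whole
#'   series. Convenience: a single value in (0, 1) selects that trailing
#'   fraction of frames (`window = 0.1` is "the last 10%").
#' @return A list of class `series_stats`: `pointwise` (tibble `index`,
#'   `mean`, `sd`), `window` (one-row tibble `from`, `to`, `mean`, `sd` of
#'   the windowed replicate means).
#' @export
replicate_stats <- function(series_list, window = NULL) {
  if (is.data.frame(series_list)) series_list <- as.list(series_list)
  if (length(series_list) < 1) {
    abort("At least one series is required.",
          class = "halokin_invalid_parameter")
  }
  len <- unique(lengths(series_list))
  if (length(len) != 1) {
    abort("All series must have equal length.",
          class = "halokin_invalid_parameter")
  }
  mat <- do.call(cbind, series_list)
  pointwise <- tibble(index = seq_len(len),
                      mean = rowMeans(mat),
                      sd = if (ncol(mat) > 1) apply(mat, 1, sd) else
                        rep(0, len))
  if (is.null(window)) {
    win_idx <- seq_len(len)
  } else if (length(window) == 1 && window > 0 && window < 1) {
    win_idx <- seq.int(len - floor(window * len) + 1L, len)
  } else {
    win_idx <- as.integer(window)
    if (any(win_idx < 1 | win_idx > len)) {
      abort("Window indices outside the series bounds.",
            class = "halokin_invalid_parameter")
    }
  }
  rep_means <- colMeans(mat[win_idx, , drop = FALSE])
  window_tbl <- tibble(from = min(win_idx), to = max(win_idx),
                       mean = mean(rep_means),
                       sd = if (length(rep_means) > 1) sd(rep_means) else 0)
  structure(list(pointwise = pointwise, window = window_tbl),
            class = "series_stats")
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf("Replicate series: %d points; window [%d, %d]: %.4g +/- %.4g\n",
              nrow(x$pointwise), x$window$from, x$window$to,
              x$window$mean, x$window$sd))
  invisible(x)
}
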