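# Trajectory container and readers (multi-model PDB, plain XYZ), plus atom
# selections. A trajectory is a light list: a topology tibble and a list of
# n_atoms x 3 coordinate matrices.

#' Build a trajectory
#'
#' @param topology Atoms tibble (see [parse_pdb()]).
#' @param frames List of `n_atoms x 3` numeric matrices in Angstrom.
#' @param times Optional per-frame times in ns.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  check_columns(topology, c("x", "y", "z"), "topology")
  n_atoms <- nrow(topology)
  if (length(frames) == 0) {
    abort("A trajectory needs at least one frame.",
          class = "halokin_invalid_parameter")
  }
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) dimnames(f) <- NULL
    f
  })
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || nrow(f) != n_atoms || ncol(f) != 3) {
      abort(sprintf("Frame %d is not an %d x 3 coordinate matrix.",
                    k, n_atoms), class = "halokin_invalid_parameter")
    }
    if (any(!is.finite(f))) {
      abort(sprintf("Frame %d contains non-finite coordinates.", k),
            class = "halokin_invalid_parameter")
    }
  }
  if (!is.null(times) && length(times) != length(frames)) {
    abort("`times` must have one entry per frame.",
          class = "halokin_invalid_parameter")
  }
  structure(list(topology = as_tibble(topology), frames = frames,
                 times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a trajectory from multi-model PDB or XYZ text
#'
#' Multi-model PDB files (MODEL/ENDMDL blocks) carry their own topology; the
#' plain-XYZ dialect is `n_atoms`, a comment line, then `element x y z` lines
#' per frame, with the topology taken from the first frame (serials and
#' residue numbers assigned sequentially).
#'
#' @param x File path or text.
#' @param format `"auto"` (default), `"pdb"` or `"xyz"`.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(x, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  lines <- pdb_lines(x)
  if (format == "auto") {
    format <- if (any(grepl("^(ATOM  |HETATM|MODEL)", lines))) "pdb" else "xyz"
  }
  if (format == "pdb") read_trajectory_pdb(lines) else read_trajectory_xyz(lines)
}

read_trajectory_pdb <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    atoms <- parse_pdb(lines)
    return(trajectory(atoms, list(as.matrix(atoms[, c("x", "y", "z")]))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
  frames <- vector("list", length(starts))
  topology <- NULL
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    atoms <- parse_pdb(block)
    if (is.null(topology)) {
      topology <- atoms
    } else if (nrow(atoms) != nrow(topology)) {
      abort(sprintf("Model %d has %d atoms; expected %d.",
                    k, nrow(atoms), nrow(topology)),
            class = "halokin_format_error")
    }
    frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  trajectory(topology, frames)
}

read_trajectory_xyz <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  frames <- list()
  topology <- NULL
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n <= 0) {
      abort(sprintf("Expected an atom count on line %d.", pos),
            class = "halokin_format_error")
    }
    if (pos + 1 + n > length(lines) + 1) {
      abort("Truncated XYZ frame.", class = "halokin_format_error")
    }
    block <- lines[(pos + 2):(pos + 1 + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- toupper(vapply(tok, `[`, character(1), 1))
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(tok, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (any(!is.finite(xyz))) {
      abort(sprintf("Unparseable coordinates in XYZ frame starting line %d.",
                    pos), class = "halokin_format_error")
    }
    if (is.null(topology)) {
      topology <- tibble(serial = seq_len(n), atom_name = el, element = el,
                         residue_name = "UNK", chain_id = "A",
                         residue_seq = seq_len(n),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         vdw_radius = lookup_vdw(el), mass = lookup_mass(el))
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  trajectory(topology, frames)
}

#' Define an atom selection
#'
#' A predicate over the topology: any combination of chain ids, 1-based
#' inclusive residue ranges, atom names and residue names. `NULL` fields
#' match everything.
#'
#' @param chain_id Chain identifier(s).
#' @param residues Residue numbers (e.g. `178:190`).
#' @param atom_name Atom name set (e.g. `"CA"`).
#' @param residue_name Residue name set (e.g. `"G6P"`).
#' @return An object of class `atom_selection`.
#' @examples
#' atom_selection(chain_id = "A", residues = 178:190)
#' @export
atom_selection <- function(chain_id = NULL, residues = NULL,
                           atom_name = NULL, residue_name = NULL) {
  structure(list(chain_id = chain_id, residues = residues,
                 atom_name = atom_name, residue_name = residue_name),
            class = "atom_selection")
}

#' Resolve a selection to atom indices
#'
#' @param topology Atoms tibble.
#' @param sel An [atom_selection()], an integer index vector, or `NULL`
#'   (all atoms).
#' @return Integer indices into the topology; errors if empty.
#' @export
select_atoms <- function(topology, sel = NULL) {
  if (is.null(sel)) return(seq_len(nrow(topology)))
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (length(idx) == 0 || any(idx < 1 | idx > nrow(topology))) {
      abort("Selection indices out of range or empty.",
            class = "halokin_empty_selection")
    }
    return(idx)
  }
  stopifnot(inherits(sel, "atom_selection"))
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(sel$chain_id)) keep <- keep & topology$chain_id %in% sel$chain_id
  if (!is.null(sel$residues)) keep <- keep & topology$residue_seq %in% sel$residues
  if (!is.null(sel$atom_name)) keep <- keep & topology$atom_name %in% sel$atom_name
  if (!is.null(sel$residue_name)) {
    keep <- keep & topology$residue_name %in% sel$residue_name
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    abort("Selection resolves to no atoms on this topology.",
          class = "halokin_empty_selection")
  }
  idx
}
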