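# Fixed-column PDB parsing and writing. Structures are plain tibbles of atoms
# so they compose with dplyr; one row per atom.

# van der Waals radii (A); homology models are heavy-atom so the common
# protein elements dominate. Unknown elements fall back to carbon.
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                       H = 1.20)
vdw_fallback <- 1.70

element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, SE = 78.971, FE = 55.845,
                    ZN = 65.38, MG = 24.305, NA. = 22.990, CL = 35.45,
                    K = 39.098, CA = 40.078, MN = 54.938)
mass_fallback <- 12.011

two_letter_elements <- c("FE", "ZN", "MG", "CL", "BR", "NA", "MN", "SE", "CA")

lookup_mass <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- unname(element_masses[key])
  ifelse(is.na(m), mass_fallback, m)
}

lookup_vdw <- function(element, radii = default_vdw_radii) {
  r <- unname(radii[element])
  ifelse(is.na(r), vdw_fallback, r)
}

# Element from columns 77-78 when present, else from the atom name: digits
# stripped, a leading two-letter metal/halogen recognised, else first letter.
infer_element <- function(element_field, atom_name) {
  el <- toupper(trimws(element_field))
  need <- el == "" | is.na(el)
  if (any(need)) {
    nm <- toupper(gsub("[0-9' ]", "", atom_name[need]))
    two <- substr(nm, 1, 2)
    el[need] <- ifelse(two %in% two_letter_elements, two, substr(nm, 1, 1))
  }
  el
}

parse_coord <- function(field, line_no, axis) {
  x <- suppressWarnings(as.numeric(field))
  bad <- which(is.na(x) | trimws(field) == "")
  if (length(bad) > 0) {
    abort(sprintf("Unparseable %s coordinate '%s' on line %d.",
                  axis, trimws(field[bad[1]]), line_no[bad[1]]),
          class = "halokin_format_error")
  }
  x
}

#' Parse a PDB structure into an atoms tibble
#'
#' Fixed-column parsing of ATOM/HETATM records (x/y/z from columns 31-38,
#' 39-46, 47-54; element from columns 77-78 with an atom-name fallback). Only
#' the first MODEL of a multi-model file is read — use [read_trajectory()]
#' for trajectories. Van der Waals radii and atomic masses are assigned per
#' element; hydrogens are retained and can be dropped with `keep_hydrogens =
#' FALSE` (surface-area work on heavy-atom models usually excludes them).
#'
#' @param x PDB text (single string or character vector of lines) or a file
#'   path.
#' @param keep_hydrogens Keep hydrogen atoms? Default `TRUE`.
#' @param radii Named vector of van der Waals radii per element symbol,
#'   overriding the built-in table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
#'   H 1.20; other elements 1.70).
#' @return A tibble with one row per atom: `serial`, `atom_name`, `element`,
#'   `residue_name`, `chain_id`, `residue_seq`, `x`, `y`, `z`, `vdw_radius`,
#'   `mass`.
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' parse_pdb(pdb)
#' @export
parse_pdb <- function(x, keep_hydrogens = TRUE, radii = NULL) {
  lines <- pdb_lines(x)
  # only the first model: stop at the first ENDMDL
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    abort("No ATOM/HETATM records found.", class = "halokin_empty_structure")
  }
  ln <- which(is_atom)
  rec <- lines[is_atom]
  atoms <- tibble(
    serial = suppressWarnings(as.integer(trimws(substr(rec, 7, 11)))),
    atom_name = trimws(substr(rec, 13, 16)),
    residue_name = trimws(substr(rec, 18, 20)),
    chain_id = substr(rec, 22, 22),
    residue_seq = suppressWarnings(as.integer(trimws(substr(rec, 23, 26)))),
    x = parse_coord(substr(rec, 31, 38), ln, "x"),
    y = parse_coord(substr(rec, 39, 46), ln, "y"),
    z = parse_coord(substr(rec, 47, 54), ln, "z"),
    element = infer_element(substr(rec, 77, 78), trimws(substr(rec, 13, 16)))
  )
  radii_table <- default_vdw_radii
  if (!is.null(radii)) radii_table[names(radii)] <- radii
  atoms$vdw_radius <- lookup_vdw(atoms$element, radii_table)
  atoms$mass <- lookup_mass(atoms$element)
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", ]
  dplyr::select(atoms, "serial", "atom_name", "element", "residue_name",
                "chain_id", "residue_seq", "x", "y", "z", "vdw_radius",
                "mass")
}

pdb_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  x
}

#' Read a radii table from TSV
#'
#' Two columns `element` and `radius_A`; used to override the built-in van
#' der Waals table in [parse_pdb()].
#'
#' @param path TSV file.
#' @return Named numeric vector of radii.
#' @export
read_radii_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("element", "radius_A"), "radii tsv")
  setNames(df$radius_A, toupper(df$element))
}

format_atom_line <- function(atoms, i) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$serial[i] %% 100000,
          ifelse(nchar(atoms$atom_name[i]) < 4,
                 paste0(" ", atoms$atom_name[i]), atoms$atom_name[i]),
          atoms$residue_name[i], atoms$chain_id[i], atoms$residue_seq[i],
          atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
}

#' Write an atoms tibble as a PDB file
#'
#' @param atoms Atoms tibble as from [parse_pdb()] or [gen_toy_structure()].
#' @param path Output file; when `NULL` the text is returned instead.
#' @return The PDB text, invisibly when written to a file.
#' @export
write_pdb <- function(atoms, path = NULL) {
  check_columns(atoms, c("serial", "atom_name", "residue_name", "chain_id",
                         "residue_seq", "x", "y", "z", "element"), "atoms")
  txt <- c(vapply(seq_len(nrow(atoms)), function(i) format_atom_line(atoms, i),
                  character(1)), "END")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A [trajectory()] object.
#' @param path Output file; when `NULL` the text is returned.
#' @return The text, invisibly when written.
#' @export
write_trajectory_pdb <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  atoms <- traj$topology
  txt <- unlist(lapply(seq_along(traj$frames), function(f) {
    atoms$x <- traj$frames[[f]][, 1]
    atoms$y <- traj$frames[[f]][, 2]
    atoms$z <- traj$frames[[f]][, 3]
    c(sprintf("MODEL     %4d", f),
      vapply(seq_len(nrow(atoms)), function(i) format_atom_line(atoms, i),
             character(1)),
      "ENDMDL")
  }))
  txt <- c(txt, "END")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
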