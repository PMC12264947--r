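# The ensemble container: frame-stacked coordinates plus a light topology.

# Per-element atomic masses (Da) and Bondi van der Waals radii (Angstrom).
ELEMENT_PROPERTIES <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974),
  radius  = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
  stringsAsFactors = FALSE
)

infer_element <- function(atom_name) {
  # strip digits and take the first letter; PDB convention for standard
  # protein atoms (CA -> C, 1HB -> H, OXT -> O ...)
  stripped <- gsub("[0-9]", "", trimws(atom_name))
  toupper(substr(stripped, 1, 1))
}

#' Construct a conformational ensemble
#'
#' An `ensemble` bundles frame-stacked Cartesian coordinates (Angstrom) with
#' the per-atom topology shared by every frame: atom names, 1-based residue
#' indices, residue names, atomic masses and van der Waals radii. All
#' analysis functions in the package consume this container.
#'
#' @param coords Numeric array of dimension `n_frames x n_atoms x 3`, or an
#'   `n_atoms x 3` matrix for a single frame. Units are Angstrom.
#' @param atom_name Character vector of atom names (`"N"`, `"CA"`, ...).
#' @param residue_index Integer vector of 1-based residue numbers per atom;
#'   must be non-decreasing and start at 1.
#' @param residue_name Character vector of three-letter residue codes, one
#'   per atom (recycled per residue internally).
#' @param element Optional per-atom element symbols; inferred from the first
#'   letter of the atom name when missing.
#'
#' @return An object of class `ensemble` with fields `coords`, `atoms`
#'   (a tibble with columns `atom_name`, `residue_index`, `residue_name`,
#'   `element`, `mass`, `radius`), and counts `n_frames`, `n_atoms`,
#'   `n_residues`.
#' @export
new_ensemble <- function(coords, atom_name, residue_index, residue_name,
                         element = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort_ed("`coords` must be an n_frames x n_atoms x 3 array.", "format")
  }
  check_finite(coords, "coords", kind = "invalid_coordinates")
  n_atoms <- dim(coords)[2]
  if (length(atom_name) != n_atoms || length(residue_index) != n_atoms) {
    abort_ed("`atom_name` and `residue_index` must have one entry per atom.", "topology")
  }
  residue_index <- as.integer(residue_index)
  if (min(residue_index) != 1L || any(diff(residue_index) < 0L)) {
    abort_ed("`residue_index` must be non-decreasing with minimum 1.", "topology")
  }
  if (length(residue_name) == length(unique(residue_index))) {
    residue_name <- residue_name[residue_index]
  }
  element <- element %||% infer_element(atom_name)
  idx <- match(element, ELEMENT_PROPERTIES$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    abort_ed(
      sprintf("Unknown element(s) %s: no mass/radius available.", paste(bad, collapse = ", ")),
      "element_lookup"
    )
  }
  atoms <- tibble::tibble(
    atom_name = as.character(atom_name),
    residue_index = residue_index,
    residue_name = as.character(residue_name),
    element = element,
    mass = ELEMENT_PROPERTIES$mass[idx],
    radius = ELEMENT_PROPERTIES$radius[idx]
  )
  structure(
    list(
      coords = coords,
      atoms = atoms,
      n_frames = dim(coords)[1],
      n_atoms = n_atoms,
      n_residues = length(unique(residue_index))
    ),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> %d frame(s), %d atoms, %d residues\n",
    x$n_frames, x$n_atoms, x$n_residues
  ))
  invisible(x)
}

#' Number of frames, atoms and residues in an ensemble
#' @param x An `ensemble`.
#' @return An integer count.
#' @export
n_frames <- function(x) x$n_frames

#' @rdname n_frames
#' @export
n_atoms <- function(x) x$n_atoms

#' @rdname n_frames
#' @export
n_residues <- function(x) x$n_residues

check_frames <- function(ensemble, frames) {
  if (is.null(frames)) {
    return(seq_len(ensemble$n_frames))
  }
  frames <- as.integer(frames)
  if (length(frames) == 0L) {
    abort_ed("Empty frame selection.", "empty_selection")
  }
  if (any(frames < 1L | frames > ensemble$n_frames)) {
    abort_ed(
      sprintf("Frame indices must lie in 1..%d.", ensemble$n_frames),
      "index"
    )
  }
  frames
}

#' Subset an ensemble by frame
#'
#' @param ensemble An `ensemble`.
#' @param frames Integer vector of 1-based frame indices.
#' @return An `ensemble` containing only the selected frames, in the order
#'   given.
#' @export
subset_frames <- function(ensemble, frames) {
  frames <- check_frames(ensemble, frames)
  new_ensemble(
    ensemble$coords[frames, , , drop = FALSE],
    ensemble$atoms$atom_name,
    ensemble$atoms$residue_index,
    ensemble$atoms$residue_name,
    element = ensemble$atoms$element
  )
}

# single-frame coordinates as an n_atoms x 3 matrix
frame_coords <- function(ensemble, frame) {
  matrix(ensemble$coords[frame, , ], ncol = 3L)
}

#' Read a multi-MODEL PDB file into an ensemble
#'
#' Each `MODEL` record becomes one frame; a file without `MODEL` records
#' yields a single-frame ensemble. Masses and van der Waals radii are filled
#' from an element lookup keyed on the first letter of the atom name.
#' Residue numbering is remapped to contiguous 1-based indices.
#'
#' @param path Path to a PDB file.
#' @return An [new_ensemble()] object.
#' @export
read_multi_model_pdb <- function(path) {
  if (!file.exists(path)) {
    abort_ed(sprintf("File not found: %s", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  if (!any(atom_lines)) {
    abort_ed("No ATOM records found: not a parseable PDB file.", "format")
  }
  # models must agree in atom count before bio3d stacks them
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- table(model_id[atom_lines])
    if (length(unique(as.integer(counts))) != 1L) {
      abort_ed("Inconsistent atom count across MODEL records.", "topology")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_fr <- nrow(xyz)
  n_at <- ncol(xyz) / 3L
  coords <- array(0, dim = c(n_fr, n_at, 3L))
  for (k in 1:3) {
    coords[, , k] <- xyz[, seq(k, by = 3L, length.out = n_at), drop = FALSE]
  }
  resno <- pdb$atom$resno
  residue_index <- match(resno, unique(resno))
  new_ensemble(
    coords,
    atom_name = trimws(pdb$atom$elety),
    residue_index = residue_index,
    residue_name = trimws(pdb$atom$resid)
  )
}

#' Write an ensemble (or a frame subset) as a multi-MODEL PDB file
#'
#' @param ensemble An `ensemble`.
#' @param path Output file path.
#' @param frames 1-based frame indices to write; default all frames.
#' @return `path`, invisibly.
#' @export
write_multi_model_pdb <- function(ensemble, path, frames = NULL) {
  frames <- check_frames(ensemble, frames)
  n_at <- ensemble$n_atoms
  xyz <- matrix(0, nrow = length(frames), ncol = 3L * n_at)
  for (k in 1:3) {
    xyz[, seq(k, by = 3L, length.out = n_at)] <-
      ensemble$coords[frames, , k, drop = FALSE]
  }
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = ensemble$atoms$residue_index,
    resid = ensemble$atoms$residue_name,
    eleno = seq_len(n_at),
    elety = ensemble$atoms$atom_name,
    chain = rep("A", n_at)
  )
  invisible(path)
}
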