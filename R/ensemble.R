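#' Construct a conformational ensemble
#'
#' The central container consumed by every trajectory analysis: a fixed atom
#' roster plus an ordered stack of coordinate frames. Coordinates are stored
#' as an `n_atoms x 3 x n_frames` array in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `element`. The combination
#'   `(chain_id, residue_number, atom_name)` must be unique: it is the identity
#'   used to map atoms across frames.
#' @param coords numeric array `n_atoms x 3 x n_frames` (or an
#'   `n_atoms x 3` matrix for a single frame), Angstrom.
#' @param frame_times optional numeric vector of frame times in ps, strictly
#'   increasing, one per frame. Defaults to the 0-based frame index.
#' @return An object of class `ConformationalEnsemble`.
#' @export
conformational_ensemble <- function(atoms, coords, frame_times = NULL) {
  required <- c("serial", "atom_name", "residue_name", "residue_number",
                "chain_id", "element")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("'atoms' must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("'coords' must be an n_atoms x 3 x n_frames array")
  n_atoms <- nrow(atoms)
  if (dim(coords)[1] != n_atoms)
    stop("coordinate array has ", dim(coords)[1], " atoms but roster has ",
         n_atoms)
  if (dim(coords)[3] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  key <- atom_key(atoms)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom identity in roster: ", dup)
  }
  n_frames <- dim(coords)[3]
  if (is.null(frame_times)) {
    frame_times <- seq_len(n_frames) - 1
  } else {
    if (length(frame_times) != n_frames)
      stop("frame_times length (", length(frame_times),
           ") does not match number of frames (", n_frames, ")")
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(
    list(atoms = atoms, coords = coords, frame_times = as.numeric(frame_times)),
    class = "ConformationalEnsemble"
  )
}

atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, sep = "/")
}

#' @export
print.ConformationalEnsemble <- function(x, ...) {
  cat("ConformationalEnsemble:", n_atoms(x), "atoms,", n_frames(x), "frames\n")
  res <- unique(paste(x$atoms$chain_id, x$atoms$residue_number))
  cat("  residues:", length(res),
      " chains:", paste(unique(x$atoms$chain_id), collapse = ","), "\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `ConformationalEnsemble`
#' @return integer frame count
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Number of atoms in an ensemble roster
#' @param ensemble a `ConformationalEnsemble`
#' @return integer atom count
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[1]

#' Extract a subset of frames
#'
#' Frame slicing (stride, equilibration discard) is exposed here; no analysis
#' applies a default discard.
#'
#' @param ensemble a `ConformationalEnsemble`
#' @param frames integer vector of frame indices to keep, in the order given
#' @return a `ConformationalEnsemble` with the selected frames
#' @export
slice_frames <- function(ensemble, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(ensemble)))
    stop("frame indices out of range 1..", n_frames(ensemble))
  ft <- ensemble$frame_times[frames]
  if (any(diff(ft) <= 0)) ft <- seq_along(frames) - 1
  conformational_ensemble(ensemble$atoms,
                          ensemble$coords[, , frames, drop = FALSE],
                          frame_times = ft)
}

#' Indices of roster atoms matching a selection
#'
#' @param ensemble a `ConformationalEnsemble`
#' @param atom_names optional character vector of atom names (e.g. `"CA"`)
#' @param residues optional integer vector of residue numbers
#' @param chains optional character vector of chain identifiers
#' @return integer vector of roster row indices (possibly empty)
#' @export
atom_indices <- function(ensemble, atom_names = NULL, residues = NULL,
                         chains = NULL) {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (!is.null(residues))   keep <- keep & a$residue_number %in% residues
  if (!is.null(chains))     keep <- keep & a$chain_id %in% chains
  which(keep)
}

# One selected atom per residue, or an informative error. Residues that match
# the atom-name filter ambiguously (>=2 atoms) always error; a residue listed
# in `residues` that matches nothing errors too.
residue_atom_indices <- function(ensemble, atom_names = "CA",
                                 residues = NULL, chains = NULL) {
  idx <- atom_indices(ensemble, atom_names, residues, chains)
  if (length(idx) == 0)
    stop("selection matched no atoms (atom names: ",
         paste(atom_names, collapse = ","), ")")
  a <- ensemble$atoms[idx, ]
  res_key <- paste(a$chain_id, a$residue_number)
  counts <- table(res_key)
  if (any(counts >= 2)) {
    bad <- names(counts)[counts >= 2][1]
    stop("residue ", bad, " contributes ", max(counts),
         " atoms to the selection; exactly one is required")
  }
  if (!is.null(residues)) {
    missing <- setdiff(residues, a$residue_number)
    if (length(missing) > 0)
      stop("residue ", missing[1], " has no atom matching the selection (",
           paste(atom_names, collapse = ","), ")")
  }
  ord <- order(a$chain_id, a$residue_number)
  idx[ord]
}
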