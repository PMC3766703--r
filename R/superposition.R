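#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets, via singular value
#' decomposition of the cross-covariance matrix with reflection correction:
#' if the optimal orthogonal matrix has determinant -1, the sign of the
#' smallest singular vector is flipped so a proper rotation is returned.
#'
#' The returned transform maps `mobile` onto `reference`:
#' `aligned = mobile %*% t(rotation) + translation` (row vectors).
#'
#' @param mobile numeric `n x 3` matrix, Angstrom
#' @param reference numeric `n x 3` matrix, same `n`
#' @param weights optional numeric vector of `n` non-negative weights
#'   (default uniform)
#' @return a `RigidTransform`: list with `rotation` (3x3 orthonormal,
#'   det = +1), `translation` (length-3), and `rmsd` (Angstrom, the minimised
#'   value)
#' @export
kabsch_align <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (ncol(mobile) != 3) stop("coordinates must be n x 3")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points are required for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be ", n, " non-negative values with positive sum")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)      # centered mobile
  Q <- sweep(reference, 2, cr)   # centered reference

  # degenerate (collinear) configurations leave the rotation underdetermined
  sv_ref <- svd(Q * sqrt(w), nu = 0, nv = 0)$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1e-12))
    stop("degenerate (collinear) point configuration; superposition is ",
         "underdetermined")

  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)

  translation <- as.numeric(cr - R %*% cm)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords numeric `n x 3` matrix
#' @param transform a `RigidTransform` from [kabsch_align()]
#' @return transformed `n x 3` matrix
#' @export
apply_rigid_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "RigidTransform"))
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

# Superpose every frame of an ensemble on a common reference using the atoms
# in `fit_idx`; the fitted transform is applied to all atoms.
# fit = "frame0": reference is the frame with index ref; "iterative-mean":
# align on frame 1, then realign on the running mean structure (n_iter
# passes); "none": identity.
superpose_frames <- function(ensemble, fit_idx,
                             fit = c("iterative-mean", "frame0", "none"),
                             ref = 1L, n_iter = 2L) {
  fit <- match.arg(fit)
  if (fit == "none") return(ensemble)
  coords <- ensemble$coords
  nf <- dim(coords)[3]
  align_all <- function(coords, reference) {
    for (m in seq_len(nf)) {
      tr <- kabsch_align(coords[fit_idx, , m], reference)
      coords[, , m] <- apply_rigid_transform(coords[, , m], tr)
    }
    coords
  }
  reference <- coords[fit_idx, , ref]
  coords <- align_all(coords, reference)
  if (fit == "iterative-mean") {
    for (it in seq_len(n_iter)) {
      reference <- apply(coords[fit_idx, , , drop = FALSE], c(1, 2), mean)
      coords <- align_all(coords, reference)
    }
  }
  ensemble$coords <- coords
  ensemble
}

#' Per-frame RMSD from a reference frame
#'
#' Each frame's selected atoms are least-squares superposed onto the
#' reference frame's before the deviation is measured, so the series is
#' invariant to global rigid motion.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param reference_frame index of the reference frame (default 1, the
#'   starting structure)
#' @param atom_names atom-name filter (default `"CA"`)
#' @param residues optional residue-number filter
#' @param chains optional chain filter
#' @return numeric vector, one minimised RMSD (Angstrom) per frame; the entry
#'   at the reference index is 0
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L, atom_names = "CA",
                        residues = NULL, chains = NULL) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"))
  nf <- n_frames(ensemble)
  if (reference_frame < 1 || reference_frame > nf)
    stop("reference_frame out of range 1..", nf)
  idx <- atom_indices(ensemble, atom_names, residues, chains)
  if (length(idx) == 0) stop("selection matched no atoms")
  ref <- ensemble$coords[idx, , reference_frame]
  vapply(seq_len(nf), function(m) {
    if (m == reference_frame) return(0)
    kabsch_align(ensemble$coords[idx, , m], ref)$rmsd
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed (per `fit`), then for each residue's selected
#' atom `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`. Each selected residue must
#' contribute exactly one atom (default: its C-alpha).
#'
#' @param ensemble a [conformational_ensemble()] with >= 2 frames
#' @param atom_names atom-name filter, default `"CA"`
#' @param residues,chains optional filters
#' @param fit superposition mode: `"iterative-mean"` (default; align on the
#'   ensemble mean, recompute, repeat), `"frame0"` (align on the first frame)
#'   or `"none"`
#' @param unit `"angstrom"` (default) or `"nm"`
#' @return a `FluctuationProfile`: data.frame with columns `residue_number`
#'   and `rmsf`, with the unit recorded in attribute `"unit"`
#' @export
rmsf_profile <- function(ensemble, atom_names = "CA", residues = NULL,
                         chains = NULL,
                         fit = c("iterative-mean", "frame0", "none"),
                         unit = c("angstrom", "nm")) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"))
  fit <- match.arg(fit)
  unit <- match.arg(unit)
  if (n_frames(ensemble) < 2) stop("RMSF requires at least 2 frames")
  idx <- residue_atom_indices(ensemble, atom_names, residues, chains)
  ens <- superpose_frames(ensemble, idx, fit = fit)
  sel <- ens$coords[idx, , , drop = FALSE]
  mean_str <- apply(sel, c(1, 2), mean)
  dev2 <- sweep(sel, c(1, 2), mean_str)^2
  rmsf <- sqrt(apply(dev2, 1, mean) * 3)  # mean over (axis, frame) * 3 axes
  if (unit == "nm") rmsf <- rmsf / 10
  structure(data.frame(residue_number = ens$atoms$residue_number[idx],
                       rmsf = rmsf),
            class = c("FluctuationProfile", "data.frame"),
            unit = unit)
}
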