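#' Salt-bridge occupancy along a trajectory
#'
#' For each frame, the minimum distance over all cross pairs of the two
#' residues' selector atoms is computed; the bridge is "formed" when that
#' distance is at or below the pair's cutoff. Occupancy (the "existence"
#' percentage) is 100 times the formed-frame fraction. The criterion is a
#' pure distance (no angular term), so occupancy is monotone in the cutoff.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param pair a [residue_pair_spec()]
#' @return an `OccupancyTrace`: list with `pair`, `per_frame_state` (logical),
#'   `per_frame_min_distance` (Angstrom) and `occupancy_percent`
#' @export
salt_bridge_occupancy <- function(ensemble, pair) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"),
            inherits(pair, "ResiduePairSpec"))
  idx_a <- atom_indices(ensemble, pair$atoms_a, pair$residue_a$number,
                        pair$residue_a$chain)
  if (length(idx_a) == 0)
    stop("residue ", pair$residue_a$chain, ":", pair$residue_a$number,
         " has no atom matching selector {",
         paste(pair$atoms_a, collapse = ","), "}")
  idx_b <- atom_indices(ensemble, pair$atoms_b, pair$residue_b$number,
                        pair$residue_b$chain)
  if (length(idx_b) == 0)
    stop("residue ", pair$residue_b$chain, ":", pair$residue_b$number,
         " has no atom matching selector {",
         paste(pair$atoms_b, collapse = ","), "}")
  md <- min_cross_distances(ensemble$coords, idx_a, idx_b)
  state <- md <= pair$cutoff
  structure(list(pair = pair,
                 per_frame_state = state,
                 per_frame_min_distance = md,
                 occupancy_percent = 100 * mean(state)),
            class = "OccupancyTrace")
}

# per-frame minimum Euclidean distance over the idx_a x idx_b cross pairs
min_cross_distances <- function(coords, idx_a, idx_b) {
  nf <- dim(coords)[3]
  vapply(seq_len(nf), function(m) {
    A <- matrix(coords[idx_a, , m], ncol = 3)
    B <- matrix(coords[idx_b, , m], ncol = 3)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

#' @export
print.OccupancyTrace <- function(x, ...) {
  p <- x$pair
  cat(sprintf("Salt bridge %s:%d - %s:%d (cutoff %.2f A): occupancy %.1f%% over %d frames\n",
              p$residue_a$chain, p$residue_a$number,
              p$residue_b$chain, p$residue_b$number,
              p$cutoff, x$occupancy_percent, length(x$per_frame_state)))
  invisible(x)
}

#' Nearest-partner profile of a probe residue
#'
#' For each frame, finds which candidate residue is nearest to the probe
#' (minimum cross-atom distance); ties are broken towards the lower residue
#' number. Used to detect side-chain contact-partner switches, e.g. a
#' tryptophan changing its helix-16 contact from one residue to its
#' neighbour.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param probe list/vector `(chain, number)` of the probe residue
#' @param probe_atoms character vector of probe atom names
#' @param candidates list of candidates, each a list with elements `chain`,
#'   `number` and `atoms` (character vector)
#' @return a `PartnerProfile`: list with `probe`, `candidates`,
#'   `per_frame_nearest` (integer candidate indices),
#'   `per_frame_min_distance` and `fraction_per_partner` (sums to 1)
#' @export
partner_switch_profile <- function(ensemble, probe, probe_atoms, candidates) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"))
  if (length(candidates) < 2)
    stop("at least 2 candidate partners are required")
  idx_p <- atom_indices(ensemble, probe_atoms, as.integer(probe[[2]]),
                        as.character(probe[[1]]))
  if (length(idx_p) == 0)
    stop("probe residue ", probe[[1]], ":", probe[[2]],
         " has no atom matching selector {",
         paste(probe_atoms, collapse = ","), "}")
  cand_idx <- lapply(candidates, function(cd) {
    ii <- atom_indices(ensemble, cd$atoms, as.integer(cd$number),
                       as.character(cd$chain))
    if (length(ii) == 0)
      stop("candidate residue ", cd$chain, ":", cd$number,
           " has no atom matching selector {",
           paste(cd$atoms, collapse = ","), "}")
    ii
  })
  dmat <- vapply(cand_idx, function(ii)
    min_cross_distances(ensemble$coords, idx_p, ii),
    numeric(n_frames(ensemble)))
  dmat <- matrix(dmat, nrow = n_frames(ensemble))
  cand_resnum <- vapply(candidates, function(cd) as.integer(cd$number), 1L)
  ord <- order(cand_resnum)  # tie-break: lower residue number wins
  nearest <- apply(dmat[, ord, drop = FALSE], 1, which.min)
  nearest <- ord[nearest]
  frac <- tabulate(nearest, nbins = length(candidates)) / length(nearest)
  structure(list(probe = probe, candidates = candidates,
                 per_frame_nearest = nearest,
                 per_frame_min_distance = dmat[cbind(seq_along(nearest),
                                                     nearest)],
                 fraction_per_partner = frac),
            class = "PartnerProfile")
}
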