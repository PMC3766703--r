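# Independent oracles and small constructors used across tests.

# Horn's closed-form quaternion superposition: returns the minimised RMSD of
# mobile onto reference. Independent of the SVD-based implementation in the
# package.
horn_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / n))
}

# Naive two-loop DCCM on an N x 3 x T coordinate block (no superposition):
# per-pair scalar covariance of displacements from the mean, normalised.
naive_dccm <- function(coords) {
  n <- dim(coords)[1]; Tn <- dim(coords)[3]
  mu <- apply(coords, c(1, 2), mean)
  cm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (t in seq_len(Tn)) {
        di <- coords[i, , t] - mu[i, ]
        dj <- coords[j, , t] - mu[j, ]
        s <- s + sum(di * dj)
      }
      cm[i, j] <- s / Tn
    }
  }
  v <- diag(cm)
  cm / sqrt(outer(v, v))
}

# Naive minimum cross-pair distance between two atom index sets in one frame.
naive_min_distance <- function(frame, idx_a, idx_b) {
  best <- Inf
  for (i in idx_a) for (j in idx_b) {
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# A C-alpha-only ensemble from an N x 3 x T array.
make_ca_ensemble <- function(coords) {
  n <- dim(coords)[1]
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA",
                      residue_name = "ALA", residue_number = seq_len(n),
                      chain_id = "A", element = "C",
                      stringsAsFactors = FALSE)
  conformational_ensemble(atoms, coords)
}

# Random proper rotation (for rigid-congruence tests); independent of the
# package's quaternion sampler.
random_rotation_qr <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply one rigid motion (R, t) to every atom of one frame.
move_frame <- function(frame, R, tr) sweep(frame %*% t(R), 2, tr, `+`)
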