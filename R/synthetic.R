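#' Specification of a synthetic Gaussian conformational ensemble
#'
#' Describes an ensemble of C-alpha traces: a fixed mean structure plus
#' zero-mean Gaussian displacements with prescribed per-residue standard
#' deviations and prescribed inter-residue scalar correlations, optionally
#' composited with random global rigid-body motion. Correlations are
#' isotropic (the same rho couples x, y and z), which makes the expected
#' dynamic cross-correlation between two residues exactly rho — the cleanest
#' ground truth for recovery tests.
#'
#' @param n_residues number of residues (one C-alpha each)
#' @param sigma per-residue displacement standard deviation per coordinate,
#'   Angstrom; scalar or vector of length `n_residues`
#' @param correlation_blocks list of blocks, each a list with elements `a`
#'   and `b` (residue-number vectors) and `rho` in `[-1, 1]`: every pair
#'   (i in a, j in b, i != j) receives correlation rho. `a` and `b` may be
#'   equal (within-block coupling).
#' @param mean_structure optional `n_residues x 3` matrix; default an ideal
#'   helix-like chain with 3.8 Angstrom C-alpha spacing
#' @param rigid_body if `TRUE`, each frame is additionally rotated by a
#'   uniform random rotation and translated uniformly within a 10 Angstrom
#'   cube, to exercise superposition removal
#' @param n_frames number of frames (>= 2)
#' @param seed integer RNG seed; the ensemble is fully reproducible from it
#' @return an `EnsembleSpec`
#' @export
ensemble_spec <- function(n_residues, sigma = 0.5, correlation_blocks = list(),
                          mean_structure = NULL, rigid_body = FALSE,
                          n_frames = 1000L, seed = 1L) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 2) stop("need at least 2 residues")
  if (length(sigma) == 1) sigma <- rep(sigma, n_residues)
  if (length(sigma) != n_residues)
    stop("sigma must be scalar or length n_residues")
  if (any(sigma <= 0)) stop("sigma values must be positive")
  for (bl in correlation_blocks) {
    if (!all(c("a", "b", "rho") %in% names(bl)))
      stop("each correlation block needs elements a, b, rho")
    if (abs(bl$rho) > 1) stop("|rho| must be <= 1")
    if (any(!c(bl$a, bl$b) %in% seq_len(n_residues)))
      stop("block residues must lie in 1..", n_residues)
  }
  if (is.null(mean_structure)) mean_structure <- helix_chain(n_residues)
  mean_structure <- as.matrix(mean_structure)
  if (!all(dim(mean_structure) == c(n_residues, 3)))
    stop("mean_structure must be n_residues x 3")
  structure(list(n_residues = n_residues, sigma = as.numeric(sigma),
                 correlation_blocks = correlation_blocks,
                 mean_structure = mean_structure,
                 rigid_body = isTRUE(rigid_body),
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "EnsembleSpec")
}

# ideal helix-like C-alpha chain: 3.8 A between consecutive residues
helix_chain <- function(n) {
  radius <- 2.3; turn <- 100 * pi / 180  # deg per residue, alpha-helix-like
  rise <- sqrt(3.8^2 - (2 * radius * sin(turn / 2))^2)
  i <- seq_len(n) - 1
  cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
}

#' Build the displacement covariance model of an ensemble spec
#'
#' Assembles the N x N scalar correlation matrix (unit diagonal, block
#' entries from the spec), validates positive semidefiniteness, and scales by
#' the per-residue sigmas. Because couplings are isotropic, the full 3N x 3N
#' model is this matrix Kronecker the 3x3 identity; the scalar form is what
#' all downstream computations need.
#'
#' @param spec an [ensemble_spec()]
#' @return list with `correlation` (N x N) and `covariance` (N x N,
#'   Angstrom^2)
#' @export
build_covariance <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  n <- spec$n_residues
  R <- diag(n)
  for (k in seq_along(spec$correlation_blocks)) {
    bl <- spec$correlation_blocks[[k]]
    for (i in bl$a) for (j in bl$b) {
      if (i == j) next
      if (R[i, j] != 0 && R[i, j] != bl$rho)
        stop("conflicting correlation requests for residues ", i, ",", j)
      R[i, j] <- R[j, i] <- bl$rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("requested correlation blocks are inconsistent (model not positive ",
         "semidefinite; smallest eigenvalue ", signif(min(ev), 3), ")")
  C <- R * tcrossprod(spec$sigma)
  list(correlation = R, covariance = C)
}

#' Sample a synthetic conformational ensemble
#'
#' Draws `n_frames` frames of Gaussian displacements with the spec's
#' covariance model around the mean structure, then (optionally) applies an
#' independent random rigid motion to every frame. Deterministic given the
#' spec's seed.
#'
#' @param spec an [ensemble_spec()]
#' @return a [conformational_ensemble()] of C-alpha pseudo-atoms (chain "A",
#'   residues 1..N)
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  if (spec$n_frames < 2) stop("n_frames must be >= 2")
  model <- build_covariance(spec)
  n <- spec$n_residues; nf <- spec$n_frames
  eg <- eigen(model$covariance, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  sq <- eg$vectors %*% (t(eg$vectors) * sqrt(lam))  # symmetric sqrt, PSD-safe
  set.seed(spec$seed)
  coords <- array(0, dim = c(n, 3L, nf))
  for (ax in 1:3) {
    disp <- sq %*% matrix(stats::rnorm(n * nf), n, nf)  # N x T, cov = C
    coords[, ax, ] <- spec$mean_structure[, ax] + disp
  }
  if (spec$rigid_body) {
    for (m in seq_len(nf)) {
      R <- random_rotation()
      tr <- stats::runif(3, -5, 5)
      coords[, , m] <- sweep(coords[, , m] %*% t(R), 2, tr, `+`)
    }
  }
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA",
                      residue_name = "ALA", residue_number = seq_len(n),
                      chain_id = "A", element = "C",
                      stringsAsFactors = FALSE)
  conformational_ensemble(atoms, coords)
}

# uniform rotation on SO(3) via a normalized random quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Specification of a two-state (telegraph) salt-bridge trajectory
#'
#' A two-state Markov chain alternating between a "formed" and a "broken"
#' geometry with a prescribed stationary formed probability `p` and a
#' persistence parameter `dwell`: exit probabilities are `(1-p)/dwell` from
#' the formed and `p/dwell` from the broken state, so the stationary formed
#' fraction is exactly `p` for any `dwell`, the chain's relaxation time is
#' `dwell` frames (lag-1 autocorrelation `1 - 1/dwell`), and `dwell = 1`
#' gives i.i.d. states, for which the empirical occupancy is exactly
#' binomial. The mean dwell time in the formed state is `dwell/(1-p)` frames.
#'
#' @param p stationary formed probability, strictly in (0, 1)
#' @param dwell persistence (relaxation time) in frames, >= 1
#' @param formed_distance,broken_distance selector-atom distances (Angstrom)
#'   in the two states; formed must be below and broken above the analysis
#'   cutoff
#' @param cutoff the analysis cutoff the distances are validated against
#' @param n_frames number of frames
#' @param seed integer RNG seed
#' @return a `TelegraphSpec`
#' @export
telegraph_spec <- function(p, dwell = 1, formed_distance = 3.0,
                           broken_distance = 8.0, cutoff = 4.0,
                           n_frames = 10000L, seed = 1L) {
  if (p <= 0 || p >= 1) stop("p must be strictly inside (0, 1)")
  if (dwell < 1) stop("dwell must be >= 1 frame")
  if (!(formed_distance < cutoff && cutoff < broken_distance))
    stop("need formed_distance < cutoff < broken_distance")
  alpha <- (1 - p) / dwell  # P(leave formed)
  beta <- p / dwell         # P(leave broken); stationary P(formed) = p
  structure(list(p = p, dwell = dwell, alpha = alpha, beta = beta,
                 formed_distance = formed_distance,
                 broken_distance = broken_distance, cutoff = cutoff,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "TelegraphSpec")
}

#' Sample a two-state salt-bridge trajectory as a minimal ensemble
#'
#' Generates the Markov state sequence (initial state drawn from the
#' stationary distribution, so occupancy is unbiased at any length) and
#' builds a two-residue Glu/Arg system whose selector atoms sit at the
#' formed or broken distance along x in each frame. The true state sequence
#' is attached as attribute `"states"`.
#'
#' @param spec a [telegraph_spec()]
#' @return a [conformational_ensemble()] with residues GLU 1 (OE1, OE2) and
#'   ARG 2 (NH1, NH2, NE), chain "A"
#' @export
sample_telegraph <- function(spec) {
  stopifnot(inherits(spec, "TelegraphSpec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  u <- stats::runif(nf)
  states <- logical(nf)
  states[1] <- u[1] < spec$p
  for (m in 2:nf) {
    states[m] <- if (states[m - 1]) u[m] >= spec$alpha else u[m] < spec$beta
  }
  # roster: carboxylate pair on GLU 1 at the origin, guanidinium on ARG 2
  # displaced along x by the state distance
  atoms <- data.frame(
    serial = 1:5,
    atom_name = c("OE1", "OE2", "NH1", "NH2", "NE"),
    residue_name = c("GLU", "GLU", "ARG", "ARG", "ARG"),
    residue_number = c(1L, 1L, 2L, 2L, 2L),
    chain_id = "A", element = c("O", "O", "N", "N", "N"),
    stringsAsFactors = FALSE)
  base <- rbind(c(0, 0, 0), c(0, 1.1, 0),
                c(0, 0, 0), c(0, 1.1, 0), c(0, -1.1, 0))
  coords <- array(0, dim = c(5L, 3L, nf))
  d <- ifelse(states, spec$formed_distance, spec$broken_distance)
  for (m in seq_len(nf)) {
    fr <- base
    fr[3:5, 1] <- fr[3:5, 1] + d[m]
    coords[, , m] <- fr
  }
  ens <- conformational_ensemble(atoms, coords)
  attr(ens, "states") <- states
  ens
}

#' Specification of a synthetic kinetics time course
#'
#' First-order cleavage accumulation (`plateau * (1 - exp(-k t))`) or
#' religation decay (`plateau * exp(-k t)`) observed with multiplicative
#' Gaussian noise, mimicking densitometry of a gel time course.
#'
#' @param model `"cleavage_rise"` or `"religation_decay"`
#' @param k first-order rate constant, per minute, > 0
#' @param plateau amplitude in percent of lane signal, > 0
#' @param times sampling times in minutes, strictly increasing; default a
#'   9-point grid spanning 0.25-30 min for the rise model, and the same grid
#'   anchored at t = 0 for the decay model (a religation course includes the
#'   pre-reaction aliquot as its t = 0 point)
#' @param cv multiplicative noise coefficient of variation, >= 0
#' @param lane_total simulated total lane signal (arbitrary units)
#' @param seed integer RNG seed
#' @return a `KineticsSpec`
#' @export
kinetics_spec <- function(model = c("cleavage_rise", "religation_decay"),
                          k, plateau = 80, times = NULL,
                          cv = 0.05, lane_total = 5000, seed = 1L) {
  model <- match.arg(model)
  if (is.null(times)) {
    times <- if (model == "cleavage_rise") {
      c(0.25, 0.5, 1, 2, 4, 8, 12, 20, 30)
    } else {
      c(0, 0.5, 1, 2, 4, 8, 12, 20, 30)
    }
  }
  if (k <= 0) stop("rate k must be positive")
  if (plateau <= 0) stop("plateau must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (cv < 0) stop("cv must be non-negative")
  structure(list(model = model, k = k, plateau = plateau,
                 times = as.numeric(times), cv = cv,
                 lane_total = lane_total, seed = as.integer(seed)),
            class = "KineticsSpec")
}

#' Sample a noisy kinetics time course
#'
#' Evaluates the spec's first-order curve, applies multiplicative noise
#' `y * (1 + cv * eps)` with standard-normal `eps`, clips negative values at
#' zero (count recorded in attribute `"n_clipped"`), and packages the result
#' as band/lane-total signals so that the lane fraction reconstructs the
#' noisy percentage.
#'
#' @param spec a [kinetics_spec()]
#' @param label series label carried through to the [time_course()]
#' @return a [time_course()]
#' @export
sample_timecourse <- function(spec, label = spec$model) {
  stopifnot(inherits(spec, "KineticsSpec"))
  y <- if (spec$model == "cleavage_rise") {
    spec$plateau * (1 - exp(-spec$k * spec$times))
  } else {
    spec$plateau * exp(-spec$k * spec$times)
  }
  set.seed(spec$seed)
  obs <- y * (1 + spec$cv * stats::rnorm(length(y)))
  n_clipped <- sum(obs < 0)
  if (n_clipped > 0) {
    warning(n_clipped, " observation(s) clipped at 0")
    obs[obs < 0] <- 0
  }
  obs <- pmin(obs, 100)  # a band cannot exceed its lane
  tc <- time_course(times = spec$times,
                    band_signal = spec$lane_total * obs / 100,
                    lane_total = rep(spec$lane_total, length(obs)),
                    label = label)
  attr(tc, "n_clipped") <- n_clipped
  tc
}
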