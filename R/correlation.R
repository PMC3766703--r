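#' Displacement covariance of selected atoms
#'
#' After superposition (per `fit`), computes for every residue pair the
#' scalar displacement covariance `<dr_i . dr_j>`, the 3-D dot product of
#' displacements from the mean structure averaged over frames — the raw
#' quantity underlying the dynamic cross-correlation map.
#'
#' @inheritParams rmsf_profile
#' @return list with `residue_numbers`, `mean_structure` (N x 3) and
#'   `covariance` (N x N symmetric matrix, Angstrom^2)
#' @export
displacement_covariance <- function(ensemble, atom_names = "CA",
                                    residues = NULL, chains = NULL,
                                    fit = c("iterative-mean", "frame0",
                                            "none")) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"))
  fit <- match.arg(fit)
  if (n_frames(ensemble) < 2)
    stop("covariance requires at least 2 frames")
  idx <- residue_atom_indices(ensemble, atom_names, residues, chains)
  ens <- superpose_frames(ensemble, idx, fit = fit)
  sel <- ens$coords[idx, , , drop = FALSE]   # N x 3 x T
  mean_str <- apply(sel, c(1, 2), mean)
  dev <- sweep(sel, c(1, 2), mean_str)
  Tn <- dim(dev)[3]
  # sum over axes of per-axis N x N cross-products
  covm <- (dev[, 1, ] %*% t(dev[, 1, ]) +
           dev[, 2, ] %*% t(dev[, 2, ]) +
           dev[, 3, ] %*% t(dev[, 3, ])) / Tn
  list(residue_numbers = ens$atoms$residue_number[idx],
       mean_structure = mean_str,
       covariance = covm)
}

#' Dynamic cross-correlation matrix of C-alpha fluctuations
#'
#' Computes `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, the normalised
#' covariance of atomic displacement vectors, in `[-1, 1]`; positive entries
#' indicate correlated motion, negative anticorrelated. One map is estimated
#' from the full trajectory (no windowing by default).
#'
#' @inheritParams rmsf_profile
#' @return a `CorrelationMatrix`: N x N numeric matrix with residue numbers
#'   as dimnames and attribute `"residue_numbers"`; symmetric with unit
#'   diagonal
#' @export
dccm <- function(ensemble, atom_names = "CA", residues = NULL, chains = NULL,
                 fit = c("iterative-mean", "frame0", "none")) {
  dc <- displacement_covariance(ensemble, atom_names, residues, chains, fit)
  v <- diag(dc$covariance)
  zero <- which(v <= .Machine$double.eps * max(v, 1))
  if (length(zero) > 0)
    stop("residue ", dc$residue_numbers[zero[1]],
         " has zero fluctuation variance; correlation undefined")
  s <- sqrt(v)
  cm <- dc$covariance / tcrossprod(s)
  cm <- (cm + t(cm)) / 2
  cm[cm > 1] <- 1; cm[cm < -1] <- -1
  diag(cm) <- 1
  correlation_matrix(cm, dc$residue_numbers)
}

#' Construct a CorrelationMatrix object
#'
#' @param values N x N numeric matrix, symmetric with unit diagonal, entries
#'   in `[-1, 1]`
#' @param residue_numbers integer vector of length N
#' @return a `CorrelationMatrix`
#' @export
correlation_matrix <- function(values, residue_numbers) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("correlation matrix must be square")
  if (length(residue_numbers) != n)
    stop("residue_numbers length does not match matrix size")
  if (max(abs(values - t(values))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  if (any(values > 1 + 1e-8) || any(values < -1 - 1e-8))
    stop("correlation entries must lie in [-1, 1]")
  dimnames(values) <- list(residue_numbers, residue_numbers)
  structure(values, class = c("CorrelationMatrix", "matrix", "array"),
            residue_numbers = as.integer(residue_numbers))
}

#' Plot a correlation map
#'
#' Thin convenience rendering; the canonical output is the TSV matrix via
#' [write_matrix_tsv()].
#'
#' @param x a `CorrelationMatrix`
#' @param ... passed to [graphics::image()]
#' @export
plot.CorrelationMatrix <- function(x, ...) {
  rn <- attr(x, "residue_numbers")
  graphics::image(rn, rn, unclass(x)[, rev(seq_along(rn))],
                  zlim = c(-1, 1), xlab = "residue", ylab = "residue",
                  col = grDevices::hcl.colors(51, "Blue-Red 3"), ...)
  invisible(x)
}

#' Domain-block summary of a correlation map
#'
#' Averages correlation entries over all residue pairs of each domain pair,
#' turning the visual reading of a correlation map ("the linker moves
#' anticorrelated with the C-terminal domain") into numbers. Diagonal entries
#' are excluded from within-domain blocks. Residues outside every domain are
#' excluded, with their count reported via a warning.
#'
#' @param matrix a `CorrelationMatrix`
#' @param domains a [domain_map()]
#' @return a `BlockSummary`: list with `domain_names`, `block_means` (D x D)
#'   and `block_extremes` (D x D, the signed entry of maximum magnitude)
#' @export
block_summary <- function(matrix, domains) {
  stopifnot(inherits(matrix, "CorrelationMatrix"),
            inherits(domains, "DomainMap"))
  rn <- attr(matrix, "residue_numbers")
  member <- assign_domains(rn, domains)
  n_out <- sum(is.na(member))
  if (n_out > 0)
    warning(n_out, " residue(s) outside all domains excluded from blocks")
  dn <- domains$name
  idx_by_dom <- lapply(dn, function(d) which(!is.na(member) & member == d))
  empty <- which(vapply(idx_by_dom, length, 1L) == 0)
  if (length(empty) > 0)
    stop("domain '", dn[empty[1]], "' contains no residues of the matrix")
  D <- length(dn)
  means <- matrix(NA_real_, D, D, dimnames = list(dn, dn))
  extremes <- means
  vals <- unclass(matrix)
  for (a in seq_len(D)) for (b in seq_len(a)) {
    block <- vals[idx_by_dom[[a]], idx_by_dom[[b]], drop = FALSE]
    if (a == b) {
      keep <- row(block) != col(block)
      x <- block[keep]
      if (length(x) == 0) x <- 1  # single-residue domain: only the diagonal
    } else {
      x <- as.vector(block)
    }
    means[a, b] <- means[b, a] <- mean(x)
    ext <- x[which.max(abs(x))]
    extremes[a, b] <- extremes[b, a] <- ext
  }
  structure(list(domain_names = dn, block_means = means,
                 block_extremes = extremes),
            class = "BlockSummary")
}

#' @export
print.BlockSummary <- function(x, ...) {
  cat("Domain-block correlation summary (means):\n")
  print(round(x$block_means, 3))
  invisible(x)
}

#' Compose a two-triangle comparison map
#'
#' Builds the conventional side-by-side rendering of two systems in one
#' matrix: the strict upper triangle from one map (e.g. wild type), the
#' strict lower triangle from the other (e.g. mutant), unit diagonal.
#'
#' @param upper,lower `CorrelationMatrix` objects over identical residues
#' @return N x N numeric matrix (not symmetric in general)
#' @export
compose_triangle_map <- function(upper, lower) {
  stopifnot(inherits(upper, "CorrelationMatrix"),
            inherits(lower, "CorrelationMatrix"))
  ru <- attr(upper, "residue_numbers"); rl <- attr(lower, "residue_numbers")
  if (length(ru) != length(rl) || any(ru != rl))
    stop("matrices must share identical residue numbers")
  out <- matrix(0, length(ru), length(ru), dimnames = list(ru, ru))
  u <- unclass(upper); l <- unclass(lower)
  out[upper.tri(out)] <- u[upper.tri(u)]
  out[lower.tri(out)] <- l[lower.tri(l)]
  diag(out) <- 1
  out
}

#' Compare two correlation maps
#'
#' Quantifies how much correlation one system has lost relative to another:
#' per-domain-block mean differences (`a - b`) and the global mean absolute
#' off-diagonal correlation of each map.
#'
#' @param map_a,map_b `CorrelationMatrix` objects over identical residues
#' @param domains a [domain_map()]
#' @return list with `block_delta` (D x D mean differences),
#'   `mean_abs_a`, `mean_abs_b` (global mean |C| off the diagonal) and
#'   `delta_mean_abs` (`mean_abs_a - mean_abs_b`)
#' @export
correlation_loss <- function(map_a, map_b, domains) {
  ra <- attr(map_a, "residue_numbers"); rb <- attr(map_b, "residue_numbers")
  if (length(ra) != length(rb) || any(ra != rb))
    stop("matrices must share identical residue numbers")
  ba <- block_summary(map_a, domains)
  bb <- block_summary(map_b, domains)
  off <- function(m) {
    v <- unclass(m); abs(v[row(v) != col(v)])
  }
  list(block_delta = ba$block_means - bb$block_means,
       mean_abs_a = mean(off(map_a)),
       mean_abs_b = mean(off(map_b)),
       delta_mean_abs = mean(off(map_a)) - mean(off(map_b)))
}
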