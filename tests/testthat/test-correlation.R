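test_that("displacement covariance is zero for a static ensemble", {
  base <- matrix(rnorm(12, sd = 2), 4, 3)
  e <- make_ca_ensemble(array(rep(base, 3), c(4, 3, 3)))
  dc <- displacement_covariance(e, fit = "none")
  expect_lt(max(abs(dc$covariance)), 1e-14)
  expect_equal(dc$mean_structure, base, ignore_attr = TRUE)
})

test_that("duplicated and mirrored displacement streams give +/-1", {
  set.seed(5)
  base <- matrix(rnorm(12, sd = 3), 4, 3)
  Tn <- 50
  coords <- array(rep(base, Tn), c(4, 3, Tn))
  stream <- rnorm(Tn, sd = 0.8)
  coords[1, 1, ] <- base[1, 1] + stream
  coords[2, 1, ] <- base[2, 1] + stream       # duplicated
  coords[3, 1, ] <- base[3, 1] - stream       # mirrored
  coords[4, 2, ] <- base[4, 2] + rnorm(Tn)    # independent
  cm <- dccm(make_ca_ensemble(coords), fit = "none")
  expect_equal(cm[1, 2], 1, tolerance = 1e-12)
  expect_equal(cm[1, 3], -1, tolerance = 1e-12)
  # identical streams also have identical variance
  dc <- displacement_covariance(make_ca_ensemble(coords), fit = "none")
  expect_equal(dc$covariance[1, 2], dc$covariance[1, 1], tolerance = 1e-12)
})

test_that("vectorized DCCM equals the naive double-loop oracle", {
  e <- sample_ensemble(ensemble_spec(
    8, sigma = 0.6, n_frames = 50, seed = 17,
    correlation_blocks = list(list(a = 1:2, b = 5:6, rho = -0.5))))
  cm <- dccm(e, fit = "none")
  expect_lt(max(abs(unclass(cm) - naive_dccm(e$coords))), 1e-12)
})

test_that("DCCM agrees with an independent reference implementation", {
  e <- sample_ensemble(ensemble_spec(
    10, sigma = 0.5, n_frames = 200, seed = 23,
    correlation_blocks = list(list(a = 1:3, b = 1:3, rho = 0.4))))
  cm <- dccm(e, fit = "none")
  xyz <- t(apply(e$coords, 3, function(fr) as.vector(t(fr))))
  ref <- bio3d::dccm.xyz(xyz)
  expect_lt(max(abs(unclass(cm) - unclass(ref))), 1e-6)
})

test_that("DCCM output is a valid correlation matrix on random ensembles", {
  for (s in 1:5) {
    e <- sample_ensemble(ensemble_spec(
      12, sigma = runif(1, 0.2, 1.5), n_frames = 120, seed = 100 + s,
      rigid_body = s %% 2 == 0))
    cm <- dccm(e)
    v <- unclass(cm)
    expect_lt(max(abs(v - t(v))), 1e-12)
    expect_equal(unname(diag(v)), rep(1, 12))
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("DCCM is invariant to removable global rigid motion", {
  plain <- sample_ensemble(ensemble_spec(30, sigma = 0.5, n_frames = 400,
                                         seed = 77))
  rigid <- sample_ensemble(ensemble_spec(30, sigma = 0.5, n_frames = 400,
                                         seed = 77, rigid_body = TRUE))
  cm_plain <- dccm(plain, fit = "iterative-mean")
  cm_rigid <- dccm(rigid, fit = "iterative-mean")
  expect_lt(max(abs(unclass(cm_plain) - unclass(cm_rigid))), 1e-8)
})

test_that("zero-variance residues are named in the error", {
  base <- matrix(rnorm(12), 4, 3)
  coords <- array(rep(base, 10), c(4, 3, 10))
  coords[1, 1, ] <- base[1, 1] + rnorm(10)
  coords[2, 2, ] <- base[2, 2] + rnorm(10)
  coords[4, 3, ] <- base[4, 3] + rnorm(10)
  expect_error(dccm(make_ca_ensemble(coords), fit = "none"),
               "residue 3 has zero fluctuation")
})

test_that("block summary averages constructed blocks exactly", {
  dm <- htop1_domains()
  rn <- 1:765
  ones <- correlation_matrix(matrix(1, 765, 765), rn)
  bs <- block_summary(ones, dm)
  expect_true(all(bs$block_means == 1))
  expect_equal(bs$domain_names, dm$name)

  vals <- diag(765)
  linker <- 636:712; cterm <- 713:765
  vals[linker, cterm] <- -0.4
  vals[cterm, linker] <- -0.4
  bs2 <- block_summary(correlation_matrix(vals, rn), dm)
  expect_equal(bs2$block_means["linker", "C-terminal"], -0.4)
  expect_equal(bs2$block_extremes["linker", "C-terminal"], -0.4)
  expect_equal(bs2$block_means["N-terminal", "core"], 0)
  # within-domain means exclude the unit diagonal
  expect_equal(bs2$block_means["core", "core"], 0)
})

test_that("residues outside all domains are excluded with a warning", {
  dm <- domain_map(c("a", "b"), c(1, 6), c(5, 10))
  cm <- correlation_matrix(diag(12), 1:12)
  expect_warning(bs <- block_summary(cm, dm), "2 residue")
  expect_equal(dim(bs$block_means), c(2L, 2L))
  dm_missing <- domain_map(c("a", "far"), c(1, 100), c(5, 110))
  expect_error(suppressWarnings(block_summary(cm, dm_missing)),
               "'far' contains no residues")
})

test_that("triangle composition merges and round-trips two maps", {
  set.seed(9)
  mk <- function(seed) {
    e <- sample_ensemble(ensemble_spec(6, sigma = 0.5, n_frames = 80,
                                       seed = seed))
    dccm(e, fit = "none")
  }
  wt <- mk(1); mut <- mk(2)
  comp <- compose_triangle_map(wt, mut)
  expect_equal(comp[upper.tri(comp)], unclass(wt)[upper.tri(wt)])
  expect_equal(comp[lower.tri(comp)], unclass(mut)[lower.tri(mut)])
  expect_equal(unname(diag(comp)), rep(1, 6))

  # upper == lower reproduces the map
  expect_equal(compose_triangle_map(wt, wt), unclass(wt), ignore_attr = TRUE)

  # decompose then recompose is the identity
  up <- unclass(comp); up[lower.tri(up)] <- t(up)[lower.tri(up)]
  lo <- unclass(comp); lo[upper.tri(lo)] <- t(lo)[upper.tri(lo)]
  re <- compose_triangle_map(correlation_matrix(up, 1:6),
                             correlation_matrix(lo, 1:6))
  expect_equal(re, comp)

  bad <- dccm(sample_ensemble(ensemble_spec(7, n_frames = 60, seed = 3)),
              fit = "none")
  expect_error(compose_triangle_map(wt, bad), "identical residue numbers")
})

test_that("correlation loss quantifies block and global differences", {
  dm <- domain_map(c("left", "right"), c(1, 4), c(3, 6))
  rn <- 1:6
  a <- diag(6); a[4:6, 1:3] <- -0.5; a[1:3, 4:6] <- -0.5
  b <- diag(6)
  loss <- correlation_loss(correlation_matrix(a, rn),
                           correlation_matrix(b, rn), dm)
  expect_equal(loss$block_delta["left", "right"], -0.5)
  expect_equal(loss$block_delta["left", "left"], 0)
  expect_gt(loss$mean_abs_a, loss$mean_abs_b)

  same <- correlation_loss(correlation_matrix(a, rn),
                           correlation_matrix(a, rn), dm)
  expect_true(all(same$block_delta == 0))
  expect_equal(same$delta_mean_abs, 0)
})

test_that("correlated ensembles carry more global correlation than decoupled ones", {
  dm <- domain_map(c("linker", "cterm"), c(1, 13), c(12, 24))
  blocks <- list(list(a = 1:12, b = 1:12, rho = 0.49),
                 list(a = 13:24, b = 13:24, rho = 0.49),
                 list(a = 1:12, b = 13:24, rho = -0.49))
  for (s in 1:3) {
    coupled <- dccm(sample_ensemble(ensemble_spec(
      24, sigma = 0.5, n_frames = 600, seed = 300 + s,
      correlation_blocks = blocks)), fit = "none")
    decoupled <- dccm(sample_ensemble(ensemble_spec(
      24, sigma = 0.5, n_frames = 600, seed = 400 + s)), fit = "none")
    loss <- correlation_loss(coupled, decoupled, dm)
    expect_gt(loss$delta_mean_abs, 0)
    expect_lt(loss$block_delta["linker", "cterm"], 0)
  }
})
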