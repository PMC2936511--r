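# Covariance PCA of superposed coordinates, projection, and state clustering.

# Ensemble displaced from its mean only along one internal (rigid-orthogonal)
# direction with symmetric amplitudes.
rank_one_ensemble <- function(m = 20, amps = c(-2, -1, 1, 2)) {
  ref <- make_reference(m, "zigzag")
  xyz0 <- ca_coords(ref)
  r0 <- xyz_to_flat(xyz0)
  set.seed(31)
  v <- rnorm(3 * m)
  rb <- confatlas:::.rigid_basis(xyz0)
  v <- v - rb %*% crossprod(rb, v)
  v <- as.numeric(v / sqrt(sum(v^2)))
  mat <- t(vapply(amps, function(a) r0 + a * v, numeric(3 * m)))
  list(ensemble = new_ensemble(mat, positions = seq_len(m)), direction = v)
}

test_that("a rank-one ensemble yields PC1 along the planted direction", {
  ro <- rank_one_ensemble()
  model <- fit_pca(ro$ensemble)
  expect_gte(abs(sum(model$vectors[, 1] * ro$direction)), 1 - 1e-8)
  expect_equal(model$variance_fraction[1], 1, tolerance = 1e-8)
})

test_that("eigenvalues conserve the total positional variance", {
  spec <- synthetic_spec(15, 20, mode_variances = c(3, 1),
                         noise_sigma = 0.2, seed = 6)
  ens <- sample_ensemble(spec)$ensemble
  model <- fit_pca(ens)
  sup <- confatlas:::.superpose_to_mean(ens$coords,
                                        seq_along(ens$positions),
                                        tol = 1e-12)
  x <- confatlas:::array_to_flat(sup$coords)
  total_var <- sum(apply(x, 2, var))
  expect_equal(sum(model$values), total_var, tolerance = 1e-8 * total_var)
  # spectrum invariants
  expect_true(all(diff(model$values) <= 1e-12))
  expect_true(all(model$values >= 0))
  expect_equal(crossprod(model$vectors[, 1:10]), diag(10),
               tolerance = 1e-8)
})

test_that("planted orthogonal modes are recovered from a modest ensemble", {
  spec <- synthetic_spec(40, 300, mode_variances = c(9, 4, 1),
                         noise_sigma = 0.01, seed = 14)
  out <- sample_ensemble(spec)
  model <- fit_pca(out$ensemble)
  rel_err <- abs(model$values[1:3] - c(9, 4, 1)) / c(9, 4, 1)
  expect_true(all(rel_err < 0.15))
  cosines <- abs(colSums(model$vectors[, 1:3] * out$truth$mode_directions))
  expect_true(all(cosines > 0.99))
})

test_that("projection scores reproduce eigenvalues and the mean maps to zero", {
  spec <- synthetic_spec(12, 25, mode_variances = c(2, 0.5),
                         noise_sigma = 0.1, seed = 9)
  ens <- sample_ensemble(spec)$ensemble
  model <- fit_pca(ens)
  proj <- project(ens, model, k = 5)
  expect_equal(unname(apply(proj$scores, 2, var)), model$values[1:5],
               tolerance = 1e-6)
  mean_scores <- project(flat_to_xyz(model$mean), model, k = 3)$scores
  expect_equal(max(abs(mean_scores)), 0, tolerance = 1e-8)
})

test_that("full-rank reconstruction reproduces fitting conformers", {
  spec <- synthetic_spec(8, 10, mode_variances = 1.5, noise_sigma = 0.3,
                         seed = 17)
  ens <- sample_ensemble(spec)$ensemble
  model <- fit_pca(ens)
  k <- ncol(model$vectors)
  proj <- project(ens, model, k = k)
  sup <- confatlas:::.superpose_to_mean(ens$coords,
                                        seq_along(ens$positions),
                                        tol = 1e-12)
  x <- confatlas:::array_to_flat(sup$coords)
  recon <- sweep(proj$scores %*% t(model$vectors[, 1:k]), 2, model$mean,
                 "+")
  expect_lt(max(abs(recon - x)), 1e-6)
})

test_that("a rigidly transformed conformer projects like the original", {
  spec <- synthetic_spec(15, 10, mode_variances = 2, noise_sigma = 0.2,
                         seed = 23)
  ens <- sample_ensemble(spec)$ensemble
  model <- fit_pca(ens)
  moved <- ens
  for (i in seq_len(dim(ens$coords)[1]))
    moved$coords[i, , ] <- random_rigid_copy(ens$coords[i, , ], seed = i)
  expect_equal(project(moved, model, k = 4)$scores,
               project(ens, model, k = 4)$scores, tolerance = 1e-6)
})

test_that("eigenvalue spectrum is invariant to conformer ordering", {
  spec <- synthetic_spec(10, 15, mode_variances = c(2, 1),
                         noise_sigma = 0.2, seed = 41)
  ens <- sample_ensemble(spec)$ensemble
  shuffled <- ens
  set.seed(1)
  ord <- sample(15)
  shuffled$coords <- ens$coords[ord, , ]
  shuffled$conformer_ids <- ens$conformer_ids[ord]
  expect_equal(fit_pca(shuffled)$values, fit_pca(ens)$values,
               tolerance = 1e-8)
})

test_that("two planted clusters separate on PC1 and cluster exactly", {
  out <- two_state_fixture(m_residues = 30, n_conformers = 40,
                           separation = 10, noise_sigma = 0.5, seed = 2)
  model <- fit_pca(out$ensemble)
  proj <- project(out$ensemble, model, k = 2)
  pc1 <- proj$scores[, 1]
  centers <- tapply(pc1, out$truth$labels, mean)
  expect_equal(abs(diff(centers)), 10, tolerance = 0.5,
               ignore_attr = TRUE)
  clustered <- cluster_projections(proj, 2)
  expect_equal(partition_agreement(out$truth$labels, clustered$cluster), 1)
})

test_that("three well-separated clusters are recovered perfectly", {
  m <- 24
  dirs <- confatlas:::.random_modes(3 * m, 2, seed = 55)
  offsets <- rbind(12 * dirs[, 1], -12 * dirs[, 1], 12 * dirs[, 2])
  spec <- synthetic_spec(m, 30, cluster_offsets = offsets,
                         cluster_weights = rep(1 / 3, 3),
                         noise_sigma = 0.3, seed = 19)
  out <- sample_ensemble(spec)
  model <- fit_pca(out$ensemble)
  proj <- cluster_projections(project(out$ensemble, model, k = 3), 3)
  expect_equal(partition_agreement(out$truth$labels, proj$cluster), 1)
})

test_that("degenerate and mismatched inputs are rejected", {
  ro <- rank_one_ensemble(m = 10, amps = c(-1, 0, 1))
  model <- fit_pca(ro$ensemble)
  same <- ro$ensemble
  same$coords[2, , ] <- same$coords[1, , ]
  same$coords[3, , ] <- same$coords[1, , ]
  proj <- project(same, model, k = 2)
  expect_error(cluster_projections(proj, 2), "distinct")

  other <- ro$ensemble
  other$positions <- other$positions + 100L
  expect_error(project(other, model), "frame mismatch")

  arr <- ro$ensemble$coords[1:2, , ]
  expect_error(fit_pca(new_ensemble(arr, positions = 1:10)), "at least 3")
})

test_that("atlas bundles round-trip through plain text", {
  spec <- synthetic_spec(12, 15, mode_variances = c(2, 1),
                         noise_sigma = 0.2, seed = 28)
  ens <- sample_ensemble(spec)$ensemble
  core <- find_core(ens, stop_fraction = 0.6)
  model <- fit_pca(ens, core)
  dir <- withr::local_tempdir()
  save_atlas(model, dir, k = 6)
  back <- load_atlas(dir)
  expect_equal(back$mean, model$mean, tolerance = 1e-12)
  expect_equal(back$values, model$values[1:6], tolerance = 1e-12)
  proj_a <- project(ens, model, k = 3)$scores
  proj_b <- project(ens, back, k = 3)$scores
  expect_equal(proj_a, proj_b, tolerance = 1e-9)
})
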