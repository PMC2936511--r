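# Ensembles and trajectories with known ground truth: planted principal
# modes, state clusters, rigid cores with flexible appendages, and planted
# residue-residue correlation structure. Every analysis stage can therefore
# be validated offline against the quantity that was planted.

# Deterministic per-conformer substream: conformer i of a spec with seed s
# always sees the same draws, so growing N never reshuffles earlier members.
.substream <- function(seed, i) {
  set.seed((as.integer(seed) %% 1000003L) * 2017L + i)
}

# Random proper rotation with angle ~ N(0, angle_sd) about a uniform axis.
.random_rotation <- function(angle_sd) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::rnorm(1, 0, angle_sd)
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

.apply_rigid <- function(xyz, rot, trans) {
  ctr <- colMeans(xyz)
  sweep(sweep(xyz, 2, ctr) %*% rot, 2, ctr + trans, "+")
}

#' Build an ideal reference chain
#'
#' Generates a C-alpha-only poly-alanine chain with ideal geometry:
#' an alpha-helix (rise 1.5 Angstrom, 100 degrees per residue, radius 2.3),
#' a planar zigzag (virtual bond 3.8 Angstrom; every pseudo torsion is
#' exactly 180 degrees), or a seeded self-avoiding random coil
#' (step 3.8 Angstrom).
#'
#' @param m_residues Number of residues (>= 4).
#' @param geometry `"helix"`, `"zigzag"` or `"random-coil"`.
#' @param seed Seed for the random-coil geometry.
#' @return A `structure3d`.
#' @export
make_reference <- function(m_residues,
                           geometry = c("zigzag", "helix", "random-coil"),
                           seed = 1) {
  geometry <- match.arg(geometry)
  if (m_residues < 4) stop("need at least 4 residues")
  t <- seq_len(m_residues) - 1
  xyz <- switch(geometry,
    helix = {
      ang <- t * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
    },
    zigzag = {
      dx <- 3.1; dy <- sqrt(3.8^2 - dx^2)
      cbind(dx * t, dy * (t %% 2), 0)
    },
    `random-coil` = {
      set.seed(seed)
      pts <- matrix(0, m_residues, 3)
      for (i in 2:m_residues) {
        for (try in 1:200) {
          step <- stats::rnorm(3)
          cand <- pts[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
          d2 <- rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)
          if (all(d2 > 3.0^2) || try == 200) break
        }
        pts[i, ] <- cand
      }
      pts
    })
  atoms <- data.frame(
    atom_name = "CA", element = "C", residue_name = "ALA",
    residue_number = seq_len(m_residues), insertion_code = "",
    chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", het = FALSE, ligand = FALSE,
    stringsAsFactors = FALSE)
  new_structure(atoms, id = paste0("synthetic_", geometry))
}

#' Specification of a synthetic ensemble or trajectory
#'
#' Collects everything needed to generate conformers with known ground
#' truth. Planted modes are mutually orthogonal unit directions in the
#' 3M-dimensional coordinate space with given variances; cluster offsets are
#' fixed 3M displacement vectors sampled by weight; a planted M x M
#' residue-residue correlation matrix (symmetric PSD, unit diagonal) drives
#' trajectory displacements; isotropic noise and optional rigid-body jitter
#' contaminate every conformer.
#'
#' @param m_residues Number of residues.
#' @param n_conformers Number of conformers/frames.
#' @param geometry Reference geometry (see [make_reference()]).
#' @param mode_variances Variances (Angstrom^2) of the planted modes.
#' @param mode_directions Optional 3M x K orthonormal matrix; `NULL` draws
#'   seeded random orthonormal directions.
#' @param cluster_offsets Optional K_c x 3M matrix (or list of 3M vectors)
#'   of state offsets.
#' @param cluster_weights Mixing weights (sum to 1); default uniform.
#' @param correlation Optional M x M target correlation matrix for
#'   trajectories.
#' @param displacement_sigma Per-axis displacement amplitude (Angstrom) for
#'   correlated trajectory sampling; scalar or one value per residue
#'   (default 1). Giving a subset of residues a much smaller amplitude
#'   creates quasi-rigid anchors to superpose on, emulating core-fitting:
#'   fitting on fluctuating residues would otherwise absorb the rigid-like
#'   component of the planted correlated motion.
#' @param noise_sigma Isotropic per-coordinate noise (Angstrom).
#' @param rigid_jitter `NULL` or `list(rotation = <rad>, translation = <A>)`
#'   scales of per-conformer rigid contamination.
#' @param seed Integer seed; all sampling is fully reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m_residues, n_conformers,
                           geometry = "zigzag",
                           mode_variances = numeric(0),
                           mode_directions = NULL,
                           cluster_offsets = NULL,
                           cluster_weights = NULL,
                           correlation = NULL,
                           displacement_sigma = 1,
                           noise_sigma = 0,
                           rigid_jitter = NULL,
                           seed = 1) {
  if (!is.null(mode_directions)) {
    mode_directions <- as.matrix(mode_directions)
    stopifnot(nrow(mode_directions) == 3 * m_residues,
              ncol(mode_directions) == length(mode_variances))
    g <- crossprod(mode_directions)
    if (max(abs(g - diag(ncol(g)))) > 1e-6)
      stop("mode directions must be mutually orthonormal")
  }
  if (!is.null(cluster_offsets)) {
    if (is.list(cluster_offsets))
      cluster_offsets <- do.call(rbind, cluster_offsets)
    stopifnot(ncol(cluster_offsets) == 3 * m_residues)
    if (is.null(cluster_weights))
      cluster_weights <- rep(1 / nrow(cluster_offsets),
                             nrow(cluster_offsets))
    if (abs(sum(cluster_weights) - 1) > 1e-8)
      stop("cluster weights must sum to 1")
  }
  if (!is.null(correlation)) {
    stopifnot(nrow(correlation) == m_residues,
              ncol(correlation) == m_residues)
    if (max(abs(correlation - t(correlation))) > 1e-8)
      stop("correlation matrix must be symmetric")
    if (max(abs(diag(correlation) - 1)) > 1e-8)
      stop("correlation matrix must have unit diagonal")
    if (min(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop("correlation matrix must be positive semi-definite")
  }
  out <- list(m_residues = as.integer(m_residues),
              n_conformers = as.integer(n_conformers),
              geometry = geometry,
              mode_variances = mode_variances,
              mode_directions = mode_directions,
              cluster_offsets = cluster_offsets,
              cluster_weights = cluster_weights,
              correlation = correlation,
              displacement_sigma = displacement_sigma,
              noise_sigma = noise_sigma,
              rigid_jitter = rigid_jitter,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

# Orthonormal basis (3M x 6) of rigid-body motions about a reference:
# 3 translations plus 3 infinitesimal rotations.
.rigid_basis <- function(xyz0) {
  m <- nrow(xyz0)
  ctr <- sweep(xyz0, 2, colMeans(xyz0))
  basis <- matrix(0, 3 * m, 6)
  for (ax in 1:3) basis[seq(ax, 3 * m, by = 3), ax] <- 1
  basis[, 4] <- xyz_to_flat(cbind(0, -ctr[, 3], ctr[, 2]))
  basis[, 5] <- xyz_to_flat(cbind(ctr[, 3], 0, -ctr[, 1]))
  basis[, 6] <- xyz_to_flat(cbind(-ctr[, 2], ctr[, 1], 0))
  qr.Q(qr(basis))
}

# Seeded random orthonormal directions (3M x K), sign-fixed for determinism.
# Directions are orthogonalized against the rigid-body subspace of the
# reference: superposition makes rigid components unobservable, so a planted
# "mode" is by definition an internal motion.
.random_modes <- function(m3, k, seed, xyz0 = NULL) {
  set.seed(seed)
  raw <- matrix(stats::rnorm(m3 * k), m3, k)
  if (!is.null(xyz0)) {
    rb <- .rigid_basis(xyz0)
    raw <- raw - rb %*% crossprod(rb, raw)
  }
  q <- qr.Q(qr(raw))
  for (j in seq_len(k)) {
    peak <- which.max(abs(q[, j]))
    if (q[peak, j] < 0) q[, j] <- -q[, j]
  }
  q
}

.spec_modes <- function(spec, xyz0 = NULL) {
  k <- length(spec$mode_variances)
  if (k == 0) return(NULL)
  if (is.null(spec$mode_directions))
    .random_modes(3 * spec$m_residues, k, spec$seed, xyz0)
  else spec$mode_directions
}

#' Sample an ensemble with planted modes and clusters
#'
#' Each conformer is the reference chain plus (a) mode displacements
#' `a_k v_k` with `a_k ~ N(0, variance_k)`, (b) a cluster offset sampled by
#' weight, (c) isotropic Gaussian noise, and (d) optional rigid-body jitter.
#' The ground truth records the planted directions, variances and cluster
#' labels.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `ensemble` (a `coord_ensemble`) and `truth`
#'   (`mode_directions`, `mode_variances`, `labels`, `reference`).
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ref <- make_reference(spec$m_residues, spec$geometry, seed = spec$seed)
  xyz0 <- ca_coords(ref)
  r0 <- xyz_to_flat(xyz0)
  m3 <- length(r0)
  modes <- .spec_modes(spec, xyz0)
  n <- spec$n_conformers
  labels <- integer(n)
  mat <- matrix(NA_real_, n, m3)
  for (i in seq_len(n)) {
    .substream(spec$seed, i)
    x <- r0
    if (!is.null(modes)) {
      amp <- stats::rnorm(ncol(modes), 0, sqrt(spec$mode_variances))
      x <- x + as.numeric(modes %*% amp)
    }
    if (!is.null(spec$cluster_offsets)) {
      labels[i] <- sample.int(nrow(spec$cluster_offsets), 1,
                              prob = spec$cluster_weights)
      x <- x + spec$cluster_offsets[labels[i], ]
    }
    if (spec$noise_sigma > 0)
      x <- x + stats::rnorm(m3, 0, spec$noise_sigma)
    xyz <- flat_to_xyz(x)
    if (!is.null(spec$rigid_jitter)) {
      rot <- .random_rotation(spec$rigid_jitter$rotation %||% 0)
      trans <- stats::rnorm(3, 0, spec$rigid_jitter$translation %||% 0)
      xyz <- .apply_rigid(xyz, rot, trans)
    }
    mat[i, ] <- xyz_to_flat(xyz)
  }
  ens <- new_ensemble(mat, positions = seq_len(spec$m_residues),
                      states = if (any(labels > 0)) labels else NULL)
  list(ensemble = ens,
       truth = list(mode_directions = modes,
                    mode_variances = spec$mode_variances,
                    labels = if (any(labels > 0)) labels else NULL,
                    reference = r0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a trajectory with planted residue-residue correlation
#'
#' Per-frame displacements are drawn from a zero-mean Gaussian whose
#' residue-level correlation equals the target matrix; the same correlation
#' is applied independently to the x, y and z axes, so the residue-level
#' cross-correlation map of the displacements equals the target exactly in
#' expectation. Rigid-body jitter is applied after the displacements to
#' exercise its removal by superposition.
#'
#' @param spec A `synthetic_spec` with a `correlation` matrix.
#' @return List with `ensemble` (frames in order) and `truth`
#'   (`correlation`, `reference`).
#' @export
sample_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$correlation))
    stop("spec has no target correlation matrix")
  ref <- make_reference(spec$m_residues, spec$geometry, seed = spec$seed)
  xyz0 <- ca_coords(ref)
  m <- spec$m_residues
  e <- eigen(spec$correlation, symmetric = TRUE)
  l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m)
  sig <- spec$displacement_sigma
  if (length(sig) == 1) sig <- rep(sig, m)
  if (length(sig) != m)
    stop("displacement_sigma must be scalar or one value per residue")
  n <- spec$n_conformers
  arr <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n)) {
    .substream(spec$seed, i)
    disp <- sig * (l %*% matrix(stats::rnorm(3 * m), m, 3))
    xyz <- xyz0 + disp
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * m, 0, spec$noise_sigma), m, 3)
    if (!is.null(spec$rigid_jitter)) {
      rot <- .random_rotation(spec$rigid_jitter$rotation %||% 0)
      trans <- stats::rnorm(3, 0, spec$rigid_jitter$translation %||% 0)
      xyz <- .apply_rigid(xyz, rot, trans)
    }
    arr[i, , ] <- xyz
  }
  ens <- new_ensemble(arr, positions = seq_len(m))
  list(ensemble = ens,
       truth = list(correlation = spec$correlation,
                    reference = xyz_to_flat(xyz0)))
}

#' Plant a flexible appendage on an ensemble
#'
#' Adds an independent per-conformer rigid displacement (translation of the
#' given scale plus a proportional rotation about the appendage centroid) to
#' the listed positions, turning them into a mobile appendage on an
#' otherwise rigid body. The ground truth records the planted rigid core as
#' the complement, which [find_core()] should recover.
#'
#' @param ensemble A `coord_ensemble`.
#' @param positions Residue numbers to perturb (non-empty).
#' @param jitter_scale Translation scale in Angstrom (rotation scale is
#'   0.05 rad per Angstrom of jitter); 0 leaves the ensemble unchanged.
#' @param seed Seed for the per-conformer displacements.
#' @return List with `ensemble` and `truth` (`appendage`, `core`).
#' @export
plant_flexible_appendage <- function(ensemble, positions, jitter_scale,
                                     seed = 1) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (!length(positions)) stop("appendage positions must be non-empty")
  idx <- match(positions, ensemble$positions)
  if (anyNA(idx))
    stop("appendage positions outside the frame: ",
         paste(positions[is.na(idx)], collapse = ", "))
  arr <- ensemble$coords
  if (jitter_scale > 0) {
    for (i in seq_len(dim(arr)[1])) {
      .substream(seed, i)
      rot <- .random_rotation(0.05 * jitter_scale)
      trans <- stats::rnorm(3, 0, jitter_scale)
      arr[i, idx, ] <- .apply_rigid(matrix(arr[i, idx, ], ncol = 3),
                                    rot, trans)
    }
  }
  out <- ensemble
  out$coords <- arr
  list(ensemble = out,
       truth = list(appendage = sort(positions),
                    core = sort(setdiff(ensemble$positions, positions))))
}

#' Two-state "GTP-like/GDP-like" toy fixture
#'
#' Convenience generator for a two-cluster ensemble emulating, at toy scale,
#' the separation of nucleotide states along the leading principal
#' component: the two cluster offsets displace a contiguous "switch" block
#' of residues in opposite directions along the first planted mode.
#'
#' @param m_residues Chain length (default 30).
#' @param n_conformers Ensemble size.
#' @param separation Distance between cluster centers along the planted
#'   mode, Angstrom (default 10).
#' @param noise_sigma Isotropic noise (default 0.5).
#' @param switch_positions Residues carrying the offset (default the middle
#'   third of the chain).
#' @param seed Seed.
#' @return List with `ensemble` and `truth` as in [sample_ensemble()].
#' @export
two_state_fixture <- function(m_residues = 30, n_conformers = 40,
                              separation = 10, noise_sigma = 0.5,
                              switch_positions = NULL, seed = 1) {
  if (is.null(switch_positions))
    switch_positions <- seq(floor(m_residues / 3),
                            floor(2 * m_residues / 3))
  dir <- numeric(3 * m_residues)
  coord_idx <- as.vector(vapply(switch_positions,
                                function(p) (3 * (p - 1) + 1):(3 * p),
                                integer(3)))
  dir[coord_idx] <- 1
  # a state change is an internal rearrangement: remove the rigid-body
  # component (which superposition would absorb) before scaling
  ref <- make_reference(m_residues, "zigzag")
  rb <- .rigid_basis(ca_coords(ref))
  dir <- dir - as.numeric(rb %*% crossprod(rb, dir))
  dir <- dir / sqrt(sum(dir^2))
  offsets <- rbind(dir * separation / 2, -dir * separation / 2)
  spec <- synthetic_spec(m_residues, n_conformers,
                         geometry = "zigzag",
                         mode_variances = 1,
                         mode_directions = matrix(dir, ncol = 1),
                         cluster_offsets = offsets,
                         cluster_weights = c(0.5, 0.5),
                         noise_sigma = noise_sigma,
                         seed = seed)
  sample_ensemble(spec)
}
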