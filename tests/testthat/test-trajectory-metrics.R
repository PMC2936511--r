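# RMSD series, RMSF with paired tests, DCCMs, distance series and pseudo
# torsions.

# Trajectory whose frames are copies of a reference with chosen blocks
# displaced; anchors stay put so fitting on them is exact.
block_trajectory <- function(m = 20, n = 6, displace = NULL) {
  ref <- ca_coords(make_reference(m, "zigzag"))
  arr <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n)) {
    xyz <- ref
    if (!is.null(displace)) xyz <- displace(xyz, i)
    arr[i, , ] <- xyz
  }
  list(traj = new_ensemble(arr, positions = seq_len(m)), ref = ref)
}

test_that("rmsd_series is zero for identical frames and exact for a shift", {
  bt <- block_trajectory()
  ref_struct <- make_reference(20, "zigzag")
  rs <- rmsd_series(bt$traj, ref_struct)
  expect_equal(rs$rmsd, rep(0, 6), tolerance = 1e-10)

  # displace the selection perpendicular to the chain plane by exactly d,
  # fit on the untouched rigid set -> RMSD equals d
  d <- 1.7
  bt2 <- block_trajectory(displace = function(xyz, i) {
    xyz[15:20, 3] <- xyz[15:20, 3] + d
    xyz
  })
  rs2 <- rmsd_series(bt2$traj, bt2$ref, selection = 15:20, fit = 1:10)
  expect_equal(rs2$rmsd, rep(d, 6), tolerance = 1e-9)
})

test_that("a two-state trajectory gives a step-function RMSD series", {
  m <- 15
  ref <- ca_coords(make_reference(m, "zigzag"))
  a <- ref
  b <- ref; b[10:15, 2] <- b[10:15, 2] + 2.5
  arr <- array(NA_real_, c(20, m, 3))
  for (i in 1:20) arr[i, , ] <- if (i <= 10) a else b
  traj <- new_ensemble(arr, positions = seq_len(m))
  rs <- rmsd_series(traj, ref, fit = 1:8)
  level_a <- rmsd_between(a, ref, superpose = TRUE)
  level_b <- sqrt(mean(rowSums((b - ref)^2)))
  expect_equal(rs$rmsd[1:10], rep(level_a, 10), tolerance = 1e-9)
  expect_equal(rs$rmsd[11:20], rep(level_b, 10), tolerance = 1e-6)
  expect_equal(attr(rs, "summary")[["max"]], max(rs$rmsd))
})

test_that("rmsd_series with fit = selection matches rmsd_between per frame", {
  spec <- synthetic_spec(18, 8, mode_variances = 2, noise_sigma = 0.3,
                         seed = 44)
  traj <- sample_ensemble(spec)$ensemble
  ref <- ca_coords(make_reference(18, "zigzag"))
  rs <- rmsd_series(traj, ref, selection = NULL, fit = NULL)
  direct <- vapply(1:8, function(i)
    rmsd_between(traj$coords[i, , ], ref, superpose = TRUE), numeric(1))
  expect_equal(rs$rmsd, direct, tolerance = 1e-9)
})

test_that("rmsf vanishes for static or rigidly moving trajectories", {
  bt <- block_trajectory()
  expect_equal(unname(rmsf(bt$traj)), rep(0, 20), tolerance = 1e-12)
  moved <- bt$traj
  for (i in 1:6)
    moved$coords[i, , ] <- random_rigid_copy(bt$traj$coords[i, , ], i)
  expect_lt(max(rmsf(moved)), 1e-6)
})

test_that("rmsf recovers planted per-residue noise amplitudes", {
  m <- 30; n <- 2000
  sig <- c(rep(0.001, 10), seq(0.3, 1.0, length.out = 20))
  ref <- ca_coords(make_reference(m, "zigzag"))
  set.seed(61)
  arr <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n))
    arr[i, , ] <- ref + matrix(rnorm(3 * m, 0, sig), m, 3)
  traj <- new_ensemble(arr, positions = seq_len(m))
  fl <- rmsf(traj, fit = 1:10)  # fit on the quasi-static anchors
  expected <- sig * sqrt(3)
  expect_true(all(abs(fl[11:30] - expected[11:30]) /
                    expected[11:30] < 0.05))
})

test_that("compare_rmsf handles identical, offset and noisy profiles", {
  a <- rmsf_profile(list(c(a = 1, b = 2, c = 1.5, d = 1.2, e = 0.8)))
  same <- compare_rmsf(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  b <- a; b$mean <- a$mean + 0.5
  shifted <- compare_rmsf(a, b)
  expect_true(shifted$degenerate)
  expect_lt(shifted$p_value, 1e-10)
  expect_equal(shifted$mean_difference, 0.5)

  # planted 0.3 A offset with residue noise sd 0.2 at M=166: paired t is
  # significant at the 0.01 level in (nearly) every seeded replicate
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    base <- runif(166, 0.5, 2)
    pa <- list(positions = 1:166, per_run = rbind(base), mean = base,
               sd = rep(0, 166))
    class(pa) <- "rmsf_profile"
    pb <- pa
    pb$mean <- base + 0.3 + rnorm(166, 0, 0.2)
    if (compare_rmsf(pa, pb)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
  expect_error(compare_rmsf(a, rmsf_profile(list(c(x = 1, y = 2)))),
               "frames differ")
})

test_that("dccm has unit diagonal, symmetry and exact planted signs", {
  # residues 12 and 18 move with identical vectors, 12 and 15 opposite
  bt <- block_trajectory(n = 12, displace = function(xyz, i) {
    u <- c(0, 0, sin(i))
    xyz[12, ] <- xyz[12, ] + u
    xyz[18, ] <- xyz[18, ] + u
    xyz[15, ] <- xyz[15, ] - u
    xyz
  })
  d <- dccm(bt$traj, fit = 1:10)
  expect_equal(d$matrix, t(d$matrix))
  expect_equal(unname(diag(d$matrix)), rep(1, 20))
  expect_equal(d$matrix["12", "18"], 1, tolerance = 1e-9)
  expect_equal(d$matrix["12", "15"], -1, tolerance = 1e-9)
  expect_true(all(d$matrix >= -1 & d$matrix <= 1))
  # static residues are flagged zeros
  expect_true(2 %in% attr(d, "zero_variance"))
  expect_equal(d$matrix["2", "12"], 0)
  # masking is a view, never applied to stored values
  masked <- dccm_display(d, threshold = 0.9)
  expect_true(anyNA(masked))
  expect_false(anyNA(d$matrix))
})

test_that("dccm recovers a planted block correlation matrix", {
  M <- 24
  C <- diag(M)
  C[9:16, 9:16] <- 0.8; C[17:24, 17:24] <- 0.8
  C[9:16, 17:24] <- -0.5; C[17:24, 9:16] <- -0.5
  diag(C) <- 1
  spec <- synthetic_spec(M, 3000, correlation = C,
                         displacement_sigma = c(rep(0.02, 8), rep(1, 16)),
                         rigid_jitter = list(rotation = 0.1,
                                             translation = 1),
                         seed = 13)
  traj <- sample_trajectory(spec)$ensemble
  d <- dccm(traj, fit = 1:8)
  expect_lt(max(abs(d$matrix[9:24, 9:24] - C[9:24, 9:24])), 0.05)
})

test_that("rmsf and dccm are invariant to global rigid motion", {
  spec <- synthetic_spec(15, 40, mode_variances = 1, noise_sigma = 0.2,
                         seed = 71)
  traj <- sample_ensemble(spec)$ensemble
  moved <- traj
  rigid <- random_rigid_copy(diag(3), seed = 5)  # just to get a transform
  for (i in seq_len(dim(traj$coords)[1]))
    moved$coords[i, , ] <- random_rigid_copy(traj$coords[i, , ], seed = 303)
  expect_equal(rmsf(moved), rmsf(traj), tolerance = 1e-6)
  expect_equal(dccm(moved)$matrix, dccm(traj)$matrix, tolerance = 1e-6)
})

test_that("atom distance series track planted geometries", {
  # one CA anchor plus a GTP PG ligand atom per frame
  make_frames <- function(pg_xyz) {
    lapply(seq_len(nrow(pg_xyz)), function(i) data.frame(
      type = c("ATOM", "ATOM", "ATOM", "ATOM", "HETATM"),
      name = c("CA", "CA", "CA", "CA", "PG"),
      resname = c("ALA", "ALA", "ALA", "ALA", "GTP"),
      chain = "A", resno = c(1:4, 201),
      x = c(0, 3.8, 7.6, 11.4, pg_xyz[i, 1]),
      y = c(0, 2.0, 0, 2.0, pg_xyz[i, 2]),
      z = c(0, 0, 0, 0, pg_xyz[i, 3])))
  }
  path <- withr::local_tempfile(fileext = ".pdb")
  # fixed 5 A above residue 1
  write_stack_pdb(make_frames(cbind(0, 0, rep(5, 4))), path)
  stack <- read_conformer_stack(path)
  ds <- atom_distance_series(stack, c("1:CA", "GTP:PG"))
  expect_equal(ds$distance, rep(5, 4))
  expect_equal(unname(attr(ds, "summary")), c(5, 5, 5))

  # orbit at radius 7 around residue 1
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  write_stack_pdb(make_frames(cbind(7 * cos(th), 7 * sin(th), 0)), path)
  ds2 <- atom_distance_series(read_conformer_stack(path), c("1:CA", "GTP:PG"))
  # PDB fixed-point coordinates carry 0.001 A precision
  expect_equal(ds2$distance, rep(7, 8), tolerance = 2e-3)

  # linear approach 20 -> 10 A over 101 frames: mean 15, min 10, max 20
  zs <- seq(20, 10, length.out = 101)
  write_stack_pdb(make_frames(cbind(0, 0, zs)), path)
  ds3 <- atom_distance_series(read_conformer_stack(path), c("1:CA", "GTP:PG"))
  sm <- attr(ds3, "summary")
  expect_equal(unname(sm[c("min", "max", "mean")]), c(10, 20, 15),
               tolerance = 1e-9)
  expect_error(
    atom_distance_series(stack, c("1:CA", "GTP:XX")), "not found")
})

test_that("pseudo torsions are 180 on a zigzag and wrap correctly", {
  ref <- make_reference(10, "zigzag")
  pt <- pseudo_torsions(ref)
  expect_equal(pt$positions, 2:8)
  expect_equal(abs(pt$angles), rep(180, 7), tolerance = 1e-9)
  expect_equal(unname(torsion_delta(pt, pt)), rep(0, 7))

  p1 <- structure(list(positions = 2:4, angles = c(170, 10, -100)),
                  class = "pseudo_torsion")
  p2 <- structure(list(positions = 2:4, angles = c(-170, -10, 100)),
                  class = "pseudo_torsion")
  expect_equal(unname(torsion_delta(p1, p2)), c(20, 20, 160))

  # helix torsions fall in (-180, 180] and are position-independent
  hx <- pseudo_torsions(make_reference(20, "helix"))
  expect_true(all(hx$angles > -180 & hx$angles <= 180))
  expect_equal(diff(range(hx$angles)), 0, tolerance = 1e-9)
})

test_that("chain breaks mark affected torsions undefined", {
  xyz <- ca_coords(make_reference(12, "zigzag"))
  xyz[7:12, 1] <- xyz[7:12, 1] + 30  # break between residues 6 and 7
  pt <- pseudo_torsions(xyz)
  expect_true(all(is.na(pt$angles[pt$positions %in% 5:7])))
  expect_true(all(!is.na(pt$angles[pt$positions %in% c(2:4, 8:10)])))
  expect_error(pseudo_torsions(xyz[1:3, ]), "at least 4")
})
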