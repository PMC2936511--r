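# Per-trajectory analytics: RMSD series, replicate-averaged RMSF with paired
# t-tests, dynamic cross-correlation maps, atom-pair distance series, and
# pseudo C-alpha torsion difference profiles.

#' Named residue regions of the Ras catalytic domain
#'
#' Functional regions in author numbering: the phosphate-binding P-loop
#' (10-17) and the nucleotide-state-dependent switch loops: switch 1 (25-40),
#' switch 2 (57-75) and switch 3 (47-49 plus 161-165).
#'
#' @param name One of `"ploop"`, `"switch1"`, `"switch2"`, `"switch3"`.
#' @return Integer vector of residue numbers.
#' @export
ras_region <- function(name = c("switch1", "switch2", "switch3", "ploop")) {
  name <- match.arg(name)
  switch(name,
         ploop = 10:17,
         switch1 = 25:40,
         switch2 = 57:75,
         switch3 = c(47:49, 161:165))
}

# Resolve a selection (residue numbers, region name, core_selection or NULL)
# to frame indices.
.selection_indices <- function(selection, positions) {
  if (is.null(selection)) return(seq_along(positions))
  if (is.character(selection) && length(selection) == 1)
    selection <- ras_region(selection)
  if (inherits(selection, "core_selection")) selection <- selection$positions
  idx <- which(positions %in% selection)
  if (!length(idx)) stop("empty selection after mapping onto the frame")
  idx
}

#' RMSD time series of a trajectory against a reference conformer
#'
#' Every frame is superposed onto the reference over the fit set (default:
#' all frame positions; typically the ensemble core), then the RMSD is
#' evaluated over the selection without further fitting, so mobile-region
#' deviations are measured in the core reference frame.
#'
#' @param traj A `coord_ensemble` (frames in order).
#' @param reference A `structure3d` or an M x 3 matrix on the trajectory
#'   frame.
#' @param selection Residue numbers, a region name (see [ras_region()]), a
#'   `core_selection`, or `NULL` for all positions.
#' @param fit Fit set in the same forms as `selection`; default all
#'   positions.
#' @param times Optional frame times; default the frame index.
#' @return A data.frame (`frame`, `time`, `rmsd`) with a `summary` attribute
#'   (min/max/mean).
#' @export
rmsd_series <- function(traj, reference, selection = NULL, fit = NULL,
                        times = NULL) {
  stopifnot(inherits(traj, "coord_ensemble"))
  ref <- if (inherits(reference, "structure3d")) {
    m <- ca_coords(reference, residues = traj$positions)
    if (nrow(m) != length(traj$positions))
      stop("reference lacks C-alpha atoms at trajectory positions: ",
           paste(setdiff(traj$positions, as.integer(rownames(m))),
                 collapse = ", "))
    m[match(traj$positions, as.integer(rownames(m))), , drop = FALSE]
  } else reference
  stopifnot(nrow(ref) == length(traj$positions))
  sel_idx <- .selection_indices(selection, traj$positions)
  fit_idx <- .selection_indices(fit, traj$positions)
  n <- dim(traj$coords)[1]
  vals <- vapply(seq_len(n), function(i) {
    xyz <- traj$coords[i, , ]
    sup <- kabsch_fit(xyz, ref, fit_idx)
    xyz <- apply_superposition(sup, xyz)
    sqrt(mean(rowSums((xyz[sel_idx, , drop = FALSE] -
                       ref[sel_idx, , drop = FALSE])^2)))
  }, numeric(1))
  if (is.null(times)) times <- seq_len(n)
  out <- data.frame(frame = seq_len(n), time = times, rmsd = vals)
  attr(out, "summary") <- c(min = min(vals), max = max(vals),
                            mean = mean(vals))
  out
}

# Superpose trajectory frames for fluctuation analysis: initial fit to
# frame 1, then the mean is recomputed once and frames are refit to it.
.fluctuation_frame <- function(traj, fit = NULL) {
  fit_idx <- .selection_indices(fit, traj$positions)
  sup <- .superpose_to_mean(traj$coords, fit_idx)
  sup
}

#' Root-mean-square fluctuation per residue
#'
#' RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2), computed after
#' superposing all frames onto their mean over the fit set. A trajectory
#' that differs only by rigid-body motion therefore has zero RMSF.
#'
#' @param traj A `coord_ensemble` with at least 2 frames.
#' @param fit Fit set (core selection, residue numbers, region name or
#'   `NULL` for all positions).
#' @return Named numeric vector (names = residue numbers), Angstrom.
#' @export
rmsf <- function(traj, fit = NULL) {
  stopifnot(inherits(traj, "coord_ensemble"))
  if (dim(traj$coords)[1] < 2) stop("need at least 2 frames")
  sup <- .fluctuation_frame(traj, fit)
  dev <- sweep(sup$coords, c(2, 3), sup$mean)
  out <- sqrt(apply(dev^2, 2, function(sl) mean(rowSums(sl))))
  names(out) <- traj$positions
  out
}

#' Replicate RMSF profile
#'
#' Aggregates per-run RMSF vectors from replicate trajectories of one system
#' into a profile with replicate mean and standard deviation per residue.
#'
#' @param runs List of `coord_ensemble` replicates (or a list of precomputed
#'   RMSF vectors on the same positions).
#' @param fit Fit set forwarded to [rmsf()].
#' @return Object of class `rmsf_profile`: `positions`, `per_run` (R x M),
#'   `mean`, `sd` (zero when R = 1).
#' @export
rmsf_profile <- function(runs, fit = NULL) {
  stopifnot(length(runs) >= 1)
  vecs <- lapply(runs, function(r)
    if (inherits(r, "coord_ensemble")) rmsf(r, fit) else r)
  positions <- suppressWarnings(as.integer(names(vecs[[1]])))
  if (is.null(positions) || anyNA(positions))
    positions <- seq_along(vecs[[1]])
  per_run <- do.call(rbind, vecs)
  sds <- apply(per_run, 2, stats::sd)
  if (nrow(per_run) == 1) sds <- rep(0, ncol(per_run))
  out <- list(positions = positions, per_run = per_run,
              mean = colMeans(per_run), sd = sds)
  class(out) <- "rmsf_profile"
  out
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("<rmsf_profile> ", nrow(x$per_run), " run(s) x ",
      length(x$positions), " residues; mean RMSF ",
      sprintf("%.2f", mean(x$mean)), " A\n", sep = "")
  invisible(x)
}

#' Paired t-test between two replicate-mean RMSF profiles
#'
#' Pairs the replicate-mean fluctuation of each residue across the two
#' systems and applies the classic two-sided paired t-test with M-1 degrees
#' of freedom, as used to ask whether one system is significantly more
#' dynamic than another.
#'
#' If the per-residue differences have zero variance the statistic is
#' undefined; the result is then flagged `degenerate` and reported as the
#' limit (t = 0, p = 1 for identical profiles; p = 0 for a constant nonzero
#' offset).
#'
#' @param profile_a,profile_b `rmsf_profile` objects (or plain numeric
#'   vectors) on identical position frames.
#' @return List: `t`, `df`, `p_value`, `mean_difference` (b minus a),
#'   `degenerate`.
#' @export
compare_rmsf <- function(profile_a, profile_b) {
  a <- if (inherits(profile_a, "rmsf_profile")) profile_a$mean else profile_a
  b <- if (inherits(profile_b, "rmsf_profile")) profile_b$mean else profile_b
  pa <- if (inherits(profile_a, "rmsf_profile")) profile_a$positions
        else seq_along(a)
  pb <- if (inherits(profile_b, "rmsf_profile")) profile_b$positions
        else seq_along(b)
  if (!identical(as.integer(pa), as.integer(pb)))
    stop("position frames differ between the two profiles")
  d <- b - a
  m <- length(d)
  if (stats::sd(d) < .Machine$double.eps^0.5 * (1 + mean(abs(d)))) {
    if (all(abs(d) < 1e-12))
      return(list(t = 0, df = m - 1, p_value = 1, mean_difference = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = m - 1, p_value = 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Dynamic cross-correlation map
#'
#' After the same mean-frame superposition as [rmsf()], computes
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) with dr the
#' instantaneous displacement from the mean position. The matrix is
#' symmetric with unit diagonal and entries in [-1, 1]. Residues with zero
#' fluctuation have undefined correlations; these are stored as flagged
#' zeros (diagonal 1) and listed in the `zero_variance` attribute.
#'
#' The conventional display cutoff (only |C| > threshold shown, 0.25 by
#' default) is a view option recorded on the object; stored values are never
#' masked.
#'
#' @param traj A `coord_ensemble` with at least 3 frames.
#' @param fit Fit set as in [rmsf()].
#' @param display_threshold Display cutoff stored on the result.
#' @return Object of class `dccm_map`: `matrix` (M x M, dimnames = residue
#'   numbers), `display_threshold`.
#' @export
dccm <- function(traj, fit = NULL, display_threshold = 0.25) {
  stopifnot(inherits(traj, "coord_ensemble"))
  n <- dim(traj$coords)[1]
  if (n < 3) stop("need at least 3 frames")
  sup <- .fluctuation_frame(traj, fit)
  dev <- sweep(sup$coords, c(2, 3), sup$mean)
  cross <- (crossprod(dev[, , 1]) + crossprod(dev[, , 2]) +
            crossprod(dev[, , 3])) / n
  amp <- diag(cross)
  zero <- amp < 1e-20
  denom <- sqrt(pmax(amp, 1e-300))
  cmat <- cross / outer(denom, denom)
  cmat[zero, ] <- 0; cmat[, zero] <- 0
  diag(cmat) <- 1
  cmat <- pmin(pmax((cmat + t(cmat)) / 2, -1), 1)
  dimnames(cmat) <- list(traj$positions, traj$positions)
  out <- list(matrix = cmat, display_threshold = display_threshold)
  attr(out, "zero_variance") <- traj$positions[zero]
  class(out) <- "dccm_map"
  out
}

#' @export
print.dccm_map <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat("<dccm_map> ", nrow(x$matrix), " residues; ",
      sprintf("%.1f", 100 * mean(abs(off) > x$display_threshold)),
      "% of pairs above |C| = ", x$display_threshold, "\n", sep = "")
  invisible(x)
}

#' Displayable view of a DCCM
#'
#' Returns a copy of the correlation matrix with entries of absolute value
#' at or below the display threshold set to `NA`, leaving the stored matrix
#' untouched.
#'
#' @param x A `dccm_map`.
#' @param threshold Cutoff; default the stored `display_threshold`.
#' @return M x M matrix with sub-threshold entries `NA`.
#' @export
dccm_display <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "dccm_map"))
  if (is.null(threshold)) threshold <- x$display_threshold
  m <- x$matrix
  m[abs(m) <= threshold] <- NA
  m
}

# Parse an atom spec: "61:NE2" (residue number) or "GTP:PG" (residue name).
.parse_atom_spec <- function(spec) {
  if (is.list(spec)) return(spec)
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("atom spec must be 'residue:atom', e.g. '61:NE2' or 'GTP:PG'")
  if (grepl("^[0-9]+$", parts[1]))
    list(residue_number = as.integer(parts[1]), atom = parts[2])
  else
    list(residue_name = parts[1], atom = parts[2])
}

.find_atom <- function(meta, spec) {
  if (!is.null(spec$residue_number))
    idx <- which(meta$residue_number == spec$residue_number &
                 meta$atom_name == spec$atom & !meta$het)
  else
    idx <- which(meta$residue_name == spec$residue_name &
                 meta$atom_name == spec$atom)
  idx
}

#' Distance time series between two atoms
#'
#' Tracks the Euclidean distance between two atoms across all frames of a
#' conformer stack read with [read_conformer_stack()], e.g. between the Q61
#' side-chain NE2 and the nucleotide gamma-phosphate PG.
#'
#' @param stack A `coord_ensemble` carrying the `"all_atoms"` attribute
#'   (from [read_conformer_stack()]).
#' @param pair Length-2 specification: each element `"61:NE2"` style
#'   (residue number) or `"GTP:PG"` style (ligand residue name), or an
#'   equivalent list.
#' @param times Optional frame times; default the frame index.
#' @return A data.frame (`frame`, `time`, `distance`) with a `summary`
#'   attribute (min/max/mean) and a `pair` attribute.
#' @export
atom_distance_series <- function(stack, pair, times = NULL) {
  all_atoms <- attr(stack, "all_atoms")
  if (is.null(all_atoms))
    stop("stack carries no full-atom coordinates; read it with ",
         "read_conformer_stack()")
  stopifnot(length(pair) == 2)
  sp <- lapply(pair, .parse_atom_spec)
  idx <- lapply(sp, .find_atom, meta = all_atoms$meta)
  for (k in 1:2) {
    if (!length(idx[[k]]))
      stop("atom not found in any frame: ",
           paste(unlist(sp[[k]]), collapse = ":"))
    idx[[k]] <- idx[[k]][1]
  }
  xyz <- all_atoms$xyz
  n <- dim(xyz)[1]
  a <- xyz[, idx[[1]], , drop = FALSE]
  b <- xyz[, idx[[2]], , drop = FALSE]
  if (anyNA(a) || anyNA(b)) {
    bad <- which(apply(is.na(a[, 1, ]) | is.na(b[, 1, ]), 1, any))[1]
    miss <- if (anyNA(a[bad, 1, ])) sp[[1]] else sp[[2]]
    stop("atom ", paste(unlist(miss), collapse = ":"),
         " missing coordinates in frame ", bad)
  }
  vals <- sqrt(rowSums((a[, 1, ] - b[, 1, ])^2))
  if (is.null(times)) times <- seq_len(n)
  out <- data.frame(frame = seq_len(n), time = times, distance = vals)
  attr(out, "summary") <- c(min = min(vals), max = max(vals),
                            mean = mean(vals))
  attr(out, "pair") <- vapply(sp, function(s)
    paste(unlist(s), collapse = ":"), character(1))
  out
}

# Dihedral angle (degrees, (-180, 180]) over four points given as rows.
.dihedral <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Pseudo C-alpha torsion profile
#'
#' The pseudo torsion at residue i is the dihedral over C-alpha atoms
#' i-1, i, i+1, i+2, a backbone-conformation descriptor that needs no
#' side-chain or full-backbone detail. Positions spanning a chain break
#' (consecutive C-alpha distance above `break_cutoff`; the C-alpha virtual
#' bond is ~3.8 Angstrom) are marked undefined (`NA`).
#'
#' @param conformer M x 3 C-alpha matrix (M >= 4), a `structure3d`, or a
#'   `coord_ensemble` member selected with `frame`.
#' @param positions Residue numbers for the M rows (default 1..M, or the
#'   frame of the supplied object).
#' @param frame Frame index when `conformer` is a `coord_ensemble`.
#' @param break_cutoff Chain-break distance cutoff in Angstrom.
#' @return Object of class `pseudo_torsion`: `positions` (residues i with a
#'   defined quadruple), `angles` (degrees in (-180, 180], `NA` at breaks).
#' @export
pseudo_torsions <- function(conformer, positions = NULL, frame = 1,
                            break_cutoff = 4.5) {
  if (inherits(conformer, "coord_ensemble")) {
    positions <- conformer$positions
    conformer <- conformer$coords[frame, , ]
  } else if (inherits(conformer, "structure3d")) {
    m <- ca_coords(conformer)
    positions <- as.integer(rownames(m))
    conformer <- m
  }
  stopifnot(is.matrix(conformer), ncol(conformer) == 3)
  m <- nrow(conformer)
  if (m < 4) stop("need at least 4 C-alpha positions")
  if (is.null(positions)) positions <- seq_len(m)
  gaps <- sqrt(rowSums((conformer[-1, , drop = FALSE] -
                        conformer[-m, , drop = FALSE])^2)) > break_cutoff
  idx <- 2:(m - 2)
  angles <- vapply(idx, function(i) {
    if (any(gaps[(i - 1):(i + 1)])) return(NA_real_)
    .dihedral(conformer[(i - 1):(i + 2), , drop = FALSE])
  }, numeric(1))
  out <- list(positions = positions[idx], angles = angles)
  class(out) <- "pseudo_torsion"
  out
}

#' Wrapped absolute torsion differences against a reference profile
#'
#' Differences are wrapped onto the circle, so 170 vs -170 degrees is a
#' 20-degree change, and reported as absolute values in [0, 180].
#'
#' @param profile,reference `pseudo_torsion` objects on the same positions.
#' @return Named numeric vector of absolute differences (degrees, [0, 180]);
#'   `NA` where either torsion is undefined.
#' @export
torsion_delta <- function(profile, reference) {
  stopifnot(inherits(profile, "pseudo_torsion"),
            inherits(reference, "pseudo_torsion"))
  if (!identical(profile$positions, reference$positions))
    stop("torsion profiles are on different position frames")
  d <- abs(((profile$angles - reference$angles + 180) %% 360) - 180)
  names(d) <- profile$positions
  d
}
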