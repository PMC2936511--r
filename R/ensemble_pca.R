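# Covariance PCA of core-superposed C-alpha coordinates, projection of new
# conformers into the PC subspace, and clustering of projections into
# conformational states.

# Superpose all conformers onto the ensemble mean over the given fit indices:
# initial fit to conformer 1, then refits to the running mean. The default
# single refit matches the usual fluctuation-analysis convention; with
# `tol` set, refitting iterates until the mean stops moving, so a subsequent
# fit of any member onto the converged mean is the identity transform.
.superpose_to_mean <- function(arr, fit_idx, tol = NULL, max_iter = 100) {
  arr <- .superpose_round(arr, arr[1, , ], fit_idx)
  mean_xyz <- .ensemble_mean(arr)
  arr <- .superpose_round(arr, mean_xyz, fit_idx)
  if (!is.null(tol)) {
    for (it in seq_len(max_iter)) {
      new_mean <- .ensemble_mean(arr)
      if (max(abs(new_mean - mean_xyz)) < tol) break
      mean_xyz <- new_mean
      arr <- .superpose_round(arr, mean_xyz, fit_idx)
    }
  }
  list(coords = arr, mean = .ensemble_mean(arr))
}

.core_indices <- function(core, positions) {
  if (is.null(core)) return(seq_along(positions))
  pos <- if (inherits(core, "core_selection")) core$positions else core
  idx <- match(pos, positions)
  if (anyNA(idx))
    stop("core positions absent from ensemble frame: ",
         paste(pos[is.na(idx)], collapse = ", "))
  idx
}

#' Principal component analysis of a coordinate ensemble
#'
#' Superposes every conformer onto the ensemble mean over the core positions,
#' then diagonalizes the covariance matrix of all 3M Cartesian C-alpha
#' coordinates (divisor N-1). The covariance is computed over the full frame
#' even though only the core defines the reference orientation: mobile
#' regions (e.g. the nucleotide switch loops) then dominate the leading
#' components, which is what separates conformational states.
#'
#' Eigenvector sign is fixed so the largest-magnitude coordinate of each
#' column is positive, making projections reproducible.
#'
#' @param ensemble A `coord_ensemble` with at least 3 conformers.
#' @param core A `core_selection` (or residue-number vector) used for the
#'   superposition; `NULL` fits on all positions.
#' @return Object of class `pca_atlas`: `mean` (3M), `vectors` (3M x K
#'   orthonormal), `values` (descending, Angstrom^2), `variance_fraction`,
#'   `positions`, `core`.
#' @export
fit_pca <- function(ensemble, core = NULL) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  n <- dim(ensemble$coords)[1]
  if (n < 3) stop("PCA needs at least 3 conformers")
  fit_idx <- .core_indices(core, ensemble$positions)
  sup <- .superpose_to_mean(ensemble$coords, fit_idx, tol = 1e-12)
  x <- array_to_flat(sup$coords)
  mu <- colMeans(x)
  cv <- stats::cov(x)
  e <- eigen(cv, symmetric = TRUE)
  values <- pmax(e$values, 0)
  vectors <- e$vectors
  # sign convention: largest-magnitude coordinate positive
  for (k in seq_len(ncol(vectors))) {
    peak <- which.max(abs(vectors[, k]))
    if (vectors[peak, k] < 0) vectors[, k] <- -vectors[, k]
  }
  out <- list(mean = mu, vectors = vectors, values = values,
              variance_fraction = values / sum(diag(cv)),
              positions = ensemble$positions,
              core = core,
              states = ensemble$states)
  class(out) <- "pca_atlas"
  out
}

#' @export
print.pca_atlas <- function(x, ...) {
  k <- min(3, length(x$values))
  cat("<pca_atlas> ", length(x$mean) / 3, " positions; PC1-",
      k, " variance fractions: ",
      paste(sprintf("%.3f", x$variance_fraction[1:k]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project conformers into a PCA atlas
#'
#' Each conformer is first superposed onto the atlas mean conformation over
#' the core positions, then scored against the leading eigenvectors. Rigidly
#' transformed copies of a conformer therefore project identically.
#'
#' @param conformers A `coord_ensemble` on the same residue frame as the
#'   model (or a single M x 3 matrix).
#' @param model A `pca_atlas`.
#' @param k Number of components (default 3).
#' @return Object of class `projection_set`: `scores` (N x k, columns
#'   `PC1..PCk`), `conformer_ids`, `states`, `cluster` (NULL until
#'   [cluster_projections()] is applied).
#' @export
project <- function(conformers, model, k = 3) {
  stopifnot(inherits(model, "pca_atlas"))
  if (is.matrix(conformers) && ncol(conformers) == 3) {
    # single conformer: wrap as a 1-member pseudo-ensemble
    arr <- array(NA_real_, c(1, nrow(conformers), 3))
    arr[1, , ] <- conformers
    conformers <- structure(
      list(coords = arr, positions = model$positions,
           conformer_ids = "conformer_1", states = NULL),
      class = "coord_ensemble")
  }
  stopifnot(inherits(conformers, "coord_ensemble"))
  if (!identical(as.integer(conformers$positions),
                 as.integer(model$positions))) {
    bad <- union(setdiff(conformers$positions, model$positions),
                 setdiff(model$positions, conformers$positions))
    stop("residue frame mismatch between conformers and atlas at positions: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  k <- min(k, ncol(model$vectors))
  fit_idx <- .core_indices(model$core, model$positions)
  mean_xyz <- flat_to_xyz(model$mean)
  n <- dim(conformers$coords)[1]
  scores <- matrix(NA_real_, n, k,
                   dimnames = list(conformers$conformer_ids,
                                   paste0("PC", seq_len(k))))
  for (i in seq_len(n)) {
    xyz <- conformers$coords[i, , ]
    fit <- kabsch_fit(xyz, mean_xyz, fit_idx)
    xyz <- apply_superposition(fit, xyz)
    scores[i, ] <- (xyz_to_flat(xyz) - model$mean) %*%
      model$vectors[, seq_len(k), drop = FALSE]
  }
  out <- list(scores = scores, conformer_ids = conformers$conformer_ids,
              states = conformers$states, cluster = NULL)
  class(out) <- "projection_set"
  out
}

#' @export
print.projection_set <- function(x, ...) {
  cat("<projection_set> ", nrow(x$scores), " conformers x ",
      ncol(x$scores), " components",
      if (!is.null(x$cluster)) paste0(", ", length(unique(x$cluster)),
                                      " clusters"),
      "\n", sep = "")
  invisible(x)
}

#' Cluster projected conformers into conformational states
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance in the projected subspace), with the tree cut at `k_clusters`.
#' Labels are renumbered by descending cluster size, so label 1 is always
#' the dominant state.
#'
#' @param projections A `projection_set`.
#' @param k_clusters Number of clusters (>= 2).
#' @param method Linkage passed to [stats::hclust()] (default "complete").
#' @return The `projection_set` with `cluster` labels filled in.
#' @export
cluster_projections <- function(projections, k_clusters = 2,
                                method = "complete") {
  stopifnot(inherits(projections, "projection_set"), k_clusters >= 2)
  sc <- projections$scores
  if (nrow(unique(sc)) < k_clusters)
    stop("fewer distinct projected points (", nrow(unique(sc)),
         ") than requested clusters (", k_clusters, ")")
  hc <- stats::hclust(stats::dist(sc), method = method)
  raw <- stats::cutree(hc, k = k_clusters)
  sizes <- table(raw)
  relabel <- rank(-as.numeric(sizes), ties.method = "first")
  projections$cluster <- as.integer(relabel[match(raw, names(sizes))])
  projections
}

#' Export projections as CSV
#'
#' @param projections A `projection_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(projections, path) {
  df <- data.frame(conformer_id = projections$conformer_ids,
                   state = if (is.null(projections$states)) NA_character_
                           else projections$states,
                   projections$scores,
                   cluster = if (is.null(projections$cluster)) NA_integer_
                             else projections$cluster,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Persist a PCA atlas as a plain-text bundle
#'
#' Writes mean, eigenvalues, eigenvectors, frame positions and core residues
#' as CSV/text files under `dir` so an atlas can be rebuilt without any
#' binary artifacts.
#'
#' @param model A `pca_atlas`.
#' @param dir Output directory (created if needed).
#' @param k Number of eigenvectors to persist (default: all with
#'   non-negligible variance).
#' @return `dir`, invisibly.
#' @export
save_atlas <- function(model, dir, k = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(k)) k <- max(which(model$values > 1e-12 * model$values[1]), 3)
  k <- min(k, ncol(model$vectors))
  utils::write.csv(data.frame(coordinate = seq_along(model$mean),
                              mean = model$mean),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_len(k),
                              eigenvalue = model$values[1:k],
                              variance_fraction = model$variance_fraction[1:k]),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$vectors[, 1:k, drop = FALSE]),
                   file.path(dir, "eigenvectors.csv"), row.names = FALSE)
  writeLines(as.character(model$positions), file.path(dir, "positions.txt"))
  core_pos <- if (is.null(model$core)) model$positions
              else if (inherits(model$core, "core_selection")) model$core$positions
              else model$core
  writeLines(as.character(core_pos), file.path(dir, "core_residues.txt"))
  invisible(dir)
}

#' Load a PCA atlas persisted by [save_atlas()]
#'
#' @param dir Bundle directory.
#' @return A `pca_atlas`.
#' @export
load_atlas <- function(dir) {
  mean_vec <- utils::read.csv(file.path(dir, "mean.csv"))$mean
  ev <- utils::read.csv(file.path(dir, "eigenvalues.csv"))
  vectors <- as.matrix(utils::read.csv(file.path(dir, "eigenvectors.csv")))
  dimnames(vectors) <- NULL
  positions <- as.integer(readLines(file.path(dir, "positions.txt")))
  core <- as.integer(readLines(file.path(dir, "core_residues.txt")))
  out <- list(mean = mean_vec, vectors = vectors,
              values = ev$eigenvalue,
              variance_fraction = ev$variance_fraction,
              positions = positions, core = core, states = NULL)
  class(out) <- "pca_atlas"
  out
}
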