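# Least-squares rigid superposition, RMSD, and the iterated-exclusion
# search for the structurally invariant core of an ensemble.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `target` over a set of fit positions. Reflections are
#' corrected so the rotation always has determinant +1.
#'
#' @param mobile,target M x 3 coordinate matrices on the same frame.
#' @param fit_positions Row indices used in the fit (default: all). At least
#'   3 non-collinear points are required.
#' @return Object of class `superposition`: `rotation` (3 x 3, applied on the
#'   right of row vectors), `translation` (length-3), `rmsd` over the fit
#'   positions (Angstrom), `n_fit`.
#' @export
kabsch_fit <- function(mobile, target, fit_positions = NULL) {
  stopifnot(ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) == nrow(target))
  if (is.null(fit_positions)) fit_positions <- seq_len(nrow(mobile))
  if (length(fit_positions) < 3)
    stop("need at least 3 fit positions")
  p <- mobile[fit_positions, , drop = FALSE]
  q <- target[fit_positions, , drop = FALSE]
  cp <- colMeans(p); cq <- colMeans(q)
  a <- sweep(p, 2, cp); b <- sweep(q, 2, cq)
  # degenerate fit sets (coincident or collinear points) have rank < 2
  if (svd(a)$d[2] < 1e-8 || svd(b)$d[2] < 1e-8)
    stop("degenerate fit set: points are coincident or collinear")
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a %*% r
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  out <- list(rotation = r,
              translation = as.numeric(cq - cp %*% r),
              rmsd = rmsd,
              n_fit = length(fit_positions))
  class(out) <- "superposition"
  out
}

#' Apply a superposition to coordinates
#'
#' @param fit A `superposition` from [kabsch_fit()].
#' @param coords M x 3 matrix.
#' @return Transformed M x 3 matrix.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd = ", sprintf("%.4f", x$rmsd), " A over ",
      x$n_fit, " positions\n", sep = "")
  invisible(x)
}

#' Root-mean-square deviation between two conformers
#'
#' @param a,b M x 3 coordinate matrices on the same frame.
#' @param positions Row indices to evaluate (default: all).
#' @param superpose If `TRUE` (default) superpose `a` onto `b` over
#'   `positions` first.
#' @return RMSD in Angstrom.
#' @export
rmsd_between <- function(a, b, positions = NULL, superpose = TRUE) {
  stopifnot(nrow(a) == nrow(b))
  if (is.null(positions)) positions <- seq_len(nrow(a))
  if (superpose) {
    fit <- kabsch_fit(a, b, positions)
    a <- apply_superposition(fit, a)
  }
  sqrt(mean(rowSums((a[positions, , drop = FALSE] -
                     b[positions, , drop = FALSE])^2)))
}

# One round of superposing every conformer onto the current mean over the
# given frame indices; returns the updated coordinate array.
.superpose_round <- function(arr, mean_xyz, fit_idx) {
  n <- dim(arr)[1]
  for (i in seq_len(n)) {
    fit <- kabsch_fit(arr[i, , ], mean_xyz, fit_idx)
    arr[i, , ] <- apply_superposition(fit, arr[i, , ])
  }
  arr
}

.ensemble_mean <- function(arr) apply(arr, c(2, 3), mean)

# Per-position total variance: trace of the 3x3 coordinate covariance
# across conformers (N-1 divisor).
.position_variance <- function(arr) {
  apply(arr, 2, function(sl) sum(apply(sl, 2, stats::var)))
}

#' Find the structurally invariant core of an ensemble
#'
#' Iterated-exclusion superposition: in each round, all conformers are
#' superposed onto the ensemble mean over the currently retained positions,
#' the mean is recomputed, each retained position is scored by the trace of
#' its 3 x 3 coordinate covariance across conformers, and the `batch`
#' highest-variance positions are removed. Iteration stops once the retained
#' set is no larger than `max(stop_fraction * M, min_positions)`. The full
#' removal history is recorded so any other cut can be revisited.
#'
#' Ties on equal variance are broken by removing the higher residue index
#' first; an ensemble of identical conformers therefore retains the
#' lowest-index positions.
#'
#' @param ensemble A `coord_ensemble`.
#' @param batch Positions removed per round (default 1).
#' @param stop_fraction Fraction of positions to retain (default 0.5).
#' @param min_positions Never retain fewer than this many positions
#'   (default 3, the minimum for a rigid fit).
#' @return Object of class `core_selection`: `positions` (sorted residue
#'   numbers retained), `history` (data.frame with one row per round:
#'   `round`, `n_retained`, `removed`, `variance_retained`), and the
#'   ensemble `frame`.
#' @export
find_core <- function(ensemble, batch = 1, stop_fraction = 0.5,
                      min_positions = 3) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (min_positions < 3) stop("min_positions must be at least 3")
  arr <- ensemble$coords
  n <- dim(arr)[1]; m <- dim(arr)[2]
  if (n < 2) stop("need at least 2 conformers")
  if (m < min_positions) stop("frame smaller than min_positions")
  positions <- ensemble$positions
  current <- seq_len(m)          # indices into the frame
  threshold <- max(stop_fraction * m, min_positions)
  history <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    mean_xyz <- .ensemble_mean(arr)
    arr <- .superpose_round(arr, mean_xyz, current)
    mean_xyz <- .ensemble_mean(arr)
    v <- .position_variance(arr)[current]
    if (length(current) <= threshold) {
      history[[round_i]] <- data.frame(
        round = round_i, n_retained = length(current), removed = "",
        variance_retained = sum(v))
      break
    }
    n_remove <- min(batch, length(current) - max(min_positions,
                                                 ceiling(threshold)))
    n_remove <- max(n_remove, 1L)
    # highest variance first; ties -> higher residue index first
    ord <- order(-v, -positions[current])
    drop_idx <- current[ord[seq_len(n_remove)]]
    current <- setdiff(current, drop_idx)
    history[[round_i]] <- data.frame(
      round = round_i, n_retained = length(current),
      removed = paste(sort(positions[drop_idx]), collapse = ","),
      variance_retained = sum(.position_variance(arr)[current]))
    if (length(current) <= threshold) {
      # final superposition pass over the converged core
      mean_xyz <- .ensemble_mean(arr)
      arr <- .superpose_round(arr, mean_xyz, current)
      break
    }
  }
  out <- list(positions = sort(positions[current]),
              history = do.call(rbind, history),
              frame = positions)
  class(out) <- "core_selection"
  out
}

#' @export
print.core_selection <- function(x, ...) {
  cat("<core_selection> ", length(x$positions), " of ", length(x$frame),
      " positions retained after ", nrow(x$history), " round(s)\n", sep = "")
  invisible(x)
}

#' Write a core selection as plain text
#'
#' Writes the retained residue list (author numbering, one per line) and the
#' per-round history as CSV.
#'
#' @param core A `core_selection`.
#' @param residues_path Output path for the residue list.
#' @param history_path Optional output path for the history CSV.
#' @return `residues_path`, invisibly.
#' @export
write_core <- function(core, residues_path, history_path = NULL) {
  writeLines(as.character(core$positions), residues_path)
  if (!is.null(history_path))
    utils::write.csv(core$history, history_path, row.names = FALSE)
  invisible(residues_path)
}
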