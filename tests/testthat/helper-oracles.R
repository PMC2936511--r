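# Independent oracles and small fixture builders used across tests.

# Euler-angle rotation (z-y-z convention).
euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force minimum RMSD over all proper rotations (translation solved by
# centroid matching): coarse Euler grid followed by Nelder-Mead refinement
# from the best grid points. Independent of the SVD-based implementation.
bruteforce_min_rmsd <- function(p, q) {
  a <- sweep(p, 2, colMeans(p))
  b <- sweep(q, 2, colMeans(q))
  obj <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((a %*% r - b)^2)))
  }
  step <- pi / 6
  grid <- expand.grid(a1 = seq(0, 2 * pi - step, by = step),
                      a2 = seq(0, pi, by = step),
                      a3 = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, obj)
  starts <- grid[order(vals)[1:8], , drop = FALSE]
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# Random rigid motion applied to an M x 3 matrix.
random_rigid_copy <- function(xyz, seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  sweep(xyz %*% r, 2, stats::rnorm(3, 0, 10), "+")
}

# Write a multi-model PDB from a list of per-frame atom tables
# (columns: type, name, resname, chain, resno, x, y, z).
write_stack_pdb <- function(frames, path) {
  con <- file(path, "w")
  for (k in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    f <- frames[[k]]
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                         f$type[i], i, paste0(" ", f$name[i]), "",
                         f$resname[i], f$chain[i], f$resno[i], "",
                         f$x[i], f$y[i], f$z[i], 1.0, 0.0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  path
}

# Agreement of two labelings up to label permutation (exact match fraction
# under the best assignment; 1 means identical partitions).
partition_agreement <- function(a, b) {
  la <- unique(a)
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(unique(b))) {
    mapped <- p[match(b, unique(b))]
    best <- max(best, mean(mapped == a))
  }
  best
}
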