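# Orchestration of the full analysis from a config: crystallographic
# ensemble -> invariant core -> PCA atlas -> projection/clustering, and
# trajectory -> RMSF/DCCM/distances/torsions/PC-score reports.

#' Build a run configuration
#'
#' A single configuration drives both [run_atlas()] and
#' [run_trajectory_report()]. It can also be read from a YAML file with
#' [read_run_config()]; arguments given here override file values.
#'
#' @param manifest Path to the ensemble manifest: a CSV/TSV table with
#'   columns `path` (PDB file), optional `chain`, `state`, `system`, `run`.
#' @param residue_window Inclusive residue range on the reference
#'   (default `c(1, 166)`, the Ras catalytic domain).
#' @param core_batch,core_stop_fraction,core_min_positions Parameters of
#'   [find_core()].
#' @param n_components Components kept for projection (default 3).
#' @param k_clusters Clusters cut from the projection tree (default 2).
#' @param regions Regions for per-region RMSD series: a character vector of
#'   [ras_region()] preset names (default switch 1/2/3) or a named list of
#'   residue-number vectors.
#' @param atom_pairs List of atom-pair specs for distance series, each a
#'   length-2 character vector like `c("61:NE2", "GTP:PG")`.
#' @param output_dir Where result tables are written.
#' @param seed Seed recorded in the run log.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest = NULL,
                       residue_window = c(1L, 166L),
                       core_batch = 1,
                       core_stop_fraction = 0.5,
                       core_min_positions = 3,
                       n_components = 3,
                       k_clusters = 2,
                       regions = c("switch1", "switch2", "switch3"),
                       atom_pairs = NULL,
                       output_dir = "confatlas_run",
                       seed = 1) {
  out <- list(manifest = manifest, residue_window = residue_window,
              core_batch = core_batch,
              core_stop_fraction = core_stop_fraction,
              core_min_positions = core_min_positions,
              n_components = n_components, k_clusters = k_clusters,
              regions = regions, atom_pairs = atom_pairs,
              output_dir = output_dir, seed = seed)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @param ... Overrides applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Read an ensemble manifest table
#'
#' One row per structure: `path` (required), optional `chain`, `state`,
#' `system`, `run`. Comma- or tab-separated; relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest file.
#' @return data.frame with normalized columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"path" %in% names(df)) stop("manifest lacks a 'path' column")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  for (col in c("chain", "state", "system", "run"))
    if (!col %in% names(df)) df[[col]] <- NA
  df
}

# Write the machine-readable parameter sidecar for a run.
.write_run_log <- function(config, dir, extra = list()) {
  log <- c(unclass(config), extra)
  log$regions <- as.list(log$regions)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Build a PCA atlas from an ensemble manifest
#'
#' Executes the full crystallographic-ensemble stage: read every structure
#' in the manifest, map them onto the first entry as reference, build the
#' common-frame ensemble over the residue window, find the invariant core,
#' fit the PCA, project the fitting ensemble and cluster the projections.
#' All outputs (projections CSV, core residue list and history, plain-text
#' atlas bundle, parameter log) are written under `config$output_dir`.
#'
#' Referenced files are checked before any computation; a missing file is
#' reported by name.
#'
#' @param config A `run_config` with a `manifest`.
#' @return Invisibly, a list: `model`, `projections`, `core`, `ensemble`,
#'   `paths`.
#' @export
run_atlas <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$manifest)) stop("config has no manifest")
  man <- read_manifest(config$manifest)
  missing <- man$path[!file.exists(man$path)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  structures <- lapply(seq_len(nrow(man)), function(i)
    read_pdb(man$path[i]))
  chains <- if (all(is.na(man$chain))) NULL else
    ifelse(is.na(man$chain), "A", man$chain)
  states <- if (all(is.na(man$state))) NULL else man$state

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ensemble <- stage("build_ensemble",
    build_ensemble(structures, structures[[1]],
                   residue_window = config$residue_window,
                   chains = chains, states = states))
  core <- stage("find_core",
    find_core(ensemble, batch = config$core_batch,
              stop_fraction = config$core_stop_fraction,
              min_positions = config$core_min_positions))
  model <- stage("fit_pca", fit_pca(ensemble, core))
  proj <- stage("project", project(ensemble, model,
                                   k = config$n_components))
  proj <- stage("cluster_projections",
                cluster_projections(proj, config$k_clusters))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    projections = file.path(config$output_dir, "projections.csv"),
    core = file.path(config$output_dir, "core_residues.txt"),
    core_history = file.path(config$output_dir, "core_history.csv"),
    atlas = file.path(config$output_dir, "atlas"))
  write_projections(proj, paths$projections)
  write_core(core, paths$core, paths$core_history)
  save_atlas(model, paths$atlas)
  .write_run_log(config, config$output_dir,
                 list(n_conformers = nrow(man),
                      n_positions = length(ensemble$positions),
                      n_core = length(core$positions)))
  invisible(list(model = model, projections = proj, core = core,
                 ensemble = ensemble, paths = paths))
}

# Subset a trajectory ensemble to the atlas residue frame.
.align_to_atlas <- function(traj, model) {
  idx <- match(model$positions, traj$positions)
  if (anyNA(idx))
    stop("trajectory lacks atlas frame residues: ",
         paste(model$positions[is.na(idx)], collapse = ", "))
  out <- traj
  out$coords <- traj$coords[, idx, , drop = FALSE]
  out$positions <- model$positions
  attr(out, "all_atoms") <- attr(traj, "all_atoms")
  out
}

#' Per-trajectory metric report against an atlas
#'
#' For every trajectory in the table: RMSF (fit on the atlas core), DCCM,
#' per-frame PC scores in the atlas, RMSD series against the trajectory's
#' mean or a supplied reference, per-region RMSD series, and requested
#' atom-pair distance series. Replicate runs are aggregated per system
#' (mean and SD RMSF); when exactly two systems are present, their
#' replicate-mean RMSF profiles are compared with a paired t-test.
#'
#' @param config A `run_config`.
#' @param trajectories data.frame with columns `path`, `system`, optional
#'   `run` (or a named character vector of paths, names = system).
#' @param atlas A `pca_atlas` (e.g. from [run_atlas()] or [load_atlas()]).
#' @param reference Optional `structure3d` for RMSD series.
#' @return Invisibly, a list: `rmsf` (long data.frame), `profiles` (per
#'   system), `comparison` (paired t table or NULL), `scores` (per-frame PC
#'   scores), `dccm` (list per run), `rmsd` (long data.frame or NULL),
#'   `distances` (long data.frame or NULL), `paths`.
#' @export
run_trajectory_report <- function(config, trajectories, atlas,
                                  reference = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(atlas, "pca_atlas"))
  if (is.character(trajectories))
    trajectories <- data.frame(path = trajectories,
                               system = if (is.null(names(trajectories)))
                                 "system1" else names(trajectories),
                               stringsAsFactors = FALSE)
  if (!"run" %in% names(trajectories))
    trajectories$run <- stats::ave(seq_len(nrow(trajectories)),
                                   trajectories$system, FUN = seq_along)
  missing <- trajectories$path[!file.exists(trajectories$path)]
  if (length(missing))
    stop("missing trajectory file(s): ", paste(missing, collapse = ", "))

  core <- atlas$core
  rmsf_rows <- list(); score_rows <- list(); dccm_list <- list()
  rmsd_rows <- list(); dist_rows <- list()
  per_system <- split(seq_len(nrow(trajectories)), trajectories$system)

  for (i in seq_len(nrow(trajectories))) {
    traj <- read_conformer_stack(trajectories$path[i])
    tr <- .align_to_atlas(traj, atlas)
    sys <- trajectories$system[i]; runid <- trajectories$run[i]

    fl <- rmsf(tr, fit = core)
    rmsf_rows[[i]] <- data.frame(system = sys, run = runid,
                                 residue = tr$positions, rmsf = fl)
    if (dim(tr$coords)[1] >= 3)
      dccm_list[[paste(sys, runid, sep = "_")]] <- dccm(tr, fit = core)
    sc <- project(tr, atlas, k = config$n_components)
    score_rows[[i]] <- data.frame(system = sys, run = runid,
                                  frame = seq_len(nrow(sc$scores)),
                                  sc$scores, check.names = FALSE)
    ref <- reference
    if (!is.null(ref)) {
      regs <- config$regions
      if (is.character(regs))
        regs <- stats::setNames(lapply(regs, ras_region), regs)
      regs <- c(list(all = NULL), regs)
      for (rn in names(regs)) {
        rs <- rmsd_series(tr, ref, selection = regs[[rn]], fit = core)
        rmsd_rows[[length(rmsd_rows) + 1]] <-
          data.frame(system = sys, run = runid, region = rn, rs)
      }
    }
    if (!is.null(config$atom_pairs) &&
        !is.null(attr(traj, "all_atoms"))) {
      for (pair in config$atom_pairs) {
        ds <- atom_distance_series(traj, pair)
        dist_rows[[length(dist_rows) + 1]] <-
          data.frame(system = sys, run = runid,
                     pair = paste(attr(ds, "pair"), collapse = "--"), ds)
      }
    }
  }

  profiles <- lapply(per_system, function(idx) {
    vecs <- lapply(idx, function(i) {
      v <- rmsf_rows[[i]]$rmsf
      names(v) <- rmsf_rows[[i]]$residue
      v
    })
    rmsf_profile(vecs)
  })
  comparison <- NULL
  if (length(profiles) == 2) {
    cmp <- compare_rmsf(profiles[[1]], profiles[[2]])
    comparison <- data.frame(system_a = names(profiles)[1],
                             system_b = names(profiles)[2],
                             t = cmp$t, df = cmp$df, p_value = cmp$p_value,
                             mean_difference = cmp$mean_difference,
                             degenerate = cmp$degenerate)
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rmsf_long <- do.call(rbind, rmsf_rows)
  rmsf_long$mean <- NA_real_
  rmsf_long$sd <- NA_real_
  for (sys in names(profiles)) {
    pr <- profiles[[sys]]
    sel <- rmsf_long$system == sys
    rmsf_long$mean[sel] <- pr$mean[match(rmsf_long$residue[sel],
                                         pr$positions)]
    rmsf_long$sd[sel] <- pr$sd[match(rmsf_long$residue[sel], pr$positions)]
  }
  paths <- list(rmsf = file.path(config$output_dir, "rmsf.csv"),
                scores = file.path(config$output_dir, "pc_scores.csv"))
  utils::write.csv(rmsf_long, paths$rmsf, row.names = FALSE)
  utils::write.csv(do.call(rbind, score_rows), paths$scores,
                   row.names = FALSE)
  for (nm in names(dccm_list)) {
    p <- file.path(config$output_dir, paste0("dccm_", nm, ".txt"))
    utils::write.table(dccm_list[[nm]]$matrix, p, quote = FALSE)
    paths[[paste0("dccm_", nm)]] <- p
  }
  if (length(rmsd_rows)) {
    paths$rmsd <- file.path(config$output_dir, "rmsd_series.csv")
    utils::write.csv(do.call(rbind, rmsd_rows), paths$rmsd,
                     row.names = FALSE)
  }
  if (length(dist_rows)) {
    paths$distances <- file.path(config$output_dir, "distances.csv")
    utils::write.csv(do.call(rbind, dist_rows), paths$distances,
                     row.names = FALSE)
  }
  if (!is.null(comparison)) {
    paths$comparison <- file.path(config$output_dir,
                                  "rmsf_comparison.csv")
    utils::write.csv(comparison, paths$comparison, row.names = FALSE)
  }
  .write_run_log(config, config$output_dir,
                 list(n_trajectories = nrow(trajectories),
                      systems = as.list(unique(trajectories$system))))
  invisible(list(rmsf = rmsf_long, profiles = profiles,
                 comparison = comparison,
                 scores = do.call(rbind, score_rows),
                 dccm = dccm_list,
                 rmsd = if (length(rmsd_rows)) do.call(rbind, rmsd_rows),
                 distances = if (length(dist_rows))
                   do.call(rbind, dist_rows),
                 paths = paths))
}
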