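# Reading and writing of structures and conformer stacks, C-alpha frame
# extraction, and residue mapping across near-identical isoform sequences.

# Residue names treated as water (always dropped on read).
.water_names <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD", "H2O")

#' Recognized nucleotide ligand residue names
#'
#' Residue codes treated as guanine-nucleotide ligands when flagging HETATM
#' records. `GNP` and `GCP` are the common non-hydrolyzable GTP analogs
#' (GppNHp, GppCH2p) found in active-state crystal structures. The gamma- and
#' beta-phosphate atoms of these ligands are named `PG` and `PB`.
#'
#' @return Character vector of residue names.
#' @export
nucleotide_names <- function() {
  getOption("confatlas.nucleotides", c("GTP", "GDP", "GNP", "GCP"))
}

#' Construct a structure object
#'
#' Low-level constructor for a parsed atomic model. Most users will obtain
#' structures from [read_pdb()] or [make_reference()].
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `residue_name`,
#'   `residue_number` (author numbering), `insertion_code`, `chain_id`,
#'   `x`, `y`, `z` (Angstrom), `occupancy`, `altloc`, `het` (logical),
#'   `ligand` (logical).
#' @param id Identifier, e.g. PDB id plus chain.
#' @return Object of class `structure3d`.
#' @export
new_structure <- function(atoms, id = "structure") {
  required <- c("atom_name", "element", "residue_name", "residue_number",
                "insertion_code", "chain_id", "x", "y", "z", "occupancy",
                "altloc", "het", "ligand")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1)))
    stop("occupancy outside [0, 1]")
  obj <- list(id = id, atoms = atoms, sequence = .chain_sequences(atoms))
  class(obj) <- "structure3d"
  obj
}

# One-letter sequence per chain from protein C-alpha records.
.chain_sequences <- function(atoms) {
  prot <- atoms[!atoms$het & atoms$atom_name == "CA", , drop = FALSE]
  if (!nrow(prot)) return(character(0))
  out <- vapply(split(prot, prot$chain_id), function(d) {
    d <- d[order(d$residue_number, d$insertion_code), , drop = FALSE]
    paste(bio3d::aa321(d$residue_name), collapse = "")
  }, character(1))
  out
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records via [bio3d::read.pdb()], drops waters,
#' resolves alternate locations to the highest-occupancy copy (first in file
#' on ties), and flags HETATM nucleotide/ion records so they can be used for
#' catalytic distance measurements.
#'
#' @param path Path to a PDB-format file.
#' @param model_index Which MODEL to keep for multi-model files (1-based).
#' @param id Identifier for the returned structure; defaults to the file name.
#' @return A `structure3d` object.
#' @export
read_pdb <- function(path, model_index = 1, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ",
         nmod, " model(s))")
  if (model_index != 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- .normalize_atoms(at)
  at <- at[!(at$residue_name %in% .water_names), , drop = FALSE]
  at <- .resolve_altloc(at)
  if (!any(!at$het))
    stop("no protein atoms in ", path)
  new_structure(at, id = if (is.null(id)) sub("\\.pdb$", "", basename(path)) else id)
}

# bio3d atom table -> package atom table.
.normalize_atoms <- function(at) {
  data.frame(
    atom_name = trimws(at$elety),
    element = trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                            substr(trimws(at$elety), 1, 1), at$elesy)),
    residue_name = trimws(at$resid),
    residue_number = at$resno,
    insertion_code = ifelse(is.na(at$insert), "", at$insert),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, pmin(pmax(at$o, 0), 1)),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    ligand = at$type == "HETATM" & trimws(at$resid) %in% nucleotide_names(),
    stringsAsFactors = FALSE
  )
}

# Keep the highest-occupancy altloc per (chain, residue, insert, atom);
# ties go to the copy appearing first in the file.
.resolve_altloc <- function(at) {
  if (!nrow(at)) return(at)
  key <- paste(at$chain_id, at$residue_number, at$insertion_code,
               at$residue_name, at$atom_name, sep = "\r")
  ord <- order(match(key, unique(key)), -at$occupancy, seq_len(nrow(at)))
  at2 <- at[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- at2[keep, , drop = FALSE]
  out <- out[order(match(paste(out$chain_id, out$residue_number,
                               out$insertion_code, out$residue_name,
                               out$atom_name, sep = "\r"), unique(key))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.structure3d <- function(x, ...) {
  nres <- sum(!x$atoms$het & x$atoms$atom_name == "CA")
  cat("<structure3d> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      nres, " residues (", paste(names(x$sequence), collapse = ","),
      ")\n", sep = "")
  invisible(x)
}

#' Extract C-alpha coordinates from a structure
#'
#' @param structure A `structure3d` object.
#' @param chain Chain id; default the first protein chain.
#' @param residues Optional residue numbers (author numbering) to keep.
#' @return M x 3 matrix with residue numbers as rownames.
#' @export
ca_coords <- function(structure, chain = NULL, residues = NULL) {
  at <- structure$atoms
  ca <- at[!at$het & at$atom_name == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("structure has no C-alpha atoms")
  if (is.null(chain)) chain <- ca$chain_id[1]
  ca <- ca[ca$chain_id == chain, , drop = FALSE]
  if (!nrow(ca)) stop("no C-alpha atoms in chain ", chain)
  ca <- ca[order(ca$residue_number, ca$insertion_code), , drop = FALSE]
  if (!is.null(residues)) ca <- ca[ca$residue_number %in% residues, , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$residue_number
  m
}

#' Construct a coordinate ensemble
#'
#' An ensemble holds N conformers over a common residue frame of M positions.
#'
#' @param coords N x M x 3 array (Angstrom) or N x 3M matrix
#'   (x1,y1,z1,x2,...).
#' @param positions Integer vector of residue numbers defining the frame.
#' @param conformer_ids Labels, one per conformer.
#' @param states Optional per-conformer annotation (e.g. GTP/GDP/mutant).
#' @return Object of class `coord_ensemble`.
#' @export
new_ensemble <- function(coords, positions,
                         conformer_ids = NULL, states = NULL) {
  if (is.matrix(coords)) coords <- flat_to_array(coords)
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n <- dim(coords)[1]; m <- dim(coords)[2]
  if (length(positions) != m)
    stop("positions length (", length(positions),
         ") does not match frame size (", m, ")")
  if (n < 2) stop("an ensemble needs at least 2 conformers")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(conformer_ids)) conformer_ids <- paste0("conformer_", seq_len(n))
  if (!is.null(states) && length(states) != n)
    stop("states must have one entry per conformer")
  obj <- list(coords = coords, positions = as.integer(positions),
              conformer_ids = conformer_ids, states = states)
  class(obj) <- "coord_ensemble"
  obj
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat("<coord_ensemble> ", dim(x$coords)[1], " conformers x ",
      dim(x$coords)[2], " positions\n", sep = "")
  invisible(x)
}

#' @export
dim.coord_ensemble <- function(x) dim(x$coords)

# Flatten M x 3 -> 3M (x1,y1,z1,...) and back.
#' @rdname new_ensemble
#' @param flat Numeric vector of length 3M.
#' @export
flat_to_xyz <- function(flat) matrix(flat, ncol = 3, byrow = TRUE)

#' @rdname new_ensemble
#' @param xyz M x 3 coordinate matrix.
#' @export
xyz_to_flat <- function(xyz) as.vector(t(xyz))

# N x 3M matrix -> N x M x 3 array.
flat_to_array <- function(mat) {
  n <- nrow(mat); m <- ncol(mat) / 3
  arr <- array(NA_real_, c(n, m, 3))
  for (ax in 1:3) arr[, , ax] <- mat[, seq(ax, 3 * m, by = 3), drop = FALSE]
  arr
}

# N x M x 3 array -> N x 3M matrix.
array_to_flat <- function(arr) {
  n <- dim(arr)[1]; m <- dim(arr)[2]
  mat <- matrix(NA_real_, n, 3 * m)
  for (ax in 1:3) mat[, seq(ax, 3 * m, by = 3)] <- arr[, , ax]
  mat
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL becomes one ensemble member, in file order. All models must
#' contain the same atoms; a mismatch is reported naming the first offending
#' model. Non-C-alpha atoms (including retained HETATM ligand atoms) are kept
#' alongside the C-alpha frame so that catalytic atom-pair distances can be
#' measured with [atom_distance_series()].
#'
#' @param path Multi-model PDB file.
#' @param chain Chain id for the C-alpha frame; default first protein chain.
#' @return A `coord_ensemble` whose `"all_atoms"` attribute holds the full
#'   per-frame atom coordinates.
#' @export
read_conformer_stack <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  .check_model_homogeneity(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- .normalize_atoms(pdb$atom)
  n <- nrow(pdb$xyz)
  if (n < 1) stop("no models in ", path)
  natoms <- nrow(at)
  xyz <- array(NA_real_, c(n, natoms, 3))
  for (ax in 1:3) xyz[, , ax] <- pdb$xyz[, seq(ax, 3 * natoms, by = 3), drop = FALSE]

  ca_idx <- which(!at$het & at$atom_name == "CA")
  if (!length(ca_idx)) stop("no protein C-alpha atoms in ", path)
  if (is.null(chain)) chain <- at$chain_id[ca_idx[1]]
  ca_idx <- ca_idx[at$chain_id[ca_idx] == chain]
  ord <- order(at$residue_number[ca_idx])
  ca_idx <- ca_idx[ord]
  if (n < 2) {
    # single-model file: still represent as a 1-frame stack for downstream use
    ens <- list(coords = xyz[, ca_idx, , drop = FALSE],
                positions = as.integer(at$residue_number[ca_idx]),
                conformer_ids = "model_1", states = NULL)
    class(ens) <- "coord_ensemble"
  } else {
    ens <- new_ensemble(xyz[, ca_idx, , drop = FALSE],
                        positions = at$residue_number[ca_idx],
                        conformer_ids = paste0("model_", seq_len(n)))
  }
  attr(ens, "all_atoms") <- list(meta = at, xyz = xyz)
  ens
}

# Scan MODEL blocks and verify identical atom composition; names the first
# offending model in the error. Files without MODEL records count as 1 model.
.check_model_homogeneity <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    if (!any(is_atom)) stop("no models or atoms in ", path)
    return(invisible(1L))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  keyset <- NULL
  for (k in seq_along(model_starts)) {
    block <- lines[model_starts[k]:model_ends[k]]
    atoms <- block[grepl("^(ATOM  |HETATM)", block)]
    # identity key: atom name + altloc + residue name + chain + residue number
    keys <- substr(atoms, 13, 27)
    if (is.null(keyset)) {
      keyset <- keys
    } else if (!identical(keys, keyset)) {
      stop("model ", k, " of ", path,
           " has a different atom composition than model 1")
    }
  }
  invisible(length(model_starts))
}

#' Write a conformer stack to a multi-model PDB file
#'
#' Inverse of [read_conformer_stack()] for C-alpha ensembles: each conformer
#' becomes one MODEL holding the frame's C-alpha atoms (poly-alanine labels
#' unless residue names are supplied).
#'
#' @param ensemble A `coord_ensemble`.
#' @param path Output file.
#' @param residue_names Optional residue names, one per frame position.
#' @param chain Chain id to write.
#' @return `path`, invisibly.
#' @export
write_conformers <- function(ensemble, path, residue_names = NULL,
                             chain = "A") {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  m <- dim(ensemble$coords)[2]
  if (is.null(residue_names)) residue_names <- rep("ALA", m)
  xyz <- array_to_flat(ensemble$coords)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ensemble$positions,
                   resid = residue_names,
                   elety = rep("CA", m),
                   chain = rep(chain, m))
  invisible(path)
}

#' Write a single structure to a PDB file
#'
#' @param structure A `structure3d`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$residue_number,
                   resid = at$residue_name,
                   elety = at$atom_name,
                   chain = at$chain_id,
                   o = at$occupancy)
  invisible(path)
}

#' Map equivalent residues between two near-identical sequences
#'
#' Global pairwise alignment with match +1, mismatch 0, linear gap -1
#' (no substitution matrix; the intended use is isoforms at >90% identity
#' where the alignment is insensitive to the scoring details). Identity is
#' computed over aligned, non-gap columns.
#'
#' @param a,b `structure3d` objects or plain one-letter sequences.
#' @param chain_a,chain_b Chain to use when a structure has several.
#' @return Object of class `residue_mapping`: `pairs` (two-column matrix of
#'   1-based sequence positions, strictly increasing in both), `identity_percent`,
#'   `n_aligned`.
#' @export
map_residues <- function(a, b, chain_a = NULL, chain_b = NULL) {
  sa <- .as_sequence(a, chain_a)
  sb <- .as_sequence(b, chain_b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  alphabet <- sort(unique(c(strsplit(sa, "")[[1]], strsplit(sb, "")[[1]], "X")))
  mat <- matrix(0, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    pattern = sa, subject = sb, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- 0L; j <- 0L
  pairs <- matrix(0L, 0, 2); ident <- 0L
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) i <- i + 1L
    if (!gb) j <- j + 1L
    if (!ga && !gb) {
      pairs <- rbind(pairs, c(i, j))
      if (pa[k] == pb[k]) ident <- ident + 1L
    }
  }
  out <- list(pairs = pairs,
              identity_percent = 100 * ident / nrow(pairs),
              n_aligned = nrow(pairs))
  class(out) <- "residue_mapping"
  out
}

.as_sequence <- function(x, chain = NULL) {
  if (inherits(x, "structure3d")) {
    if (!length(x$sequence)) stop("structure has no protein chain")
    if (is.null(chain)) chain <- names(x$sequence)[1]
    if (!chain %in% names(x$sequence))
      stop("no chain ", chain, " in structure ", x$id)
    x$sequence[[chain]]
  } else {
    toupper(as.character(x)[1])
  }
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat("<residue_mapping> ", x$n_aligned, " aligned pairs, ",
      sprintf("%.1f", x$identity_percent), "% identity\n", sep = "")
  invisible(x)
}

#' Build a coordinate ensemble from mapped structures
#'
#' Maps every structure onto a reference with [map_residues()], restricts to
#' a residue window (author numbering on the reference), and keeps the
#' intersection of positions mapped by all members. Coordinates are gathered
#' from C-alpha atoms only.
#'
#' @param structures List of `structure3d` objects.
#' @param mapping_reference Reference `structure3d` defining the frame.
#' @param residue_window Inclusive `c(first, last)` residue range on the
#'   reference; default `c(1, 166)`, the Ras catalytic domain.
#' @param chains Optional chain ids, one per structure (default: first
#'   protein chain of each).
#' @param states Optional per-structure state labels.
#' @return A `coord_ensemble` on the common residue frame.
#' @export
build_ensemble <- function(structures, mapping_reference,
                           residue_window = c(1L, 166L),
                           chains = NULL, states = NULL) {
  stopifnot(length(structures) >= 2)
  ref_chain <- names(mapping_reference$sequence)[1]
  ref_ca <- ca_coords(mapping_reference, chain = ref_chain)
  ref_resno <- as.integer(rownames(ref_ca))
  window <- ref_resno[ref_resno >= residue_window[1] &
                      ref_resno <= residue_window[2]]
  if (!length(window)) stop("residue window selects no reference residues")

  per_struct <- vector("list", length(structures))
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    ch <- if (is.null(chains)) names(st$sequence)[1] else chains[s]
    mp <- map_residues(st, mapping_reference,
                       chain_a = ch, chain_b = ref_chain)
    ca <- ca_coords(st, chain = ch)
    st_resno <- as.integer(rownames(ca))
    # pairs are sequence positions; translate to author residue numbers
    ref_pos <- ref_resno[mp$pairs[, 2]]
    st_pos <- st_resno[mp$pairs[, 1]]
    keep <- ref_pos %in% window
    if (sum(keep) < 0.5 * length(window))
      stop("structure ", st$id, " maps fewer than 50% of the residue window")
    co <- ca[match(st_pos[keep], st_resno), , drop = FALSE]
    rownames(co) <- ref_pos[keep]
    per_struct[[s]] <- co
  }
  frame <- Reduce(intersect, lapply(per_struct, function(co)
    as.integer(rownames(co))))
  frame <- sort(frame)
  if (!length(frame)) stop("no residue positions common to all structures")
  n <- length(structures)
  arr <- array(NA_real_, c(n, length(frame), 3))
  for (s in seq_len(n))
    arr[s, , ] <- per_struct[[s]][match(frame, as.integer(rownames(per_struct[[s]]))), ]
  new_ensemble(arr, positions = frame,
               conformer_ids = vapply(structures, function(x) x$id, character(1)),
               states = states)
}
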