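#' Trajectory objects
#'
#' A `cdn_traj` holds a conformational ensemble: an `F x A x 3` coordinate
#' array (Angstrom) plus a per-atom metadata table with columns `elety`
#' (atom name), `resid` (residue name), `chain` and `resno`. All frames share
#' one atom ordering. Use [load_trajectory()] to read one from a multi-model
#' PDB file and [sample_trajectory()] to generate one synthetically.
#'
#' @param coords numeric array of dimension `c(frames, atoms, 3)`.
#' @param atoms data.frame with columns `elety`, `resid`, `chain`, `resno`.
#' @param provenance list recording the source of the ensemble.
#' @return An object of class `cdn_traj`.
#' @export
trajectory <- function(coords, atoms, provenance = list(source = "memory")) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_validation("coords must be an F x A x 3 array")
  if (dim(coords)[1] < 1L)
    stop_validation("a trajectory needs at least 1 frame")
  if (dim(coords)[2] < 1L)
    stop_validation("a trajectory needs at least 1 atom")
  if (!all(is.finite(coords)))
    stop_validation("coordinates must be finite")
  req <- c("elety", "resid", "chain", "resno")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop_validation("atoms must be a data.frame with columns ",
                    paste(req, collapse = ", "))
  if (nrow(atoms) != dim(coords)[2])
    stop_validation("atom table (", nrow(atoms), " rows) does not match ",
                    "coordinate array (", dim(coords)[2], " atoms)")
  structure(list(coords = coords, atoms = atoms, provenance = provenance),
            class = "cdn_traj")
}

#' @export
print.cdn_traj <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms,",
      length(unique(res_id(x$atoms$chain, x$atoms$resno))), "residues\n")
  cat("  source:", x$provenance$source %||% "unknown", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
n_frames <- function(traj) UseMethod("n_frames")
#' @export
n_frames.cdn_traj <- function(traj) dim(traj$coords)[1]

# Pre-scan a PDB file: per-model atom counts, for a clean error message when
# models disagree before handing the file to the parser.
scan_pdb_models <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) == 0L)
    return(list(n_models = if (any(is_atom)) 1L else 0L,
                counts = sum(is_atom)))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  counts <- vapply(seq_along(model_starts), function(m) {
    sum(is_atom[model_starts[m]:model_ends[m]])
  }, integer(1))
  list(n_models = length(model_starts), counts = counts)
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame. All models must contain the
#' same atoms in the same order; a model whose atom count differs from the
#' first is reported by its model index. Files with insertion codes are
#' rejected: residues are keyed by `(chain, resno)` only.
#'
#' @param path path to a multi-model PDB file.
#' @param dialect input format; only `"pdb"` is supported.
#' @param frame_stride keep every `frame_stride`-th model (default 1 = all).
#' @return A [trajectory()] with one frame per retained model.
#' @export
load_trajectory <- function(path, dialect = "pdb", frame_stride = 1L) {
  dialect <- match.arg(dialect, "pdb")
  frame_stride <- as.integer(check_scalar_number(frame_stride, "frame_stride",
                                                 lower = 1))
  if (!file.exists(path))
    stop_io("cannot read trajectory file: ", path)
  lines <- readLines(path, warn = FALSE)
  scan <- scan_pdb_models(lines)
  if (scan$n_models >= 2L) {
    bad <- which(scan$counts != scan$counts[1])
    if (length(bad) > 0L)
      stop_format("model ", bad[1], " has ", scan$counts[bad[1]],
                  " atoms but model 1 has ", scan$counts[1])
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop_io("failed to parse ", path, ": ",
                                              conditionMessage(e)))
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (n_models < 2L)
    stop_validation("trajectory must contain at least 2 models, found ",
                    n_models, " in ", path)
  if (any(!is.na(pdb$atom$insert) & nzchar(pdb$atom$insert)))
    stop_validation("insertion codes are not supported; residues are keyed ",
                    "by (chain, resno)")
  keep <- seq(1L, n_models, by = frame_stride)
  coords <- xyz_to_coords(pdb$xyz[keep, , drop = FALSE])
  if (length(keep) < 2L)
    stop_validation("frame_stride ", frame_stride, " leaves fewer than 2 of ",
                    n_models, " models")
  atoms <- data.frame(elety = pdb$atom$elety,
                      resid = pdb$atom$resid,
                      chain = ifelse(is.na(pdb$atom$chain), "A",
                                     pdb$atom$chain),
                      resno = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms,
             provenance = list(source = path, dialect = dialect,
                               frame_stride = frame_stride))
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param b optional per-atom B-factor column (e.g. RMSF values broadcast to
#'   atoms) for tube-style visualisation.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, b = NULL) {
  at <- traj$atoms
  bio3d::write.pdb(file = path,
                   xyz = coords_to_xyz(traj$coords),
                   resno = at$resno, resid = at$resid,
                   chain = at$chain, elety = at$elety,
                   b = if (is.null(b)) rep(0, nrow(at)) else b)
  invisible(path)
}

#' Select one analysis atom per residue
#'
#' The network nodes are alpha carbons; contact analysis uses beta carbons
#' with the alpha carbon standing in for glycine (which has no C-beta). The
#' same fallback applies to any residue lacking a C-beta atom.
#'
#' @param traj a [trajectory()].
#' @param role `"calpha"`, `"cbeta"` (with C-alpha fallback), or `"custom"`.
#' @param elety atom name used when `role = "custom"`.
#' @return An object of class `cdn_selection` with fields `indices` (atom rows
#'   into the trajectory), `ids`, `chain`, `resno` and `role`.
#' @export
select_atoms <- function(traj, role = c("calpha", "cbeta", "custom"),
                         elety = NULL) {
  role <- match.arg(role)
  at <- traj$atoms
  key <- res_id(at$chain, at$resno)
  residues <- unique(key)          # file order
  pick_one <- function(rows, wanted) {
    hit <- rows[at$elety[rows] %in% wanted]
    if (length(hit) > 0L) hit[1] else NA_integer_
  }
  rows_by_res <- split(seq_len(nrow(at)), factor(key, levels = residues))
  idx <- vapply(residues, function(r) {
    rows <- rows_by_res[[r]]
    i <- switch(role,
      calpha = pick_one(rows, "CA"),
      cbeta  = {
        cb <- pick_one(rows, "CB")
        if (is.na(cb)) pick_one(rows, "CA") else cb
      },
      custom = {
        if (is.null(elety)) stop_validation("role 'custom' requires elety")
        pick_one(rows, elety)
      })
    if (is.na(i))
      stop_validation("residue ", r, " has no ",
                      switch(role, calpha = "CA atom",
                             cbeta = "CB or fallback CA atom",
                             custom = paste0(elety, " atom")))
    i
  }, integer(1))
  structure(list(indices = unname(idx),
                 ids = residues,
                 chain = at$chain[idx],
                 resno = at$resno[idx],
                 role = role),
            class = "cdn_selection")
}

#' @export
print.cdn_selection <- function(x, ...) {
  cat("Atom selection:", length(x$indices), "residues, role", x$role, "\n")
  invisible(x)
}

#' Iterative least-squares superposition onto the mean structure
#'
#' Removes rigid-body translation and rotation so that downstream
#' fluctuations and correlations reflect internal motion only. Each frame is
#' Kabsch-fitted (via [bio3d::fit.xyz()]) on the selection atoms to a
#' reference that starts as frame 1 and is re-estimated as the mean structure
#' until it moves by less than `tol` (RMSD, Angstrom) or `max_iter` rounds.
#'
#' @param traj a [trajectory()].
#' @param sel an atom selection; defaults to the C-alpha selection.
#' @param max_iter maximum mean-structure refinement rounds (default 200;
#'   the fit typically converges in well under 100).
#' @param tol convergence tolerance on the mean-structure shift (Angstrom);
#'   the default 1e-8 leaves fluctuation statistics reproducible to better
#'   than 1e-6 regardless of the input's rigid-body contamination.
#' @return An object of class `cdn_superposition` with fields `trajectory`
#'   (aligned), `reference` (n x 3 mean structure of the selection),
#'   `rmsd` (per-frame RMSD to the reference, Angstrom) and `iterations`.
#' @export
superpose <- function(traj, sel = NULL, max_iter = 200L, tol = 1e-8) {
  if (is.null(sel)) sel <- select_atoms(traj, "calpha")
  if (length(sel$indices) < 3L)
    stop_validation("superposition needs at least 3 selection atoms, got ",
                    length(sel$indices))
  check_scalar_number(tol, "tol", lower = 0)
  xyz <- coords_to_xyz(traj$coords)
  inds <- as.vector(t(outer(sel$indices - 1L, 1:3,
                            function(a, k) 3L * a + k)))
  # start from the raw mean structure: for an already-aligned ensemble every
  # per-frame fit is then the identity, making superposition idempotent.
  # Heavily tumbled frames average to a collapsed mean (a degenerate
  # reference that can trap the iteration); detect that via the radius of
  # gyration and fall back to frame 1 in that case.
  sel_mat <- xyz[, inds, drop = FALSE]
  ref <- colMeans(sel_mat)
  rg <- function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }
  if (rg(ref) < 0.9 * mean(apply(sel_mat, 1, rg)))
    ref <- sel_mat[1, ]
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # bio3d's least-squares fit can warn about NaNs from a degenerate
    # eigenvalue sign flip that it handles internally; silence just that
    xyz <- withCallingHandlers(
      bio3d::fit.xyz(fixed = ref, mobile = xyz,
                     fixed.inds = seq_along(ref), mobile.inds = inds),
      warning = function(w) {
        if (grepl("NaN", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    new_ref <- colMeans(xyz[, inds, drop = FALSE])
    shift <- sqrt(sum((new_ref - ref)^2) / (length(ref) / 3))
    ref <- new_ref
    if (shift < tol) break
  }
  d <- sweep(xyz[, inds, drop = FALSE], 2, ref)
  rmsd <- sqrt(rowSums(d^2) / (length(ref) / 3))
  out <- traj
  out$coords <- xyz_to_coords(xyz)
  out$provenance$superposed <- TRUE
  structure(list(trajectory = out,
                 reference = matrix(ref, ncol = 3, byrow = TRUE),
                 rmsd = unname(rmsd),
                 iterations = iters),
            class = "cdn_superposition")
}

#' @export
print.cdn_superposition <- function(x, ...) {
  cat("Superposition:", length(x$rmsd), "frames,", x$iterations,
      "iterations, mean RMSD", signif(mean(x$rmsd), 4), "A\n")
  invisible(x)
}
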