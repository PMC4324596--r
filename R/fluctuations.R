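# Per-residue fluctuation and coupling statistics on aligned ensembles.

sel_coords <- function(traj, sel) {
  traj$coords[, sel$indices, , drop = FALSE]
}

#' Per-residue root mean square fluctuations
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` on the selection atoms. The
#' trajectory should be superposed first (see [superpose()]) unless it is
#' known to contain no rigid-body motion, as with synthetic ensembles.
#'
#' @param traj an aligned [trajectory()].
#' @param sel an atom selection; defaults to C-alpha.
#' @return A data.frame of class `cdn_rmsf` with columns `id`, `chain`,
#'   `resno`, `rmsf` (Angstrom); attribute `frames`.
#' @export
compute_rmsf <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- select_atoms(traj, "calpha")
  if (length(sel$indices) == 0L) stop_validation("empty atom selection")
  x <- sel_coords(traj, sel)
  fr <- dim(x)[1]
  if (fr < 2L) stop_validation("fluctuations need at least 2 frames")
  dev2 <- 0
  for (k in 1:3) {
    m <- matrix(x[, , k], nrow = fr)
    mc <- sweep(m, 2, colMeans(m))
    dev2 <- dev2 + colSums(mc^2)
  }
  out <- data.frame(id = sel$ids, chain = sel$chain, resno = sel$resno,
                    rmsf = sqrt(as.vector(dev2) / fr),
                    stringsAsFactors = FALSE)
  attr(out, "frames") <- fr
  class(out) <- c("cdn_rmsf", "data.frame")
  out
}

#' Dynamic cross-correlation map
#'
#' Scalar-product normalised cross-correlation of displacement vectors:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr_i(t) = r_i(t) - <r_i>`. Values lie in `[-1, 1]`; 1 is fully
#' correlated motion, -1 fully anti-correlated. Residues with zero
#' fluctuation have undefined correlations, reported as `NA` (never 0).
#'
#' @param traj an aligned [trajectory()].
#' @param sel an atom selection; defaults to C-alpha.
#' @return An object of class `cdn_cmap`: list with `C` (symmetric matrix,
#'   unit diagonal, residue ids as dimnames), `ids`, `chain`, `resno`,
#'   `frames`, `role`.
#' @export
compute_correlation_map <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- select_atoms(traj, "calpha")
  n <- length(sel$indices)
  if (n < 2L) stop_validation("need at least 2 residues to correlate")
  x <- sel_coords(traj, sel)
  fr <- dim(x)[1]
  if (fr < 2L) stop_validation("correlation needs at least 2 frames")
  cov_raw <- 0
  for (k in 1:3) {
    xc <- sweep(x[, , k], 2, colMeans(x[, , k]))
    cov_raw <- cov_raw + crossprod(xc) / fr
  }
  v <- diag(cov_raw)
  if (all(v == 0))
    stop_validation("trajectory is static: no fluctuations to correlate")
  denom <- sqrt(outer(v, v))
  C <- cov_raw / denom
  C[denom == 0] <- NA_real_
  diag(C)[v > 0] <- 1
  dimnames(C) <- list(sel$ids, sel$ids)
  correlation_map(C, chain = sel$chain, resno = sel$resno,
                  frames = fr, role = sel$role)
}

#' Construct a correlation map from a precomputed matrix
#'
#' @param C symmetric matrix in `[-1, 1]` with residue ids as dimnames
#'   (`NA` entries mark undefined correlations).
#' @param chain,resno residue metadata; parsed from ids (`chain:resno`)
#'   when omitted.
#' @param frames number of frames behind the estimate (`NA` if unknown).
#' @param role selection role the matrix was computed on.
#' @return An object of class `cdn_cmap`.
#' @export
correlation_map <- function(C, chain = NULL, resno = NULL, frames = NA,
                            role = "precomputed") {
  if (!is.matrix(C) || nrow(C) != ncol(C) || nrow(C) < 2L)
    stop_validation("C must be a square matrix with N >= 2")
  if (is.null(rownames(C)))
    stop_validation("C must carry residue ids as dimnames")
  ok <- !is.na(C)
  if (any(abs(C[ok]) > 1 + 1e-9))
    stop_validation("correlations must lie in [-1, 1]")
  if (max(abs(C - t(C)), na.rm = TRUE) > 1e-9)
    stop_validation("correlation matrix must be symmetric")
  if (is.null(chain) || is.null(resno)) {
    parts <- strsplit(rownames(C), ":", fixed = TRUE)
    chain <- vapply(parts, `[`, "", 1)
    resno <- as.integer(vapply(parts, `[`, "", 2))
  }
  structure(list(C = C, ids = rownames(C), chain = chain, resno = resno,
                 frames = frames, role = role),
            class = "cdn_cmap")
}

#' @export
print.cdn_cmap <- function(x, ...) {
  cat("Correlation map:", length(x$ids), "residues,",
      x$frames, "frames, role", x$role, "\n")
  invisible(x)
}

#' Pairwise contact frequency over frames
#'
#' `omega_c(i, j)` is the fraction of frames in which the selected atoms of
#' residues i and j lie within `cutoff` Angstrom (boundary inclusive).
#' Contacts follow the C-beta convention (C-alpha for glycine).
#'
#' @param traj a [trajectory()] (alignment is irrelevant: distances are
#'   rigid-motion invariant).
#' @param sel atom selection; defaults to the C-beta selection.
#' @param cutoff contact distance in Angstrom (default 7.5).
#' @return An object of class `cdn_contacts`: list with `omega` (symmetric
#'   matrix in `[0, 1]`, unit diagonal), `ids`, `cutoff`, `frames`.
#' @export
compute_contact_frequency <- function(traj, sel = NULL, cutoff = 7.5) {
  if (is.null(sel)) sel <- select_atoms(traj, "cbeta")
  check_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0) stop_validation("cutoff must be positive, got ", cutoff)
  x <- sel_coords(traj, sel)
  fr <- dim(x)[1]; n <- dim(x)[2]
  acc <- numeric(n * (n - 1) / 2)
  for (f in seq_len(fr)) {
    d <- stats::dist(x[f, , ])
    acc <- acc + (d <= cutoff)
  }
  omega <- matrix(0, n, n, dimnames = list(sel$ids, sel$ids))
  omega[lower.tri(omega)] <- acc / fr
  omega <- omega + t(omega)
  diag(omega) <- 1
  structure(list(omega = omega, ids = sel$ids, chain = sel$chain,
                 resno = sel$resno, cutoff = cutoff, frames = fr),
            class = "cdn_contacts")
}

#' @export
print.cdn_contacts <- function(x, ...) {
  cat("Contact frequencies:", length(x$ids), "residues, cutoff",
      x$cutoff, "A,", x$frames, "frames\n")
  invisible(x)
}
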