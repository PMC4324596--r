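# Gaussian factor-model generator of ensembles with planted correlation
# structure: communities of concerted motion, designated bottleneck residues
# bridging them, and weakly coupled or independent remainder residues.
#
# Each community k has a latent factor g_k(t). A residue assigned to
# community k with coupling level rho moves as
#   x_i = sqrt(rho) * g_k + sqrt(1 - rho) * eps_i
# per Cartesian axis (isotropic loading, independent innovations), so the
# scalar-product cross-correlation of two members is sqrt(rho_i * rho_j).
# A bottleneck bridging the community set S at level rho_b moves as
#   x_b = sqrt(rho_b / |S|) * sum_{k in S} g_k + sqrt(1 - rho_b) * eps_b.
# All variances are unity, so the implied covariance is a correlation
# matrix and positive semidefinite by construction.

#' Specify a synthetic ensemble with planted network structure
#'
#' @param communities list of `list(size, rho)` entries: `size` residues
#'   coupled at level `rho` (the pairwise correlation of two members is
#'   `sqrt(rho_i * rho_j)`, i.e. `rho` when both use the same level). An
#'   entry may carry `member_of = k` to load on the factor of community `k`
#'   instead of a factor of its own: low-`rho` members attached this way
#'   model the weakly coupled remainder of a protein domain.
#' @param bottlenecks list of `list(bridges, rho)` entries: one residue
#'   bridging the communities indexed by `bridges` at total level `rho`.
#' @param frames number of frames to sample (default 5000).
#' @param seed random seed (default 1).
#' @param amplitude per-axis displacement scale in Angstrom (default 0.3,
#'   i.e. RMSF sqrt(3) * 0.3 ~ 0.5 A, typical of a folded core, and small
#'   against the 7.5 A contact cutoff so the designed chain contact
#'   topology is stable).
#' @param spacing C-alpha spacing of the linear chain geometry (default
#'   3.8 A).
#' @return An object of class `cdn_synspec` with per-residue `membership`,
#'   `rho`, `bridges`, plus `frames`, `seed`, `amplitude`, `spacing`.
#'   Residues are laid out along the chain community by community, each
#'   bottleneck placed between the first two communities it bridges.
#' @export
synthetic_spec <- function(communities = list(list(size = 30, rho = 0.7),
                                              list(size = 30, rho = 0.7)),
                           bottlenecks = list(list(bridges = c(1, 2),
                                                   rho = 0.6)),
                           frames = 5000L, seed = 1L, amplitude = 0.3,
                           spacing = 3.8) {
  if (length(communities) == 0L)
    stop_validation("at least one community is required")
  # assign latent factors: entries with member_of share the factor of the
  # community they point at
  factor_of <- integer(length(communities))
  n_factors <- 0L
  for (k in seq_along(communities)) {
    co <- communities[[k]]
    if (is.null(co$size) || co$size < 1L)
      stop_validation("communities must be non-empty")
    check_scalar_number(co$rho, "community rho", lower = 0, upper = 1 - 1e-12)
    if (!is.null(co$member_of)) {
      if (co$member_of >= k || co$member_of < 1L)
        stop_validation("member_of must point at an earlier community")
      factor_of[k] <- factor_of[[co$member_of]]
    } else {
      n_factors <- n_factors + 1L
      factor_of[k] <- n_factors
    }
  }
  for (b in bottlenecks) {
    if (length(b$bridges) < 2L ||
        any(!b$bridges %in% seq_along(communities)))
      stop_validation("each bottleneck must bridge >= 2 valid communities")
    if (anyDuplicated(factor_of[b$bridges]))
      stop_validation("a bottleneck must bridge communities with distinct ",
                      "factors")
    check_scalar_number(b$rho, "bottleneck rho", lower = 0, upper = 1 - 1e-12)
  }
  check_scalar_number(frames, "frames", lower = 2)
  check_scalar_number(amplitude, "amplitude", lower = 1e-12)
  check_scalar_number(spacing, "spacing", lower = 1e-12)

  # chain layout: community 1, bottlenecks bridging it, community 2, ...
  membership <- integer(0); rho <- numeric(0)
  bridges <- list(); is_bottleneck <- logical(0)
  for (k in seq_along(communities)) {
    co <- communities[[k]]
    membership <- c(membership, rep(factor_of[k], co$size))
    rho <- c(rho, rep(co$rho, co$size))
    bridges <- c(bridges, rep(list(NULL), co$size))
    is_bottleneck <- c(is_bottleneck, rep(FALSE, co$size))
    for (b in bottlenecks) {
      if (min(b$bridges) == k) {
        membership <- c(membership, NA_integer_)
        rho <- c(rho, b$rho)
        bridges <- c(bridges, list(sort(unique(factor_of[b$bridges]))))
        is_bottleneck <- c(is_bottleneck, TRUE)
      }
    }
  }
  structure(list(membership = membership, rho = rho, bridges = bridges,
                 is_bottleneck = is_bottleneck,
                 n = length(membership),
                 n_communities = n_factors,
                 frames = as.integer(frames), seed = as.integer(seed),
                 amplitude = amplitude, spacing = spacing),
            class = "cdn_synspec")
}

#' Default planted-bottleneck specification
#'
#' Two strongly coupled 30-residue communities (`rho = 0.7`) joined by a
#' single bottleneck residue (`rho = 0.6`), embedded among 63 residues
#' weakly attached to community 1's factor (`rho = 0.06`, pairwise
#' correlation ~0.2 with community-1 members) that model the weakly coupled
#' remainder of a protein domain. The strongly coupled assembly comprises
#' half of the 124 residues, so the automatic cutoff lands the connectivity
#' transition with the full two-community assembly as the largest
#' component, as in a real domain where roughly half the residues
#' participate in concerted motion.
#'
#' @param frames,seed passed to [synthetic_spec()].
#' @return A `cdn_synspec`.
#' @export
default_synthetic_spec <- function(frames = 5000L, seed = 1L) {
  synthetic_spec(
    communities = list(list(size = 30, rho = 0.7),
                       list(size = 30, rho = 0.7),
                       list(size = 63, rho = 0.06, member_of = 1)),
    bottlenecks = list(list(bridges = c(1, 2), rho = 0.6)),
    frames = frames, seed = seed)
}

#' Single-community null specification
#'
#' One 30-residue community plus 30 weakly attached remainder residues and
#' no bottleneck: the pipeline should find no critical nodes.
#'
#' @param frames,seed passed to [synthetic_spec()].
#' @return A `cdn_synspec`.
#' @export
null_synthetic_spec <- function(frames = 5000L, seed = 1L) {
  synthetic_spec(
    communities = list(list(size = 30, rho = 0.7),
                       list(size = 30, rho = 0.06, member_of = 1)),
    bottlenecks = list(),
    frames = frames, seed = seed)
}

#' @export
print.cdn_synspec <- function(x, ...) {
  cat("Synthetic spec:", x$n, "residues,", x$n_communities, "communities,",
      sum(x$is_bottleneck), "bottleneck(s),", x$frames, "frames, seed",
      x$seed, "\n")
  invisible(x)
}

syn_ids <- function(spec) res_id("A", seq_len(spec$n))

# Factor loading matrix: n residues x K community factors.
syn_loadings <- function(spec) {
  L <- matrix(0, spec$n, spec$n_communities)
  for (i in seq_len(spec$n)) {
    if (spec$is_bottleneck[i]) {
      S <- spec$bridges[[i]]
      L[i, S] <- sqrt(spec$rho[i] / length(S))
    } else {
      L[i, spec$membership[i]] <- sqrt(spec$rho[i])
    }
  }
  L
}

#' Correlation matrix implied by a synthetic specification
#'
#' Closed form from the factor construction: `C = L L' + diag(1 - ||L_i||^2)`
#' where `L` is the loading matrix. Positive semidefinite by construction
#' (asserted anyway).
#'
#' @param spec a [synthetic_spec()].
#' @return Symmetric correlation matrix with residue ids as dimnames.
#' @export
implied_correlation <- function(spec) {
  L <- syn_loadings(spec)
  C <- tcrossprod(L)
  diag(C) <- 1
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_validation("implied covariance is not positive semidefinite")
  dimnames(C) <- list(syn_ids(spec), syn_ids(spec))
  C
}

#' Planted critical nodes and intended inter-community path of a spec
#'
#' @param spec a [synthetic_spec()].
#' @return list with `spec`, `correlation` (implied matrix), `critical`
#'   (ids of planted bottlenecks) and `paths` (list of intended optimal
#'   inter-community chain segments, `neighbour - bottleneck - neighbour`).
#' @export
ground_truth <- function(spec) {
  ids <- syn_ids(spec)
  bpos <- which(spec$is_bottleneck)
  list(spec = spec,
       correlation = implied_correlation(spec),
       critical = ids[bpos],
       paths = lapply(bpos, function(p) ids[c(p - 1L, p, p + 1L)]))
}

#' Sample a synthetic ensemble from a specification
#'
#' Frames are iid draws from the implied Gaussian model, applied as rigid
#' per-residue displacements (identical on C-alpha and pseudo C-beta) to a
#' fixed linear-chain reference geometry: C-alpha atoms at `spacing`
#' intervals along x, pseudo C-beta atoms offset 1.53 A in y. Chain
#' neighbours therefore sit well inside the 7.5 A contact distance while
#' non-neighbours stay beyond it, so the contact-filtered path graph is the
#' chain itself and every inter-community path crosses the planted
#' bottleneck. No rigid-body motion is added, so the ensemble may be
#' analysed without superposition.
#'
#' @param spec a [synthetic_spec()].
#' @param frames,seed override the spec values.
#' @return list with `trajectory` (a [trajectory()]; atoms CA and CB per
#'   residue, all residues ALA on chain A) and `truth` ([ground_truth()]).
#' @export
sample_trajectory <- function(spec, frames = spec$frames, seed = spec$seed) {
  frames <- as.integer(check_scalar_number(frames, "frames", lower = 2))
  set.seed(as.integer(seed))
  n <- spec$n
  L <- syn_loadings(spec)
  uniq <- sqrt(pmax(0, 1 - rowSums(L^2)))
  disp <- array(0, dim = c(frames, n, 3))
  for (k in 1:3) {
    G <- matrix(stats::rnorm(frames * ncol(L)), frames, ncol(L))
    E <- matrix(stats::rnorm(frames * n), frames, n)
    disp[, , k] <- spec$amplitude * (G %*% t(L) +
                                       sweep(E, 2, uniq, `*`))
  }
  ca <- cbind((seq_len(n) - 1) * spec$spacing, 0, 0)
  cb <- sweep(ca, 2, c(0, 1.53, 0), `+`)
  coords <- array(0, dim = c(frames, 2L * n, 3))
  for (k in 1:3) {
    coords[, seq(1L, 2L * n, by = 2L), k] <-
      sweep(disp[, , k], 2, ca[, k], `+`)
    coords[, seq(2L, 2L * n, by = 2L), k] <-
      sweep(disp[, , k], 2, cb[, k], `+`)
  }
  atoms <- data.frame(
    elety = rep(c("CA", "CB"), n),
    resid = "ALA",
    chain = "A",
    resno = rep(seq_len(n), each = 2L),
    stringsAsFactors = FALSE)
  traj <- trajectory(coords, atoms,
                     provenance = list(source = "synthetic", seed = seed,
                                       frames = frames, superposed = TRUE))
  list(trajectory = traj, truth = ground_truth(spec))
}

#' Read a synthetic specification from YAML or JSON
#'
#' The file mirrors the [synthetic_spec()] arguments, e.g.
#' `communities: [{size: 30, rho: 0.7}, ...]`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `cdn_synspec`.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop_io("cannot read spec file: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(synthetic_spec, raw)
}
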