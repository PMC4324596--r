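# Independent oracles: brute-force double/triple loops for the statistics,
# igraph-free graph algorithms (BFS components, DFS articulation points,
# exhaustive simple-path enumeration) for the network operations.

# --- statistics on an F x n x 3 displacement array ------------------------

brute_rmsf <- function(x) {
  fr <- dim(x)[1]; n <- dim(x)[2]
  out <- numeric(n)
  for (i in seq_len(n)) {
    mu <- c(mean(x[, i, 1]), mean(x[, i, 2]), mean(x[, i, 3]))
    s <- 0
    for (f in seq_len(fr))
      s <- s + sum((x[f, i, ] - mu)^2)
    out[i] <- sqrt(s / fr)
  }
  out
}

brute_correlation <- function(x) {
  fr <- dim(x)[1]; n <- dim(x)[2]
  mu <- array(0, c(n, 3))
  for (i in seq_len(n)) for (k in 1:3) mu[i, k] <- mean(x[, i, k])
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(fr)) {
      di <- x[f, i, ] - mu[i, ]
      dj <- x[f, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di^2)
      vj <- vj + sum(dj^2)
    }
    if (vi > 0 && vj > 0) C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

brute_contact_freq <- function(x, cutoff) {
  fr <- dim(x)[1]; n <- dim(x)[2]
  omega <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { omega[i, j] <- 1; next }
    hits <- 0
    for (f in seq_len(fr))
      if (sqrt(sum((x[f, i, ] - x[f, j, ])^2)) <= cutoff) hits <- hits + 1
    omega[i, j] <- hits / fr
  }
  omega
}

# --- trajectory fixtures ---------------------------------------------------

# random free-floating residues (CA + CB per residue, CB offset fixed)
random_traj <- function(n_res, n_frames, seed, scale = 1) {
  set.seed(seed)
  disp <- array(rnorm(n_frames * n_res * 3, sd = scale),
                dim = c(n_frames, n_res, 3))
  # well-spread 3-D base geometry (a collinear base would leave the
  # superposition rotation under-determined about the chain axis)
  base <- matrix(runif(n_res * 3, 0, 15 * sqrt(n_res)), ncol = 3)
  coords <- array(0, dim = c(n_frames, 2 * n_res, 3))
  for (k in 1:3) {
    dk <- matrix(disp[, , k], nrow = n_frames)
    coords[, seq(1, 2 * n_res, 2), k] <- sweep(dk, 2, base[, k], `+`)
    coords[, seq(2, 2 * n_res, 2), k] <-
      sweep(dk, 2, base[, k] + c(0, 1.5, 0)[k], `+`)
  }
  trajectory(coords,
             data.frame(elety = rep(c("CA", "CB"), n_res), resid = "ALA",
                        chain = "A", resno = rep(seq_len(n_res), each = 2),
                        stringsAsFactors = FALSE),
             provenance = list(source = "fixture"))
}

ca_displacements <- function(traj) {
  sel <- select_atoms(traj, "calpha")
  traj$coords[, sel$indices, , drop = FALSE]
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(traj, seed = 1) {
  set.seed(seed)
  out <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    out$coords[f, , ] <- sweep(traj$coords[f, , ] %*% R, 2, t, `+`)
  }
  out
}

# fixed-width multi-model PDB writer for constructed parse fixtures
pdb_fixture_lines <- function(models, atoms) {
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- models[[m]]
    for (a in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        a, atoms$elety[a], atoms$resid[a], atoms$chain[a], atoms$resno[a],
        xyz[a, 1], xyz[a, 2], xyz[a, 3], 1, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

peptide_atoms <- function(resids = c("ALA", "GLY", "LEU", "SER", "VAL")) {
  rows <- list()
  for (i in seq_along(resids)) {
    elety <- if (resids[i] == "GLY") c("N", "CA", "C")
             else c("N", "CA", "CB", "C")
    rows[[i]] <- data.frame(elety = elety, resid = resids[i], chain = "A",
                            resno = i, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

peptide_coords <- function(atoms, seed = 1, sd = 0.3) {
  set.seed(seed)
  base <- cbind(atoms$resno * 3.8 + seq_len(nrow(atoms)) * 0.37, 0, 0)
  base + matrix(rnorm(nrow(atoms) * 3, sd = sd), ncol = 3)
}

# --- igraph-free graph oracles --------------------------------------------

# edges: 2-column matrix of 1-based endpoints; n: node count
bfs_components <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# classic DFS articulation-point algorithm (recursive; n kept small)
dfs_articulation <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  disc <- rep(0L, n); low <- rep(0L, n); parent <- rep(0L, n)
  ap <- rep(FALSE, n); timer <- 0L
  visit <- function(u) {
    timer <<- timer + 1L
    disc[u] <<- timer; low[u] <<- timer
    children <- 0L
    for (v in adj[[u]]) {
      if (disc[v] == 0L) {
        children <- children + 1L
        parent[v] <<- u
        visit(v)
        low[u] <<- min(low[u], low[v])
        if (parent[u] == 0L && children > 1L) ap[u] <<- TRUE
        if (parent[u] != 0L && low[v] >= disc[u]) ap[u] <<- TRUE
      } else if (v != parent[u]) {
        low[u] <<- min(low[u], disc[v])
      }
    }
  }
  for (u in seq_len(n)) if (disc[u] == 0L) visit(u)
  which(ap)
}

# brute-force critical nodes: remove each node of the largest component,
# BFS the remainder, apply the component-size rule
brute_critical <- function(edges, n, min_component) {
  comp <- bfs_components(edges, n)
  tab <- table(comp)
  big <- as.integer(names(tab)[which.max(tab)])
  members <- which(comp == big)
  crit <- integer(0)
  sizes_all <- list()
  for (a in members) {
    keep <- setdiff(members, a)
    idx <- match(keep, keep)
    sub <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    sub2 <- cbind(match(sub[, 1], keep), match(sub[, 2], keep))
    cc <- bfs_components(sub2, length(keep))
    sizes <- sort(as.integer(table(cc)), decreasing = TRUE)
    sizes_all[[as.character(a)]] <- sizes
    if (length(sizes) >= 2 && sum(sizes >= min_component) >= 2)
      crit <- c(crit, a)
  }
  list(critical = crit, members = members, sizes = sizes_all)
}

# exhaustive minimum simple-path weight between s and t
enumerate_shortest <- function(edges, w, n, s, t) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, w[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[e]))
  }
  best <- Inf
  visited <- rep(FALSE, n)
  recurse <- function(v, acc) {
    if (v == t) { best <<- min(best, acc); return() }
    visited[v] <<- TRUE
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      nb <- adj[[v]][r, 1]; wt <- adj[[v]][r, 2]
      if (!visited[nb]) recurse(nb, acc + wt)
    }
    visited[v] <<- FALSE
  }
  recurse(s, 0)
  best
}

# random correlation-like map: a genuine correlation matrix via cov2cor
random_cmap <- function(n, seed, spread = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2), sd = spread), n + 2, n)
  C <- stats::cov2cor(crossprod(A))
  dimnames(C) <- list(paste0("A:", 1:n), paste0("A:", 1:n))
  correlation_map(C, chain = rep("A", n), resno = 1:n, frames = n + 2,
                  role = "calpha")
}

# cmap built from an explicit weight matrix (for hand-constructed graphs)
cmap_from_matrix <- function(W) {
  n <- nrow(W)
  diag(W) <- 1
  dimnames(W) <- list(paste0("A:", 1:n), paste0("A:", 1:n))
  correlation_map(W, chain = rep("A", n), resno = 1:n)
}

# graph object from an explicit weight matrix at a cutoff
graph_from_weights <- function(W, cutoff) {
  build_coupling_graph(cmap_from_matrix(W), cutoff)
}

edges_from_graph <- function(graph) {
  el <- igraph::as_data_frame(graph$graph, what = "edges")
  cbind(match(el$from, graph$ids), match(el$to, graph$ids))
}
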