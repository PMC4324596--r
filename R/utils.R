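# Internal helpers shared across modules.

res_id <- function(chain, resno) paste0(chain, ":", resno)

# Order key for residues: by chain, then residue number.
res_order <- function(chain, resno) order(chain, resno)

stop_validation <- function(...) {
  stop(structure(class = c("cdnet_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_io <- function(...) {
  stop(structure(class = c("cdnet_io_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_format <- function(...) {
  stop(structure(class = c("cdnet_format_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_validation(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

# Convert an F x A x 3 coordinate array to a bio3d-style F x 3A xyz matrix
# (atom-major ordering x1,y1,z1,x2,...).
coords_to_xyz <- function(coords) {
  fr <- dim(coords)[1]; na <- dim(coords)[2]
  xyz <- matrix(0, fr, 3L * na)
  for (k in 1:3) xyz[, seq(k, 3L * na, by = 3L)] <- coords[, , k]
  xyz
}

xyz_to_coords <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  fr <- nrow(xyz); na <- ncol(xyz) / 3L
  coords <- array(0, dim = c(fr, na, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * na, by = 3L)]
  coords
}

# Largest-component size as a function of a descending edge-weight threshold,
# via incremental union-find (edges are added as the threshold is lowered,
# which mirrors retaining all edges with weight >= threshold).
# edges: data.frame/list with i, j (1-based node indices) and w (weights).
# Returns, for each candidate (ascending distinct weights), the size of the
# largest connected component when edges with w >= candidate are retained.
largest_component_scan <- function(i, j, w, n_nodes) {
  stopifnot(length(i) == length(j), length(j) == length(w))
  cand <- sort(unique(w))
  parent <- seq_len(n_nodes)
  size <- rep(1L, n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ord <- order(w, decreasing = TRUE)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  largest <- if (n_nodes > 0L) 1L else 0L
  out <- integer(length(cand))
  e <- 1L
  n_edges <- length(w)
  for (ci in rev(seq_along(cand))) {        # descending candidates
    c_val <- cand[ci]
    while (e <= n_edges && w[e] >= c_val) {
      ra <- find(i[e]); rb <- find(j[e])
      if (ra != rb) {
        if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        size[ra] <- size[ra] + size[rb]
        if (size[ra] > largest) largest <- size[ra]
      }
      e <- e + 1L
    }
    out[ci] <- largest
  }
  list(cutoffs = cand, largest = out)
}
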