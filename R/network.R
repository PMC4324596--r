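# Correlation-weighted residue networks: construction, critical-cutoff
# selection, and bottleneck (critical node) detection.

cmap_weights <- function(cmap, use_abs = TRUE) {
  W <- if (use_abs) abs(cmap$C) else cmap$C
  diag(W) <- NA_real_          # no self-edges
  W
}

cmap_edges <- function(cmap, use_abs = TRUE) {
  W <- cmap_weights(cmap, use_abs)
  n <- nrow(W)
  ut <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2], w = W[ut])
}

new_coupling_graph <- function(g, cmap_ids, chain, resno, cutoff, mode,
                               use_abs = NA) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # tie-break: component containing the smallest residue id (chain, resno)
    ord <- res_order(chain, resno)
    first_touch <- vapply(big, function(ci) {
      match(TRUE, comp$membership[ord] == ci)
    }, integer(1))
    big <- big[which.min(first_touch)]
  }
  largest <- names(comp$membership)[comp$membership == big]
  structure(list(graph = g, ids = cmap_ids, chain = chain, resno = resno,
                 cutoff = cutoff, mode = mode, use_abs = use_abs,
                 membership = comp$membership, largest = largest),
            class = "cdn_graph")
}

#' Build the coupled-dynamics residue graph
#'
#' Residues are nodes; an edge joins i and j when its weight (|C_ij| by
#' default, the signed C_ij with `use_abs = FALSE`) is at least `cutoff`
#' (inclusive: only edges strictly below the cutoff are eliminated).
#' Undefined (`NA`) correlations never produce edges.
#'
#' @param cmap a correlation map.
#' @param cutoff correlation cutoff in `[0, 1]`.
#' @param use_abs use `|C_ij|` as the edge weight (default); anti-correlated
#'   motion is still coupling.
#' @return An object of class `cdn_graph`: list with `graph` (igraph, edge
#'   attribute `weight`), `ids`, `cutoff`, `mode = "dynamic"`, `membership`
#'   (component labels) and `largest` (ids of the largest component, ties
#'   broken by smallest contained residue id).
#' @export
build_coupling_graph <- function(cmap, cutoff, use_abs = TRUE) {
  check_scalar_number(cutoff, "cutoff", lower = 0, upper = 1)
  ed <- cmap_edges(cmap, use_abs)
  keep <- ed$w >= cutoff
  g <- igraph::graph_from_data_frame(
    data.frame(from = cmap$ids[ed$i[keep]], to = cmap$ids[ed$j[keep]],
               weight = ed$w[keep]),
    directed = FALSE,
    vertices = data.frame(name = cmap$ids))
  new_coupling_graph(g, cmap$ids, cmap$chain, cmap$resno, cutoff,
                     mode = "dynamic", use_abs = use_abs)
}

#' @export
print.cdn_graph <- function(x, ...) {
  cat("Coupling graph (", x$mode, "): ", length(x$ids), " nodes, ",
      igraph::ecount(x$graph), " edges, cutoff ",
      signif(x$cutoff, 4), "\n", sep = "")
  cat("  largest component:", length(x$largest), "nodes\n")
  invisible(x)
}

#' Select the critical correlation cutoff
#'
#' Scans all distinct edge weights as candidate cutoffs and records
#' `f(c)`, the fraction of residues in the largest connected component when
#' edges of weight >= c are retained. `f` is non-increasing in c. The
#' selected cutoff is the smallest candidate with `f(c) <= target_fraction`
#' ("eliminating edges until the largest component comprises approximately
#' 50% of the nodes", the connectivity transition). If no candidate reaches
#' the target the largest candidate is selected with a warning. A warning is
#' also emitted when `f` jumps by more than 0.25 across the selected cutoff
#' (sharp percolation transition: the choice of cutoff is then delicate and
#' worth expert review, so the full scan is always returned).
#'
#' @param cmap a correlation map (N >= 4).
#' @param target_fraction target largest-component fraction (default 0.5).
#' @param use_abs weight edges by `|C_ij|` (default).
#' @return A data.frame of class `cdn_cutoff_scan` with columns `cutoff` and
#'   `fraction` (ascending candidates); attributes `selected`, `target`,
#'   `n_nodes`, `use_abs`.
#' @export
select_cutoff <- function(cmap, target_fraction = 0.5, use_abs = TRUE) {
  check_scalar_number(target_fraction, "target_fraction", lower = 0, upper = 1)
  n <- length(cmap$ids)
  if (n < 4L) stop_validation("cutoff selection needs at least 4 residues")
  ed <- cmap_edges(cmap, use_abs)
  if (nrow(ed) == 0L) stop_validation("correlation map has no defined edges")
  scan <- largest_component_scan(ed$i, ed$j, ed$w, n)
  f <- scan$largest / n
  hit <- which(f <= target_fraction)
  if (length(hit) > 0L) {
    sel_i <- hit[1]
  } else {
    sel_i <- length(scan$cutoffs)
    warning("no cutoff reaches largest-component fraction <= ",
            target_fraction, "; selecting the largest candidate ",
            signif(scan$cutoffs[sel_i], 4))
  }
  f_below <- if (sel_i > 1L) f[sel_i - 1L] else 1
  f_above <- if (sel_i < length(f)) f[sel_i + 1L] else 1 / n
  if (f_below - f[sel_i] > 0.25 || f[sel_i] - f_above > 0.25)
    warning("sharp transition in largest-component fraction across the ",
            "selected cutoff (", signif(f_below, 3), " -> ",
            signif(f[sel_i], 3), " -> ", signif(f_above, 3),
            "); consider reviewing the scan")
  out <- data.frame(cutoff = scan$cutoffs, fraction = f)
  attr(out, "selected") <- scan$cutoffs[sel_i]
  attr(out, "target") <- target_fraction
  attr(out, "n_nodes") <- n
  attr(out, "use_abs") <- use_abs
  class(out) <- c("cdn_cutoff_scan", "data.frame")
  out
}

#' @export
selected_cutoff <- function(scan) attr(scan, "selected")

#' @export
print.cdn_cutoff_scan <- function(x, ...) {
  cat("Cutoff scan:", nrow(x), "candidates over", attr(x, "n_nodes"),
      "nodes\n")
  sel <- attr(x, "selected")
  cat("  selected cutoff", signif(sel, 4), "with largest-component fraction",
      signif(x$fraction[match(sel, x$cutoff)], 4), "(target",
      attr(x, "target"), ")\n")
  invisible(x)
}

#' Identify bottleneck ("critical node") residues
#'
#' Each node of the largest connected component is removed in turn and the
#' components of the remainder (restricted to the former largest component)
#' are measured. A node is critical when its removal splits the component
#' into two or more parts of at least `min_component` residues each: the
#' node is then the lone conduit of dynamic coupling between sizeable
#' regions. Every critical node is necessarily an articulation point; the
#' converse does not hold (an articulation point shedding only a small
#' fragment is not critical).
#'
#' @param graph a `cdn_graph`.
#' @param min_component minimum size of a split-off component (default 10).
#' @return A data.frame of class `cdn_critical` with one row per node of the
#'   largest component: `id`, `chain`, `resno`, `n_components`,
#'   `largest_after`, `second_after`, `is_critical`; attribute
#'   `component_sizes` (named list of full size vectors), `min_component`.
#' @export
find_critical_nodes <- function(graph, min_component = 10L) {
  min_component <- as.integer(check_scalar_number(min_component,
                                                  "min_component", lower = 1))
  sub <- igraph::induced_subgraph(graph$graph, graph$largest)
  nodes <- igraph::V(sub)$name
  sizes_list <- lapply(nodes, function(v) {
    comp <- igraph::components(igraph::delete_vertices(sub, v))
    sort(comp$csize, decreasing = TRUE)
  })
  names(sizes_list) <- nodes
  n_meet <- vapply(sizes_list, function(s) sum(s >= min_component), integer(1))
  ord <- match(nodes, graph$ids)
  out <- data.frame(
    id = nodes,
    chain = graph$chain[ord],
    resno = graph$resno[ord],
    n_components = vapply(sizes_list, length, integer(1)),
    largest_after = vapply(sizes_list,
                           function(s) as.integer(if (length(s) > 0L) s[1] else 0L),
                           integer(1)),
    second_after = vapply(sizes_list,
                          function(s) as.integer(if (length(s) > 1L) s[2] else 0L),
                          integer(1)),
    is_critical = vapply(sizes_list, length, integer(1)) >= 2L & n_meet >= 2L,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[res_order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "component_sizes") <- sizes_list
  attr(out, "min_component") <- min_component
  attr(out, "largest_component_size") <- length(nodes)
  class(out) <- c("cdn_critical", "data.frame")
  out
}

#' @export
critical_ids <- function(report) report$id[report$is_critical]

#' @export
print.cdn_critical <- function(x, ...) {
  crit <- x$id[x$is_critical]
  cat("Critical-node scan over", nrow(x), "nodes of the largest component",
      "(min component size", attr(x, "min_component"), ")\n")
  if (length(crit) == 0L) cat("  no critical nodes\n")
  else cat("  critical nodes:", paste(crit, collapse = ", "), "\n")
  invisible(x)
}

#' Static contact-count network from a single structure
#'
#' Contrast network for the dynamic analysis: edges are weighted by the
#' number of heavy-atom pairs (one atom from each residue) within
#' `contact_distance`, normalised to `[0, 1]` by the maximum count so that
#' downstream path and bottleneck operations apply unchanged.
#'
#' @param traj a single-frame [trajectory()] (built e.g. from a one-model
#'   PDB via [bio3d::read.pdb()] or by subsetting).
#' @param contact_distance heavy-atom contact distance in Angstrom
#'   (default 4.5, the standard heavy-atom contact convention).
#' @return A `cdn_graph` with `mode = "static"`; edge attributes `count`
#'   (raw contact count) and `weight` (normalised).
#' @export
build_static_contact_graph <- function(traj, contact_distance = 4.5) {
  if (dim(traj$coords)[1] != 1L)
    stop_validation("static contact network needs exactly one frame; use the ",
                    "dynamic correlation mode for ensembles")
  check_scalar_number(contact_distance, "contact_distance", lower = 0)
  at <- traj$atoms
  heavy <- !grepl("^[0-9]*H", at$elety)
  key <- res_id(at$chain, at$resno)
  residues <- unique(key)
  n <- length(residues)
  res_idx <- match(key, residues)
  xyz <- matrix(traj$coords[1, , ], ncol = 3)
  counts <- matrix(0L, n, n)
  hrows <- which(heavy)
  for (a in hrows) {
    later <- hrows[hrows > a & res_idx[hrows] != res_idx[a]]
    if (length(later) == 0L) next
    d2 <- rowSums(sweep(xyz[later, , drop = FALSE], 2, xyz[a, ])^2)
    hit <- later[d2 <= contact_distance^2]
    for (b in hit) {
      i <- res_idx[a]; j <- res_idx[b]
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[i, j]
    }
  }
  ut <- which(upper.tri(counts) & counts > 0L, arr.ind = TRUE)
  wmax <- if (nrow(ut) > 0L) max(counts[ut]) else 1L
  g <- igraph::graph_from_data_frame(
    data.frame(from = residues[ut[, 1]], to = residues[ut[, 2]],
               count = counts[ut], weight = counts[ut] / wmax),
    directed = FALSE, vertices = data.frame(name = residues))
  first <- match(residues, key)
  new_coupling_graph(g, residues, at$chain[first], at$resno[first],
                     cutoff = NA_real_, mode = "static")
}
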