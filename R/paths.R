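# Optimal dynamic-coupling paths on the contact-filtered correlation graph.

#' Query for optimal coupling paths between two residue sets
#'
#' @param source,target non-empty, disjoint residue sets: character ids
#'   (`chain:resno`) or residue numbers (interpreted on chain "A" or matched
#'   against the graph at query time).
#' @param min_freq contact-frequency threshold used when building the path
#'   graph (default 0.5).
#' @param contact_distance contact distance (Angstrom, default 7.5);
#'   recorded for provenance.
#' @return An object of class `cdn_path_query`.
#' @export
path_query <- function(source, target, min_freq = 0.5,
                       contact_distance = 7.5) {
  if (length(source) == 0L || length(target) == 0L)
    stop_validation("source and target sets must be non-empty")
  source <- as.character(source); target <- as.character(target)
  if (length(intersect(source, target)) > 0L)
    stop_validation("source and target sets must be disjoint: ",
                    paste(intersect(source, target), collapse = ", "))
  check_scalar_number(min_freq, "min_freq", lower = 0, upper = 1)
  check_scalar_number(contact_distance, "contact_distance", lower = 0)
  structure(list(source = source, target = target, min_freq = min_freq,
                 contact_distance = contact_distance),
            class = "cdn_path_query")
}

#' Build the contact-filtered path graph
#'
#' Coupling is transferred through physical interactions, so only residue
#' pairs in frequent contact carry edges: edge (i, j) is retained when
#' `omega_c(i, j) >= min_freq` (boundary inclusive) and `C_ij` is defined.
#' Edge weights are the coupling distances `1 - |C_ij|`: perfectly
#' correlated pairs transfer for free (weight 0), uncorrelated pairs cost 1.
#'
#' @param cmap a correlation map.
#' @param contacts a contact-frequency map over the same residues.
#' @param min_freq minimum contact frequency (default 0.5).
#' @return A `cdn_graph` with `mode = "path"`; edge attributes `weight`
#'   (`1 - |C|`), `correlation` and `omega`.
#' @export
build_path_graph <- function(cmap, contacts, min_freq = 0.5) {
  check_scalar_number(min_freq, "min_freq", lower = 0, upper = 1)
  if (!identical(cmap$ids, contacts$ids))
    stop_validation("correlation map and contact map cover different ",
                    "residue sets")
  if (!is.na(cmap$frames) && !is.na(contacts$frames) &&
      cmap$frames != contacts$frames)
    warning("correlation map (", cmap$frames, " frames) and contact map (",
            contacts$frames, " frames) appear to come from different ",
            "trajectories")
  W <- abs(cmap$C)
  diag(W) <- NA_real_
  ut <- which(upper.tri(W) & !is.na(W) & contacts$omega >= min_freq,
              arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = cmap$ids[ut[, 1]], to = cmap$ids[ut[, 2]],
               weight = 1 - W[ut],
               correlation = cmap$C[ut],
               omega = contacts$omega[ut]),
    directed = FALSE, vertices = data.frame(name = cmap$ids))
  gr <- new_coupling_graph(g, cmap$ids, cmap$chain, cmap$resno,
                           cutoff = NA_real_, mode = "path")
  gr$min_freq <- min_freq
  gr
}

# Deterministic choice among equally short paths: fewest hops first, then
# lexicographic on the node sequence ordered by (chain, resno).
pick_path <- function(paths, rank_of) {
  if (length(paths) == 1L) return(paths[[1]])
  hops <- vapply(paths, length, integer(1))
  paths <- paths[hops == min(hops)]
  if (length(paths) == 1L) return(paths[[1]])
  keys <- lapply(paths, function(p) rank_of[p])
  best <- 1L
  for (k in seq_along(keys)[-1]) {
    a <- keys[[best]]; b <- keys[[k]]
    cmp <- which(a != b)
    if (length(cmp) > 0L && b[cmp[1]] < a[cmp[1]]) best <- k
  }
  paths[[best]]
}

#' Optimal coupling paths between residue sets
#'
#' Runs Dijkstra's algorithm on the path graph (edge weights `1 - |C_ij|`)
#' for every source-target pair of the query. Among equal-length optimal
#' paths the one with fewer hops, then the lexicographically smallest node
#' sequence, is reported, so results are deterministic. Unreachable pairs
#' are flagged, not errored. A path census counts how often each residue
#' lies on the reported optimal paths, which highlights the residues
#' mediating coupling between the two regions.
#'
#' @param graph a `cdn_graph` in path mode ([build_path_graph()]) or static
#'   mode ([build_static_contact_graph()]; weights are converted to
#'   distances `1 - weight`).
#' @param query a [path_query()].
#' @return An object of class `cdn_paths`: list with `pairs` (data.frame:
#'   `source`, `target`, `length`, `hops`, `unreachable`, `path` string),
#'   `paths` (list of id vectors), `edge_weights` (list of per-edge weight
#'   vectors), `best` (row index of the overall best pair) and `census`
#'   (data.frame `id`, `count`).
#' @export
shortest_path <- function(graph, query) {
  if (!graph$mode %in% c("path", "static"))
    stop_validation("shortest paths need a path-mode graph ",
                    "(build_path_graph) or a static contact graph")
  g <- graph$graph
  resolve <- function(x, what) {
    miss <- setdiff(x, graph$ids)
    if (length(miss) > 0L) {
      # allow bare residue numbers when unambiguous
      bynum <- lapply(miss, function(m) graph$ids[graph$resno == m])
      if (all(lengths(bynum) == 1L)) {
        x[match(miss, x)] <- unlist(bynum)
      } else {
        stop_validation(what, " residues absent from the graph: ",
                        paste(miss, collapse = ", "))
      }
    }
    x
  }
  src <- resolve(query$source, "source")
  tgt <- resolve(query$target, "target")
  w <- igraph::E(g)$weight
  if (graph$mode == "static") w <- 1 - w
  rank_of <- stats::setNames(match(graph$ids,
                                   graph$ids[res_order(graph$chain,
                                                       graph$resno)]),
                             graph$ids)
  pairs <- expand.grid(source = src, target = tgt,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paths <- vector("list", nrow(pairs))
  ew <- vector("list", nrow(pairs))
  len <- rep(NA_real_, nrow(pairs))
  for (s in src) {
    rows <- which(pairs$source == s)
    reach <- tgt[is.finite(igraph::distances(g, v = s, to = tgt,
                                             weights = w))]
    if (length(reach) == 0L) next
    asp <- igraph::all_shortest_paths(g, from = s, to = reach, weights = w)
    vp <- lapply(asp$vpaths %||% asp$res, function(p) igraph::as_ids(p))
    ends <- vapply(vp, function(p) p[length(p)], character(1))
    for (r in rows) {
      cand <- vp[ends == pairs$target[r]]
      if (length(cand) == 0L) next
      p <- pick_path(cand, rank_of)
      paths[[r]] <- p
      eids <- igraph::get_edge_ids(g, rep(p, each = 2)[-c(1, 2 * length(p))])
      ew[[r]] <- w[eids]
      len[r] <- sum(w[eids])
    }
  }
  pairs$length <- len
  pairs$hops <- vapply(paths, function(p) max(length(p) - 1L, 0L), integer(1))
  pairs$unreachable <- vapply(paths, is.null, logical(1))
  pairs$path <- vapply(paths, function(p)
    if (is.null(p)) NA_character_ else paste(p, collapse = " -> "),
    character(1))
  reach <- which(!pairs$unreachable)
  best <- if (length(reach) > 0L) reach[which.min(len[reach])] else NA_integer_
  counts <- table(unlist(paths[reach]))
  census <- data.frame(id = graph$ids,
                       count = as.integer(counts[graph$ids]),
                       stringsAsFactors = FALSE)
  census$count[is.na(census$count)] <- 0L
  structure(list(pairs = pairs, paths = paths, edge_weights = ew,
                 best = best, census = census, query = query),
            class = "cdn_paths")
}

#' @export
print.cdn_paths <- function(x, ...) {
  cat("Optimal coupling paths:", nrow(x$pairs), "source-target pairs,",
      sum(x$pairs$unreachable), "unreachable\n")
  if (!is.na(x$best)) {
    b <- x$pairs[x$best, ]
    cat("  best: ", b$source, " -> ", b$target, " length ",
        signif(b$length, 4), " via ", b$path, "\n", sep = "")
  }
  invisible(x)
}
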