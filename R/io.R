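# Delimited-text and graph exports. All tables are TSV with a header row;
# matrices carry residue ids as both header row and first column.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("id", colnames(M)))
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}

#' Write / read a correlation map as TSV
#'
#' Symmetric matrix with residue ids (`chain:resno`) as the header row and
#' first column; `NA` marks undefined (zero-fluctuation) entries.
#'
#' @param cmap a correlation map.
#' @param path file path.
#' @return `path` (write) or a `cdn_cmap` (read).
#' @export
write_correlation_map <- function(cmap, path) write_matrix_tsv(cmap$C, path)

#' @rdname write_correlation_map
#' @export
read_correlation_map <- function(path) {
  if (!file.exists(path)) stop_io("cannot read correlation map: ", path)
  correlation_map(read_matrix_tsv(path))
}

#' Write an RMSF profile as two-column TSV
#'
#' @param rmsf a `cdn_rmsf` profile.
#' @param path file path.
#' @export
write_rmsf <- function(rmsf, path) {
  write_tsv(data.frame(id = rmsf$id, rmsf = rmsf$rmsf), path)
}

#' Write a reference structure with RMSF in the B-factor column
#'
#' One model (the frame mean) with each atom's B-factor set to its
#' residue's RMSF, for tube-style rendering in external viewers.
#'
#' @param traj the trajectory the profile was computed on.
#' @param rmsf a `cdn_rmsf` profile.
#' @param path output PDB path.
#' @export
write_rmsf_pdb <- function(traj, rmsf, path) {
  at <- traj$atoms
  key <- res_id(at$chain, at$resno)
  b <- rmsf$rmsf[match(key, rmsf$id)]
  b[is.na(b)] <- 0
  mean_xyz <- colMeans(coords_to_xyz(traj$coords))
  bio3d::write.pdb(file = path, xyz = mean_xyz,
                   resno = at$resno, resid = at$resid,
                   chain = at$chain, elety = at$elety, b = b)
  invisible(path)
}

#' Export a coupling graph
#'
#' `write_edge_list()` writes a TSV of `res_i`, `res_j`, `weight` (plus
#' `count` for static graphs); `write_graphml()` writes GraphML via
#' [igraph::write_graph()] for external network viewers.
#'
#' @param graph a `cdn_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph$graph, what = "edges")
  names(el)[1:2] <- c("res_i", "res_j")
  write_tsv(el, path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}

#' Write component membership and the critical-node table
#'
#' @param graph a `cdn_graph` (for components).
#' @param report a `cdn_critical` report.
#' @param path file path.
#' @export
write_components <- function(graph, path) {
  write_tsv(data.frame(id = graph$ids,
                       component = as.integer(graph$membership),
                       in_largest = graph$ids %in% graph$largest), path)
}

#' @rdname write_components
#' @export
write_critical_nodes <- function(report, path) {
  df <- as.data.frame(report)
  sizes <- attr(report, "component_sizes")[df$id]
  df$component_sizes <- vapply(sizes, paste, "", collapse = ",")
  write_tsv(df, path)
}

#' Write optimal-path results
#'
#' `write_paths()` ranks pairs by path length; `write_path_census()` writes
#' the per-residue count of optimal paths passing through each node.
#'
#' @param paths a `cdn_paths` result.
#' @param path file path.
#' @export
write_paths <- function(paths, path) {
  df <- paths$pairs
  df <- df[order(df$unreachable, df$length, df$source, df$target), ]
  df$rank <- seq_len(nrow(df))
  write_tsv(df[, c("rank", "source", "target", "length", "hops",
                   "unreachable", "path")], path)
}

#' @rdname write_paths
#' @export
write_path_census <- function(paths, path) write_tsv(paths$census, path)

#' Write a cutoff scan
#'
#' @param scan a `cdn_cutoff_scan`.
#' @param path file path.
#' @export
write_cutoff_scan <- function(scan, path) {
  write_tsv(data.frame(cutoff = scan$cutoff, fraction = scan$fraction,
                       selected = scan$cutoff == attr(scan, "selected")),
            path)
}
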