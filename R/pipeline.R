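# End-to-end pipeline: ensemble -> fluctuations -> correlation -> network
# -> critical nodes -> optimal paths, with a machine-readable manifest.

#' Named residue regions of CFTR NBD1
#'
#' The regulatory insertion (RI, 404-435), structurally diverse region
#' (SDR, 532-552), RI-SDR bridge (492-502), F508 loop (507-514) and part of
#' the ATP-binding sub-domain (570-600). Shipped as an ordinary region
#' preset; the pipeline itself is protein-agnostic.
#'
#' @return Named list of residue-number vectors.
#' @export
nbd1_regions <- function() {
  list(RI = 404:435,
       SDR = 532:552,
       RI_SDR_bridge = 492:502,
       F508_loop = 507:514,
       ATP_binding = 570:600)
}

#' Pipeline configuration
#'
#' Defaults follow the published analysis conventions: 7.5 Angstrom C-beta
#' contact distance, minimum contact frequency 0.5, automatic cutoff at
#' target largest-component fraction 0.5, minimum split-component size 10.
#'
#' @param trajectory path to a multi-model PDB, or a [trajectory()] object.
#' @param correlation optional path to a precomputed correlation-map TSV
#'   (skips the trajectory stages; RMSF/contacts then unavailable).
#' @param selection node selection role (default `"calpha"`).
#' @param superpose remove rigid-body motion before analysis (default TRUE;
#'   set FALSE for pre-aligned or synthetic inputs).
#' @param frame_stride keep every n-th frame on loading.
#' @param cutoff `"auto"` (select at `target_fraction`) or a number.
#' @param target_fraction largest-component target for automatic cutoff.
#' @param use_abs weight edges by `|C_ij|`.
#' @param min_component minimum split-component size for critical nodes.
#' @param contact_distance C-beta contact distance (Angstrom).
#' @param min_freq minimum contact frequency for path edges.
#' @param regions named list of residue-number vectors (or id vectors);
#'   optimal paths are computed between all region pairs. See
#'   [nbd1_regions()] for the CFTR NBD1 preset.
#' @param diff_threshold `|dC|` mask level used by [compare_runs()].
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed feeds synthetic generation when a
#'   `cdn_synspec` is supplied as the trajectory).
#' @return An object of class `cdn_config`.
#' @export
run_config <- function(trajectory = NULL, correlation = NULL,
                       selection = "calpha", superpose = TRUE,
                       frame_stride = 1L, cutoff = "auto",
                       target_fraction = 0.5, use_abs = TRUE,
                       min_component = 10L, contact_distance = 7.5,
                       min_freq = 0.5, regions = NULL,
                       diff_threshold = 0.2, out_dir = NULL, seed = 1L) {
  if (is.null(trajectory) && is.null(correlation))
    stop_validation("config needs a trajectory or a precomputed correlation")
  if (!identical(cutoff, "auto"))
    check_scalar_number(cutoff, "cutoff", lower = 0, upper = 1)
  check_scalar_number(target_fraction, "target_fraction", 0, 1)
  check_scalar_number(min_freq, "min_freq", 0, 1)
  check_scalar_number(contact_distance, "contact_distance", lower = 1e-12)
  check_scalar_number(min_component, "min_component", lower = 1)
  structure(list(trajectory = trajectory, correlation = correlation,
                 selection = selection, superpose = superpose,
                 frame_stride = frame_stride, cutoff = cutoff,
                 target_fraction = target_fraction, use_abs = use_abs,
                 min_component = as.integer(min_component),
                 contact_distance = contact_distance, min_freq = min_freq,
                 regions = regions, diff_threshold = diff_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "cdn_config")
}

resolve_region <- function(name, members, ids, resno) {
  hit <- if (is.character(members)) ids[ids %in% members]
         else ids[resno %in% members]
  if (length(hit) == 0L)
    stop_validation("region '", name, "' matches no residues in the ",
                    "structure (residues ", min(resno), "-", max(resno), ")")
  hit
}

run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(c(paste("stage:", stage), paste("error:",
                                                 conditionMessage(e))),
                 file.path(out_dir, "FAILED"))
    }
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full coupled-dynamics network pipeline
#'
#' Stages: load -> superpose -> RMSF -> correlation -> contact frequencies
#' -> network (automatic or manual cutoff) -> critical nodes -> optimal
#' paths between all configured region pairs. When `out_dir` is set, all
#' tables (TSV), the graph (edge list + GraphML), a JSON manifest with
#' every parameter and the cutoff scan, and a plain-text summary are
#' written; a stage failure leaves a `FAILED` marker naming the stage next
#' to whatever partial outputs exist.
#'
#' @param config a [run_config()].
#' @return An object of class `cdn_run`: list with `config`, `trajectory`,
#'   `rmsf`, `cmap`, `contacts`, `scan`, `graph`, `critical`, `paths`
#'   (named list per region pair) and `manifest`.
#' @export
run_pipeline <- function(config) {
  od <- config$out_dir
  if (!is.null(od)) dir.create(od, recursive = TRUE, showWarnings = FALSE)

  traj <- run_stage("load", od, {
    tr <- config$trajectory
    if (inherits(tr, "cdn_synspec"))
      tr <- sample_trajectory(tr, seed = config$seed)$trajectory
    else if (is.character(tr))
      tr <- load_trajectory(tr, frame_stride = config$frame_stride)
    tr
  })

  rmsf <- cmap <- contacts <- NULL
  if (!is.null(traj)) {
    sel <- run_stage("select", od,
                     select_atoms(traj, config$selection))
    if (isTRUE(config$superpose)) {
      traj <- run_stage("superpose", od, superpose(traj, sel)$trajectory)
    }
    rmsf <- run_stage("rmsf", od, compute_rmsf(traj, sel))
    cmap <- run_stage("correlation", od, compute_correlation_map(traj, sel))
    contacts <- run_stage("contacts", od, {
      csel <- select_atoms(traj, "cbeta")
      compute_contact_frequency(traj, csel,
                                cutoff = config$contact_distance)
    })
  }
  if (!is.null(config$correlation) && is.null(cmap)) {
    cmap <- run_stage("correlation", od,
                      read_correlation_map(config$correlation))
  }

  scan <- NULL
  cutoff <- config$cutoff
  if (identical(cutoff, "auto")) {
    scan <- run_stage("cutoff", od,
                      select_cutoff(cmap, config$target_fraction,
                                    config$use_abs))
    cutoff <- attr(scan, "selected")
  }
  graph <- run_stage("network", od,
                     build_coupling_graph(cmap, cutoff, config$use_abs))
  critical <- run_stage("critical_nodes", od,
                        find_critical_nodes(graph, config$min_component))

  paths <- NULL
  if (!is.null(config$regions) && !is.null(contacts)) {
    paths <- run_stage("paths", od, {
      regs <- lapply(names(config$regions), function(nm)
        resolve_region(nm, config$regions[[nm]], cmap$ids, cmap$resno))
      names(regs) <- names(config$regions)
      pg <- build_path_graph(cmap, contacts, config$min_freq)
      out <- list()
      nms <- names(regs)
      for (a in seq_along(regs)) for (b in seq_along(regs)) {
        if (a >= b) next
        if (length(intersect(regs[[a]], regs[[b]])) > 0L) next
        q <- path_query(regs[[a]], regs[[b]], config$min_freq,
                        config$contact_distance)
        out[[paste(nms[a], nms[b], sep = "-")]] <- shortest_path(pg, q)
      }
      out
    })
  }

  manifest <- list(
    package = "cdnet",
    version = as.character(utils::packageVersion("cdnet")),
    seed = config$seed,
    parameters = list(
      selection = config$selection,
      superpose = isTRUE(config$superpose),
      frame_stride = config$frame_stride,
      cutoff_mode = if (identical(config$cutoff, "auto")) "auto" else "manual",
      target_fraction = config$target_fraction,
      use_abs = config$use_abs,
      min_component = config$min_component,
      contact_distance = config$contact_distance,
      min_freq = config$min_freq,
      diff_threshold = config$diff_threshold),
    n_residues = length(cmap$ids),
    frames = cmap$frames,
    selected_cutoff = cutoff,
    largest_component_size = length(graph$largest),
    largest_component_fraction = length(graph$largest) / length(cmap$ids),
    critical_nodes = critical$id[critical$is_critical],
    regions = lapply(config$regions, as.integer),
    scan = if (!is.null(scan))
      list(cutoffs = scan$cutoff, fractions = scan$fraction))

  bundle <- structure(list(config = config, trajectory = traj, rmsf = rmsf,
                           cmap = cmap, contacts = contacts, scan = scan,
                           graph = graph, critical = critical, paths = paths,
                           manifest = manifest),
                      class = "cdn_run")
  if (!is.null(od)) run_stage("write", od, write_run(bundle, od))
  bundle
}

write_run <- function(bundle, od) {
  if (!is.null(bundle$rmsf)) write_rmsf(bundle$rmsf, file.path(od, "rmsf.tsv"))
  write_correlation_map(bundle$cmap, file.path(od, "correlation.tsv"))
  if (!is.null(bundle$contacts))
    write_matrix_tsv(bundle$contacts$omega, file.path(od, "contacts.tsv"))
  if (!is.null(bundle$scan))
    write_cutoff_scan(bundle$scan, file.path(od, "cutoff_scan.tsv"))
  write_edge_list(bundle$graph, file.path(od, "network_edges.tsv"))
  write_graphml(bundle$graph, file.path(od, "network.graphml"))
  write_components(bundle$graph, file.path(od, "components.tsv"))
  write_critical_nodes(bundle$critical, file.path(od, "critical_nodes.tsv"))
  if (!is.null(bundle$paths)) {
    for (nm in names(bundle$paths)) {
      write_paths(bundle$paths[[nm]],
                  file.path(od, paste0("paths_", nm, ".tsv")))
      write_path_census(bundle$paths[[nm]],
                        file.path(od, paste0("path_census_", nm, ".tsv")))
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(summary_lines(bundle), file.path(od, "summary.txt"))
  invisible(od)
}

summary_lines <- function(bundle) {
  m <- bundle$manifest
  crit <- m$critical_nodes
  c(paste("cdnet run:", m$n_residues, "residues,", m$frames, "frames"),
    paste("selected cutoff:", signif(m$selected_cutoff, 4),
          "( mode:", m$parameters$cutoff_mode, ")"),
    paste("largest component:", m$largest_component_size, "residues (",
          signif(m$largest_component_fraction, 3), "of total )"),
    if (length(crit) == 0) "critical nodes: none"
    else paste("critical nodes:", paste(crit, collapse = ", ")),
    if (!is.null(bundle$paths))
      paste("path queries:", paste(names(bundle$paths), collapse = ", ")))
}

#' @export
print.cdn_run <- function(x, ...) {
  cat(summary_lines(x), sep = "\n")
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Builds the difference map of the two correlation maps (run B minus run
#' A, e.g. mutant minus wild type), per-residue and per-region RMSF deltas,
#' and the change in critical-node sets.
#'
#' @param run_a,run_b `cdn_run` bundles.
#' @param mapping optional residue pairing (see [compute_difference_map()]);
#'   defaults to pairing by residue id with gaps at deletions.
#' @param out_dir optional directory for TSV + summary output.
#' @return An object of class `cdn_comparison`: list with `diffmap`,
#'   `rmsf_delta` (data.frame, when both runs carry RMSF), `region_delta`,
#'   `critical_changes` (data.frame `id`, `in_a`, `in_b`).
#' @export
compare_runs <- function(run_a, run_b, mapping = NULL, out_dir = NULL) {
  if (is.null(run_a$cmap) || is.null(run_b$cmap))
    stop_validation("both runs must contain correlation maps")
  dm <- compute_difference_map(run_a$cmap, run_b$cmap, mapping,
                               threshold = run_a$config$diff_threshold)
  rmsf_delta <- NULL
  if (!is.null(run_a$rmsf) && !is.null(run_b$rmsf)) {
    paired <- dm$mapping[!is.na(dm$mapping$a) & !is.na(dm$mapping$b), ]
    rmsf_delta <- data.frame(
      id_a = paired$a, id_b = paired$b,
      delta = run_b$rmsf$rmsf[match(paired$b, run_b$rmsf$id)] -
        run_a$rmsf$rmsf[match(paired$a, run_a$rmsf$id)],
      stringsAsFactors = FALSE)
  }
  region_delta <- NULL
  if (!is.null(rmsf_delta) && !is.null(run_a$config$regions)) {
    resno_a <- run_a$cmap$resno[match(rmsf_delta$id_a, run_a$cmap$ids)]
    region_delta <- data.frame(
      region = names(run_a$config$regions),
      mean_delta = vapply(run_a$config$regions, function(rr)
        mean(rmsf_delta$delta[resno_a %in% rr]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  crit_a <- run_a$critical$id[run_a$critical$is_critical]
  crit_b <- run_b$critical$id[run_b$critical$is_critical]
  changed <- sort(union(setdiff(crit_a, crit_b), setdiff(crit_b, crit_a)))
  critical_changes <- data.frame(id = changed,
                                 in_a = changed %in% crit_a,
                                 in_b = changed %in% crit_b,
                                 stringsAsFactors = FALSE)
  out <- structure(list(diffmap = dm, rmsf_delta = rmsf_delta,
                        region_delta = region_delta,
                        critical_changes = critical_changes),
                   class = "cdn_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(dm$delta, file.path(out_dir, "difference_map.tsv"))
    if (!is.null(rmsf_delta))
      write_tsv(rmsf_delta, file.path(out_dir, "rmsf_delta.tsv"))
    if (!is.null(region_delta))
      write_tsv(region_delta, file.path(out_dir, "rmsf_delta_regions.tsv"))
    write_tsv(critical_changes, file.path(out_dir, "critical_changes.tsv"))
    writeLines(c(
      paste("mapped residues:", nrow(dm$delta)),
      paste("unmapped:", paste(c(dm$unmapped_a, dm$unmapped_b),
                               collapse = ", ")),
      paste("lost couplings:", sum(dm$lost[upper.tri(dm$lost)])),
      paste("gained couplings:", sum(dm$gained[upper.tri(dm$gained)])),
      paste("critical-node changes:",
            if (nrow(critical_changes) == 0) "none"
            else paste(critical_changes$id, collapse = ", "))),
      file.path(out_dir, "comparison_summary.txt"))
  }
  out
}

#' @export
print.cdn_comparison <- function(x, ...) {
  cat("Run comparison over", nrow(x$diffmap$delta), "mapped residues\n")
  cat("  lost couplings:", sum(x$diffmap$lost[upper.tri(x$diffmap$lost)]),
      " gained:", sum(x$diffmap$gained[upper.tri(x$diffmap$gained)]), "\n")
  cat("  critical-node changes:",
      if (nrow(x$critical_changes) == 0) "none"
      else paste(x$critical_changes$id, collapse = ", "), "\n")
  invisible(x)
}
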