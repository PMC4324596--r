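# Difference maps between two correlation maps (e.g. mutant minus wild type).

#' Pair residues of two correlation maps by residue number
#'
#' Default pairing for deletion mutants: residues present in both maps (same
#' chain and residue number) are paired; positions listed in `deleted_a` /
#' `deleted_b` (or simply absent from the other map) become gaps.
#'
#' @param map_a,map_b correlation maps ([compute_correlation_map()]).
#' @param deleted_a,deleted_b residue ids to force as gaps on either side.
#' @return data.frame with columns `a` and `b` (residue ids, `NA` for gaps),
#'   one row per residue of either map.
#' @export
pair_residues <- function(map_a, map_b, deleted_a = character(),
                          deleted_b = character()) {
  a_ids <- setdiff(map_a$ids, deleted_a)
  b_ids <- setdiff(map_b$ids, deleted_b)
  common <- intersect(a_ids, b_ids)
  rows <- data.frame(a = map_a$ids,
                     b = ifelse(map_a$ids %in% common, map_a$ids, NA),
                     stringsAsFactors = FALSE)
  only_b <- setdiff(map_b$ids, common)
  if (length(only_b) > 0L)
    rows <- rbind(rows, data.frame(a = NA, b = only_b))
  rows
}

#' Difference of two correlation maps
#'
#' `dC = C_b - C_a` over mapped residue pairs, with lost-coupling
#' (`dC < -threshold`) and gained-coupling (`dC > threshold`) masks.
#' Conventionally `map_a` is the wild type and `map_b` the mutant, so "lost"
#' means coupling present in the wild type and absent in the mutant.
#' Unmapped residues (deletion gaps) are reported, never silently dropped.
#'
#' @param map_a,map_b correlation maps.
#' @param mapping data.frame with columns `a`, `b` (residue ids, `NA` = gap);
#'   defaults to [pair_residues()] on the two maps.
#' @param threshold mask level on `|dC|` (default 0.2).
#' @return An object of class `cdn_diffmap`: list with `delta` (matrix over
#'   mapped residues, named by the `map_a` ids), `lost`, `gained` (logical
#'   masks), `mapping`, `unmapped_a`, `unmapped_b`, `threshold`.
#' @export
compute_difference_map <- function(map_a, map_b, mapping = NULL,
                                   threshold = 0.2) {
  check_scalar_number(threshold, "threshold", lower = 0)
  if (is.null(mapping)) mapping <- pair_residues(map_a, map_b)
  if (!all(c("a", "b") %in% names(mapping)))
    stop_validation("mapping must have columns 'a' and 'b'")
  bad_a <- setdiff(mapping$a[!is.na(mapping$a)], map_a$ids)
  bad_b <- setdiff(mapping$b[!is.na(mapping$b)], map_b$ids)
  if (length(bad_a) > 0L)
    stop_validation("mapping references residues unknown to map A: ",
                    paste(bad_a, collapse = ", "))
  if (length(bad_b) > 0L)
    stop_validation("mapping references residues unknown to map B: ",
                    paste(bad_b, collapse = ", "))
  paired <- mapping[!is.na(mapping$a) & !is.na(mapping$b), , drop = FALSE]
  if (nrow(paired) < 2L)
    stop_validation("mapping pairs fewer than 2 residues")
  delta <- map_b$C[paired$b, paired$b] - map_a$C[paired$a, paired$a]
  dimnames(delta) <- list(paired$a, paired$a)
  structure(list(delta = delta,
                 lost = !is.na(delta) & delta < -threshold,
                 gained = !is.na(delta) & delta > threshold,
                 mapping = mapping,
                 unmapped_a = mapping$a[!is.na(mapping$a) & is.na(mapping$b)],
                 unmapped_b = mapping$b[is.na(mapping$a) & !is.na(mapping$b)],
                 threshold = threshold),
            class = "cdn_diffmap")
}

#' @export
print.cdn_diffmap <- function(x, ...) {
  n <- nrow(x$delta)
  cat("Difference map over", n, "mapped residues; |dC| threshold",
      x$threshold, "\n")
  cat("  lost couplings:", sum(x$lost[upper.tri(x$lost)]),
      " gained:", sum(x$gained[upper.tri(x$gained)]), "\n")
  if (length(x$unmapped_a) + length(x$unmapped_b) > 0L)
    cat("  unmapped:",
        paste(c(x$unmapped_a, x$unmapped_b), collapse = ", "), "\n")
  invisible(x)
}
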