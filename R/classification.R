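# Product-outcome classification of surviving poses and the report tallies:
# which olefin would be formed by deprotonation (from realized geometry, not
# from the generating hypothesis), where the docked water sits relative to
# the pyrophosphate oxygens, and which C13 epimer a water attack would give.

#' Classify a pose by the olefin product its geometry implies
#'
#' Geometric rule: among the abstractable (alpha) hydrogens, those with
#' O(base)...H <= `dist_gate` and C-H...O angle >= `angle_gate` are
#' candidates; the candidate nearest the base hydroxyl oxygen wins and maps
#' to its olefin product. With no candidate the pose is "unassigned". The
#' gate is deliberately looser than the docking restraint flat bottom so that
#' near-miss poses are still attributed.
#'
#' @param pose a pose; @param receptor a `receptor` with a base hydroxyl;
#' @param lib the pose's `conformer_library`;
#' @param g the carbocation [cation_graph];
#' @param sites,products precomputed enumerations (defaults recomputed).
#' @param dist_gate Angstrom (default 2.8); @param angle_gate degrees (100).
#' @return product id string, or "unassigned".
#' @export
classify_pose <- function(pose, receptor, lib, g,
                          sites = enumerate_deprotonation_sites(g),
                          products = enumerate_olefin_products(g, sites),
                          dist_gate = 2.8, angle_gate = 100) {
  if (is.na(receptor$sites$base_o)) return("unassigned")
  lig <- pose_ligand_coords(pose, lib)
  bo <- receptor_site_xyz(receptor, "base:O")
  best <- NULL; best_d <- Inf
  for (s in seq_len(nrow(sites))) {
    h <- lig[sites$hydrogen_name[s], ]
    cc <- lig[sites$carbon_name[s], ]
    d <- vnorm(h - bo)
    if (d > dist_gate) next
    ang <- acos(max(-1, min(1, sum(unitv(cc - h) * unitv(bo - h))))) * 180 / pi
    if (ang < angle_gate) next
    if (d < best_d) { best_d <- d; best <- products$product_id[s] }
  }
  if (is.null(best)) "unassigned" else best
}

#' Classify the docked water position relative to the pyrophosphate oxygens
#'
#' Returns the label class of the nearest labeled oxygen ("bridging" for OB,
#' "terminal" for OT*) within `cutoff`, else "none".
#'
#' @param pose a pose carrying a water; @param receptor a `receptor` with a
#'   placed cofactor cluster; @param cutoff Angstrom (default 3.5).
#' @export
classify_water_location <- function(pose, receptor, cutoff = 3.5) {
  if (is.null(pose$water)) stop("pose carries no water")
  if (is.null(receptor$pp)) stop("cofactor cluster not placed")
  ox <- receptor$pp[grepl("^O", rownames(receptor$pp)), , drop = FALSE]
  d <- sqrt(rowSums(sweep(ox, 2, pose$water)^2))
  i <- which.min(d)
  if (d[i] > cutoff) return("none")
  if (rownames(ox)[i] == "OB") "bridging" else "terminal"
}

#' Classify the C13 epimer implied by a water-carrying pose of species B
#'
#' The prochiral face of C13 occupied by the water oxygen maps to the
#' abietaenol epimer: alpha -> "6a", beta -> "6b".
#'
#' @param pose a pose with water; @param lib its `conformer_library`.
#' @export
classify_epimer <- function(pose, lib) {
  if (is.null(pose$water)) stop("pose carries no water")
  lig <- pose_ligand_coords(pose, lib)
  assign_addition_face(lig, center = "C13", ref = c("C12", "C14", "C15"),
                       probe = pose$water)$epimer
}

#' Tally classified outcomes into a report
#'
#' @param labels character vector of product labels (one per pose).
#' @param group optional grouping vector (e.g. per-set water mode).
#' @return object of class `outcome_report`: counts per product, denominator,
#'   "k/n" renderings, majority product (if any strict majority exists).
#' @export
tally_outcomes <- function(labels, group = NULL) {
  n <- length(labels)
  cnt <- if (n) table(labels) else table(character(0))
  counts <- as.list(as.integer(cnt)); names(counts) <- names(cnt)
  rendered <- if (n) setNames(sprintf("%d/%d", as.integer(cnt), n), names(cnt))
              else character(0)
  majority <- NA_character_
  if (n && max(cnt) > n / 2) majority <- names(cnt)[which.max(cnt)]
  by_group <- NULL
  if (!is.null(group) && n) {
    by_group <- lapply(split(labels, group), function(l) tally_outcomes(l))
  }
  structure(list(counts = counts, denominator = n, rendered = rendered,
                 majority = majority, by_group = by_group),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome_report> n = %d\n", x$denominator))
  for (k in names(x$counts))
    cat(sprintf("  %-12s %s%s\n", k, x$rendered[[k]],
                if (identical(x$majority, k)) "  (majority)" else ""))
  invisible(x)
}

#' Serialise an outcome report to JSON / TSV
#' @param report an `outcome_report`; @param file path.
#' @export
write_report_json <- function(report, file) {
  jsonlite::write_json(unclass_report(report), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

unclass_report <- function(r) {
  out <- list(counts = r$counts, denominator = r$denominator,
              rendered = as.list(r$rendered), majority = r$majority)
  if (!is.null(r$by_group)) out$by_group <- lapply(r$by_group, unclass_report)
  out
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, file) {
  df <- data.frame(product = names(report$counts),
                   count = unlist(report$counts),
                   rendered = unname(report$rendered))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
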