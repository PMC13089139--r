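# Flat-bottom geometric restraints and the constraint sets that encode each
# mechanistic hypothesis: catalytic-base deprotonation at one of the alpha
# C-H sites, pyrophosphate anchoring of the vinyl methylene, reactant-water
# approach to one prochiral face of C13, and the wild-type C7-residue-723
# proximity check.

#' Construct a flat-bottom restraint
#'
#' Penalty is 0 for measured values inside `[lower, upper]` and
#' `((x - nearest_edge)/sd)^2 * weight` outside, so a violation of exactly one
#' softness unit `sd` beyond the flat bottom scores `weight`. Distances in
#' Angstrom, angles in degrees.
#'
#' @param kind "distance" (2 members), "angle" (3 members, vertex second) or
#'   "face" (face-approach: members are the trigonal center and the probe;
#'   the measured value is the angle in degrees between the signed face normal
#'   and the center-to-probe vector).
#' @param members list of selectors, each `list(body=, atom=)` with body one of
#'   "receptor", "carbocation", "water", "pp_mg".
#' @param lower,upper flat-bottom bounds; @param sd softness (> 0);
#' @param weight dimensionless multiplier.
#' @param face for `kind = "face"`: `"alpha"` or `"beta"`, selecting the sign
#'   of the reference normal at the trigonal center.
#' @param ref for `kind = "face"`: ordered substituent atom names defining the
#'   plane normal (default `c("C12","C14","C15")`).
#' @export
flat_bottom_restraint <- function(kind, members, lower, upper, sd, weight = 1,
                                  face = NULL, ref = c("C12", "C14", "C15")) {
  stopifnot(kind %in% c("distance", "angle", "face"), lower <= upper, sd > 0)
  nmem <- c(distance = 2L, angle = 3L, face = 2L)[[kind]]
  stopifnot(length(members) == nmem)
  structure(list(kind = kind, members = members, lower = lower, upper = upper,
                 sd = sd, weight = weight, face = face, ref = ref),
            class = "flat_bottom_restraint")
}

sel <- function(body, atom) list(body = body, atom = atom)

#' Flat-bottom penalty for a measured value
#' @param restraint a [flat_bottom_restraint]; @param x measured value.
#' @export
restraint_penalty <- function(restraint, x) {
  edge <- if (x < restraint$lower) restraint$lower
          else if (x > restraint$upper) restraint$upper
          else return(0)
  ((x - edge) / restraint$sd)^2 * restraint$weight
}

# Measure a restraint given a coordinate lookup: function(body, atom) -> xyz.
measure_restraint <- function(r, lookup) {
  p <- lapply(r$members, function(m) lookup(m$body, m$atom))
  if (r$kind == "distance") return(vnorm(p[[1]] - p[[2]]))
  if (r$kind == "angle") {
    v1 <- unitv(p[[1]] - p[[2]]); v2 <- unitv(p[[3]] - p[[2]])
    return(acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi)
  }
  # face: signed normal at the trigonal center from the ordered reference
  # substituents; measured value = angle(normal_signed, center -> probe).
  sref <- lapply(r$ref, function(a) lookup(r$members[[1]]$body, a))
  nrm <- pracma_cross(sref[[2]] - sref[[1]], sref[[3]] - sref[[1]])
  if (identical(r$face, "beta")) nrm <- -nrm
  v <- p[[2]] - p[[1]]
  acos(max(-1, min(1, sum(unitv(nrm) * unitv(v))))) * 180 / pi
}

#' Construct a constraint set
#'
#' @param set_id unique identifier; @param restraints list of
#'   [flat_bottom_restraint]; @param product_hypothesis product id or `NA`;
#' @param anchor which pyrophosphate terminal oxygen anchors the ligand;
#' @param water_mode one of "none", "reactive_6a", "reactive_6b",
#'   "loose_6a", "loose_6b".
#' @export
constraint_set <- function(set_id, restraints, product_hypothesis = NA_character_,
                           anchor = NA_character_, water_mode = "none") {
  stopifnot(water_mode %in% c("none", "reactive_6a", "reactive_6b",
                              "loose_6a", "loose_6b"))
  structure(list(set_id = set_id, restraints = restraints,
                 product_hypothesis = product_hypothesis, anchor = anchor,
                 water_mode = water_mode),
            class = "constraint_set")
}

# Default restraint parameters (Angstrom / degrees): proton-transfer /
# hydrogen-bond geometry norms, all overridable through the params arguments
# of the builders.
cst_defaults <- function() {
  list(oh_lo = 1.6, oh_hi = 2.6, oh_sd = 0.3,
       ang_lo = 120, ang_hi = 180, ang_sd = 20,
       anchor_lo = 2.5, anchor_hi = 4.5, anchor_sd = 0.5,
       wat_lo = 2.6, wat_hi = 3.4, wat_loose_hi = 5.0, wat_sd = 0.4,
       face_lo = 0, face_hi = 35, face_sd = 10,
       mech_lo = 3.5, mech_hi = 5.5, mech_sd = 0.5)
}

#' Build the deprotonation-scan constraint sets
#'
#' One set per (deprotonation site x pyrophosphate anchor): an O(base)...H
#' distance restraint, a C-H...O approach-angle restraint, and a vinyl
#' methylene (C16)...anchor distance restraint. For the five alpha protons of
#' the isopimarenyl cation and two anchors this yields the ten-set scan.
#'
#' @param g the carbocation [cation_graph].
#' @param sites [enumerate_deprotonation_sites] output (or subset).
#' @param base_o,base_h receptor atom keys of the catalytic hydroxyl
#'   (defaults `"base:O"`, `"base:H"`).
#' @param anchors character vector of pp_mg terminal-oxygen atom names
#'   (default `c("OT1","OT2")`).
#' @param anchor_atom ligand atom constrained to the anchor (default "C16",
#'   the vinyl methylene of species A and its descendant atom in B).
#' @param params optional list overriding [cst_defaults] entries.
#' @return list of [constraint_set], length `nrow(sites) * length(anchors)`.
#' @export
build_deprotonation_sets <- function(g, sites = enumerate_deprotonation_sites(g),
                                     base_o = "base:O", base_h = "base:H",
                                     anchors = c("OT1", "OT2"),
                                     anchor_atom = "C16", params = list()) {
  if (!nrow(sites)) stop("no deprotonation sites supplied")
  p <- utils::modifyList(cst_defaults(), params)
  prods <- enumerate_olefin_products(g, sites)
  out <- list()
  for (s in seq_len(nrow(sites))) {
    cn <- sites$carbon_name[s]; hn <- sites$hydrogen_name[s]
    for (an in anchors) {
      rs <- list(
        flat_bottom_restraint("distance",
                              list(sel("receptor", base_o), sel("carbocation", hn)),
                              p$oh_lo, p$oh_hi, p$oh_sd),
        flat_bottom_restraint("angle",
                              list(sel("carbocation", cn), sel("carbocation", hn),
                                   sel("receptor", base_o)),
                              p$ang_lo, p$ang_hi, p$ang_sd),
        flat_bottom_restraint("distance",
                              list(sel("carbocation", anchor_atom), sel("pp_mg", an)),
                              p$anchor_lo, p$anchor_hi, p$anchor_sd))
      out[[length(out) + 1L]] <- constraint_set(
        set_id = sprintf("depro_%s_%s_anchor%s", cn, hn, an),
        restraints = rs,
        product_hypothesis = prods$product_id[s],
        anchor = an)
    }
  }
  out
}

#' Build reactant-water restraints for one abietaenol epimer
#'
#' Reactive mode (species B, water attacks C13): O(water)...C13 distance in
#' \[2.6, 3.4\] Angstrom plus a face-approach angle <= 35 degrees measured from
#' the epimer's signed face normal at C13. Loose mode (species A, water
#' present but non-reactive): the upper distance bound is raised to 5.0
#' Angstrom, same face restraint.
#'
#' @param epimer "6a" (alpha face) or "6b" (beta face).
#' @param reactive logical; `FALSE` gives the loosened variant.
#' @param params optional list overriding [cst_defaults] entries.
#' @return list of two [flat_bottom_restraint].
#' @export
build_water_constraints <- function(epimer, reactive = TRUE, params = list()) {
  stopifnot(epimer %in% c("6a", "6b"))
  p <- utils::modifyList(cst_defaults(), params)
  face <- if (epimer == "6a") "alpha" else "beta"
  hi <- if (reactive) p$wat_hi else p$wat_loose_hi
  list(
    flat_bottom_restraint("distance",
                          list(sel("water", "O"), sel("carbocation", "C13")),
                          p$wat_lo, hi, p$wat_sd),
    flat_bottom_restraint("face",
                          list(sel("carbocation", "C13"), sel("water", "O")),
                          p$face_lo, p$face_hi, p$face_sd, face = face))
}

#' Build the wild-type mechanism-check restraint (C7 near residue 723)
#'
#' A single distance restraint between ligand C7 and the side-chain tip of
#' residue 723, bounds \[3.5, 5.5\] Angstrom: tests whether poses consistent
#' with the native reaction keep C7 close enough for the introduced hydroxyl
#' of the 723 variants to reach it.
#'
#' @param species "A" or "B" (same atom pair and bounds for both).
#' @param params optional list overriding [cst_defaults] entries.
#' @export
build_wt_mechanism_constraints <- function(species = "A", params = list()) {
  stopifnot(species %in% c("A", "B"))
  p <- utils::modifyList(cst_defaults(), params)
  list(flat_bottom_restraint("distance",
                             list(sel("carbocation", "C7"), sel("receptor", "723:tip")),
                             p$mech_lo, p$mech_hi, p$mech_sd))
}

#' Attach water restraints to existing constraint sets
#'
#' Appends the epimer's water restraints to every set and stamps the
#' corresponding `water_mode`.
#' @param sets list of [constraint_set]; @param epimer "6a"/"6b";
#' @param reactive logical; @param params see [cst_defaults].
#' @export
add_water_to_sets <- function(sets, epimer, reactive = FALSE, params = list()) {
  wr <- build_water_constraints(epimer, reactive, params)
  mode <- paste0(if (reactive) "reactive_" else "loose_", epimer)
  lapply(sets, function(cs) {
    constraint_set(paste0(cs$set_id, "_water", epimer),
                   c(cs$restraints, wr), cs$product_hypothesis, cs$anchor, mode)
  })
}

#' Per-ligand constraint score of a pose geometry
#'
#' For each ligand body, sums the penalties of all restraints whose member
#' set includes that body. A pose satisfies the set when every per-ligand
#' score is strictly below one.
#'
#' @param lookup coordinate lookup `function(body, atom) -> xyz` for the pose.
#' @param cset a [constraint_set].
#' @param bodies ligand bodies to score (default the non-receptor bodies
#'   appearing in the set).
#' @return named numeric vector of per-ligand scores.
#' @export
ligand_constraint_score <- function(lookup, cset, bodies = NULL) {
  rb <- lapply(cset$restraints, function(r)
    unique(vapply(r$members, `[[`, "", "body")))
  if (is.null(bodies)) {
    bodies <- setdiff(unique(unlist(rb)), "receptor")
  }
  pen <- vapply(cset$restraints, function(r)
    restraint_penalty(r, measure_restraint(r, lookup)), numeric(1))
  out <- vapply(bodies, function(b)
    sum(pen[vapply(rb, function(x) b %in% x, logical(1))]), numeric(1))
  setNames(out, bodies)
}

# ---- text / JSON round-trip -------------------------------------------------

restraint_to_line <- function(r) {
  mem <- paste(vapply(r$members, function(m) paste0(m$body, ":", m$atom), ""),
               collapse = " ")
  extra <- if (r$kind == "face") paste0(" face=", r$face, " ref=",
                                        paste(r$ref, collapse = ",")) else ""
  sprintf("%s %s %.6g %.6g %.6g %.6g%s", r$kind, mem, r$lower, r$upper,
          r$sd, r$weight, extra)
}

line_to_restraint <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  kind <- f[1]
  nmem <- c(distance = 2L, angle = 3L, face = 2L)[[kind]]
  members <- lapply(f[2:(1 + nmem)], function(s) {
    p <- strsplit(s, ":", fixed = TRUE)[[1]]
    sel(p[1], paste(p[-1], collapse = ":"))
  })
  nums <- as.numeric(f[(2 + nmem):(5 + nmem)])
  face <- NULL; ref <- c("C12", "C14", "C15")
  rest <- f[-seq_len(5 + nmem)]
  for (tok in rest) {
    if (startsWith(tok, "face=")) face <- sub("^face=", "", tok)
    if (startsWith(tok, "ref=")) ref <- strsplit(sub("^ref=", "", tok), ",")[[1]]
  }
  flat_bottom_restraint(kind, members, nums[1], nums[2], nums[3], nums[4],
                        face = face, ref = ref)
}

#' Write / read constraint sets in a line-oriented text format
#'
#' One header line per set (`set <id> <product> <anchor> <water_mode>`)
#' followed by one restraint per line
#' (`kind body:atom... lower upper sd weight`). Round-trips exactly.
#' @param sets list of [constraint_set]; @param file path.
#' @export
write_constraints <- function(sets, file) {
  lines <- unlist(lapply(sets, function(cs) {
    c(sprintf("set %s %s %s %s", cs$set_id,
              ifelse(is.na(cs$product_hypothesis), ".", cs$product_hypothesis),
              ifelse(is.na(cs$anchor), ".", cs$anchor), cs$water_mode),
      vapply(cs$restraints, restraint_to_line, ""))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(file) {
  lines <- readLines(file)
  out <- list(); cur <- NULL
  flush <- function() if (!is.null(cur)) out[[length(out) + 1L]] <<- do.call(constraint_set, cur)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "set ")) {
      flush()
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(set_id = f[2],
                  restraints = list(),
                  product_hypothesis = if (f[3] == ".") NA_character_ else f[3],
                  anchor = if (f[4] == ".") NA_character_ else f[4],
                  water_mode = f[5])
    } else {
      cur$restraints[[length(cur$restraints) + 1L]] <- line_to_restraint(ln)
    }
  }
  flush()
  out
}

#' Emit the constraint sets of a named experiment
#'
#' Recipes: `"a723t_depro_scan"` (ten deprotonation sets for species A),
#' `"wt_water_6a"` / `"wt_water_6b"` (anchor-only sets plus reactive water),
#' `"wt_mechanism"` (anchor sets plus water plus the C7-723 restraint).
#' @param experiment recipe name; @param species ligand species key;
#' @param params see [cst_defaults].
#' @export
experiment_constraint_sets <- function(experiment, species = NULL, params = list()) {
  p <- params
  switch(experiment,
    a723t_depro_scan = {
      g <- load_species(if (is.null(species)) "A" else species)
      build_deprotonation_sets(g, params = p)
    },
    wt_water_6a = wt_water_sets("6a", if (is.null(species)) "B" else species, p),
    wt_water_6b = wt_water_sets("6b", if (is.null(species)) "B" else species, p),
    wt_mechanism = {
      sp <- if (is.null(species)) "A" else species
      sets <- wt_water_sets("6a", sp, p)
      mech <- build_wt_mechanism_constraints(sp, p)
      lapply(sets, function(cs)
        constraint_set(paste0(cs$set_id, "_mech"), c(cs$restraints, mech),
                       cs$product_hypothesis, cs$anchor, cs$water_mode))
    },
    stop("unknown experiment recipe: ", experiment))
}

wt_water_sets <- function(epimer, species, params = list()) {
  p <- utils::modifyList(cst_defaults(), params)
  reactive <- identical(species, "B")
  wr <- build_water_constraints(epimer, reactive, params)
  lapply(c("OT1", "OT2"), function(an) {
    anc <- flat_bottom_restraint("distance",
                                 list(sel("carbocation", "C16"), sel("pp_mg", an)),
                                 p$anchor_lo, p$anchor_hi, p$anchor_sd)
    constraint_set(sprintf("wt_%s_%s_anchor%s", species, epimer, an),
                   c(list(anc), wr),
                   product_hypothesis = if (reactive) epimer else NA_character_,
                   anchor = an,
                   water_mode = paste0(if (reactive) "reactive_" else "loose_", epimer))
  })
}
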