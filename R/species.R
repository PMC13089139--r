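#' @importFrom stats optim rnorm runif setNames
#' @importFrom utils head tail write.table read.table
NULL

# ---- cation_graph construction ---------------------------------------------

#' Construct a molecular graph for a (carbo)cationic or neutral species
#'
#' A `cation_graph` is the package's central ligand representation: an explicit
#' atom table (all hydrogens present), a bond table with integer orders, and an
#' optional designated cationic carbon. Deprotonation-site enumeration and
#' product mapping operate on this graph; geometry lives in conformers.
#'
#' @param atoms data.frame with columns `id` (1-based integer), `element`
#'   (e.g. "C", "H", "O", "P", "MG") and `name` (unique atom name, e.g. "C7").
#' @param bonds data.frame with columns `i`, `j` (atom ids) and `order`
#'   (integer bond order).
#' @param cation_center atom id of the trivalent cationic carbon, or `NA` for
#'   neutral species.
#' @param label species identifier (e.g. "A", "B", "water", "pp_mg").
#' @return object of class `cation_graph`.
#' @export
cation_graph <- function(atoms, bonds, cation_center = NA_integer_, label = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  atoms <- data.frame(id = as.integer(atoms$id), element = as.character(atoms$element),
                      name = as.character(atoms$name), stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$id)) stop("duplicate atom ids")
  if (anyDuplicated(atoms$name)) stop("duplicate atom names")
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (!all(c(bonds$i, bonds$j) %in% atoms$id)) stop("bond references unknown atom id")
  g <- structure(list(atoms = atoms, bonds = bonds,
                      cation_center = as.integer(cation_center), label = label),
                 class = "cation_graph")
  validate_cation_graph(g)
  g
}

#' @export
print.cation_graph <- function(x, ...) {
  cat(sprintf("<cation_graph '%s'> %d atoms (%d H), %d bonds", x$label,
              nrow(x$atoms), sum(x$atoms$element == "H"), nrow(x$bonds)))
  if (!is.na(x$cation_center))
    cat(sprintf(", cation center %s", atom_name(x, x$cation_center)))
  cat("\n")
  invisible(x)
}

validate_cation_graph <- function(g) {
  if (nrow(g$atoms) > 1L) {
    ig <- graph_as_igraph(g)
    if (!igraph::is_connected(ig)) stop(sprintf("species '%s': disconnected graph", g$label))
  }
  # every hydrogen has exactly one bond
  h_ids <- g$atoms$id[g$atoms$element == "H"]
  if (length(h_ids)) {
    deg <- vapply(h_ids, function(a) sum(g$bonds$i == a | g$bonds$j == a), integer(1))
    if (any(deg != 1L)) stop(sprintf("species '%s': hydrogen with bond count != 1", g$label))
  }
  if (!is.na(g$cation_center)) {
    cc <- g$cation_center
    if (g$atoms$element[match(cc, g$atoms$id)] != "C")
      stop(sprintf("species '%s': cation center is not carbon", g$label))
    vs <- sum(g$bonds$order[g$bonds$i == cc | g$bonds$j == cc])
    if (vs != 3L)
      stop(sprintf("species '%s': cation center valence %d != 3", g$label, vs))
  }
  invisible(g)
}

graph_as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = data.frame(from = g$bonds$i, to = g$bonds$j),
    directed = FALSE,
    vertices = data.frame(name = g$atoms$id))
}

atom_id <- function(g, name) {
  i <- match(name, g$atoms$name)
  if (any(is.na(i))) stop(sprintf("species '%s': no atom named %s", g$label,
                                  paste(name[is.na(i)], collapse = ", ")))
  g$atoms$id[i]
}

atom_name <- function(g, id) g$atoms$name[match(id, g$atoms$id)]

neighbors_of <- function(g, id) {
  c(g$bonds$j[g$bonds$i == id], g$bonds$i[g$bonds$j == id])
}

# Build atoms/bonds from a heavy-atom skeleton plus per-carbon hydrogen counts.
# heavy: data.frame(name, element); hbonds: matrix-like list of c(name_i, name_j, order)
assemble_species <- function(heavy, hbonds, h_counts, cation_center_name, label) {
  atoms <- data.frame(id = seq_len(nrow(heavy)), element = heavy$element,
                      name = heavy$name, stringsAsFactors = FALSE)
  bonds <- data.frame(
    i = atoms$id[match(vapply(hbonds, `[[`, "", 1L), atoms$name)],
    j = atoms$id[match(vapply(hbonds, `[[`, "", 2L), atoms$name)],
    order = as.integer(vapply(hbonds, `[[`, "", 3L)))
  nid <- nrow(atoms)
  for (cn in names(h_counts)) {
    nh <- h_counts[[cn]]
    if (nh == 0) next
    ci <- atoms$id[match(cn, atoms$name)]
    num <- sub("^[A-Za-z]+", "", cn)
    for (k in seq_len(nh)) {
      nid <- nid + 1L
      hname <- if (nh == 1L) paste0("H", num) else paste0("H", num, letters[k])
      atoms <- rbind(atoms, data.frame(id = nid, element = "H", name = hname))
      bonds <- rbind(bonds, data.frame(i = ci, j = nid, order = 1L))
    }
  }
  cc <- if (is.na(cation_center_name)) NA_integer_ else atoms$id[match(cation_center_name, atoms$name)]
  cation_graph(atoms, bonds, cc, label)
}

# Tricyclic diterpene skeleton shared by the pimarane/abietane cations:
# rings A (C1-C2-C3-C4-C5-C10), B (C5-C6-C7-C8-C9-C10), C (C8-C9-C11-C12-C13-C14),
# gem-dimethyl C18/C19 on C4, angular methyl C20 on C10.
diterpene_core_bonds <- function() {
  list(c("C1","C2","1"), c("C2","C3","1"), c("C3","C4","1"), c("C4","C5","1"),
       c("C5","C10","1"), c("C10","C1","1"),
       c("C5","C6","1"), c("C6","C7","1"), c("C7","C8","1"), c("C8","C9","1"),
       c("C9","C10","1"),
       c("C14","C13","1"), c("C13","C12","1"), c("C12","C11","1"), c("C11","C9","1"),
       c("C4","C18","1"), c("C4","C19","1"), c("C10","C20","1"))
}

species_A <- function() {
  # isopimara-15-en-8-yl cation: C8+ flanked by C7 (2H), C9 (1H), C14 (2H);
  # C13 quaternary bearing the C17 methyl and the C15=C16 vinyl.
  heavy <- data.frame(name = c(paste0("C", 1:20)), element = "C")
  hb <- c(diterpene_core_bonds(),
          list(c("C8","C14","1"), c("C13","C17","1"), c("C13","C15","1"),
               c("C15","C16","2")))
  hc <- c(C1 = 2, C2 = 2, C3 = 2, C4 = 0, C5 = 1, C6 = 2, C7 = 2, C8 = 0,
          C9 = 1, C10 = 0, C11 = 2, C12 = 2, C13 = 0, C14 = 2, C15 = 1,
          C16 = 2, C17 = 3, C18 = 3, C19 = 3, C20 = 3)
  assemble_species(heavy, hb, as.list(hc), "C8", "A")
}

species_B <- function() {
  # abieta-8(14)-en-13-yl cation: C13+ flanked by C12 (2H), C14 (1H, vinylic)
  # and C15 (1H, isopropyl methine carrying the C16/C17 methyls); C8=C14 olefin.
  heavy <- data.frame(name = c(paste0("C", 1:20)), element = "C")
  hb <- c(diterpene_core_bonds(),
          list(c("C8","C14","2"), c("C13","C15","1"), c("C15","C16","1"),
               c("C15","C17","1")))
  hc <- c(C1 = 2, C2 = 2, C3 = 2, C4 = 0, C5 = 1, C6 = 2, C7 = 2, C8 = 0,
          C9 = 1, C10 = 0, C11 = 2, C12 = 2, C13 = 0, C14 = 1, C15 = 1,
          C16 = 3, C17 = 3, C18 = 3, C19 = 3, C20 = 3)
  assemble_species(heavy, hb, as.list(hc), "C13", "B")
}

species_water <- function() {
  cation_graph(
    atoms = data.frame(id = 1:3, element = c("O", "H", "H"),
                       name = c("O", "H1", "H2")),
    bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L), order = c(1L, 1L)),
    cation_center = NA_integer_, label = "water")
}

# Rigid 7-point pyrophosphate-magnesium cluster: bridging oxygen OB (the former
# ester oxygen), two phosphorus atoms, terminal oxygens OT1 (distal on P1) and
# OT2/OT3 (on P2), one magnesium. OT1/OT2 are the maximally separated terminal
# pair used as the two docking anchors ("either end" of the co-product).
species_pp_mg <- function() {
  cation_graph(
    atoms = data.frame(id = 1:7,
                       element = c("O", "P", "P", "O", "O", "O", "MG"),
                       name = c("OB", "P1", "P2", "OT1", "OT2", "OT3", "MG")),
    bonds = data.frame(i = c(1L, 1L, 2L, 3L, 3L, 7L),
                       j = c(2L, 3L, 4L, 5L, 6L, 6L),
                       order = c(1L, 1L, 1L, 1L, 1L, 1L)),
    cation_center = NA_integer_, label = "pp_mg")
}

# Reference coordinates (Angstrom) for the rigid cofactor species.
pp_mg_coords <- function() {
  # P-O 1.60, P-OB-P 130 deg; terminal oxygens splayed outward.
  a <- 130 * pi / 180
  p1 <- c(1.60, 0, 0)
  p2 <- 1.60 * c(cos(a), sin(a), 0)
  rbind(OB  = c(0, 0, 0),
        P1  = p1,
        P2  = p2,
        OT1 = p1 + c(1.45, 0.6, 0.4),
        OT2 = p2 + 1.55 * c(cos(a), sin(a), 0) + c(0, 0, 0.3),
        OT3 = p2 + c(0.3, 0.9, -1.2),
        MG  = p2 + c(0.9, 1.8, -1.6))
}

water_coords <- function() {
  rbind(O = c(0, 0, 0), H1 = c(0.9572, 0, 0),
        H2 = 0.9572 * c(cos(104.52 * pi / 180), sin(104.52 * pi / 180), 0))
}

# ---- load_species -----------------------------------------------------------

#' Load a built-in reaction species or a ligand file
#'
#' Built-in species: `"A"` (isopimara-15-en-8-yl cation, cation center C8),
#' `"B"` (abieta-8(14)-en-13-yl cation, cation center C13), `"water"`, and
#' `"pp_mg"` (rigid pyrophosphate--magnesium cluster with labeled bridging and
#' terminal oxygens). Files ending in `.sdf` or `.xyz` are parsed instead; the
#' cation center of an SDF species is taken from its `M  CHG` +1 entry.
#'
#' @param name_or_file species key or path to an SDF/XYZ file.
#' @param add_hydrogens if `TRUE` and a file-read graph has no hydrogens, a
#'   chemistry-free valence fill is NOT attempted; an error is raised instead
#'   (explicit hydrogens are required for deprotonation enumeration).
#' @return a [cation_graph].
#' @export
load_species <- function(name_or_file, add_hydrogens = FALSE) {
  builtin <- c("A", "B", "water", "pp_mg")
  if (name_or_file %in% builtin) {
    return(switch(name_or_file,
                  A = species_A(), B = species_B(),
                  water = species_water(), pp_mg = species_pp_mg()))
  }
  if (file.exists(name_or_file)) {
    ext <- tolower(tools::file_ext(name_or_file))
    g <- switch(ext,
                sdf = read_sdf(name_or_file),
                xyz = read_xyz(name_or_file),
                stop("unsupported ligand file type: ", ext))
    if (!any(g$atoms$element == "H") && !add_hydrogens &&
        !is.na(g$cation_center))
      stop("ligand file has no explicit hydrogens; deprotonation enumeration requires them")
    return(g)
  }
  stop("unknown species key or missing file: ", name_or_file)
}

# ---- deprotonation sites and olefin products --------------------------------

# natural sort key for atom names like C7 < C14
name_order <- function(nm) {
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", sub("[a-z]$", "", nm))))
  order(ifelse(is.na(num), Inf, num), nm)
}

#' Enumerate deprotonation sites around the cationic carbon
#'
#' A deprotonation site is a hydrogen on a carbon directly bonded to the
#' cation center (an alpha C--H); abstraction of that proton quenches the
#' cation as an olefin. For the isopimarenyl cation A this yields the five
#' flanking protons (two on C7, two on C14, one on C9).
#'
#' @param g a [cation_graph] with a cation center.
#' @return data.frame with columns `carbon`, `hydrogen` (atom ids) and
#'   `carbon_name`, `hydrogen_name`, sorted by carbon name then hydrogen id.
#' @export
enumerate_deprotonation_sites <- function(g) {
  if (is.na(g$cation_center)) stop("species has no cation center")
  alpha <- neighbors_of(g, g$cation_center)
  alpha <- alpha[g$atoms$element[match(alpha, g$atoms$id)] == "C"]
  rows <- list()
  for (ca in alpha) {
    hs <- neighbors_of(g, ca)
    hs <- hs[g$atoms$element[match(hs, g$atoms$id)] == "H"]
    for (h in hs)
      rows[[length(rows) + 1L]] <- data.frame(carbon = ca, hydrogen = h)
  }
  if (!length(rows))
    return(data.frame(carbon = integer(), hydrogen = integer(),
                      carbon_name = character(), hydrogen_name = character()))
  out <- do.call(rbind, rows)
  out$carbon_name <- atom_name(g, out$carbon)
  out$hydrogen_name <- atom_name(g, out$hydrogen)
  # canonical order: carbon name (natural numeric), then hydrogen name --
  # invariant under any permutation of the atom input order
  cnum <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", out$carbon_name)))
  out <- out[order(ifelse(is.na(cnum), Inf, cnum), out$carbon_name,
                   out$hydrogen_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Registry of named products. Deprotonation products of A carry the
# compound numbers of the isopimaradiene literature; water-addition epimers
# of B are the abietaenol pair.
product_registry <- function() {
  list(
    "7"  = list(product_id = "7",  name = "isopimara-7,15-diene",
                species = "A", alpha = "C7",  origin = "deprotonation"),
    "8"  = list(product_id = "8",  name = "isopimara-8(14),15-diene",
                species = "A", alpha = "C14", origin = "deprotonation"),
    "10" = list(product_id = "10", name = "isopimara-8,15-diene",
                species = "A", alpha = "C9",  origin = "deprotonation"),
    "6a" = list(product_id = "6a", name = "abieta-8(14)-en-13alpha-ol",
                species = "B", face = "alpha", origin = "water_addition"),
    "6b" = list(product_id = "6b", name = "abieta-8(14)-en-13beta-ol",
                species = "B", face = "beta", origin = "water_addition"))
}

#' Map deprotonation sites to the distinct olefin products they form
#'
#' Sites on the same alpha carbon collapse to one product (loss of either
#' geminal proton gives the same olefin). For species A the map is
#' C7 -> "7", C14 -> "8", C9 -> "10"; for other species synthetic ids
#' `olefin_<center>_<alpha>` are generated.
#'
#' @param g a [cation_graph] with a cation center.
#' @param sites optionally precomputed [enumerate_deprotonation_sites] output.
#' @return data.frame, one row per site, with `product_id` and `new_bond_i`,
#'   `new_bond_j` (the olefin bond: cation center to alpha carbon).
#' @export
enumerate_olefin_products <- function(g, sites = enumerate_deprotonation_sites(g)) {
  if (!nrow(sites)) return(cbind(sites, product_id = character(0),
                                 new_bond_i = integer(0), new_bond_j = integer(0)))
  reg <- product_registry()
  pid <- vapply(sites$carbon_name, function(cn) {
    hit <- Filter(function(p) identical(p$species, g$label) &&
                    identical(p$alpha, cn) && p$origin == "deprotonation", reg)
    if (length(hit)) hit[[1]]$product_id
    else paste0("olefin_", atom_name(g, g$cation_center), "_", cn)
  }, character(1))
  out <- sites
  out$product_id <- unname(pid)
  out$new_bond_i <- g$cation_center
  out$new_bond_j <- sites$carbon
  out
}

# ---- prochiral face assignment ---------------------------------------------

#' Assign the prochiral face of a trigonal center occupied by a probe point
#'
#' The face is the sign of the scalar triple product
#' \eqn{(s_2-s_1)\times(s_3-s_1)\cdot(p-c)} for the ordered reference
#' substituents \eqn{s_1,s_2,s_3} of the trigonal carbon \eqn{c} and probe
#' \eqn{p}. Positive is "alpha" (epimer 6a for C13 of the abietenyl cation),
#' negative "beta" (6b). Mirror reflection of all coordinates flips the label.
#'
#' @param coords numeric matrix (n x 3), rownames are atom names.
#' @param center atom name of the trigonal carbon (default "C13").
#' @param ref character(3), ordered reference substituent names
#'   (default `c("C12","C14","C15")`).
#' @param probe numeric(3), the approaching atom position (e.g. water oxygen).
#' @param tol coplanarity tolerance in cubic Angstrom; a |triple product|
#'   below it raises a degenerate-geometry error.
#' @return list(face = "alpha"|"beta", epimer = "6a"|"6b", volume = signed value).
#' @export
assign_addition_face <- function(coords, center = "C13",
                                 ref = c("C12", "C14", "C15"),
                                 probe, tol = 1e-6) {
  stopifnot(is.matrix(coords), !is.null(rownames(coords)))
  need <- c(center, ref)
  miss <- setdiff(need, rownames(coords))
  if (length(miss)) stop("coordinates missing atoms: ", paste(miss, collapse = ", "))
  s <- coords[ref, , drop = FALSE]
  c0 <- coords[center, ]
  v <- det(rbind(s[2, ] - s[1, ], s[3, ] - s[1, ], probe - c0))
  if (abs(v) < tol)
    stop("degenerate geometry: probe within coplanarity tolerance of the substituent plane")
  face <- if (v > 0) "alpha" else "beta"
  list(face = face, epimer = if (face == "alpha") "6a" else "6b", volume = v)
}

# ---- SDF / XYZ / JSON I/O ---------------------------------------------------

#' Write a species and coordinates to an SDF (V2000) file
#' @param g a [cation_graph]; @param coords n x 3 matrix in graph atom order.
#' @param file output path.
#' @param energy optional energy written as an SD `<energy>` tag (kcal/mol).
#' @param append append a record to an existing multi-record file.
#' @export
write_sdf <- function(g, coords, file, energy = NULL, append = FALSE) {
  stopifnot(nrow(coords) == nrow(g$atoms))
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(g$label, "  cationdock", ""), con)
  writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(g$atoms), nrow(g$bonds)), con)
  for (k in seq_len(nrow(g$atoms)))
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       coords[k, 1], coords[k, 2], coords[k, 3],
                       g$atoms$element[k]), con)
  for (k in seq_len(nrow(g$bonds)))
    writeLines(sprintf("%3d%3d%3d  0", g$bonds$i[k], g$bonds$j[k], g$bonds$order[k]), con)
  if (!is.na(g$cation_center))
    writeLines(sprintf("M  CHG  1 %3d   1", g$cation_center), con)
  writeLines("M  END", con)
  if (!is.null(energy))
    writeLines(c("> <energy>", sprintf("%.6f", energy), ""), con)
  writeLines("$$$$", con)
  invisible(file)
}

#' Read the first record of an SDF (V2000) file as a species graph
#' @param file path; @return a [cation_graph] with a `coords` attribute.
#' @export
read_sdf <- function(file) {
  recs <- read_sdf_records(file)
  recs[[1]]$graph_with_coords
}

read_sdf_records <- function(file) {
  lines <- readLines(file)
  brk <- c(0L, which(lines == "$$$$"))
  out <- list()
  for (r in seq_len(length(brk) - 1L)) {
    rec <- lines[(brk[r] + 1L):(brk[r + 1L] - 1L)]
    if (!length(rec) || all(!nzchar(rec))) next
    label <- trimws(rec[1])
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
    at <- rec[5:(4 + na)]
    coords <- t(vapply(at, function(l) as.numeric(c(substr(l, 1, 10), substr(l, 11, 20),
                                                    substr(l, 21, 30))), numeric(3)))
    elem <- trimws(substr(at, 32, 34))
    bl <- if (nb > 0) rec[(5 + na):(4 + na + nb)] else character(0)
    bonds <- if (nb > 0)
      data.frame(i = as.integer(substr(bl, 1, 3)), j = as.integer(substr(bl, 4, 6)),
                 order = as.integer(substr(bl, 7, 9)))
    else data.frame(i = integer(), j = integer(), order = integer())
    cc <- NA_integer_
    chg <- grep("^M  CHG", rec, value = TRUE)
    if (length(chg)) {
      f <- strsplit(trimws(sub("^M  CHG", "", chg[1])), "\\s+")[[1]]
      n <- as.integer(f[1])
      for (k in seq_len(n)) {
        if (as.integer(f[2 * k + 1]) == 1L) cc <- as.integer(f[2 * k])
      }
    }
    cnt <- integer(0); nm <- character(na)
    for (k in seq_len(na)) {
      e <- elem[k]
      cnt[e] <- if (is.na(cnt[e])) 1L else cnt[e] + 1L
      nm[k] <- paste0(e, cnt[e])
    }
    g <- cation_graph(data.frame(id = seq_len(na), element = elem, name = nm),
                      bonds, cc, label)
    rownames(coords) <- nm
    energy <- NA_real_
    ei <- which(grepl("^> *<energy>", rec))
    if (length(ei)) energy <- as.numeric(rec[ei[1] + 1L])
    gwc <- g; attr(gwc, "coords") <- coords
    out[[length(out) + 1L]] <- list(graph_with_coords = gwc, coords = coords,
                                    energy = energy, label = label)
  }
  out
}

#' Write coordinates in XYZ format
#' @export
#' @param g a [cation_graph]; @param coords n x 3; @param file path;
#' @param comment second-line comment.
write_xyz <- function(g, coords, file, comment = g$label) {
  writeLines(c(as.character(nrow(coords)), comment,
               sprintf("%-3s %12.6f %12.6f %12.6f", g$atoms$element,
                       coords[, 1], coords[, 2], coords[, 3])), file)
  invisible(file)
}

#' Read an XYZ file as a bonds-free species graph (bonds inferred by distance)
#'
#' Bonds are assigned between atom pairs closer than 1.75 Angstrom (1.2 for
#' pairs involving hydrogen); no cation center is inferred from XYZ input.
#' @param file path.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(lines[1])
  f <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elem <- vapply(f, `[[`, "", 1L)
  coords <- t(vapply(f, function(x) as.numeric(x[2:4]), numeric(3)))
  cnt <- integer(0); nm <- character(n)
  for (k in seq_len(n)) {
    e <- elem[k]; cnt[e] <- if (is.na(cnt[e])) 1L else cnt[e] + 1L
    nm[k] <- paste0(e, cnt[e])
  }
  d <- as.matrix(stats::dist(coords))
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    cut <- if (elem[a] == "H" || elem[b] == "H") 1.2 else 1.75
    if (d[a, b] < cut) bonds <- rbind(bonds, data.frame(i = a, j = b, order = 1L))
  }
  g <- cation_graph(data.frame(id = seq_len(n), element = elem, name = nm),
                    bonds, NA_integer_, tools::file_path_sans_ext(basename(file)))
  rownames(coords) <- nm
  attr(g, "coords") <- coords
  g
}

#' Dump the built-in species registry as JSON
#'
#' Writes atom names, bonds and cation centers of the four built-in species
#' (documentation / test fixture aid).
#' @param file output path.
#' @export
species_registry_json <- function(file) {
  dump <- lapply(c("A", "B", "water", "pp_mg"), function(k) {
    g <- load_species(k)
    list(label = g$label, atoms = g$atoms, bonds = g$bonds,
         cation_center = if (is.na(g$cation_center)) NULL else
           atom_name(g, g$cation_center))
  })
  names(dump) <- c("A", "B", "water", "pp_mg")
  jsonlite::write_json(dump, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
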