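# Conformer generation and filtering.
#
# The quantum-chemistry stages used in full-scale versions of this analysis
# (DFT optimisation, metadynamics conformer search) are replaced by a self-contained,
# seeded distance-geometry embedding plus a pluggable energy function, so the
# whole pipeline is reproducible on a desk machine. Users with external
# (e.g. QM) energies can inject them via energy_table_fn().

bond_length_ref <- function(e1, e2, order = 1L) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  if (key == "C-C") return(if (order >= 2L) 1.33 else 1.53)
  if (key == "C-H") return(1.09)
  if (key == "H-O") return(0.9572)
  if (key == "O-P") return(1.60)
  if (key == "H-H") return(1.60)   # water H-H 1-3 treated via angle
  1.50
}

# ---- geometry helpers -------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Optimal-superposition heavy-atom RMSD (Kabsch)
#'
#' Superposes `y` onto `x` by the rotation minimising the coordinate RMSD
#' (SVD of the cross-covariance with reflection correction) and returns the
#' residual RMSD. Used for conformer duplicate detection.
#'
#' @param x,y n x 3 coordinate matrices in the same atom order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y))
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dev <- xc - yc %*% t(rot)
  sqrt(sum(dev^2) / nrow(x))
}

# ---- embedding --------------------------------------------------------------

# Bounded-distance stress for heavy-atom embedding, with analytic gradient.
embed_stress <- function(par, n, bi, bj, b0, ai, aj, a0, ri, rj, rmin) {
  x <- matrix(par, n, 3)
  g <- matrix(0, n, 3)
  e <- 0
  pair_term <- function(i, j, target, w, lower_only = FALSE) {
    d <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    dn <- sqrt(rowSums(d * d)) + 1e-12
    if (lower_only) {
      viol <- pmax(0, target - dn)
      e <<- e + w * sum(viol^2)
      coef <- -2 * w * viol / dn
    } else {
      e <<- e + w * sum((dn - target)^2)
      coef <- 2 * w * (dn - target) / dn
    }
    gi <- d * coef
    for (k in 1:3) {
      g[, k] <<- g[, k] + tabulate_add(i, gi[, k], n) - tabulate_add(j, gi[, k], n)
    }
  }
  if (length(bi)) pair_term(bi, bj, b0, 10)
  if (length(ai)) pair_term(ai, aj, a0, 2)
  if (length(ri)) pair_term(ri, rj, rmin, 1, lower_only = TRUE)
  list(value = e, grad = as.numeric(g))
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Embed heavy atoms of a graph: bonds at reference lengths, 1-3 distances at
# ~111 deg, nonbonded repulsion floor 2.45 A. Randomised start, seeded.
embed_heavy <- function(g, seed) {
  heavy <- g$atoms[g$atoms$element != "H", ]
  n <- nrow(heavy)
  idx <- match(heavy$id, g$atoms$id)  # heavy order == graph order restricted
  hmap <- setNames(seq_len(n), heavy$id)
  hb <- g$bonds[g$bonds$i %in% heavy$id & g$bonds$j %in% heavy$id, ]
  bi <- unname(hmap[as.character(hb$i)]); bj <- unname(hmap[as.character(hb$j)])
  b0 <- mapply(function(i, j, o) bond_length_ref(heavy$element[i], heavy$element[j], o),
               bi, bj, hb$order)
  # 1-3 pairs via shared neighbor
  adj <- lapply(seq_len(n), function(k) {
    a <- heavy$id[k]
    nb <- c(hb$j[hb$i == a], hb$i[hb$j == a])
    unname(hmap[as.character(nb)])
  })
  ai <- integer(0); aj <- integer(0); a0 <- numeric(0)
  for (k in seq_len(n)) {
    nb <- adj[[k]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (cc in seq_len(ncol(cmb))) {
      p <- cmb[1, cc]; q <- cmb[2, cc]
      l1 <- b0[which((bi == k & bj == p) | (bi == p & bj == k))][1]
      l2 <- b0[which((bi == k & bj == q) | (bi == q & bj == k))][1]
      th <- 111 * pi / 180
      ai <- c(ai, p); aj <- c(aj, q)
      a0 <- c(a0, sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(th)))
    }
  }
  # nonbonded repulsion pairs (graph distance >= 3)
  ig <- igraph::graph_from_data_frame(data.frame(from = bi, to = bj),
                                      directed = FALSE,
                                      vertices = data.frame(name = seq_len(n)))
  topod <- igraph::distances(ig)
  topod <- topod[as.character(seq_len(n)), as.character(seq_len(n))]
  pr <- which(upper.tri(topod) & topod >= 3, arr.ind = TRUE)
  ri <- pr[, 1]; rj <- pr[, 2]
  rmin <- rep(2.45, length(ri))
  set.seed(seed)
  best <- NULL
  for (attempt in 1:10) {
    x0 <- matrix(rnorm(3 * n, sd = 2.2), n, 3)
    fr <- function(p) embed_stress(p, n, bi, bj, b0, ai, aj, a0, ri, rj, rmin)$value
    gr <- function(p) embed_stress(p, n, bi, bj, b0, ai, aj, a0, ri, rj, rmin)$grad
    opt <- stats::optim(as.numeric(x0), fr, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    x <- matrix(opt$par, n, 3)
    dlen <- sqrt(rowSums((x[bi, , drop = FALSE] - x[bj, , drop = FALSE])^2))
    ok <- all(dlen > 0.7 & dlen < 1.9)
    if (ok) { best <- x; break }
    if (is.null(best) || opt$value < attr(best, "val")) {
      attr(x, "val") <- opt$value; best <- x
    }
  }
  if (is.null(best)) stop(sprintf("embedding failed for species '%s'", g$label))
  rownames(best) <- heavy$name
  list(coords = best, map = hmap)
}

# Place hydrogens on an embedded heavy-atom frame at 1.09/0.96 A using
# idealised local geometry (tetrahedral completion of the heavy neighbors).
place_hydrogens <- function(g, heavy_coords) {
  n <- nrow(g$atoms)
  coords <- matrix(NA_real_, n, 3, dimnames = list(g$atoms$name, NULL))
  coords[rownames(heavy_coords), ] <- heavy_coords
  for (k in which(g$atoms$element != "H")) {
    a <- g$atoms$id[k]
    nb <- neighbors_of(g, a)
    hnb <- nb[g$atoms$element[match(nb, g$atoms$id)] == "H"]
    if (!length(hnb)) next
    hv <- nb[g$atoms$element[match(nb, g$atoms$id)] != "H"]
    p0 <- coords[atom_name(g, a), ]
    u <- lapply(hv, function(b) unitv(coords[atom_name(g, b), ] - p0))
    blen <- bond_length_ref(g$atoms$element[k], "H")
    dirs <- hydrogen_directions(u, length(hnb))
    for (m in seq_along(hnb))
      coords[atom_name(g, hnb[m]), ] <- p0 + blen * dirs[[m]]
  }
  coords
}

hydrogen_directions <- function(u, m) {
  k <- length(u)
  if (k == 0) {          # isolated heavy atom (e.g. water O)
    base <- list(c(1, 0, 0), c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0),
                 c(0, 0, 1))
    return(base[seq_len(m)])
  }
  if (k >= 3) {
    d <- -unitv(Reduce(`+`, u))
    return(rep(list(d), m))
  }
  if (k == 2) {
    w <- -unitv(u[[1]] + u[[2]])
    p <- pracma_cross(u[[1]], u[[2]])
    if (vnorm(p) < 1e-8) p <- orth_any(u[[1]]) else p <- unitv(p)
    if (m == 1) return(list(w))
    half <- 0.5 * (109.47 * pi / 180)
    return(list(unitv(w * cos(half) + p * sin(half)),
                unitv(w * cos(half) - p * sin(half))))
  }
  # k == 1: staggered cone at 109.47 deg around -u1
  ax <- -u[[1]]
  e1 <- orth_any(ax); e2 <- pracma_cross(ax, e1)
  th <- 109.47 * pi / 180
  out <- list()
  for (j in seq_len(m)) {
    phi <- 2 * pi * (j - 1) / max(m, 3)
    # angle between the existing bond u1 and each H direction is 109.47 deg
    out[[j]] <- unitv(cos(pi - th) * ax +
                        sin(pi - th) * (cos(phi) * e1 + sin(phi) * e2))
  }
  out
}

orth_any <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(pracma_cross(v, a))
}

# ---- energy -----------------------------------------------------------------

#' Default conformer energy: torsional rule term plus soft Lennard-Jones clash
#'
#' \eqn{E = k_t \sum_{torsions} (1 + \cos 3\phi) + \sum_{nb} \min(E_{cap},
#' 4\epsilon (\sigma/d)^{12})} over heavy-atom pairs at graph distance >= 4,
#' with \eqn{k_t = 0.3}, \eqn{\epsilon = 0.1} kcal/mol, \eqn{\sigma = 3.0}
#' Angstrom, cap 10 kcal/mol. A crude but smooth stand-in for a molecular
#' mechanics strain energy, on a relative kcal/mol scale.
#'
#' @param g a [cation_graph]; @param coords full-atom coordinate matrix.
#' @return energy (kcal/mol, relative scale).
#' @export
default_energy_fn <- function(g, coords) {
  heavy <- g$atoms[g$atoms$element != "H", ]
  hb <- g$bonds[g$bonds$i %in% heavy$id & g$bonds$j %in% heavy$id, ]
  e <- 0
  # torsions: for each heavy bond b-c, one torsion a-b-c-d (first neighbors)
  for (r in seq_len(nrow(hb))) {
    b <- hb$i[r]; cc <- hb$j[r]
    a <- setdiff(neighbors_of(g, b), cc)
    a <- a[g$atoms$element[match(a, g$atoms$id)] != "H"]
    d <- setdiff(neighbors_of(g, cc), b)
    d <- d[g$atoms$element[match(d, g$atoms$id)] != "H"]
    if (!length(a) || !length(d)) next
    phi <- dihedral_angle(coords[atom_name(g, a[1]), ], coords[atom_name(g, b), ],
                          coords[atom_name(g, cc), ], coords[atom_name(g, d[1]), ])
    e <- e + 0.3 * (1 + cos(3 * phi))
  }
  # soft LJ repulsion on distant heavy pairs
  hid <- heavy$id
  if (length(hid) >= 2) {
    ig <- graph_as_igraph(g)
    topod <- igraph::distances(ig, v = as.character(hid), to = as.character(hid))
    xy <- coords[heavy$name, , drop = FALSE]
    dm <- as.matrix(stats::dist(xy))
    sel <- upper.tri(dm) & topod >= 4
    dd <- dm[sel]
    e <- e + sum(pmin(10, 4 * 0.1 * (3.0 / dd)^12))
  }
  e
}

#' Energy function adapter for an external energy table
#'
#' Returns an energy function that looks conformers up by index in `energies`
#' (e.g. QM single-point energies computed outside the package).
#' @param energies numeric vector, kcal/mol, one per generated conformer.
#' @export
energy_table_fn <- function(energies) {
  i <- 0L
  function(g, coords) {
    i <<- i + 1L
    energies[[i]]
  }
}

# ---- library ----------------------------------------------------------------

#' Generate a seeded conformer library for a species
#'
#' Heavy atoms are embedded by randomised bounded-distance geometry
#' (BFGS-refined; 10 restart attempts per conformer), hydrogens are placed by
#' idealised local geometry, and each conformer is scored by `energy_fn`.
#' Deterministic for a fixed seed.
#'
#' @param g a [cation_graph].
#' @param n number of conformers (>= 1).
#' @param seed integer RNG seed.
#' @param energy_fn callable `(g, coords) -> kcal/mol`; default
#'   [default_energy_fn].
#' @return object of class `conformer_library`: list of conformers
#'   (`coords`, `energy`), `energy_min`, `provenance`.
#' @export
generate_conformers <- function(g, n, seed = 1L, energy_fn = default_energy_fn) {
  stopifnot(n >= 1)
  confs <- vector("list", n)
  for (k in seq_len(n)) {
    emb <- embed_heavy(g, seed = seed * 1000L + k)
    coords <- place_hydrogens(g, emb$coords)
    confs[[k]] <- list(id = k, coords = coords, energy = energy_fn(g, coords))
  }
  structure(list(species = g$label, conformers = confs,
                 energy_min = min(vapply(confs, `[[`, 0, "energy")),
                 provenance = list(generator = "cationdock-dg", seed = seed, n = n)),
            class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat(sprintf("<conformer_library '%s'> %d conformers, Emin %.3f kcal/mol\n",
              x$species, length(x$conformers), x$energy_min))
  invisible(x)
}

#' Build a conformer library directly from coordinate sets
#'
#' @param g a [cation_graph]; @param coord_list list of n x 3 matrices;
#' @param energies numeric vector of matching length (kcal/mol).
#' @export
conformer_library <- function(g, coord_list, energies) {
  stopifnot(length(coord_list) == length(energies))
  confs <- Map(function(k, xyz, e) list(id = k, coords = xyz, energy = e),
               seq_along(coord_list), coord_list, energies)
  structure(list(species = g$label, conformers = confs,
                 energy_min = min(energies),
                 provenance = list(generator = "external", seed = NA, n = length(confs))),
            class = "conformer_library")
}

#' Filter a conformer library by energy window and duplicate RMSD
#'
#' Keeps conformers within `window` kcal/mol of the library minimum, then
#' removes duplicates: conformers within `dup_rmsd` heavy-atom RMSD (optimal
#' Kabsch superposition) of an already-kept lower-energy member. The global
#' minimum always survives; the operation is idempotent.
#'
#' @param lib a `conformer_library`.
#' @param window energy window above the minimum, kcal/mol (default 5).
#' @param dup_rmsd duplicate threshold, Angstrom heavy-atom RMSD (default 0.25).
#' @param species optional [cation_graph] to identify heavy atoms; by default
#'   rows whose names do not start with "H" are used.
#' @export
filter_library <- function(lib, window = 5, dup_rmsd = 0.25, species = NULL) {
  stopifnot(length(lib$conformers) >= 1)
  en <- vapply(lib$conformers, `[[`, 0, "energy")
  emin <- min(en)
  keep_idx <- which(en <= emin + window)
  keep_idx <- keep_idx[order(en[keep_idx])]
  heavy_rows <- function(xyz) xyz[!startsWith(rownames(xyz), "H"), , drop = FALSE]
  kept <- list()
  for (k in keep_idx) {
    xk <- heavy_rows(lib$conformers[[k]]$coords)
    dup <- FALSE
    for (m in kept) {
      if (kabsch_rmsd(heavy_rows(lib$conformers[[m]]$coords), xk) < dup_rmsd) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, k)
  }
  kept <- sort(unlist(kept))
  confs <- lib$conformers[kept]
  structure(list(species = lib$species, conformers = confs,
                 energy_min = min(vapply(confs, `[[`, 0, "energy")),
                 provenance = c(lib$provenance,
                                list(filtered = TRUE, window = window, dup_rmsd = dup_rmsd))),
            class = "conformer_library")
}

#' Write / read a conformer library as a multi-record SDF file
#' @param lib a `conformer_library`; @param g its [cation_graph]; @param file path.
#' @export
write_library_sdf <- function(lib, g, file) {
  first <- TRUE
  for (cf in lib$conformers) {
    write_sdf(g, cf$coords, file, energy = cf$energy, append = !first)
    first <- FALSE
  }
  invisible(file)
}

#' @rdname write_library_sdf
#' @export
read_library_sdf <- function(g, file) {
  recs <- read_sdf_records(file)
  conformer_library(g, lapply(recs, `[[`, "coords"),
                    vapply(recs, `[[`, 0, "energy"))
}
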