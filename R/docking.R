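# Rigid-body constrained docking into a (rigid, apo) receptor pocket:
# seeded pose sampling, a documented soft-sphere/contact scorer standing in
# for a full molecular-mechanics score function, and the three-stage filter
# cascade (per-ligand constraint score < 1, lowest-decile total score,
# lowest-decile carbocation interface energy). Absolute pose counts of any
# particular force field are not reproduced here -- the procedure is.

# ---- configuration ----------------------------------------------------------

#' Docking run configuration
#'
#' @param n_poses_per_set rigid poses sampled per constraint set (default 4000).
#' @param seed integer base seed; every constraint set derives an independent
#'   stream seed from it, so adding sets never perturbs existing streams.
#' @param w_rep,w_att,w_cst score weights (soft-sphere repulsion, contact
#'   attraction, restraint penalty).
#' @param grid_spacing cofactor placement grid spacing, Angstrom.
#' @param percentile filter-cascade fraction kept at stages 2 and 3
#'   (default 0.10, the lowest 10 percent).
#' @param water_grid_extent,water_grid_spacing local water search grid around
#'   its constraint target, Angstrom.
#' @export
docking_config <- function(n_poses_per_set = 4000L, seed = 1L,
                           w_rep = 1.0, w_att = 0.4, w_cst = 1.0,
                           grid_spacing = 1.0, percentile = 0.10,
                           water_grid_extent = 3.0, water_grid_spacing = 0.75) {
  stopifnot(n_poses_per_set >= 1, percentile > 0, percentile < 1)
  structure(list(n_poses_per_set = as.integer(n_poses_per_set),
                 seed = as.integer(seed), w_rep = w_rep, w_att = w_att,
                 w_cst = w_cst, grid_spacing = grid_spacing,
                 percentile = percentile,
                 water_grid_extent = water_grid_extent,
                 water_grid_spacing = water_grid_spacing),
            class = "docking_config")
}

# 32-bit FNV-1a hash of a string, masked to 31 bits: per-set RNG stream seed.
# 32-bit arithmetic is done on 16-bit halves so values stay inside R's
# integer range.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo16 <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h <- (h %/% 65536) * 65536 + lo16
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

stream_seed <- function(base_seed, set_id) fnv1a32(paste0(base_seed, "|", set_id))

# ---- receptor ---------------------------------------------------------------

receptor_obj <- function(atoms, pocket, variant, sites, pp = NULL) {
  structure(list(atoms = atoms, pocket = pocket, variant = variant,
                 sites = sites, pp = pp), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %d atoms, variant 723=%s, pocket r=%.1f A, pp %s\n",
              nrow(x$atoms), x$variant, x$pocket$radius,
              if (is.null(x$pp)) "absent" else "placed"))
  invisible(x)
}

# place atom D given reference atoms A-B-C, bond |CD|, angle BCD, dihedral ABCD
nerf_place <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180; ph <- dihedral_deg * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

#' Load a receptor PDB and set the residue-723 variant
#'
#' Reads the structure with `bio3d`, optionally swaps the residue-723 side
#' chain in silico by ideal-geometry grafting (A -> S/T adds the hydroxyl
#' OG/OG1 and proton at standard internal coordinates off CB; S/T -> A strips
#' beyond CB), and resolves the functional-site selectors: the catalytic base
#' hydroxyl (`base:O`, `base:H`), the side-chain tip (`723:tip`), and -- if
#' the file carries a `PPM` cofactor residue -- the labeled pyrophosphate
#' oxygens.
#'
#' @param pdb_path path to a PDB file.
#' @param pocket list(center = numeric(3), radius = Angstrom).
#' @param variant residue 723 identity: "A", "S" or "T".
#' @return object of class `receptor`.
#' @export
load_receptor <- function(pdb_path, pocket, variant = "T") {
  stopifnot(variant %in% c("A", "S", "T"))
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resname = trimws(at$resid), resno = at$resno,
                      element = ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy),
                                       substr(trimws(at$elety), 1, 1)),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  ppsel <- atoms$resname == "PPM"
  pp <- NULL
  if (any(ppsel)) {
    pp <- as.matrix(atoms[ppsel, c("x", "y", "z")])
    rownames(pp) <- atoms$name[ppsel]
    atoms <- atoms[!ppsel, , drop = FALSE]
  }
  r7 <- atoms$resno == 723
  if (!any(r7)) stop("receptor lacks residue 723")
  crystal <- unname(c(ALA = "A", SER = "S", THR = "T")[atoms$resname[which(r7)[1]]])
  if (is.na(crystal)) crystal <- "?"
  if (!identical(crystal, variant)) {
    need <- c("N", "CA", "CB")
    have <- atoms$name[r7]
    miss <- setdiff(need, have)
    if (length(miss)) stop("residue 723 grafting needs atoms: ",
                           paste(miss, collapse = ", "))
    xyz7 <- function(nm) as.numeric(atoms[r7 & atoms$name == nm, c("x", "y", "z")][1, ])
    # strip any side-chain atoms beyond CB, then rebuild for the target variant
    drop <- r7 & !(atoms$name %in% c("N", "CA", "C", "O", "CB", "H", "HA"))
    atoms <- atoms[!drop, ]
    r7 <- atoms$resno == 723
    newres <- c(A = "ALA", S = "SER", T = "THR")[[variant]]
    atoms$resname[r7] <- newres
    add_atom <- function(nm, el, xyz) {
      atoms <<- rbind(atoms, data.frame(serial = max(atoms$serial) + 1L, name = nm,
                                        resname = newres, resno = 723L, element = el,
                                        x = xyz[1], y = xyz[2], z = xyz[3]))
    }
    if (variant %in% c("S", "T")) {
      on <- if (variant == "T") "OG1" else "OG"
      hn <- if (variant == "T") "HG1" else "HG"
      nb <- xyz7("N"); ca <- xyz7("CA"); cb <- xyz7("CB")
      og <- nerf_place(nb, ca, cb, 1.43, 109.5, 180)
      add_atom(on, "O", og)
      add_atom(hn, "H", nerf_place(ca, cb, og, 0.96, 109.5, 180))
      if (variant == "T")
        add_atom("CG2", "C", nerf_place(nb, ca, cb, 1.53, 109.5, -60))
    }
  }
  r7 <- atoms$resno == 723
  find7 <- function(nm) {
    i <- which(r7 & atoms$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  base_o <- if (variant == "T") find7("OG1") else if (variant == "S") find7("OG") else NA_integer_
  base_h <- if (variant == "T") find7("HG1") else if (variant == "S") find7("HG") else NA_integer_
  tip <- if (!is.na(base_o)) base_o else find7("CB")
  sites <- list(base_o = base_o, base_h = base_h, tip = tip)
  if (!is.na(base_o)) {
    bo <- as.numeric(atoms[base_o, c("x", "y", "z")])
    if (vnorm(bo - pocket$center) > pocket$radius + 2.5)
      stop("base hydroxyl oxygen lies outside the declared pocket")
  }
  rownames(atoms) <- NULL
  receptor_obj(atoms, pocket, variant, sites, pp)
}

#' Write a receptor (and its cofactor cluster, if placed) to a PDB file
#' @param receptor a `receptor`; @param file path.
#' @export
write_receptor_pdb <- function(receptor, file) {
  at <- receptor$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  eleno <- at$serial; elety <- at$name; resid <- at$resname; resno <- at$resno
  elesy <- at$element
  if (!is.null(receptor$pp)) {
    npp <- nrow(receptor$pp)
    xyz <- c(xyz, as.numeric(t(receptor$pp)))
    eleno <- c(eleno, max(at$serial) + seq_len(npp))
    elety <- c(elety, rownames(receptor$pp))
    resid <- c(resid, rep("PPM", npp))
    resno <- c(resno, rep(900L, npp))
    elesy <- c(elesy, sub("[0-9]+$", "", rownames(receptor$pp)))
  }
  bio3d::write.pdb(file = file, xyz = xyz, eleno = eleno, elety = elety,
                   resid = resid, resno = resno, elesy = elesy)
  invisible(file)
}

receptor_xyz <- function(receptor) {
  m <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

receptor_site_xyz <- function(receptor, key) {
  if (key == "base:O") i <- receptor$sites$base_o
  else if (key == "base:H") i <- receptor$sites$base_h
  else if (key == "723:tip") i <- receptor$sites$tip
  else {
    p <- strsplit(key, ":", fixed = TRUE)[[1]]
    i <- which(receptor$atoms$resno == as.integer(p[1]) & receptor$atoms$name == p[2])[1]
  }
  if (is.na(i) || !length(i))
    stop("receptor selector cannot be resolved: ", key)
  as.numeric(receptor$atoms[i, c("x", "y", "z")])
}

# ---- cofactor placement -----------------------------------------------------

#' Place the pyrophosphate--magnesium cluster by exhaustive grid search
#'
#' Scans a cubic grid (spacing `cfg$grid_spacing`) inside the pocket sphere,
#' translating the rigid cluster reference geometry, and keeps the grid point
#' minimising soft-sphere clash with the receptor plus any supplied
#' cofactor restraints. The grid is anchored at the pocket center so halving
#' the spacing refines (supersets) the previous grid; ties break to the
#' lexicographically smallest grid index. Fails if no clash-free point exists.
#'
#' @param receptor a `receptor` without placed cofactors.
#' @param cfg a [docking_config] (grid spacing is taken from it).
#' @param restraints optional list of [flat_bottom_restraint] whose members
#'   reference bodies "pp_mg" and "receptor".
#' @return the receptor with `$pp` set to the placed cluster coordinates.
#' @export
place_cofactors <- function(receptor, cfg = docking_config(), restraints = NULL) {
  ref <- pp_mg_coords()
  ref <- sweep(ref, 2, colMeans(ref))   # centroid at origin
  ctr <- receptor$pocket$center; rad <- receptor$pocket$radius
  sp <- cfg$grid_spacing
  k <- floor(rad / sp)
  ax <- (-k:k) * sp
  gpts <- as.matrix(expand.grid(z = ax, y = ax, x = ax))[, c("x", "y", "z")]
  gpts <- gpts[sqrt(rowSums(gpts^2)) <= rad, , drop = FALSE]
  gpts <- sweep(gpts, 2, ctr, `+`)
  rx <- receptor_xyz(receptor)
  best <- NULL; best_pen <- Inf; any_clash_free <- FALSE
  for (gi in seq_len(nrow(gpts))) {
    p <- gpts[gi, ]
    clus <- sweep(ref, 2, p, `+`)
    d <- sqrt(pmax(outer(rowSums(clus^2), rowSums(rx^2), `+`) - 2 * clus %*% t(rx), 0))
    clash <- sum(((2.8 - d[d < 2.8]) / 2.8)^2)
    pen <- clash
    if (!is.null(restraints)) {
      lookup <- function(body, atom) {
        if (body == "pp_mg") clus[atom, ]
        else if (body == "receptor") receptor_site_xyz(receptor, atom)
        else stop("cofactor placement restraints may only reference pp_mg/receptor")
      }
      pen <- pen + sum(vapply(restraints, function(r)
        restraint_penalty(r, measure_restraint(r, lookup)), numeric(1)))
    }
    if (clash == 0) any_clash_free <- TRUE
    if (pen < best_pen - 1e-12) {
      best_pen <- pen; best <- clus
    }
  }
  if (is.null(best) || !any_clash_free)
    stop("no clash-free grid point for the cofactor cluster")
  receptor$pp <- best
  attr(receptor$pp, "penalty") <- best_pen
  receptor
}

# ---- pose representation ----------------------------------------------------

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Shoemake's method: uniform random unit quaternions from three U(0,1) draws.
shoemake_quat <- function(u) {
  s1 <- sqrt(1 - u[1]); s2 <- sqrt(u[1])
  t1 <- 2 * pi * u[2]; t2 <- 2 * pi * u[3]
  c(s1 * sin(t1), s1 * cos(t1), s2 * sin(t2), s2 * cos(t2))
}

#' Transformed ligand coordinates of a pose
#' @param pose a pose; @param lib the conformer library it indexes.
#' @return n x 3 matrix with atom-name rownames.
#' @export
pose_ligand_coords <- function(pose, lib) {
  xyz <- lib$conformers[[pose$conformer_id]]$coords
  ctr <- colMeans(xyz)
  rot <- quat_to_rot(pose$quat)
  out <- sweep(xyz, 2, ctr) %*% t(rot)
  out <- sweep(out, 2, pose$trans, `+`)
  rownames(out) <- rownames(xyz)
  out
}

# precomputed per-set scoring context: receptor coordinate matrix and the
# resolved receptor site coordinates referenced by the set
scoring_context <- function(receptor, cset) {
  keys <- unique(unlist(lapply(cset$restraints, function(r)
    vapply(Filter(function(m) m$body == "receptor", r$members), `[[`, "", "atom"))))
  site <- if (length(keys))
    lapply(setNames(keys, keys), function(k) receptor_site_xyz(receptor, k))
  else list()
  rx <- rbind(receptor_xyz(receptor), if (!is.null(receptor$pp)) unname(receptor$pp))
  list(site = site, rx = rx)
}

# coordinate lookup for restraint evaluation on one pose
pose_lookup <- function(receptor, lig_xyz, water = NULL, site = NULL) {
  function(body, atom) {
    switch(body,
           receptor = {
             if (!is.null(site) && !is.null(site[[atom]])) site[[atom]]
             else receptor_site_xyz(receptor, atom)
           },
           carbocation = {
             if (!atom %in% rownames(lig_xyz))
               stop("ligand selector cannot be resolved: ", atom)
             lig_xyz[atom, ]
           },
           water = {
             if (is.null(water)) stop("pose carries no water")
             water
           },
           pp_mg = {
             if (is.null(receptor$pp)) stop("cofactor cluster not placed")
             if (!atom %in% rownames(receptor$pp))
               stop("pp_mg selector cannot be resolved: ", atom)
             receptor$pp[atom, ]
           },
           stop("unknown body: ", body))
  }
}

# vectorised water placement: local grid around the C13 target, scored by the
# set's water restraints plus hard-core clash with receptor and ligand
# analytic ideal water point: on the set's face normal at C13, at the middle
# of the distance flat bottom (used when the pose cannot pass stage 1 anyway)
water_ideal_point <- function(lig_xyz, cset) {
  wr <- Filter(function(r) any(vapply(r$members, function(m) m$body == "water",
                                      logical(1))), cset$restraints)
  dist_r <- Filter(function(r) r$kind == "distance", wr)
  face_r <- Filter(function(r) r$kind == "face", wr)
  d0 <- if (length(dist_r)) (dist_r[[1]]$lower + dist_r[[1]]$upper) / 2 else 3.0
  sgn <- if (length(face_r) && identical(face_r[[1]]$face, "beta")) -1 else 1
  ref <- if (length(face_r)) face_r[[1]]$ref else c("C12", "C14", "C15")
  sref <- lig_xyz[ref, , drop = FALSE]
  nrm <- unitv(pracma_cross(sref[2, ] - sref[1, ], sref[3, ] - sref[1, ]))
  lig_xyz["C13", ] + sgn * d0 * nrm
}

place_water_grid <- function(receptor, lig_xyz, cset, cfg) {
  wr <- Filter(function(r) any(vapply(r$members, function(m) m$body == "water",
                                      logical(1))), cset$restraints)
  target <- lig_xyz["C13", ]
  sp <- cfg$water_grid_spacing; ext <- cfg$water_grid_extent
  ax <- seq(-ext, ext, by = sp)
  gp <- as.matrix(expand.grid(z = ax, y = ax, x = ax))[, c("x", "y", "z")]
  gp <- sweep(gp, 2, target, `+`)
  rx <- rbind(receptor_xyz(receptor),
              if (!is.null(receptor$pp)) unname(receptor$pp),
              unname(lig_xyz))
  near <- rowSums(sweep(rx, 2, target)^2) < (ext + 3.5)^2
  rx <- rx[near, , drop = FALSE]
  if (!nrow(rx)) return(gp[1, ])
  d2 <- outer(rowSums(gp^2), rowSums(rx^2), `+`) - 2 * gp %*% t(rx)
  dmin2 <- d2[, 1]
  for (k in seq_len(ncol(d2))[-1]) dmin2 <- pmin(dmin2, d2[, k])
  dmin <- sqrt(pmax(0, dmin2))
  # the water cannot interpenetrate receptor or ligand: placement is a hard
  # steric filter (2.25 A clearance, just under the water-oxygen contact
  # distance), then restraint-optimal within the allowed region. If nothing
  # clears, the best-clearance point is used -- its restraint penalties then
  # report the infeasibility.
  allowed <- dmin >= 2.25
  if (!any(allowed)) allowed <- dmin >= max(dmin) - 1e-9
  gp <- gp[allowed, , drop = FALSE]
  pen <- (pmax(0, 2.4 - dmin[allowed]) / 0.3)^2
  pen_vec <- function(r, x) {
    v <- pmax(r$lower - x, 0) + pmax(x - r$upper, 0)
    (v / r$sd)^2 * r$weight
  }
  for (r in wr) {
    if (r$kind == "distance") {
      other <- Filter(function(m) m$body != "water", r$members)[[1]]
      oxyz <- if (other$body == "carbocation") lig_xyz[other$atom, ]
              else receptor_site_xyz(receptor, other$atom)
      dd <- sqrt(rowSums(sweep(gp, 2, oxyz)^2))
      pen <- pen + pen_vec(r, dd)
    } else if (r$kind == "face") {
      sref <- lig_xyz[r$ref, , drop = FALSE]
      nrm <- pracma_cross(sref[2, ] - sref[1, ], sref[3, ] - sref[1, ])
      if (identical(r$face, "beta")) nrm <- -nrm
      nrm <- unitv(nrm)
      v <- sweep(gp, 2, lig_xyz["C13", ])
      cosang <- (v %*% nrm) / sqrt(rowSums(v^2) + 1e-12)
      ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
      pen <- pen + pen_vec(r, ang)
    }
  }
  gp[which.min(pen), ]
}

# Deterministic constraint-guided translation refinement: starting from the
# tentative uniform translation, iteratively shift the whole ligand by the
# mean displacement that would bring each ligand-vs-fixed-point distance
# restraint to its flat bottom. Orientations are untouched (they stay uniform
# on SO(3)); the translation distribution becomes the projection of the
# uniform draw onto the restraint-feasible region, emulating the original
# protocol's transformer, which places ligands subject to the constraints
# rather than rejection-sampling them.
snap_targets <- function(receptor, cset) {
  targets <- list()
  for (r in cset$restraints) {
    if (r$kind != "distance") next
    bod <- vapply(r$members, `[[`, "", "body")
    if (sum(bod == "carbocation") != 1L || any(bod == "water")) next
    li <- which(bod == "carbocation"); fi <- which(bod != "carbocation")
    fixed <- if (bod[fi] == "receptor") {
      receptor_site_xyz(receptor, r$members[[fi]]$atom)
    } else {
      if (is.null(receptor$pp)) stop("cofactor cluster not placed")
      receptor$pp[r$members[[fi]]$atom, ]
    }
    targets[[length(targets) + 1L]] <- list(
      atom = r$members[[li]]$atom, fixed = fixed,
      lower = r$lower, upper = r$upper)
  }
  targets
}

snap_translation <- function(trans, rot_local, targets, n_iter = 12) {
  if (!length(targets)) return(trans)
  targets <- lapply(targets, function(tg) {
    tg$local <- rot_local[tg$atom, ]
    tg
  })
  for (it in seq_len(n_iter)) {
    shift <- c(0, 0, 0)
    for (tg in targets) {
      a <- tg$local + trans
      v <- tg$fixed - a
      d <- vnorm(v)
      want <- if (d < tg$lower) d - tg$lower else if (d > tg$upper) d - tg$upper else 0
      if (want != 0) shift <- shift + want * v / max(d, 1e-9)
    }
    if (vnorm(shift) < 1e-9) break
    trans <- trans + shift / length(targets)
  }
  trans
}

#' Sample rigid-body poses for one constraint set
#'
#' Conformers are drawn uniformly from the library, orientations uniformly on
#' SO(3) (Shoemake quaternions), and the translation starts from a uniform
#' draw inside the pocket sphere, then receives a deterministic
#' constraint-guided refinement: the ligand is shifted toward the flat-bottom
#' region of the set's ligand-vs-site distance restraints (angles are left to
#' the filters). When the set carries a water mode, the water oxygen is placed
#' on a deterministic local grid around its constraint target (C13),
#' minimising the water restraints plus clash. Each set uses an independent
#' RNG stream derived from `(cfg$seed, set_id)`, so pose lists are fully
#' reproducible.
#'
#' @param receptor a `receptor` with cofactors placed (if any restraint
#'   references `pp_mg`).
#' @param lib a `conformer_library`.
#' @param cset a [constraint_set].
#' @param cfg a [docking_config].
#' @return list of poses (`pose_id`, `conformer_id`, `quat`, `trans`,
#'   `water`, `set_id`), length `cfg$n_poses_per_set`, unscored.
#' @export
sample_poses <- function(receptor, lib, cset, cfg = docking_config()) {
  stopifnot(length(lib$conformers) >= 1)
  n <- cfg$n_poses_per_set
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(cfg$seed, cset$set_id))
  conf_idx <- sample.int(length(lib$conformers), n, replace = TRUE)
  u <- matrix(runif(3 * n), n, 3)
  # uniform point in the pocket sphere: direction x radius^(1/3) scaling
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rads <- receptor$pocket$radius * runif(n)^(1 / 3)
  trans <- sweep(dirs * rads, 2, receptor$pocket$center, `+`)
  with_water <- cset$water_mode != "none"
  targets <- snap_targets(receptor, cset)
  ctx <- scoring_context(receptor, cset)
  dry <- constraint_set(cset$set_id, Filter(function(r)
    !any(vapply(r$members, function(m) m$body == "water", logical(1))),
    cset$restraints), water_mode = "none")
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    q <- shoemake_quat(u[i, ])
    xyz <- lib$conformers[[conf_idx[i]]]$coords
    rot_local <- sweep(xyz, 2, colMeans(xyz)) %*% t(quat_to_rot(q))
    rownames(rot_local) <- rownames(xyz)
    pose <- list(pose_id = sprintf("%s_%05d", cset$set_id, i),
                 conformer_id = conf_idx[i],
                 quat = q,
                 trans = snap_translation(trans[i, ], rot_local, targets),
                 water = NULL, set_id = cset$set_id)
    if (with_water) {
      lig_xyz <- pose_ligand_coords(pose, lib)
      # full grid search only where the pose can still pass stage 1: if the
      # carbocation's non-water restraints alone already reach a score of 1,
      # the pose is dead and the analytic ideal point suffices for bookkeeping
      carb <- if (length(dry$restraints))
        ligand_constraint_score(pose_lookup(receptor, lig_xyz, site = ctx$site),
                                dry)["carbocation"]
      else 0
      pose$water <- if (!is.na(carb) && carb < 1)
        place_water_grid(receptor, lig_xyz, cset, cfg)
      else water_ideal_point(lig_xyz, cset)
    }
    poses[[i]] <- pose
  }
  poses
}

# ---- scoring ----------------------------------------------------------------

# soft-sphere repulsion + capped shell contacts for one body vs receptor(+pp)
body_energy <- function(bx, rx) {
  d2 <- outer(rowSums(bx^2), rowSums(rx^2), `+`) - 2 * bx %*% t(rx)
  d <- sqrt(pmax(d2, 0))
  rep_e <- sum(((3.0 - d[d < 3.0]) / 3.0)^2)
  contacts <- rowSums(d >= 3.2 & d <= 4.5)
  att_e <- -sum(pmin(4, contacts))
  c(rep = rep_e, att = att_e)
}

#' Score a pose: constraint scores, total score, carbocation interface energy
#'
#' `total = w_rep * repulsion(all ligand bodies) + w_att * attraction(all) +
#' w_cst * sum(restraint penalties)`; repulsion is the soft-sphere overlap
#' `((3.0 - d)/3.0)^2` below 3.0 Angstrom, attraction the per-atom-capped
#' count of receptor contacts in the 3.2--4.5 Angstrom shell. The interface
#' energy is the repulsion+attraction of the carbocation body alone,
#' restraints excluded.
#'
#' @param receptor a `receptor`; @param pose a pose from [sample_poses];
#' @param lib its `conformer_library`; @param cset its [constraint_set];
#' @param cfg a [docking_config].
#' @return the pose with `cst_scores`, `total_score`, `interface_energy`.
#' @export
score_pose <- function(receptor, pose, lib, cset, cfg = docking_config(),
                       ctx = NULL) {
  if (is.null(ctx)) ctx <- scoring_context(receptor, cset)
  lig_xyz <- pose_ligand_coords(pose, lib)
  rx <- ctx$rx
  e_lig <- body_energy(unname(lig_xyz), rx)
  e_wat <- if (!is.null(pose$water)) body_energy(matrix(pose$water, 1, 3), rx)
           else c(rep = 0, att = 0)
  lookup <- pose_lookup(receptor, lig_xyz, pose$water, ctx$site)
  cst <- ligand_constraint_score(lookup, cset)
  cst_total <- {
    pen <- vapply(cset$restraints, function(r)
      restraint_penalty(r, measure_restraint(r, lookup)), numeric(1))
    sum(pen)
  }
  pose$cst_scores <- cst
  pose$total_score <- cfg$w_rep * (e_lig["rep"] + e_wat["rep"]) +
    cfg$w_att * (e_lig["att"] + e_wat["att"]) + cfg$w_cst * cst_total
  pose$interface_energy <- cfg$w_rep * e_lig[["rep"]] + cfg$w_att * e_lig[["att"]]
  pose$total_score <- unname(pose$total_score)
  pose
}

#' Score a list of poses
#' @inheritParams score_pose
#' @param poses list of poses.
#' @export
score_poses <- function(receptor, poses, lib, cset, cfg = docking_config()) {
  ctx <- scoring_context(receptor, cset)
  lapply(poses, function(p) score_pose(receptor, p, lib, cset, cfg, ctx))
}

#' Add water restraints to an existing pose and rescore it
#'
#' Places the water oxygen for `cset` (a water-carrying constraint set, e.g.
#' from [add_water_to_sets]) on its deterministic local grid given the pose's
#' ligand geometry, then rescores the pose against the augmented set. Used to
#' ask, pose by pose, whether a docking result remains constraint-satisfying
#' once the reactant water is required — the paired form of the with-water
#' rerun.
#'
#' @inheritParams score_pose
#' @export
augment_pose_with_water <- function(receptor, pose, lib, cset,
                                    cfg = docking_config(), ctx = NULL) {
  stopifnot(cset$water_mode != "none")
  lig_xyz <- pose_ligand_coords(pose, lib)
  pose$water <- place_water_grid(receptor, lig_xyz, cset, cfg)
  score_pose(receptor, pose, lib, cset, cfg, ctx)
}

# ---- filter cascade ---------------------------------------------------------

#' Three-stage pose filter cascade
#'
#' Stage 1 keeps poses whose every per-ligand constraint score is strictly
#' below one ("constraint fulfillment"); stage 2 keeps the
#' `max(1, floor(percentile * n1))` lowest total scores; stage 3 keeps the
#' `max(1, floor(percentile * k1))` lowest carbocation interface energies.
#' Ties break by pose id (stable), so the output is invariant to input order.
#'
#' @param poses scored poses; @param cfg a [docking_config].
#' @return list(poses = surviving poses, trace = list(n0, n1, k1, k2)).
#' @export
filter_cascade <- function(poses, cfg = docking_config()) {
  n0 <- length(poses)
  if (!n0) return(list(poses = list(), trace = list(n0 = 0L, n1 = 0L, k1 = 0L, k2 = 0L)))
  ids <- vapply(poses, `[[`, "", "pose_id")
  poses <- poses[order(ids)]
  pass1 <- Filter(function(p) all(p$cst_scores < 1), poses)
  n1 <- length(pass1)
  if (!n1) return(list(poses = list(), trace = list(n0 = n0, n1 = 0L, k1 = 0L, k2 = 0L)))
  k1 <- max(1L, floor(cfg$percentile * n1))
  tot <- vapply(pass1, `[[`, 0, "total_score")
  stage2 <- pass1[order(tot, vapply(pass1, `[[`, "", "pose_id"))][seq_len(k1)]
  k2 <- max(1L, floor(cfg$percentile * k1))
  ife <- vapply(stage2, `[[`, 0, "interface_energy")
  stage3 <- stage2[order(ife, vapply(stage2, `[[`, "", "pose_id"))][seq_len(k2)]
  list(poses = stage3,
       trace = list(n0 = n0, n1 = n1, k1 = as.integer(k1), k2 = as.integer(k2)))
}

# ---- pose serialisation -----------------------------------------------------

#' Tabulate poses (one row per pose) for TSV export
#' @param poses list of (scored) poses.
#' @export
poses_to_table <- function(poses) {
  if (!length(poses))
    return(data.frame(pose_id = character(), set_id = character(),
                      conformer_id = integer(), total_score = numeric(),
                      interface_energy = numeric(), max_cst = numeric()))
  data.frame(
    pose_id = vapply(poses, `[[`, "", "pose_id"),
    set_id = vapply(poses, `[[`, "", "set_id"),
    conformer_id = vapply(poses, function(p) as.integer(p$conformer_id), 1L),
    total_score = vapply(poses, function(p) p$total_score %||% NA_real_, 0),
    interface_energy = vapply(poses, function(p) p$interface_energy %||% NA_real_, 0),
    max_cst = vapply(poses, function(p)
      if (is.null(p$cst_scores)) NA_real_ else max(p$cst_scores), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write passing poses as a multi-model PDB (receptor + ligands per MODEL)
#' @param receptor a `receptor`; @param poses list of poses;
#' @param lib their `conformer_library`; @param g ligand [cation_graph];
#' @param file output path.
#' @export
write_poses_pdb <- function(receptor, poses, lib, g, file) {
  con <- file(file, "w"); on.exit(close(con))
  fmt <- function(serial, name, res, resno, xyz, el, het = FALSE) {
    sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            if (het) "HETATM" else "ATOM", serial, substr(name, 1, 4), res,
            resno, xyz[1], xyz[2], xyz[3], el)
  }
  for (m in seq_along(poses)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- receptor$atoms
    for (i in seq_len(nrow(at)))
      writeLines(fmt(at$serial[i], at$name[i], at$resname[i], at$resno[i],
                     as.numeric(at[i, c("x", "y", "z")]), at$element[i]), con)
    s <- max(at$serial)
    if (!is.null(receptor$pp))
      for (i in seq_len(nrow(receptor$pp))) {
        s <- s + 1L
        writeLines(fmt(s, rownames(receptor$pp)[i], "PPM", 900L,
                       receptor$pp[i, ], sub("[0-9]+$", "", rownames(receptor$pp)[i]),
                       het = TRUE), con)
      }
    lx <- pose_ligand_coords(poses[[m]], lib)
    for (i in seq_len(nrow(lx))) {
      s <- s + 1L
      writeLines(fmt(s, rownames(lx)[i], "LIG", 901L, lx[i, ],
                     g$atoms$element[i], het = TRUE), con)
    }
    if (!is.null(poses[[m]]$water)) {
      s <- s + 1L
      writeLines(fmt(s, "O", "HOH", 902L, poses[[m]]$water, "O", het = TRUE), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
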