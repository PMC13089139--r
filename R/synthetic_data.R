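# Synthetic fixtures: a toy pocket-shell receptor with a helix-break-like
# hydroxyl probe site and a labeled pyrophosphate cluster, star-shaped toy
# cations with a prescribed alpha-proton census, and planted pose sets with
# known truth labels and controlled score distributions. Everything is
# generated programmatically and serialises through the pipeline's own
# readers; no external structure is required anywhere in the test suite.

#' Fixture specification for the synthetic generators
#'
#' @param seed RNG seed; @param pocket_radius pocket sphere radius (Angstrom);
#' @param shell_atoms number of pseudo-atoms forming the pocket wall;
#' @param base_polar_angle polar angle (degrees) of the residue-723 probe site
#'   on the shell; @param pp_center cluster centroid position (numeric(3)
#'   relative to the pocket center) or `NULL` to defer to [place_cofactors];
#' @param fractions named planted outcome distribution (sums to 1);
#' @param score_noise_sd standard deviation of planted score noise;
#' @param geom_noise_sd standard deviation (Angstrom) of positional jitter
#'   applied to planted poses -- at 0 the planted truth is recovered exactly;
#' @param n_poses planted pose count.
#' @export
fixture_spec <- function(seed = 1L, pocket_radius = 8, shell_atoms = 80,
                         base_polar_angle = 90, pp_center = NULL,
                         fractions = c("7" = 1.0), score_noise_sd = 0,
                         geom_noise_sd = 0, n_poses = 100L) {
  stopifnot(pocket_radius > 0, shell_atoms > 3,
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0),
            score_noise_sd >= 0, geom_noise_sd >= 0, n_poses >= 1)
  structure(list(seed = as.integer(seed), pocket_radius = pocket_radius,
                 shell_atoms = as.integer(shell_atoms),
                 base_polar_angle = base_polar_angle, pp_center = pp_center,
                 fractions = fractions, score_noise_sd = score_noise_sd,
                 geom_noise_sd = geom_noise_sd, n_poses = as.integer(n_poses)),
            class = "fixture_spec")
}

# deterministic quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a toy pocket-shell receptor
#'
#' A spherical shell of carbon pseudo-atoms (residues numbered from 1) of
#' radius `pocket_radius + 1.6` around the origin, one inward-pointing
#' residue-723 probe (backbone N/CA plus CB on the pocket axis set by
#' `base_polar_angle`; hydroxyl OG1/HG1 and methyl CG2 added for variant "T",
#' OG/HG for "S", bare CB for "A"), and -- unless `spec$pp_center` is `NULL`
#' -- the rigid pyrophosphate--magnesium cluster centered there. Seeded shell
#' jitter; identical site topology across seeds.
#'
#' @param spec a [fixture_spec]; @param variant residue 723 identity.
#' @return a `receptor` (PDB-serialisable via [write_receptor_pdb]).
#' @export
make_toy_receptor <- function(spec = fixture_spec(), variant = "T") {
  stopifnot(variant %in% c("A", "S", "T"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rshell <- spec$pocket_radius + 1.6
  dirs <- fibonacci_sphere(spec$shell_atoms)
  jitter <- matrix(rnorm(3 * spec$shell_atoms, sd = 0.15), ncol = 3)
  shell <- dirs * rshell + jitter
  th <- spec$base_polar_angle * pi / 180
  u <- c(sin(th), 0, cos(th))              # outward pocket axis of the probe
  # drop shell atoms too close to the probe stalk so the site stays open
  keep <- sqrt(rowSums((shell - outer(rep(1, nrow(shell)), rshell * u))^2)) > 3.0
  shell <- shell[keep, , drop = FALSE]
  atoms <- data.frame(serial = seq_len(nrow(shell)), name = "CA",
                      resname = "GLY", resno = seq_len(nrow(shell)),
                      element = "C", x = shell[, 1], y = shell[, 2],
                      z = shell[, 3], stringsAsFactors = FALSE)
  ca <- (rshell + 0.4) * u
  nb <- ca + 1.45 * orth_any(u)
  cb <- ca - 1.53 * u                       # side chain protrudes into the pocket
  newres <- c(A = "ALA", S = "SER", T = "THR")[[variant]]
  add <- function(nm, el, xyz) {
    atoms <<- rbind(atoms, data.frame(serial = max(atoms$serial) + 1L, name = nm,
                                      resname = newres, resno = 723L, element = el,
                                      x = xyz[1], y = xyz[2], z = xyz[3]))
  }
  add("N", "N", nb); add("CA", "C", ca); add("CB", "C", cb)
  if (variant %in% c("S", "T")) {
    og <- cb - 1.43 * u
    hg <- og - 0.96 * u
    add(if (variant == "T") "OG1" else "OG", "O", og)
    add(if (variant == "T") "HG1" else "HG", "H", hg)
    if (variant == "T") add("CG2", "C", nerf_place(nb, ca, cb, 1.53, 109.5, -60))
  }
  r7 <- atoms$resno == 723
  find7 <- function(nm) { i <- which(r7 & atoms$name == nm); if (length(i)) i[1] else NA_integer_ }
  base_o <- if (variant == "T") find7("OG1") else if (variant == "S") find7("OG") else NA_integer_
  base_h <- if (variant == "T") find7("HG1") else if (variant == "S") find7("HG") else NA_integer_
  tip <- if (!is.na(base_o)) base_o else find7("CB")
  pp <- NULL
  if (!is.null(spec$pp_center)) {
    ref <- pp_mg_coords()
    pp <- sweep(sweep(ref, 2, colMeans(ref)), 2, spec$pp_center, `+`)
  }
  receptor_obj(atoms, pocket = list(center = c(0, 0, 0), radius = spec$pocket_radius),
               variant = variant,
               sites = list(base_o = base_o, base_h = base_h, tip = tip), pp = pp)
}

#' Generate a star-shaped toy cation with a prescribed alpha-proton census
#'
#' The cation center C1 is bonded to one alpha carbon per census entry; each
#' alpha carbon carries the requested hydrogens, with methyl groups filling
#' its remaining valence. Census entries must be 0--3 and at most 3 alpha
#' carbons are allowed (the center is trivalent); short censuses are padded
#' with hydrogen-free neopentyl-type neighbors.
#'
#' @param census integer vector, hydrogens per alpha carbon
#'   (e.g. `c(2, 2, 1)` mimics the C7/C14/C9 census of the isopimarenyl cation).
#' @param seed seed for the single returned conformer.
#' @return list(graph = [cation_graph], library = single-member
#'   `conformer_library`).
#' @export
make_toy_cation <- function(census, seed = 1L) {
  stopifnot(length(census) >= 1)
  if (length(census) > 3) stop("cation center is trivalent: at most 3 alpha carbons")
  if (any(census < 0 | census > 3)) stop("chemically impossible census: 0-3 H per alpha carbon")
  census <- as.integer(census)
  heavy <- data.frame(name = "C1", element = "C")
  hb <- list()
  hc <- list(C1 = 0L)
  nxt <- 1L
  newc <- function() { nxt <<- nxt + 1L; nm <- paste0("C", nxt)
    heavy <<- rbind(heavy, data.frame(name = nm, element = "C")); nm }
  alphas <- character(length(census))
  for (k in seq_along(census)) {
    an <- newc(); alphas[k] <- an
    hb[[length(hb) + 1L]] <- c("C1", an, "1")
    hc[[an]] <- census[k]
    for (m in seq_len(3L - census[k])) {   # fill valence with methyls
      mn <- newc()
      hb[[length(hb) + 1L]] <- c(an, mn, "1")
      hc[[mn]] <- 3L
    }
  }
  for (pad in seq_len(3L - length(census))) {  # hydrogen-free padding neighbors
    qn <- newc()
    hb[[length(hb) + 1L]] <- c("C1", qn, "1")
    hc[[qn]] <- 0L
    for (m in 1:3) {
      mn <- newc()
      hb[[length(hb) + 1L]] <- c(qn, mn, "1")
      hc[[mn]] <- 3L
    }
  }
  g <- assemble_species(heavy, hb, hc, "C1", paste0("toy[", paste(census, collapse = ","), "]"))
  lib <- generate_conformers(g, 1L, seed = seed)
  list(graph = g, library = lib, alpha_carbons = alphas)
}

rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
align_rotation <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- pracma_cross(a, b); c0 <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c0 > 0) return(diag(3))
    p <- orth_any(a)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

#' Plant pose sets with known truth labels and controlled scores
#'
#' For deprotonation products, each pose is rigidly placed so that the
#' hydrogen of its planted product satisfies the classification gate exactly:
#' the C-H bond is aligned onto the inward base-hydroxyl axis with
#' O(base)...H = 2.0 Angstrom (angle 180 degrees). For the water-addition
#' epimers ("6a"/"6b"), the ligand is kept at the pocket center and the water
#' oxygen planted 2.9 Angstrom off the corresponding prochiral face of C13.
#' Per-ligand constraint scores, total scores and interface energies are
#' drawn from simple configurable distributions so filter-cascade behavior is
#' controllable; planted fraction counts are exact (largest-remainder
#' apportionment, then a seeded shuffle).
#'
#' @param receptor a `receptor` with a base hydroxyl (for deprotonation
#'   planting); @param g the planted species' [cation_graph];
#' @param lib its `conformer_library`; @param spec a [fixture_spec]
#'   (`n_poses`, `fractions`, `score_noise_sd`, `seed`).
#' @param cst_fail_fraction fraction of poses given a per-ligand constraint
#'   score >= 1 (they fail cascade stage 1).
#' @return list(poses = scored poses, truth = character labels).
#' @export
plant_poses <- function(receptor, g, lib, spec = fixture_spec(),
                        cst_fail_fraction = 0) {
  n <- spec$n_poses
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  # exact largest-remainder apportionment of the planted fractions
  fr <- spec$fractions
  base_cnt <- floor(fr * n)
  rem <- n - sum(base_cnt)
  if (rem > 0) {
    extra <- order(fr * n - base_cnt, decreasing = TRUE)[seq_len(rem)]
    base_cnt[extra] <- base_cnt[extra] + 1
  }
  truth <- sample(rep(names(fr), times = base_cnt))
  sites <- if (!is.na(g$cation_center)) enumerate_deprotonation_sites(g) else NULL
  products <- if (!is.null(sites)) enumerate_olefin_products(g, sites) else NULL
  xyz <- lib$conformers[[1]]$coords
  ctr <- colMeans(xyz)
  poses <- vector("list", n)
  n_fail <- round(cst_fail_fraction * n)
  fail_idx <- if (n_fail) sample.int(n, n_fail) else integer(0)
  for (i in seq_len(n)) {
    lab <- truth[i]
    if (lab %in% c("6a", "6b")) {
      quat <- c(1, 0, 0, 0); trans <- ctr
      sref <- xyz[c("C12", "C14", "C15"), , drop = FALSE]
      nrm <- unitv(pracma_cross(sref[2, ] - sref[1, ], sref[3, ] - sref[1, ]))
      sgn <- if (lab == "6a") 1 else -1
      water <- xyz["C13", ] + sgn * 2.9 * nrm
    } else {
      s <- which(products$product_id == lab)[1]
      if (is.na(s)) stop("planted product has no deprotonation site: ", lab)
      hn <- sites$hydrogen_name[s]; cn <- sites$carbon_name[s]
      bo <- receptor_site_xyz(receptor, "base:O")
      w_in <- unitv(receptor$pocket$center - bo)
      R <- align_rotation(xyz[cn, ] - xyz[hn, ], w_in)
      h_target <- bo + 2.0 * w_in
      quat <- rot_to_quat(R)
      trans <- h_target - as.numeric(R %*% (xyz[hn, ] - ctr))
      water <- NULL
    }
    if (spec$geom_noise_sd > 0)
      trans <- trans + rnorm(3, sd = spec$geom_noise_sd)
    cstv <- abs(rnorm(1, sd = 0.2))
    if (spec$score_noise_sd > 0) cstv <- cstv + abs(rnorm(1, sd = spec$score_noise_sd))
    cstv <- min(cstv, 0.999)
    if (i %in% fail_idx) cstv <- 1 + abs(rnorm(1, sd = 0.5))
    poses[[i]] <- list(pose_id = sprintf("planted_%05d", i), conformer_id = 1L,
                       quat = quat, trans = as.numeric(trans), water = water,
                       set_id = "planted",
                       cst_scores = c(carbocation = cstv),
                       total_score = rnorm(1), interface_energy = rnorm(1))
  }
  list(poses = poses, truth = truth)
}

#' Build a mechanistically consistent snug pocket for a docked species
#'
#' Generates a reference conformer, places it (unrotated) at the origin, and
#' builds an active site organised around that one reactive orientation, the
#' way a closed terpene synthase pocket hugs its substrate: a molecular-
#' surface wall of carbon pseudo-atoms offset `wall_offset` Angstrom from the
#' reference ligand surface, a hydroxyl probe seated on the extension of the
#' first C7-H bond (so the probe sits on the planted C7-proton approach
#' vector), the pyrophosphate cluster with its anchor oxygen OT1 placed 3.5
#' Angstrom beyond C16, and a single water-sized bulge carved into the wall
#' on the alpha (6a) face of C13. In this pocket the reactant-water
#' restraints are geometrically satisfiable only for orientations close to
#' the reference one -- the feature the with-water docking experiments probe.
#'
#' @param species built-in species key (default "A").
#' @param seed generator seed; @param n_conformers library size.
#' @param wall_offset wall distance from the ligand surface, Angstrom.
#' @param wall_spacing approximate wall pseudo-atom spacing, Angstrom.
#' @return list(receptor, graph, library, ref_coords).
#' @export
make_consistent_pocket <- function(species = "A", seed = 1L, n_conformers = 3L,
                                   wall_offset = 3.0, wall_spacing = 1.5) {
  g <- load_species(species)
  lib <- generate_conformers(g, n_conformers, seed = seed)
  xyz <- lib$conformers[[1]]$coords
  xyz <- sweep(xyz, 2, colMeans(xyz))      # reference ligand at the origin
  lig_extent <- max(sqrt(rowSums(xyz^2)))
  sites <- enumerate_deprotonation_sites(g)
  s7 <- which(sites$carbon_name == "C7")[1]
  hn <- sites$hydrogen_name[s7]
  probe_dir <- unitv(xyz[hn, ] - xyz["C7", ])
  bo <- xyz[hn, ] + 2.0 * probe_dir        # probe O on the C7-H extension
  anchor_dir <- unitv(xyz["C16", ] - xyz["C13", ])
  ot1_target <- xyz["C16", ] + 3.5 * anchor_dir
  ppref <- pp_mg_coords()
  pp <- sweep(ppref, 2, ot1_target - ppref["OT1", ], `+`)
  # water bulge on the alpha face of C13 (substituent order C12, C14, C15).
  # Poses satisfying the C7 proton-transfer geometry form a rotation family
  # about the probe axis (the anchor flat bottom tolerates a band of
  # rotations), so the bulge is carved along the arc the face point traces
  # under that family, not at a single spot.
  sref <- xyz[c("C12", "C14", "C15"), , drop = FALSE]
  wat_cav <- xyz["C13", ] + 3.0 * unitv(pracma_cross(
    sref[2, ] - sref[1, ], sref[3, ] - sref[1, ]))
  arc <- t(vapply(seq(-60, 60, by = 15) * pi / 180, function(th) {
    v <- wat_cav - bo; u <- probe_dir
    bo + v * cos(th) + pracma_cross(u, v) * sin(th) + u * sum(u * v) * (1 - cos(th))
  }, numeric(3)))
  # molecular-surface wall: per-atom spheres, outer surface only, deduped;
  # a second layer 1.9 A further out closes the gaps of the first
  dirs <- fibonacci_sphere(48)
  cand <- do.call(rbind, lapply(c(wall_offset, wall_offset + 1.9), function(off)
    do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
      sweep(dirs * off, 2, xyz[i, ], `+`)))))
  dmin <- apply(cand, 1, function(p) min(sqrt(rowSums(sweep(xyz, 2, p)^2))))
  cand <- cand[dmin > wall_offset - 0.1, , drop = FALSE]
  # clear the probe stalk and the water bulge generously, but let the wall
  # hug the cofactor cluster tightly (no water-sized voids around it)
  aux_wide <- rbind(bo, bo + (0.96 + 0.5) * probe_dir, wat_cav, arc)
  d_wide <- apply(cand, 1, function(p) min(sqrt(rowSums(sweep(aux_wide, 2, p)^2))))
  d_pp <- apply(cand, 1, function(p) min(sqrt(rowSums(sweep(pp, 2, p)^2))))
  cand <- cand[d_wide > 2.8 & d_pp > 1.9, , drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cand <- cand[sample(nrow(cand)), , drop = FALSE]   # seeded dedup order
  wall <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!nrow(wall) || min(sqrt(rowSums(sweep(wall, 2, p)^2))) >= wall_spacing)
      wall <- rbind(wall, p)
  }
  atoms <- data.frame(serial = seq_len(nrow(wall)), name = "CA",
                      resname = "GLY", resno = seq_len(nrow(wall)),
                      element = "C", x = wall[, 1], y = wall[, 2],
                      z = wall[, 3], stringsAsFactors = FALSE)
  # residue-723 probe seated on the C7-H axis, side chain pointing inward
  seat <- list(N = bo + (1.43 + 1.53) * probe_dir + 1.45 * orth_any(probe_dir),
               CA = bo + (1.43 + 1.53) * probe_dir,
               CB = bo + 1.43 * probe_dir,
               OG1 = bo, HG1 = bo + 0.96 * orth_any(probe_dir),
               CG2 = bo + 1.43 * probe_dir +
                 1.53 * unitv(orth_any(probe_dir) + 0.5 * probe_dir))
  el <- c(N = "N", CA = "C", CB = "C", OG1 = "O", HG1 = "H", CG2 = "C")
  for (nm in names(seat))
    atoms <- rbind(atoms, data.frame(serial = max(atoms$serial) + 1L, name = nm,
                                     resname = "THR", resno = 723L,
                                     element = el[[nm]], x = seat[[nm]][1],
                                     y = seat[[nm]][2], z = seat[[nm]][3]))
  r7 <- atoms$resno == 723
  find7 <- function(nm) which(r7 & atoms$name == nm)[1]
  rec <- receptor_obj(atoms,
                      pocket = list(center = c(0, 0, 0), radius = lig_extent + 2),
                      variant = "T",
                      sites = list(base_o = find7("OG1"), base_h = find7("HG1"),
                                   tip = find7("OG1")),
                      pp = pp)
  list(receptor = rec, graph = g, library = lib, ref_coords = xyz)
}

#' Write a complete demo workspace of fixtures
#'
#' Emits a toy receptor PDB, the species SDF files, the ten-set constraint
#' file of the deprotonation scan, a JSON run configuration and the planted
#' truth labels -- everything needed to exercise the pipeline end to end.
#'
#' @param dir output directory (created if missing); @param seed seed.
#' @export
write_fixture_workspace <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture_spec(seed = seed, pp_center = c(0, 0, -5))
  rec <- make_toy_receptor(spec, variant = "T")
  write_receptor_pdb(rec, file.path(dir, "toy_receptor.pdb"))
  for (k in c("A", "B")) {
    g <- load_species(k)
    lib <- generate_conformers(g, 1L, seed = seed)
    write_sdf(g, lib$conformers[[1]]$coords, file.path(dir, paste0("species_", k, ".sdf")),
              energy = lib$conformers[[1]]$energy)
  }
  gA <- load_species("A")
  write_constraints(build_deprotonation_sets(gA),
                    file.path(dir, "a723t_depro_scan.cst"))
  toy <- make_toy_cation(c(2, 2, 1), seed = seed)
  pl <- plant_poses(rec, gA, generate_conformers(gA, 1L, seed = seed),
                    fixture_spec(seed = seed, fractions = c("7" = 0.5, "8" = 0.5),
                                 n_poses = 50L))
  jsonlite::write_json(list(seed = seed, truth = pl$truth),
                       file.path(dir, "planted_truth.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(experiment = "a723t_depro_scan", variant = "T",
                            species = "A", n_poses_per_set = 4000, seed = seed),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
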