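# Receptor handling, cofactor placement, pose sampling, scoring and the
# three-stage filter cascade.

test_that("residue-723 grafting adds the hydroxyl and is identity when matched", {
  spec <- fixture_spec(seed = 2, pp_center = c(0, 0, -4))
  recA <- make_toy_receptor(spec, variant = "A")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(recA, f)
  pocket <- list(center = c(0, 0, 0), radius = spec$pocket_radius)
  recT <- load_receptor(f, pocket, variant = "T")
  expect_false(is.na(recT$sites$base_o))
  expect_true(all(c("OG1", "HG1", "CG2") %in%
                    recT$atoms$name[recT$atoms$resno == 723]))
  # hydroxyl O at ideal bond length from CB
  cb <- as.numeric(recT$atoms[recT$atoms$resno == 723 &
                                recT$atoms$name == "CB", c("x", "y", "z")])
  og <- as.numeric(recT$atoms[recT$sites$base_o, c("x", "y", "z")])
  expect_equal(sqrt(sum((og - cb)^2)), 1.43, tolerance = 1e-3)
  # loading at the crystal identity leaves coordinates unchanged
  recA2 <- load_receptor(f, pocket, variant = "A")
  expect_equal(recA2$atoms$x, recA$atoms$x, tolerance = 1e-3)
  expect_true(is.na(recA2$sites$base_o))
  # round-trip: write the loaded receptor again and re-read
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(recT, f2)
  recT2 <- load_receptor(f2, pocket, variant = "T")
  expect_equal(recT2$atoms$x, recT$atoms$x, tolerance = 1e-3)
  expect_equal(recT2$atoms$name, recT$atoms$name)
  expect_equal(unname(recT2$pp), unname(recT$pp), tolerance = 1e-3)
})

test_that("missing residue 723 is reported by name", {
  spec <- fixture_spec(seed = 2)
  rec <- make_toy_receptor(spec, variant = "A")
  rec$atoms <- rec$atoms[rec$atoms$resno != 723, ]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(rec, f)
  expect_error(load_receptor(f, list(center = c(0, 0, 0), radius = 8), "T"),
               "723")
})

test_that("cofactor grid placement finds the planted cavity and refines monotonically", {
  spec <- fixture_spec(seed = 6, pocket_radius = 6, shell_atoms = 60)
  rec <- make_toy_receptor(spec, variant = "T")   # no pp placed
  # plant an attractor: restrain the bridging oxygen near a chosen point
  target <- c(2, 1, -2)
  rec2 <- rec
  rec2$atoms <- rbind(rec2$atoms,
                      data.frame(serial = max(rec$atoms$serial) + 1L,
                                 name = "XX", resname = "TGT", resno = 800L,
                                 element = "C", x = target[1], y = target[2],
                                 z = target[3]))
  rcst <- list(flat_bottom_restraint("distance",
                                     list(list(body = "pp_mg", atom = "OB"),
                                          list(body = "receptor", atom = "800:XX")),
                                     2.9, 3.1, 0.2))
  placed1 <- place_cofactors(rec2, docking_config(grid_spacing = 2.0), rcst)
  placed2 <- place_cofactors(rec2, docking_config(grid_spacing = 1.0), rcst)
  expect_false(is.null(placed1$pp))
  # chosen bridging O within one coarse spacing of the planted shell optimum
  expect_lt(abs(sqrt(sum((placed1$pp["OB", ] - target)^2)) - 3.0), 2.0 + 0.2)
  # halving the spacing cannot worsen the achieved penalty (grid is a superset)
  expect_lte(attr(placed2$pp, "penalty"), attr(placed1$pp, "penalty") + 1e-12)
  # fully blocked pocket -> explicit failure
  blocked <- rec
  dense <- as.matrix(expand.grid(x = seq(-5, 5, 2), y = seq(-5, 5, 2),
                                 z = seq(-5, 5, 2)))
  blocked$atoms <- rbind(blocked$atoms,
                         data.frame(serial = max(rec$atoms$serial) + seq_len(nrow(dense)),
                                    name = "CX", resname = "BLK",
                                    resno = 801L, element = "C",
                                    x = dense[, 1], y = dense[, 2], z = dense[, 3]))
  expect_error(place_cofactors(blocked, docking_config(grid_spacing = 2.0)),
               "clash-free")
})

test_that("pose sampling delivers the configured budget, reproducibly", {
  cp <- fx_pocket()
  sets <- build_deprotonation_sets(cp$graph)[1:2]
  cfg <- docking_config(n_poses_per_set = 200, seed = 5)
  pooled <- unlist(lapply(sets, function(cs)
    sample_poses(cp$receptor, cp$library, cs, cfg)), recursive = FALSE)
  expect_length(pooled, 400L)
  expect_equal(anyDuplicated(vapply(pooled, `[[`, "", "pose_id")), 0L)
  again <- unlist(lapply(sets, function(cs)
    sample_poses(cp$receptor, cp$library, cs, cfg)), recursive = FALSE)
  expect_identical(pooled, again)
  other <- sample_poses(cp$receptor, cp$library, sets[[1]],
                        docking_config(n_poses_per_set = 200, seed = 6))
  expect_false(identical(pooled[1:200], other))
  # quaternions are unit and the sampler leaves the global RNG untouched
  qn <- vapply(pooled, function(p) abs(sqrt(sum(p$quat^2)) - 1), 0)
  expect_true(all(qn < 1e-9))
})

test_that("rotation sampling is uniform by the mean-pairwise-dot sanity check", {
  u <- matrix(runif(3 * 10000), ncol = 3)
  qs <- t(apply(u, 1, cationdock:::shoemake_quat))
  dots <- rowSums(qs[seq(1, 9999, by = 2), ] * qs[seq(2, 10000, by = 2), ])
  expect_lt(abs(mean(dots)), 4 / sqrt(length(dots)))
})

test_that("pose scores equal a naive double-loop re-evaluation", {
  toy <- fx_toy221()
  spec <- fixture_spec(seed = 8, pocket_radius = 6, shell_atoms = 40,
                       pp_center = c(0, 0, -3.5))
  rec <- make_toy_receptor(spec, variant = "T")
  sites <- enumerate_deprotonation_sites(toy$graph)
  cs <- build_deprotonation_sets(toy$graph, sites[1, , drop = FALSE],
                                 anchor_atom = "C2")[[1]]
  cfg <- docking_config(n_poses_per_set = 25, seed = 13)
  poses <- sample_poses(rec, toy$library, cs, cfg)
  scored <- score_poses(rec, poses, toy$library, cs, cfg)
  rx <- rbind(as.matrix(rec$atoms[, c("x", "y", "z")]), unname(rec$pp))
  for (p in scored) {
    lig <- pose_ligand_coords(p, toy$library)
    e <- oracle_body_energy(unname(lig), rx)
    # independent restraint total
    cstt <- 0
    for (r in cs$restraints) {
      pts <- lapply(r$members, function(m) {
        if (m$body == "carbocation") lig[m$atom, ]
        else if (m$body == "pp_mg") rec$pp[m$atom, ]
        else as.numeric(rec$atoms[rec$sites$base_o, c("x", "y", "z")])
      })
      x <- if (r$kind == "distance") sqrt(sum((pts[[1]] - pts[[2]])^2)) else {
        v1 <- pts[[1]] - pts[[2]]; v2 <- pts[[3]] - pts[[2]]
        acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }
      cstt <- cstt + oracle_penalty(r$lower, r$upper, r$sd, r$weight, x)
    }
    expect_equal(p$total_score,
                 cfg$w_rep * e[["rep"]] + cfg$w_att * e[["att"]] + cfg$w_cst * cstt,
                 tolerance = 1e-9)
    expect_equal(p$interface_energy,
                 cfg$w_rep * e[["rep"]] + cfg$w_att * e[["att"]],
                 tolerance = 1e-9)
  }
})

test_that("identical poses score identically and far poses have zero contacts", {
  cp <- fx_pocket()
  cs <- build_deprotonation_sets(cp$graph)[[1]]
  cfg <- docking_config(n_poses_per_set = 2, seed = 3)
  ps <- sample_poses(cp$receptor, cp$library, cs, cfg)
  s1 <- score_pose(cp$receptor, ps[[1]], cp$library, cs, cfg)
  s2 <- score_pose(cp$receptor, ps[[1]], cp$library, cs, cfg)
  expect_identical(s1$total_score, s2$total_score)
  far <- ps[[1]]; far$trans <- c(500, 500, 500)
  sf <- score_pose(cp$receptor, far, cp$library, cs, cfg)
  expect_equal(sf$interface_energy, 0)
  expect_gte(sf$total_score, 0)
})

test_that("the filter cascade applies the strict-gate and decile arithmetic", {
  mkpose <- function(i, cst, tot, ife) list(
    pose_id = sprintf("p_%05d", i), conformer_id = 1L, quat = c(1, 0, 0, 0),
    trans = c(0, 0, 0), water = NULL, set_id = "s",
    cst_scores = c(carbocation = cst), total_score = tot, interface_energy = ife)
  set.seed(77)
  n <- 4000
  poses <- lapply(seq_len(n), function(i)
    mkpose(i, runif(1, 0, 0.99), rnorm(1), rnorm(1)))
  out <- filter_cascade(poses, docking_config())
  expect_equal(out$trace, list(n0 = 4000L, n1 = 4000L, k1 = 400L, k2 = 40L))
  expect_length(out$poses, 40L)
  # survivors are the lowest-interface subset of the lowest-total subset
  tot <- vapply(poses, `[[`, 0, "total_score")
  keep1 <- poses[order(tot)][1:400]
  ife <- vapply(keep1, `[[`, 0, "interface_energy")
  expect_setequal(vapply(out$poses, `[[`, "", "pose_id"),
                  vapply(keep1[order(ife)][1:40], `[[`, "", "pose_id"))
  # all-violating input dies at stage 1
  bad <- lapply(poses, function(p) { p$cst_scores <- c(carbocation = 1.0); p })
  expect_equal(filter_cascade(bad, docking_config())$trace$n1, 0L)
  # empty input
  expect_equal(filter_cascade(list(), docking_config())$trace,
               list(n0 = 0L, n1 = 0L, k1 = 0L, k2 = 0L))
})

test_that("cascade counts follow max(1, floor(p*.)) for random sizes and resist shuffling", {
  mkpose <- function(i) list(
    pose_id = sprintf("p_%05d", i), conformer_id = 1L, quat = c(1, 0, 0, 0),
    trans = c(0, 0, 0), water = NULL, set_id = "s",
    cst_scores = c(carbocation = 0), total_score = rnorm(1),
    interface_energy = rnorm(1))
  set.seed(101)
  for (n in sample(1:5000, 8)) {
    poses <- lapply(seq_len(n), mkpose)
    out <- filter_cascade(poses, docking_config())
    k1 <- max(1L, floor(0.10 * n)); k2 <- max(1L, floor(0.10 * k1))
    expect_equal(out$trace$k1, k1)
    expect_equal(out$trace$k2, k2)
    expect_length(out$poses, k2)
    shuf <- filter_cascade(sample(poses), docking_config())
    expect_identical(vapply(shuf$poses, `[[`, "", "pose_id"),
                     vapply(out$poses, `[[`, "", "pose_id"))
  }
})

test_that("per-set seed streams are independent of the set roster", {
  cp <- fx_pocket()
  sets <- build_deprotonation_sets(cp$graph)
  cfg <- docking_config(n_poses_per_set = 50, seed = 9)
  alone <- sample_poses(cp$receptor, cp$library, sets[[3]], cfg)
  after_others <- {
    invisible(sample_poses(cp$receptor, cp$library, sets[[1]], cfg))
    sample_poses(cp$receptor, cp$library, sets[[3]], cfg)
  }
  expect_identical(alone, after_others)
})

test_that("passing poses serialise to a multi-model PDB", {
  cp <- fx_pocket()
  cs <- build_deprotonation_sets(cp$graph)[[1]]
  cfg <- docking_config(n_poses_per_set = 5, seed = 2)
  ps <- sample_poses(cp$receptor, cp$library, cs, cfg)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_poses_pdb(cp$receptor, ps[1:3], cp$library, cp$graph, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), 3L)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3L)
  expect_true(any(grepl("^HETATM.*LIG", lines)))
})
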