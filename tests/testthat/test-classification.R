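# Geometric product classification, water-position taxonomy and tallies.

test_that("noise-free planted poses are classified with full accuracy", {
  cp <- fx_pocket()
  spec <- fixture_spec(seed = 10, fractions = c("7" = 1.0), n_poses = 30)
  pl <- plant_poses(cp$receptor, cp$graph, cp$library, spec)
  labs <- vapply(pl$poses, function(p)
    classify_pose(p, cp$receptor, cp$library, cp$graph), character(1))
  expect_true(all(labs == "7"))
  # mixture over all three olefins recovers every planted label
  spec3 <- fixture_spec(seed = 11, fractions = c("7" = 0.4, "8" = 0.4, "10" = 0.2),
                        n_poses = 60)
  pl3 <- plant_poses(cp$receptor, cp$graph, cp$library, spec3)
  labs3 <- vapply(pl3$poses, function(p)
    classify_pose(p, cp$receptor, cp$library, cp$graph), character(1))
  expect_identical(labs3, pl3$truth)
})

test_that("poses with no hydrogen inside the gate are unassigned", {
  cp <- fx_pocket()
  pl <- plant_poses(cp$receptor, cp$graph, cp$library,
                    fixture_spec(seed = 3, fractions = c("7" = 1), n_poses = 1))
  p <- pl$poses[[1]]
  p$trans <- p$trans + c(30, 0, 0)   # move everything far from the probe
  expect_identical(classify_pose(p, cp$receptor, cp$library, cp$graph),
                   "unassigned")
})

test_that("random rigid poses agree with the exhaustive per-hydrogen oracle", {
  cp <- fx_pocket()
  g <- cp$graph
  sites <- enumerate_deprotonation_sites(g)
  products <- enumerate_olefin_products(g, sites)
  bo <- cationdock:::receptor_site_xyz(cp$receptor, "base:O")
  set.seed(17)
  n_match <- 0L
  for (k in 1:500) {
    p <- list(pose_id = "r", conformer_id = 1L,
              quat = { q <- rnorm(4); q / sqrt(sum(q^2)) },
              trans = bo + rnorm(3, sd = 3), water = NULL, set_id = "r")
    lig <- pose_ligand_coords(p, cp$library)
    expect_identical(classify_pose(p, cp$receptor, cp$library, g),
                     oracle_classify(lig, bo, sites, products))
    if (classify_pose(p, cp$receptor, cp$library, g) != "unassigned")
      n_match <- n_match + 1L
  }
  expect_gt(n_match, 0L)   # the random cloud does produce assigned poses
})

test_that("water location takes the nearest labeled oxygen within the cutoff", {
  cp <- fx_pocket()
  rec <- cp$receptor
  mk <- function(w) list(pose_id = "w", conformer_id = 1L, quat = c(1, 0, 0, 0),
                         trans = c(0, 0, 0), water = w, set_id = "w")
  ob <- rec$pp["OB", ]
  near_ob <- ob + 3.0 * unitv_test(ob - rec$pp["OT2", ])
  expect_identical(classify_water_location(mk(near_ob), rec),
                   oracle_water_label(near_ob, rec$pp))
  far <- ob + c(10, 10, 10)
  expect_identical(classify_water_location(mk(far), rec), "none")
  expect_error(classify_water_location(mk(NULL), rec), "no water")
  set.seed(23)
  for (k in 1:200) {
    w <- rec$pp["OB", ] + rnorm(3, sd = 4)
    expect_identical(classify_water_location(mk(w), rec),
                     oracle_water_label(w, rec$pp))
  }
})

test_that("epimer classification flips under mirror reflection", {
  gB <- fx_species_B()
  libB <- fx("libB", function() generate_conformers(fx_species_B(), 1L, seed = 6))
  xyz <- libB$conformers[[1]]$coords
  sref <- xyz[c("C12", "C14", "C15"), ]
  nrm <- unitv_test(cross_test(sref[2, ] - sref[1, ], sref[3, ] - sref[1, ]))
  mk <- function(w) list(pose_id = "e", conformer_id = 1L, quat = c(1, 0, 0, 0),
                         trans = colMeans(xyz), water = w, set_id = "e")
  expect_identical(classify_epimer(mk(xyz["C13", ] + 2.9 * nrm), libB), "6a")
  expect_identical(classify_epimer(mk(xyz["C13", ] - 2.9 * nrm), libB), "6b")
})

test_that("planted epimer mixtures are recovered exactly by the tally", {
  cp <- fx_pocket()
  gB <- fx_species_B()
  libB <- fx("libB", function() generate_conformers(fx_species_B(), 1L, seed = 6))
  spec <- fixture_spec(seed = 19, fractions = c("6a" = 0.7, "6b" = 0.3),
                       n_poses = 200)
  pl <- plant_poses(cp$receptor, gB, libB, spec)
  labs <- vapply(pl$poses, function(p) classify_epimer(p, libB), character(1))
  expect_identical(labs, pl$truth)
  rep <- tally_outcomes(labs)
  expect_equal(rep$counts[["6a"]], 140L)
  expect_equal(rep$counts[["6b"]], 60L)
  expect_equal(rep$rendered[["6a"]], "140/200")
  expect_identical(rep$majority, "6a")
})

test_that("tallies render counts, majorities and conserve the denominator", {
  labs <- c(rep("7", 22), rep("8", 20))
  rep1 <- tally_outcomes(labs)
  expect_equal(rep1$rendered[["7"]], "22/42")
  expect_identical(rep1$majority, "7")
  expect_equal(sum(unlist(rep1$counts)), rep1$denominator)
  empty <- tally_outcomes(character(0))
  expect_equal(empty$denominator, 0L)
  expect_true(is.na(empty$majority))
  set.seed(5)
  for (k in 1:10) {
    ls <- sample(c("7", "8", "10", "unassigned"), sample(1:300, 1), replace = TRUE)
    rp <- tally_outcomes(ls)
    expect_equal(sum(unlist(rp$counts)), length(ls))
    ht <- table(ls)
    for (nm in names(ht)) expect_equal(rp$counts[[nm]], unname(as.integer(ht[nm])))
  }
})

test_that("fully satisfied restraints imply agreement with the set hypothesis", {
  # a pose with zero constraint score for a C7 deprotonation set must
  # classify as the hypothesised product
  cp <- fx_pocket()
  pl <- plant_poses(cp$receptor, cp$graph, cp$library,
                    fixture_spec(seed = 29, fractions = c("7" = 1), n_poses = 10))
  sets <- build_deprotonation_sets(cp$graph)
  cs7 <- Filter(function(s) s$product_hypothesis == "7" && s$anchor == "OT1", sets)[[1]]
  # keep only the deprotonation-geometry restraints (the planted poses make
  # no promise about the pyrophosphate anchor)
  depro_only <- constraint_set("depro_only",
                               Filter(function(r) !any(vapply(r$members,
                                 function(m) m$body == "pp_mg", logical(1))),
                                 cs7$restraints))
  hit <- 0L
  for (p in pl$poses) {
    lig <- pose_ligand_coords(p, cp$library)
    lookup <- cationdock:::pose_lookup(cp$receptor, lig)
    sc <- ligand_constraint_score(lookup, depro_only)
    expect_lt(max(sc), 1e-6)   # planting satisfies the hypothesised geometry
    expect_identical(classify_pose(p, cp$receptor, cp$library, cp$graph), "7")
    hit <- hit + 1L
  }
  expect_equal(hit, 10L)
})
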