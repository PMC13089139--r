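# Flat-bottom restraints and the mechanistic constraint sets.

test_that("the deprotonation scan for species A yields exactly ten sets", {
  g <- fx_species_A()
  sets <- build_deprotonation_sets(g)
  expect_length(sets, 10L)
  ids <- vapply(sets, `[[`, "", "set_id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(vapply(sets, function(s) length(s$restraints), 0L) == 3L))
  # hypotheses follow the site -> product registry
  hyp <- vapply(sets, `[[`, "", "product_hypothesis")
  expect_setequal(unique(hyp), c("7", "8", "10"))
})

test_that("set count equals sites x anchors for arbitrary fixtures", {
  g <- fx_species_A()
  sites <- enumerate_deprotonation_sites(g)
  set.seed(12)
  for (k in 1:6) {
    ns <- sample(nrow(sites), 1)
    na <- sample(1:3, 1)
    anchors <- paste0("OT", seq_len(na))
    sets <- build_deprotonation_sets(g, sites[seq_len(ns), , drop = FALSE],
                                     anchors = anchors)
    expect_length(sets, ns * na)
    expect_equal(anyDuplicated(vapply(sets, `[[`, "", "set_id")), 0L)
  }
})

test_that("flat-bottom penalty has the documented closed form", {
  r <- flat_bottom_restraint("distance",
                             list(sel_ <- list(body = "water", atom = "O"),
                                  list(body = "carbocation", atom = "C13")),
                             lower = 2.6, upper = 3.4, sd = 0.4, weight = 1)
  for (x in seq(2.6, 3.4, by = 0.1)) expect_equal(restraint_penalty(r, x), 0)
  expect_equal(restraint_penalty(r, 3.4 + 0.4), 1.0)    # one sd out scores 1
  expect_equal(restraint_penalty(r, 2.6 - 0.8), 4.0)
  set.seed(3)
  for (x in runif(50, 0, 8))
    expect_equal(restraint_penalty(r, x), oracle_penalty(2.6, 3.4, 0.4, 1, x))
  # continuity at the edges
  expect_lt(restraint_penalty(r, 3.4 + 1e-7), 1e-10)
})

test_that("water constraints encode the reactive/loose and face semantics", {
  r6a <- build_water_constraints("6a", reactive = TRUE)
  r6b <- build_water_constraints("6b", reactive = TRUE)
  d6a <- r6a[[1]]; d6b <- r6b[[1]]
  expect_equal(c(d6a$lower, d6a$upper), c(d6b$lower, d6b$upper))
  expect_equal(c(d6a$lower, d6a$upper), c(2.6, 3.4))
  expect_identical(r6a[[2]]$face, "alpha")
  expect_identical(r6b[[2]]$face, "beta")
  loose <- build_water_constraints("6a", reactive = FALSE)
  expect_gt(loose[[1]]$upper, d6a$upper)
  expect_equal(loose[[1]]$upper, 5.0)
  expect_equal(restraint_penalty(d6a, d6a$upper + d6a$sd), 1.0)
})

test_that("the wild-type mechanism restraint anchors C7 to residue 723", {
  for (sp in c("A", "B")) {
    rs <- build_wt_mechanism_constraints(sp)
    expect_length(rs, 1L)
    mem <- vapply(rs[[1]]$members, function(m) paste(m$body, m$atom), "")
    expect_setequal(mem, c("carbocation C7", "receptor 723:tip"))
    expect_equal(c(rs[[1]]$lower, rs[[1]]$upper), c(3.5, 5.5))
  }
  expect_equal(restraint_penalty(build_wt_mechanism_constraints("A")[[1]], 4.5), 0)
})

test_that("per-ligand scores match independent re-evaluation on random geometry", {
  g <- fx_species_A()
  sets <- build_deprotonation_sets(g)
  cs <- sets[[1]]
  set.seed(21)
  for (k in 1:20) {
    pts <- list(receptor = list(`base:O` = rnorm(3, sd = 3)),
                carbocation = list(), pp_mg = list(OT1 = rnorm(3, sd = 3)))
    for (r in cs$restraints) for (m in r$members)
      if (m$body == "carbocation" && is.null(pts$carbocation[[m$atom]]))
        pts$carbocation[[m$atom]] <- rnorm(3, sd = 3)
    lookup <- function(body, atom) pts[[body]][[atom]]
    got <- ligand_constraint_score(lookup, cs)
    # independent recomputation: measure each restraint directly
    exp_carb <- 0; exp_pp <- 0
    for (r in cs$restraints) {
      p <- lapply(r$members, function(m) lookup(m$body, m$atom))
      x <- if (r$kind == "distance") sqrt(sum((p[[1]] - p[[2]])^2)) else {
        v1 <- p[[1]] - p[[2]]; v2 <- p[[3]] - p[[2]]
        acos(max(-1, min(1, sum(v1 * v2) /
                           sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }
      pen <- oracle_penalty(r$lower, r$upper, r$sd, r$weight, x)
      bods <- vapply(r$members, `[[`, "", "body")
      if ("carbocation" %in% bods) exp_carb <- exp_carb + pen
      if ("pp_mg" %in% bods) exp_pp <- exp_pp + pen
    }
    expect_equal(unname(got["carbocation"]), exp_carb, tolerance = 1e-12)
    expect_equal(unname(got["pp_mg"]), exp_pp, tolerance = 1e-12)
  }
})

test_that("a pose at one softness unit past the edge fails the strict <1 gate", {
  g <- fx_species_A()
  cs <- build_deprotonation_sets(g)[[1]]
  dist_r <- cs$restraints[[1]]
  hn <- dist_r$members[[2]]$atom
  lookup <- function(body, atom) {
    if (body == "receptor") return(c(0, 0, 0))
    if (body == "carbocation" && atom == hn)
      return(c(dist_r$upper + dist_r$sd, 0, 0))
    if (body == "carbocation") return(c(dist_r$upper + dist_r$sd + 1.09, 0, 0))
    # anchor satisfied: 3.5 A from the C16 stand-in position above
    if (body == "pp_mg") return(c(dist_r$upper + dist_r$sd + 1.09 + 3.5, 0, 0))
    stop("unexpected")
  }
  sc <- ligand_constraint_score(lookup, cs)
  expect_equal(unname(sc["carbocation"]), 1.0, tolerance = 1e-9)
  # nudged an ulp-safe hair past the softness unit, the strict gate fails
  lookup2 <- function(body, atom) {
    p <- lookup(body, atom)
    if (body == "carbocation" && atom == hn)
      p[1] <- dist_r$upper + dist_r$sd * 1.000001
    p
  }
  sc2 <- ligand_constraint_score(lookup2, cs)
  expect_false(all(sc2 < 1))
})

test_that("constraint files round-trip through the text format", {
  g <- fx_species_A()
  sets <- c(build_deprotonation_sets(g),
            list(constraint_set("wat", build_water_constraints("6b", FALSE),
                                water_mode = "loose_6b")))
  f <- withr::local_tempfile(fileext = ".cst")
  write_constraints(sets, f)
  back <- read_constraints(f)
  expect_length(back, length(sets))
  for (k in seq_along(sets)) {
    expect_identical(back[[k]]$set_id, sets[[k]]$set_id)
    expect_identical(back[[k]]$water_mode, sets[[k]]$water_mode)
    for (j in seq_along(sets[[k]]$restraints)) {
      a <- sets[[k]]$restraints[[j]]; b <- back[[k]]$restraints[[j]]
      expect_equal(c(a$lower, a$upper, a$sd, a$weight),
                   c(b$lower, b$upper, b$sd, b$weight))
      expect_identical(a$kind, b$kind)
      expect_identical(a$members, b$members)
    }
  }
})

test_that("experiment recipes emit the documented set collections", {
  expect_length(experiment_constraint_sets("a723t_depro_scan"), 10L)
  w6a <- experiment_constraint_sets("wt_water_6a")
  expect_length(w6a, 2L)
  expect_true(all(vapply(w6a, `[[`, "", "water_mode") == "reactive_6a"))
  mech <- experiment_constraint_sets("wt_mechanism", species = "A")
  expect_true(all(vapply(mech, function(s)
    any(vapply(s$restraints, function(r)
      any(vapply(r$members, function(m)
        identical(m$atom, "723:tip"), logical(1))), logical(1))), logical(1))))
  expect_error(experiment_constraint_sets("nope"), "unknown experiment")
})
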