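# Shared fixtures, built lazily once per test run.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, fixture_env)) assign(name, builder(), fixture_env)
  get(name, fixture_env)
}

fx_species_A <- function() fx("gA", function() load_species("A"))
fx_species_B <- function() fx("gB", function() load_species("B"))

fx_libA <- function() fx("libA", function()
  generate_conformers(fx_species_A(), 2L, seed = 42L))

fx_toy221 <- function() fx("toy221", function() make_toy_cation(c(2, 2, 1), seed = 5L))

fx_pocket <- function() fx("pocket", function()
  make_consistent_pocket("A", seed = 3L, n_conformers = 2L))

fx_receptor <- function() fx_pocket()$receptor
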