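# Shared fixtures and independent oracles. The oracle implementations here
# are deliberately written as naive direct summations, independent of the
# package's vectorized symmetry path.

# fast scattering tables for tests: direct Mott-Bethe evaluation, no fitting
mb_table <- function(model) build_sfac_table(model, use_fit = FALSE)

# brute-force structure factors: expand every site over every operator and
# sum atom by atom, reflection by reflection
oracle_structure_factors <- function(model, hkl, sfac) {
  s <- s_magnitude(model$cell, hkl)
  Fc <- complex(length.out = nrow(hkl))
  for (site in model$sites) {
    if (site$is_hydrogen) {
      f <- site$nu * sfac[["H+1"]]$fun(s)
    } else {
      fn <- sfac[[site$ion$element]]$fun(s)
      if (site$ion$dZ == 0L) f <- fn
      else f <- site$nu * sfac[[species_label(site$ion)]]$fun(s) + (1 - site$nu) * fn
    }
    for (op in model$ops) {
      x <- as.vector(op$R %*% site$xyz + op$t)
      if (length(site$u) == 1L) {
        dw <- exp(-8 * pi^2 * site$u * s^2)
      } else {
        hp <- hkl %*% op$R
        dw <- exp(-2 * pi^2 * as.vector(isfac:::.aniso_quadform(hp, model$cell) %*% site$u))
      }
      Fc <- Fc + site$occ * f * dw * as.vector(exp(2i * pi * (hkl %*% x)))
    }
  }
  Fc
}

# scale-relative maximum deviation between two complex structure-factor sets
max_rel_dev <- function(Fa, Fb) max(Mod(Fa - Fb)) / max(Mod(Fb))

# plain neutral-atom IAM sum (ionic terms excised entirely)
oracle_iam <- function(model, hkl, sfac) {
  m2 <- model
  m2$sites <- Filter(function(s) !s$is_hydrogen, m2$sites)
  m2$sites <- lapply(m2$sites, function(s) { s$ion <- ion_spec(s$ion$element, 0L); s$nu <- 0; s })
  oracle_structure_factors(m2, hkl, sfac)
}

# small deterministic reflection set for a model
test_hkl <- function(model, d_min = 1.0, n = Inf) {
  hkl <- unique_reflections(model$cell, model$ops, d_min, 15)[, 1:3, drop = FALSE]
  if (nrow(hkl) > n) hkl <- hkl[seq(1, nrow(hkl), length.out = n), , drop = FALSE]
  hkl
}

# memoised expensive fixtures shared across test files (single process)
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) assign(key, fn(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a small converged refinement reused by several tests: ionic pair, 2% noise
refined_pair <- function() fixture("refined_pair", function() {
  m <- make_structure("ionic-pair-P1")
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.05, noise = 0.02, seed = 3)
  data <- simulate_dataset(m, spec)
  set.seed(21)
  start <- isfac:::.perturb_start(m)
  cfg <- refine_config(sump = list(target = 0, sigma = 0.001))
  run <- refine_charges(start, data, cfg)
  list(model = m, data = data, run = run, config = cfg)
})

# converged zwitterion refinement at full resolution, 2% noise
refined_zwitterion <- function() fixture("refined_zwitterion", function() {
  m <- make_structure("toy-zwitterion-P212121")
  spec <- synthetic_spec("toy-zwitterion-P212121", noise = 0.02, seed = 11)
  data <- simulate_dataset(m, spec)
  set.seed(77)
  start <- isfac:::.perturb_start(m)
  cfg <- refine_config(sump = list(target = 0, sigma = 0.001))
  run <- refine_charges(start, data, cfg)
  list(model = m, data = data, start = start, run = run, config = cfg)
})

zwitterion_nu_zero <- function() {
  m <- make_structure("toy-zwitterion-P212121")
  for (j in seq_along(m$sites)) m$sites[[j]]$nu <- 0
  m
}
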