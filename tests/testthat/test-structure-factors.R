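test_that("Debye-Waller factors match hand arithmetic and conventions", {
  cell <- unit_cell(8, 9, 10)
  site0 <- atom_site("C1", ion_spec("C", 0L), c(0.1, 0.2, 0.3), u = 0)
  expect_equal(debye_waller(site0, rbind(c(1, 2, 3), c(5, 0, 1)), cell), c(1, 1))

  # hand evaluation at U_iso = 0.02, s = 0.5
  site <- atom_site("C1", ion_spec("C", 0L), c(0.1, 0.2, 0.3), u = 0.02)
  hkl <- c(8, 0, 0)  # s = 0.5 for a = 8
  expect_equal(debye_waller(site, hkl, cell), exp(-8 * pi^2 * 0.02 * 0.25),
               tolerance = 1e-12)

  # isotropic value filled into a diagonal anisotropic tensor agrees
  aniso <- atom_site("C1", ion_spec("C", 0L), c(0.1, 0.2, 0.3),
                     u = c(0.02, 0.02, 0.02, 0, 0, 0))
  h <- rbind(c(1, 2, 3), c(3, 1, 0), c(0, 0, 4))
  expect_equal(debye_waller(aniso, h, cell), debye_waller(site, h, cell),
               tolerance = 1e-10)

  # indefinite tensor warns but still evaluates
  bad <- atom_site("C1", ion_spec("C", 0L), c(0.1, 0.2, 0.3),
                   u = c(0.02, 0.02, -0.05, 0, 0, 0))
  expect_warning(v <- debye_waller(bad, c(1, 1, 1), cell), "positive semidefinite")
  expect_true(is.finite(v))
})

test_that("a single neutral atom at the origin gives F = f(s) with phase 0", {
  m <- crystal_model(unit_cell(6, 7, 8), symmetry_ops(),
                     list(atom_site("C1", ion_spec("C", 0L), c(0, 0, 0), u = 0)))
  tab <- mb_table(m)
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(1, 1, 3))
  sf <- structure_factors(m, hkl, tab)
  expect_equal(Re(sf$F), mott_bethe(ion_spec("C", 0L), sf$s), tolerance = 1e-12)
  expect_equal(Im(sf$F), rep(0, 3), tolerance = 1e-12)
})

test_that("with all nu = 0 the mixing rule reduces to the neutral IAM sum", {
  m <- zwitterion_nu_zero()
  tab <- mb_table(m)
  hkl <- test_hkl(m, 0.9)
  sf <- structure_factors(m, hkl, tab)
  expect_lt(max_rel_dev(sf$F, oracle_iam(m, hkl, tab)), 1e-10)
})

test_that("symmetry summation equals brute-force P1 expansion per reflection", {
  p21 <- crystal_model(unit_cell(6, 8, 10),
                       symmetry_ops("-X, 1/2+Y, -Z", latt = -1L),
                       list(atom_site("C1", ion_spec("C", -1L), c(0.13, 0.21, 0.34),
                                      nu = 0.2),
                            atom_site("O1", ion_spec("O", -1L), c(0.4, 0.1, 0.6),
                                      u = c(0.02, 0.03, 0.025, 0.002, -0.003, 0.001),
                                      nu = 0.3)))
  fixtures <- list(p21 = p21,
                   p212121 = make_structure("toy-zwitterion-P212121"),
                   pnma = make_structure("framework-Pnma"))
  for (nm in names(fixtures)) {
    m <- fixtures[[nm]]
    tab <- mb_table(m)
    hkl <- test_hkl(m, 1.0, 150)
    sf <- structure_factors(m, hkl, tab)
    expect_lt(max_rel_dev(sf$F, oracle_structure_factors(m, hkl, tab)), 1e-8,
              label = paste("oracle equivalence", nm))
  }
})

test_that("symmetry-equivalent reflections share |F|^2", {
  set.seed(7)
  m <- make_structure("toy-zwitterion-P212121")
  tab <- mb_table(m)
  base <- rbind(c(2, 3, 1), c(1, 4, 2), c(3, 1, 5))
  for (i in seq_len(nrow(base))) {
    h <- base[i, ]
    equivs <- unique(do.call(rbind, lapply(m$ops, function(op)
      rbind(as.integer(h %*% op$R), as.integer(-h %*% op$R)))))
    fsq <- Mod(structure_factors(m, equivs, tab)$F)^2
    expect_lt(diff(range(fsq)) / mean(fsq), 1e-10)
  }
})

test_that("centrosymmetric models give phases 0 or pi", {
  m <- make_structure("framework-Pnma")
  sf <- structure_factors(m, test_hkl(m, 1.2), mb_table(m))
  expect_lt(max(abs(Im(sf$F))) / max(Mod(sf$F)), 1e-10)
})

test_that("analytic derivatives agree with central finite differences", {
  set.seed(42)
  m <- make_structure("toy-zwitterion-P212121")
  m$sites[[4]]$u <- c(0.02, 0.025, 0.018, 0.002, -0.001, 0.003)
  tab <- mb_table(m)
  hkl <- test_hkl(m, 1.0, 40)
  sf <- structure_factors(m, hkl, tab, derivs = TRUE)
  fd_err <- function(setter, val, dF, h = 1e-5) {
    Fp <- structure_factors(setter(m, val + h), hkl, tab)$F
    Fm <- structure_factors(setter(m, val - h), hkl, tab)$F
    max(Mod((Fp - Fm) / (2 * h) - dF)) / max(Mod(dF))
  }
  expect_lt(fd_err(function(m, v) { m$sites[[2]]$xyz[3] <- v; m },
                   m$sites[[2]]$xyz[3], sf$d[[2]]$dx[, 3]), 1e-6)
  expect_lt(fd_err(function(m, v) { m$sites[[3]]$u <- v; m },
                   m$sites[[3]]$u, sf$d[[3]]$du[, 1]), 1e-6)
  expect_lt(fd_err(function(m, v) { m$sites[[4]]$u[5] <- v; m },
                   m$sites[[4]]$u[5], sf$d[[4]]$du[, 5]), 1e-6)
  expect_lt(fd_err(function(m, v) { m$sites[[1]]$nu <- v; m },
                   m$sites[[1]]$nu, sf$d[[1]]$dnu), 1e-6)
  expect_lt(fd_err(function(m, v) { m$sites[[6]]$nu <- v; m },
                   m$sites[[6]]$nu, sf$d[[6]]$dnu), 1e-6)
})

test_that("increasing nu moves low-resolution F towards the ionic curve", {
  m <- crystal_model(unit_cell(8, 8, 8), symmetry_ops(),
                     list(atom_site("Cl1", ion_spec("Cl", -1L), c(0, 0, 0), u = 0)))
  tab <- mb_table(m)
  hkl <- matrix(c(1, 0, 0), 1)  # s = 1/16, low resolution
  s <- s_magnitude(m$cell, hkl)
  direction <- sign(mott_bethe(ion_spec("Cl", -1L), s) -
                    mott_bethe(ion_spec("Cl", 0L), s))
  f_at <- function(nu) { m$sites[[1]]$nu <- nu; Re(structure_factors(m, hkl, tab)$F) }
  vals <- vapply(c(0, 0.25, 0.5, 0.75), f_at, 0)
  expect_true(all(sign(diff(vals)) == direction))
})

test_that("intensities scale linearly and close the simulation loop", {
  m <- make_structure("ionic-pair-P1")
  tab <- mb_table(m)
  hkl <- test_hkl(m, 1.5)
  sf <- structure_factors(m, hkl, tab)
  expect_equal(calc_intensities(m, hkl, 1, tab), Mod(sf$F)^2, tolerance = 1e-12)
  expect_equal(calc_intensities(m, hkl, 2, tab),
               2 * calc_intensities(m, hkl, 1, tab), tolerance = 1e-12)
  expect_error(calc_intensities(m, hkl, 0, tab), "positive")

  # noise-free simulated data regenerate exactly from the generating model
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.5, noise = 0, seed = 4)
  data <- simulate_dataset(m, spec, tab)
  icalc <- calc_intensities(m, as.matrix(data[, c("h", "k", "l")]),
                            attr(data, "scale"), tab)
  expect_equal(data$I, icalc, tolerance = 1e-12)
})
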