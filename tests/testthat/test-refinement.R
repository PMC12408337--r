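test_that("parameter assembly counts scale, coordinates, ADPs and fractions", {
  m1 <- crystal_model(unit_cell(6, 7, 8), symmetry_ops(),
                      list(atom_site("C1", ion_spec("C", -1L), c(0.1, 0.2, 0.3))))
  ap <- assemble_parameters(m1)
  expect_length(ap$par, 6L)                      # scale + xyz + U_iso + nu
  expect_equal(ap$map$kind, c("scale", "x", "x", "x", "u", "nu"))

  m1$sites[[1]]$nu_fixed <- TRUE
  expect_length(assemble_parameters(m1)$par, 5L)

  mz <- make_structure("toy-zwitterion-P212121")
  ap <- assemble_parameters(mz)
  # independent count: every site free (iso): 3 + 1 + 1 each, plus scale
  expect_length(ap$par, 1L + 5L * length(mz$sites))

  # riding mode removes hydrogen coordinates and ADPs but keeps fractions
  ap_r <- assemble_parameters(mz, refine_config(free_h = FALSE))
  n_h <- 5L
  expect_length(ap_r$par, 1L + 5L * (length(mz$sites) - n_h) + n_h)

  expect_error(assemble_parameters(crystal_model(unit_cell(5, 5, 5),
                                                 symmetry_ops(), list())),
               "no sites")
})

test_that("residuals vanish at the generating truth on noise-free data", {
  m <- make_structure("ionic-pair-P1")
  tab <- mb_table(m)
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.3, noise = 0, seed = 2)
  data <- simulate_dataset(m, spec, tab)
  cfg <- refine_config()
  ap <- assemble_parameters(m, cfg, scale = attr(data, "scale"))
  rj <- residuals_jacobian(m, data, cfg, ap$par, ap$map, tab)
  expect_lt(max(abs(rj$r)), 1e-6)
})

test_that("the intensity Jacobian matches central finite differences", {
  m <- make_structure("toy-zwitterion-P212121")
  tab <- mb_table(m)
  spec <- synthetic_spec("toy-zwitterion-P212121", d_min = 1.1, noise = 0.02,
                         seed = 9)
  data <- simulate_dataset(m, spec, tab)
  cfg <- refine_config(sump = list(target = 0, sigma = 0.001))
  ap <- assemble_parameters(m, cfg, scale = attr(data, "scale"))
  rj <- residuals_jacobian(m, data, cfg, ap$par, ap$map, tab)
  h <- 1e-6
  for (i in c(1L,                                          # scale
              which(ap$map$kind == "x")[2],
              which(ap$map$kind == "u")[3],
              which(ap$map$kind == "nu")[1],
              which(ap$map$kind == "nu")[7])) {
    pp <- ap$par; pp[i] <- pp[i] + h
    pm <- ap$par; pm[i] <- pm[i] - h
    fd <- (residuals_jacobian(m, data, cfg, pp, ap$map, tab)$r -
           residuals_jacobian(m, data, cfg, pm, ap$map, tab)$r) / (2 * h)
    expect_lt(max(abs(fd - rj$J[, i])) / max(abs(fd)), 1e-6,
              label = paste("Jacobian column", ap$map$kind[i]))
  }
})

test_that("the total-charge restraint row is built as specified", {
  m <- make_structure("ionic-pair-P1")
  tab <- mb_table(m)
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.3, noise = 0, seed = 2)
  data <- simulate_dataset(m, spec, tab)
  cfg <- refine_config(sump = list(target = 0.1, sigma = 0.02))
  ap <- assemble_parameters(m, cfg, scale = attr(data, "scale"))
  rj <- residuals_jacobian(m, data, cfg, ap$par, ap$map, tab)
  nu_idx <- which(ap$map$kind == "nu")
  dz <- vapply(nu_idx, function(i) m$sites[[ap$map$site[i]]]$ion$dZ, 0L)
  expected <- (0.1 - sum(dz * ap$par[nu_idx])) / 0.02
  expect_equal(rj$r[length(rj$r)], expected, tolerance = 1e-12)
  expect_equal(rj$J[nrow(rj$J), nu_idx], -dz / 0.02, tolerance = 1e-12)
})

test_that("refinement started at the truth converges immediately", {
  m <- make_structure("ionic-pair-P1")
  tab <- mb_table(m)
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.3, noise = 0, seed = 2)
  data <- simulate_dataset(m, spec, tab)
  res <- refine(m, data, refine_config(use_fit = FALSE), tab)
  expect_true(res$converged)
  expect_lt(res$R1, 1e-6)
  expect_lt(res$max_shift_esd, 0.01)
})

test_that("perturbed starts recover the generating charges within 3 esu", {
  fx <- refined_pair()
  expect_true(fx$run$result$converged)
  ch <- extract_charges(fx$run$result)
  truth <- attr(fx$model, "truth")
  i <- match(truth$label, ch$label)
  expect_true(all(abs(ch$dq[i] - truth$dq) <= 3 * ch$esu[i]))
  # accepted steps never increase the weighted sum of squares
  expect_true(all(diff(fx$run$result$wssq_history) <= 1e-9))
  # SUMP keeps the refined model neutral
  expect_lt(abs(sum(ch$dq)), 0.01)
})

test_that("wrong-sign starts flip and reach the right-sign answer", {
  fx <- refined_pair()
  # start with Cl modelled as a cation: nu refines negative, flip recovers
  m_wrong <- fx$model
  m_wrong$sites[[2]]$ion <- ion_spec("Cl", 1L)
  m_wrong$sites[[2]]$nu <- 0.1
  run_wrong <- refine_charges(m_wrong, fx$data, fx$config)
  expect_true("Cl1" %in% run_wrong$flipped)
  ch_wrong <- extract_charges(run_wrong$result)
  ch_right <- extract_charges(fx$run$result)
  expect_equal(ch_wrong$dq, ch_right$dq, tolerance = 1e-4)

  # an all-positive result is left untouched
  fl <- apply_sign_flip(fx$run$model, fx$run$result)
  expect_length(fl$flipped, 0L)
  # a negative fraction beyond tolerance is negated
  res_fake <- fx$run$result
  res_fake$model$sites[[2]]$nu <- -0.11
  res_fake$model$sites[[2]]$ion <- ion_spec("Cl", -1L)
  fl2 <- apply_sign_flip(fx$run$model, res_fake)
  expect_equal(fl2$flipped, "Cl1")
  expect_equal(fl2$model$sites[[2]]$ion$dZ, 1L)
  expect_equal(fl2$model$sites[[2]]$nu, 0.11)
})

test_that("fractions fluctuating about zero are fixed neutral", {
  m <- make_structure("ionic-pair-P1")
  hist <- cbind(Na1 = c(0.30, 0.31, 0.30), Cl1 = c(0.01, -0.02, 0.01))
  fx <- fix_fluctuating_neutral(m, hist, threshold = 0.05)
  expect_equal(fx$fixed, "Cl1")
  expect_true(fx$model$sites[[2]]$nu_fixed)
  expect_equal(fx$model$sites[[2]]$nu, 0)
  expect_false(fx$model$sites[[1]]$nu_fixed)
})

test_that("agreement statistics match hand arithmetic", {
  m <- crystal_model(unit_cell(6, 7, 8), symmetry_ops(),
                     list(atom_site("C1", ion_spec("C", 0L), c(0.1, 0.2, 0.3),
                                    u = 0.02)))
  tab <- mb_table(m)
  hkl <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))
  ic <- calc_intensities(m, hkl, 1, tab)
  # perfect data
  data0 <- reflection_data(hkl[, 1], hkl[, 2], hkl[, 3], ic, rep(0.01, 3))
  rf0 <- r_factors(m, data0, scale = 1, tab)
  expect_equal(rf0$R1, 0, tolerance = 1e-12)
  expect_equal(rf0$wR2, 0, tolerance = 1e-12)
  # perturb one |F| by 10%: hand-computed R1
  ic2 <- ic; ic2[1] <- ic[1] * 1.1^2
  data1 <- reflection_data(hkl[, 1], hkl[, 2], hkl[, 3], ic2, rep(0.01, 3))
  fo <- sqrt(ic2); fc <- sqrt(ic)
  expect_equal(r_factors(m, data1, scale = 1, tab)$R1,
               sum(abs(fo - fc)) / sum(fo), tolerance = 1e-12)
  # GooF undefined when data do not exceed parameters
  expect_true(is.na(r_factors(m, data1, scale = 1, tab, n_par = 3L)$goof))
})

test_that("GooF is near one for correctly weighted synthetic noise", {
  fx <- refined_pair()
  expect_equal(fx$run$result$goof, 1, tolerance = 0.15)
})

test_that("fixing all fractions at zero reproduces conventional refinement", {
  m_ion <- make_structure("ionic-pair-P1")
  tab <- mb_table(m_ion)
  spec <- synthetic_spec("ionic-pair-P1", d_min = 1.2, noise = 0.02, seed = 6)
  # data generated from the neutral model
  m_neutral0 <- m_ion
  for (j in 1:2) { m_neutral0$sites[[j]]$nu <- 0 }
  data <- simulate_dataset(m_neutral0, spec, tab)
  set.seed(31)
  start <- isfac:::.perturb_start(m_neutral0)
  # route 1: ionic assignments with fractions fixed at zero
  m_fix <- start
  for (j in 1:2) { m_fix$sites[[j]]$nu <- 0; m_fix$sites[[j]]$nu_fixed <- TRUE }
  res_fix <- refine(m_fix, data, refine_config(use_fit = FALSE), tab)
  # route 2: plain neutral-species model
  m_iam <- start
  for (j in 1:2) { m_iam$sites[[j]]$ion <- ion_spec(m_iam$sites[[j]]$ion$element, 0L)
                   m_iam$sites[[j]]$nu <- 0 }
  res_iam <- refine(m_iam, data, refine_config(use_fit = FALSE), tab)
  expect_equal(res_fix$model$sites[[2]]$xyz, res_iam$model$sites[[2]]$xyz,
               tolerance = 1e-8)
  expect_equal(res_fix$model$sites[[1]]$u, res_iam$model$sites[[1]]$u,
               tolerance = 1e-8)
  expect_equal(res_fix$scale, res_iam$scale, tolerance = 1e-6)
})

test_that("leave-one-out refinements report stable charges", {
  fx <- refined_pair()
  small <- fx$data[1:30, ]
  rc <- r_complete(fx$run$model, small, fx$config)
  expect_equal(nrow(rc$charges), 30L)
  expect_true(all(is.finite(rc$charges)))
  spread <- rc$charge_stats$max - rc$charge_stats$min
  expect_true(all(spread >= 0))
  # a reflection with (near) zero weight does not move the parameters
  data_w <- fx$data
  data_w$sig[5] <- 1e6
  base <- refine(fx$run$model, data_w, fx$config)
  omit <- refine(fx$run$model, data_w[-5, ], fx$config)
  expect_equal(base$par, omit$par, tolerance = 1e-6)
  # unconverged baselines are refused
  cfg_bad <- fx$config; cfg_bad$max_cycles <- 1L
  m_far <- fx$model; m_far$sites[[2]]$nu <- 0.9
  expect_error(r_complete(m_far, small, cfg_bad), "converge")
})

test_that("resolution truncation inflates uncertainties", {
  fx <- refined_zwitterion()
  scan <- resolution_scan(fx$run$model, fx$data, c(0.75, 1.2), fx$config)
  full <- scan[scan$d_min == 0.75, ]
  cut <- scan[scan$d_min == 1.2, ]
  # the full-resolution row reproduces the baseline refinement
  base_ch <- extract_charges(fx$run$result)
  expect_equal(full$dq[match(base_ch$label, full$label)], base_ch$dq,
               tolerance = 1e-3)
  # fewer data, larger esu for every atom
  expect_true(all(cut$esu > full$esu))
  expect_true(all(cut$n_reflections < full$n_reflections))
})

test_that("mild distance restraints help where proton geometry degrades", {
  # at poor resolution and higher noise the freely refined protons wander off
  # their bonds; restraining them to the generating distances recovers both
  # the geometry and the charges
  m <- make_structure("toy-zwitterion-P212121")
  truth <- attr(m, "truth")
  spec <- synthetic_spec("toy-zwitterion-P212121", noise = 0.05, seed = 11)
  data <- simulate_dataset(m, spec)
  set.seed(77)
  start <- isfac:::.perturb_start(m)
  pairs <- data.frame(
    label_i = c("H1A", "H1B", "H1C", "HA", "HB"),
    label_j = c("N1", "N1", "N1", "C2", "C2"),
    target = c(0.91, 0.91, 0.91, 1.05, 1.05), sigma = 0.02)
  cfg <- refine_config(sump = list(target = 0, sigma = 0.001), d_min = 1.5)
  res_free <- refine(start, data, cfg)
  cfg$distance_restraints <- pairs
  res_restr <- refine(start, data, cfg)
  err <- function(res) {
    ch <- extract_charges(res, force = TRUE)
    mean(abs(ch$dq[match(truth$label, ch$label)] - truth$dq))
  }
  geo <- function(res) {
    labels <- vapply(m$sites, function(s) s$label, "")
    max(vapply(seq_len(nrow(pairs)), function(i) {
      d <- res$model$sites[[match(pairs$label_i[i], labels)]]$xyz -
           res$model$sites[[match(pairs$label_j[i], labels)]]$xyz
      abs(sqrt(sum((d * c(7.5, 9, 11.5))^2)) - pairs$target[i])
    }, 0))
  }
  expect_gt(geo(res_free), 0.1)         # irregular free-proton geometry
  expect_lt(geo(res_restr), 0.06)       # restraints restore the bonds
  expect_lt(err(res_restr), err(res_free))
})

test_that("singular parameterizations are reported, not silently inverted", {
  # a floating origin along the P2(1) screw axis makes y undetermined
  m <- crystal_model(unit_cell(6, 8, 10),
                     symmetry_ops("-X, 1/2+Y, -Z", latt = -1L),
                     list(atom_site("C1", ion_spec("C", 0L), c(0.13, 0.21, 0.34))))
  tab <- mb_table(m)
  spec <- synthetic_spec("one-atom-P1", d_min = 1.2, noise = 0.01, seed = 8)
  hkl <- test_hkl(m, 1.2)
  ic <- calc_intensities(m, hkl, 1, tab)
  data <- reflection_data(hkl[, 1], hkl[, 2], hkl[, 3], ic, pmax(0.01 * ic, 1e-4))
  expect_error(refine(m, data, refine_config(use_fit = FALSE), tab), "singular")
})
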