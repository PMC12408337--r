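## Full-matrix weighted least-squares refinement of scale, coordinates,
## displacement parameters and ionic fractions against reflection
## intensities, with soft restraints entering as extra weighted residual
## rows. Estimated standard uncertainties come from the inverse normal
## matrix scaled by the goodness of fit.

#' Refinement configuration
#'
#' @param weighting `"sigma"` for w = 1/sigma^2(I) (default) or `"shelx"` for
#'   the two-parameter scheme w = 1/(sigma^2 + (aP)^2 + bP) with
#'   P = (max(I_obs,0) + 2 I_calc)/3.
#' @param wpar Parameters (a, b) of the two-parameter scheme.
#' @param max_cycles Cycle cap for the Levenberg--Marquardt loop.
#' @param shift_tol Convergence threshold on max |shift/esd|.
#' @param sump Optional total-charge restraint, `list(target = 0,
#'   sigma = 0.001)`; each free ionic fraction enters with coefficient dZ so
#'   the restrained quantity is the summed partial charge.
#' @param distance_restraints Optional data frame with columns `label_i`,
#'   `label_j`, `target` (Å), `sigma` (Å).
#' @param d_min,d_max Optional resolution cuts applied to the data (Å).
#' @param free_h If `TRUE` hydrogen coordinates and ADPs refine freely (full
#'   iSFAC mode); if `FALSE` hydrogens ride on their parent atom and only
#'   their ionic fraction refines.
#' @param h_adp_factor Riding-hydrogen ADP multiplier.
#' @param scale_start Optional starting scale; estimated by a linear fit when
#'   `NULL`.
#' @param window Scattering-factor fit window ([fit_window()]).
#' @param use_fit Use fitted Cromer--Mann curves (`TRUE`) or direct
#'   Mott--Bethe evaluation.
#' @return Object of class `refine_config`.
#' @export
refine_config <- function(weighting = c("sigma", "shelx"), wpar = c(0, 0),
                          max_cycles = 200L, shift_tol = 0.01,
                          sump = NULL, distance_restraints = NULL,
                          d_min = NULL, d_max = NULL,
                          free_h = TRUE, h_adp_factor = 1.2,
                          scale_start = NULL,
                          window = fit_window(), use_fit = TRUE) {
  weighting <- match.arg(weighting)
  if (shift_tol <= 0) stop("shift_tol must be positive", call. = FALSE)
  if (!is.null(sump)) {
    sump$target <- if (is.null(sump$target)) 0 else sump$target
    sump$sigma <- if (is.null(sump$sigma)) 0.001 else sump$sigma
    if (sump$sigma <= 0) stop("sump sigma must be positive", call. = FALSE)
  }
  if (!is.null(distance_restraints) && any(distance_restraints$sigma <= 0))
    stop("distance restraint sigmas must be positive", call. = FALSE)
  structure(list(weighting = weighting, wpar = wpar,
                 max_cycles = as.integer(max_cycles), shift_tol = shift_tol,
                 sump = sump, distance_restraints = distance_restraints,
                 d_min = d_min, d_max = d_max,
                 free_h = free_h, h_adp_factor = h_adp_factor,
                 scale_start = scale_start,
                 window = window, use_fit = use_fit),
            class = "refine_config")
}

## riding table: for each riding hydrogen, its parent index and fixed
## fractional offset captured from the starting geometry
.riding_table <- function(model, config) {
  if (config$free_h) return(NULL)
  labels <- site_labels(model)
  rows <- list()
  for (j in seq_along(model$sites)) {
    site <- model$sites[[j]]
    if (site$is_hydrogen && !is.null(site$ride_on)) {
      p <- match(site$ride_on, labels)
      if (is.na(p)) stop("riding parent '", site$ride_on, "' not found", call. = FALSE)
      rows[[length(rows) + 1L]] <- list(h = j, parent = p,
                                        offset = site$xyz - model$sites[[p]]$xyz)
    }
  }
  rows
}

#' Assemble the free-parameter vector of a model
#'
#' Ordering: overall scale first, then per site x, y, z (unless fixed or
#' riding), ADP components, and the ionic fraction nu (unless `nu_fixed`).
#'
#' @param model A [crystal_model()].
#' @param config A [refine_config()].
#' @param scale Starting scale stored in slot 1.
#' @return List with `par` (numeric vector) and `map` (data frame with
#'   columns `kind`, `site`, `comp`).
#' @export
assemble_parameters <- function(model, config = refine_config(), scale = 1) {
  if (length(model$sites) == 0L) stop("model has no sites", call. = FALSE)
  riding <- .riding_table(model, config)
  riding_h <- vapply(riding, function(r) r$h, 0L)
  kind <- "scale"; sitei <- 0L; comp <- 0L; par <- scale
  for (j in seq_along(model$sites)) {
    site <- model$sites[[j]]
    rides <- j %in% riding_h
    ## a hydrogen fixed at nu = 0 contributes nothing to the model, so none
    ## of its parameters are determinable
    if (site$is_hydrogen && site$nu_fixed && site$nu == 0) next
    if (!site$xyz_fixed && !rides) {
      kind <- c(kind, rep("x", 3)); sitei <- c(sitei, rep(j, 3)); comp <- c(comp, 1:3)
      par <- c(par, site$xyz)
    }
    if (!rides) {
      nu_ <- length(site$u)
      kind <- c(kind, rep("u", nu_)); sitei <- c(sitei, rep(j, nu_)); comp <- c(comp, seq_len(nu_))
      par <- c(par, site$u)
    }
    ## a neutral species assignment (dZ = 0) has no ionic curve to mix, so
    ## its fraction is not a degree of freedom
    if (!site$nu_fixed && (site$is_hydrogen || site$ion$dZ != 0L)) {
      kind <- c(kind, "nu"); sitei <- c(sitei, j); comp <- c(comp, 1L)
      par <- c(par, site$nu)
    }
  }
  list(par = par,
       map = data.frame(kind = kind, site = sitei, comp = comp,
                        stringsAsFactors = FALSE))
}

## write a parameter vector back into the model; returns list(model, scale).
## Riding offsets are captured from the geometry of `model` as passed in,
## i.e. the starting geometry, before any parameter is applied.
.apply_parameters <- function(model, par, map, config, riding = NULL) {
  if (is.null(riding)) riding <- .riding_table(model, config)
  scale <- par[1]
  for (i in seq_along(par)[-1]) {
    j <- map$site[i]; cc <- map$comp[i]
    switch(map$kind[i],
           x = { model$sites[[j]]$xyz[cc] <- par[i] },
           u = { model$sites[[j]]$u[cc] <- par[i] },
           nu = { model$sites[[j]]$nu <- par[i] })
  }
  for (r in riding) {
    model$sites[[r$h]]$xyz <- model$sites[[r$parent]]$xyz + r$offset
    if (length(model$sites[[r$h]]$u) == 1L && length(model$sites[[r$parent]]$u) == 1L)
      model$sites[[r$h]]$u <- config$h_adp_factor * model$sites[[r$parent]]$u
  }
  list(model = model, scale = scale)
}

.apply_cuts <- function(model, data, config) {
  s <- s_magnitude(model$cell, as.matrix(data[, c("h", "k", "l")]))
  d <- 1 / (2 * s)
  keep <- rep(TRUE, nrow(data))
  if (!is.null(config$d_min)) keep <- keep & d >= config$d_min
  if (!is.null(config$d_max)) keep <- keep & d <= config$d_max
  if (!any(keep)) stop("all reflections excluded by resolution cuts", call. = FALSE)
  data[keep, , drop = FALSE]
}

.weights <- function(data, icalc, config) {
  if (config$weighting == "sigma") {
    1 / data$sig^2
  } else {
    P <- (pmax(data$I, 0) + 2 * icalc) / 3
    1 / (data$sig^2 + (config$wpar[1] * P)^2 + config$wpar[2] * P)
  }
}

#' Weighted residual vector and analytic Jacobian
#'
#' Data rows are \eqn{\sqrt{w}(I_{obs} - I_{calc})}; restraint rows (total
#' charge, distances) are appended scaled by 1/sigma. The Jacobian is the
#' derivative of the residual vector with respect to the free parameters.
#'
#' @param model A [crystal_model()].
#' @param data Reflection data frame (`h k l I sig`), already cut.
#' @param config A [refine_config()].
#' @param par Parameter vector matching `map`.
#' @param map Parameter map from [assemble_parameters()].
#' @param sfac A [build_sfac_table()] table.
#' @return List with `r` (residuals), `J` (Jacobian), `n_data` (number of
#'   data rows) and `model`/`scale` at `par`.
#' @export
residuals_jacobian <- function(model, data, config, par, map, sfac) {
  if (nrow(data) == 0L) stop("no reflections to refine against", call. = FALSE)
  riding <- .riding_table(model, config)
  st <- .apply_parameters(model, par, map, config, riding)
  model <- st$model; scale <- st$scale
  hkl <- as.matrix(data[, c("h", "k", "l")])
  sf <- structure_factors(model, hkl, sfac, derivs = TRUE)
  Fc <- sf$F
  icalc <- scale * Mod(Fc)^2
  w <- .weights(data, icalc, config)
  sw <- sqrt(w)
  npar <- length(par)
  n <- nrow(data)

  ## dI/dp = scale * 2 Re(Conj(F) dF/dp); scale column is |F|^2
  dI <- matrix(0, n, npar)
  dI[, 1] <- Mod(Fc)^2
  for (i in seq_len(npar)[-1]) {
    j <- map$site[i]; cc <- map$comp[i]
    dF <- switch(map$kind[i],
                 x = sf$d[[j]]$dx[, cc],
                 u = sf$d[[j]]$du[, cc],
                 nu = sf$d[[j]]$dnu)
    ## riding hydrogens: chain their geometric response onto the parent
    if (!is.null(riding)) for (r in riding) {
      if (r$parent == j && map$kind[i] == "x")
        dF <- dF + sf$d[[r$h]]$dx[, cc]
      if (r$parent == j && map$kind[i] == "u" && cc == 1L &&
          length(model$sites[[r$h]]$u) == 1L)
        dF <- dF + config$h_adp_factor * sf$d[[r$h]]$du[, 1]
    }
    dI[, i] <- scale * 2 * Re(Conj(Fc) * dF)
  }
  r <- sw * (data$I - icalc)
  J <- -sw * dI

  ## SUMP total-charge restraint row
  if (!is.null(config$sump)) {
    free_nu <- which(map$kind == "nu")
    dz <- vapply(free_nu, function(i) model$sites[[map$site[i]]]$ion$dZ, 0L)
    total <- sum(dz * par[free_nu])
    row <- numeric(npar); row[free_nu] <- -dz / config$sump$sigma
    r <- c(r, (config$sump$target - total) / config$sump$sigma)
    J <- rbind(J, row)
  }
  ## distance restraints (minimum-image, metric-tensor gradient)
  if (!is.null(config$distance_restraints)) {
    labels <- site_labels(model)
    G <- model$cell$G
    for (k in seq_len(nrow(config$distance_restraints))) {
      dr <- config$distance_restraints[k, ]
      i1 <- match(dr$label_i, labels); i2 <- match(dr$label_j, labels)
      if (is.na(i1) || is.na(i2))
        stop("distance restraint references unknown site", call. = FALSE)
      dx <- model$sites[[i1]]$xyz - model$sites[[i2]]$xyz
      dx <- dx - round(dx)
      dist <- sqrt(as.numeric(t(dx) %*% G %*% dx))
      grad <- as.vector(G %*% dx) / dist    # d(dist)/d(x_i1)
      row <- numeric(npar)
      for (cc in 1:3) {
        p1 <- which(map$kind == "x" & map$site == i1 & map$comp == cc)
        p2 <- which(map$kind == "x" & map$site == i2 & map$comp == cc)
        if (length(p1)) row[p1] <- -grad[cc] / dr$sigma
        if (length(p2)) row[p2] <- grad[cc] / dr$sigma
      }
      r <- c(r, (dr$target - dist) / dr$sigma)
      J <- rbind(J, row)
    }
  }
  list(r = as.numeric(r), J = unname(J), n_data = n, model = model, scale = scale)
}

## inverse of the normal matrix for esd/covariance estimation. When the
## matrix has become numerically singular mid-refinement (e.g. a hydrogen
## whose ionic fraction reached zero no longer scatters, so its coordinates
## lose all leverage) a small ridge proportional to the diagonal is added:
## undetermined parameters then carry very large uncertainties instead of
## aborting the run.
.safe_inverse <- function(A) {
  ## Jacobi scaling: parameters carry wildly different units, so invert the
  ## correlation-form matrix and scale back
  d <- sqrt(pmax(diag(A), max(diag(A)) * 1e-12))
  sc <- outer(d, d)
  C <- A / sc
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) {
    ## ridge on the unit diagonal: undetermined directions get large, not
    ## infinite, uncertainties instead of aborting the run
    for (eps in c(1e-10, 1e-8, 1e-6, 1e-4)) {
      Ci <- tryCatch(solve(C + eps * diag(nrow(C))), error = function(e) NULL)
      if (!is.null(Ci)) break
    }
  }
  if (is.null(Ci)) stop("normal matrix could not be inverted", call. = FALSE)
  Ci / sc
}

.estimate_scale <- function(model, data, sfac) {
  icalc1 <- calc_intensities(model, as.matrix(data[, c("h", "k", "l")]), 1, sfac)
  w <- 1 / data$sig^2
  max(sum(w * data$I * icalc1) / sum(w * icalc1^2), 1e-8)
}

#' Full-matrix least-squares refinement
#'
#' Levenberg--Marquardt iteration on the normal equations until
#' max |shift/esd| drops below `config$shift_tol` or the cycle cap is hit.
#' Estimated standard uncertainties are the square roots of the diagonal of
#' the inverse normal matrix scaled by the goodness of fit.
#'
#' @param model A [crystal_model()] providing the starting values.
#' @param data Reflection data frame with columns `h k l I sig`.
#' @param config A [refine_config()].
#' @param sfac Optional scattering-factor table (built if `NULL`).
#' @return Object of class `refine_result`: refined `model`, `scale`, `par`,
#'   `map`, `esd`, `cov`, `R1`, `wR2`, `goof`, `converged`, `cycles`,
#'   `nu_history` (cycle x site matrix), `max_shift_esd`.
#' @export
refine <- function(model, data, config = refine_config(), sfac = NULL) {
  data <- .apply_cuts(model, data, config)
  if (any(data$sig <= 0)) stop("sigma(I) must be positive", call. = FALSE)
  if (is.null(sfac)) sfac <- build_sfac_table(model, config$window, config$use_fit)

  scale0 <- if (is.null(config$scale_start)) .estimate_scale(model, data, sfac)
            else config$scale_start
  ap <- assemble_parameters(model, config, scale = scale0)
  par <- ap$par; map <- ap$map
  if (nrow(data) <= length(par))
    warning("fewer reflections (", nrow(data), ") than parameters (",
            length(par), ")")

  nu_idx <- which(map$kind == "nu")
  nu_hist <- matrix(par[nu_idx], 1, length(nu_idx),
                    dimnames = list(NULL, site_labels(model)[map$site[nu_idx]]))

  rj <- residuals_jacobian(model, data, config, par, map, sfac)
  wssq <- sum(rj$r^2)
  wssq_history <- wssq
  lambda <- 1e-4
  converged <- FALSE
  max_shift_esd <- Inf
  cycles <- 0L

  for (cycle in seq_len(config$max_cycles)) {
    cycles <- cycle
    A <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    dA <- diag(A)
    if (cycle == 1L) {
      ## unit-free singularity check: zero-leverage parameters (e.g. a
      ## floating-origin coordinate) and exact linear dependences
      null_par <- which(dA <= max(dA) * 1e-20)
      if (length(null_par) == 0L) {
        C <- A / sqrt(outer(dA, dA))
        ev <- eigen(C, symmetric = TRUE)
        if (min(ev$values) < 1e-12)
          null_par <- which.max(abs(ev$vectors[, which.min(ev$values)]))
      }
      if (length(null_par) > 0L)
        stop("singular normal matrix; undetermined parameter(s): ",
             paste(sprintf("%s[site %s]",
                           map$kind[null_par],
                           vapply(null_par, function(i) {
                             j <- map$site[i]
                             if (j == 0L) "-" else site_labels(model)[j]
                           }, "")),
                   collapse = ", "), call. = FALSE)
    }
    accepted <- FALSE
    for (try in 1:12) {
      Ad <- A + lambda * diag(dA, nrow(A))
      step <- tryCatch(solve(Ad, -g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      par_new <- par + as.numeric(step)
      rj_new <- residuals_jacobian(model, data, config, par_new, map, sfac)
      wssq_new <- sum(rj_new$r^2)
      if (is.finite(wssq_new) && all(is.finite(rj_new$J)) && wssq_new <= wssq) {
        accepted <- TRUE
        par <- par_new; rj <- rj_new; wssq <- wssq_new
        lambda <- max(lambda / 3, 1e-12)
        break
      }
      lambda <- lambda * 5
    }
    nu_hist <- rbind(nu_hist, par[nu_idx])
    wssq_history <- c(wssq_history, wssq)
    if (!accepted) break
    ## shift/esd from the (safely inverted) undamped normal matrix
    Ai <- .safe_inverse(A)
    dof <- max(length(rj$r) - length(par), 1L)
    esd <- sqrt(pmax(diag(Ai), 0) * wssq / dof)
    max_shift_esd <- max(abs(as.numeric(step)) / pmax(esd, 1e-300))
    if (max_shift_esd < config$shift_tol) { converged <- TRUE; break }
    ## essentially perfect fits drive esd -> 0 and make shift/esd meaningless;
    ## negligible absolute steps count as converged
    if (max(abs(as.numeric(step)) / (1e-8 + abs(par))) < 1e-9) {
      converged <- TRUE; max_shift_esd <- 0; break
    }
  }

  A <- crossprod(rj$J)
  Ai <- .safe_inverse(A)
  dof <- max(length(rj$r) - length(par), 1L)
  cov <- Ai * wssq / dof
  esd <- sqrt(pmax(diag(cov), 0))
  st <- .apply_parameters(model, par, map, config)
  rf <- r_factors(st$model, data, scale = st$scale, sfac = sfac,
                  n_par = length(par), config = config)

  structure(list(model = st$model, scale = st$scale, par = par, map = map,
                 esd = esd, cov = cov,
                 R1 = rf$R1, wR2 = rf$wR2, goof = rf$goof,
                 converged = converged, cycles = cycles,
                 nu_history = nu_hist, max_shift_esd = max_shift_esd,
                 wssq = wssq, wssq_history = wssq_history,
                 n_data = nrow(data), data = data,
                 sfac = sfac, config = config),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> %s after %d cycles (max shift/esd = %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$cycles, x$max_shift_esd))
  cat(sprintf("  R1 = %.4f  wR2 = %.4f  GooF = %s  (%d data, %d parameters)\n",
              x$R1, x$wR2,
              if (is.na(x$goof)) "undefined" else sprintf("%.3f", x$goof),
              x$n_data, length(x$par)))
  invisible(x)
}

#' Crystallographic agreement statistics
#'
#' R1 on |F| (with |F_obs| = sqrt(max(I_obs, 0)/scale)), wR2 on intensities,
#' and the goodness of fit sqrt(sum w (I_o - I_c)^2 / (n_obs - n_par)).
#'
#' @param model A [crystal_model()].
#' @param data Reflection data frame.
#' @param scale Scale factor relating I_obs to |F_calc|^2.
#' @param sfac Optional scattering-factor table.
#' @param n_par Number of refined parameters (for the GooF denominator).
#' @param config A [refine_config()] (for the weighting scheme).
#' @return List with `R1`, `wR2`, `goof` (`NA` when n_obs <= n_par).
#' @export
r_factors <- function(model, data, scale, sfac = NULL, n_par = 0L,
                      config = refine_config()) {
  if (is.null(sfac)) sfac <- build_sfac_table(model, config$window, config$use_fit)
  hkl <- as.matrix(data[, c("h", "k", "l")])
  icalc <- calc_intensities(model, hkl, scale, sfac)
  fobs <- sqrt(pmax(data$I, 0) / scale)
  fcalc <- sqrt(icalc / scale)
  w <- .weights(data, icalc, config)
  R1 <- sum(abs(fobs - fcalc)) / sum(fobs)
  wR2 <- sqrt(sum(w * (data$I - icalc)^2) / sum(w * data$I^2))
  goof <- if (nrow(data) > n_par)
    sqrt(sum(w * (data$I - icalc)^2) / (nrow(data) - n_par)) else NA_real_
  list(R1 = R1, wR2 = wR2, goof = goof)
}

#' Swap wrongly signed ions and restart from the magnitude
#'
#' Sites whose refined ionic fraction is negative beyond `tol` get their
#' charge offset negated and nu reset to |nu|; the caller re-refines. This is
#' the cation/anion robustness protocol: modelling the wrong sign drives nu
#' negative, and the swap recovers the same |charge| from the correct side.
#'
#' @param model A [crystal_model()] (typically `result$model`).
#' @param result A [refine()] result carrying the refined fractions.
#' @param tol Negativity tolerance.
#' @return List with `model` (updated) and `flipped` (labels).
#' @export
apply_sign_flip <- function(model, result, tol = 0.01) {
  flipped <- character()
  for (j in seq_along(model$sites)) {
    site <- result$model$sites[[j]]
    if (site$nu_fixed || site$is_hydrogen) next
    if (site$nu < -tol) {
      model$sites[[j]]$ion <- ion_spec(site$ion$element, -site$ion$dZ)
      model$sites[[j]]$nu <- abs(site$nu)
      flipped <- c(flipped, site$label)
    } else {
      model$sites[[j]]$nu <- site$nu
    }
  }
  list(model = model, flipped = flipped)
}

#' Fix atoms that fluctuate about neutrality
#'
#' Sites whose ionic fraction changes sign across refinement cycles while
#' staying small are set to exactly neutral (`nu = 0`, fixed), mirroring the
#' protocol of unusing the free variable of an atom that fluctuates about 0.
#'
#' @param model A [crystal_model()].
#' @param history Cycle-by-site matrix of nu values (`result$nu_history`).
#' @param threshold Magnitude below which fluctuation counts as neutral.
#' @return List with `model` and `fixed` (labels).
#' @export
fix_fluctuating_neutral <- function(model, history, threshold = 0.05) {
  fixed <- character()
  labels <- colnames(history)
  model_labels <- site_labels(model)
  for (lab in labels) {
    h <- history[, lab]
    h <- h[is.finite(h)]
    if (length(h) < 2L) next
    sign_change <- any(h > 0) && any(h < 0)
    if (sign_change && max(abs(h)) < threshold) {
      j <- match(lab, model_labels)
      model$sites[[j]]$nu <- 0
      model$sites[[j]]$nu_fixed <- TRUE
      ## a neutral hydrogen no longer scatters at all: pin its geometry
      if (model$sites[[j]]$is_hydrogen) model$sites[[j]]$xyz_fixed <- TRUE
      fixed <- c(fixed, lab)
    }
  }
  list(model = model, fixed = fixed)
}

#' Refinement driver with the full charge-assignment protocol
#'
#' Refines, swaps wrongly signed ions and re-refines until stable (at most
#' `max_flips` rounds), then fixes atoms fluctuating about neutrality and
#' re-refines once more if any were fixed.
#'
#' With `nu_starts`, the whole protocol is repeated from each listed ionic
#' fraction starting value (applied to every free site, signs carried by the
#' ion assignment) and the run with the lowest weighted sum of squares is
#' kept. The charge landscape can hold shallow local minima in which pairs
#' of bonded atoms trade compensating charges; restarting from a different
#' fraction escapes them deterministically.
#'
#' @param model Starting [crystal_model()].
#' @param data Reflection data frame.
#' @param config A [refine_config()].
#' @param max_flips Cap on sign-flip rounds.
#' @param fix_neutral Apply the fluctuating-neutral rule.
#' @param nu_starts Optional numeric vector of starting ionic fractions for
#'   the multi-start protocol.
#' @return List with final `result` ([refine_result]), `model`, `flipped`
#'   (all labels ever flipped) and `fixed`.
#' @export
refine_charges <- function(model, data, config = refine_config(),
                           max_flips = 5L, fix_neutral = FALSE,
                           nu_starts = NULL) {
  if (!is.null(nu_starts)) {
    best <- NULL
    for (nu0 in nu_starts) {
      m0 <- model
      for (j in seq_along(m0$sites))
        if (!m0$sites[[j]]$nu_fixed) m0$sites[[j]]$nu <- nu0
      run <- refine_charges(m0, data, config, max_flips, fix_neutral)
      if (is.null(best) || run$result$wssq < best$result$wssq) best <- run
    }
    return(best)
  }
  sfac <- build_sfac_table(model, config$window, config$use_fit)
  result <- refine(model, data, config, sfac)
  all_flipped <- character()
  for (round in seq_len(max_flips)) {
    fl <- apply_sign_flip(model, result)
    if (length(fl$flipped) == 0L) break
    all_flipped <- union(all_flipped, fl$flipped)
    model <- fl$model
    result <- refine(model, data, config, sfac)
  }
  fixed <- character()
  if (fix_neutral) {
    fx <- fix_fluctuating_neutral(result$model, result$nu_history)
    if (length(fx$fixed) > 0L) {
      fixed <- fx$fixed
      model <- fx$model
      result <- refine(model, data, config, sfac)
    }
  }
  list(result = result, model = result$model, flipped = all_flipped,
       fixed = fixed)
}

#' Leave-one-out cross-validation of the refined charges
#'
#' Starting from a converged baseline, each reflection in turn is omitted and
#' the model re-refined; the omitted reflection's cross-validated residual
#' and every atom's partial charge are recorded. The aggregate statistic is
#' an R1-type ratio on |F| using each reflection's omit-refined calculated
#' value.
#'
#' @param model Baseline [crystal_model()].
#' @param data Reflection data frame.
#' @param config A [refine_config()].
#' @return Object of class `rcomplete_result`: `r_complete`, `per_reflection`
#'   (data frame), `charges` (omission x atom matrix of partial charges),
#'   `charge_stats` (per-atom mean, sd, min, max) and the `baseline` result.
#' @export
r_complete <- function(model, data, config = refine_config()) {
  sfac <- build_sfac_table(model, config$window, config$use_fit)
  baseline <- refine(model, data, config, sfac)
  if (!baseline$converged)
    stop("baseline refinement did not converge; r_complete refused", call. = FALSE)
  data <- baseline$data
  n <- nrow(data)
  labels <- site_labels(model)
  loo_config <- config
  loo_config$scale_start <- baseline$scale
  dq <- matrix(NA_real_, n, length(labels), dimnames = list(NULL, labels))
  fo <- sqrt(pmax(data$I, 0) / baseline$scale)
  fc_cv <- numeric(n)
  start_model <- baseline$model
  for (i in seq_len(n)) {
    res_i <- refine(start_model, data[-i, , drop = FALSE], loo_config, sfac)
    ch <- extract_charges(res_i, res_i$model)
    dq[i, ] <- ch$dq[match(labels, ch$label)]
    fc_cv[i] <- sqrt(calc_intensities(res_i$model,
                                      matrix(as.numeric(data[i, c("h", "k", "l")]), 1, 3),
                                      res_i$scale, sfac) / res_i$scale)
  }
  stats <- data.frame(label = labels,
                      mean = colMeans(dq), sd = apply(dq, 2, stats::sd),
                      min = apply(dq, 2, min), max = apply(dq, 2, max))
  structure(list(r_complete = sum(abs(fo - fc_cv)) / sum(fo),
                 per_reflection = data.frame(data,
                                             F_obs = fo, F_calc_cv = fc_cv),
                 charges = dq, charge_stats = stats, baseline = baseline),
            class = "rcomplete_result")
}

#' Partial charges as a function of the high-resolution cut
#'
#' Repeats the refinement for each d_min cut and tabulates every atom's
#' partial charge and its uncertainty. Cuts that leave fewer reflections than
#' parameters are flagged and still refined (with a warning).
#'
#' @param model Starting [crystal_model()].
#' @param data Reflection data frame.
#' @param cuts Numeric vector of d_min values (Å).
#' @param config A [refine_config()].
#' @return Data frame with columns `d_min`, `n_reflections`, `flagged`,
#'   `label`, `dq`, `esu`.
#' @export
resolution_scan <- function(model, data, cuts, config = refine_config()) {
  sfac <- build_sfac_table(model, config$window, config$use_fit)
  out <- list()
  for (cut in cuts) {
    cfg <- config
    cfg$d_min <- cut
    dat_cut <- .apply_cuts(model, data, cfg)
    res <- withCallingHandlers(
      refine(model, dat_cut, cfg, sfac),
      warning = function(w) invokeRestart("muffleWarning"))
    ch <- extract_charges(res, res$model)
    flagged <- nrow(dat_cut) <= length(res$par)
    out[[length(out) + 1L]] <- data.frame(
      d_min = cut, n_reflections = nrow(dat_cut), flagged = flagged,
      label = ch$label, dq = ch$dq, esu = ch$esu)
  }
  do.call(rbind, out)
}
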