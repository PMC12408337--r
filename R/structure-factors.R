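## Kinematical structure factors under the ionic-fraction mixing rule:
##   F(hkl) = sum_{non-H j} (nu_j f_ion + (1 - nu_j) f_neut) T_j e^{2 pi i h x_j}
##          + sum_{H k}      nu_k f_{H+}                     T_k e^{2 pi i h x_k}
## with T the Debye-Waller factor. Analytic derivatives with respect to
## coordinates, displacement parameters and ionic fractions feed the
## full-matrix refinement.

.TWO_PI <- 2 * pi

u6_matrix <- function(u) {
  ## SHELX order U11 U22 U33 U23 U13 U12
  matrix(c(u[1], u[6], u[5],
           u[6], u[2], u[4],
           u[5], u[4], u[3]), 3, 3)
}

#' Debye--Waller factor of one site for given reflections
#'
#' Isotropic: \eqn{\exp(-8\pi^2 U_{iso} s^2)}. Anisotropic (SHELX component
#' order `U11 U22 U33 U23 U13 U12`):
#' \eqn{\exp(-2\pi^2 \sum_{ij} U_{ij} h_i h_j a_i^* a_j^*)}.
#' Both equal 1 when U = 0. A non-positive-semidefinite anisotropic tensor
#' raises a warning but the value is still computed.
#'
#' @param site An [atom_site()].
#' @param hkl Length-3 vector or n x 3 matrix of Miller indices.
#' @param cell A [unit_cell()].
#' @return Numeric vector of factors in (0, 1] (values above 1 are possible
#'   only for indefinite anisotropic tensors).
#' @export
debye_waller <- function(site, hkl, cell) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (length(site$u) == 1L) {
    s <- s_magnitude(cell, h)
    exp(-8 * pi^2 * site$u * s^2)
  } else {
    if (min(eigen(u6_matrix(site$u), symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      warning("anisotropic U of site ", site$label, " is not positive semidefinite")
    q <- .aniso_quadform(h, cell)
    exp(-2 * pi^2 * as.vector(q %*% site$u))
  }
}

## n x 6 matrix of quadratic-form factors multiplying (U11..U12) in the
## anisotropic Debye-Waller exponent
.aniso_quadform <- function(h, cell) {
  as_ <- cell$astar
  cbind(h[, 1]^2 * as_[1]^2,
        h[, 2]^2 * as_[2]^2,
        h[, 3]^2 * as_[3]^2,
        2 * h[, 2] * h[, 3] * as_[2] * as_[3],
        2 * h[, 1] * h[, 3] * as_[1] * as_[3],
        2 * h[, 1] * h[, 2] * as_[1] * as_[2])
}

## mixed scattering factor of a site and its derivative with respect to nu
.site_form_factor <- function(site, s, sfac) {
  if (site$is_hydrogen) {
    fh <- sfac_lookup(sfac, ion_spec("H", 1L))$fun(s)
    list(f = site$nu * fh, dnu = fh)
  } else {
    fneut <- sfac_lookup(sfac, ion_spec(site$ion$element, 0L))$fun(s)
    if (site$ion$dZ == 0L) {
      list(f = fneut, dnu = 0 * s)
    } else {
      fion <- sfac_lookup(sfac, site$ion)$fun(s)
      list(f = site$nu * fion + (1 - site$nu) * fneut, dnu = fion - fneut)
    }
  }
}

#' Structure factors (and analytic derivatives) for a model
#'
#' Sums over the asymmetric unit and the symmetry operators; for operator
#' (R, t) the contribution of a site at x uses the transformed index
#' h' = h R, the phase shift exp(2 pi i h t) and the Debye--Waller factor
#' evaluated at h', which is equivalent to summing over the expanded P1 cell.
#'
#' @param model A [crystal_model()].
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param sfac A [build_sfac_table()] table (built on demand when `NULL`).
#' @param derivs If `TRUE`, per-site complex derivative blocks are returned.
#' @return List with `F` (complex n-vector), `s` (n-vector) and, when
#'   `derivs`, a per-site list `d` with components `dnu` (n), `dx` (n x 3)
#'   and `du` (n x 1 or n x 6).
#' @export
structure_factors <- function(model, hkl, sfac = NULL, derivs = FALSE) {
  if (is.null(sfac)) sfac <- build_sfac_table(model)
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  n <- nrow(h)
  s <- s_magnitude(model$cell, h)
  if (any(s <= 0)) stop("structure factors need s > 0 (remove (0,0,0))", call. = FALSE)

  ops <- model$ops
  Hp <- lapply(ops, function(op) h %*% op$R)
  pht <- lapply(ops, function(op) exp(.TWO_PI * 1i * as.vector(h %*% op$t)))

  Ftot <- complex(n)
  dlist <- if (derivs) vector("list", length(model$sites)) else NULL

  for (j in seq_along(model$sites)) {
    site <- model$sites[[j]]
    ff <- .site_form_factor(site, s, sfac)
    iso <- length(site$u) == 1L
    A <- complex(n)
    dAx <- if (derivs) matrix(0i, n, 3) else NULL
    dAu <- if (derivs) matrix(0i, n, if (iso) 1L else 6L) else NULL
    ## the exponent cap keeps transiently nonphysical (very negative) U
    ## values finite during refinement instead of overflowing to Inf
    if (iso) dw_iso <- exp(pmin(-8 * pi^2 * site$u * s^2, 50))
    for (k in seq_along(ops)) {
      hp <- Hp[[k]]
      geom <- pht[[k]] * exp(.TWO_PI * 1i * as.vector(hp %*% site$xyz))
      if (iso) {
        term <- dw_iso * geom
      } else {
        q <- .aniso_quadform(hp, model$cell)
        term <- exp(pmin(-2 * pi^2 * as.vector(q %*% site$u), 50)) * geom
      }
      A <- A + term
      if (derivs) {
        dAx <- dAx + (.TWO_PI * 1i) * hp * term
        dAu <- dAu + if (iso) matrix(-8 * pi^2 * s^2 * term, n, 1)
                     else (-2 * pi^2) * q * term
      }
    }
    Ftot <- Ftot + site$occ * ff$f * A
    if (derivs) {
      dlist[[j]] <- list(
        dnu = site$occ * ff$dnu * A,
        dx  = site$occ * ff$f * dAx,
        du  = site$occ * ff$f * dAu)
    }
  }
  out <- list(F = Ftot, s = s, hkl = h)
  if (derivs) {
    names(dlist) <- site_labels(model)
    out$d <- dlist
  }
  out
}

#' Calculated structure-factor table
#'
#' @param model A [crystal_model()].
#' @param hkl n x 3 integer matrix.
#' @param sfac Optional [build_sfac_table()] table.
#' @return Data frame with `h k l s Fre Fim Fsq phase` (phase in radians).
#' @export
structure_factor_set <- function(model, hkl, sfac = NULL) {
  sf <- structure_factors(model, hkl, sfac)
  data.frame(h = sf$hkl[, 1], k = sf$hkl[, 2], l = sf$hkl[, 3], s = sf$s,
             Fre = Re(sf$F), Fim = Im(sf$F),
             Fsq = Mod(sf$F)^2, phase = Arg(sf$F))
}

#' Kinematical intensities I = scale * |F|^2
#'
#' @param model A [crystal_model()].
#' @param hkl n x 3 integer matrix.
#' @param scale Positive overall scale factor.
#' @param sfac Optional [build_sfac_table()] table.
#' @return Numeric vector of calculated intensities.
#' @export
calc_intensities <- function(model, hkl, scale = 1, sfac = NULL) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  sf <- structure_factors(model, hkl, sfac)
  scale * Mod(sf$F)^2
}
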