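## Electron scattering factors for neutral atoms and (possibly nonphysical)
## ions, built from the charge-offset Mott-Bethe formula and parametrized in
## Cromer-Mann form for use in structure-factor calculations and SFAC cards.

#' Mott--Bethe prefactor 1/(8 pi^2 a0) in inverse Angstrom
#'
#' The conversion constant between an X-ray form-factor deficit and the
#' electron scattering factor, \eqn{1/(8\pi^2 a_0)} with the Bohr radius
#' \eqn{a_0 = 0.529177210903} Å.
#'
#' @return A length-one numeric, approximately 0.02393366 Å\eqn{^{-1}}.
#' @export
mott_bethe_constant <- function() 1 / (8 * pi^2 * 0.529177210903)

## International Tables for Crystallography Vol. C (1992) 4-Gaussian X-ray
## form-factor coefficients, neutral atoms. Row order: a1..a4, b1..b4, c.
.xray_it92 <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038, Z0 = 1L),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600, Z0 = 6L),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290, Z0 = 7L),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800, Z0 = 8L),
  F  = list(a = c(3.53920, 2.64120, 1.51700, 1.02430),
            b = c(10.2825, 4.29440, 0.261500, 26.1476), c = 0.277600, Z0 = 9L),
  Na = list(a = c(4.76260, 3.17360, 1.26740, 1.11280),
            b = c(3.28500, 8.84220, 0.313600, 129.424), c = 0.676000, Z0 = 11L),
  Al = list(a = c(6.42020, 1.90020, 1.59360, 1.96460),
            b = c(3.03870, 0.742600, 31.5472, 85.0886), c = 1.11510, Z0 = 13L),
  Si = list(a = c(6.29150, 3.03530, 1.98910, 1.54100),
            b = c(2.43860, 32.3337, 0.678500, 81.6937), c = 1.14070, Z0 = 14L),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490, Z0 = 15L),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900, Z0 = 16L),
  Cl = list(a = c(11.4604, 7.19640, 6.25560, 1.64550),
            b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.55740, Z0 = 17L),
  Ca = list(a = c(8.62660, 7.38730, 1.58990, 1.02110),
            b = c(10.4421, 0.659900, 85.7484, 178.437), c = 1.37510, Z0 = 20L)
)

#' Elements with embedded X-ray form factors
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() names(.xray_it92)

.xray_entry <- function(element) {
  entry <- .xray_it92[[element]]
  if (is.null(entry))
    stop("unsupported element '", element, "'; supported: ",
         paste(names(.xray_it92), collapse = ", "), call. = FALSE)
  entry
}

#' Atomic number of a neutral element
#' @param element Element symbol (e.g. `"C"`).
#' @return Integer atomic number.
#' @export
atomic_number <- function(element) .xray_entry(element)$Z0

#' X-ray form factor of a neutral atom
#'
#' Evaluates the embedded International-Tables 4-Gaussian-plus-constant
#' parametrization \eqn{f_X(s) = c + \sum_i a_i \exp(-b_i s^2)} with
#' \eqn{s = \sin\theta/\lambda} in Å\eqn{^{-1}}.
#'
#' @param element Element symbol.
#' @param s Scattering-vector magnitudes (Å\eqn{^{-1}}), `s >= 0`.
#' @return Numeric vector of form-factor values (electrons).
#' @export
xray_form_factor <- function(element, s) {
  if (any(s < 0)) stop("s must be >= 0", call. = FALSE)
  entry <- .xray_entry(element)
  eval_cromer_mann(cromer_mann(entry$a, entry$b, entry$c), s)
}

#' Specify a neutral atom or a charge-offset ion
#'
#' An ion is defined by its element and an integer charge offset `dZ` added to
#' the neutral atomic number in the Mott--Bethe formula: `dZ = +4` for
#' Si\eqn{^{4+}}, `dZ = -1` for C\eqn{^-}, `dZ = 0` for the neutral atom.
#' Nonphysical species such as C\eqn{^+} or O\eqn{^+} are deliberately allowed;
#' they are what makes both charge signs refinable for every atom.
#'
#' @param element Element symbol present in the embedded X-ray table.
#' @param dZ Integer charge offset (signed; 0 for neutral).
#' @return An object of class `ion_spec` with fields `element`, `Z0`, `dZ`.
#' @export
ion_spec <- function(element, dZ = 0L) {
  Z0 <- atomic_number(element)
  dZ <- as.integer(dZ)
  if (length(dZ) != 1L || is.na(dZ)) stop("dZ must be a single integer", call. = FALSE)
  structure(list(element = element, Z0 = Z0, dZ = dZ), class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat(sprintf("<ion_spec> %s  Z0 = %d  dZ = %+d\n", x$element, x$Z0, x$dZ))
  invisible(x)
}

#' Label for an ion species ("C", "C-1", "Si+4", "H+1")
#' @param ion An [ion_spec()].
#' @return Character label.
#' @export
species_label <- function(ion) {
  if (ion$dZ == 0L) ion$element else sprintf("%s%+d", ion$element, ion$dZ)
}

#' Electron scattering factor from the charge-offset Mott--Bethe formula
#'
#' \deqn{f(s) = \frac{1}{8\pi^2 a_0}\,\frac{Z_0 + \Delta Z - f_X(s)}{s^2}}
#' where \eqn{f_X} is the X-ray form factor of the *neutral* atom. For charged
#' species (`dZ != 0`) the factor diverges as \eqn{s \to 0} with the sign of
#' `dZ`; the formula is therefore only evaluated for `s > 0`.
#'
#' @param ion An [ion_spec()].
#' @param s Scattering-vector magnitudes (Å\eqn{^{-1}}), strictly positive.
#' @return Numeric vector of electron scattering-factor values.
#' @export
mott_bethe <- function(ion, s) {
  stopifnot(inherits(ion, "ion_spec"))
  if (any(s <= 0)) stop("mott_bethe requires s > 0 (diverges at s = 0)", call. = FALSE)
  fx <- xray_form_factor(ion$element, s)
  mott_bethe_constant() * (ion$Z0 + ion$dZ - fx) / s^2
}

#' Build a cation/anion pair for sign testing
#'
#' Supports the sign-robustness protocol in which an atom modelled with the
#' wrong charge sign refines to a negative ionic fraction and is then swapped
#' to the opposite ion.
#'
#' @param element Element symbol.
#' @param magnitude Positive integer charge magnitude.
#' @return List with components `cation` and `anion` ([ion_spec()] objects).
#' @export
make_ion_pair <- function(element, magnitude = 1L) {
  magnitude <- as.integer(magnitude)
  if (length(magnitude) != 1L || is.na(magnitude) || magnitude < 1L)
    stop("magnitude must be a positive integer", call. = FALSE)
  list(cation = ion_spec(element, magnitude),
       anion  = ion_spec(element, -magnitude))
}

#' Cromer--Mann 9-coefficient parametrization
#'
#' \eqn{f(s) = c + \sum_{i=1}^{4} a_i \exp(-b_i s^2)}. Exponents must be
#' non-negative so every term decays.
#'
#' @param a Four amplitudes (dimensionless).
#' @param b Four exponents (Å\eqn{^2}), all `>= 0`.
#' @param c Constant term.
#' @return Object of class `cromer_mann`.
#' @export
cromer_mann <- function(a, b, c) {
  stopifnot(length(a) == 4L, length(b) == 4L, length(c) == 1L)
  if (any(b < 0)) stop("Cromer-Mann exponents b must be >= 0", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = "cromer_mann")
}

#' Evaluate a Cromer--Mann curve
#' @param cm A [cromer_mann()] object.
#' @param s Scattering-vector magnitudes (Å\eqn{^{-1}}).
#' @return Numeric vector `f(s)`.
#' @export
eval_cromer_mann <- function(cm, s) {
  f <- rep(cm$c, length(s))
  for (i in 1:4) f <- f + cm$a[i] * exp(-cm$b[i] * s^2)
  f
}

#' @export
print.cromer_mann <- function(x, ...) {
  cat("<cromer_mann>\n")
  cat(sprintf("  a: %s\n", paste(formatC(x$a, digits = 6, format = "f"), collapse = " ")))
  cat(sprintf("  b: %s\n", paste(formatC(x$b, digits = 6, format = "f"), collapse = " ")))
  cat(sprintf("  c: %s\n", formatC(x$c, digits = 6, format = "f")))
  invisible(x)
}

#' Resolution window for scattering-factor fits
#'
#' The window is given in resolution d (Å) and mapped to
#' \eqn{s \in [1/(2 d_{max}), 1/(2 d_{min})]}. Ionic curves are never fitted or
#' evaluated below the low-resolution edge, where they diverge.
#'
#' @param d_max Low-resolution bound (Å), default 15.
#' @param d_min High-resolution bound (Å), default 0.75.
#' @param n_points Number of equally spaced sample points in s, `>= 20`.
#' @return Object of class `fit_window`.
#' @export
fit_window <- function(d_max = 15, d_min = 0.75, n_points = 200L) {
  if (!(d_max > d_min && d_min > 0)) stop("need d_max > d_min > 0", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("n_points must be >= 20", call. = FALSE)
  structure(list(d_max = d_max, d_min = d_min, n_points = n_points,
                 s_min = 1 / (2 * d_max), s_max = 1 / (2 * d_min)),
            class = "fit_window")
}

window_s_grid <- function(window) {
  seq(window$s_min, window$s_max, length.out = window$n_points)
}

## Linear least-squares for (a1..a4, c) at fixed exponents b: the CM model is
## linear in the amplitudes, which gives a robust Levenberg-Marquardt start.
.cm_linear_init <- function(s, f, b0) {
  X <- cbind(exp(-outer(s^2, b0)), 1)
  beta <- tryCatch(qr.solve(X, f), error = function(e) rep(0, 5))
  cromer_mann(beta[1:4], b0, beta[5])
}

#' Fit Cromer--Mann coefficients to an ionic or neutral scattering curve
#'
#' Samples the charge-offset Mott--Bethe curve of `ion` at `n_points` equally
#' spaced values of s across the window and fits the 9 Cromer--Mann
#' coefficients by Levenberg--Marquardt least squares (unit weights, analytic
#' Jacobian). The exponents are kept non-negative by squared reparametrization.
#'
#' The fit report contains the maximum absolute residual, the maximum
#' pointwise relative residual |Δf/f| (which is unbounded when an anion curve
#' crosses zero inside the window) and the scale-relative residual
#' max|Δf| / max|f| used as the package's fit-quality measure.
#'
#' @param ion An [ion_spec()].
#' @param window A [fit_window()].
#' @param max_iter Maximum Levenberg--Marquardt iterations.
#' @return Object of class `sfac_fit`: fields `ion`, `window`, `cm`,
#'   `report` (max_abs, max_rel_point, max_rel_scale, rms), `converged`.
#' @export
fit_cromer_mann <- function(ion, window = fit_window(), max_iter = 500L) {
  s <- window_s_grid(window)
  target <- mott_bethe(ion, s)
  best <- .fit_cm_curve(s, target, max_iter)
  cm <- best$cm
  res <- eval_cromer_mann(cm, s) - target
  report <- list(max_abs = max(abs(res)),
                 max_rel_point = max(abs(res / target)),
                 max_rel_scale = max(abs(res)) / max(abs(target)),
                 rms = sqrt(mean(res^2)))
  converged <- report$max_rel_scale < 0.005
  if (!converged)
    warning("Cromer-Mann fit for ", species_label(ion),
            " has scale-relative residual ",
            formatC(report$max_rel_scale, digits = 3, format = "g"))
  structure(list(ion = ion, window = window, cm = cm, report = report,
                 converged = converged),
            class = "sfac_fit")
}

## Levenberg-Marquardt core: fit 9 Cromer-Mann coefficients to an arbitrary
## sampled target curve (squared reparametrization keeps exponents >= 0)
.fit_cm_curve <- function(s, target, max_iter = 500L) {
  resid_fn <- function(p) {
    a <- p[1:4]; b <- p[5:8]^2; cc <- p[9]
    f <- rep(cc, length(s))
    for (i in 1:4) f <- f + a[i] * exp(-b[i] * s^2)
    f - target
  }
  jac_fn <- function(p) {
    a <- p[1:4]; braw <- p[5:8]
    E <- exp(-outer(s^2, braw^2))            # n x 4
    dB <- sweep(E * s^2, 2, -2 * braw * a, "*")
    cbind(E, dB, 1)
  }

  ## Multi-start: the divergent 1/s^2 part of ionic curves needs steep
  ## Gaussians (b of order 10^2-10^3 A^2), so starts are geometric ladders of
  ## exponents; amplitudes and c come from a linear solve at fixed exponents.
  starts <- list()
  for (bmax in c(50, 200, 400, 800, 1600, 3200))
    for (r in c(3, 5, 8)) starts[[length(starts) + 1L]] <- bmax / r^(0:3)
  scale <- max(abs(target))
  best <- NULL
  for (b0 in starts) {
    init <- .cm_linear_init(s, target, b0)
    p0 <- c(init$a, sqrt(init$b), init$c)
    ## iteration-cap warnings are irrelevant: quality is judged on the report
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = max_iter, ftol = 1e-15, ptol = 1e-15,
                             gtol = 1e-15))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (max(abs(best$fvec)) / scale < 1e-7) break
  }
  if (is.null(best)) stop("Cromer-Mann fit failed", call. = FALSE)
  p <- best$par
  list(cm = cromer_mann(p[1:4], p[5:8]^2, p[9]), deviance = best$deviance)
}

#' @export
print.sfac_fit <- function(x, ...) {
  cat(sprintf("<sfac_fit> %s over %.4g-%.4g A (n = %d)\n", species_label(x$ion),
              x$window$d_max, x$window$d_min, x$window$n_points))
  cat(sprintf("  max |df| = %.3g, max |df|/max|f| = %.3g, rms = %.3g\n",
              x$report$max_abs, x$report$max_rel_scale, x$report$rms))
  print(x$cm)
  invisible(x)
}

#' Export a fitted curve as a SHELX-style SFAC card
#'
#' Layout: `SFAC label a1 b1 a2 b2 a3 b3 a4 b4 c` followed by placeholder
#' physical columns (f', f'', mu, r, weight). Round-trips through
#' [read_instruction()].
#'
#' @param label Species label, non-empty.
#' @param cm A [cromer_mann()] object.
#' @return A single text line.
#' @export
export_sfac_card <- function(label, cm) {
  if (!nzchar(label)) stop("label must be non-empty", call. = FALSE)
  coeff <- as.vector(rbind(cm$a, cm$b))
  paste0("SFAC ", label, " ",
         paste(sprintf("%.6f", c(coeff, cm$c)), collapse = " "),
         " 0.0 0.0 0.0 0.0 0.0")
}

## -------- species table used by structure-factor and refinement code --------

.sfac_cache <- new.env(parent = emptyenv())

.cached_fit <- function(ion, window) {
  key <- sprintf("%s|%g|%g|%d", species_label(ion),
                 window$d_max, window$d_min, window$n_points)
  hit <- .sfac_cache[[key]]
  if (!is.null(hit)) return(hit)
  fit <- fit_cromer_mann(ion, window)
  assign(key, fit, envir = .sfac_cache)
  fit
}

#' Build the scattering-factor table a model needs
#'
#' For every non-hydrogen element appearing in `model` the table carries the
#' neutral curve and both signed ionic curves at the element's assigned |dZ|
#' (so the sign-flip protocol never needs a refit); hydrogens use the H+
#' curve only. Curves are fitted Cromer--Mann parametrizations over `window`
#' and cached per session.
#'
#' @param model A [crystal_model()].
#' @param window A [fit_window()].
#' @param use_fit If `FALSE`, curves evaluate the Mott--Bethe formula directly
#'   instead of the fitted parametrization.
#' @return Named list of entries `list(ion, cm, fun)`, keyed by
#'   [species_label()]; class `sfac_table`.
#' @export
build_sfac_table <- function(model, window = fit_window(), use_fit = TRUE) {
  ions <- list()
  add <- function(ion) {
    key <- species_label(ion)
    if (is.null(ions[[key]])) ions[[key]] <<- ion
    invisible(NULL)
  }
  for (site in model$sites) {
    if (site$is_hydrogen) {
      add(ion_spec("H", 1L))
    } else {
      add(ion_spec(site$ion$element, 0L))
      m <- abs(site$ion$dZ)
      if (m > 0L) {
        add(ion_spec(site$ion$element, m))
        add(ion_spec(site$ion$element, -m))
      }
    }
  }
  entries <- lapply(ions, function(ion) {
    if (use_fit) {
      fit <- .cached_fit(ion, window)
      list(ion = ion, cm = fit$cm,
           fun = local({ cm <- fit$cm; function(s) eval_cromer_mann(cm, s) }))
    } else {
      list(ion = ion, cm = NULL,
           fun = local({ io <- ion; function(s) mott_bethe(io, s) }))
    }
  })
  structure(entries, class = "sfac_table", window = window)
}

sfac_lookup <- function(table, ion) {
  key <- species_label(ion)
  entry <- table[[key]]
  if (is.null(entry))
    stop("no scattering curve for species '", key, "' in table", call. = FALSE)
  entry
}

#' Two-column (s, f) curve export for plotting and diagnostics
#' @param ion An [ion_spec()].
#' @param window A [fit_window()].
#' @param path Optional output path; when `NULL` the data frame is returned.
#' @return Data frame with columns `s` and `f` (invisibly when written).
#' @export
export_curve <- function(ion, window = fit_window(), path = NULL) {
  s <- window_s_grid(window)
  df <- data.frame(s = s, f = mott_bethe(ion, s))
  if (!is.null(path)) {
    utils::write.table(format(df, digits = 8), path, quote = FALSE,
                       row.names = FALSE, sep = "\t")
    return(invisible(df))
  }
  df
}
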