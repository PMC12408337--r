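## Ground-truth toy crystals and simulated noisy intensity datasets. The
## templates are the study conditions every pipeline stage is tested under:
## a single neutral atom, an ionic pair, a glycine-like zwitterion with an
## NH3+/COO- charge pattern in P2(1)2(1)2(1), and a centrosymmetric
## silicate-like framework with a positively charged tetrahedral site.

#' Synthetic study specification
#'
#' @param template One of `"one-atom-P1"`, `"ionic-pair-P1"`,
#'   `"toy-zwitterion-P212121"`, `"framework-Pnma"`.
#' @param d_min,d_max Resolution range of the simulated data (Å).
#' @param completeness Random fraction of reflections kept, in (0, 1].
#' @param noise Gaussian intensity-noise fraction:
#'   sigma(I) = max(noise * I, floor).
#' @param n_crystals Number of replicate datasets.
#' @param seed Integer random seed recorded in every output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(template = "toy-zwitterion-P212121",
                           d_min = 0.75, d_max = 15,
                           completeness = 1, noise = 0.02,
                           n_crystals = 1L, seed = 1L) {
  if (!(completeness > 0 && completeness <= 1))
    stop("completeness must lie in (0, 1]", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(template = template, d_min = d_min, d_max = d_max,
                 completeness = completeness, noise = noise,
                 n_crystals = as.integer(n_crystals), seed = as.integer(seed)),
            class = "synthetic_spec")
}

.spec_hash <- function(spec) {
  txt <- paste(deparse(unclass(spec)), collapse = "")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1000000007
}

.unit <- function(v) v / sqrt(sum(v^2))

## orthorhombic helper: Cartesian molecule -> fractional sites
.frac <- function(cart, offset, cell_len) (cart + offset) / cell_len

#' Build a ground-truth toy structure
#'
#' Returns the generating model: sites carry the true ionic fractions and the
#' true ion assignments; the per-atom ground truth is also attached as
#' attribute `"truth"` (data frame `label`, `dZ`, `nu`, `dq`). All templates
#' have total true charge zero. In the P1 templates the first site is
#' coordinate-fixed to pin the floating origin.
#'
#' @param spec A [synthetic_spec()] (or a template name).
#' @return A [crystal_model()] with attribute `"truth"`.
#' @export
make_structure <- function(spec = synthetic_spec()) {
  template <- if (inherits(spec, "synthetic_spec")) spec$template else spec
  if (template == "one-atom-P1") {
    cell <- unit_cell(6, 7, 8)
    sites <- list(atom_site("C1", ion_spec("C", -1L), c(0.1, 0.2, 0.3),
                            u = 0.02, nu = 0, xyz_fixed = TRUE))
    model <- crystal_model(cell, symmetry_ops(), sites)
  } else if (template == "ionic-pair-P1") {
    cell <- unit_cell(6, 6, 6)
    sites <- list(
      atom_site("Na1", ion_spec("Na", 1L), c(0.15, 0.20, 0.25),
                u = 0.02, nu = 0.5, xyz_fixed = TRUE),
      atom_site("Cl1", ion_spec("Cl", -1L), c(0.55, 0.60, 0.65),
                u = 0.02, nu = 0.5))
    model <- crystal_model(cell, symmetry_ops(), sites)
  } else if (template == "toy-zwitterion-P212121") {
    len <- c(7.5, 9.0, 11.5)
    cell <- unit_cell(len[1], len[2], len[3])
    symm <- c("1/2-X, -Y, 1/2+Z", "1/2+X, 1/2-Y, -Z", "-X, 1/2+Y, 1/2-Z")
    off <- c(1.9, 2.3, 2.9)
    C2 <- c(0, 0, 0)
    C1 <- c(1.52, 0, 0)
    O1 <- C1 + 1.25 * .unit(c(0.5, 0.866, 0))
    O2 <- C1 + 1.25 * .unit(c(0.5, -0.866, 0))
    N1 <- C2 + 1.48 * .unit(c(-0.39, 0.82, 0.42))
    HA <- C2 + 1.05 * .unit(c(-0.3, -0.9, 0.4))
    HB <- C2 + 1.05 * .unit(c(-0.3, -0.2, -0.95))
    H1A <- N1 + 0.91 * .unit(c(-1, 0.4, 0.2))
    H1B <- N1 + 0.91 * .unit(c(0.2, 0.9, 0.8))
    H1C <- N1 + 0.91 * .unit(c(0, 0.3, -1))
    ## true charges: NH3+ / COO- zwitterion pattern summing to zero
    def <- list(
      list("N1",  "N", N1,  -0.45, "N1", NULL),
      list("C1",  "C", C1,  -0.20, "C1", NULL),
      list("C2",  "C", C2,  -0.10, "C2", NULL),
      list("O1",  "O", O1,  -0.30, "O1", NULL),
      list("O2",  "O", O2,  -0.25, "O2", NULL),
      list("H1A", "H", H1A, +0.35, "H1A", "N1"),
      list("H1B", "H", H1B, +0.30, "H1B", "N1"),
      list("H1C", "H", H1C, +0.25, "H1C", "N1"),
      list("HA",  "H", HA,  +0.20, "HA", "C2"),
      list("HB",  "H", HB,  +0.20, "HB", "C2"))
    sites <- lapply(def, function(d) {
      dq <- d[[4]]
      if (d[[2]] == "H") {
        atom_site(d[[1]], ion_spec("H", 1L), .frac(d[[3]], off, len),
                  u = 0.03, nu = dq, ride_on = d[[6]])
      } else {
        atom_site(d[[1]], ion_spec(d[[2]], as.integer(sign(dq))),
                  .frac(d[[3]], off, len), u = 0.02, nu = abs(dq))
      }
    })
    model <- crystal_model(cell, symmetry_ops(symm, latt = -1L), sites,
                           latt = -1L, symm = symm)
  } else if (template == "framework-Pnma") {
    cell <- unit_cell(9, 8, 7)
    symm <- c("1/2-X, -Y, 1/2+Z", "-X, 1/2+Y, -Z", "1/2+X, 1/2-Y, 1/2-Z")
    sites <- list(
      ## tetrahedral cation site (positive), bridging oxygens (negative);
      ## O2 sits on the mirror plane y = 1/4 with half occupancy
      atom_site("Si1", ion_spec("Si", 4L), c(0.100, 0.050, 0.150),
                u = 0.015, nu = 0.100),
      atom_site("O1", ion_spec("O", -1L), c(0.2556, 0.1250, 0.2286),
                u = 0.025, nu = 0.300),
      atom_site("O2", ion_spec("O", -1L), c(0.0556, 0.2500, 0.4000),
                u = 0.025, occ = 0.5, nu = 0.200))
    model <- crystal_model(cell, symmetry_ops(symm, latt = 1L), sites,
                           latt = 1L, symm = symm)
  } else stop("unknown template '", template, "'", call. = FALSE)

  truth <- data.frame(
    label = site_labels(model),
    dZ = vapply(model$sites, function(s) s$ion$dZ, 0L),
    nu = vapply(model$sites, function(s) s$nu, 0),
    occ = vapply(model$sites, function(s) s$occ, 0))
  truth$dq <- truth$nu * truth$dZ
  attr(model, "truth") <- truth
  model
}

#' Simulate noisy intensity data from a model
#'
#' Enumerates the symmetry-unique reflections in the spec's resolution range,
#' computes kinematical intensities, adds seeded Gaussian noise with
#' sigma(I) = max(noise * I, floor) and applies random completeness
#' thinning. Replicate crystals use seeds derived from the spec seed.
#'
#' @param model A [crystal_model()] (typically from [make_structure()]).
#' @param spec A [synthetic_spec()].
#' @param sfac Optional scattering-factor table.
#' @return A [reflection_data()] frame (or a list of them when
#'   `n_crystals > 1`), with attributes `seed`, `scale`, `spec_hash` and
#'   `I_true`.
#' @export
simulate_dataset <- function(model, spec = synthetic_spec(), sfac = NULL) {
  if (is.null(sfac)) sfac <- build_sfac_table(model)
  hkl <- unique_reflections(model$cell, model$ops, spec$d_min, spec$d_max)
  itrue_all <- calc_intensities(model, hkl[, 1:3, drop = FALSE], 1, sfac)
  scale <- 100 / mean(itrue_all)
  itrue_all <- itrue_all * scale
  ## the sigma floor keeps weights finite; for noise-free data the sigmas
  ## stay proportional to I (plus a small offset) so the weighting matches
  ## the relative scheme of the noisy case
  floor_ <- if (spec$noise > 0) 0.1 * spec$noise * stats::median(itrue_all)
            else 1e-6 * 0.01 * stats::median(itrue_all)

  one <- function(rep_i) {
    seed_i <- spec$seed + 7919L * (rep_i - 1L)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed_i)
    keep <- if (spec$completeness < 1)
      stats::runif(length(itrue_all)) <= spec$completeness
    else rep(TRUE, length(itrue_all))
    itrue <- itrue_all[keep]
    sig <- if (spec$noise > 0) pmax(spec$noise * itrue, floor_)
           else pmax(1e-6 * itrue, floor_)
    iobs <- if (spec$noise > 0) itrue + stats::rnorm(length(itrue), 0, sig)
            else itrue
    out <- reflection_data(hkl[keep, 1], hkl[keep, 2], hkl[keep, 3], iobs, sig)
    attr(out, "seed") <- seed_i
    attr(out, "scale") <- scale
    attr(out, "spec_hash") <- .spec_hash(spec)
    attr(out, "I_true") <- itrue
    out
  }
  if (spec$n_crystals == 1L) one(1L) else lapply(seq_len(spec$n_crystals), one)
}

## jitter a starting model: coordinates by sd_cart Å, nu restarted at
## 0.1 with the generating sign, ADPs nudged
.perturb_start <- function(model, sd_cart = 0.02, nu_start = 0.1) {
  len <- c(model$cell$a, model$cell$b, model$cell$c)
  for (j in seq_along(model$sites)) {
    s <- model$sites[[j]]
    if (!s$xyz_fixed)
      model$sites[[j]]$xyz <- s$xyz + stats::rnorm(3, 0, sd_cart) / len
    if (!s$nu_fixed)
      model$sites[[j]]$nu <- if (s$is_hydrogen) nu_start
                             else nu_start
    model$sites[[j]]$u <- s$u * 1.1
  }
  model
}

#' Charge-recovery experiment on synthetic data
#'
#' For each replicate: simulate a dataset, perturb the starting model
#' (coordinates jittered 0.02 Å, ionic fractions restarted at 0.1 with the
#' generating sign), run [refine_charges()] with the sign-flip protocol, and
#' compare the recovered charges to the ground truth.
#'
#' @param spec A [synthetic_spec()] (noise may be zero for closure checks).
#' @param config A [refine_config()].
#' @param n_rep Number of seeded replicates.
#' @param nu_starts Starting ionic fractions for the multi-start protocol
#'   (see [refine_charges()]); the run with the lowest weighted sum of
#'   squares per replicate is kept.
#' @return Object of class `recovery_report`: `per_atom` (data frame with
#'   bias, rmse, mean esu, 3-esu coverage), `cells` (atom x replicate
#'   details), `n_unconverged`, `spec`.
#' @export
recovery_experiment <- function(spec = synthetic_spec(),
                                config = refine_config(sump = list(target = 0, sigma = 0.001)),
                                n_rep = spec$n_crystals,
                                nu_starts = c(0.1, 0.05, 0.2)) {
  model0 <- make_structure(spec)
  truth <- attr(model0, "truth")
  sfac <- build_sfac_table(model0, config$window, config$use_fit)
  cells <- list()
  n_unconv <- 0L
  for (rep_i in seq_len(n_rep)) {
    spec_i <- spec; spec_i$seed <- spec$seed + 7919L * (rep_i - 1L)
    spec_i$n_crystals <- 1L
    data <- simulate_dataset(model0, spec_i, sfac)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec_i$seed + 13L)
    start <- .perturb_start(model0)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    run <- refine_charges(start, data, config, nu_starts = nu_starts)
    if (!run$result$converged) n_unconv <- n_unconv + 1L
    ch <- extract_charges(run$result, force = TRUE)
    i <- match(truth$label, ch$label)
    cells[[rep_i]] <- data.frame(
      replicate = rep_i, label = truth$label,
      dq_true = truth$dq, dq = ch$dq[i], esu = ch$esu[i],
      converged = run$result$converged)
  }
  cells <- do.call(rbind, cells)
  per_atom <- do.call(rbind, lapply(split(cells, cells$label), function(d) {
    err <- d$dq - d$dq_true
    data.frame(label = d$label[1], dq_true = d$dq_true[1],
               bias = mean(err), rmse = sqrt(mean(err^2)),
               mean_esu = mean(d$esu),
               coverage3 = mean(abs(err) <= 3 * d$esu))
  }))
  rownames(per_atom) <- NULL
  structure(list(per_atom = per_atom, cells = cells,
                 n_unconverged = n_unconv, spec = spec),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> template %s, %d replicates (%d unconverged)\n",
              x$spec$template, max(x$cells$replicate), x$n_unconverged))
  print(x$per_atom, digits = 3)
  invisible(x)
}
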