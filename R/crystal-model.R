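## Unit cell, symmetry, atom sites and reflection geometry. Coordinates are
## fractional throughout; symmetry operators are supplied as coordinate-triplet
## strings plus a SHELX-style lattice code rather than space-group lookup.

#' Construct a unit cell
#'
#' @param a,b,c Cell edges in Å, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return Object of class `unit_cell` carrying the direct and reciprocal
#'   metric tensors, the cell volume (Å^3) and the fractional-to-Cartesian
#'   orthogonalization matrix.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (any(len <= 0)) stop("cell lengths must be positive", call. = FALSE)
  if (any(ang <= 0 | ang >= 180)) stop("cell angles must lie in (0, 180)", call. = FALSE)
  ca <- cos(ang * pi / 180); sa <- sin(ang * pi / 180)
  ## direct metric tensor
  G <- matrix(c(a * a,           a * b * ca[3], a * c * ca[2],
                a * b * ca[3],   b * b,         b * c * ca[1],
                a * c * ca[2],   b * c * ca[1], c * c), 3, 3)
  vol2 <- det(G)
  if (vol2 <= 0) stop("cell angles give non-positive volume", call. = FALSE)
  V <- sqrt(vol2)
  Gstar <- solve(G)
  ## standard orthogonalization (a along x, b in xy-plane)
  M <- matrix(c(a, b * ca[3], c * ca[2],
                0, b * sa[3], c * (ca[1] - ca[2] * ca[3]) / sa[3],
                0, 0,         V / (a * b * sa[3])), 3, 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 G = G, Gstar = Gstar, volume = V, orth = M,
                 astar = sqrt(diag(Gstar))),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %.4f %.4f %.4f  %.3f %.3f %.3f  V = %.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Cartesian coordinates from fractional
#' @param cell A [unit_cell()].
#' @param x Fractional coordinates, length-3 vector or n x 3 matrix.
#' @return Cartesian coordinates in Å, same shape.
#' @export
frac_to_cart <- function(cell, x) {
  if (is.matrix(x)) t(cell$orth %*% t(x)) else as.vector(cell$orth %*% x)
}

#' Magnitude of the scattering vector s = sin(theta)/lambda
#'
#' Computed from the reciprocal metric: \eqn{s = d^*(hkl)/2} with
#' \eqn{d^{*2} = h^T G^* h}. `s(0,0,0) = 0`.
#'
#' @param cell A [unit_cell()].
#' @param hkl Length-3 integer vector or n x 3 matrix of Miller indices.
#' @return Numeric vector of s values (Å\eqn{^{-1}}).
#' @export
s_magnitude <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  0.5 * sqrt(rowSums((h %*% cell$Gstar) * h))
}

## ---------------------------- symmetry ------------------------------------

#' Parse a coordinate-triplet symmetry operator
#'
#' Accepts strings like `"x, y, z"`, `"1/2-X, -Y, 1/2+Z"` or `"-x, y+0.5, -z"`.
#'
#' @param text Coordinate triplet.
#' @return Object of class `symop` with integer rotation matrix `R` and
#'   translation `t` reduced mod 1.
#' @export
parse_symop <- function(text) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(text)), ",")[[1]]
  if (length(parts) != 3L) stop("symmetry operator needs three components: ", text,
                                call. = FALSE)
  R <- matrix(0L, 3, 3); tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    ## split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9.]+/[0-9.]+$", body)) {
        nums <- as.numeric(strsplit(body, "/")[[1]])
        tr[i] <- tr[i] + sign * nums[1] / nums[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tr[i] <- tr[i] + sign * as.numeric(body)
      } else stop("cannot parse symmetry term '", term, "' in: ", text, call. = FALSE)
    }
  }
  symop(R, tr)
}

#' Construct a symmetry operator
#' @param R 3 x 3 integer rotation part with determinant +1 or -1.
#' @param t Translation vector; reduced mod 1.
#' @return Object of class `symop`.
#' @export
symop <- function(R, t = c(0, 0, 0)) {
  R <- matrix(as.integer(round(R)), 3, 3)
  if (abs(abs(det(R)) - 1) > 1e-9) stop("rotation determinant must be +-1", call. = FALSE)
  structure(list(R = R, t = (t %% 1)), class = "symop")
}

#' Render a symmetry operator as a coordinate triplet
#' @param op A [symop()].
#' @return Character string such as `"1/2-x, -y, 1/2+z"`.
#' @export
symop_to_string <- function(op) {
  comp <- character(3)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    str <- ""
    ti <- op$t[i]
    if (abs(ti) > 1e-9) {
      fr <- .as_fraction(ti)
      str <- fr
    }
    for (j in 1:3) {
      if (op$R[i, j] == 1L) str <- paste0(str, "+", ax[j])
      else if (op$R[i, j] == -1L) str <- paste0(str, "-", ax[j])
    }
    comp[i] <- sub("^\\+", "", str)
  }
  paste(comp, collapse = ", ")
}

.as_fraction <- function(x) {
  for (den in c(2, 3, 4, 6)) {
    num <- round(x * den)
    if (abs(x - num / den) < 1e-9) return(sprintf("%d/%d", num, den))
  }
  sprintf("%.6f", x)
}

.op_key <- function(R, t) paste(c(R, round((t %% 1) * 48)), collapse = ",")

#' Expand SYMM records and a lattice code into the full operator list
#'
#' Mirrors the SHELX convention: `latt` magnitude selects the centering
#' (1 = P, 2 = I, 3 = rhombohedral obverse, 4 = F, 5 = A, 6 = B, 7 = C) and a
#' positive sign adds the inversion centre at the origin. The identity is
#' always included and never needs to be listed.
#'
#' @param symm Character vector of coordinate triplets (may be empty), or a
#'   list of [symop()] objects.
#' @param latt Integer lattice code, default `-1` (primitive, acentric).
#' @return List of [symop()] objects, de-duplicated.
#' @export
symmetry_ops <- function(symm = character(), latt = -1L) {
  base <- list(symop(diag(3)))
  for (sopi in symm) {
    base[[length(base) + 1L]] <- if (inherits(sopi, "symop")) sopi else parse_symop(sopi)
  }
  cent <- switch(as.character(abs(latt)),
                 "1" = list(c(0, 0, 0)),
                 "2" = list(c(0, 0, 0), c(0.5, 0.5, 0.5)),
                 "3" = list(c(0, 0, 0), c(2/3, 1/3, 1/3), c(1/3, 2/3, 2/3)),
                 "4" = list(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),
                 "5" = list(c(0, 0, 0), c(0, 0.5, 0.5)),
                 "6" = list(c(0, 0, 0), c(0.5, 0, 0.5)),
                 "7" = list(c(0, 0, 0), c(0.5, 0.5, 0)),
                 stop("unknown lattice code ", latt, call. = FALSE))
  ops <- list(); seen <- character()
  push <- function(R, t) {
    key <- .op_key(R, t)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      ops[[length(ops) + 1L]] <<- symop(R, t)
    }
  }
  for (op in base) {
    for (ct in cent) {
      push(op$R, op$t + ct)
      if (latt > 0) push(-op$R, -op$t + ct)
    }
  }
  ops
}

## ---------------------------- atom sites ----------------------------------

#' Construct an atom site
#'
#' @param label Unique site label (e.g. `"O1"`).
#' @param ion An [ion_spec()] giving the element and the current ionic sign
#'   assignment used for the site's ionic scattering curve.
#' @param xyz Fractional coordinates, length 3.
#' @param u Either a single U_iso (Å^2) or six anisotropic components in SHELX
#'   order `U11 U22 U33 U23 U13 U12`.
#' @param occ Occupancy in (0, 1]; sites on special positions carry the
#'   reduced value (e.g. 0.5 on a mirror).
#' @param nu Ionic fraction; the refined iSFAC parameter.
#' @param nu_fixed If `TRUE` the ionic fraction is held (a `nu = 0` fixed site
#'   contributes as a purely neutral atom, or not at all for hydrogen).
#' @param xyz_fixed If `TRUE` coordinates are excluded from refinement.
#' @param ride_on Optional label of a parent site for riding hydrogens.
#' @return Object of class `atom_site`.
#' @export
atom_site <- function(label, ion, xyz, u = 0.02, occ = 1, nu = 0,
                      nu_fixed = FALSE, xyz_fixed = FALSE, ride_on = NULL) {
  stopifnot(inherits(ion, "ion_spec"), length(xyz) == 3L)
  if (!(occ > 0 && occ <= 1)) stop("occupancy must lie in (0, 1]", call. = FALSE)
  if (!length(u) %in% c(1L, 6L)) stop("u must be U_iso or 6 components", call. = FALSE)
  structure(list(label = label, ion = ion, xyz = as.numeric(xyz),
                 u = as.numeric(u), occ = occ, nu = nu,
                 is_hydrogen = identical(ion$element, "H"),
                 nu_fixed = nu_fixed, xyz_fixed = xyz_fixed,
                 ride_on = ride_on),
            class = "atom_site")
}

#' Assemble a crystal model
#'
#' @param cell A [unit_cell()].
#' @param ops List of [symop()] from [symmetry_ops()].
#' @param sites List of [atom_site()] with unique labels.
#' @param latt Lattice code kept for round-tripping instruction files.
#' @param symm Original SYMM strings kept for round-tripping.
#' @return Object of class `crystal_model`.
#' @export
crystal_model <- function(cell, ops, sites, latt = -1L, symm = character()) {
  stopifnot(inherits(cell, "unit_cell"))
  labels <- vapply(sites, function(s) s$label, "")
  if (anyDuplicated(labels)) stop("site labels must be unique", call. = FALSE)
  structure(list(cell = cell, ops = ops, sites = sites,
                 latt = as.integer(latt), symm = symm),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("<crystal_model> %d sites, %d symmetry operators\n",
              length(x$sites), length(x$ops)))
  print(x$cell)
  for (s in x$sites)
    cat(sprintf("  %-5s %-4s dZ=%+d  xyz = %7.4f %7.4f %7.4f  occ = %.2f  nu = %+7.4f%s\n",
                s$label, s$ion$element, s$ion$dZ, s$xyz[1], s$xyz[2], s$xyz[3],
                s$occ, s$nu, if (s$nu_fixed) " (fixed)" else ""))
  invisible(x)
}

site_labels <- function(model) vapply(model$sites, function(s) s$label, "")

get_site <- function(model, label) {
  i <- match(label, site_labels(model))
  if (is.na(i)) stop("no site labelled '", label, "'", call. = FALSE)
  model$sites[[i]]
}

#' Expand sites to the full P1 cell
#'
#' Applies every symmetry operator to every site, reduces coordinates into
#' [0, 1) and merges images that coincide within `tol` Å (special positions).
#' Merged entries are flagged and keep the occupancy of the input site, so the
#' summed content `occ * n_images` stays consistent with the cell content.
#'
#' @param model A [crystal_model()], or a list of sites when `ops` and `cell`
#'   are given explicitly.
#' @param ops,cell Operator list and cell (defaults from `model`).
#' @param tol Merge distance in Å.
#' @return Data frame with one row per expanded position: `label`, `element`,
#'   `dZ`, `x`, `y`, `z`, `occ`, `nu`, `multiplicity`, `special`.
#' @export
expand_to_p1 <- function(model, ops = model$ops, cell = model$cell, tol = 0.01) {
  sites <- if (inherits(model, "crystal_model")) model$sites else model
  rows <- list()
  for (site in sites) {
    imgs <- matrix(NA_real_, length(ops), 3)
    for (k in seq_along(ops)) {
      op <- ops[[k]]
      imgs[k, ] <- (op$R %*% site$xyz + op$t) %% 1
    }
    keep <- rep(TRUE, nrow(imgs)); count <- rep(1L, nrow(imgs))
    for (k in seq_len(nrow(imgs))) {
      if (!keep[k]) next
      if (k < nrow(imgs)) for (m in (k + 1L):nrow(imgs)) {
        if (!keep[m]) next
        d <- imgs[m, ] - imgs[k, ]
        d <- d - round(d)                    # minimum image
        if (sqrt(sum(frac_to_cart(cell, d)^2)) < tol) {
          keep[m] <- FALSE
          count[k] <- count[k] + 1L
        }
      }
    }
    for (k in which(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = site$label, element = site$ion$element, dZ = site$ion$dZ,
        x = imgs[k, 1], y = imgs[k, 2], z = imgs[k, 3],
        occ = site$occ, nu = site$nu,
        multiplicity = count[k], special = count[k] > 1L)
    }
  }
  do.call(rbind, rows)
}

## canonical representative of each row's symmetry orbit (Friedel included):
## lexicographically largest equivalent index h R (and -h R) over all rotations
.canonical_hkl_matrix <- function(grid, rots) {
  best <- NULL
  for (R in rots) {
    for (sgn in c(1, -1)) {
      cand <- sgn * (grid %*% R)
      if (is.null(best)) { best <- cand; next }
      better <- cand[, 1] > best[, 1] |
        (cand[, 1] == best[, 1] & (cand[, 2] > best[, 2] |
         (cand[, 2] == best[, 2] & cand[, 3] > best[, 3])))
      best[better, ] <- cand[better, , drop = FALSE]
    }
  }
  best
}

#' Enumerate symmetry-unique reflections in a resolution shell
#'
#' One representative per symmetry-equivalence class with
#' `d_min <= d <= d_max`; Friedel mates are merged (centrosymmetric intensity
#' model). (0,0,0) is never included.
#'
#' @param cell A [unit_cell()].
#' @param ops Operator list from [symmetry_ops()].
#' @param d_min High-resolution cut (Å).
#' @param d_max Low-resolution cut (Å), `> d_min`.
#' @return Integer matrix with columns `h`, `k`, `l`, plus a `d` column (Å).
#' @export
unique_reflections <- function(cell, ops, d_min, d_max = Inf) {
  if (!(d_max > d_min)) stop("need d_max > d_min", call. = FALSE)
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  s <- s_magnitude(cell, grid)
  d <- ifelse(s > 0, 1 / (2 * s), Inf)
  sel <- is.finite(d) & d >= d_min & d <= d_max & rowSums(abs(grid)) > 0
  grid <- grid[sel, , drop = FALSE]; d <- d[sel]
  rots <- unique(lapply(ops, function(op) op$R))
  reps <- .canonical_hkl_matrix(grid, rots)
  storage.mode(reps) <- "integer"
  keys <- paste(reps[, 1], reps[, 2], reps[, 3], sep = ",")
  first <- !duplicated(keys)
  out <- cbind(reps[first, , drop = FALSE], d = d[first])
  colnames(out) <- c("h", "k", "l", "d")
  out[order(-out[, "d"]), , drop = FALSE]
}
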