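## Electrostatic-potential maps: Fourier synthesis of structure factors on a
## cell grid with an explicit F(000) override (the constant term is
## ill-defined under ionic scattering factors), Gaussian CUBE text I/O, and
## Pearson comparison of grids with non-identical spacing.

.BOHR <- 0.529177210903  # Angstrom per Bohr

#' ESP grid container
#'
#' @param values 3D numeric array (nx x ny x nz).
#' @param origin Cartesian origin in Å.
#' @param axes 3 x 3 matrix whose rows are the Å step vectors per grid
#'   increment along each array dimension; rows must be linearly independent.
#' @return Object of class `esp_grid`.
#' @export
esp_grid <- function(values, origin = c(0, 0, 0), axes) {
  stopifnot(length(dim(values)) == 3L, nrow(axes) == 3L, ncol(axes) == 3L)
  if (any(dim(values) < 2L)) stop("grid needs >= 2 points per axis", call. = FALSE)
  if (abs(det(axes)) < 1e-12) stop("axis vectors must be linearly independent",
                                   call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 axes = unname(as.matrix(axes))),
            class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<esp_grid> %d x %d x %d  min %.4g  max %.4g  mean %.4g  sd %.4g\n",
              d[1], d[2], d[3], min(x$values), max(x$values),
              mean(x$values), stats::sd(as.vector(x$values))))
  invisible(x)
}

#' Cartesian coordinates of every grid point
#' @param grid An [esp_grid()].
#' @return n x 3 matrix, fastest-varying first array index.
#' @export
grid_points <- function(grid) {
  d <- dim(grid$values)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  sweep(idx %*% grid$axes, 2, grid$origin, "+")
}

#' Fourier synthesis of an ESP map on the unit-cell grid
#'
#' \deqn{\rho(r) = (1/V) \sum_{hkl} F(hkl) e^{-2\pi i h\cdot x}} over the
#' full reflection sphere to `d_min`, with the constant term replaced by the
#' supplied `f000` (which must be given explicitly: ionic scattering factors
#' leave F(000) ill-defined). Friedel completeness makes the synthesis real;
#' the tiny imaginary residue is dropped after a sanity check.
#'
#' @param model A [crystal_model()].
#' @param d_min High-resolution limit of the synthesis (Å).
#' @param dims Grid dimensions, length 3; chosen Nyquist-safe when `NULL`
#'   (at least 3 points per minimum resolution element per axis).
#' @param f000 The F(000) value to place at the origin term. Mandatory.
#' @param sfac Optional scattering-factor table.
#' @return An [esp_grid()] spanning the unit cell (values in scattering
#'   units per Å^3, i.e. the arbitrary crystallographic potential scale).
#' @export
fourier_esp <- function(model, d_min, dims = NULL, f000, sfac = NULL) {
  if (missing(f000) || is.null(f000))
    stop("f000 must be supplied explicitly (it is ill-defined under ionic ",
         "scattering factors); use the conventional-refinement value",
         call. = FALSE)
  cell <- model$cell
  hmax <- pmin(ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L, 64L)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  s <- s_magnitude(cell, grid)
  sel <- s > 0 & s <= 1 / (2 * d_min)
  grid <- grid[sel, , drop = FALSE]
  sf <- structure_factors(model, grid, sfac)
  if (is.null(dims)) dims <- pmax(2L * hmax + 2L, ceiling(3 * c(cell$a, cell$b, cell$c) / d_min))
  dims <- as.integer(dims)
  if (any(dims <= 2L * hmax)) stop("grid dims too small for the hkl range", call. = FALSE)
  synthesize_esp(cell, grid, sf$F, dims, f000)
}

#' Fourier synthesis from explicit structure factors
#'
#' Lower-level entry: places the given coefficients (plus `f000` at the
#' origin) on an FFT mesh and synthesizes \eqn{(1/V)\sum F e^{-2\pi i hx}}.
#' The hkl list must be Friedel-complete (both +h and -h present, or a
#' centrosymmetric-real coefficient set) for a real map.
#'
#' @param cell A [unit_cell()].
#' @param hkl n x 3 integer matrix.
#' @param F Complex coefficients matching `hkl`.
#' @param dims Grid dimensions (each must exceed twice the max index).
#' @param f000 Constant term.
#' @return An [esp_grid()] over the unit cell.
#' @export
synthesize_esp <- function(cell, hkl, F, dims, f000) {
  dims <- as.integer(dims)
  arr <- array(0i, dims)
  idx <- sweep(hkl, 2, dims, "%%") + 1L
  for (i in seq_len(nrow(hkl)))
    arr[idx[i, 1], idx[i, 2], idx[i, 3]] <- arr[idx[i, 1], idx[i, 2], idx[i, 3]] + F[i]
  arr[1, 1, 1] <- arr[1, 1, 1] + f000
  ## rho_ijk = (1/V) sum_h F_h exp(-2 pi i (h i/n1 + k j/n2 + l k/n3)): a
  ## forward DFT of the coefficient mesh
  rho <- fft(arr) / cell$volume
  im_ratio <- max(abs(Im(rho))) / max(abs(Re(rho)) + 1e-300)
  if (im_ratio > 1e-6)
    warning("synthesis is not Friedel-complete (imaginary ratio ",
            formatC(im_ratio, digits = 3, format = "g"), ")")
  axes <- diag(1 / dims) %*% t(cell$orth)   # row i: cell vector i / n_i
  esp_grid(Re(rho), origin = c(0, 0, 0), axes = axes)
}

## ------------------------------- CUBE I/O ---------------------------------

#' Write a grid as Gaussian CUBE text
#'
#' Standard CUBE layout: two comment lines, atom count and origin (Bohr),
#' three axis records (count + step vector in Bohr), optional atom block,
#' then values with the last axis fastest. Deterministic output.
#'
#' @param grid An [esp_grid()].
#' @param path Output file.
#' @param atoms Optional data frame with `Z`, `x`, `y`, `z` (Cartesian Å).
#' @return Invisibly, `path`.
#' @export
write_cube <- function(grid, path, atoms = NULL) {
  d <- dim(grid$values)
  natom <- if (is.null(atoms)) 0L else nrow(atoms)
  lines <- c("isfac electrostatic potential map",
             "values in arbitrary crystallographic units",
             sprintf("%5d%12.6f%12.6f%12.6f", natom,
                     grid$origin[1] / .BOHR, grid$origin[2] / .BOHR,
                     grid$origin[3] / .BOHR))
  for (i in 1:3)
    lines <- c(lines, sprintf("%5d%12.6f%12.6f%12.6f", d[i],
                              grid$axes[i, 1] / .BOHR, grid$axes[i, 2] / .BOHR,
                              grid$axes[i, 3] / .BOHR))
  if (!is.null(atoms))
    for (i in seq_len(nrow(atoms)))
      lines <- c(lines, sprintf("%5d%12.6f%12.6f%12.6f%12.6f", atoms$Z[i], 0,
                                atoms$x[i] / .BOHR, atoms$y[i] / .BOHR,
                                atoms$z[i] / .BOHR))
  ## values: first index slowest, last fastest, 6 per line
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest after transpose
  ord <- sprintf("%13.5E", vals)
  ## regroup: for each (i, j) row of nz values, lines of 6
  nz <- d[3]
  vlines <- character()
  pos <- 1L
  for (blk in seq_len(d[1] * d[2])) {
    row <- ord[pos:(pos + nz - 1L)]
    pos <- pos + nz
    vlines <- c(vlines, vapply(split(row, ceiling(seq_along(row) / 6)),
                               paste, "", collapse = ""))
  }
  writeLines(c(lines, vlines), path)
  invisible(path)
}

#' Read a Gaussian CUBE file
#'
#' @param path Input file.
#' @return An [esp_grid()] (coordinates converted from Bohr to Å) with any
#'   atom block attached as attribute `"atoms"`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("CUBE parse error at line 1: file too short",
                               call. = FALSE)
  parse_nums <- function(i, n_expected) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < n_expected || anyNA(v[seq_len(n_expected)]))
      stop("CUBE parse error at line ", i, call. = FALSE)
    v
  }
  hdr <- parse_nums(3, 4)
  natom <- abs(as.integer(hdr[1]))
  origin <- hdr[2:4] * .BOHR
  dims <- integer(3); axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- parse_nums(3 + i, 4)
    dims[i] <- as.integer(abs(v[1]))
    ## negative counts flag Angstrom units in some dialects; positive = Bohr
    conv <- if (v[1] < 0) 1 else .BOHR
    axes[i, ] <- v[2:4] * conv
  }
  atoms <- NULL
  if (natom > 0L) {
    rows <- lapply(seq_len(natom), function(i) parse_nums(6 + i, 5))
    atoms <- data.frame(Z = vapply(rows, function(r) as.integer(r[1]), 0L),
                        x = vapply(rows, function(r) r[3], 0) * .BOHR,
                        y = vapply(rows, function(r) r[4], 0) * .BOHR,
                        z = vapply(rows, function(r) r[5], 0) * .BOHR)
  }
  start <- 7L + natom
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[start:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop("CUBE parse error: expected ", prod(dims), " values, found ",
         length(vals), call. = FALSE)
  arr <- aperm(array(vals, rev(dims)), c(3, 2, 1))  # stored last-axis-fastest
  g <- esp_grid(arr, origin = origin, axes = axes)
  attr(g, "atoms") <- atoms
  g
}

## ------------------------- grid comparison --------------------------------

## trilinear interpolation of grid values at fractional indices (0-based)
.trilinear <- function(values, fi) {
  d <- dim(values)
  i0 <- pmin(pmax(floor(fi), 0), matrix(rep(d - 2L, each = nrow(fi)), ncol = 3))
  t_ <- fi - i0
  v <- numeric(nrow(fi))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) t_[, 1] else 1 - t_[, 1]) *
         (if (dy == 1) t_[, 2] else 1 - t_[, 2]) *
         (if (dz == 1) t_[, 3] else 1 - t_[, 3])
    v <- v + w * values[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L,
                              i0[, 3] + dz + 1L)]
  }
  v
}

#' Pearson correlation of two grids with non-identical spacing
#'
#' Resamples `grid_b` onto `grid_a`'s points by trilinear interpolation over
#' the spatial overlap (points of `grid_a` falling outside `grid_b` are
#' excluded) and computes the Pearson coefficient over the sampled pairs.
#' The coefficient is invariant under affine rescaling of either map.
#'
#' @param grid_a,grid_b [esp_grid()] objects with overlapping support.
#' @param mask Optional `list(centers = n x 3 Cartesian Å, radius = Å)`
#'   restricting the comparison to points near selected atoms.
#' @return List with `pearson` and `n` (points compared).
#' @export
grid_pearson <- function(grid_a, grid_b, mask = NULL) {
  pts <- grid_points(grid_a)
  va <- as.vector(grid_a$values)
  ## fractional index of each point in grid_b's frame
  fi <- sweep(pts, 2, grid_b$origin, "-") %*% solve(grid_b$axes)
  db <- dim(grid_b$values)
  inside <- fi[, 1] >= 0 & fi[, 1] <= db[1] - 1 &
            fi[, 2] >= 0 & fi[, 2] <= db[2] - 1 &
            fi[, 3] >= 0 & fi[, 3] <= db[3] - 1
  if (!is.null(mask)) {
    keep <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(mask$centers))) {
      dd <- sweep(pts, 2, as.numeric(mask$centers[i, ]), "-")
      keep <- keep | rowSums(dd^2) <= mask$radius^2
    }
    inside <- inside & keep
  }
  if (sum(inside) < 3L) stop("empty (or near-empty) grid overlap", call. = FALSE)
  vb <- .trilinear(grid_b$values, fi[inside, , drop = FALSE])
  list(pearson = stats::cor(va[inside], vb), n = sum(inside))
}

#' Min/max/mean/sd summary of a grid
#' @param grid An [esp_grid()].
#' @return Named numeric vector.
#' @export
grid_stats <- function(grid) {
  v <- as.vector(grid$values)
  c(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
}
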