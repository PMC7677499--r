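# Grid state codes shared across the package
.SB_UNSEEN <- 0L
.SB_RAIN_VISITED <- 1L
.SB_RAIN_COVERED <- 2L
.SB_MATERIAL <- 3L
.SB_CAVITY_CENTER <- 4L
.SB_CAVITY_COVERED <- 5L

#' Probe and lattice parameters
#'
#' Bundles the tunable parameters of the cavity search: the lattice constant
#' `a` (grid spacing, Angstrom), the water-probe radius `r_w` (Angstrom), the
#' number of random box rotations to average over, and the RNG seed.
#'
#' @param a Lattice constant in Angstrom (default 0.6). Must satisfy `a < r_w`
#'   so a marching probe cannot tunnel through a blocking atom between steps.
#' @param r_w Water-probe radius in Angstrom (default 1.42).
#' @param n_rotations Number of random rotations averaged over (default 5).
#' @param seed Integer seed making the rotation protocol reproducible.
#' @param padding Box padding in Angstrom on every side; `NULL` (default)
#'   computes `max(vdw) + 2 * r_w + 3 * a` per structure.
#' @param vt_includes_cavity If `TRUE`, the total volume V_T counts cavity
#'   points in addition to material points.
#' @param pocket_threshold Closure-fraction threshold below which a cavity is
#'   labeled a pocket (default 0.21).
#' @param max_points Guard on the grid size; exceeding it is an error
#'   suggesting a larger `a`.
#' @return An object of class `sb_params`.
#' @export
probe_params <- function(a = 0.6, r_w = 1.42, n_rotations = 5L, seed = 1L,
                         padding = NULL, vt_includes_cavity = FALSE,
                         pocket_threshold = 0.21, max_points = 3e8) {
  stopifnot(a > 0, r_w > 0, n_rotations >= 1)
  if (a >= r_w) stop("lattice constant a must be smaller than the probe radius r_w")
  structure(list(a = a, r_w = r_w, n_rotations = as.integer(n_rotations),
                 seed = as.integer(seed), padding = padding,
                 vt_includes_cavity = isTRUE(vt_includes_cavity),
                 pocket_threshold = pocket_threshold,
                 max_points = max_points),
            class = "sb_params")
}

#' @export
print.sb_params <- function(x, ...) {
  cat(sprintf("sb_params: a = %g A, r_w = %g A, rotations = %d, seed = %d\n",
              x$a, x$r_w, x$n_rotations, x$seed))
  invisible(x)
}

#' Build the padded cuboid lattice box around a structure
#'
#' The axis-aligned box encloses every atom sphere with a padding of at least
#' `max(vdw) + 2 r_w + 3 a` on each side, so rain, probe covering and cavity
#' halos never clip at the walls. All points start in the UNSEEN state.
#'
#' @param structure An `sb_structure` with radii assigned.
#' @param params An `sb_params`.
#' @return An `sb_grid`: list with `origin` (A), `a`, `dims` (3 integers) and
#'   `state` (integer vector of length `prod(dims)`, column-major, i fastest).
#' @export
build_box <- function(structure, params) {
  stopifnot(inherits(structure, "sb_structure"), inherits(params, "sb_params"))
  if (.sb_natoms(structure) == 0) stop("empty structure")
  if (anyNA(structure$atom$vdw)) stop("assign van der Waals radii before building the box")
  pad <- params$padding
  if (is.null(pad)) pad <- max(structure$atom$vdw) + 2 * params$r_w + 3 * params$a
  xyz <- .sb_coords(structure)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / params$a)) + 1L
  if (prod(as.numeric(dims)) > params$max_points) {
    stop(sprintf("grid of %d x %d x %d points exceeds max_points = %g; raise the lattice constant a",
                 dims[1], dims[2], dims[3], params$max_points))
  }
  base::structure(list(origin = lo, a = params$a, dims = dims,
                       state = integer(prod(dims))),
                  class = "sb_grid")
}

#' @export
print.sb_grid <- function(x, ...) {
  counts <- tabulate(x$state + 1L, nbins = 6L)
  cat(sprintf("sb_grid: %d x %d x %d points, a = %g A\n",
              x$dims[1], x$dims[2], x$dims[3], x$a))
  cat(sprintf("  unseen %d | rain %d | rain-covered %d | material %d | cavity %d | cavity-covered %d\n",
              counts[1], counts[2], counts[3], counts[4], counts[5], counts[6]))
  invisible(x)
}

#' Cartesian coordinates of grid points
#'
#' @param grid An `sb_grid`.
#' @param idx 1-based linear indices into the grid (default: all points).
#' @return Numeric matrix (length(idx) x 3) of Angstrom coordinates.
#' @export
grid_coords <- function(grid, idx = seq_len(prod(grid$dims))) {
  i0 <- idx - 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]
  i <- i0 %% nx
  j <- (i0 %/% nx) %% ny
  k <- i0 %/% (nx * ny)
  cbind(grid$origin[1] + grid$a * i,
        grid$origin[2] + grid$a * j,
        grid$origin[3] + grid$a * k)
}

# integer offset ball: all (di,dj,dk) with |d * a| <= r, optionally without 0
.sb_ball_offsets <- function(r, a, include_zero = FALSE) {
  m <- floor(r / a)
  g <- as.matrix(expand.grid(di = -m:m, dj = -m:m, dk = -m:m))
  keep <- (g[, 1]^2 + g[, 2]^2 + g[, 3]^2) * a^2 <= r^2
  if (!include_zero) keep <- keep & rowSums(abs(g)) > 0
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Reproducible uniform random rotation
#'
#' Draws a proper rotation matrix uniformly from SO(3) (normalized 4-D Gaussian
#' quaternion), deterministically for a given `(seed, index)` pair and without
#' disturbing the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param index 0-based rotation index within the protocol.
#' @return A 3x3 rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed, index = 0L) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  sub_seed <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(index) * 1234567 + 11
  set.seed(as.integer(sub_seed %% 2147483647))
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a structure about its centroid
#'
#' @param structure An `sb_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param center Point to rotate about; defaults to the atom-coordinate centroid.
#' @return The rotated structure.
#' @export
rotate_structure <- function(structure, rotation, center = NULL) {
  stopifnot(inherits(structure, "sb_structure"))
  xyz <- .sb_coords(structure)
  if (is.null(center)) center <- colMeans(xyz)
  rot <- sweep(xyz, 2, center) %*% t(rotation)
  rot <- sweep(rot, 2, center, "+")
  structure$atom$x <- rot[, 1]
  structure$atom$y <- rot[, 2]
  structure$atom$z <- rot[, 3]
  structure
}

#' Rain water probes from the six box walls
#'
#' For each of the six axis directions and each perpendicular grid line, a
#' probe center marches inward from the wall in steps of `a`, marking every
#' visited point, and halts the line permanently at the first position where
#' the probe sphere overlaps any atom sphere (strictly, center distance
#' `< r_w + r_atom`; touching spheres do not block). Afterwards every point
#' within `r_w` of a visited point and not itself visited is marked
#' rain-covered: together these delimit the outside of the structure.
#'
#' @param grid An `sb_grid` from [build_box()].
#' @param structure The (possibly rotated) structure with radii assigned.
#' @param params An `sb_params`.
#' @return The grid with states RAIN_VISITED/RAIN_COVERED set, and the
#'   probe-overlap mask cached for [classify_points()].
#' @export
rain <- function(grid, structure, params) {
  stopifnot(inherits(grid, "sb_grid"), inherits(params, "sb_params"))
  blocked <- cpp_overlap_mask(.sb_coords(structure), structure$atom$vdw,
                              extra = params$r_w, origin = grid$origin,
                              a = grid$a, dims = grid$dims, strict = TRUE)
  visited <- cpp_rain(blocked, grid$dims)
  off <- .sb_ball_offsets(params$r_w, grid$a)
  covered <- cpp_dilate(visited, grid$dims, off) & !visited
  state <- grid$state
  state[visited] <- .SB_RAIN_VISITED
  state[covered] <- .SB_RAIN_COVERED
  grid$state <- state
  grid$blocked <- blocked
  grid
}
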