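#' Classify unseen grid points into material and cavity
#'
#' After the rain, every still-unseen point is tested with the water probe:
#' if the probe sphere placed there overlaps any atom sphere the point belongs
#' to the structure (MATERIAL), otherwise it is a cavity center. Every point
#' within `r_w` of a cavity center that is neither a center nor exterior-marked
#' becomes cavity-covered: the probe-encompassed halo that is counted into the
#' cavity volume.
#'
#' @param grid Post-[rain()] `sb_grid`.
#' @param structure The structure the rain was run against.
#' @param params An `sb_params`.
#' @return The grid with MATERIAL / CAVITY_CENTER / CAVITY_COVERED states set.
#' @export
classify_points <- function(grid, structure, params) {
  stopifnot(inherits(grid, "sb_grid"))
  blocked <- grid$blocked
  if (is.null(blocked)) {
    blocked <- cpp_overlap_mask(.sb_coords(structure), structure$atom$vdw,
                                extra = params$r_w, origin = grid$origin,
                                a = grid$a, dims = grid$dims, strict = TRUE)
  }
  state <- grid$state
  unseen <- state == .SB_UNSEEN
  state[unseen & blocked] <- .SB_MATERIAL
  centers <- unseen & !blocked
  state[centers] <- .SB_CAVITY_CENTER
  off <- .sb_ball_offsets(params$r_w, grid$a)
  halo <- cpp_dilate(centers, grid$dims, off)
  halo <- halo & !centers & state != .SB_RAIN_VISITED & state != .SB_RAIN_COVERED
  state[halo] <- .SB_CAVITY_COVERED
  grid$state <- state
  grid$blocked <- blocked
  grid
}

#' Label cavity chambers
#'
#' Connected components of cavity-center points under 6-connectivity (face
#' adjacency). Each chamber is then augmented with its probe-covered halo;
#' a halo point reachable from several chambers goes to the chamber with more
#' center points (tie: lower label).
#'
#' @param grid Classified `sb_grid`.
#' @param params An `sb_params` (for the halo radius `r_w`).
#' @return List of class `sb_chambers`: `labels` (per-point chamber id over
#'   centers), `halo_labels` (per-point chamber id over halo points),
#'   `chamber_map` (union of both), `n_chambers`, and a `sizes` data frame
#'   (center, halo and total point counts and volumes in nm^3 per chamber).
#' @export
label_chambers <- function(grid, params) {
  stopifnot(inherits(grid, "sb_grid"))
  centers <- grid$state == .SB_CAVITY_CENTER
  labels <- cpp_label6(centers, grid$dims)
  n <- max(labels)
  halo <- grid$state == .SB_CAVITY_COVERED
  if (n == 0) {
    sizes <- data.frame(label = integer(0), centers = integer(0),
                        halo = integer(0), total = integer(0), nm3 = numeric(0))
    return(base::structure(list(labels = labels, halo_labels = integer(length(labels)),
                                chamber_map = labels, n_chambers = 0L, sizes = sizes),
                           class = "sb_chambers"))
  }
  center_sizes <- tabulate(labels[labels > 0L], nbins = n)
  off <- .sb_ball_offsets(params$r_w, grid$a)
  halo_labels <- cpp_halo_assign(halo, labels, center_sizes, grid$dims, off)
  halo_sizes <- tabulate(halo_labels[halo_labels > 0L], nbins = n)
  total <- center_sizes + halo_sizes
  sizes <- data.frame(label = seq_len(n), centers = center_sizes,
                      halo = halo_sizes, total = total,
                      nm3 = total * grid$a^3 / 1000)
  chamber_map <- labels
  chamber_map[halo_labels > 0L] <- halo_labels[halo_labels > 0L]
  base::structure(list(labels = labels, halo_labels = halo_labels,
                       chamber_map = chamber_map, n_chambers = n, sizes = sizes),
                  class = "sb_chambers")
}

#' Total and cavity volumes
#'
#' `V_T` is the material point count times `a^3`; `V_C` is the point count
#' (centers plus halo) of the largest chamber times `a^3`. Both in nm^3.
#'
#' @param grid Classified `sb_grid`.
#' @param chambers An `sb_chambers` from [label_chambers()].
#' @param params An `sb_params`; with `vt_includes_cavity = TRUE`, V_T also
#'   counts all cavity points.
#' @return List with `V_T`, `V_C` (nm^3), `largest` (chamber label or `NA`),
#'   and `chamber_nm3` (per-chamber volumes).
#' @export
measure_volumes <- function(grid, chambers, params) {
  a3 <- grid$a^3 / 1000
  n_mat <- sum(grid$state == .SB_MATERIAL)
  n_cav_all <- sum(chambers$sizes$total)
  V_T <- a3 * (n_mat + if (params$vt_includes_cavity) n_cav_all else 0)
  if (chambers$n_chambers == 0) {
    return(list(V_T = V_T, V_C = 0, largest = NA_integer_, chamber_nm3 = numeric(0)))
  }
  largest <- which.max(chambers$sizes$total)   # ties: lower label
  list(V_T = V_T, V_C = chambers$sizes$nm3[largest],
       largest = chambers$sizes$label[largest], chamber_nm3 = chambers$sizes$nm3)
}

#' Find entrance points of a chamber
#'
#' A cavity point (center or halo) counts as an entrance when along at least
#' one of the six axis-aligned rays from the point to the box wall no grid
#' point lies strictly inside any atom's van der Waals sphere, i.e. there is a
#' straight line connecting the cavity to the outside that passes no protein
#' atom. A sealed chamber has an empty entrance set.
#'
#' @param grid Classified `sb_grid`.
#' @param structure The structure the grid was built for.
#' @param chambers An `sb_chambers`.
#' @param label Chamber label to examine (default: largest chamber).
#' @return List with `idx` (1-based grid indices, possibly empty) and `coords`
#'   (matrix of Angstrom coordinates).
#' @export
find_entrances <- function(grid, structure, chambers, label = NULL) {
  if (chambers$n_chambers == 0) {
    return(list(idx = integer(0), coords = matrix(numeric(0), ncol = 3)))
  }
  if (is.null(label)) label <- chambers$sizes$label[which.max(chambers$sizes$total)]
  inside <- cpp_overlap_mask(.sb_coords(structure), structure$atom$vdw,
                             extra = 0, origin = grid$origin, a = grid$a,
                             dims = grid$dims, strict = TRUE)
  clear <- cpp_clear_any_axis(inside, grid$dims)
  idx <- which(chambers$chamber_map == label & clear)
  list(idx = idx, coords = grid_coords(grid, idx))
}

# run the full pipeline for a single orientation; returns grid + chambers + record
.sb_run_single <- function(structure, params, rotation = diag(3)) {
  rot <- rotate_structure(structure, rotation)
  grid <- build_box(rot, params)
  grid <- rain(grid, rot, params)
  grid <- classify_points(grid, rot, params)
  chambers <- label_chambers(grid, params)
  vol <- measure_volumes(grid, chambers, params)
  entr <- find_entrances(grid, rot, chambers, label = vol$largest)
  cav_idx <- if (is.na(vol$largest)) integer(0) else which(chambers$chamber_map == vol$largest)
  list(grid = grid, chambers = chambers, structure_rot = rot, rotation = rotation,
       record = list(V_T = vol$V_T, V_C = vol$V_C,
                     n_chambers = chambers$n_chambers,
                     chamber_nm3 = vol$chamber_nm3, largest = vol$largest,
                     cavity_idx = cav_idx,
                     cavity_coords = grid_coords(grid, cav_idx),
                     entrance_idx = entr$idx, entrance_coords = entr$coords))
}

#' Run the full rotation-averaged cavity search
#'
#' Executes build-box, rain, classification, chamber labeling and volume
#' measurement for `n_rotations` uniformly random orientations of the
#' structure (the grid box stays axis-aligned and is rebuilt per rotation),
#' and summarizes the volumes as mean and standard deviation. The rotation
#' with the median cavity volume (even count: lower median) is kept as the
#' reference orientation for downstream surface and shell analysis.
#'
#' @param structure An `sb_structure`; radii are assigned from the default
#'   table if missing.
#' @param params An `sb_params`.
#' @return Object of class `spaceball`: per-rotation records (`rotations`),
#'   `summary` (mean/sd of V_T and V_C), `reference_rotation` (1-based index)
#'   and `reference` (grid, chambers and rotated structure of that rotation).
#' @export
run_spaceball <- function(structure, params = probe_params()) {
  stopifnot(inherits(structure, "sb_structure"), inherits(params, "sb_params"))
  if (.sb_natoms(structure) == 0) stop("empty structure")
  if (anyNA(structure$atom$vdw)) structure <- assign_radii(structure)
  runs <- vector("list", params$n_rotations)
  for (r in seq_len(params$n_rotations)) {
    rot <- random_rotation(params$seed, r - 1L)
    runs[[r]] <- .sb_run_single(structure, params, rot)
    runs[[r]]$grid$blocked <- NULL
  }
  vc <- vapply(runs, function(x) x$record$V_C, 0)
  vt <- vapply(runs, function(x) x$record$V_T, 0)
  ord <- order(vc)
  nr <- length(vc)
  ref <- ord[if (nr %% 2 == 1) (nr + 1) / 2 else nr / 2]
  records <- lapply(runs, `[[`, "record")
  out <- base::structure(list(
    id = structure$id,
    params = params,
    rotations = records,
    summary = list(V_T_mean = mean(vt), V_T_sd = stats::sd(vt),
                   V_C_mean = mean(vc), V_C_sd = stats::sd(vc)),
    reference_rotation = ref,
    reference = runs[[ref]]
  ), class = "spaceball")
  out
}

#' @export
print.spaceball <- function(x, ...) {
  s <- x$summary
  cat(sprintf("spaceball result for '%s' (%d rotation%s, a = %g A, r_w = %g A)\n",
              x$id, length(x$rotations), if (length(x$rotations) > 1) "s" else "",
              x$params$a, x$params$r_w))
  cat(sprintf("  V_C = %.2f +/- %.2f nm^3 | V_T = %.2f +/- %.2f nm^3\n",
              s$V_C_mean, if (is.na(s$V_C_sd)) 0 else s$V_C_sd,
              s$V_T_mean, if (is.na(s$V_T_sd)) 0 else s$V_T_sd))
  ref <- x$rotations[[x$reference_rotation]]
  cat(sprintf("  reference rotation %d: %d chamber(s), largest = %.2f nm^3, %d entrance point(s)\n",
              x$reference_rotation, ref$n_chambers, ref$V_C, length(ref$entrance_idx)))
  invisible(x)
}

#' Dump cavity grid points as PDB pseudo-atoms
#'
#' Writes the cavity points of the reference rotation as HETATM-free pseudo
#' oxygen atoms (one residue per chamber, occupancy = chamber id) for quick
#' visual inspection in any molecular viewer.
#'
#' @param result A `spaceball` result.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
dump_cavity_pdb <- function(result, path) {
  stopifnot(inherits(result, "spaceball"))
  ref <- result$reference
  idx <- which(ref$chambers$chamber_map > 0L)
  if (length(idx) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  xyz <- grid_coords(ref$grid, idx)
  lab <- ref$chambers$chamber_map[idx]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = lab,
                   resid = rep("CAV", length(idx)),
                   eleno = seq_along(idx),
                   elety = rep("O", length(idx)),
                   o = lab, b = rep(0, length(idx)),
                   elesy = rep("O", length(idx)))
  invisible(path)
}
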