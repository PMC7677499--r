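#' Extract the cavity surface and its area
#'
#' The chamber's cavity-center points are turned into a pseudo-structure of
#' probe-radius spheres and the rain is re-run against it; the rain-reachable
#' side of the chamber boundary is its surface, while boundary faces towards
#' holes enclosed inside the chamber blob are excluded. The area is counted
#' grid-natively: each exposed face between a chamber point and an
#' exterior-side neighbor contributes `a^2`.
#'
#' @param result A `spaceball` result (its reference rotation is analyzed), or
#'   a single-run list as produced internally.
#' @param params An `sb_params`.
#' @param label Chamber label; default the largest chamber.
#' @return Object of class `sb_surface`: `surface_idx` (grid indices),
#'   `coords`, `faces` (per-surface-point exposed face counts), `S_C` (nm^2),
#'   and the grid/structure context used downstream.
#' @export
extract_surface <- function(result, params, label = NULL) {
  run <- if (inherits(result, "spaceball")) result$reference else result
  grid <- run$grid
  chambers <- run$chambers
  if (chambers$n_chambers == 0) {
    return(base::structure(list(surface_idx = integer(0),
                                coords = matrix(numeric(0), ncol = 3),
                                faces = integer(0), S_C = 0,
                                label = NA_integer_, grid = grid,
                                structure_rot = run$structure_rot),
                           class = "sb_surface"))
  }
  if (is.null(label)) label <- chambers$sizes$label[which.max(chambers$sizes$total)]
  pset <- chambers$chamber_map == label
  centers_idx <- which(chambers$labels == label)
  pseudo <- grid_coords(grid, centers_idx)
  r_w <- params$r_w
  blocked2 <- cpp_overlap_mask(pseudo, rep(r_w, nrow(pseudo)), extra = r_w,
                               origin = grid$origin, a = grid$a,
                               dims = grid$dims, strict = TRUE)
  visited2 <- cpp_rain(blocked2, grid$dims)
  off <- .sb_ball_offsets(r_w, grid$a)
  covered2 <- cpp_dilate(visited2, grid$dims, off) & !visited2
  exterior2 <- visited2 | covered2
  unseen2 <- !exterior2
  hole2 <- unseen2 & !blocked2             # enclosed holes of the pseudo-structure
  if (any(hole2)) {
    hole_halo <- cpp_dilate(hole2, grid$dims, off) & !exterior2
    interior_excl <- hole2 | hole_halo
  } else {
    interior_excl <- hole2
  }
  ext_ok <- !pset & !interior_excl
  faces <- cpp_boundary_faces(pset, ext_ok, grid$dims)
  surface_idx <- which(faces > 0L)
  base::structure(list(surface_idx = surface_idx,
                       coords = grid_coords(grid, surface_idx),
                       faces = faces[surface_idx],
                       S_C = sum(faces) * grid$a^2 / 100,
                       label = label, grid = grid,
                       structure_rot = run$structure_rot),
                  class = "sb_surface")
}

#' Split the cavity surface into protein-contact and open-cap parts
#'
#' A surface point is in immediate protein contact when its nearest atom
#' center lies within `r_w + r_atom + a` (one lattice spacing absorbs grid
#' quantization). Contact faces make up `S_CP`; the rest is the open cap that
#' closes the cavity towards the solvent. The closure fraction `s = S_CP/S_C`
#' is 1 for a fully sealed cavity and small for open pockets.
#'
#' @param surface An `sb_surface` from [extract_surface()].
#' @param structure Structure in the same frame as the surface (the rotated
#'   reference structure; taken from the surface object when omitted).
#' @param params An `sb_params`.
#' @return Object of class `sb_surface_metrics`: `S_C`, `S_CP` (nm^2), `s`
#'   (`NA` when `S_C = 0`), per-point `contact` flags and the surface context.
#' @export
contact_split <- function(surface, structure = NULL, params = probe_params()) {
  stopifnot(inherits(surface, "sb_surface"))
  if (is.null(structure)) structure <- surface$structure_rot
  if (length(surface$surface_idx) == 0 || surface$S_C == 0) {
    return(base::structure(list(S_C = 0, S_CP = 0, s = NA_real_,
                                contact = logical(0), surface = surface),
                           class = "sb_surface_metrics"))
  }
  grid <- surface$grid
  contact_mask <- cpp_overlap_mask(.sb_coords(structure), structure$atom$vdw,
                                   extra = params$r_w + params$a,
                                   origin = grid$origin, a = grid$a,
                                   dims = grid$dims, strict = FALSE)
  contact <- contact_mask[surface$surface_idx]
  S_CP <- sum(surface$faces[contact]) * grid$a^2 / 100
  base::structure(list(S_C = surface$S_C, S_CP = S_CP, s = S_CP / surface$S_C,
                       contact = contact, surface = surface),
                  class = "sb_surface_metrics")
}

#' Pocket versus cavity classification
#'
#' A formation whose closure fraction falls below the threshold is mostly
#' exposed to the solvent and is labeled a pocket; the default threshold 0.21
#' derives from the survey statistics mean(s) - 3 sd(s) with mean 0.36 and
#' sd 0.05. The inequality is strict: `s` equal to the threshold is a cavity.
#'
#' @param s Closure fraction in `[0, 1]` (NA allowed, gives NA).
#' @param threshold Classification threshold (default 0.21).
#' @return `"pocket"` or `"cavity"` (character, vectorized; `NA` for `NA` s).
#' @export
classify_pocket <- function(s, threshold = 0.21) {
  ifelse(is.na(s), NA_character_, ifelse(s < threshold, "pocket", "cavity"))
}

#' Surface metrics of the reference-rotation cavity
#'
#' Convenience wrapper: extracts the surface of the largest chamber of the
#' reference rotation, splits it into contact and cap, and classifies the
#' formation as pocket or cavity.
#'
#' @param result A `spaceball` result.
#' @param params The `sb_params` used for the run (defaults to the ones stored
#'   in the result).
#' @param label Optional chamber label.
#' @return An `sb_surface_metrics` with an added `label_class` field.
#' @export
surface_metrics <- function(result, params = NULL, label = NULL) {
  stopifnot(inherits(result, "spaceball"))
  if (is.null(params)) params <- result$params
  surf <- extract_surface(result, params, label = label)
  met <- contact_split(surf, params = params)
  met$label_class <- classify_pocket(met$s, params$pocket_threshold)
  met
}

#' @export
print.sb_surface_metrics <- function(x, ...) {
  cat(sprintf("cavity surface: S_C = %.2f nm^2, S_CP = %.2f nm^2, s = %s -> %s\n",
              x$S_C, x$S_CP,
              if (is.na(x$s)) "NA" else sprintf("%.2f", x$s),
              if (is.null(x$label_class) || is.na(x$label_class)) "unclassified" else x$label_class))
  invisible(x)
}

#' Dump the cavity surface as PDB pseudo-atoms
#'
#' B-factor 1 marks protein-contact points, 0 cap points.
#'
#' @param metrics An `sb_surface_metrics`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
dump_surface_pdb <- function(metrics, path) {
  stopifnot(inherits(metrics, "sb_surface_metrics"))
  surf <- metrics$surface
  n <- length(surf$surface_idx)
  if (n == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(surf$coords)),
                   resno = rep(1L, n), resid = rep("SRF", n),
                   eleno = seq_len(n), elety = rep("O", n),
                   o = rep(1, n), b = as.numeric(metrics$contact),
                   elesy = rep("O", n))
  invisible(path)
}
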