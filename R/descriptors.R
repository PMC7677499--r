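#' Assign the cavity shell residues
#'
#' For every cavity-surface point the residue containing the nearest atom
#' (minimum center distance minus van der Waals radius) is recorded; the union
#' over all surface points is the cavity shell. The pairing is done in the
#' frame the surface was computed in (the rotated reference structure), while
#' residue positions reported downstream come from the structure's own input
#' coordinates (shell membership is frame-independent).
#'
#' @param surface An `sb_surface` from [extract_surface()].
#' @param structure The original (unrotated) `sb_structure`; defaults to the
#'   rotated structure stored in the surface, which gives identical membership.
#' @return Object of class `sb_shell`: `residues` (residue-level data frame
#'   with centers of mass, masses and hydropathy indices), `n` (N_CP), `com`
#'   (mass-weighted center of mass of all shell-residue atoms), and the
#'   shell-atom table.
#' @export
assign_shell <- function(surface, structure = NULL) {
  stopifnot(inherits(surface, "sb_surface"))
  paired <- surface$structure_rot
  if (is.null(structure)) structure <- paired
  if (length(surface$surface_idx) == 0) {
    return(base::structure(list(residues = structure_residues(structure)[0, ],
                                n = 0L, com = c(NA_real_, NA_real_, NA_real_),
                                atom = structure$atom[0, ]),
                           class = "sb_shell"))
  }
  nearest <- cpp_nearest_atom(surface$coords, .sb_coords(paired), paired$atom$vdw)
  keys <- unique(.sb_residue_key(paired$atom)[nearest])
  all_res <- structure_residues(structure)
  res <- all_res[all_res$key %in% keys, , drop = FALSE]
  rownames(res) <- NULL
  atom <- structure$atom[.sb_residue_key(structure$atom) %in% keys, , drop = FALSE]
  m <- atom$mass
  com <- c(sum(m * atom$x), sum(m * atom$y), sum(m * atom$z)) / sum(m)
  base::structure(list(residues = res, n = nrow(res), com = com, atom = atom),
                  class = "sb_shell")
}

#' @export
print.sb_shell <- function(x, ...) {
  cat(sprintf("cavity shell: %d residue(s), %d atom(s)\n", x$n, nrow(x$atom)))
  invisible(x)
}

#' Cavity hydrophobicity H
#'
#' Sum of Kyte-Doolittle hydropathy indices over the shell residues, each
#' residue counted once. Residues without a defined index (non-standard) are
#' excluded; their count is attached as attribute `n_excluded`.
#'
#' @param shell An `sb_shell`.
#' @return Numeric H (0 for an empty shell), with attribute `n_excluded`.
#' @export
hydropathy_H <- function(shell) {
  stopifnot(inherits(shell, "sb_shell"))
  q <- shell$residues$q
  H <- sum(q, na.rm = TRUE)
  attr(H, "n_excluded") <- sum(is.na(q))
  H
}

#' Hydropathy vector of the cavity shell
#'
#' First moment of the shell residues' hydropathy about the shell center of
#' mass: `h = sum_i q_i * delta_i`, where `delta_i` is the residue center of
#' mass relative to the shell center of mass. A large norm signals a
#' hydropathy gradient across the cavity.
#'
#' @param shell An `sb_shell` with at least one residue.
#' @return List with `h_vec` (3-vector, hydropathy x Angstrom) and `h_norm`;
#'   `NULL` for an empty shell.
#' @export
hydropathy_vector <- function(shell) {
  stopifnot(inherits(shell, "sb_shell"))
  if (shell$n == 0) return(NULL)
  res <- shell$residues
  ok <- !is.na(res$q)
  delta <- cbind(res$cx, res$cy, res$cz)[ok, , drop = FALSE]
  delta <- sweep(delta, 2, shell$com)
  h <- colSums(res$q[ok] * delta)
  list(h_vec = h, h_norm = sqrt(sum(h^2)))
}

#' Radius of gyration of the cavity shell
#'
#' Root-mean-square distance of the shell residues' centers of mass from the
#' shell center of mass, in Angstrom.
#'
#' @param shell An `sb_shell` with at least one residue.
#' @return Numeric R_g in Angstrom; `NULL` for an empty shell.
#' @export
radius_of_gyration <- function(shell) {
  stopifnot(inherits(shell, "sb_shell"))
  if (shell$n == 0) return(NULL)
  res <- shell$residues
  d <- sweep(cbind(res$cx, res$cy, res$cz), 2, shell$com)
  sqrt(mean(rowSums(d^2)))
}

#' Inertia radii and shape parameter of the cavity shell
#'
#' The inertia tensor is computed mass-weighted over all atoms of the shell
#' residues about the shell center of mass; its eigenvalues `D_1 <= D_2 <= D_3`
#' give the main radii `R_alpha = sqrt(D_alpha / N_C)` with `N_C` the shell
#' residue count (normalization by residue count as published). The shape
#' parameter is `w = (R_2 - Rbar) / Rbar` with `Rbar = (R_1 + R_3)/2`:
#' about 0 for spherical shells, substantially positive for elongated
#' (cigar-like) shells where `R_2` approaches `R_3`, negative for planar ones.
#'
#' @param shell An `sb_shell` with at least 3 residues and non-degenerate
#'   (non-collinear) geometry.
#' @return List with `radii` (R_1, R_2, R_3, Angstrom-like units), `w`,
#'   `R_bar`, `delta_R` and the eigenvalues `D`.
#' @export
shape_parameter <- function(shell) {
  stopifnot(inherits(shell, "sb_shell"))
  if (shell$n < 3) stop("shape parameter needs at least 3 shell residues")
  a <- shell$atom
  r <- sweep(cbind(a$x, a$y, a$z), 2, shell$com)
  m <- a$mass
  r2 <- rowSums(r^2)
  I <- diag(c(sum(m * r2), sum(m * r2), sum(m * r2)))
  for (i in 1:3) for (j in 1:3) I[i, j] <- I[i, j] - sum(m * r[, i] * r[, j])
  D <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  D[D < 0] <- 0   # numerical noise
  if (D[3] <= 0 || D[1] / D[3] < 1e-12) {
    stop("degenerate (collinear or point-like) shell geometry")
  }
  radii <- sqrt(D / shell$n)
  R_bar <- (radii[1] + radii[3]) / 2
  delta_R <- radii[2] - R_bar
  list(radii = radii, w = delta_R / R_bar, R_bar = R_bar, delta_R = delta_R, D = D)
}

#' All shell descriptors in one record
#'
#' @param shell An `sb_shell`.
#' @return Object of class `sb_descriptors` with fields N_CP, H, h_vec,
#'   h_norm, H_per_residue, R_g, R1, R2, R3, w; geometric fields are `NA` for
#'   empty or degenerate shells.
#' @export
shell_descriptors <- function(shell) {
  stopifnot(inherits(shell, "sb_shell"))
  out <- list(N_CP = shell$n, H = NA_real_, h_vec = rep(NA_real_, 3),
              h_norm = NA_real_, H_per_residue = NA_real_, R_g = NA_real_,
              R1 = NA_real_, R2 = NA_real_, R3 = NA_real_, w = NA_real_,
              n_excluded = 0L)
  if (shell$n == 0) {
    out$H <- 0
    return(base::structure(out, class = "sb_descriptors"))
  }
  H <- hydropathy_H(shell)
  out$n_excluded <- attr(H, "n_excluded")
  out$H <- as.numeric(H)
  out$H_per_residue <- out$H / shell$n
  hv <- hydropathy_vector(shell)
  out$h_vec <- hv$h_vec
  out$h_norm <- hv$h_norm
  out$R_g <- radius_of_gyration(shell)
  if (shell$n >= 3) {
    sp <- tryCatch(shape_parameter(shell), error = function(e) NULL)
    if (!is.null(sp)) {
      out$R1 <- sp$radii[1]; out$R2 <- sp$radii[2]; out$R3 <- sp$radii[3]
      out$w <- sp$w
    }
  }
  base::structure(out, class = "sb_descriptors")
}

#' @export
print.sb_descriptors <- function(x, ...) {
  cat(sprintf("shell descriptors: N_CP = %d, H = %.1f (%.2f/residue), |h| = %.1f\n",
              x$N_CP, x$H, x$H_per_residue, x$h_norm))
  cat(sprintf("  R_g = %.2f A, radii = (%.2f, %.2f, %.2f), w = %.2f\n",
              x$R_g, x$R1, x$R2, x$R3, x$w))
  invisible(x)
}
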