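# Synthetic PDB-format structures with analytically known cavity properties.
#
# All generators place one pseudo-atom per pseudo-residue (element C unless
# overridden) on a Fibonacci lattice over a sphere, stamped with chosen
# 3-letter residue codes, so the hydropathy descriptors are exactly
# controllable. Atom spacing is kept below 0.8 * 2 * r_w so a water probe can
# never leak between neighboring atoms where closure is intended.

.sb_fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)                 # polar angle from +z
  theta <- pi * (1 + sqrt(5)) * i            # golden-angle azimuth
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# largest nearest-neighbor distance over a point set (leak check)
.sb_max_nn <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  d2 <- as.matrix(stats::dist(xyz))^2
  diag(d2) <- Inf
  sqrt(max(apply(d2, 1, min)))
}

# number of Fibonacci points needed for a target spacing on a sphere of radius R;
# 3.809 R / sqrt(n) approximates the mean nearest-neighbor distance, the 1.18
# factor absorbs the slightly looser polar neighborhoods
.sb_fib_count <- function(R, spacing) ceiling((3.809 * R * 1.18 / spacing)^2)

.sb_shell_atoms <- function(unit, R_s, center = c(0, 0, 0), resname = "GLY",
                            chain = "A", element = "C", resno_start = 1L,
                            jitter = 0, seed = NULL) {
  xyz <- unit * R_s
  if (jitter > 0) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(if (is.null(seed)) 1L else as.integer(seed))
    xyz <- xyz + matrix(stats::runif(length(xyz), -jitter, jitter), ncol = 3)
  }
  xyz <- sweep(xyz, 2, center, "+")
  n <- nrow(xyz)
  resname <- rep_len(resname, n)
  chain <- rep_len(chain, n)
  data.frame(
    serial = resno_start - 1L + seq_len(n),
    element = toupper(element),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    resid = toupper(resname),
    chain = chain,
    resno = resno_start - 1L + seq_len(n),
    insert = "",
    elety = paste0(toupper(element), "1"),
    vdw = NA_real_,
    mass = .sb_element_mass(toupper(element)),
    stringsAsFactors = FALSE
  )
}

.sb_fixture <- function(atom, id, atom_radius, expected) {
  s <- .sb_new_structure(atom, id = id)
  s$atom$vdw <- atom_radius
  list(structure = s, expected = expected)
}

.sb_check_seal <- function(xyz, r_w, what) {
  max_nn <- .sb_max_nn(xyz)
  limit <- 0.8 * 2 * r_w
  if (max_nn > limit) {
    stop(sprintf("%s: atom spacing %.2f A exceeds the leak bound %.2f A; increase the point count",
                 what, max_nn, limit))
  }
  max_nn
}

#' Sealed hollow-sphere fixture
#'
#' Atoms on a Fibonacci lattice over a sphere of radius `R_s` enclose a void
#' whose cavity volume (centers plus probe halo) is analytically
#' `(4/3) pi (R_s - atom_radius)^3`: the probe-center ball of radius
#' `R_s - atom_radius - r_w` dilated back by `r_w`. Expected closure fraction
#' approaches 1, shape parameter 0, hydropathy vector 0 and the entrance set
#' is empty.
#'
#' @param R_s Shell radius in Angstrom; must exceed `atom_radius + 2 r_w`.
#' @param atom_radius Radius stamped on every pseudo-atom (default 1.70 A,
#'   matching the shipped carbon radius so PDB round trips preserve geometry).
#' @param n_atoms Number of shell atoms; `NULL` chooses the smallest count
#'   that satisfies the leak bound.
#' @param resname Residue code(s) stamped on the pseudo-residues.
#' @param r_w Probe radius used for the leak bound (default 1.42 A).
#' @param jitter Optional uniform coordinate jitter amplitude (A), seeded.
#' @param seed Seed for the jitter.
#' @return List with `structure` (an `sb_structure`) and `expected` (analytic
#'   values, formulas and tolerances, machine-readable).
#' @export
make_hollow_sphere <- function(R_s = 15, atom_radius = 1.70, n_atoms = NULL,
                               resname = "GLY", r_w = 1.42, jitter = 0, seed = NULL) {
  if (R_s <= atom_radius + 2 * r_w) stop("R_s must exceed atom_radius + 2 * r_w")
  if (is.null(n_atoms)) n_atoms <- .sb_fib_count(R_s, 0.8 * 2 * r_w)
  unit <- .sb_fib_sphere(n_atoms)
  atom <- .sb_shell_atoms(unit, R_s, resname = resname, jitter = jitter, seed = seed)
  .sb_check_seal(as.matrix(atom[, c("x", "y", "z")]), r_w, "hollow sphere")
  R_in <- R_s - atom_radius
  .sb_fixture(atom, sprintf("hollow_sphere_R%g", R_s), atom_radius, list(
    kind = "hollow_sphere",
    V_C_nm3 = 4 / 3 * pi * R_in^3 / 1000,
    V_C_formula = "(4/3) * pi * (R_s - atom_radius)^3",
    V_C_tol_rel = 0.10,
    s_min = 0.95, w_abs_max = 0.05, n_entrances = 0L, n_chambers = 1L
  ))
}

#' Open-cup fixture
#'
#' A hollow sphere with a polar cap removed (full cone angle `aperture_deg`
#' about +z). Larger apertures leave more of the cavity boundary open, so the
#' closure fraction `s` decreases with the aperture and large apertures drive
#' the formation below the pocket threshold.
#'
#' Because the cavity is the straight-line shadow region, which always keeps
#' a contact footprint on the wall, cups erode closure only down to s ~ 0.7
#' (apertures 10-120 degrees) and never cross the pocket threshold; at still
#' wider apertures the residual crescent hugs the wall and s rises again
#' while the volume keeps falling.
#'
#' @inheritParams make_hollow_sphere
#' @param aperture_deg Full aperture angle in degrees, 10-180.
#' @export
make_open_cup <- function(R_s = 15, aperture_deg = 60, atom_radius = 1.70,
                          n_atoms = NULL, resname = "GLY", r_w = 1.42) {
  if (aperture_deg < 10 || aperture_deg > 180) stop("aperture_deg must be in [10, 180]")
  if (is.null(n_atoms)) n_atoms <- .sb_fib_count(R_s, 0.8 * 2 * r_w)
  unit <- .sb_fib_sphere(n_atoms)
  polar <- acos(pmin(1, pmax(-1, unit[, 3])))
  keep <- polar > (aperture_deg / 2) * pi / 180
  atom <- .sb_shell_atoms(unit[keep, , drop = FALSE], R_s, resname = resname)
  .sb_fixture(atom, sprintf("open_cup_%gdeg", aperture_deg), atom_radius, list(
    kind = "open_cup", aperture_deg = aperture_deg,
    # closure erodes with aperture while the shadow cavity is substantial;
    # beyond ~120 deg the residual wall-hugging crescent drives s back up
    s_monotone_range_deg = c(10, 120),
    V_C_decreasing_in_aperture = TRUE
  ))
}

#' Bored-sphere fixture
#'
#' A hollow sphere with a cylindrical bore along +z: atoms whose distance from
#' the +z axis is below `bore_radius` (on the top hemisphere) are removed.
#' With `atom_radius < bore_radius < r_w + atom_radius` the bore admits
#' straight atom-free lines from the cavity to the outside (entrance points)
#' while remaining too narrow for the water probe, so the cavity stays sealed.
#'
#' @inheritParams make_hollow_sphere
#' @param bore_radius Bore radius in Angstrom (default 2.6).
#' @export
make_bored_sphere <- function(R_s = 15, bore_radius = 2.6, atom_radius = 1.70,
                              n_atoms = NULL, resname = "GLY", r_w = 1.42) {
  if (is.null(n_atoms)) n_atoms <- .sb_fib_count(R_s, 0.8 * 2 * r_w)
  unit <- .sb_fib_sphere(n_atoms)
  xyz <- unit * R_s
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  keep <- !(rho < bore_radius & xyz[, 3] > 0)
  atom <- .sb_shell_atoms(unit[keep, , drop = FALSE], R_s, resname = resname)
  .sb_fixture(atom, sprintf("bored_sphere_r%g", bore_radius), atom_radius, list(
    kind = "bored_sphere", bore_radius = bore_radius,
    sealed_to_probe = bore_radius < r_w + atom_radius,
    entrances_expected = bore_radius > atom_radius
  ))
}

#' Dumbbell fixture with two chambers
#'
#' Two hollow spheres of inner shell radii `r1 >= r2` centered `separation`
#' apart along x. Sealed (default): the voids are disjoint, two chambers, and
#' the cavity volume is the larger void's analytic volume. With
#' `merged = TRUE` the shells overlap and the atoms facing the neighboring
#' void are culled, opening a passage wider than the probe, so both voids form
#' a single chamber.
#'
#' @param r1,r2 Shell radii in Angstrom of the two spheres.
#' @param separation Center separation; defaults to `r1 + r2 + 2` (sealed) or
#'   `r1 + r2 - 4` (merged).
#' @param merged Open a probe-passable passage between the voids.
#' @inheritParams make_hollow_sphere
#' @export
make_dumbbell <- function(r1 = 12, r2 = 8, separation = NULL, merged = FALSE,
                          atom_radius = 1.70, resname = "GLY", r_w = 1.42) {
  if (r1 < r2) stop("r1 must be >= r2")
  if (is.null(separation)) separation <- if (merged) r1 + r2 - 4 else r1 + r2 + 2
  u1 <- .sb_fib_sphere(.sb_fib_count(r1, 0.8 * 2 * r_w))
  u2 <- .sb_fib_sphere(.sb_fib_count(r2, 0.8 * 2 * r_w))
  c1 <- c(0, 0, 0); c2 <- c(separation, 0, 0)
  a1 <- .sb_shell_atoms(u1, r1, center = c1, resname = resname, chain = "A")
  a2 <- .sb_shell_atoms(u2, r2, center = c2, resname = resname, chain = "B",
                        resno_start = nrow(a1) + 1L)
  if (merged) {
    # cull atoms strictly inside the other void so the voids connect
    keep1 <- sqrt((a1$x - c2[1])^2 + a1$y^2 + a1$z^2) > r2 - atom_radius
    keep2 <- sqrt((a2$x - c1[1])^2 + a2$y^2 + a2$z^2) > r1 - atom_radius
    a1 <- a1[keep1, , drop = FALSE]
    a2 <- a2[keep2, , drop = FALSE]
  }
  atom <- rbind(a1, a2)
  atom$serial <- seq_len(nrow(atom))
  V1 <- 4 / 3 * pi * (r1 - atom_radius)^3 / 1000
  V2 <- 4 / 3 * pi * (r2 - atom_radius)^3 / 1000
  .sb_fixture(atom, if (merged) "dumbbell_merged" else "dumbbell", atom_radius, list(
    kind = "dumbbell", merged = merged,
    n_chambers = if (merged) 1L else 2L,
    V_C_nm3 = if (merged) NA_real_ else max(V1, V2),
    V_small_nm3 = min(V1, V2), V_C_tol_rel = 0.10
  ))
}

#' Hydropathy-controlled shell fixture
#'
#' A sealed hollow sphere whose pseudo-residues are stamped with chosen codes:
#' `scheme = "uniform"` stamps one code on all residues (shell hydrophobicity
#' is then exactly `n * q`), `scheme = "bipartite"` stamps one code on the
#' upper (+z) hemisphere and another on the lower, producing a hydropathy
#' vector along +z of analytically computable magnitude.
#'
#' @param R_s Shell radius (default 7.5 A, sized so 200 residues seal it).
#' @param n_res Number of pseudo-residues (default 200).
#' @param scheme `"uniform"` or `"bipartite"`.
#' @param res_uniform Residue code for the uniform scheme (default ILE).
#' @param res_top,res_bottom Codes for the bipartite hemispheres.
#' @inheritParams make_hollow_sphere
#' @export
make_hydropathy_shell <- function(R_s = 7.5, n_res = 200,
                                  scheme = c("uniform", "bipartite"),
                                  res_uniform = "ILE", res_top = "ILE",
                                  res_bottom = "ARG", atom_radius = 1.70,
                                  r_w = 1.42) {
  scheme <- match.arg(scheme)
  unit <- .sb_fib_sphere(n_res)
  resname <- if (scheme == "uniform") rep(res_uniform, n_res) else
    ifelse(unit[, 3] >= 0, res_top, res_bottom)
  atom <- .sb_shell_atoms(unit, R_s, resname = resname)
  .sb_check_seal(as.matrix(atom[, c("x", "y", "z")]), r_w, "hydropathy shell")
  q <- kd_index(resname)
  xyz <- unit * R_s
  com <- colMeans(xyz)              # equal masses: plain centroid
  h <- colSums(q * sweep(xyz, 2, com))
  .sb_fixture(atom, sprintf("hydropathy_shell_%s", scheme), atom_radius, list(
    kind = "hydropathy_shell", scheme = scheme,
    H = sum(q), h_vec = h, h_norm = sqrt(sum(h^2)), n_res = n_res
  ))
}

#' Ring-of-chains (quaternary structure) fixture
#'
#' A sealed hollow sphere whose atoms are divided into `n_chains` azimuthal
#' wedge chains: no single chain encloses space, but the assembly does,
#' mirroring cavities that exist only in the complete quaternary structure.
#' With `gap_deg > 0` azimuthal gaps are cut between the wedges and the polar
#' caps (|latitude| > 60 degrees) are removed, so the assembly leaks along
#' straight lines. Because probes travel along straight lines only, narrow
#' gaps carve narrow columns and leave large shadow cavities; the wedges must
#' be narrow (gaps of ~90 degrees for 3 chains, leaving ~30-degree wedges)
#' before the interior is reachable from essentially every direction and the
#' residual cavity drops to a fraction of a percent of the sealed volume.
#'
#' @param n_chains Number of chains (>= 3).
#' @param gap_deg Azimuthal gap between consecutive wedges, degrees.
#' @inheritParams make_hollow_sphere
#' @export
make_tetramer_ring <- function(n_chains = 4, R_s = 13, gap_deg = 0,
                               atom_radius = 1.70, resname = "GLY", r_w = 1.42) {
  if (n_chains < 3) stop("n_chains must be >= 3")
  n_atoms <- .sb_fib_count(R_s, 0.8 * 2 * r_w)
  unit <- .sb_fib_sphere(n_atoms)
  az <- atan2(unit[, 2], unit[, 1]) %% (2 * pi)
  sector <- 2 * pi / n_chains
  chain_i <- pmin(floor(az / sector), n_chains - 1)
  keep <- rep(TRUE, n_atoms)
  if (gap_deg > 0) {
    gap <- gap_deg * pi / 180
    within_gap <- (az %% sector) < gap / 2 | (az %% sector) > sector - gap / 2
    lat <- asin(pmin(1, pmax(-1, unit[, 3])))
    keep <- !within_gap & abs(lat) < pi / 3
  }
  atom <- .sb_shell_atoms(unit[keep, , drop = FALSE], R_s, resname = resname,
                          chain = LETTERS[chain_i[keep] + 1L])
  if (gap_deg == 0) {
    .sb_check_seal(as.matrix(atom[, c("x", "y", "z")]), r_w, "ring assembly")
  }
  .sb_fixture(atom, sprintf("ring_%dchains_gap%g", n_chains, gap_deg), atom_radius, list(
    kind = "tetramer_ring", n_chains = n_chains, gap_deg = gap_deg,
    sealed = gap_deg == 0,
    V_C_nm3 = if (gap_deg == 0) 4 / 3 * pi * (R_s - atom_radius)^3 / 1000 else 0,
    V_C_leaky_max_nm3 = 0.2
  ))
}

#' Write a fixture to PDB plus a machine-readable expected-value record
#'
#' @param fixture A fixture list from one of the `make_*` generators.
#' @param pdb_path Output PDB path.
#' @param expected_path Optional JSON path for the expected-value record.
#' @return `pdb_path`, invisibly.
#' @export
write_fixture <- function(fixture, pdb_path, expected_path = NULL) {
  write_structure_pdb(fixture$structure, pdb_path)
  if (!is.null(expected_path)) {
    jsonlite::write_json(fixture$expected, expected_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(pdb_path)
}
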