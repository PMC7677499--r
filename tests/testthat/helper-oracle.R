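# Independent brute-force oracles and small builders shared across tests.

# hand-built structure from bare coordinates and radii
tiny_structure <- function(coords, radii, resname = "GLY", chain = "A",
                           element = "C", id = "tiny") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  atom <- data.frame(
    serial = seq_len(n), element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    resid = rep_len(toupper(resname), n), chain = rep_len(chain, n),
    resno = seq_len(n), insert = "", elety = paste0(element, "1"),
    vdw = rep_len(radii, n), mass = 12.011, stringsAsFactors = FALSE
  )
  st <- structure(list(id = id, atom = atom), class = "sb_structure")
  st
}

# brute-force probe-overlap mask: for every grid point test every atom
oracle_blocked <- function(grid, st, r_w, extra = r_w, strict = TRUE) {
  pts <- grid_coords(grid)
  xyz <- as.matrix(st$atom[, c("x", "y", "z")])
  rr <- st$atom$vdw + extra
  out <- rep(FALSE, nrow(pts))
  for (t in seq_len(nrow(xyz))) {
    d2 <- (pts[, 1] - xyz[t, 1])^2 + (pts[, 2] - xyz[t, 2])^2 + (pts[, 3] - xyz[t, 3])^2
    out <- out | if (strict) d2 < rr[t]^2 else d2 <= rr[t]^2
  }
  out
}

# brute-force rain: for each of the 6 wall directions and each grid line,
# every probe position from the wall up to (excluding) the first blocked one
# is visited
oracle_rain <- function(blocked, dims) {
  B <- array(blocked, dim = dims)
  V <- array(FALSE, dim = dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  for (j in seq_len(ny)) for (k in seq_len(nz)) {
    line <- B[, j, k]
    V[, j, k] <- V[, j, k] | (cumsum(line) == 0) | rev(cumsum(rev(line)) == 0)
  }
  for (i in seq_len(nx)) for (k in seq_len(nz)) {
    line <- B[i, , k]
    V[i, , k] <- V[i, , k] | (cumsum(line) == 0) | rev(cumsum(rev(line)) == 0)
  }
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    line <- B[i, j, ]
    V[i, j, ] <- V[i, j, ] | (cumsum(line) == 0) | rev(cumsum(rev(line)) == 0)
  }
  as.vector(V)
}

# exact within-radius test between grid points and a set of marked points,
# chunked to keep memory bounded; small grids only
oracle_within <- function(grid, mark_idx, r) {
  pts <- grid_coords(grid)
  src <- grid_coords(grid, mark_idx)
  out <- rep(FALSE, nrow(pts))
  if (length(mark_idx) == 0) return(out)
  step <- 2000L
  for (s in seq(1, nrow(pts), by = step)) {
    e <- min(s + step - 1L, nrow(pts))
    d2 <- outer(pts[s:e, 1], src[, 1], "-")^2 +
      outer(pts[s:e, 2], src[, 2], "-")^2 +
      outer(pts[s:e, 3], src[, 3], "-")^2
    out[s:e] <- apply(d2 <= r^2, 1, any)
  }
  out
}

# random blob of atoms for oracle-equivalence sweeps
random_fixture <- function(seed, n_atoms = 12, box = 8) {
  set.seed(seed)
  coords <- matrix(runif(3 * n_atoms, -box / 2, box / 2), ncol = 3)
  radii <- runif(n_atoms, 1.2, 2.0)
  tiny_structure(coords, radii, id = paste0("random_", seed))
}

# fixed-column PDB line builder for I/O tests
pdb_line <- function(record = "ATOM", serial, name, alt = "", resid, chain,
                     resno, icode = "", x, y, z, occ = 1, b = 0, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resid, chain, resno, icode, x, y, z, occ, b, element)
}

# lazy cache so expensive runs are shared between test files
.sb_test_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .sb_test_cache)) {
    assign(name, force(expr), envir = .sb_test_cache)
  }
  get(name, envir = .sb_test_cache)
}

# the workhorse reference run: sealed hollow sphere, single orientation
sphere_record <- function() {
  cached("sphere_record", {
    fx <- make_hollow_sphere()
    list(fixture = fx,
         record = analyze_structure(fx$structure, probe_params(n_rotations = 1, seed = 1)))
  })
}
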