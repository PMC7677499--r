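#' @useDynLib spaceball, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.sb_standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.sb_kd <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5
)

.sb_vdw <- c(H = 1.20, C = 1.70, N = 1.50, O = 1.40, S = 1.85, P = 1.90)

# standard atomic weights, u; enough for protein work plus common heteroelements
.sb_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  MN = 54.938, CU = 63.546, "NA" = 22.990, K = 39.098, CL = 35.45, F = 18.998,
  BR = 79.904, I = 126.904, NI = 58.693, CO = 58.933, MO = 95.95
)

#' Kyte-Doolittle hydropathy scale
#'
#' The shipped per-residue hydropathy indices \eqn{q_i} (dimensionless) for the
#' 20 standard amino acids. Positive values are hydrophobic (ILE is most, 4.5),
#' negative hydrophilic (ARG is least, -4.5).
#'
#' @return Named numeric vector, names are 3-letter residue codes.
#' @export
kd_scale <- function() .sb_kd

#' Look up the hydropathy index of a residue
#'
#' @param residue_name 3-letter residue code(s), case-insensitive.
#' @param fallback If `TRUE`, unknown residues yield `NA` (callers exclude them
#'   from shell sums and report a count) instead of an error.
#' @param scale Named numeric vector mapping residue codes to indices;
#'   defaults to the shipped Kyte-Doolittle table (see [kd_scale()]).
#' @return Numeric vector of hydropathy indices.
#' @examples
#' kd_index("ILE")  # 4.5
#' kd_index("gly")  # -0.4
#' @export
kd_index <- function(residue_name, fallback = FALSE, scale = kd_scale()) {
  key <- toupper(trimws(residue_name))
  q <- unname(scale[key])
  if (anyNA(q) && !fallback) {
    bad <- unique(key[is.na(q)])
    stop("no hydropathy index for residue(s): ", paste(bad, collapse = ", "),
         " (use fallback = TRUE to exclude them)")
  }
  q
}

#' Default van der Waals radii table
#'
#' Per-element radii in Angstrom used to inflate atoms into hard spheres.
#' Elements absent from the table fall back to `default_radius` (1.80 A)
#' unless defaults are disabled in [assign_radii()].
#'
#' @return Named numeric vector (element symbol to Angstrom).
#' @export
default_vdw_radii <- function() .sb_vdw

#' Read a key-value table (element -> radius or residue -> hydropathy)
#'
#' Flat two-column whitespace-separated text, `#` comments allowed. Used to
#' override the shipped radii or hydropathy tables from the command line.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_kv_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed key-value line(s) in ", path)
  val <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(val)) stop("non-numeric value(s) in ", path)
  names(val) <- toupper(vapply(parts, `[[`, "", 1L))
  val
}

.sb_element_mass <- function(element, default = 12.011) {
  m <- unname(.sb_masses[toupper(trimws(element))])
  m[is.na(m)] <- default
  m
}

.sb_residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, atom$resid, sep = "|")
}

.sb_new_structure <- function(atom, id = "structure") {
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom), class = "sb_structure")
}

#' Read and sanitize a PDB structure
#'
#' Reads a PDB file (plain or gzipped), keeps protein atoms only (standard
#' amino-acid residues from ATOM records), removes waters, ligands, nucleic
#' acids and other HETATM records, reduces alternate locations to a single
#' conformer (blank or 'A' altloc, first occurrence), and uses the first MODEL
#' of multi-model files. Hydrogens are kept when present but never added.
#'
#' @param path Path to a PDB file (optionally `.gz`).
#' @param chains Optional character vector of chain identifiers to retain.
#' @param keep_nonstandard Keep non-standard (e.g. MSE) non-water residues,
#'   including HETATM records, instead of dropping them with a warning.
#'   Retained non-standard residues get element-based radii and are excluded
#'   from hydropathy sums.
#' @param id Label for the structure; defaults to the file name.
#' @return An object of class `sb_structure`: a list with `id` and an `atom`
#'   data frame (serial, element, x, y, z, resid, chain, resno, insert, elety,
#'   vdw, mass).
#' @export
read_structure <- function(path, chains = NULL, keep_nonstandard = FALSE, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  real <- path
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    lines <- readLines(con, warn = FALSE)
    real <- tempfile(fileext = ".pdb")
    writeLines(lines, real)
    on.exit(unlink(real), add = TRUE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(real, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ", conditionMessage(e))
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) stop("no atom records in ", path)
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""

  if (!is.null(chains)) {
    avail <- sort(unique(atom$chain))
    missing <- setdiff(chains, avail)
    if (length(missing) > 0) {
      stop("chain(s) not present: ", paste(missing, collapse = ", "),
           "; available chains: ", paste(avail, collapse = ", "))
    }
    atom <- atom[atom$chain %in% chains, , drop = FALSE]
  }

  water <- toupper(atom$resid) %in% c("HOH", "WAT", "DOD", "H2O")
  std <- toupper(atom$resid) %in% .sb_standard_aa
  if (keep_nonstandard) {
    # retain non-standard amino-acid-like residues (MSE, PTR, ...): anything
    # non-water whose residue carries a CA atom; bare ligands/nucleotides do not
    rkey <- paste(atom$chain, atom$resno, atom$insert, atom$resid, sep = "|")
    has_ca <- rkey %in% unique(rkey[trimws(atom$elety) == "CA" &
                                      toupper(trimws(atom$elesy)) != "CA"])
    keep <- !water & (std | has_ca)
  } else {
    keep <- atom$type == "ATOM" & std
    dropped <- unique(toupper(atom$resid[atom$type == "ATOM" & !std & !water]))
    if (length(dropped) > 0) {
      warning("dropped non-standard residue(s): ", paste(dropped, collapse = ", "),
              " (use keep_nonstandard = TRUE to retain)")
    }
  }
  atom <- atom[keep, , drop = FALSE]

  # altloc: blank or 'A' only, then first record per (chain, resno, insert, elety)
  atom <- atom[atom$alt %in% c("", " ", "A"), , drop = FALSE]
  site <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  atom <- atom[!duplicated(site), , drop = FALSE]

  if (nrow(atom) == 0) stop("no protein atoms left after sanitization of ", path)

  element <- toupper(trimws(atom$elesy))
  fix <- is.na(element) | !nzchar(element)
  if (any(fix)) element[fix] <- toupper(bio3d::atom2ele(atom$elety[fix]))

  out <- data.frame(
    serial = atom$eleno,
    element = element,
    x = atom$x, y = atom$y, z = atom$z,
    resid = toupper(atom$resid),
    chain = atom$chain,
    resno = atom$resno,
    insert = atom$insert,
    elety = trimws(atom$elety),
    vdw = NA_real_,
    mass = .sb_element_mass(element),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$x + out$y + out$z))) stop("non-finite coordinates in ", path)
  .sb_new_structure(out, id = if (is.null(id)) sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)) else id)
}

#' Assign van der Waals radii to every atom
#'
#' @param structure An `sb_structure`.
#' @param radii_table Named numeric vector (element to Angstrom); entries
#'   override the shipped defaults element-wise.
#' @param default_radius Radius for elements absent from the table (1.80 A).
#' @param allow_default If `FALSE`, an element without a table entry is an
#'   error (the message lists the elements).
#' @return The structure with `atom$vdw` filled; all radii are positive.
#' @export
assign_radii <- function(structure, radii_table = default_vdw_radii(),
                         default_radius = 1.80, allow_default = TRUE) {
  stopifnot(inherits(structure, "sb_structure"))
  tab <- default_vdw_radii()
  if (!missing(radii_table) && !is.null(radii_table)) {
    nm <- toupper(names(radii_table))
    tab[nm] <- radii_table
  }
  r <- unname(tab[structure$atom$element])
  if (anyNA(r)) {
    if (!allow_default) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(structure$atom$element[is.na(r)]), collapse = ", "))
    }
    r[is.na(r)] <- default_radius
  }
  if (any(r <= 0)) stop("van der Waals radii must be positive")
  structure$atom$vdw <- r
  structure
}

#' Residue-level view of a structure
#'
#' @param structure An `sb_structure`.
#' @return Data frame with one row per residue: key, resid, chain, resno,
#'   insert, n_atoms, mass-weighted center of mass (cx, cy, cz), total mass,
#'   and hydropathy index `q` (`NA` for non-standard residues).
#' @export
structure_residues <- function(structure) {
  stopifnot(inherits(structure, "sb_structure"))
  a <- structure$atom
  key <- .sb_residue_key(a)
  ord <- !duplicated(key)
  ks <- key[ord]
  idx <- split(seq_len(nrow(a)), factor(key, levels = ks))
  com <- t(vapply(idx, function(ii) {
    m <- a$mass[ii]
    c(sum(m * a$x[ii]), sum(m * a$y[ii]), sum(m * a$z[ii])) / sum(m)
  }, numeric(3)))
  data.frame(
    key = ks,
    resid = a$resid[ord],
    chain = a$chain[ord],
    resno = a$resno[ord],
    insert = a$insert[ord],
    n_atoms = lengths(idx),
    cx = com[, 1], cy = com[, 2], cz = com[, 3],
    mass = vapply(idx, function(ii) sum(a$mass[ii]), 0),
    q = kd_index(a$resid[ord], fallback = TRUE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_structure()] for sanitized/synthetic structures; a written
#' file re-reads to identical atom count, coordinates and residue identities.
#'
#' @param structure An `sb_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "sb_structure"))
  a <- structure$atom
  chain <- ifelse(a$chain == " " | !nzchar(a$chain), NA, a$chain)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno,
    resid = a$resid,
    eleno = a$serial,
    elety = a$elety,
    chain = chain,
    insert = ifelse(nzchar(a$insert), a$insert, NA),
    o = rep(1, nrow(a)),
    b = rep(0, nrow(a)),
    elesy = a$element
  )
  invisible(path)
}

#' @export
print.sb_structure <- function(x, ...) {
  nres <- length(unique(.sb_residue_key(x$atom)))
  cat(sprintf("sb_structure '%s': %d atoms, %d residues, chains: %s\n",
              x$id, nrow(x$atom), nres,
              paste(sort(unique(x$atom$chain)), collapse = " ")))
  invisible(x)
}

# number of atoms helper used across modules
.sb_natoms <- function(structure) nrow(structure$atom)

.sb_coords <- function(structure) as.matrix(structure$atom[, c("x", "y", "z")])
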