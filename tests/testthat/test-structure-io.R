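make_test_pdb <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, " N", "", "ALA", "A", 1, "", 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, " CA", "", "ALA", "A", 1, "", 1.4, 0, 0, element = "C"),
    pdb_line("ATOM", 3, " N", "A", "GLY", "A", 2, "", 3.0, 1, 0, element = "N"),
    pdb_line("ATOM", 4, " N", "B", "GLY", "A", 2, "", 3.2, 1, 0, element = "N"),
    pdb_line("ATOM", 5, " CA", "", "GLY", "A", 2, "", 4.4, 1, 0, element = "C"),
    pdb_line("ATOM", 6, " CA", "", "ILE", "B", 1, "", 0, 5, 0, element = "C"),
    pdb_line("HETATM", 7, " O", "", "HOH", "A", 90, "", 8, 8, 8, element = "O"),
    pdb_line("HETATM", 8, " O", "", "HOH", "A", 91, "", 9, 9, 9, element = "O"),
    pdb_line("HETATM", 9, "FE", "", "HEM", "A", 92, "", 7, 7, 7, element = "FE"),
    "END"
  )
  writeLines(lines, path)
  path
}

test_that("reading strips waters, ligands and duplicate altlocs", {
  path <- make_test_pdb(tempfile(fileext = ".pdb"))
  st <- read_structure(path)
  # 6 protein ATOM records minus the altloc B duplicate
  expect_equal(nrow(st$atom), 5L)
  expect_false(any(st$atom$resid %in% c("HOH", "HEM")))
  # altloc A kept, B dropped
  expect_equal(sum(st$atom$resno == 2 & st$atom$elety == "N" & st$atom$chain == "A"), 1L)
  expect_equal(st$atom$x[st$atom$resno == 2 & st$atom$elety == "N" & st$atom$chain == "A"], 3.0)
})

test_that("chain selection retains the requested chain and names the available ones", {
  path <- make_test_pdb(tempfile(fileext = ".pdb"))
  stA <- read_structure(path, chains = "A")
  expect_true(all(stA$atom$chain == "A"))
  expect_equal(nrow(stA$atom), 4L)
  err <- tryCatch(read_structure(path, chains = "Q"), error = conditionMessage)
  expect_match(err, "available chains")
  expect_match(err, "A")
})

test_that("non-standard residues are dropped with a warning, empty structures error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, " CA", "", "ALA", "A", 1, "", 0, 0, 0, element = "C"),
    pdb_line("ATOM", 2, " CA", "", "MSE", "A", 2, "", 3, 0, 0, element = "C"),
    "END"
  ), path)
  expect_warning(st <- read_structure(path), "MSE")
  expect_equal(nrow(st$atom), 1L)
  st2 <- suppressWarnings(read_structure(path, keep_nonstandard = TRUE))
  expect_equal(nrow(st2$atom), 2L)

  water_only <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("HETATM", 1, " O", "", "HOH", "A", 1, "", 0, 0, 0, element = "O"), "END"),
             water_only)
  expect_error(read_structure(water_only), "no protein atoms")
})

test_that("radius assignment uses shipped defaults, overrides and the default fallback", {
  st <- tiny_structure(rbind(c(0, 0, 0), c(3, 0, 0)), radii = NA_real_)
  st$atom$element <- c("O", "C")
  st <- assign_radii(st)
  expect_equal(st$atom$vdw, c(1.40, 1.70))
  st2 <- assign_radii(st, radii_table = c(C = 1.77))
  expect_equal(st2$atom$vdw, c(1.40, 1.77))
  st$atom$element <- c("XX", "C")
  expect_equal(assign_radii(st)$atom$vdw[1], 1.80)
  expect_error(assign_radii(st, allow_default = FALSE), "XX")
})

test_that("hydropathy lookups match the shipped scale and handle fallback", {
  expect_equal(kd_index("ILE"), 4.5)
  expect_equal(kd_index("gly"), -0.4)
  expect_equal(kd_index(c("ARG", "TRP")), c(-4.5, -0.9))
  expect_error(kd_index("MSE"), "MSE")
  expect_true(is.na(kd_index("MSE", fallback = TRUE)))
  expect_equal(length(kd_scale()), 20L)
  expect_equal(sum(kd_scale() > 0), 7L)  # 7 hydrophobic residues in the scale
})

test_that("key-value config tables round-trip the shipped defaults", {
  radii_file <- system.file("extdata", "vdw_radii.txt", package = "spaceball")
  kd_file <- system.file("extdata", "kd_hydropathy.txt", package = "spaceball")
  expect_equal(read_kv_table(radii_file), default_vdw_radii())
  expect_equal(read_kv_table(kd_file)[names(kd_scale())], kd_scale())
})

test_that("write/read round trip preserves geometry and is idempotent", {
  fx <- make_hydropathy_shell(n_res = 50, R_s = 4.5, scheme = "bipartite")
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(fx$structure, path)
  st <- read_structure(path)
  expect_equal(nrow(st$atom), nrow(fx$structure$atom))
  expect_equal(st$atom$resid, fx$structure$atom$resid)
  expect_equal(st$atom$x, fx$structure$atom$x, tolerance = 1e-3)
  expect_equal(st$atom$chain, fx$structure$atom$chain)
  # idempotence: write + read the sanitized structure again, nothing changes
  path2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, path2)
  st2 <- read_structure(path2)
  expect_equal(st2$atom[, c("x", "y", "z", "resid", "resno", "chain")],
               st$atom[, c("x", "y", "z", "resid", "resno", "chain")])
})

test_that("gzipped PDB input is accepted", {
  fx <- make_hydropathy_shell(n_res = 60, R_s = 4)
  plain <- tempfile(fileext = ".pdb")
  write_structure_pdb(fx$structure, plain)
  gz <- paste0(plain, ".gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  st <- read_structure(gz)
  expect_equal(nrow(st$atom), 60L)
})

test_that("residue view partitions the atoms and carries hydropathy", {
  fx <- make_hydropathy_shell(n_res = 40, R_s = 4.2, scheme = "bipartite")
  res <- structure_residues(fx$structure)
  expect_equal(sum(res$n_atoms), nrow(fx$structure$atom))
  expect_setequal(unique(res$resid), c("ILE", "ARG"))
  expect_equal(res$q[res$resid == "ILE"][1], 4.5)
})
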