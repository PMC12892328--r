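test_that("a minimal single-atom PDB parses with a backbone flag", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  st <- read_pdb(path)
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$atom_name, "CA")
  expect_true(st$atoms$is_backbone)
  expect_equal(st$atoms$element, "C")
})

test_that("PDB write/read round-trips names, residues and positions", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy9$structure, path)
  back <- read_pdb(path)
  a0 <- toy9$structure$atoms
  a1 <- back$atoms
  expect_equal(a1$atom_name, a0$atom_name)
  expect_equal(a1$residue_name, a0$residue_name)
  expect_equal(a1$residue_seq, a0$residue_seq)
  expect_equal(a1$is_backbone, a0$is_backbone)
  # PDB stores 3 decimals
  expect_equal(a1$x, round(a0$x, 3), tolerance = 1e-9)
  expect_equal(a1$y, round(a0$y, 3), tolerance = 1e-9)
  expect_equal(a1$z, round(a0$z, 3), tolerance = 1e-9)
})

test_that("PDB parsing agrees with an independent reader on positions", {
  library(bio3d)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy9$structure, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-9)
  expect_equal(ours$atoms$y, ref$atom$y, tolerance = 1e-9)
  expect_equal(ours$atoms$z, ref$atom$z, tolerance = 1e-9)
  expect_equal(trimws(ours$atoms$atom_name), trimws(ref$atom$elety))
})

test_that("garbled coordinates and empty files raise named errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C   ALA A   1      12.3a4   0.000   0.000  1.00  0.00           C"),
    path)
  expect_error(read_pdb(path), "x-coordinate field at line 2")
  writeLines("REMARK nothing here", path)
  expect_error(read_pdb(path), "no ATOM/HETATM")
})

test_that("water HETATM records are dropped, ions kept", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A  90       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 FE    FE A  91       8.000   0.000   0.000  1.00  0.00          FE"),
    path)
  st <- read_pdb(path)
  expect_equal(nrow(st$atoms), 2)
  expect_true("FE" %in% st$atoms$atom_name)
  expect_equal(st$atoms$element[st$atoms$atom_name == "FE"], "other")
})

test_that("Tinker xyz: neighbour lists deduplicate to unordered bonds and round-trip", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "     3  water-like",
    "     1  O     0.000000    0.000000    0.000000     1 2 3",
    "     2  H     0.960000    0.000000    0.000000     1 1",
    "     3  H    -0.240000    0.930000    0.000000     1 1"), path)
  st <- read_tinker_xyz(path)
  expect_equal(nrow(st$bonds), 2)  # both directions collapse
  expect_setequal(st$bonds[, 1], c(1, 1))
  # round-trip through the writer
  out <- withr::local_tempfile(fileext = ".xyz")
  write_tinker_xyz(st, out)
  back <- read_tinker_xyz(out)
  expect_equal(back$atoms$atom_name, st$atoms$atom_name)
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-6)
  expect_equal(back$bonds, st$bonds)
})

test_that("Tinker xyz errors: count mismatch and out-of-range neighbour", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("     5  broken",
               "     1  O   0.0 0.0 0.0   1 2",
               "     2  H   1.0 0.0 0.0   1 1",
               "     3  H   0.0 1.0 0.0   1 1",
               "     4  H   0.0 0.0 1.0   1 1"), path)
  expect_error(read_tinker_xyz(path), "declared atom count 5 but found 4")
  writeLines(c("     2  broken",
               "     1  O   0.0 0.0 0.0   1 9",
               "     2  H   1.0 0.0 0.0   1 1"), path)
  expect_error(read_tinker_xyz(path), "out of range")
})

test_that("dipole tables convert units, reject duplicates and unknown tags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("serial\tdx\tdy\tdz\tunit",
               "7\t0\t0\t0\tD",
               "8\t3.33564e-30\t0\t0\tC.m"), path)
  tab <- read_dipole_table(path)
  expect_equal(tab$dx[tab$serial == 7], 0)
  expect_equal(tab$dx[tab$serial == 8], 1.0, tolerance = 1e-12)
  writeLines(c("serial\tdx\tdy\tdz\tunit", "7\t0\t0\t0\tD", "7\t1\t0\t0\tD"),
             path)
  expect_error(read_dipole_table(path), "duplicate serial")
  writeLines(c("serial\tdx\tdy\tdz\tunit", "7\t0\t0\t0\tfurlong"), path)
  expect_error(read_dipole_table(path), "unknown dipole unit")
})

test_that("Debye <-> C.m conversion is involutive", {
  x <- c(0, 1, -2.5, 1e-3)
  expect_equal(convert_dipole_units(convert_dipole_units(x, "D", "C.m"),
                                    "C.m", "D"),
               x, tolerance = 1e-12)
})

test_that("attach_dipoles matches serials, reports counts, flags unknowns", {
  st <- toy9$structure
  st$atoms$dx <- NA_real_; st$atoms$dy <- NA_real_; st$atoms$dz <- NA_real_
  empty <- attach_dipoles(st, data.frame(serial = integer(), dx = numeric(),
                                         dy = numeric(), dz = numeric()))
  expect_equal(attr(empty, "n_attached"), 0L)
  expect_true(all(is.na(empty$atoms$dx)))
  full <- attach_dipoles(st, toy9$dipoles)
  expect_equal(attr(full, "n_attached"), nrow(st$atoms))
  expect_false(anyNA(full$atoms$dx))
  bad <- data.frame(serial = 999L, dx = 1, dy = 0, dz = 0)
  expect_error(attach_dipoles(st, bad), "999")
})
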