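test_that("cropping partitions atoms and matches a brute-force distance scan", {
  st <- toy9$structure
  a <- st$atoms
  key <- residue_key("A", 4, "GLU")
  for (radius in c(0, 5, 9, 30)) {
    env <- crop_environment(st, key, radius)
    expect_true(all(env$self_atoms$residue_seq == 4))
    self_idx <- which(a$residue_seq == 4)
    expect_equal(nrow(env$self_atoms), length(self_idx))
    d <- sqrt((a$x - env$ca[1])^2 + (a$y - env$ca[2])^2 + (a$z - env$ca[3])^2)
    expected <- setdiff(which(d <= radius), self_idx)
    expect_setequal(env$context_atoms$serial, a$serial[expected])
  }
  # isolated single residue: no context at all
  lone <- protein_structure(make_ideal_residue("ASP"), source_id = "lone")
  env <- crop_environment(lone, residue_key("A", 1, "ASP"), 9)
  expect_equal(nrow(env$context_atoms), 0)
  expect_error(crop_environment(st, residue_key("A", 99, "ASP"), 9),
               "not found")
})

test_that("heavy-neighbour counts match exhaustive pairwise checks and grow with radius", {
  st <- toy9$structure
  a <- st$atoms
  key <- residue_key("A", 6, "HIS")
  env <- crop_environment(st, key, 9)
  ca_atom <- env$self_atoms[env$self_atoms$atom_name == "CA", ]
  prev <- c(C = 0L, N = 0L, O = 0L, S = 0L)
  for (radius in c(2, 4, 6, 9)) {
    counts <- count_heavy_neighbors(env, ca_atom, radius)
    # brute force against all atoms of other residues inside the crop
    ctx <- env$context_atoms
    d <- sqrt((ctx$x - ca_atom$x)^2 + (ctx$y - ca_atom$y)^2 +
              (ctx$z - ca_atom$z)^2)
    for (el in c("C", "N", "O", "S"))
      expect_equal(counts[[el]], sum(ctx$element == el & d <= radius))
    expect_true(all(counts >= prev))  # monotone in radius
    prev <- counts
  }
  lone <- protein_structure(make_ideal_residue("ASP"), source_id = "lone")
  lenv <- crop_environment(lone, residue_key("A", 1, "ASP"), 9)
  expect_equal(unname(count_heavy_neighbors(
    lenv, lenv$self_atoms[lenv$self_atoms$atom_name == "CA", ], 9)),
    c(0L, 0L, 0L, 0L))
  expect_error(count_heavy_neighbors(env, data.frame(serial = 99999L), 5),
               "not in the target residue")
})

test_that("hydrogen bonds follow the distance/angle criterion with role bookkeeping", {
  # hand-built N-H...O=C geometry: H...O 1.9 A, N-H-O angle 165 deg
  ang <- (180 - 165) * pi / 180
  o_pos <- c(1.01 + 1.9 * cos(ang), 1.9 * sin(ang), 0)
  atoms <- data.frame(
    serial = 1:4,
    atom_name = c("N", "H", "O", "C"),
    element = c("N", "H", "O", "C"),
    residue_name = c("GLY", "GLY", "ALA", "ALA"),
    residue_seq = c(1L, 1L, 2L, 2L), chain_id = "A",
    x = c(0, 1.01, o_pos[1], o_pos[1] + 1.23),
    y = c(0, 0, o_pos[2], o_pos[2]),
    z = 0, is_backbone = TRUE, stringsAsFactors = FALSE)
  st <- protein_structure(atoms, source_id = "hb")
  hb <- detect_hydrogen_bonds(st)
  expect_equal(hb$n_donor[hb$serial == 1], 1)
  expect_equal(hb$n_acceptor[hb$serial == 1], 0)
  expect_equal(hb$n_acceptor[hb$serial == 3], 1)
  expect_equal(hb$n_donor[hb$serial == 3], 0)
  expect_equal(sum(hb$n_donor), sum(hb$n_acceptor))  # one increment per triple
  # same pair pushed out of range: nothing detected
  atoms2 <- atoms
  atoms2$x[3:4] <- atoms2$x[3:4] + 1.6  # H...O now 3.5 A
  hb2 <- detect_hydrogen_bonds(protein_structure(atoms2, source_id = "hb2"))
  expect_true(all(hb2$n_donor == 0) && all(hb2$n_acceptor == 0))
  # no hydrogens at all: all zero
  hb3 <- detect_hydrogen_bonds(
    protein_structure(atoms[-2, ], source_id = "noH"))
  expect_true(all(hb3$n_donor == 0) && all(hb3$n_acceptor == 0))
})

test_that("intra-residue donor/acceptor pairs are not counted", {
  atoms <- data.frame(
    serial = 1:3, atom_name = c("N", "H", "OD1"),
    element = c("N", "H", "O"), residue_name = "ASP", residue_seq = 1L,
    chain_id = "A", x = c(0, 1.01, 2.5), y = 0, z = 0,
    is_backbone = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  hb <- detect_hydrogen_bonds(protein_structure(atoms, source_id = "intra"))
  expect_true(all(hb$n_donor == 0) && all(hb$n_acceptor == 0))
})

test_that("SASA: closed-form sphere, no occlusion at distance, full burial, rigid motion", {
  one <- data.frame(serial = 1L, atom_name = "C", element = "C",
                    residue_name = "UNK", residue_seq = 1L, chain_id = "A",
                    x = 0, y = 0, z = 0, is_backbone = FALSE,
                    stringsAsFactors = FALSE)
  st1 <- protein_structure(one, source_id = "c1")
  s1 <- compute_sasa(st1, n_points = 960, probe = 1.4)
  expect_equal(s1$sasa, 4 * pi * 3.1^2, tolerance = 1e-9)  # exact: no occluders
  # two atoms farther apart than 2 (r + probe): both fully exposed
  two <- rbind(one, transform(one, serial = 2L, x = 7))
  s2 <- compute_sasa(protein_structure(two, source_id = "c2"), 960, 1.4)
  expect_equal(s2$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
  # atom caged by a tight octahedral shell plus cube corners: zero area
  shell <- expand.grid(x = c(-1.4, 0, 1.4), y = c(-1.4, 0, 1.4),
                       z = c(-1.4, 0, 1.4))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  cage <- data.frame(serial = seq_len(nrow(shell) + 1L),
                     atom_name = "C", element = "C", residue_name = "UNK",
                     residue_seq = 1L, chain_id = "A",
                     x = c(0, shell$x), y = c(0, shell$y), z = c(0, shell$z),
                     is_backbone = FALSE, stringsAsFactors = FALSE)
  s3 <- compute_sasa(protein_structure(cage, source_id = "cage"), 96, 1.4)
  expect_equal(s3$sasa[1], 0)
  expect_error(compute_sasa(st1, n_points = 8), "too coarse")
})

test_that("total SASA is invariant under rigid motion within quadrature noise", {
  st <- toy9$structure
  base <- sum(compute_sasa(st, 240, 1.4)$sasa)
  set.seed(31)
  for (i in 1:3) {
    moved <- rigid_move_structure(st, random_rotation(), stats::rnorm(3, sd = 8))
    tot <- sum(compute_sasa(moved, 240, 1.4)$sasa)
    expect_lt(abs(tot - base) / base, 0.005)
  }
})
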