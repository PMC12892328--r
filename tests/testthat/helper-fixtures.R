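# Shared fixtures, built once per test run.

# uniform random rotation matrix (quaternion construction)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move_structure <- function(structure, R, tr) {
  a <- structure$atoms
  xyz <- cbind(a$x, a$y, a$z) %*% t(R)
  a$x <- xyz[, 1] + tr[1]
  a$y <- xyz[, 2] + tr[2]
  a$z <- xyz[, 3] + tr[3]
  dip <- cbind(a$dx, a$dy, a$dz)
  has <- !is.na(dip[, 1])
  dip[has, ] <- dip[has, , drop = FALSE] %*% t(R)
  a$dx <- dip[, 1]; a$dy <- dip[, 2]; a$dz <- dip[, 3]
  protein_structure(a, bonds = structure$bonds, source_id = structure$source_id)
}

# one 9-residue toy protein (spacers + ASP/GLU/HIS/LYS) reused across files
toy9 <- make_toy_protein(fixture_spec(9, seed = 42), source_id = "toy9")
toy9_labels <- pkagraph:::ionizable_label_table(toy9$structure,
                                                source_id = "toy9")
toy9_graphs <- build_dataset(toy9$structure, toy9_labels, radius = 9)

# small labeled training set for optimisation tests
tiny_planted <- make_planted_dataset(24, radius = 9, sigma = 0.1, seed = 7,
                                     residues_per_protein = 6L)
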