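# Environment-derived per-atom descriptors: spherical cropping around the
# target C-alpha, heavy-atom neighbour counts, geometric hydrogen-bond
# detection, and a deterministic Shrake-Rupley SASA.

# van der Waals radii (Angstrom) used for SASA.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, other = 1.80)

#' Crop the spherical local environment of a residue
#'
#' Splits a structure into the target residue's own atoms and all other
#' atoms whose distance to the target C-alpha is at most `radius`
#' (closed ball).  The environment enters the graph representation only
#' through derived features; graph nodes remain the residue's own atoms.
#'
#' @param structure a [protein_structure()].
#' @param key a [residue_key()].
#' @param radius crop radius in Angstrom (the study uses 7-11).
#' @return a `residue_environment`: list with `key`, `radius`,
#'   `self_atoms`, `context_atoms`, `ca` (C-alpha position).
#' @export
crop_environment <- function(structure, key, radius) {
  stopifnot(inherits(structure, "protein_structure"),
            inherits(key, "residue_key"), radius >= 0)
  a <- structure$atoms
  self_idx <- which(a$chain_id == key$chain_id &
                    a$residue_seq == key$residue_seq)
  if (!length(self_idx))
    stop("residue ", format(key), " not found in structure ",
         structure$source_id)
  if (!all(a$residue_name[self_idx] == key$residue_name))
    stop("residue ", format(key), " has type ",
         unique(a$residue_name[self_idx])[1], " in the structure")
  ca_row <- self_idx[a$atom_name[self_idx] == "CA"]
  if (!length(ca_row))
    stop("residue ", format(key), " has no C-alpha atom")
  ca <- c(a$x[ca_row[1]], a$y[ca_row[1]], a$z[ca_row[1]])
  other_idx <- setdiff(seq_len(nrow(a)), self_idx)
  if (length(other_idx)) {
    d2 <- (a$x[other_idx] - ca[1])^2 + (a$y[other_idx] - ca[2])^2 +
          (a$z[other_idx] - ca[3])^2
    other_idx <- other_idx[d2 <= radius^2]
  }
  structure(list(key = key, radius = radius,
                 self_atoms = a[self_idx, , drop = FALSE],
                 context_atoms = a[other_idx, , drop = FALSE],
                 ca = ca),
            class = "residue_environment")
}

#' @export
print.residue_environment <- function(x, ...) {
  cat(sprintf("residue_environment %s, radius %.1f A: %d self atoms, %d context atoms\n",
              format(x$key), x$radius, nrow(x$self_atoms), nrow(x$context_atoms)))
  invisible(x)
}

#' Count heavy context atoms near one target-residue atom
#'
#' Counts C, N, O and S atoms of *other* residues (context atoms of the
#' environment) within the closed ball of `radius` around the given atom.
#' Hydrogens and unknown elements are never counted, nor are atoms of
#' the target residue itself.
#'
#' @param env a [crop_environment()] result.
#' @param atom one-row data frame (a row of `env$self_atoms`) or a serial
#'   present in the target residue.
#' @param radius count radius in Angstrom.
#' @return named integer vector `c(C=, N=, O=, S=)`.
#' @export
count_heavy_neighbors <- function(env, atom, radius) {
  stopifnot(inherits(env, "residue_environment"))
  if (is.numeric(atom) && length(atom) == 1) {
    row <- which(env$self_atoms$serial == atom)
    if (!length(row)) stop("atom with serial ", atom, " is not in the target residue")
    atom <- env$self_atoms[row, , drop = FALSE]
  }
  if (!atom$serial %in% env$self_atoms$serial)
    stop("atom ", atom$serial, " is not in the target residue")
  ctx <- env$context_atoms
  out <- c(C = 0L, N = 0L, O = 0L, S = 0L)
  if (nrow(ctx)) {
    d2 <- (ctx$x - atom$x)^2 + (ctx$y - atom$y)^2 + (ctx$z - atom$z)^2
    near <- ctx$element[d2 <= radius^2]
    tab <- table(factor(near, levels = names(out)))
    out[] <- as.integer(tab)
  }
  out
}

#' Detect hydrogen bonds with a geometric criterion
#'
#' A donor-H...acceptor triple is accepted when the hydrogen-acceptor
#' distance is at most `dist_cutoff` and the donor-H-acceptor angle is at
#' least `angle_cutoff` degrees (a Baker-Hubbard-style test).  Donors and
#' acceptors are restricted to N and O heavy atoms; pairs within the same
#' residue are excluded.  Structures without hydrogens yield all-zero
#' counts.
#'
#' @param structure a [protein_structure()]; explicit bonds, when
#'   present, identify each hydrogen's donor heavy atom (else the nearest
#'   heavy atom within 1.2 Angstrom).
#' @param dist_cutoff maximum H...acceptor distance, Angstrom.
#' @param angle_cutoff minimum donor-H-acceptor angle, degrees.
#' @return data frame `serial, n_acceptor, n_donor` covering every atom.
#' @export
detect_hydrogen_bonds <- function(structure, dist_cutoff = 2.5,
                                  angle_cutoff = 120) {
  a <- structure$atoms
  n_acc <- n_don <- integer(nrow(a))
  h_idx <- which(a$element == "H")
  acceptor_idx <- which(a$element %in% c("N", "O"))
  if (length(h_idx) && length(acceptor_idx)) {
    for (i in h_idx) {
      don <- NA_integer_
      if (!is.null(structure$bonds)) {
        hit <- structure$bonds[structure$bonds[, 1] == a$serial[i] |
                               structure$bonds[, 2] == a$serial[i], , drop = FALSE]
        partners <- setdiff(as.vector(hit), a$serial[i])
        partners <- partners[a$element[match(partners, a$serial)] != "H"]
        if (length(partners)) don <- match(partners[1], a$serial)
      }
      if (is.na(don)) {
        # the covalent donor of a hydrogen lives in its own residue
        heavy_idx <- which(a$element != "H" & a$chain_id == a$chain_id[i] &
                           a$residue_seq == a$residue_seq[i])
        if (length(heavy_idx)) {
          d2 <- (a$x[heavy_idx] - a$x[i])^2 + (a$y[heavy_idx] - a$y[i])^2 +
                (a$z[heavy_idx] - a$z[i])^2
          j <- which.min(d2)
          if (d2[j] <= 1.2^2) don <- heavy_idx[j]
        }
      }
      if (is.na(don) || !a$element[don] %in% c("N", "O")) next
      acc_cand <- acceptor_idx[acceptor_idx != don]
      # exclude acceptors in the donor's own residue
      same_res <- a$chain_id[acc_cand] == a$chain_id[don] &
                  a$residue_seq[acc_cand] == a$residue_seq[don]
      acc_cand <- acc_cand[!same_res]
      if (!length(acc_cand)) next
      ha2 <- (a$x[acc_cand] - a$x[i])^2 + (a$y[acc_cand] - a$y[i])^2 +
             (a$z[acc_cand] - a$z[i])^2
      acc_cand <- acc_cand[ha2 <= dist_cutoff^2]
      for (acc in acc_cand) {
        v1 <- c(a$x[don] - a$x[i], a$y[don] - a$y[i], a$z[don] - a$z[i])
        v2 <- c(a$x[acc] - a$x[i], a$y[acc] - a$y[i], a$z[acc] - a$z[i])
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= angle_cutoff) {
          n_don[don] <- n_don[don] + 1L
          n_acc[acc] <- n_acc[acc] + 1L
        }
      }
    }
  }
  data.frame(serial = a$serial, n_acceptor = n_acc, n_donor = n_don)
}

# Deterministic quasi-uniform sphere points (golden spiral), so SASA is
# bit-reproducible.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points are placed quasi-uniformly (golden spiral)
#' on the sphere of radius `r_vdw + probe`; the accessible area is the
#' fraction of points not inside any other atom's expanded sphere times
#' the full sphere area.  The orientation of each atom's point grid is
#' anchored to its nearest occluding neighbours, so the grid co-rotates
#' with the molecule and per-atom areas are exactly invariant under
#' rigid motion of the whole structure (and bit-reproducible, since the
#' point set is deterministic).  Computed on the whole structure -
#' cropping before SASA would fabricate exposed surface at the sphere
#' boundary.
#'
#' @param structure a [protein_structure()].
#' @param n_points number of quadrature points per atom (>= 16).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @return data frame `serial, sasa` (Angstrom squared) for every atom.
#' @export
compute_sasa <- function(structure, n_points = 960, probe = 1.4) {
  if (n_points < 16) stop("n_points < 16: quadrature too coarse")
  a <- structure$atoms
  n <- nrow(a)
  radii <- VDW_RADII[a$element] + probe
  pts <- golden_spiral_points(n_points)
  xyz <- cbind(a$x, a$y, a$z)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    # round before ordering so near-ties resolve identically after any
    # rigid motion (distances are preserved only to machine precision)
    nb <- nb[order(round(d2[nb], 6), a$serial[nb])]
    # orientation frame from the two nearest (non-collinear) neighbours
    e1 <- xyz[nb[1], ] - xyz[i, ]
    e1 <- e1 / sqrt(sum(e1^2))
    e3 <- c(0, 0, 0)
    for (j in nb[-1]) {
      u <- xyz[j, ] - xyz[i, ]
      cr <- cross3(e1, u)
      if (sum(cr^2) > 1e-16) { e3 <- cr / sqrt(sum(cr^2)); break }
    }
    if (all(e3 == 0)) {
      # all occluders collinear with e1: any perpendicular completes the frame
      ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      cr <- cross3(e1, ref)
      e3 <- cr / sqrt(sum(cr^2))
    }
    e2 <- cross3(e3, e1)
    basis <- rbind(e1, e2, e3)
    sp <- sweep((pts %*% basis) * ri, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
             (sp[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= radii[j]^2
    }
    sasa[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  data.frame(serial = a$serial, sasa = sasa)
}
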