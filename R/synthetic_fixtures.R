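# Synthetic residue/protein generator.  Structures are built from ideal
# amino-acid stereochemistry (internal coordinates placed with the
# natural-extension reference frame construction), chained with trans
# peptide bonds, and decorated with seeded isotropic induced-dipole
# vectors and labels generated by a planted function of the graph
# features.  Everything downstream is testable against these fixtures
# without any external structure database.

SPACER_TYPES <- c("GLY", "ALA")

# Place atom D given three reference positions A, B, C, the C-D bond
# length, the B-C-D angle and the A-B-C-D dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Internal-coordinate templates: each row places one atom from three
# previously placed atoms.  Backbone N, CA, C, O and the amide H are
# placed by the builders; these cover HA and the side chain.
residue_zmat <- function(type) {
  z <- function(name, a, b, c, bond, angle, torsion)
    data.frame(name = name, a = a, b = b, c = c, bond = bond,
               angle = angle, torsion = torsion, stringsAsFactors = FALSE)
  ha <- z("HA", "N", "C", "CA", 1.09, 108, 118)
  cb <- z("CB", "N", "C", "CA", 1.53, 110, -122)
  hb <- rbind(z("HB2", "N", "CA", "CB", 1.09, 109, 55),
              z("HB3", "N", "CA", "CB", 1.09, 109, 175))
  switch(type,
    GLY = rbind(z("HA2", "N", "C", "CA", 1.09, 108, 118),
                z("HA3", "N", "C", "CA", 1.09, 108, -122)),
    ALA = rbind(ha, cb,
                z("HB1", "N", "CA", "CB", 1.09, 109, 60),
                z("HB2", "N", "CA", "CB", 1.09, 109, 180),
                z("HB3", "N", "CA", "CB", 1.09, 109, -60)),
    ASP = rbind(ha, cb,
                z("CG",  "N", "CA", "CB", 1.52, 112, -65),
                z("OD1", "CA", "CB", "CG", 1.25, 118, -20),
                z("OD2", "CA", "CB", "CG", 1.25, 118, 160),
                hb),
    GLU = rbind(ha, cb,
                z("CG",  "N", "CA", "CB", 1.52, 112, -65),
                z("CD",  "CA", "CB", "CG", 1.52, 112, 180),
                z("OE1", "CB", "CG", "CD", 1.25, 118, -20),
                z("OE2", "CB", "CG", "CD", 1.25, 118, 160),
                hb,
                z("HG2", "CA", "CB", "CG", 1.09, 109, 60),
                z("HG3", "CA", "CB", "CG", 1.09, 109, -60)),
    HIS = rbind(ha, cb,
                z("CG",  "N", "CA", "CB", 1.50, 113, -65),
                z("ND1", "CA", "CB", "CG", 1.38, 122, 80),
                z("CD2", "CA", "CB", "CG", 1.36, 129, -100),
                z("CE1", "CB", "CG", "ND1", 1.32, 108, 180),
                z("NE2", "CB", "CG", "CD2", 1.37, 107, 180),
                z("HD1", "CB", "CG", "ND1", 1.01, 126, 0),
                z("HD2", "CB", "CG", "CD2", 1.08, 126, 0),
                z("HE1", "CG", "ND1", "CE1", 1.08, 126, 180),
                hb),
    LYS = rbind(ha, cb,
                z("CG",  "N", "CA", "CB", 1.52, 112, -65),
                z("CD",  "CA", "CB", "CG", 1.52, 112, 180),
                z("CE",  "CB", "CG", "CD", 1.52, 112, 180),
                z("NZ",  "CG", "CD", "CE", 1.49, 112, 180),
                hb,
                z("HG2", "CA", "CB", "CG", 1.09, 109, 60),
                z("HG3", "CA", "CB", "CG", 1.09, 109, -60),
                z("HD2", "CB", "CG", "CD", 1.09, 109, 60),
                z("HD3", "CB", "CG", "CD", 1.09, 109, -60),
                z("HE2", "CG", "CD", "CE", 1.09, 109, 60),
                z("HE3", "CG", "CD", "CE", 1.09, 109, -60),
                z("HZ1", "CD", "CE", "NZ", 1.01, 109, 60),
                z("HZ2", "CD", "CE", "NZ", 1.01, 109, 180),
                z("HZ3", "CD", "CE", "NZ", 1.01, 109, -60)),
    stop("unsupported residue type '", type, "'")
  )
}

# Intra-residue covalent bond template (atom-name pairs).
residue_bond_template <- function(type) {
  bb <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("N", "H"))
  side <- switch(type,
    GLY = list(c("CA", "HA2"), c("CA", "HA3")),
    ALA = list(c("CA", "HA"), c("CA", "CB"), c("CB", "HB1"), c("CB", "HB2"),
               c("CB", "HB3")),
    ASP = list(c("CA", "HA"), c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"),
               c("CG", "OD2"), c("CB", "HB2"), c("CB", "HB3")),
    GLU = list(c("CA", "HA"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
               c("CD", "OE1"), c("CD", "OE2"), c("CB", "HB2"), c("CB", "HB3"),
               c("CG", "HG2"), c("CG", "HG3")),
    HIS = list(c("CA", "HA"), c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"),
               c("CG", "CD2"), c("ND1", "CE1"), c("CD2", "NE2"),
               c("CE1", "NE2"), c("ND1", "HD1"), c("CD2", "HD2"),
               c("CE1", "HE1"), c("CB", "HB2"), c("CB", "HB3")),
    LYS = list(c("CA", "HA"), c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
               c("CD", "CE"), c("CE", "NZ"), c("CB", "HB2"), c("CB", "HB3"),
               c("CG", "HG2"), c("CG", "HG3"), c("CD", "HD2"), c("CD", "HD3"),
               c("CE", "HE2"), c("CE", "HE3"), c("NZ", "HZ1"), c("NZ", "HZ2"),
               c("NZ", "HZ3")),
    stop("unsupported residue type '", type, "'")
  )
  c(bb, side)
}

supported_fixture_types <- function() c(IONIZABLE_TYPES, SPACER_TYPES)

#' Build one ideal-geometry residue
#'
#' Constructs a single residue with standard amino-acid stereochemistry:
#' C-alpha to carbonyl-carbon bond 1.53 Angstrom, C=O 1.23 Angstrom,
#' C-alpha - C - O angle 121 degrees, all backbone atoms plus the side
#' chain and hydrogens from an internal-coordinate template.  At the
#' identity pose the C-alpha sits at the origin, the carbonyl C at
#' (1.53, 0, 0) and the carbonyl O in the positive-Y half of the XY
#' plane, i.e. exactly the canonical local-frame geometry.
#'
#' @param type residue type; one of ASP, GLU, HIS, LYS, GLY, ALA.
#' @param pose optional rigid motion: list with `rotation` (3x3 matrix)
#'   and `translation` (3-vector); defaults to the identity pose.
#' @param residue_seq residue number to stamp on the atoms.
#' @param chain_id chain identifier.
#' @param serial_start first atom serial.
#' @return atom data frame in the [protein_structure()] layout, with an
#'   attribute `bond_names` holding the intra-residue bond name pairs.
#' @export
make_ideal_residue <- function(type, pose = NULL, residue_seq = 1L,
                               chain_id = "A", serial_start = 1L) {
  type <- toupper(type)
  if (!type %in% supported_fixture_types())
    stop("unsupported residue type '", type, "'")
  coords <- list(
    CA = c(0, 0, 0),
    C  = c(1.53, 0, 0),
    # CA-C-O angle 121 deg, in-plane, O on the positive-Y side
    O  = c(1.53, 0, 0) + 1.23 * c(cos((180 - 121) * pi / 180),
                                  sin((180 - 121) * pi / 180), 0),
    N  = 1.458 * c(cos(111 * pi / 180), -sin(111 * pi / 180), 0)
  )
  coords$H <- place_atom(coords$C, coords$CA, coords$N, 1.01, 119, 180)
  zm <- residue_zmat(type)
  for (i in seq_len(nrow(zm))) {
    coords[[zm$name[i]]] <- place_atom(coords[[zm$a[i]]], coords[[zm$b[i]]],
                                       coords[[zm$c[i]]], zm$bond[i],
                                       zm$angle[i], zm$torsion[i])
  }
  names_out <- names(coords)
  xyz <- do.call(rbind, coords)
  if (!is.null(pose)) {
    R <- pose$rotation %||% diag(3)
    tr <- pose$translation %||% c(0, 0, 0)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, -tr)
  }
  atoms <- data.frame(
    serial = seq.int(serial_start, length.out = length(names_out)),
    atom_name = names_out,
    element = element_from_name(names_out),
    residue_name = type, residue_seq = as.integer(residue_seq),
    chain_id = chain_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_backbone = FALSE, dx = NA_real_, dy = NA_real_, dz = NA_real_,
    stringsAsFactors = FALSE)
  atoms$is_backbone <- atoms$atom_name %in% c(BACKBONE_HEAVY, "H") |
    (element_from_name(atoms$atom_name) == "H" &
       vapply(atoms$atom_name, function(nm) {
         partner <- h_partner_name(type, nm)
         !is.na(partner) && partner %in% BACKBONE_HEAVY
       }, logical(1)))
  attr(atoms, "bond_names") <- residue_bond_template(type)
  atoms
}

h_partner_name <- function(type, h_name) {
  for (pair in residue_bond_template(type)) {
    if (pair[1] == h_name) return(pair[2])
    if (pair[2] == h_name) return(pair[1])
  }
  NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of a synthetic fixture protein
#'
#' @param n_residues total number of residues in the chain.
#' @param residue_types optional character vector of length `n_residues`;
#'   when `NULL`, ionizable residues (cycling ASP, GLU, HIS, LYS) are
#'   interleaved with GLY/ALA spacers so neighbour-count features are
#'   non-trivial.
#' @param dipole_scale per-component standard deviation of the seeded
#'   isotropic induced-dipole vectors, in Debye.  Induced dipoles from a
#'   polarizable force field are typically a few tenths of a Debye.
#' @param noise_sd Gaussian noise added to planted labels (pKa units).
#' @param planted_coefficients 26-vector of planted label coefficients
#'   (see [planted_labels()]); defaults to [default_planted_coefficients()].
#' @param seed integer seed controlling dipoles and labels.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues, residue_types = NULL, dipole_scale = 0.3,
                         noise_sd = 0.3, planted_coefficients = NULL,
                         seed = 1L) {
  stopifnot(n_residues >= 1, noise_sd >= 0, dipole_scale >= 0)
  if (is.null(residue_types)) {
    residue_types <- character(n_residues)
    spacer_i <- 0L
    ion_i <- 0L
    for (i in seq_len(n_residues)) {
      if (i %% 2 == 1) {
        spacer_i <- spacer_i + 1L
        residue_types[i] <- SPACER_TYPES[(spacer_i - 1L) %% 2L + 1L]
      } else {
        ion_i <- ion_i + 1L
        residue_types[i] <- IONIZABLE_TYPES[(ion_i - 1L) %% 4L + 1L]
      }
    }
  }
  if (length(residue_types) != n_residues)
    stop("residue_types must have length n_residues")
  residue_types <- toupper(residue_types)
  bad <- setdiff(residue_types, supported_fixture_types())
  if (length(bad)) stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  structure(list(n_residues = as.integer(n_residues),
                 residue_types = residue_types,
                 dipole_scale = dipole_scale, noise_sd = noise_sd,
                 planted_coefficients = planted_coefficients %||%
                   default_planted_coefficients(),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic multi-residue protein with dipoles
#'
#' Chains ideal-geometry residues with trans peptide bonds (C-N link
#' 1.33 Angstrom, omega = 180 degrees) along a gently meandering
#' extended backbone, then assigns every atom a seeded isotropic
#' zero-mean induced-dipole vector.
#'
#' @param spec a [fixture_spec()].
#' @param source_id label stamped on the structure.
#' @return list with `structure` (a [protein_structure()] with explicit
#'   bonds and dipoles attached) and `dipoles` (the dipole table, Debye).
#' @export
make_toy_protein <- function(spec, source_id = "toy") {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  phi <- -120 + 12 * sin(seq_len(n))
  psi <- 130 + 12 * cos(seq_len(n))
  bb <- vector("list", n)  # per residue: list(N, CA, C, O, H)
  # first residue backbone in the XY plane
  Npos <- c(0, 0, 0)
  CApos <- c(1.458, 0, 0)
  Cpos <- CApos + 1.53 * c(cos((180 - 111) * pi / 180),
                           sin((180 - 111) * pi / 180), 0)
  for (i in seq_len(n)) {
    O <- place_atom(Npos, CApos, Cpos, 1.23, 121, psi[i] + 180)
    H <- if (i == 1) place_atom(Cpos, CApos, Npos, 1.01, 119, 180)
         else place_atom(bb[[i - 1]]$C, CApos, Npos, 1.01, 119, 180)
    bb[[i]] <- list(N = Npos, CA = CApos, C = Cpos, O = O, H = H)
    if (i < n) {
      Nnext <- place_atom(Npos, CApos, Cpos, 1.33, 116.2, psi[i])
      CAnext <- place_atom(CApos, Cpos, Nnext, 1.458, 121.7, 180)
      Cnext <- place_atom(Cpos, Nnext, CAnext, 1.53, 111, phi[i + 1])
      Npos <- Nnext; CApos <- CAnext; Cpos <- Cnext
    }
  }
  atom_rows <- list()
  bond_rows <- list()
  serial <- 0L
  prev_c_serial <- NA_integer_
  for (i in seq_len(n)) {
    type <- spec$residue_types[i]
    coords <- bb[[i]]
    zm <- residue_zmat(type)
    for (k in seq_len(nrow(zm))) {
      coords[[zm$name[k]]] <- place_atom(coords[[zm$a[k]]], coords[[zm$b[k]]],
                                         coords[[zm$c[k]]], zm$bond[k],
                                         zm$angle[k], zm$torsion[k])
    }
    nms <- names(coords)
    serials <- serial + seq_along(nms)
    serial_of <- stats::setNames(serials, nms)
    xyz <- do.call(rbind, coords)
    atom_rows[[i]] <- data.frame(
      serial = serials, atom_name = nms, element = element_from_name(nms),
      residue_name = type, residue_seq = i, chain_id = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_backbone = FALSE,
      dx = NA_real_, dy = NA_real_, dz = NA_real_, stringsAsFactors = FALSE)
    for (pair in residue_bond_template(type))
      bond_rows[[length(bond_rows) + 1L]] <- c(serial_of[[pair[1]]],
                                               serial_of[[pair[2]]])
    if (!is.na(prev_c_serial))
      bond_rows[[length(bond_rows) + 1L]] <- c(prev_c_serial, serial_of[["N"]])
    prev_c_serial <- serial_of[["C"]]
    serial <- serials[length(serials)]
  }
  atoms <- do.call(rbind, atom_rows)
  bonds <- do.call(rbind, bond_rows)
  atoms$is_backbone <- assign_backbone(atoms, bonds)
  struct <- protein_structure(atoms, bonds = bonds, source_id = source_id)
  dip <- with_seed(spec$seed, {
    data.frame(serial = atoms$serial,
               dx = stats::rnorm(nrow(atoms), 0, spec$dipole_scale),
               dy = stats::rnorm(nrow(atoms), 0, spec$dipole_scale),
               dz = stats::rnorm(nrow(atoms), 0, spec$dipole_scale))
  })
  struct <- attach_dipoles(struct, dip)
  list(structure = struct, dipoles = dip)
}

#' Default planted label coefficients
#'
#' A sparse 26-vector touching several feature families (local-frame
#' coordinates, heavy-atom counts, hydrogen-bond counts, SASA) with
#' effect sizes chosen so the deterministic label spread is a few pKa
#' units on top of the residue-type reference values - comparable to the
#' experimental shift range the predictor is meant to capture.
#'
#' @return named numeric vector of length 26.
#' @export
default_planted_coefficients <- function() {
  coef <- stats::setNames(numeric(26), feature_slot_names())
  coef["coord_x"] <- 0.35
  coef["coord_y"] <- 0.25
  coef["dipole_x"] <- 0.8
  coef["count_C"] <- 0.10
  coef["count_O"] <- 0.20
  coef["hbond_acceptor"] <- 0.30
  coef["sasa"] <- 0.02
  coef
}

#' Generate labels from a planted function of the graph features
#'
#' Each graph's label is the residue-type reference pKa plus a linear
#' readout of its mean-pooled (raw, pre-normalization) node features plus
#' seeded Gaussian noise: a mechanism a pooled graph regressor can
#' recover, with known ground truth for parameter-recovery experiments.
#'
#' @param graphs list of [residue_graph()] objects (pre-normalization).
#' @param coefficients numeric 26-vector.
#' @param sigma noise standard deviation (pKa units).
#' @param seed integer seed.
#' @return numeric label vector with attribute `generative` recording the
#'   coefficients, sigma, seed and the noiseless labels.
#' @export
planted_labels <- function(graphs, coefficients, sigma, seed = 1L) {
  if (length(coefficients) != 26)
    stop("planted coefficients must have length 26, got ", length(coefficients))
  stopifnot(sigma >= 0)
  noiseless <- vapply(graphs, function(g) {
    ref <- null_model_predict(g$key$residue_name)
    ref + sum(coefficients * colMeans(g$x))
  }, numeric(1))
  noise <- with_seed(seed, stats::rnorm(length(graphs), 0, sigma))
  labels <- noiseless + noise
  attr(labels, "generative") <- list(coefficients = coefficients, sigma = sigma,
                                     seed = seed, noiseless = noiseless)
  labels
}

#' Build a complete planted-mechanism dataset
#'
#' Convenience wrapper: generates toy proteins, extracts residue graphs
#' at the given crop radius, plants labels on the raw features, then
#' min-max normalizes the count features across the dataset.
#'
#' @param n_graphs target number of residue graphs.
#' @param radius crop radius in Angstrom.
#' @param sigma label noise standard deviation.
#' @param seed master seed (fans out to structure dipoles and labels).
#' @param residues_per_protein ionizable residues per fixture protein.
#' @param dipole_scale dipole component standard deviation, Debye.
#' @param coefficients planted 26-vector; default
#'   [default_planted_coefficients()].
#' @return list `graphs` (normalized), `norm` (normalization constants),
#'   `labels`, `truth` (generative record).
#' @export
make_planted_dataset <- function(n_graphs, radius = 9, sigma = 0.3, seed = 1L,
                                 residues_per_protein = 10L,
                                 dipole_scale = 0.3, coefficients = NULL) {
  coefficients <- coefficients %||% default_planted_coefficients()
  n_prot <- ceiling(n_graphs / residues_per_protein)
  graphs <- list()
  for (p in seq_len(n_prot)) {
    spec <- fixture_spec(n_residues = 2L * residues_per_protein + 1L,
                         dipole_scale = dipole_scale, noise_sd = sigma,
                         planted_coefficients = coefficients,
                         seed = seed * 10000L + p)
    toy <- make_toy_protein(spec, source_id = sprintf("toy%03d", p))
    labels <- ionizable_label_table(toy$structure, source_id = toy$structure$source_id)
    gs <- build_dataset(toy$structure, labels = labels, radius = radius,
                        normalize = FALSE)
    graphs <- c(graphs, gs)
  }
  graphs <- graphs[seq_len(min(n_graphs, length(graphs)))]
  labels <- planted_labels(graphs, coefficients, sigma, seed = seed + 7L)
  for (i in seq_along(graphs)) graphs[[i]]$label <- labels[i]
  normed <- normalize_dataset(graphs)
  list(graphs = normed$graphs, norm = normed$constants,
       labels = as.numeric(labels), truth = attr(labels, "generative"))
}

# Label table listing every ionizable residue of a structure with a
# placeholder pKa (overwritten by planted_labels).
ionizable_label_table <- function(structure, source_id = "toy") {
  a <- structure$atoms
  res <- unique(a[a$residue_name %in% IONIZABLE_TYPES,
                  c("chain_id", "residue_seq", "residue_name")])
  data.frame(pdb_id = source_id, chain = res$chain_id, resnum = res$residue_seq,
             restype = res$residue_name,
             pka_exp = vapply(res$residue_name, null_model_predict, numeric(1)),
             stringsAsFactors = FALSE)
}
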