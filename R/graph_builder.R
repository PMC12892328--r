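# Residue graph assembly: 26-feature node matrices, binary adjacency with
# self-loops, labels, dataset-level normalization and serialization.

DATASET_SCHEMA <- "pkagraph-v1"

#' Names of the 26 node feature slots, in fixed order
#'
#' 1-4 residue-type one-hot (ASP, GLU, HIS, LYS, alphabetical); 5-7
#' local-frame coordinates (Angstrom); 8-10 local-frame induced dipole
#' components (Debye); 11-14 heavy-atom neighbour counts (C, N, O, S);
#' 15-16 hydrogen-bond acceptor/donor counts; 17 SASA (Angstrom squared);
#' 18-26 atom-type one-hot (N/C/O/H split backbone vs side chain, plus a
#' single sulfur slot).
#'
#' @return character vector of length 26.
#' @export
feature_slot_names <- function() {
  c(paste0("res_", IONIZABLE_TYPES),
    "coord_x", "coord_y", "coord_z",
    "dipole_x", "dipole_y", "dipole_z",
    paste0("count_", c("C", "N", "O", "S")),
    "hbond_acceptor", "hbond_donor",
    "sasa",
    "type_N_bb", "type_N_sc", "type_C_bb", "type_C_sc",
    "type_O_bb", "type_O_sc", "type_H_bb", "type_H_sc", "type_S")
}

# slots subject to dataset-level min-max normalization
NORMALIZED_SLOTS <- 11:16

#' Residue graph container
#'
#' @param key a [residue_key()].
#' @param x N x 26 node feature matrix.
#' @param adj N x N binary symmetric adjacency with unit diagonal.
#' @param label experimental (or planted) pKa.
#' @param radius crop radius used for the environment features.
#' @param source_id originating structure label.
#' @param atom_names character vector of node atom names.
#' @param serials atom serials of the nodes.
#' @return a `residue_graph` object.
#' @export
residue_graph <- function(key, x, adj, label = NA_real_, radius = NA_real_,
                          source_id = "unknown", atom_names = NULL,
                          serials = NULL) {
  x <- as.matrix(x)
  adj <- as.matrix(adj)
  if (ncol(x) != 26) stop("node feature matrix must have 26 columns")
  if (nrow(x) != nrow(adj) || nrow(adj) != ncol(adj))
    stop("feature and adjacency dimensions disagree")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 1)) stop("adjacency diagonal must be all ones (self-loops)")
  colnames(x) <- feature_slot_names()
  if (!is.null(atom_names)) {
    rownames(x) <- atom_names
    dimnames(adj) <- list(atom_names, atom_names)
  }
  structure(list(key = key, x = x, adj = adj, label = label, radius = radius,
                 source_id = source_id,
                 atom_names = atom_names, serials = serials),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("residue_graph %s (%s): %d atoms, label %.3g, radius %.1f A\n",
              format(x$key), x$source_id, nrow(x$x), x$label, x$radius))
  invisible(x)
}

#' Build the intra-residue adjacency matrix with self-loops
#'
#' Edges are covalent bonds between atoms of the target residue only;
#' the environment never contributes edges.  Bond sources, in order of
#' preference: an explicit bond list (e.g. Tinker connectivity), the
#' per-residue bond name template, then a distance fallback (heavy-heavy
#' pairs at most 1.9 Angstrom, X-H pairs at most 1.2 Angstrom).  The
#' diagonal is set to one: self-loops let each atom retain its own
#' features during neighbourhood aggregation.
#'
#' @param env a [crop_environment()] result.
#' @param bonds optional explicit two-column serial pair matrix.
#' @return N x N binary symmetric matrix with unit diagonal.
#' @export
build_adjacency <- function(env, bonds = NULL) {
  a <- env$self_atoms
  n <- nrow(a)
  adj <- diag(1, n)
  rownames(adj) <- colnames(adj) <- a$atom_name
  add_edge <- function(i, j) {
    adj[i, j] <<- 1
    adj[j, i] <<- 1
  }
  used_template <- FALSE
  if (!is.null(bonds)) {
    keep <- bonds[, 1] %in% a$serial & bonds[, 2] %in% a$serial
    for (r in which(keep))
      add_edge(match(bonds[r, 1], a$serial), match(bonds[r, 2], a$serial))
  } else {
    tmpl <- tryCatch(residue_bond_template(a$residue_name[1]), error = function(e) NULL)
    if (!is.null(tmpl)) {
      used_template <- TRUE
      for (pair in tmpl) {
        i <- match(pair[1], a$atom_name)
        j <- match(pair[2], a$atom_name)
        if (!is.na(i) && !is.na(j)) add_edge(i, j)
      }
    }
    if (!used_template) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
        cutoff <- if (a$element[i] == "H" || a$element[j] == "H") 1.2 else 1.9
        if (a$element[i] == "H" && a$element[j] == "H") cutoff <- 0
        if (d <= cutoff) add_edge(i, j)
      }
    }
  }
  heavy <- which(a$element != "H")
  if (length(heavy) > 1) {
    sub <- adj[heavy, heavy, drop = FALSE]
    diag(sub) <- 0
    # connected-components check by repeated neighbour expansion
    reach <- c(1L)
    repeat {
      nxt <- unique(c(reach, which(rowSums(sub[, reach, drop = FALSE]) > 0)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) < length(heavy))
      warning("heavy-atom bond graph of ", format(env$key), " is disconnected")
  }
  adj
}

#' Compute the 26-feature node matrix for a residue environment
#'
#' Coordinates and dipole vectors are expressed in the residue's local
#' frame; neighbour counts are taken against context atoms only; SASA
#' and hydrogen-bond counts are looked up from whole-structure tables.
#' Atoms without an attached dipole get zero dipole features (with a
#' warning).
#'
#' @param env a [crop_environment()] result.
#' @param frame the residue's [build_local_frame()] frame.
#' @param hbonds data frame from [detect_hydrogen_bonds()].
#' @param sasa data frame from [compute_sasa()].
#' @param count_radius radius for the heavy-atom neighbour counts;
#'   defaults to the environment's crop radius.
#' @return N x 26 matrix (rows follow `env$self_atoms`).
#' @export
featurize_nodes <- function(env, frame, hbonds, sasa,
                            count_radius = env$radius) {
  a <- env$self_atoms
  n <- nrow(a)
  type <- env$key$residue_name
  if (any(!a$element %in% c("C", "N", "O", "H", "S")))
    stop("cannot one-hot encode element(s): ",
         paste(unique(a$element[!a$element %in% c("C", "N", "O", "H", "S")]),
               collapse = ", "))
  x <- matrix(0, n, 26, dimnames = list(a$atom_name, feature_slot_names()))
  x[, paste0("res_", type)] <- 1
  x[, 5:7] <- to_local(frame, cbind(a$x, a$y, a$z))
  dip <- cbind(a$dx, a$dy, a$dz)
  missing_dip <- apply(dip, 1, function(r) any(is.na(r)))
  if (any(missing_dip)) {
    warning(sum(missing_dip), " atom(s) of ", format(env$key),
            " have no dipole; dipole features zero-filled")
    dip[missing_dip, ] <- 0
  }
  x[, 8:10] <- rotate_vector(frame, dip)
  for (i in seq_len(n))
    x[i, 11:14] <- count_heavy_neighbors(env, a[i, , drop = FALSE], count_radius)
  hb_idx <- match(a$serial, hbonds$serial)
  if (anyNA(hb_idx)) stop("hydrogen-bond table lacks entries for target atoms")
  x[, 15] <- hbonds$n_acceptor[hb_idx]
  x[, 16] <- hbonds$n_donor[hb_idx]
  sa_idx <- match(a$serial, sasa$serial)
  if (anyNA(sa_idx)) stop("SASA table lacks entries for target atoms")
  x[, 17] <- sasa$sasa[sa_idx]
  loc <- ifelse(a$is_backbone, "bb", "sc")
  slot <- ifelse(a$element == "S", "type_S",
                 paste0("type_", a$element, "_", loc))
  x[cbind(seq_len(n), match(slot, feature_slot_names()))] <- 1
  x
}

#' Min-max normalize count features across a dataset
#'
#' Slots 11-16 (heavy-atom neighbour counts and hydrogen-bond counts)
#' are scaled to \[0, 1\] using minima/maxima pooled over all nodes of
#' all graphs; constant slots map to zero.  All other slots are left
#' untouched.  The returned constants reproduce the transformation at
#' inference time via [apply_normalization()].
#'
#' @param graphs list of [residue_graph()] objects.
#' @return list `graphs` (normalized) and `constants`.
#' @export
normalize_dataset <- function(graphs) {
  if (!length(graphs)) stop("cannot normalize an empty graph collection")
  pooled <- do.call(rbind, lapply(graphs, function(g) g$x[, NORMALIZED_SLOTS,
                                                          drop = FALSE]))
  mins <- apply(pooled, 2, min)
  maxs <- apply(pooled, 2, max)
  constants <- list(slots = NORMALIZED_SLOTS, min = mins, max = maxs)
  list(graphs = apply_normalization(graphs, constants), constants = constants)
}

#' Apply stored normalization constants to graphs
#'
#' @param graphs list of [residue_graph()] objects.
#' @param constants as returned by [normalize_dataset()].
#' @return normalized graphs.
#' @export
apply_normalization <- function(graphs, constants) {
  rng <- constants$max - constants$min
  lapply(graphs, function(g) {
    block <- g$x[, constants$slots, drop = FALSE]
    for (k in seq_along(constants$slots)) {
      block[, k] <- if (rng[k] > 0)
        (block[, k] - constants$min[k]) / rng[k]
      else 0
    }
    g$x[, constants$slots] <- block
    g
  })
}

#' Build a residue-graph dataset from structures, dipoles and labels
#'
#' One graph is produced per labeled residue of the four modeled types.
#' Residues that are missing, of an unsupported type, lack a C-alpha, or
#' fail local-frame construction are skipped with a logged reason (see
#' `attr(result, "skipped")`).
#'
#' @param structures a single [protein_structure()] or a named list of
#'   them (names matched against `labels$pdb_id`; a single unnamed
#'   structure matches everything).
#' @param labels data frame with columns `pdb_id, chain, resnum, restype,
#'   pka_exp` (the label-table schema; read with [read_label_csv()]).
#' @param radius crop radius in Angstrom.
#' @param count_radius neighbour-count radius (default: `radius`).
#' @param n_sasa_points,probe SASA quadrature settings.
#' @param hbond_dist,hbond_angle hydrogen-bond thresholds.
#' @param normalize when `TRUE`, min-max normalize slots 11-16 and attach
#'   the constants as `attr(result, "normalization")`.
#' @return list of [residue_graph()] objects.
#' @export
build_dataset <- function(structures, labels, radius = 9,
                          count_radius = radius, n_sasa_points = 960,
                          probe = 1.4, hbond_dist = 2.5, hbond_angle = 120,
                          normalize = FALSE) {
  if (inherits(structures, "protein_structure"))
    structures <- stats::setNames(list(structures), structures$source_id)
  needed <- c("pdb_id", "chain", "resnum", "restype", "pka_exp")
  if (!all(needed %in% names(labels)))
    stop("label table must have columns: ", paste(needed, collapse = ", "))
  graphs <- list()
  skipped <- list()
  skip <- function(row, reason)
    skipped[[length(skipped) + 1L]] <<- data.frame(
      pdb_id = row$pdb_id, chain = row$chain, resnum = row$resnum,
      restype = row$restype, reason = reason, stringsAsFactors = FALSE)
  per_structure <- split(labels, labels$pdb_id)
  for (sid in names(per_structure)) {
    struct <- if (length(structures) == 1 && is.null(names(structures)[1]))
      structures[[1]] else structures[[sid]]
    if (is.null(struct) && length(structures) == 1) struct <- structures[[1]]
    if (is.null(struct)) {
      for (r in seq_len(nrow(per_structure[[sid]])))
        skip(per_structure[[sid]][r, ], "structure not provided")
      next
    }
    hb <- detect_hydrogen_bonds(struct, hbond_dist, hbond_angle)
    sa <- compute_sasa(struct, n_points = n_sasa_points, probe = probe)
    for (r in seq_len(nrow(per_structure[[sid]]))) {
      row <- per_structure[[sid]][r, ]
      if (!toupper(row$restype) %in% IONIZABLE_TYPES) {
        skip(row, "unsupported residue type")
        next
      }
      key <- residue_key(row$chain, row$resnum, row$restype)
      g <- tryCatch({
        env <- crop_environment(struct, key, radius)
        anchors <- lapply(c("CA", "C", "O"), function(nm) {
          i <- which(env$self_atoms$atom_name == nm)
          if (!length(i)) stop("missing backbone atom ", nm)
          c(env$self_atoms$x[i[1]], env$self_atoms$y[i[1]], env$self_atoms$z[i[1]])
        })
        frame <- build_local_frame(anchors[[1]], anchors[[2]], anchors[[3]])
        adj <- build_adjacency(env, bonds = struct$bonds)
        x <- featurize_nodes(env, frame, hb, sa, count_radius)
        residue_graph(key, x, adj, label = row$pka_exp, radius = radius,
                      source_id = sid, atom_names = env$self_atoms$atom_name,
                      serials = env$self_atoms$serial)
      }, error = function(e) conditionMessage(e))
      if (is.character(g)) skip(row, g) else graphs[[length(graphs) + 1L]] <- g
    }
  }
  if (!length(graphs))
    stop("no residue graphs could be built from the provided labels")
  skip_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(pdb_id = character(), chain = character(), resnum = integer(),
               restype = character(), reason = character())
  if (normalize) {
    normed <- normalize_dataset(graphs)
    graphs <- normed$graphs
    attr(graphs, "normalization") <- normed$constants
  }
  attr(graphs, "skipped") <- skip_df
  graphs
}

#' Read a residue pKa label table
#'
#' CSV with header `pdb_id,chain,resnum,restype,pka_exp`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_label_csv <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pdb_id", "chain", "resnum", "restype", "pka_exp")
  if (!all(needed %in% names(tab)))
    stop("label CSV must have columns: ", paste(needed, collapse = ", "))
  tab
}

#' Save a residue-graph dataset to a single JSON archive
#'
#' @param graphs list of [residue_graph()] objects.
#' @param path output path.
#' @param constants optional normalization constants to store alongside.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(graphs, path, constants = NULL) {
  if (!length(graphs)) stop("refusing to save an empty dataset")
  payload <- list(
    schema = DATASET_SCHEMA,
    constants = constants,
    graphs = lapply(graphs, function(g) list(
      chain_id = g$key$chain_id, residue_seq = g$key$residue_seq,
      residue_name = g$key$residue_name,
      x = unclass(g$x), adj = unclass(g$adj), label = g$label,
      radius = g$radius, source_id = g$source_id,
      atom_names = g$atom_names, serials = g$serials)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a residue-graph dataset saved by [save_dataset()]
#'
#' @param path archive path.
#' @return list of graphs; normalization constants, when present, are
#'   attached as `attr(result, "normalization")`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE)
  if (is.null(payload$schema) || !identical(payload$schema, DATASET_SCHEMA))
    stop("dataset schema mismatch: expected '", DATASET_SCHEMA, "', found '",
         payload$schema, "'")
  gl <- payload$graphs
  graphs <- lapply(seq_len(length(gl$label)), function(i) {
    residue_graph(residue_key(gl$chain_id[i], gl$residue_seq[i],
                              gl$residue_name[i]),
                  gl$x[[i]], gl$adj[[i]], label = gl$label[i],
                  radius = gl$radius[i], source_id = gl$source_id[i],
                  atom_names = gl$atom_names[[i]], serials = gl$serials[[i]])
  })
  if (!is.null(payload$constants)) {
    cst <- payload$constants
    cst$slots <- as.integer(cst$slots)
    attr(graphs, "normalization") <- cst
  }
  graphs
}
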