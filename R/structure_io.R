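# One Debye in SI units (Coulomb metre).
DEBYE_CM <- 3.33564e-30

WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")
BACKBONE_HEAVY <- c("N", "CA", "C", "O")

#' Protein structure container
#'
#' A `protein_structure` is a list with three components:
#' \describe{
#'   \item{atoms}{data frame with one row per atom: `serial`, `atom_name`,
#'     `element` (one of C, N, O, H, S, other), `residue_name`,
#'     `residue_seq`, `chain_id`, `x`, `y`, `z` (Angstrom), `is_backbone`,
#'     and the induced dipole components `dx`, `dy`, `dz` (Debye; `NA`
#'     when no dipole has been attached).}
#'   \item{bonds}{two-column integer matrix of unordered serial pairs, or
#'     `NULL` when connectivity is unknown (plain PDB input).}
#'   \item{source_id}{character label of the originating file or fixture.}
#' }
#'
#' @param atoms atom data frame as described above.
#' @param bonds optional two-column matrix of bonded serial pairs.
#' @param source_id character label.
#' @return a `protein_structure` object.
#' @export
protein_structure <- function(atoms, bonds = NULL, source_id = "unknown") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "atom_name", "element", "residue_name", "residue_seq",
              "chain_id", "x", "y", "z", "is_backbone")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within a structure")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom positions must be finite")
  for (col in c("dx", "dy", "dz")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (!is.null(bonds)) {
    bonds <- normalize_bonds(bonds)
    bad <- !(bonds %in% atoms$serial)
    if (any(bad))
      stop("bond references unknown serial(s): ",
           paste(unique(bonds[bad]), collapse = ", "))
    if (any(bonds[, 1] == bonds[, 2]))
      stop("self-bond in bond list")
  }
  structure(list(atoms = atoms, bonds = bonds, source_id = source_id),
            class = "protein_structure")
}

normalize_bonds <- function(bonds) {
  b <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  b <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  unique(b)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure '%s': %d atoms, %d residues, %s bonds\n",
              x$source_id, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "residue_seq")])),
              if (is.null(x$bonds)) "no explicit" else nrow(x$bonds)))
  invisible(x)
}

#' Key identifying one modeled ionizable residue
#'
#' @param chain_id chain identifier.
#' @param residue_seq residue sequence number.
#' @param residue_name one of `"ASP"`, `"GLU"`, `"HIS"`, `"LYS"` - the four
#'   ionizable residue types the framework models.
#' @return a `residue_key` object.
#' @export
residue_key <- function(chain_id, residue_seq, residue_name) {
  residue_name <- toupper(residue_name)
  if (!residue_name %in% IONIZABLE_TYPES)
    stop("unsupported residue type '", residue_name,
         "' (modeled types: ", paste(IONIZABLE_TYPES, collapse = ", "), ")")
  structure(list(chain_id = as.character(chain_id),
                 residue_seq = as.integer(residue_seq),
                 residue_name = residue_name),
            class = "residue_key")
}

IONIZABLE_TYPES <- c("ASP", "GLU", "HIS", "LYS")

#' @export
format.residue_key <- function(x, ...)
  sprintf("%s/%s%d", x$chain_id, x$residue_name, x$residue_seq)

#' @export
print.residue_key <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

element_from_name <- function(atom_name) {
  lead <- sub("^[0-9']*", "", toupper(atom_name))
  first <- substr(lead, 1, 1)
  ifelse(first %in% c("C", "N", "O", "H", "S"), first, "other")
}

# H atoms inherit backbone status from their covalent heavy partner:
# explicit bond when available, else the nearest heavy atom of the same
# residue within 1.2 A (a hydrogen's covalent partner is by definition
# intra-residue).
assign_backbone <- function(atoms, bonds = NULL) {
  is_bb <- atoms$atom_name %in% BACKBONE_HEAVY & atoms$element != "H"
  h_idx <- which(atoms$element == "H")
  for (i in h_idx) {
    partner <- NA_integer_
    if (!is.null(bonds)) {
      hit <- bonds[bonds[, 1] == atoms$serial[i] | bonds[, 2] == atoms$serial[i], ,
                   drop = FALSE]
      if (nrow(hit)) {
        other <- setdiff(as.vector(hit), atoms$serial[i])
        other <- other[atoms$element[match(other, atoms$serial)] != "H"]
        if (length(other)) partner <- match(other[1], atoms$serial)
      }
    }
    if (is.na(partner)) {
      heavy_idx <- which(atoms$element != "H" &
                         atoms$chain_id == atoms$chain_id[i] &
                         atoms$residue_seq == atoms$residue_seq[i])
      if (length(heavy_idx)) {
        d2 <- (atoms$x[heavy_idx] - atoms$x[i])^2 +
              (atoms$y[heavy_idx] - atoms$y[i])^2 +
              (atoms$z[heavy_idx] - atoms$z[i])^2
        j <- which.min(d2)
        if (d2[j] <= 1.2^2) partner <- heavy_idx[j]
      }
    }
    is_bb[i] <- !is.na(partner) && atoms$atom_name[partner] %in% BACKBONE_HEAVY
  }
  is_bb
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records.  Water HETATM records are
#' dropped; other HETATM entries (metal ions, ligands) are retained with
#' the element parsed from the record.  Backbone flags are assigned from
#' the atom name (N, CA, C, O) and, for hydrogens, from the nearest heavy
#' atom within 1.2 Angstrom.
#'
#' @param path path to a PDB file.
#' @return a [protein_structure()] (no explicit bond list).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)
  parse_num <- function(txt, field, line_no) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & nzchar(trimws(txt)))
    if (length(bad) || anyNA(v))
      stop(sprintf("unparseable %s field at line %d of %s", field,
                   line_no[if (length(bad)) bad[1] else which(is.na(v))[1]], path))
    v
  }
  ln <- lines[keep]
  serial <- parse_num(trimws(substr(ln, 7, 11)), "serial", keep)
  name <- trimws(substr(ln, 13, 16))
  resn <- trimws(substr(ln, 18, 20))
  chain <- trimws(substr(ln, 22, 22))
  resseq <- parse_num(trimws(substr(ln, 23, 26)), "residue number", keep)
  x <- parse_num(trimws(substr(ln, 31, 38)), "x-coordinate", keep)
  y <- parse_num(trimws(substr(ln, 39, 46)), "y-coordinate", keep)
  z <- parse_num(trimws(substr(ln, 47, 54)), "z-coordinate", keep)
  elem_col <- trimws(substr(ln, 77, 78))
  is_het <- substr(ln, 1, 6) == "HETATM"
  water <- is_het & toupper(resn) %in% WATER_RESNAMES
  element <- ifelse(nzchar(elem_col),
                    ifelse(toupper(elem_col) %in% c("C", "N", "O", "H", "S"),
                           toupper(elem_col), "other"),
                    element_from_name(name))
  atoms <- data.frame(serial = as.integer(serial), atom_name = name,
                      element = element, residue_name = resn,
                      residue_seq = as.integer(resseq), chain_id = chain,
                      x = x, y = y, z = z, is_backbone = FALSE,
                      dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      stringsAsFactors = FALSE)
  atoms <- atoms[!water, , drop = FALSE]
  if (!nrow(atoms)) stop("structure is empty after removing waters: ", path)
  atoms$is_backbone <- assign_backbone(atoms)
  protein_structure(atoms, bonds = NULL,
                    source_id = sub("\\.pdb$", "", basename(path)))
}

#' Write a protein structure as PDB
#'
#' @param structure a [protein_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  # atom-name column convention: 1-letter element names start in column 14
  fmt_name <- ifelse(nchar(a$atom_name) < 4, sprintf(" %-3s", a$atom_name),
                     a$atom_name)
  elem <- ifelse(a$element == "other", "X", a$element)
  lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial, fmt_name, a$residue_name, a$chain_id,
                   a$residue_seq, a$x, a$y, a$z, 1, 0, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a Tinker Cartesian xyz file
#'
#' The Tinker dialect carries an atom count on the first line and, on each
#' atom line, the index, atom name, coordinates, a force-field type code,
#' and the indices of covalently bonded neighbours.  The neighbour lists
#' give an explicit bond set (deduplicated to unordered pairs).
#'
#' @param path path to a Tinker `.xyz` file.
#' @return a [protein_structure()] with an explicit bond list.  Residue
#'   annotation is not present in the format; all atoms are assigned to
#'   residue `UNK 1` of chain `A`.
#' @export
read_tinker_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Tinker xyz file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_decl <- suppressWarnings(as.integer(header[1]))
  if (is.na(n_decl)) stop("first line of ", path, " must begin with the atom count")
  body <- lines[-1]
  if (length(body) != n_decl)
    stop(sprintf("declared atom count %d but found %d atom lines in %s",
                 n_decl, length(body), path))
  serial <- integer(n_decl); nm <- character(n_decl)
  xyz <- matrix(NA_real_, n_decl, 3)
  bond_pairs <- list()
  for (i in seq_len(n_decl)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 6)
      stop("malformed atom line ", i + 1, " in ", path)
    serial[i] <- as.integer(tok[1])
    nm[i] <- tok[2]
    xyz[i, ] <- suppressWarnings(as.numeric(tok[3:5]))
    if (anyNA(xyz[i, ]))
      stop("unparseable coordinate at line ", i + 1, " of ", path)
    nb <- suppressWarnings(as.integer(tok[-(1:6)]))
    if (length(nb)) bond_pairs[[length(bond_pairs) + 1L]] <- cbind(serial[i], nb)
  }
  bonds <- if (length(bond_pairs)) do.call(rbind, bond_pairs) else NULL
  if (!is.null(bonds)) {
    out_of_range <- !(bonds[, 2] %in% serial)
    if (any(out_of_range))
      stop("neighbour index out of range in ", path, ": ",
           paste(unique(bonds[out_of_range, 2]), collapse = ", "))
    bonds <- normalize_bonds(bonds)
  }
  atoms <- data.frame(serial = serial, atom_name = nm,
                      element = element_from_name(nm),
                      residue_name = "UNK", residue_seq = 1L, chain_id = "A",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      is_backbone = FALSE, dx = NA_real_, dy = NA_real_,
                      dz = NA_real_, stringsAsFactors = FALSE)
  atoms$is_backbone <- assign_backbone(atoms, bonds)
  protein_structure(atoms, bonds = bonds,
                    source_id = sub("\\.xyz$", "", basename(path)))
}

#' Write a structure in Tinker Cartesian xyz format
#'
#' @param structure a [protein_structure()]; its bond list (or, when
#'   absent, an empty neighbour list) supplies the per-line connectivity.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tinker_xyz <- function(structure, path) {
  a <- structure$atoms
  nb <- lapply(a$serial, function(s) {
    if (is.null(structure$bonds)) integer(0)
    else {
      hit <- structure$bonds[structure$bonds[, 1] == s | structure$bonds[, 2] == s, ,
                             drop = FALSE]
      sort(setdiff(as.vector(hit), s))
    }
  })
  lines <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(sprintf("%6d  %-4s %11.6f %11.6f %11.6f %5d", a$serial[i],
                    a$atom_name[i], a$x[i], a$y[i], a$z[i], 1L),
            sprintf("%d", nb[[i]])), collapse = " ")
  }, character(1))
  writeLines(c(sprintf("%6d  %s", nrow(a), structure$source_id), lines), path)
  invisible(path)
}

#' Read a per-atom induced-dipole table
#'
#' Expects whitespace- or tab-delimited text with header
#' `serial dx dy dz unit`.  Vectors tagged `D` are taken as Debye;
#' vectors tagged `C.m` (Coulomb metre, also accepted as `Cm` or the
#' literal `C*m`) are converted to Debye via 1 D = 3.33564e-30 C.m.
#'
#' @param path path to the table.
#' @return data frame `serial, dx, dy, dz` with all components in Debye.
#' @export
read_dipole_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("serial", "dx", "dy", "dz", "unit")
  if (!all(needed %in% names(tab)))
    stop("dipole table must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(tab$serial))
    stop("duplicate serial(s) in dipole table: ",
         paste(unique(tab$serial[duplicated(tab$serial)]), collapse = ", "))
  unit <- toupper(gsub("[^A-Za-z]", "", tab$unit))
  known <- unit %in% c("D", "CM")
  if (!all(known))
    stop("unknown dipole unit tag(s): ", paste(unique(tab$unit[!known]), collapse = ", "))
  scale <- ifelse(unit == "D", 1, 1 / DEBYE_CM)
  data.frame(serial = as.integer(tab$serial),
             dx = tab$dx * scale, dy = tab$dy * scale, dz = tab$dz * scale)
}

#' Write a per-atom dipole table (Debye)
#'
#' @param dipoles data frame `serial, dx, dy, dz` in Debye.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dipole_table <- function(dipoles, path) {
  tab <- data.frame(serial = dipoles$serial, dx = dipoles$dx, dy = dipoles$dy,
                    dz = dipoles$dz, unit = "D")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert dipole magnitudes between Debye and Coulomb metre
#'
#' @param value numeric vector.
#' @param from,to `"D"` or `"C.m"`.
#' @return converted values.
#' @export
convert_dipole_units <- function(value, from = "D", to = "C.m") {
  key <- function(u) toupper(gsub("[^A-Za-z]", "", u))
  f <- key(from); t_ <- key(to)
  if (!f %in% c("D", "CM") || !t_ %in% c("D", "CM")) stop("unknown dipole unit")
  if (f == t_) return(value)
  if (f == "D") value * DEBYE_CM else value / DEBYE_CM
}

#' Attach induced dipoles to a structure
#'
#' @param structure a [protein_structure()].
#' @param dipoles data frame `serial, dx, dy, dz` (Debye), as returned by
#'   [read_dipole_table()].
#' @return the structure with dipole columns filled for matched atoms;
#'   the number of attached dipoles is available as
#'   `attr(result, "n_attached")`.
#' @export
attach_dipoles <- function(structure, dipoles) {
  stopifnot(inherits(structure, "protein_structure"))
  if (is.null(dipoles) || nrow(dipoles) == 0) {
    attr(structure, "n_attached") <- 0L
    return(structure)
  }
  unknown <- setdiff(dipoles$serial, structure$atoms$serial)
  if (length(unknown))
    stop("dipole table references serial(s) absent from structure: ",
         paste(unknown, collapse = ", "))
  idx <- match(dipoles$serial, structure$atoms$serial)
  structure$atoms$dx[idx] <- dipoles$dx
  structure$atoms$dy[idx] <- dipoles$dy
  structure$atoms$dz[idx] <- dipoles$dz
  attr(structure, "n_attached") <- length(idx)
  structure
}
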