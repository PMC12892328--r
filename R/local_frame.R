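#' Universal local coordinate frame for a target residue
#'
#' Builds the right-handed orthonormal frame that makes residue features
#' invariant to the global pose of the protein.  The origin sits on the
#' C-alpha atom; the X axis points along the C-alpha to carbonyl-carbon
#' bond; the Z axis is normal to the plane spanned by the X axis and the
#' carbonyl group; the Y axis completes the right-handed system.  With
#' ideal backbone geometry the carbonyl C lands near (1.53, 0, 0) and the
#' carbonyl O near (2.17, 1.06, 0) in every frame, so identical local
#' geometries from different proteins map onto identical coordinates.
#'
#' The Z-axis sign is fixed as `e_z = e_x x unit(O - C)`, which places the
#' carbonyl oxygen at positive local Y.
#'
#' @param ca numeric 3-vector, C-alpha position (Angstrom).
#' @param carbonyl_c numeric 3-vector, carbonyl carbon position.
#' @param carbonyl_o numeric 3-vector, carbonyl oxygen position.
#' @return An object of class `local_frame`: list with `origin` and unit
#'   axes `e_x`, `e_y`, `e_z` (rows of a rotation matrix with det +1).
#' @examples
#' fr <- build_local_frame(c(0, 0, 0), c(1.53, 0, 0), c(2.17, 1.06, 0))
#' fr$e_x  # c(1, 0, 0)
#' @export
build_local_frame <- function(ca, carbonyl_c, carbonyl_o) {
  ca <- as.numeric(ca); cc <- as.numeric(carbonyl_c); co <- as.numeric(carbonyl_o)
  stopifnot(length(ca) == 3, length(cc) == 3, length(co) == 3)
  if (!all(is.finite(c(ca, cc, co))))
    stop("frame anchors must have finite coordinates")
  v_x <- cc - ca
  n_x <- sqrt(sum(v_x^2))
  if (n_x <= 0.5)
    stop("degenerate geometry: C-alpha and carbonyl C are closer than 0.5 Angstrom")
  e_x <- v_x / n_x
  v_o <- co - cc
  n_o <- sqrt(sum(v_o^2))
  if (n_o < 1e-12)
    stop("degenerate geometry: carbonyl C and O coincide")
  u_o <- v_o / n_o
  z_raw <- cross3(e_x, u_o)
  n_z <- sqrt(sum(z_raw^2))
  # sin of the angle between e_x and the C->O direction
  if (n_z <= 1e-6)
    stop("degenerate geometry: carbonyl O collinear with the C-alpha - C axis")
  e_z <- z_raw / n_z
  e_y <- cross3(e_z, e_x)
  structure(list(origin = ca, e_x = e_x, e_y = e_y, e_z = e_z),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("Local coordinate frame\n")
  cat("  origin:", format(x$origin, digits = 4), "\n")
  cat("  e_x:   ", format(x$e_x, digits = 4), "\n")
  cat("  e_y:   ", format(x$e_y, digits = 4), "\n")
  cat("  e_z:   ", format(x$e_z, digits = 4), "\n")
  invisible(x)
}

frame_rotation <- function(frame) {
  rbind(frame$e_x, frame$e_y, frame$e_z, deparse.level = 0)
}

#' Transform positions into a local frame
#'
#' Re-expresses Cartesian positions relative to the frame origin and axes;
#' an isometry, so all pairwise distances are preserved.  The C-alpha
#' anchor maps to (0, 0, 0).
#'
#' @param frame a [build_local_frame()] result.
#' @param points numeric matrix with 3 columns (or a single 3-vector).
#' @return matrix of the same shape with local-frame coordinates.
#' @export
to_local <- function(frame, points) {
  stopifnot(inherits(frame, "local_frame"))
  single <- is.null(dim(points))
  pts <- if (single) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  stopifnot(ncol(pts) == 3)
  out <- sweep(pts, 2, frame$origin) %*% t(frame_rotation(frame))
  if (single) drop(out) else out
}

#' Rotate a free vector into a local frame
#'
#' Applies the frame rotation without the origin shift.  Used for dipole
#' moment vectors, which must co-rotate with the coordinates for the
#' representation to be rotation invariant but have no meaningful origin.
#'
#' @param frame a [build_local_frame()] result.
#' @param v numeric 3-vector or matrix with 3 columns.
#' @return rotated vector(s); norms are preserved.
#' @export
rotate_vector <- function(frame, v) {
  stopifnot(inherits(frame, "local_frame"))
  single <- is.null(dim(v))
  m <- if (single) matrix(as.numeric(v), nrow = 1) else as.matrix(v)
  stopifnot(ncol(m) == 3)
  out <- m %*% t(frame_rotation(frame))
  if (single) drop(out) else out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
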