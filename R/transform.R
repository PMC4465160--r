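#' 6-DOF rigid transform
#'
#' Maps a physical point `p` (mm) to `R (p - center) + center + t`, with
#' `R = Rz %*% Ry %*% Rx` (fixed composition order: rotation about x first,
#' then y, then z). Rotations are in radians, translations in mm. The rotation
#' center matters: the same rotation about a different center is a different
#' mapping, and the optimizer exploits this by centering local registrations
#' on the CTV centroid.
#'
#' @param rotations length-3 numeric `(rx, ry, rz)` radians.
#' @param translations length-3 numeric `(tx, ty, tz)` mm.
#' @param center length-3 numeric rotation center, mm.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3, length(translations) == 3, length(center) == 3)
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 center = as.numeric(center)),
            class = "RigidTransform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function(center = c(0, 0, 0)) rigid_transform(center = center)

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: rot (%s) deg, trans (%s) mm, center (%s) mm\n",
              paste(format(round(x$rotations * 180 / pi, 3)), collapse = ", "),
              paste(format(round(x$translations, 3)), collapse = ", "),
              paste(format(round(x$center, 2)), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#' @param t a `RigidTransform`.
#' @return 3x3 rotation matrix `Rz Ry Rx`.
#' @export
rotation_matrix <- function(t) {
  r <- t$rotations
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to physical points
#' @param t a `RigidTransform`.
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(t, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  R <- rotation_matrix(t)
  out <- sweep(pts, 2, t$center) %*% t(R)
  out <- sweep(out, 2, t$center + t$translations, "+")
  if (single) drop(out) else out
}

#' Invert a rigid transform
#' @param t a `RigidTransform`.
#' @return The inverse mapping, with the same rotation center.
#' @export
invert_transform <- function(t) {
  R <- rotation_matrix(t)
  rigid_transform(rotations = euler_zyx(t(R)),
                  translations = -as.numeric(t(R) %*% t$translations),
                  center = t$center)
}

# Extract (rx, ry, rz) with R = Rz Ry Rx. Assumes |ry| < pi/2 (always true for
# the small setup rotations this pipeline handles).
euler_zyx <- function(R) {
  ry <- asin(-R[3, 1])
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the mapping `x -> a(b(x))` (apply `b` first).
#' The result uses the rotation center of `a`.
#'
#' @param a,b `RigidTransform` objects.
#' @return A `RigidTransform` equal to `a` after `b`.
#' @export
compose_transform <- function(a, b) {
  Ra <- rotation_matrix(a); Rb <- rotation_matrix(b)
  R <- Ra %*% Rb
  # a(b(x)) = Ra(Rb(x - cb) + cb + tb - ca) + ca + ta
  #         = R (x - ca) + ca + [Ra (Rb(ca - cb) + cb + tb - ca) + ta]
  ca <- a$center; cb <- b$center
  t_new <- as.numeric(Ra %*% (Rb %*% (ca - cb) + cb + b$translations - ca)) + a$translations
  rigid_transform(rotations = euler_zyx(R), translations = t_new, center = ca)
}

#' Read/write a rigid transform as plain text
#'
#' The file holds two lines: `rx ry rz tx ty tz` (radians, mm) and
#' `cx cy cz` (mm rotation center).
#'
#' @param t a `RigidTransform`.
#' @param path file path.
#' @return `read_transform` returns a `RigidTransform`; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  writeLines(c(paste(format(c(t$rotations, t$translations), digits = 17), collapse = " "),
               paste(format(t$center, digits = 17), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  ln <- readLines(path, n = 2)
  p <- as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]])
  cc <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  if (length(p) != 6 || length(cc) != 3 || any(!is.finite(c(p, cc))))
    stop("malformed transform file: ", path)
  rigid_transform(p[1:3], p[4:6], cc)
}
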