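#' @useDynLib cbctreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames cor
#' @importFrom utils write.csv
NULL

#' Construct a 3D image volume
#'
#' An `ImageVolume` is a 3D scalar grid with axis-aligned physical geometry:
#' the physical position of 0-based voxel index `(i,j,k)` is
#' `origin + (i,j,k) * spacing`, where a voxel's position is its center.
#' Direction cosines (oblique grids) are deliberately not supported. CT
#' volumes carry Hounsfield units; CBCT volumes carry arbitrary units because
#' in-room cone-beam systems are typically not calibrated to HU.
#'
#' @param voxels 3D numeric array of finite values.
#' @param spacing length-3 positive numeric, mm per axis.
#' @param origin length-3 numeric, mm position of the center of voxel (0,0,0).
#' @param modality `"CT"` or `"CBCT"`.
#' @return An object of class `ImageVolume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0), modality = c("CT", "CBCT")) {
  modality <- match.arg(modality)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin))) stop("origin must be 3 finite values")
  if (any(!is.finite(voxels))) stop("voxel values must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), modality = modality),
            class = "ImageVolume")
}

#' Construct a binary mask on an image grid
#'
#' Same geometry model as [image_volume()] with voxel values restricted to
#' \{0, 1\}.
#'
#' @param voxels 3D array of 0/1 (logical arrays are accepted).
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim = dim(voxels))
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(voxels %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "BinaryMask")
}

#' @export
print.ImageVolume <- function(x, ...) {
  cat(sprintf("ImageVolume [%s] %s voxels, spacing %s mm, origin %s mm, range [%g, %g]\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(round(x$origin, 2)), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask %s voxels, spacing %s mm, %d foreground (%.1f cm^3)\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$voxels), mask_volume(x) / 1000))
  invisible(x)
}

#' Physical volume of a mask in mm^3
#' @param m a `BinaryMask`.
#' @return Scalar mm^3: foreground voxel count times the voxel volume.
#' @export
mask_volume <- function(m) sum(m$voxels) * prod(m$spacing)

#' Grid geometry of a volume or mask
#' @param v an `ImageVolume` or `BinaryMask`.
#' @return List with `dim`, `spacing`, `origin`.
#' @export
grid_of <- function(v) list(dim = dim(v$voxels), spacing = v$spacing, origin = v$origin)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) && all(abs(a$origin - b$origin) < tol)
}

#' Physical coordinates of all voxel centers along each axis
#' @param v volume or mask.
#' @return List of three numeric vectors (x, y, z voxel-center mm coordinates).
#' @export
grid_axes <- function(v) {
  d <- dim(v$voxels)
  lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$spacing[a])
}

#' Center of mass of a mask in physical mm
#' @param m a `BinaryMask`.
#' @return Length-3 numeric (mm).
#' @export
mask_centroid <- function(m) {
  if (sum(m$voxels) == 0) stop("empty structure")
  idx <- which(m$voxels == 1, arr.ind = TRUE) - 1
  unname(m$origin + colMeans(idx) * m$spacing)
}

#' Bundle named structure masks sharing one grid
#'
#' A `StructureSet` holds the delineated structures used by the pipeline:
#' prostate CTV, rectum, bladder and patient body, all rasterized on one
#' identical grid.
#'
#' @param ctv,rectum,bladder,body `BinaryMask` objects on the same grid.
#' @return An object of class `StructureSet` (a named list of masks).
#' @export
structure_set <- function(ctv, rectum, bladder, body) {
  s <- list(ctv = ctv, rectum = rectum, bladder = bladder, body = body)
  ref <- s[[1]]
  for (nm in names(s)) {
    if (!inherits(s[[nm]], "BinaryMask")) stop("structure '", nm, "' is not a BinaryMask")
    if (!same_grid(ref, s[[nm]])) stop("structure '", nm, "' is not on the shared grid")
  }
  structure(s, class = "StructureSet")
}

#' @export
print.StructureSet <- function(x, ...) {
  cat("StructureSet:", paste(names(x), collapse = ", "), "on grid",
      paste(dim(x[[1]]$voxels), collapse = "x"), "\n")
  invisible(x)
}

#' Resample a volume or mask onto a target grid through a rigid transform
#'
#' For every target voxel center `x`, the source is sampled at `t(x)` — i.e.
#' the transform maps target physical points into source physical space
#' (pull-back resampling). Images use linear interpolation; masks use
#' nearest-neighbor so the value set \{0,1\} is preserved. Points mapping
#' outside the source support take the `fill` value, which defaults to the
#' modality air value (CT -1000 HU, CBCT -500 au) for images and 0 for masks.
#'
#' @param v `ImageVolume` or `BinaryMask` to resample.
#' @param t a [rigid_transform()] mapping target physical points to source
#'   physical points (use [identity_transform()] for plain grid resampling).
#' @param target_grid grid geometry as returned by [grid_of()] (or any volume,
#'   whose grid is then used).
#' @param interp `"linear"` or `"nearest"`; default linear for images,
#'   nearest for masks.
#' @param fill scalar used outside the source support.
#' @return Object of the same class as `v`, on the target grid.
#' @export
resample <- function(v, t = identity_transform(), target_grid = grid_of(v),
                     interp = NULL, fill = NULL) {
  if (!is.null(target_grid$voxels)) target_grid <- grid_of(target_grid)
  is_mask <- inherits(v, "BinaryMask")
  if (is.null(interp)) interp <- if (is_mask) "nearest" else "linear"
  interp <- match.arg(interp, c("linear", "nearest"))
  if (is.null(fill)) {
    fill <- if (is_mask) 0 else if (v$modality == "CT") -1000 else -500
  }
  if (any(!is.finite(unlist(t[c("rotations", "translations", "center")]))))
    stop("non-finite transform parameters")
  out <- cpp_resample(v$voxels, as.integer(dim(v$voxels)), v$spacing, v$origin,
                      as.integer(target_grid$dim), target_grid$spacing,
                      target_grid$origin, as.numeric(rotation_matrix(t)),
                      t$translations, t$center,
                      if (interp == "linear") 0L else 1L, fill)
  if (is_mask) binary_mask(out, target_grid$spacing, target_grid$origin)
  else image_volume(out, target_grid$spacing, target_grid$origin, v$modality)
}

#' Extract surface voxel centers of a mask
#'
#' A mask voxel is a surface voxel when at least one of its six face
#' neighbors is background (voxels beyond the volume boundary count as
#' background). Points are returned in deterministic lexicographic (i, j, k)
#' index order. These point sets feed the bidirectional local distance.
#'
#' @param m nonempty `BinaryMask`.
#' @return n x 3 numeric matrix of physical mm coordinates.
#' @export
surface_points <- function(m) {
  if (sum(m$voxels) == 0) stop("empty structure")
  idx <- cpp_surface_indices(m$voxels, as.integer(dim(m$voxels)))
  sweep(sweep(idx, 2, m$spacing, "*"), 2, m$origin, "+")
}
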