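# Pre-processing pipeline: isocenter offset, body masking, bone thresholding,
# replace-gas-by-tissue filtering and CTV margin expansion.

#' Threshold configuration for pre-processing
#'
#' Bone extraction thresholds are 150 HU (CT) and -140 au (CBCT); the
#' replace-gas-by-tissue filter clamps below -150 HU (CT) and -500 au (CBCT).
#' Body thresholds separate patient tissue from surrounding air and the
#' treatment table; they are implementation defaults chosen between the
#' tissue and air intensity ranges, and configurable.
#'
#' @param bone_ct,bone_cbct bone extraction thresholds (HU / au).
#' @param gas_ct,gas_cbct gas clamp levels (HU / au).
#' @param body_ct,body_cbct body-mask thresholds (HU / au).
#' @return An object of class `ThresholdConfig`.
#' @export
threshold_config <- function(bone_ct = 150, bone_cbct = -140,
                             gas_ct = -150, gas_cbct = -500,
                             body_ct = -300, body_cbct = -400) {
  if (gas_ct >= bone_ct || gas_cbct >= bone_cbct)
    stop("gas threshold must lie below the bone threshold for each modality")
  structure(list(bone_ct = bone_ct, bone_cbct = bone_cbct, gas_ct = gas_ct,
                 gas_cbct = gas_cbct, body_ct = body_ct, body_cbct = body_cbct),
            class = "ThresholdConfig")
}

modality_threshold <- function(v, cfg, which) {
  key <- paste0(which, "_", tolower(v$modality))
  cfg[[key]]
}

#' Offset the planning CT so its isocenter matches the treatment isocenter
#'
#' Shifts the origin of the CT and all its structures by
#' `linac_isocenter - ct_isocenter`, so the physical point that was the plan
#' isocenter now sits at the machine isocenter (conventionally `(0,0,0)`).
#' Voxel values are untouched.
#'
#' @param ct planning `ImageVolume`.
#' @param ct_structs `StructureSet` on the CT grid.
#' @param ct_isocenter plan isocenter, mm, in CT physical coordinates.
#' @param linac_isocenter machine isocenter, mm (default origin).
#' @return List with offset `ct` and `ct_structs`.
#' @export
apply_isocenter_offset <- function(ct, ct_structs, ct_isocenter,
                                   linac_isocenter = c(0, 0, 0)) {
  if (any(!is.finite(c(ct_isocenter, linac_isocenter)))) stop("non-finite isocenter")
  shift <- linac_isocenter - ct_isocenter
  ct$origin <- ct$origin + shift
  structs <- lapply(ct_structs, function(m) { m$origin <- m$origin + shift; m })
  class(structs) <- class(ct_structs)
  list(ct = ct, ct_structs = structs)
}

#' Compute a patient body mask
#'
#' Thresholds at the modality body level, keeps the largest 6-connected
#' component (dropping the treatment table and artifacts), applies a
#' morphological closing with a 3-voxel-radius ball (physical radius
#' `3 * min(spacing)` mm) and fills enclosed holes slice-by-slice.
#'
#' @param v `ImageVolume`.
#' @param cfg [threshold_config()].
#' @return `BinaryMask` of the body, a single connected component.
#' @export
compute_body_mask <- function(v, cfg = threshold_config()) {
  thr <- modality_threshold(v, cfg, "body")
  raw <- array(as.numeric(v$voxels > thr), dim = dim(v$voxels))
  if (sum(raw) == 0) stop("no body found: no voxel above body threshold ", thr)
  dm <- as.integer(dim(raw))
  m <- cpp_largest_component(raw, dm)
  r <- 3 * min(v$spacing)
  # closing: dilate by r then erode by r, both via the exact physical EDT
  d2 <- cpp_sqedt(m, dm, v$spacing)
  dil <- array(as.numeric(d2 <= r^2), dim = dm)
  e2 <- cpp_sqedt(array(as.numeric(dil == 0), dim = dm), dm, v$spacing)
  closed <- array(as.numeric(e2 > r^2), dim = dm)
  filled <- cpp_fill_holes_slicewise(closed, dm)
  # closing/filling cannot disconnect, but guard against degenerate inputs
  binary_mask(cpp_largest_component(filled, dm), v$spacing, v$origin)
}

#' Clamp a volume from below at the modality bone threshold
#'
#' Everything below the bone threshold (150 HU on CT, -140 au on CBCT) is set
#' to the threshold, flattening soft tissue, gas and air to a constant so the
#' bone edges are the only remaining image gradient. The images registered in
#' the bony strategy are produced this way.
#'
#' @param v `ImageVolume`.
#' @param cfg [threshold_config()].
#' @return `ImageVolume` with `min(voxels) >= threshold`.
#' @export
threshold_bone <- function(v, cfg = threshold_config()) {
  thr <- modality_threshold(v, cfg, "bone")
  v$voxels[v$voxels < thr] <- thr
  v
}

#' Replace gas by a tissue-equivalent gray value
#'
#' Clamps all values below the modality gas threshold (-150 HU on CT, -500 au
#' on CBCT) to that threshold, removing the gas/tissue contrast inside the
#' rectum that can mislead the global and local soft-tissue registrations.
#' Bony registration inputs are never filtered (the bone clamp already
#' removes gas contrast).
#'
#' @param v `ImageVolume`.
#' @param cfg [threshold_config()].
#' @return Filtered `ImageVolume`.
#' @export
replace_gas <- function(v, cfg = threshold_config()) {
  thr <- modality_threshold(v, cfg, "gas")
  v$voxels[v$voxels < thr] <- thr
  v
}

#' Expand a mask by a physical margin
#'
#' An output voxel is foreground iff its center lies within Euclidean
#' distance `margin_mm` (physical mm, anisotropy-aware) of some input
#' foreground voxel center. Computed with an exact squared Euclidean distance
#' transform, not voxel-count dilation, because CTV margins are specified in
#' mm on anisotropic grids.
#'
#' @param m `BinaryMask`.
#' @param margin_mm non-negative scalar margin, mm.
#' @return Expanded `BinaryMask` (superset of the input).
#' @export
expand_margin <- function(m, margin_mm) {
  if (length(margin_mm) != 1 || !is.finite(margin_mm) || margin_mm < 0)
    stop("margin must be a non-negative scalar (mm)")
  if (margin_mm == 0) return(m)
  d2 <- cpp_sqedt(m$voxels, as.integer(dim(m$voxels)), m$spacing)
  binary_mask(array(as.numeric(d2 <= margin_mm^2), dim = dim(m$voxels)),
              m$spacing, m$origin)
}
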