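# Constructive-solid pelvis phantom: paired planning-CT / treatment-CBCT
# volumes with ground-truth structures, setup error, independent prostate
# displacement, rectal distension/gas and a linear CBCT intensity model.
#
# Anatomy coordinate convention: x lateral, y anterior->posterior (posterior
# positive, so the rectum sits at y > prostate), z inferior->superior. The
# anatomy is described in planning (CT) space; the setup transform maps
# anatomy points CT -> CBCT.

#' Phantom specification
#'
#' Defaults emulate the acquisition geometry of a typical prostate IGRT
#' protocol: a planning CT at 1 x 1 mm in-plane and 3 mm slice thickness, a
#' treatment CBCT at 1 mm isotropic with 168 slices, and a linear,
#' uncalibrated CBCT intensity map `a * HU + b` plus Gaussian noise. Bone
#' (700 HU) sits far above the 150 HU bone threshold and gas (-1000 HU) far
#' below the -150 HU gas threshold, so the pre-processing thresholds segment
#' them by construction. Rectal distension scales the CBCT rectum radius;
#' `gas_fraction` fills that fraction of the CBCT rectal lumen cross-section
#' with gas in the peri-prostatic region. The prostate can be displaced
#' independently of the bones, carrying the abutting rectal wall with it.
#'
#' @param grid_ct,grid_cbct lists `list(dim, spacing)`; origins are centered
#'   so the grid midpoint is (0,0,0) mm.
#' @param body_semi_axes mm semi-axes of the body ellipsoid.
#' @param iliac_center,iliac_semi_axes right iliac wing ellipsoid (mirrored in
#'   x for the left).
#' @param sacrum_center,sacrum_half sacrum block center and half-widths, mm.
#' @param prostate_center,prostate_semi_axes prostate (CTV) ellipsoid, mm.
#' @param bladder_center,bladder_semi_axes bladder ellipsoid, mm.
#' @param rectum_center_xy,rectum_radius,rectum_zrange posterior rectal tube.
#' @param distension_factor >= 1; scales the CBCT rectum radius.
#' @param gas_fraction,gas_fraction_ct fraction of the rectal lumen
#'   cross-section filled with gas in the peri-prostatic window, per scan.
#' @param gas_window_mm half-length (mm) of the peri-prostatic z-window where
#'   gas and prostate-linked wall motion apply.
#' @param setup_transform [rigid_transform()] applied to the whole anatomy,
#'   CT -> CBCT.
#' @param prostate_offset additional mm translation of the prostate (and the
#'   abutting rectal wall) relative to the bones.
#' @param ct_isocenter plan isocenter, mm (CT physical coordinates).
#' @param intensities named HU values for tissue, prostate, bladder, bone,
#'   gas and exterior air.
#' @param cbct_gain,cbct_offset linear CBCT intensity model (au = gain * HU +
#'   offset).
#' @param noise_sigma CBCT Gaussian noise SD, au.
#' @param streaks add straight +/-150 au streak lines through gas pockets.
#' @param blur_sigma_voxel optional rasterization pre-blur (voxel units).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(grid_ct = list(dim = c(160, 160, 60), spacing = c(1, 1, 3)),
                         grid_cbct = list(dim = c(160, 160, 168), spacing = c(1, 1, 1)),
                         body_semi_axes = c(72, 58, 180),
                         iliac_center = c(55, 5, 10), iliac_semi_axes = c(14, 25, 45),
                         sacrum_center = c(0, 50, 0), sacrum_half = c(18, 5, 25),
                         prostate_center = c(0, 0, 0), prostate_semi_axes = c(20, 17, 18),
                         bladder_center = c(0, -32, 32), bladder_semi_axes = c(22, 18, 22),
                         rectum_center_xy = c(0, 31), rectum_radius = 13,
                         rectum_zrange = c(-50, 50),
                         distension_factor = 1, gas_fraction = 0, gas_fraction_ct = 0,
                         gas_window_mm = 30,
                         setup_transform = identity_transform(),
                         prostate_offset = c(0, 0, 0),
                         ct_isocenter = c(0, 0, 0),
                         intensities = c(tissue = 30, prostate = 40, bladder = 10,
                                         bone = 700, gas = -1000, air = -1000),
                         cbct_gain = 0.9, cbct_offset = -20,
                         noise_sigma = 10, streaks = FALSE,
                         blur_sigma_voxel = 0, seed = 1L) {
  if (distension_factor < 1) stop("distension_factor must be >= 1")
  if (gas_fraction < 0 || gas_fraction > 1 || gas_fraction_ct < 0 || gas_fraction_ct > 1)
    stop("gas fractions must lie in [0, 1]")
  if (intensities[["bone"]] < 500) stop("bone intensity must be >= 500 HU")
  if (intensities[["gas"]] > -1000) stop("gas intensity must be <= -1000 HU")
  spec <- as.list(environment())
  structure(spec, class = "PhantomSpec")
}

centered_grid <- function(g) {
  list(dim = as.integer(g$dim), spacing = as.numeric(g$spacing),
       origin = -(as.numeric(g$dim) - 1) * as.numeric(g$spacing) / 2)
}

# Broadcast physical voxel-center coordinates of a grid into three 3D arrays.
grid_coords <- function(grid) {
  d <- grid$dim
  x <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  list(x = array(rep(x, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
       z = array(rep(z, each = d[1] * d[2]), dim = d))
}

in_ellipsoid <- function(px, py, pz, center, semi) {
  ((px - center[1]) / semi[1])^2 + ((py - center[2]) / semi[2])^2 +
    ((pz - center[3]) / semi[3])^2 <= 1
}

# Rasterize the anatomy at the given anatomy-space coordinates. `rectum_radius`
# and gas fraction are per-scan; `prostate_shift` applies to the prostate and,
# tapered, to the rectal tube axis in the peri-prostatic window.
raster_anatomy <- function(p, pp, spec, rectum_radius, gas_fraction) {
  px <- p$x; py <- p$y; pz <- p$z
  shapes <- list()
  shapes$body <- in_ellipsoid(px, py, pz, c(0, 0, 0), spec$body_semi_axes)
  ic <- spec$iliac_center
  bone <- in_ellipsoid(px, py, pz, ic, spec$iliac_semi_axes) |
    in_ellipsoid(px, py, pz, ic * c(-1, 1, 1), spec$iliac_semi_axes) |
    (abs(px - spec$sacrum_center[1]) <= spec$sacrum_half[1] &
     abs(py - spec$sacrum_center[2]) <= spec$sacrum_half[2] &
     abs(pz - spec$sacrum_center[3]) <= spec$sacrum_half[3])
  shapes$bone <- bone
  shapes$prostate <- in_ellipsoid(pp$x, pp$y, pp$z, spec$prostate_center,
                                  spec$prostate_semi_axes)
  shapes$bladder <- in_ellipsoid(px, py, pz, spec$bladder_center, spec$bladder_semi_axes)
  # rectal tube; its axis follows the prostate offset inside the peri-prostatic
  # window (linear 10-mm taper) so the abutting anterior wall moves with the gland
  taper <- 10
  w <- pmin(1, pmax(0, (spec$gas_window_mm + taper - abs(pz - spec$prostate_center[3])) / taper))
  dx <- (px - pp$x) ; dy <- (py - pp$y)
  rcx <- spec$rectum_center_xy[1] + dx * w
  rcy <- spec$rectum_center_xy[2] + dy * w
  in_z <- pz >= spec$rectum_zrange[1] & pz <= spec$rectum_zrange[2]
  r2 <- (px - rcx)^2 + (py - rcy)^2
  shapes$rectum_region <- in_z & (r2 <= rectum_radius^2)
  lum_r <- rectum_radius * sqrt(gas_fraction)
  shapes$gas <- shapes$rectum_region & (r2 <= lum_r^2) &
    (abs(pz - spec$prostate_center[3]) <= spec$gas_window_mm)
  shapes
}

compose_intensity <- function(shapes, spec) {
  ints <- spec$intensities
  vol <- array(ints[["air"]], dim = dim(shapes$body))
  vol[shapes$body] <- ints[["tissue"]]
  vol[shapes$gas] <- ints[["gas"]]
  vol[shapes$bladder] <- ints[["bladder"]]
  vol[shapes$prostate] <- ints[["prostate"]]
  vol[shapes$bone] <- ints[["bone"]]
  vol
}

# Truth structure masks with the priority bone > prostate > bladder > rectum.
shapes_to_structs <- function(shapes, grid) {
  d <- dim(shapes$body)
  msk <- function(v) binary_mask(array(as.numeric(v), dim = d), grid$spacing, grid$origin)
  occupied <- shapes$bone | shapes$prostate
  bladder <- shapes$bladder & !occupied
  occupied <- occupied | shapes$bladder
  rectum <- shapes$rectum_region & !occupied
  body <- shapes$body | shapes$bone | shapes$rectum_region | shapes$bladder | shapes$prostate
  structure_set(ctv = msk(shapes$prostate), rectum = msk(rectum),
                bladder = msk(bladder), body = msk(body))
}

#' Generate a paired CT/CBCT phantom with ground truth
#'
#' The CT is rasterized in planning pose. The CBCT voxel at physical point
#' `x` shows the anatomy at `T_setup^-1(x)` (the prostate additionally
#' shifted by `prostate_offset`), mapped through the linear intensity model
#' `a * HU + b` with additive Gaussian noise. Truth structure masks on the
#' CBCT grid are rasterized analytically from the transformed geometry, not
#' resampled from the CT masks.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `PhantomPair`: `ct`, `ct_structs`, `cbct`,
#'   `cbct_structs_truth`, `cbct_gas_truth`, `truth_setup` (anatomy map
#'   CT -> CBCT; its inverse is what registration recovers), `truth_prostate`
#'   (setup composed with the prostate offset) and the `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  gct <- centered_grid(spec$grid_ct)
  gcb <- centered_grid(spec$grid_cbct)

  # --- CT side: anatomy in planning pose -------------------------------------
  p_ct <- grid_coords(gct)
  shp_ct <- raster_anatomy(p_ct, p_ct, spec, spec$rectum_radius, spec$gas_fraction_ct)
  check_phantom_geometry(shp_ct, spec)
  ct_vol <- compose_intensity(shp_ct, spec)
  if (spec$blur_sigma_voxel > 0)
    ct_vol <- cpp_gauss3(ct_vol, gct$dim, rep(spec$blur_sigma_voxel, 3))
  ct <- image_volume(ct_vol, gct$spacing, gct$origin, "CT")
  ct_structs <- shapes_to_structs(shp_ct, gct)

  # --- CBCT side: anatomy pulled back through the setup transform ------------
  x_cb <- grid_coords(gcb)
  inv <- invert_transform(spec$setup_transform)
  p_cb <- apply_transform_arrays(inv, x_cb)
  pp_cb <- apply_transform_arrays(inv, list(x = x_cb$x - spec$prostate_offset[1],
                                            y = x_cb$y - spec$prostate_offset[2],
                                            z = x_cb$z - spec$prostate_offset[3]))
  shp_cb <- raster_anatomy(p_cb, pp_cb, spec,
                           spec$rectum_radius * spec$distension_factor, spec$gas_fraction)
  hu_cb <- compose_intensity(shp_cb, spec)
  if (spec$blur_sigma_voxel > 0)
    hu_cb <- cpp_gauss3(hu_cb, gcb$dim, rep(spec$blur_sigma_voxel, 3))
  cb_vol <- spec$cbct_gain * hu_cb + spec$cbct_offset
  if (spec$streaks && any(shp_cb$gas))
    cb_vol <- add_streaks(cb_vol, shp_cb$gas, gcb)
  if (spec$noise_sigma > 0)
    cb_vol <- cb_vol + array(rnorm(prod(gcb$dim), 0, spec$noise_sigma), dim = gcb$dim)
  cbct <- image_volume(cb_vol, gcb$spacing, gcb$origin, "CBCT")
  cbct_structs <- shapes_to_structs(shp_cb, gcb)

  truth_prostate <- spec$setup_transform
  truth_prostate$translations <- truth_prostate$translations + spec$prostate_offset
  structure(list(ct = ct, ct_structs = ct_structs, cbct = cbct,
                 cbct_structs_truth = cbct_structs,
                 cbct_gas_truth = binary_mask(array(as.numeric(shp_cb$gas), dim = gcb$dim),
                                              gcb$spacing, gcb$origin),
                 truth_setup = spec$setup_transform,
                 truth_prostate = truth_prostate,
                 spec = spec),
            class = "PhantomPair")
}

apply_transform_arrays <- function(t, p) {
  R <- rotation_matrix(t)
  cx <- t$center[1]; cy <- t$center[2]; cz <- t$center[3]
  ox <- cx + t$translations[1]; oy <- cy + t$translations[2]; oz <- cz + t$translations[3]
  dx <- p$x - cx; dy <- p$y - cy; dz <- p$z - cz
  list(x = R[1, 1] * dx + R[1, 2] * dy + R[1, 3] * dz + ox,
       y = R[2, 1] * dx + R[2, 2] * dy + R[2, 3] * dz + oy,
       z = R[3, 1] * dx + R[3, 2] * dy + R[3, 3] * dz + oz)
}

check_phantom_geometry <- function(shp, spec) {
  organs <- list(prostate = shp$prostate, bladder = shp$bladder,
                 rectum = shp$rectum_region)
  nms <- names(organs)
  for (i in seq_along(organs))
    for (j in seq_len(i - 1))
      if (any(organs[[i]] & organs[[j]]))
        stop("overlapping organ specification: ", nms[j], " and ", nms[i])
  for (nm in nms)
    if (any(organs[[nm]] & !shp$body))
      stop("organ extends outside the body: ", nm)
}

# Straight +/-150 au streak lines through each gas pocket center, in-plane,
# at fixed azimuths; a crude stand-in for the reconstruction artifacts moving
# gas pockets cause.
add_streaks <- function(vol, gas, grid) {
  d <- dim(vol)
  ks <- which(apply(gas, 3, any))
  angles <- seq(0, pi, length.out = 9)[-9]
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  for (k in ks) {
    sl <- gas[, , k]
    idx <- which(sl, arr.ind = TRUE)
    cxy <- c(mean(xs[idx[, 1]]), mean(ys[idx[, 2]]))
    X <- outer(xs - cxy[1], rep(1, d[2]))
    Y <- outer(rep(1, d[1]), ys - cxy[2])
    for (a in seq_along(angles)) {
      # perpendicular distance to the line through cxy at this azimuth
      dist <- abs(X * sin(angles[a]) - Y * cos(angles[a]))
      hit <- dist <= 0.75
      vol[, , k][hit] <- vol[, , k][hit] + if (a %% 2 == 0) 150 else -150
    }
  }
  vol
}

#' Generate a cohort of phantom pairs spanning a distension grid
#'
#' Pairs cycle through the requested `(distension_factor, gas_fraction)`
#' grid with randomized setup errors (uniform within `setup_trans_mm` and
#' `setup_rot_deg`) and prostate offsets (uniform direction, magnitude up to
#' `prostate_offset_mm`). Child seeds are derived deterministically from
#' `seed`, so the cohort is reproducible pair by pair.
#'
#' @param n_pairs number of CT/CBCT pairs (>= 1).
#' @param distension_grid list of `c(distension_factor, gas_fraction)` pairs
#'   (or a 2-column matrix), recycled over the cohort; an optional third
#'   element per entry sets the planning-scan `gas_fraction_ct`.
#' @param seed cohort seed.
#' @param base_spec template [phantom_spec()] supplying everything else.
#' @param setup_trans_mm,setup_rot_deg,prostate_offset_mm randomization ranges.
#' @param prostate_offset_dir optional fixed unit direction for the prostate
#'   offset (e.g. anterior `c(0,-1,0)` for distension-driven push); default
#'   random directions.
#' @return List of `PhantomPair` objects.
#' @export
make_cohort <- function(n_pairs, distension_grid, seed = 1L,
                        base_spec = phantom_spec(),
                        setup_trans_mm = 8, setup_rot_deg = 3,
                        prostate_offset_mm = 6, prostate_offset_dir = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (is.matrix(distension_grid))
    distension_grid <- lapply(seq_len(nrow(distension_grid)), function(i) distension_grid[i, ])
  if (length(distension_grid) == 0) stop("empty distension grid")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    g <- distension_grid[[(i - 1) %% length(distension_grid) + 1]]
    tr <- runif(3, -setup_trans_mm, setup_trans_mm)
    ro <- runif(3, -setup_rot_deg, setup_rot_deg) * pi / 180
    dir <- if (is.null(prostate_offset_dir)) runif(3, -1, 1) else as.numeric(prostate_offset_dir)
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nrm
    off <- dir * runif(1, 0, prostate_offset_mm)
    sp <- base_spec
    sp$distension_factor <- g[[1]]
    sp$gas_fraction <- g[[2]]
    if (length(g) >= 3) sp$gas_fraction_ct <- g[[3]]
    sp$setup_transform <- rigid_transform(ro, tr)
    sp$prostate_offset <- off
    sp$seed <- (seed * 1009L + i * 9973L) %% 2147483647L
    pairs[[i]] <- generate_pair(sp)
  }
  pairs
}

#' Write a phantom pair to disk
#'
#' Writes `ct.mha`, `cbct.mha`, per-structure masks, plain-text truth
#' transforms and a JSON manifest into `dir`.
#'
#' @param pair a `PhantomPair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$ct, file.path(dir, "ct.mha"))
  write_volume(pair$cbct, file.path(dir, "cbct.mha"))
  for (nm in names(pair$ct_structs))
    write_volume(pair$ct_structs[[nm]], file.path(dir, paste0("ct_", nm, ".mha")))
  for (nm in names(pair$cbct_structs_truth))
    write_volume(pair$cbct_structs_truth[[nm]], file.path(dir, paste0("cbct_", nm, ".mha")))
  write_transform(pair$truth_setup, file.path(dir, "truth_setup.txt"))
  write_transform(pair$truth_prostate, file.path(dir, "truth_prostate.txt"))
  manifest <- list(seed = pair$spec$seed,
                   distension_factor = pair$spec$distension_factor,
                   gas_fraction = pair$spec$gas_fraction,
                   prostate_offset = pair$spec$prostate_offset,
                   files = list.files(dir))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
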