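# Rigid registration engine: masked mean-subtracted normalized
# cross-correlation, relaxed gradient descent in scaled parameter space, and
# a three-level multi-resolution pyramid; plus the global / bony / local
# strategies and contour propagation.
#
# Convention: fixed = CBCT, moving = CT. The recovered transform maps CBCT
# physical points into CT space, so planning contours are propagated onto the
# CBCT grid by pull-back resampling through the same transform.

#' Registration configuration
#'
#' The optimizer follows the metric derivative with a learning factor that
#' starts at `step_size` and is multiplied by `relaxation` every time the
#' gradient changes direction; it stops when the factor drops below
#' `min_step`, the scaled-gradient norm falls below `grad_tol`, or `max_iter`
#' iterations are reached. Parameters live in a scaled space where 1 radian
#' of rotation is commensurate with `rotation_scale_mm` of translation; the
#' gradient is estimated by central finite differences with perturbation
#' `fd_step` in scaled units.
#'
#' @param step_size initial learning factor (scaled units, mm-equivalent).
#' @param relaxation multiplicative decay on gradient direction reversal.
#' @param min_step stop tolerance on the learning factor.
#' @param grad_tol stop tolerance on the scaled-gradient magnitude.
#' @param max_iter iteration cap per resolution level.
#' @param levels number of pyramid levels.
#' @param shrink integer shrink factor per level (coarse to fine).
#' @param smooth_mm Gaussian smoothing sigma (mm) per level.
#' @param rotation_scale_mm translation equivalent of 1 rad.
#' @param fd_step finite-difference perturbation (scaled units).
#' @param min_samples minimum voxels in the metric sample set.
#' @return An object of class `RegConfig`.
#' @export
reg_config <- function(step_size = 0.5, relaxation = 0.7, min_step = 0.1,
                       grad_tol = 1e-5, max_iter = 500, levels = 3,
                       shrink = c(4, 2, 1), smooth_mm = c(4, 2, 0),
                       rotation_scale_mm = 50, gradient = c("analytic", "fd"),
                       fd_step = 0.25, min_samples = 100) {
  gradient <- match.arg(gradient)
  if (relaxation <= 0 || relaxation >= 1) stop("relaxation must be in (0, 1)")
  if (min_step >= step_size) stop("min_step must be smaller than step_size")
  if (levels < 1) stop("levels must be >= 1")
  if (length(shrink) != levels || length(smooth_mm) != levels)
    stop("shrink and smooth_mm must have one entry per level")
  structure(list(step_size = step_size, relaxation = relaxation, min_step = min_step,
                 grad_tol = grad_tol, max_iter = max_iter, levels = levels,
                 shrink = shrink, smooth_mm = smooth_mm,
                 rotation_scale_mm = rotation_scale_mm, gradient = gradient,
                 fd_step = fd_step, min_samples = min_samples),
            class = "RegConfig")
}

full_mask <- function(v) binary_mask(array(1, dim = dim(v$voxels)), v$spacing, v$origin)

#' Masked normalized cross-correlation between two volumes
#'
#' Mean-subtracted NCC over fixed-grid voxels where the fixed mask is 1, the
#' point mapped through `t` lies inside the moving support and the
#' (nearest-sampled) moving mask is 1; moving intensities are linearly
#' interpolated. Invariant to positive linear intensity maps of either
#' image, which is what makes it suitable for uncalibrated CBCT.
#'
#' @param fixed,moving `ImageVolume`s.
#' @param t `RigidTransform` mapping fixed physical points to moving space.
#' @param fixed_mask,moving_mask `BinaryMask`s on the respective grids
#'   (defaults: full volumes).
#' @param min_samples minimum size of the sample set.
#' @return Scalar in [-1, 1].
#' @export
ncc <- function(fixed, moving, t = identity_transform(),
                fixed_mask = NULL, moving_mask = NULL, min_samples = 100) {
  if (is.null(fixed_mask)) fixed_mask <- full_mask(fixed)
  mm <- if (is.null(moving_mask)) 1 else moving_mask$voxels
  s <- cpp_ncc_sums(fixed$voxels, fixed_mask$voxels, as.integer(dim(fixed$voxels)),
                    fixed$spacing, fixed$origin, moving$voxels, mm,
                    as.integer(dim(moving$voxels)), moving$spacing, moving$origin,
                    as.numeric(rotation_matrix(t)), t$translations, t$center)
  n <- s[1]
  if (n < min_samples) stop("insufficient mask overlap (", n, " samples)")
  vf <- s[4] - s[2]^2 / n
  vm <- s[5] - s[3]^2 / n
  if (vf <= 0 || vm <= 0) stop("degenerate intensities (zero variance in the sample set)")
  (s[6] - s[2] * s[3] / n) / sqrt(vf * vm)
}

# Smooth (sigma in mm) then subsample a volume by an integer factor, keeping
# the first voxel so the origin is unchanged.
shrink_volume <- function(v, factor, sigma_mm, smooth = TRUE) {
  vox <- v$voxels
  if (smooth && sigma_mm > 0)
    vox <- cpp_gauss3(vox, as.integer(dim(vox)), sigma_mm / v$spacing)
  if (factor > 1) {
    d <- dim(vox)
    vox <- vox[seq(1, d[1], by = factor), seq(1, d[2], by = factor),
               seq(1, d[3], by = factor), drop = FALSE]
  }
  out <- v
  out$voxels <- vox
  out$spacing <- v$spacing * factor
  out
}

params_to_transform <- function(p, center, rot_scale) {
  rigid_transform(rotations = p[1:3] / rot_scale, translations = p[4:6], center = center)
}
transform_to_params <- function(t, rot_scale) c(t$rotations * rot_scale, t$translations)

# Derivatives of R = Rz Ry Rx in each Euler angle.
rotation_jacobians <- function(t) {
  r <- t$rotations
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3, 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3, 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3, 3)
  list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
}

# Metric value and its analytic gradient in scaled parameter space, via
# moving-image gradients and the transform Jacobian (chain rule), matching
# how the ITK-style registration frameworks differentiate NCC. The sample
# set is treated as fixed (its dependence on the transform is ignored).
ncc_with_gradient <- function(fixed, moving, t, fixed_mask, moving_mask,
                              rot_scale, min_samples = 100) {
  J <- rotation_jacobians(t)
  s <- cpp_ncc_grad_sums(fixed$voxels, fixed_mask$voxels, as.integer(dim(fixed$voxels)),
                         fixed$spacing, fixed$origin, moving$voxels,
                         moving_mask$voxels, as.integer(dim(moving$voxels)),
                         moving$spacing, moving$origin,
                         as.numeric(rotation_matrix(t)), t$translations, t$center,
                         as.numeric(J[[1]]), as.numeric(J[[2]]), as.numeric(J[[3]]))
  n <- s[1]
  if (n < min_samples) stop("insufficient mask overlap (", n, " samples)")
  A <- s[6] - s[2] * s[3] / n
  B <- s[4] - s[2]^2 / n
  C <- s[5] - s[3]^2 / n
  if (B <= 0 || C <= 0) stop("degenerate intensities (zero variance in the sample set)")
  fbar <- s[2] / n; mbar <- s[3] / n
  g1 <- s[7:12]; g2 <- s[13:18]; g3 <- s[19:24]
  dA <- g1 - fbar * g3           # sum (f - fbar) dm/dp
  dC <- g2 - mbar * g3           # sum (m - mbar) dm/dp
  grad <- (dA - (A / C) * dC) / sqrt(B * C)
  grad[1:3] <- grad[1:3] / rot_scale
  list(value = A / sqrt(B * C), gradient = grad)
}

#' Masked rigid registration by relaxed gradient descent over a pyramid
#'
#' Runs coarse-to-fine over `cfg$levels` resolution levels (images smoothed
#' and shrunk, masks subsampled without smoothing). At each level the
#' negative NCC is minimized by normalized gradient descent in scaled
#' parameter space; the learning factor shrinks by `cfg$relaxation` whenever
#' successive gradients point in opposing directions (negative dot product).
#' Each level seeds the next; the best-metric iterate of the final level is
#' returned, so the result can never be worse than its initialization. The
#' whole procedure is deterministic. A level whose mask intersection is
#' undersampled (fewer than `cfg$min_samples` voxels, which happens for
#' small CTV margins at coarse shrink factors) is skipped and the transform
#' falls through to the next finer level.
#'
#' @param fixed,moving `ImageVolume`s (fixed = CBCT, moving = CT in the
#'   strategy wrappers).
#' @param init initial `RigidTransform` (its center is kept as the
#'   optimization center).
#' @param cfg [reg_config()].
#' @param fixed_mask,moving_mask metric masks (default: full volumes).
#' @return An object of class `RegistrationResult`: `transform`,
#'   `final_metric`, `iterations` per level, `stop_reason`, `converged`.
#' @export
register_rigid <- function(fixed, moving, init = identity_transform(),
                           cfg = reg_config(), fixed_mask = NULL, moving_mask = NULL) {
  if (is.null(fixed_mask)) fixed_mask <- full_mask(fixed)
  if (is.null(moving_mask)) moving_mask <- full_mask(moving)
  center <- init$center
  rs <- cfg$rotation_scale_mm
  p <- transform_to_params(init, rs)
  iterations <- integer(cfg$levels)
  stop_reason <- "max_iterations"
  best_overall <- -Inf

  for (lev in seq_len(cfg$levels)) {
    f <- cfg$shrink[lev]
    fx <- shrink_volume(fixed, f, cfg$smooth_mm[lev])
    mv <- shrink_volume(moving, f, cfg$smooth_mm[lev])
    fm <- shrink_volume(fixed_mask, f, 0, smooth = FALSE)
    mm <- shrink_volume(moving_mask, f, 0, smooth = FALSE)
    metric_at <- function(pv) {
      t <- params_to_transform(pv, center, rs)
      ncc(fx, mv, t, fm, mm, min_samples = cfg$min_samples)
    }
    # value and gradient of -NCC at pv in scaled parameter space
    eval_at <- function(pv) {
      t <- params_to_transform(pv, center, rs)
      if (cfg$gradient == "analytic") {
        vg <- ncc_with_gradient(fx, mv, t, fm, mm, rs, cfg$min_samples)
        list(value = vg$value, gradient = -vg$gradient)
      } else {
        g <- numeric(6)
        for (k in 1:6) {
          e <- numeric(6); e[k] <- cfg$fd_step
          g[k] <- (-metric_at(pv + e) + metric_at(pv - e)) / (2 * cfg$fd_step)
        }
        list(value = metric_at(pv), gradient = g)
      }
    }
    cur <- tryCatch(eval_at(p), error = function(e) e)
    if (inherits(cur, "error")) {
      if (grepl("insufficient mask overlap", conditionMessage(cur)) && lev < cfg$levels) next
      stop(cur)
    }
    lambda <- cfg$step_size
    g_prev <- NULL
    best_p <- p
    best_m <- cur$value
    it <- 0
    stop_reason <- "max_iterations"
    while (it < cfg$max_iter) {
      it <- it + 1
      g <- cur$gradient
      if (any(!is.finite(g))) stop("non-finite metric gradient during optimization")
      gn <- sqrt(sum(g^2))
      if (gn < cfg$grad_tol) { stop_reason <- "gradient_tolerance"; break }
      if (!is.null(g_prev) && sum(g * g_prev) < 0) {
        lambda <- lambda * cfg$relaxation
        if (lambda < cfg$min_step) { stop_reason <- "step_tolerance"; break }
      }
      g_prev <- g
      p <- p - lambda * g / gn
      cur <- eval_at(p)
      if (cur$value > best_m) { best_m <- cur$value; best_p <- p }
    }
    iterations[lev] <- it
    p <- best_p
    best_overall <- best_m
  }
  structure(list(transform = params_to_transform(p, center, rs),
                 final_metric = best_overall,
                 iterations = iterations,
                 stop_reason = stop_reason,
                 converged = stop_reason != "max_iterations"),
            class = "RegistrationResult")
}

#' @export
print.RegistrationResult <- function(x, ...) {
  cat(sprintf("RegistrationResult: NCC %.5f, stop %s, iterations %s\n",
              x$final_metric, x$stop_reason, paste(x$iterations, collapse = "/")))
  print(x$transform)
  invisible(x)
}

#' Global rigid registration of CT to CBCT
#'
#' Registers the full gray-value images with the patient body masks,
#' optionally after replace-gas-by-tissue filtering of both inputs.
#'
#' @param ct moving planning CT (`ImageVolume`).
#' @param cbct fixed treatment CBCT (`ImageVolume`).
#' @param cfg [reg_config()].
#' @param filter_gas apply [replace_gas()] to both images first.
#' @param thresholds [threshold_config()].
#' @param ct_body,cbct_body optional precomputed body masks.
#' @param init initial transform (default identity centered on the CBCT
#'   volume center).
#' @return A `RegistrationResult` whose transform maps CBCT points into CT
#'   space.
#' @export
register_global <- function(ct, cbct, cfg = reg_config(), filter_gas = FALSE,
                            thresholds = threshold_config(),
                            ct_body = NULL, cbct_body = NULL, init = NULL) {
  if (is.null(ct_body)) ct_body <- compute_body_mask(ct, thresholds)
  if (is.null(cbct_body)) cbct_body <- compute_body_mask(cbct, thresholds)
  if (filter_gas) {
    ct <- replace_gas(ct, thresholds)
    cbct <- replace_gas(cbct, thresholds)
  }
  if (is.null(init)) init <- identity_transform(center = volume_center(cbct))
  register_rigid(cbct, ct, init, cfg, fixed_mask = cbct_body, moving_mask = ct_body)
}

#' Bony rigid registration on bone-thresholded images
#'
#' Clamps both images from below at the modality bone threshold so only the
#' pelvic bone edges drive the metric, then registers with the body masks.
#' Inputs are never gas-filtered: the clamp already removes all gas/tissue
#' contrast.
#'
#' @inheritParams register_global
#' @return A `RegistrationResult` (the setup-error estimate).
#' @export
register_bony <- function(ct, cbct, cfg = reg_config(),
                          thresholds = threshold_config(),
                          ct_body = NULL, cbct_body = NULL, init = NULL) {
  if (is.null(ct_body)) ct_body <- compute_body_mask(ct, thresholds)
  if (is.null(cbct_body)) cbct_body <- compute_body_mask(cbct, thresholds)
  ct_b <- threshold_bone(ct, thresholds)
  cbct_b <- threshold_bone(cbct, thresholds)
  if (is.null(init)) init <- identity_transform(center = volume_center(cbct))
  register_rigid(cbct_b, ct_b, init, cfg, fixed_mask = cbct_body, moving_mask = ct_body)
}

#' Local soft-tissue refinement around the expanded CTV
#'
#' Refines a bony registration with a soft-tissue registration restricted,
#' on the CT side, to the CTV expanded by `margin_mm` (replacing the CT body
#' mask); the CBCT side keeps its body mask. The optimizer is centered on
#' the CTV centroid and initialized at the bony transform.
#'
#' @inheritParams register_global
#' @param ctv_mask CT CTV `BinaryMask`.
#' @param margin_mm CTV expansion margin (mm), typically one of
#'   1, 3, 5, 8, 10, 12, 15, 20.
#' @param bony_result `RegistrationResult` from [register_bony()].
#' @return A `RegistrationResult`.
#' @export
register_local <- function(ct, cbct, ctv_mask, margin_mm, bony_result,
                           cfg = reg_config(), filter_gas = FALSE,
                           thresholds = threshold_config(), cbct_body = NULL) {
  if (is.null(cbct_body)) cbct_body <- compute_body_mask(cbct, thresholds)
  if (filter_gas) {
    ct <- replace_gas(ct, thresholds)
    cbct <- replace_gas(cbct, thresholds)
  }
  roi <- expand_margin(ctv_mask, margin_mm)
  ctr <- mask_centroid(ctv_mask)
  init <- recenter_transform(bony_result$transform, ctr)
  # Restrict the CBCT-side mask to the part of the body that can reach the CT
  # ROI: the metric only ever samples the mask intersection, so intersecting
  # with the pulled-back ROI dilated by 15 mm (far beyond the optimizer's
  # travel from the bony initialization) leaves the metric unchanged while
  # skipping most of the fixed-grid scan.
  reach <- propagate_contour(expand_margin(roi, 15), init, grid_of(cbct))
  fixed_mask <- binary_mask(cbct_body$voxels * reach$voxels,
                            cbct_body$spacing, cbct_body$origin)
  register_rigid(cbct, ct, init, cfg, fixed_mask = fixed_mask, moving_mask = roi)
}

#' Express a rigid transform about a different rotation center
#'
#' Returns a transform describing the same physical mapping with its
#' rotation center moved to `new_center` (the translation is adjusted
#' accordingly). Useful for comparing transforms recovered with different
#' optimization centers.
#'
#' @param t a `RigidTransform`.
#' @param new_center length-3 mm point.
#' @return An equivalent `RigidTransform` centered at `new_center`.
#' @export
recenter_transform <- function(t, new_center) {
  R <- rotation_matrix(t)
  t_new <- t$translations + as.numeric(R %*% (new_center - t$center)) - (new_center - t$center)
  rigid_transform(rotations = t$rotations, translations = t_new, center = new_center)
}

volume_center <- function(v) v$origin + (dim(v$voxels) - 1) * v$spacing / 2

#' Rigid registration of two binary contour masks
#'
#' Registers the masks themselves (Gaussian-smoothed by one voxel to create
#' gradients) with full-volume metric masks. Used on manual contours it
#' yields the per-pair upper bound on the Dice any intensity-based method
#' can reach.
#'
#' @param ct_mask moving CT contour (`BinaryMask`).
#' @param cbct_mask fixed CBCT contour (`BinaryMask`).
#' @param cfg [reg_config()].
#' @return A `RegistrationResult` mapping CBCT points into CT space.
#' @export
register_contours <- function(ct_mask, cbct_mask, cfg = reg_config()) {
  smooth1 <- function(m) {
    v <- cpp_gauss3(m$voxels, as.integer(dim(m$voxels)), c(1, 1, 1))
    image_volume(v, m$spacing, m$origin, "CT")
  }
  fx <- smooth1(cbct_mask)
  mv <- smooth1(ct_mask)
  init <- identity_transform(center = mask_centroid(cbct_mask))
  register_rigid(fx, mv, init, cfg)
}

#' Propagate a CT contour onto the CBCT grid
#'
#' Nearest-neighbor pull-back resampling of the planning contour through the
#' recovered transform: each CBCT voxel center is mapped into CT space and
#' takes the CT mask value there.
#'
#' @param ct_mask `BinaryMask` on the CT grid.
#' @param t `RigidTransform` mapping CBCT physical points into CT space
#'   (i.e. a registration result).
#' @param cbct_grid target grid (a volume or a [grid_of()] list).
#' @return `BinaryMask` on the CBCT grid.
#' @export
propagate_contour <- function(ct_mask, t, cbct_grid) {
  resample(ct_mask, t, cbct_grid, interp = "nearest", fill = 0)
}
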