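# Rectal-distension quantification: the F statistic computed from the CT
# manual contours and the gray-value CT and CBCT images after bony
# alignment, and failure prediction from an F cutoff. No manual CBCT
# contours are needed.

#' Peri-prostatic rectum portion R_partial
#'
#' Intersection of the margin-expanded CTV with the rectum contour, both on
#' the CT grid: the part of the rectum that falls inside the local
#' registration mask and whose filling can mislead the local registration.
#'
#' @param rectum_ct rectum `BinaryMask` (CT grid).
#' @param ctv_ct CTV `BinaryMask` (same grid).
#' @param margin_mm local registration margin (mm), default 8.
#' @return `BinaryMask`; empty (with a warning) when the expanded CTV misses
#'   the rectum, in which case F is undefined downstream.
#' @export
compute_rpartial <- function(rectum_ct, ctv_ct, margin_mm = 8) {
  if (!same_grid(rectum_ct, ctv_ct)) stop("masks must share the CT grid")
  roi <- expand_margin(ctv_ct, margin_mm)
  out <- binary_mask(roi$voxels * rectum_ct$voxels, roi$spacing, roi$origin)
  if (sum(out$voxels) == 0)
    warning("R_partial is empty: expanded CTV does not reach the rectum")
  out
}

#' Rectal-distension statistic F
#'
#' `F = |(I_CBCT,r - I_CBCT,p) - (I_CT,r - I_CT,p)|`, where the `r` means are
#' taken over R_partial and the `p` means over the prostate. CT means are
#' computed on the CT grid; CBCT means sample the CBCT (linear
#' interpolation) at the same masked CT-grid physical points mapped through
#' the bony alignment (pull-back, avoiding mask resampling bias). The
#' prostate-mean subtraction cancels any global CBCT intensity shift across
#' acquisitions; gas lowers the rectal mean on one side only, making F grow
#' with the change in peri-prostatic rectal filling. F is computed on
#' unfiltered images — replacing gas by tissue would erase the very signal
#' it measures.
#'
#' @param ct planning CT `ImageVolume`.
#' @param cbct treatment CBCT `ImageVolume`.
#' @param bony `RigidTransform` mapping CBCT physical points into CT space
#'   (a [register_bony()] result), or a `RegistrationResult`.
#' @param prostate_ct prostate (CTV) `BinaryMask` on the CT grid.
#' @param rpartial [compute_rpartial()] output.
#' @param cutoff failure-prediction cutoff forwarded to [predict_failure()].
#' @return An object of class `DistensionResult` with `F`, the four means,
#'   `n_voxels_rpartial`, `predicted_failure` and `cutoff`.
#' @export
compute_F <- function(ct, cbct, bony, prostate_ct, rpartial,
                      cutoff = (61.2 + 147.6) / 2) {
  if (inherits(bony, "RegistrationResult")) bony <- bony$transform
  if (sum(rpartial$voxels) == 0) stop("F undefined for this pair: empty R_partial")
  ct_to_cbct <- invert_transform(bony)
  mean_ct <- function(mask) mean(ct$voxels[mask$voxels == 1])
  mean_cbct <- function(mask) {
    idx <- which(mask$voxels == 1, arr.ind = TRUE) - 1
    pts <- sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
    mapped <- transform_points(ct_to_cbct, pts)
    sample_linear(cbct, mapped)
  }
  i_ct_r <- mean_ct(rpartial); i_ct_p <- mean_ct(prostate_ct)
  i_cb_r <- mean_cbct(rpartial); i_cb_p <- mean_cbct(prostate_ct)
  f <- abs((i_cb_r - i_cb_p) - (i_ct_r - i_ct_p))
  structure(list(F = f, mean_ct_rectum = i_ct_r, mean_ct_prostate = i_ct_p,
                 mean_cbct_rectum = i_cb_r, mean_cbct_prostate = i_cb_p,
                 n_voxels_rpartial = sum(rpartial$voxels),
                 predicted_failure = predict_failure(f, cutoff),
                 cutoff = cutoff),
            class = "DistensionResult")
}

# Mean of linear interpolation of a volume at physical points; points outside
# the support are dropped (they carry no intensity information).
sample_linear <- function(v, pts) {
  u <- sweep(sweep(pts, 2, v$origin), 2, v$spacing, "/")
  d <- dim(v$voxels)
  inside <- u[, 1] >= 0 & u[, 2] >= 0 & u[, 3] >= 0 &
    u[, 1] <= d[1] - 1 & u[, 2] <= d[2] - 1 & u[, 3] <= d[3] - 1
  u <- u[inside, , drop = FALSE]
  if (nrow(u) == 0) stop("all sample points fall outside the CBCT support")
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(d - 2, each = nrow(u)), ncol = 3))
  fr <- u - i0
  acc <- numeric(nrow(u))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
    acc <- acc + w * v$voxels[lin]
  }
  mean(acc)
}

#' @export
print.DistensionResult <- function(x, ...) {
  cat(sprintf("DistensionResult: F = %.1f (cutoff %.1f) -> %s; R_partial %d voxels\n",
              x$F, x$cutoff,
              if (x$predicted_failure) "failure predicted" else "no failure predicted",
              x$n_voxels_rpartial))
  invisible(x)
}

#' Predict local registration failure from F
#'
#' Failure is predicted when F strictly exceeds the cutoff. The default
#' cutoff 104.4 is the midpoint of F1 = 61.2 (below which registrations are
#' observed to always succeed) and F2 = 147.6 (above which all observed
#' failures lie).
#'
#' @param F distension statistic from [compute_F()].
#' @param cutoff decision threshold.
#' @return Logical flag.
#' @export
predict_failure <- function(F, cutoff = (61.2 + 147.6) / 2) {
  F > cutoff
}

#' Sensitivity and specificity of failure prediction
#'
#' Positive class = registration failure. Sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP); a component with an empty denominator is
#' reported as `NA` (absent), never as 0.
#'
#' @param predicted logical predicted-failure flags.
#' @param actual logical actual-failure flags (same length).
#' @return Named numeric `c(sensitivity=, specificity=)`.
#' @export
sensitivity_specificity <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("flag vectors must have equal length")
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  tp <- sum(predicted & actual); fn <- sum(!predicted & actual)
  tn <- sum(!predicted & !actual); fp <- sum(predicted & !actual)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Order pair evaluations by increasing F
#'
#' Reproduces the success/failure-versus-F presentation: pairs sorted
#' ascending by F (ties broken by pair id, deterministically) with their
#' outcome flags.
#'
#' @param evals data frame with columns `pair`, `F`, `failed` (and anything
#'   else to carry along).
#' @return The rows of `evals`, sorted.
#' @export
sort_pairs_by_F <- function(evals) {
  if (!all(c("pair", "F") %in% names(evals))) stop("need columns 'pair' and 'F'")
  evals[order(evals$F, evals$pair), , drop = FALSE]
}
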