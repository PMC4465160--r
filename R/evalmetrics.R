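# Quantitative validation: Dice overlap, bidirectional local distance (BLD)
# and its contour average (BD), the failure criterion, and per-method
# summaries.

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` by voxel counts on a shared grid: 1 for
#' identical nonempty masks, 0 for disjoint ones.
#'
#' @param a,b `BinaryMask`s on the same grid.
#' @return Scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!same_grid(a, b)) stop("Dice requires masks on the same grid")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("undefined Dice: both masks empty")
  2 * sum(a$voxels * b$voxels) / (na + nb)
}

#' Bidirectional local distance per reference point
#'
#' For each reference point `a`, the forward distance is the nearest distance
#' to the target set. Each target point is associated to its nearest
#' reference point (ties broken toward the lowest index); the BLD at `a` is
#' the maximum of the forward distance and the largest distance of target
#' points associated to `a` (absent when none is).
#'
#' @param ref_pts,tgt_pts nonempty n x 3 matrices of mm coordinates.
#' @return Numeric vector, one BLD (mm) per reference point.
#' @export
bld_per_point <- function(ref_pts, tgt_pts) {
  ref_pts <- as_points(ref_pts); tgt_pts <- as_points(tgt_pts)
  if (nrow(ref_pts) == 0 || nrow(tgt_pts) == 0) stop("empty point list")
  as.numeric(cpp_bld(ref_pts, tgt_pts))
}

as_points <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("points must be n x 3")
  storage.mode(p) <- "double"
  p
}

#' Bidirectional distance between two structures
#'
#' Mean of [bld_per_point()] over the surface points of the reference mask
#' against the surface points of the target mask. The reference is the
#' manual (ground-truth) contour; BD is generally asymmetric in its
#' arguments.
#'
#' @param ref_mask reference (manual) `BinaryMask`.
#' @param tgt_mask target (propagated) `BinaryMask`.
#' @return Mean BLD in mm.
#' @export
bd <- function(ref_mask, tgt_mask) {
  mean(bld_per_point(surface_points(ref_mask), surface_points(tgt_mask)))
}

#' Registration failure criterion
#'
#' A registration is unsuccessful when the Dice after registration is
#' strictly lower than 95% of the Dice without registration — below that,
#' registering has deteriorated the initial alignment. With `cap` set (e.g.
#' 0.95), the alternate reading "lower than 0.95 or 95% of the
#' no-registration Dice" is used: fail iff
#' `dice_after < min(cap, 0.95 * dice_noreg)`.
#'
#' @param dice_after Dice after registration and propagation.
#' @param dice_noreg Dice without registration (isocenter offset only).
#' @param cap optional absolute Dice cap for the alternate reading.
#' @return Logical failure flag.
#' @export
is_failure <- function(dice_after, dice_noreg, cap = NULL) {
  thr <- 0.95 * dice_noreg
  if (!is.null(cap)) thr <- pmin(cap, thr)
  dice_after < thr
}

#' Dice without registration
#'
#' Dice between the manual CBCT CTV and the planning CTV carried over
#' unchanged (identity resampling onto the CBCT grid after the isocenter
#' offset) — the baseline the failure criterion compares against.
#'
#' @param ct_ctv planning CTV `BinaryMask` (already isocenter-offset).
#' @param cbct_ctv_manual manual CTV `BinaryMask` on the CBCT grid.
#' @return Scalar Dice.
#' @export
dice_noreg <- function(ct_ctv, cbct_ctv_manual) {
  moved <- resample(ct_ctv, identity_transform(), grid_of(cbct_ctv_manual),
                    interp = "nearest", fill = 0)
  dice(moved, cbct_ctv_manual)
}

#' Per-method summary over a cohort
#'
#' Median and sample SD (n-1 denominator) of Dice and BD over the pairs,
#' plus the failure count under [is_failure()]. Mirrors the per-method
#' columns of a cohort results table.
#'
#' @param evals data frame with columns `method`, `dice_after`, `bd_mm`,
#'   `dice_noreg` (one row per pair and method), e.g. from [run_experiment()].
#' @param method method name to summarize.
#' @param cap optional failure cap, see [is_failure()].
#' @return One-row data frame of class `MethodSummary`.
#' @export
summarize_method <- function(evals, method, cap = NULL) {
  rows <- evals[evals$method == method & !is.na(evals$dice_after), , drop = FALSE]
  if (nrow(rows) == 0) stop("no evaluations for method ", method)
  if (nrow(rows) < 2) warning("SD undefined for a single pair; reported as 0")
  sdv <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- data.frame(method = method,
                    dice_median = median(rows$dice_after),
                    dice_sd = sdv(rows$dice_after),
                    bd_median_mm = median(rows$bd_mm),
                    bd_sd_mm = sdv(rows$bd_mm),
                    n_failed = sum(is_failure(rows$dice_after, rows$dice_noreg, cap)),
                    n_pairs = nrow(rows),
                    stringsAsFactors = FALSE)
  class(out) <- c("MethodSummary", class(out))
  out
}

#' Success rate as a percentage
#'
#' `100 * (1 - n_failed / n_pairs)`, rounded to the nearest integer the way
#' cohort success rates are conventionally reported.
#'
#' @param n_failed failure count.
#' @param n_pairs cohort size.
#' @param digits rounding digits (default 0).
#' @return Percentage.
#' @export
success_rate <- function(n_failed, n_pairs, digits = 0) {
  if (n_pairs < 1 || n_failed < 0 || n_failed > n_pairs) stop("invalid counts")
  round(100 * (1 - n_failed / n_pairs), digits)
}
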