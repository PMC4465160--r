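# Shared phantom fixtures. Tests run the generator at a reduced grid
# (2 x 2 x 3 mm CT / 2 mm isotropic CBCT over the same physical field of
# view) so the whole suite stays inside its time budget; the acceptance
# transform-recovery suite uses the full default resolution.
coarse_spec <- function(...) {
  args <- list(grid_ct = list(dim = c(80, 80, 40), spacing = c(2, 2, 3)),
               grid_cbct = list(dim = c(80, 80, 60), spacing = c(2, 2, 2)))
  args <- utils::modifyList(args, list(...))
  do.call(phantom_spec, args)
}

.fixture_env <- new.env(parent = emptyenv())

# Memoised fixtures: computed once per test run.
fixture <- function(name, make) {
  if (!exists(name, .fixture_env)) assign(name, make(), .fixture_env)
  get(name, .fixture_env)
}

# A moved pair: setup error + independent prostate offset, no gas.
fixture_moved_pair <- function() fixture("moved_pair", function() {
  generate_pair(coarse_spec(
    setup_transform = rigid_transform(c(1, -2, 1.5) * pi / 180, c(5, -4, 3)),
    prostate_offset = c(4, -3, 0), seed = 1301))
})

# Bony result for the moved pair (reused across registration tests).
fixture_moved_bony <- function() fixture("moved_bony", function() {
  p <- fixture_moved_pair()
  register_bony(p$ct, p$cbct)
})

# Prostate-center error of a registration result against phantom truth.
prostate_center_error <- function(pair, result) {
  t <- if (inherits(result, "RegistrationResult")) result$transform else result
  prop <- propagate_contour(pair$ct_structs$ctv, t, grid_of(pair$cbct))
  sqrt(sum((mask_centroid(prop) - mask_centroid(pair$cbct_structs_truth$ctv))^2))
}
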