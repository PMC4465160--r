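# The graded-distension stress cohort used by the filter-effect and
# failure-prediction acceptance checks (computed once, reused by both).
# 20 pairs cycling through four rectal states, from the protocol-compliant
# empty rectum to severe distension with gas on both scans; small setup
# errors and a distension-driven anterior prostate push.
fixture_filter_cohort <- function() fixture("filter_cohort", function() {
  grid <- list(c(1, 0, 0), c(1.2, 0.3, 0.1), c(1.4, 0.7, 0.15), c(1.7, 0.9, 0.15))
  cohort <- make_cohort(20, grid, seed = 501, base_spec = coarse_spec(),
                        setup_trans_mm = 2, setup_rot_deg = 0.5,
                        prostate_offset_mm = 3, prostate_offset_dir = c(0, -1, 0))
  cfg <- experiment_config(methods = c("bony", "local-8"),
                           filter_gas = c(FALSE, TRUE))
  list(cohort = cohort, result = run_experiment(cohort, cfg))
})
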