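# Shared desk-scale comparison studies, built once per test run.
# Configuration (fixed): reduced Windkessel space (d = 5), 3-vessel fixture,
# default simulator settings, Matern 5/2 ARD kernels at jitter 1e-6 for both
# GP variants, PCE orders 1..3, 10 validation / 10 test points, 10 inverted
# targets, seed 1.
study_cache <- new.env(parent = emptyenv())

desk_candidates <- function() {
  candidate_grid(gp_kernels = "Matern52", gp_time_kernels = "Matern52",
                 jitters = 1e-6, pce_orders = 1:3, ard = TRUE)
}

get_study <- function(n_train) {
  key <- paste0("n", n_train)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- suppressWarnings(run_study(
      n_train = n_train, n_valid = 10, n_test = 10, n_invert = 10,
      candidates = desk_candidates(), seed = 1, n_restarts = 3))
  }
  study_cache[[key]]
}
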