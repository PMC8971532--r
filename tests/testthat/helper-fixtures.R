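# Shared fixtures built in code. Everything is deterministic given the
# seeds fixed here.

fixture_parent <- function(seed = 3) make_parent(seed)

fixture_cylinder <- function(seed = 3, f_LV = 1, f_RV = 1) {
  equivalent_cylinder(resize(fixture_parent(seed), f_LV, f_RV))
}

fixture_fibers <- function() fiber_layers(pi / 3, -pi / 3)

# a moderate-stiffness parameter set used across solver tests
fixture_params <- function() material_params(a_f = 1, b_f = 2)

# random admissible diagonal deformation states (J = 1 exactly)
random_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lt <- runif(1, 0.85, 1.3)
    lz <- runif(1, 0.85, 1.3)
    deformation_state(1 / (lt * lz), lt, lz, alpha = runif(1, -pi / 2, pi / 2),
                      p = runif(1, -1, 1))
  })
}

# small corpus shared by surrogate-level tests (built once per test run)
fixture_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(n_examples = 300, n_parents = 10, n_test = 40,
                          seed = 11,
                          cfg = surrogate_config(hidden_layers = 2,
                                                 units = 128, epochs = 1500,
                                                 seed = 7))
      cache <<- run_training_study(cfg, run_reduced = FALSE)
    }
    cache
  }
})
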