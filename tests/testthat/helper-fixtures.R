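## shared fixtures, built once per test run

## minimal sequence container for observer runs
make_seq <- function(stim, block = NULL) {
  if (is.null(block)) block <- rep(1L, length(stim))
  data.frame(trial = seq_along(stim), block = block, stim = as.integer(stim))
}

## one assembled default (coupled) experiment design, memoized; the
## classification observer uses a 35-point grid (grid-convergence backed)
.fixture_env <- new.env()
shared_design <- function() {
  if (is.null(.fixture_env$design)) {
    set.seed(4242)
    .fixture_env$design <- assemble_experiment(
      gen_config(), observer = hier_observer(pc = 1 / 75, grid_n = 35))
  }
  .fixture_env$design
}

shared_hier_trace <- function() {
  if (is.null(.fixture_env$hier_trace)) {
    .fixture_env$hier_trace <- run_observer(
      hier_observer(pc = 1 / 75, grid_n = 35), shared_design()$sequence)
  }
  .fixture_env$hier_trace
}

shared_flat_trace <- function() {
  if (is.null(.fixture_env$flat_trace)) {
    .fixture_env$flat_trace <- run_observer(
      flat_observer(omega = 20), shared_design()$sequence)
  }
  .fixture_env$flat_trace
}

## a noise model whose confidence map cannot clip given log-precision
## confidence in roughly [2, 9]
noiseless_noise <- function() {
  noise_model(prob_slope = 1, prob_sd = 0, conf_slope = 0.05,
              conf_intercept = 0.3, conf_sd = 0)
}
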