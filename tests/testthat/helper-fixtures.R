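# shared fixtures: short protocols and memoised expensive runs
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

short_protocol <- function(n_beats = 12, rec = 3, dt = 0.02)
  pacing_protocol(n_beats = n_beats, record_last_n_beats = rec, dt = dt)

# baseline cell paced 12 beats, last 3 recorded (used by many tests)
baseline_run <- function() memo("baseline_run", {
  run_paced(baseline_parameters(), short_protocol())
})

# membrane / central mean traces in uM
membrane_trace <- function(res) {
  n <- nrow(res$Ca_cyto)
  colMeans(res$Ca_cyto[c(1, n), , drop = FALSE]) * 1e3
}
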