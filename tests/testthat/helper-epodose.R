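# Shared fixtures, built in code once per test run.
test_patient <- default_patient()
test_prec <- operator_precompute(test_patient)
test_ss <- steady_state(test_patient)

# Closed-loop runs are expensive; several test blocks assert different
# properties of the same run, so they share one lazily computed instance.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

baseline_run <- function() {
  cached_run("baseline", run_closed_loop(test_patient, nmpc_config()))
}

cohort_runs <- function() {
  cached_run("cohort", {
    lapply(default_cohort(), function(p)
      run_closed_loop(p, nmpc_config(c_gamma = attr(p, "c_gamma"))))
  })
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-3) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
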