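# Shared fixtures: a reference subject and a cached study-3 simulation
# (deterministic, reused across test files to keep the suite fast).

ref_subject <- function(bw = 70) {
  suppressWarnings(subject_profile("male", 25, bw, vo2max = 44))
}

study3_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- get_study_protocol(3)
      params <- reference_parameters(bw = 70)
      traj <- simulate_protocol(
        ref_subject(), st$protocol, params,
        settings = simulation_settings(t0 = 0, t_end = 210))
      cache <<- list(study = st, params = params, traj = traj)
    }
    cache
  }
})
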