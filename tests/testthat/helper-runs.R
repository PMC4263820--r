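# Shared simulation runs for the test suite. The default joint runs are
# expensive, so they are computed once per test session and reused across
# test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- maker()
  }
  .run_cache[[key]]
}

default_run <- function(case) {
  cached(paste0("full_", case), function() {
    run_creep(case, run_config(case))
  })
}

# march only to the end of the load ramp (cheap: ~half a minute)
ramp_run <- function(key, config) {
  cached(key, function() {
    model <- build_joint_model(config)
    march <- time_march(model, config$schedule$ramp_duration, config$solver)
    poroknee:::reduce_creep_run(config$case, config, model, march)
  })
}

zero_offset_ramp <- function() {
  cfg <- run_config("intact",
                    schedule = load_schedule(800, 1, 1200, medial_offset = 0))
  ramp_run("ramp_offset0", cfg)
}

offset_ramp <- function(offset) {
  cfg <- run_config("intact",
                    schedule = load_schedule(800, 1, 1200,
                                             medial_offset = offset))
  ramp_run(paste0("ramp_offset", offset), cfg)
}

no_switch_ramp <- function() {
  cfg <- run_config("intact", drainage_switch = FALSE)
  ramp_run("ramp_noswitch", cfg)
}
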