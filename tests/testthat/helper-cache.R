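# Heavy shared fixtures, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# The default study scenario: 10 subjects x 10 tasks x 60 frames, noise 0.15.
default_recording <- function() {
  cached("default_recording", generate_dataset(scenario_spec()))
}

# Full pipeline on the default scenario including the D5 layout benchmark.
default_report <- function() {
  cached("default_report", run_pipeline(pipeline_config(levels = 5L),
                                        recording = default_recording()))
}

# A small scenario for comparative / determinism tests.
small_recording <- function() {
  cached("small_recording",
         generate_dataset(scenario_spec(n_subjects = 5, tasks_per_subject = 6,
                                        frames_per_task = 30, seed = 101)))
}

small_dataset <- function() {
  cached("small_dataset", extract_posture_dataset(small_recording()))
}

small_geometry <- function(side = "seatpan") mat_geometry(side, 6, 7, 1)

standard_label <- function() list(trunk = "TP0", left_foot = "LFP0",
                                  right_foot = "RFP0")

standard_kinematics <- function() {
  list(rotation = 0, inclination = 0, lateral_tilt = 0,
       left_x = 0, left_y = 0, right_x = 0, right_y = 0)
}
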