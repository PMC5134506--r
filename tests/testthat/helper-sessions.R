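# Shared simulated sessions and a fitted classifier, built once per test run.

.session_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .session_cache))
    assign(name, expr, envir = .session_cache)
  get(name, envir = .session_cache)
}

# Two-subject control panel and a classifier trained on it; enough sport and
# null segments for all classifier-level tests.
small_panel <- function() {
  cached("small_panel", {
    suite <- default_benchmark_suite(seed = 7, n_subjects = 2)
    sessions <- lapply(suite$control, generate_session)
    ts <- build_training_set(sessions)
    model <- train_gesture_model(ts$X, ts$y, seed = 11)
    list(sessions = sessions, ts = ts, model = model)
  })
}

# One noisy throws-and-serves session reused across detector and
# orientation tests.
throws_session <- function() {
  cached("throws_session", {
    script <- session_script(list(baseball_throw = 8, volleyball_serve = 8),
                             seed = 42)
    generate_session(script)
  })
}

exercises_only_script <- function(reps = 4L, seed = 99) {
  ex <- setdiff(activity_templates(),
                c("baseball_throw", "volleyball_serve", "rest"))
  session_script(as.list(stats::setNames(rep(reps, length(ex)), ex)),
                 seed = seed)
}
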