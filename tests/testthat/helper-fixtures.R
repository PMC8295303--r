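# Shared synthetic bundle + pipeline run, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!exists("sim", envir = .fixture_env)) {
    dir <- file.path(tempdir(), "chromrca-sim-fixture")
    res <- suppressWarnings(simulate_chromatin(sim_config(seed = 42L), dir))
    assign("sim", res, envir = .fixture_env)
  }
  get("sim", envir = .fixture_env)
}

run_fixture <- function() {
  if (!exists("run", envir = .fixture_env)) {
    sim <- sim_fixture()
    cfg <- pipeline_config(
      inputs = sim$paths[setdiff(names(sim$paths), "manifest")])
    out <- file.path(tempdir(), "chromrca-run-fixture")
    summary <- run_pipeline(cfg, out)
    assign("run", list(summary = summary, out = out, cfg = cfg),
           envir = .fixture_env)
  }
  get("run", envir = .fixture_env)
}
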