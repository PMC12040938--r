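# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the default synthetic epigenome (seed 1)
default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_epigenome(synthetic_config(seed = 1))
  }
  .fixtures$sim
}

# a full default pipeline run (seed 1) in a temp dir; reused by the
# pipeline, TSR-recovery and acceptance tests
default_run <- function() {
  if (is.null(.fixtures$run)) {
    outdir <- file.path(tempdir(), "chromatlas_default_run")
    cfg <- pipeline_config(outdir = outdir, seed = 1, write_tracks = FALSE)
    .fixtures$run_config <- cfg
    .fixtures$run <- suppressMessages(run_pipeline(cfg))
  }
  .fixtures$run
}

default_run_config <- function() {
  default_run()
  .fixtures$run_config
}

# the 3-bin two-state toy used throughout the HMM tests
toy_model <- function() {
  state_model(pi = c(0.5, 0.5),
              A = rbind(c(0.9, 0.1), c(0.1, 0.9)),
              E = rbind(0.9, 0.1), marks = "m1")
}

toy_obs <- function() {
  observation_matrix(matrix(c(1, 1, 0), 3, 1), marks = "m1",
                     tissue = "toy", chromosome = "chr1")
}
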