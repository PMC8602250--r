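# one shared default cohort per test run (generation is cheap but not free)
.cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.cohort_cache$dir)) {
    dir <- file.path(tempdir(), "audiogene-shared-cohort")
    unlink(dir, recursive = TRUE)
    .cohort_cache$gen <- generate_cohort(cohort_spec(seed = 42), dir)
    .cohort_cache$dir <- dir
  }
  list(dir = .cohort_cache$dir, gen = .cohort_cache$gen)
}

shared_pipeline <- function() {
  if (is.null(.cohort_cache$result))
    .cohort_cache$result <- run_pipeline(shared_cohort()$dir)
  .cohort_cache$result
}
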