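# Desk-scale end-to-end runs shared by the acceptance blocks: each (seed,
# variant) pair is trained at most once per test session and cached, since
# several blocks inspect different aspects of the same experiment.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed, variant = "full") {
  key <- paste0(variant, "_", seed)
  if (is.null(.study_cache[[key]])) {
    wd <- file.path(tempdir(), "octsr_studies")
    .study_cache[[key]] <- runPhantomStudy(seed = seed, variant = variant,
                                           workDir = wd)
  }
  .study_cache[[key]]
}

study_seeds <- c(1L, 2L, 3L)
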