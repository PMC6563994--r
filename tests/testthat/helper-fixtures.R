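# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A small, noise-free study: all eight groups represented, modest depth.
small_ref <- function() {
  if (is.null(.fixture_cache$ref)) {
    cfg <- troutmir::synthetic_config(
      n_mirna_per_group_label = c(gp1a = 3L, gp1b = 3L, gp2a = 2L,
                                  gp2b = 2L, gp3a = 2L, gp3b = 2L,
                                  gp4a = 2L, gp4b = 2L),
      nb_mean = 60, frac_no_adapter = 0, frac_contaminant = 0,
      seed = 101L)
    .fixture_cache$cfg <- cfg
    .fixture_cache$ref <- troutmir::generate_references(cfg)
  }
  list(cfg = .fixture_cache$cfg, ref = .fixture_cache$ref)
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    fx <- small_ref()
    dir <- file.path(tempdir(), "troutmir_fixture_fastq")
    sim <- troutmir::simulate_library(fx$ref, fx$cfg, dir)
    prep <- troutmir::preprocess_fastq(sim$fastq_paths,
                                       adapter = fx$cfg$adapter)
    .fixture_cache$run <- list(sim = sim, prep = prep)
  }
  c(small_ref(), .fixture_cache$run)
}
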