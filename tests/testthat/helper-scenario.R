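# The default synthetic scenario (seed 42, 1e5 pairs x 2 replicates) is
# expensive enough to build once per test run and share.
.scenario_cache <- new.env(parent = emptyenv())

default_scenario <- function() {
  if (is.null(.scenario_cache$man)) {
    dir <- file.path(tempdir(), "baitlink-default-scenario")
    .scenario_cache$man <- make_scenario(dir, seed = 42L, n_pairs = 100000L)
  }
  .scenario_cache$man
}

# full pipeline on the default scenario, also cached
default_scenario_calls <- function() {
  if (is.null(.scenario_cache$calls)) {
    man <- default_scenario()
    refs <- read_fasta_refs(man$files$genome)
    fm <- read_fragment_map(man$files$fragment_map)
    bait <- bait_spec(man$bait$chrom, man$bait$position,
                      man$bait$reading_primer, fm)
    covs <- lapply(c("rep1", "rep2"), function(r)
      run_4c_replicate(man$files$fastq[[r]][1], man$files$fastq[[r]][2],
                       refs, fm, bait, replicate_id = r))
    .scenario_cache$calls <- list(
      refs = refs, fm = fm, bait = bait, covs = covs,
      calls = call_interactions(covs, bait, fm, rpm_threshold = 50))
  }
  .scenario_cache$calls
}
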