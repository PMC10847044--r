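# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

# Small virome: 3 viruses, short segments, moderate depth. Fast to simulate
# and map, deep enough for unambiguous terminus stacks.
small_sim_params <- function(seed = 11L, ...) {
  defaults <- list(n_viruses = 3, segments_per_virus = c(2, 3),
                   segment_length = c(1500, 2500),
                   depth_per_virus = c(100, 150), error_rate = 0.005,
                   seed = seed)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# truth + reads + trimmed/filtered reads + alignments + profile + termini
build_processed_fixture <- function(params) {
  truth <- simulate_virome(params)
  reads <- simulate_flds_reads(truth, params)
  contigs <- tibble::tibble(contig_id = truth$genomes$segment_id,
                            seq = truth$genomes$seq)
  samples <- tibble::tibble(contig_id = truth$genomes$segment_id,
                            sample_id = truth$genomes$sample_id)
  trimmed <- dplyr::filter(trim_adapter(reads), kept)
  qc <- quality_filter(trimmed)
  aln <- map_reads(qc$kept, contigs)
  profile <- build_stop_profile(aln, contigs)
  termini <- call_termini(profile)
  segments <- classify_segments(contigs, termini, profile, samples = samples)
  list(params = params, truth = truth, reads = reads, contigs = contigs,
       samples = samples, qc_reads = qc$kept, aln = aln, profile = profile,
       termini = termini, segments = segments)
}

get_fixture <- function(name = "small") {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  fx <- switch(
    name,
    small = build_processed_fixture(small_sim_params()),
    # two samples, bipartite viruses only: clean strain-pair truth
    two_sample = build_processed_fixture(
      small_sim_params(seed = 23L, n_viruses = 4, segments_per_virus = 2,
                       n_samples = 2)),
    # error-free library for exact-substring and mapper-equivalence checks
    errorfree = build_processed_fixture(
      small_sim_params(seed = 31L, error_rate = 0)),
    stop(sprintf("unknown fixture '%s'", name))
  )
  assign(name, fx, envir = .fixture_cache)
  fx
}

# Genome-only fixture with many ORFs for SD statistics (no reads needed).
get_sd_truth <- function() {
  if (!is.null(.fixture_cache$sd_truth)) return(.fixture_cache$sd_truth)
  p <- sim_params(n_viruses = 4, segments_per_virus = c(2, 3),
                  segment_length = c(3000, 5000), orfs_per_segment = c(4, 6),
                  sd_fraction = 0.95, seed = 41L)
  truth <- simulate_virome(p)
  .fixture_cache$sd_truth <- list(params = p, truth = truth)
  .fixture_cache$sd_truth
}
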