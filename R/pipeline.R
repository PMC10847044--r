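#' Pipeline configuration
#'
#' Collects every tunable threshold of the reconstruction pipeline. All
#' values are echoed verbatim into the run manifest so any result can be
#' traced to the exact parameters that produced it.
#'
#' @param min_overlap,max_mismatch_rate_adapter Adapter trimming (see
#'   [adapter_spec()]).
#' @param min_mean_q,min_len Quality filtering thresholds.
#' @param k,max_mismatch_rate_map Built-in mapper settings.
#' @param min_stop_reads,end_window,min_dominance Terminus calling (see
#'   [call_termini()]).
#' @param major_coverage_threshold Major-segment coverage bound.
#' @param terminal_window,link_threshold,require_ends Genome binning.
#' @param max_log2_ratio Strain pairing bound.
#' @param min_orf_len,sd_min_match Annotation settings.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `segvir_config`.
#' @export
pipeline_config <- function(min_overlap = 8L,
                            max_mismatch_rate_adapter = 0.1,
                            min_mean_q = 20,
                            min_len = 50L,
                            k = 21L,
                            max_mismatch_rate_map = 0.05,
                            min_stop_reads = 10L,
                            end_window = 50L,
                            min_dominance = 0.2,
                            major_coverage_threshold = 1000,
                            terminal_window = 30L,
                            link_threshold = 0.6,
                            require_ends = "both",
                            max_log2_ratio = 1.0,
                            min_orf_len = 150L,
                            sd_min_match = 4L,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "segvir_config")
}

#' Run the full genome-reconstruction pipeline
#'
#' Executes, in order: adapter trimming, quality filtering, read mapping
#' (built-in minimal mapper, or externally supplied alignments), stop-profile
#' construction, terminus calling, segment classification, coding-strand
#' orientation, terminal-conservation binning, strain pairing by abundance,
#' and annotation. Any stage failure aborts with the stage name. The result
#' carries a machine-readable manifest (parameters, per-stage record counts,
#' content hashes) that is identical across reruns with the same inputs and
#' configuration.
#'
#' @param reads Read tibble (`read_id`, `seq`, `qual`).
#' @param contigs Assembled contigs (tibble `contig_id`/`seq`, named
#'   character vector, or `DNAStringSet`).
#' @param config A [pipeline_config()].
#' @param samples Optional tibble (`contig_id`, `sample_id`).
#' @param alignments Optional precomputed alignment tibble (e.g. from
#'   [read_sam()]); when given, trimming/mapping of `reads` is skipped.
#' @return A list of class `segvir_result` with elements `segments`,
#'   `termini`, `profile`, `scores`, `bins`, `strain_pairs`, `annotation`,
#'   `bin_summary` and `manifest`.
#' @export
run_pipeline <- function(reads, contigs, config = pipeline_config(),
                         samples = NULL, alignments = NULL) {
  stopifnot(inherits(config, "segvir_config"))
  contigs <- as_contig_tbl(contigs)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  if (is.null(alignments)) {
    trimmed <- stage("trim", {
      tr <- trim_adapter(reads,
                         u2_adapters(config$min_overlap,
                                     config$max_mismatch_rate_adapter),
                         min_len = config$min_len)
      filter(tr, .data$kept)
    })
    counts$reads_in <- nrow(reads)
    counts$reads_trimmed_kept <- nrow(trimmed)
    qc <- stage("quality_filter",
                quality_filter(trimmed, config$min_mean_q, config$min_len))
    counts$reads_after_qc <- nrow(qc$kept)
    alignments <- stage("map", map_reads(qc$kept, contigs, k = config$k,
                                         max_mismatch_rate = config$max_mismatch_rate_map))
    counts <- c(counts, as.list(attr(alignments, "counts")))
  }
  counts$alignments <- nrow(alignments)
  profile <- stage("pileup", build_stop_profile(alignments, contigs))
  termini <- stage("call_termini",
                   call_termini(profile, config$min_stop_reads,
                                config$end_window, config$min_dominance))
  counts$termini <- nrow(termini)
  segments <- stage("classify",
                    classify_segments(contigs, termini, profile,
                                      config$major_coverage_threshold,
                                      samples))
  counts$complete_segments <- sum(segments$status == "complete")
  complete <- filter(segments, .data$status == "complete")
  if (nrow(complete) > 0L) {
    complete <- stage("orient",
                      orient_coding_strand(complete, config$min_orf_len))
    scores <- stage("terminal_identity",
                    terminal_identities(complete, config$terminal_window,
                                        config$link_threshold,
                                        config$require_ends))
    bins <- stage("bin", cluster_segments(complete, scores,
                                          config$link_threshold,
                                          config$require_ends,
                                          min_orf_len = config$min_orf_len))
    pairs <- stage("pair", pair_by_abundance(bins, complete,
                                             config$max_log2_ratio))
    ann <- stage("annotate", annotate_bin(bins, complete,
                                          config$min_orf_len))
  } else {
    scores <- terminal_identities(complete)
    bins <- tibble(bin_id = character(), contig_id = character(),
                   class_id = character(), is_alternative = logical())
    pairs <- pair_by_abundance(bins, complete)
    ann <- list(orfs = tibble(), summary = tibble(bin_id = character(),
                                                  n_members = integer(),
                                                  n_orfs = integer(),
                                                  sd_fraction = double(),
                                                  rdrp_segment = character()))
  }
  counts$bins <- dplyr::n_distinct(bins$bin_id)
  counts$strain_pairs <- nrow(pairs)
  counts$orfs <- nrow(ann$orfs)
  manifest <- list(
    parameters = unclass(config),
    counts = counts,
    hashes = list(
      segments = hash(segments), termini = hash(termini),
      bins = hash(bins), strain_pairs = hash(pairs),
      annotation = hash(ann$orfs)
    )
  )
  structure(list(
    segments = segments,
    oriented = complete,
    termini = termini,
    profile = profile,
    scores = scores,
    bins = bins,
    strain_pairs = pairs,
    annotation = ann$orfs,
    bin_summary = ann$summary,
    manifest = manifest
  ), class = "segvir_result")
}

#' @export
print.segvir_result <- function(x, ...) {
  cat("<segvir_result>\n")
  cat(sprintf("  contigs: %d (%d complete segments, %d major)\n",
              nrow(x$segments), sum(x$segments$status == "complete"),
              sum(x$segments$is_major)))
  cat(sprintf("  bins: %d   strain pairs: %d   ORFs: %d\n",
              x$manifest$counts$bins, x$manifest$counts$strain_pairs,
              x$manifest$counts$orfs))
  invisible(x)
}

#' Human-readable run summary
#'
#' Per-sample and per-bin tables of segments, bins, SD fractions and RdRP
#' segments; every number is recomputed from the result's stage outputs.
#'
#' @param result A `segvir_result`.
#' @param path Optional file to write the report to.
#' @return Character vector of report lines (invisibly when `path` given).
#' @export
summary_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "segvir_result"))
  seg <- result$segments
  lines <- c(
    "segvir run summary",
    "==================",
    sprintf("contigs analysed: %d", nrow(seg)),
    sprintf("complete segments: %d (major >%s x coverage: %d)",
            sum(seg$status == "complete"),
            format(result$manifest$parameters$major_coverage_threshold),
            sum(seg$is_major)),
    ""
  )
  if (nrow(seg)) {
    by_sample <- seg |>
      group_by(.data$sample_id) |>
      summarise(contigs = n(), complete = sum(.data$status == "complete"))
    lines <- c(lines, "per sample:",
               sprintf("  %s: %d contigs, %d complete",
                       by_sample$sample_id, by_sample$contigs,
                       by_sample$complete), "")
  }
  if (nrow(result$bin_summary)) {
    bs <- result$bin_summary
    lines <- c(lines, "bins:",
               sprintf("  %s: %d members, %d ORFs, SD fraction %.2f, RdRP: %s",
                       bs$bin_id, bs$n_members, bs$n_orfs, bs$sd_fraction,
                       ifelse(is.na(bs$rdrp_segment), "none",
                              bs$rdrp_segment)), "")
  } else {
    lines <- c(lines, "bins: none (zero findings)", "")
  }
  if (nrow(result$strain_pairs)) {
    sp <- result$strain_pairs
    lines <- c(lines, "strain pairs (same sample, similar abundance):",
               sprintf("  %s + %s [%s, log2 ratio %+.2f]", sp$a, sp$b,
                       sp$sample_id, sp$log2_ratio))
  } else {
    lines <- c(lines, "strain pairs: none")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
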