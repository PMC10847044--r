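#' Describe an adapter for 3'-end trimming
#'
#' @param name Adapter name.
#' @param sequence Adapter sequence (uppercase ACGT).
#' @param min_overlap Minimum suffix/prefix overlap in nt to trim.
#' @param max_mismatch_rate Maximum fraction of mismatches in the overlap.
#' @return A list of class `adapter_spec`.
#' @export
adapter_spec <- function(name, sequence, min_overlap = 8L,
                         max_mismatch_rate = 0.1) {
  sequence <- check_dna(sequence, "sequence", allow_n = FALSE)
  if (nchar(sequence) == 0L) abort("adapter sequence must be nonempty")
  assert_scalar_count(min_overlap, "min_overlap")
  assert_fraction(max_mismatch_rate, "max_mismatch_rate")
  if (min_overlap > nchar(sequence)) {
    abort("`min_overlap` cannot exceed the adapter length")
  }
  structure(list(name = name, sequence = sequence,
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate),
            class = "adapter_spec")
}

#' The two adapters of the fragmented-dsRNA library protocol
#'
#' U2 is ligated to the 3' end of fragmented dsRNA; U2-comp is its reverse
#' complement primer. Reads derive from both cDNA strands, so both occur as
#' read suffixes.
#'
#' @inheritParams adapter_spec
#' @return List of two `adapter_spec` objects.
#' @export
u2_adapters <- function(min_overlap = 8L, max_mismatch_rate = 0.1) {
  list(
    adapter_spec("U2", U2_SEQ, min_overlap, max_mismatch_rate),
    adapter_spec("U2-comp", U2_COMP_SEQ, min_overlap, max_mismatch_rate)
  )
}

# Longest read-suffix / adapter-prefix overlap cut point for one read:
# returns the number of bases kept, or n if nothing qualifies.
suffix_cut_point <- function(seq, adapter) {
  n <- nchar(seq)
  a <- adapter$sequence
  for (ov in seq(min(n, nchar(a)), 1L)) {
    if (ov < adapter$min_overlap) break
    mm <- str_mismatches(substr(seq, n - ov + 1L, n), substr(a, 1L, ov))
    if (mm / ov <= adapter$max_mismatch_rate) return(n - ov)
  }
  n
}

# Vectorised cut points for a whole read set against one adapter: full
# internal matches (mismatch-tolerant, leftmost) via vmatchPattern, then the
# per-read suffix-overlap scan.
adapter_cut_points <- function(seqs, adapter) {
  n <- nchar(seqs)
  alen <- nchar(adapter$sequence)
  cut <- vapply(seqs, suffix_cut_point, 0L, adapter = adapter,
                USE.NAMES = FALSE)
  max_mm_full <- floor(adapter$max_mismatch_rate * alen)
  hits <- Biostrings::vmatchPattern(adapter$sequence,
                                    Biostrings::DNAStringSet(seqs),
                                    max.mismatch = max_mm_full)
  starts <- Biostrings::startIndex(hits)
  full <- vapply(starts, function(s) if (is.null(s) || !length(s)) NA_integer_
                 else min(s) - 1L, 0L)
  pmin(cut, ifelse(is.na(full), n, full))
}

#' Trim 3' adapters from reads
#'
#' Removes, from each read's 3' end, the longest suffix matching a prefix of
#' an adapter (overlap >= `min_overlap`, mismatch rate <=
#' `max_mismatch_rate`), and everything from a full internal adapter match
#' onward. Qualities are trimmed in lockstep. Reads shorter than `min_len`
#' after trimming are flagged (`kept = FALSE`), not silently dropped.
#'
#' @param reads Tibble with `seq` and `qual` columns (e.g. from
#'   [read_fastq()] or [simulate_flds_reads()]).
#' @param adapters A single [adapter_spec()] or a list of them; defaults to
#'   the two library adapters ([u2_adapters()]).
#' @param min_len Minimum post-trim length to keep a read.
#' @return The input tibble with `seq`/`qual` trimmed and added columns
#'   `trimmed_bases` and `kept`.
#' @export
trim_adapter <- function(reads, adapters = u2_adapters(), min_len = 50L) {
  if (inherits(adapters, "adapter_spec")) adapters <- list(adapters)
  stopifnot(nrow(reads) > 0L, all(c("seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence/quality length mismatch", class = "segvir_format_error")
  }
  if (any(nchar(reads$seq) == 0L)) abort("empty read sequence")
  n <- nchar(reads$seq)
  cut <- n
  for (ad in adapters) {
    cut <- pmin(cut, adapter_cut_points(reads$seq, ad))
  }
  out <- reads
  out$seq <- substr(reads$seq, 1L, cut)
  out$qual <- substr(reads$qual, 1L, cut)
  out$trimmed_bases <- n - cut
  out$kept <- cut >= min_len
  out
}

#' Filter reads on mean quality and length
#'
#' @param reads Tibble with `seq` and `qual` (Sanger-encoded) columns.
#' @param min_mean_q Minimum mean Phred quality.
#' @param min_len Minimum read length in nt.
#' @return A list with `kept` (tibble of passing reads), `rejected` (tibble
#'   with a `reason` column: "too_short" or "low_quality") and `counts`
#'   (tibble of rejection reasons).
#' @export
quality_filter <- function(reads, min_mean_q = 20, min_len = 50L) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence/quality length mismatch", class = "segvir_format_error")
  }
  mean_q <- vapply(reads$qual, function(q) {
    if (nchar(q) == 0L) return(0)
    mean(utf8ToInt(q) - 33L)
  }, 0, USE.NAMES = FALSE)
  too_short <- nchar(reads$seq) < min_len
  low_q <- !too_short & mean_q < min_mean_q
  reason <- ifelse(too_short, "too_short", ifelse(low_q, "low_quality", NA))
  kept <- reads[is.na(reason), , drop = FALSE]
  rejected <- mutate(reads[!is.na(reason), , drop = FALSE],
                     reason = reason[!is.na(reason)])
  counts <- count(tibble(reason = reason[!is.na(reason)]), .data$reason,
                  name = "n")
  list(kept = as_tibble(kept), rejected = as_tibble(rejected), counts = counts)
}
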