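#' Tidy a pipeline result
#'
#' Broom-style accessor: returns one of the result's component tables as a
#' tibble.
#'
#' @param x A `segvir_result` from [run_pipeline()].
#' @param what Which table: `"segments"` (default), `"termini"`, `"bins"`,
#'   `"strain_pairs"` or `"orfs"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.segvir_result <- function(x, what = c("segments", "termini", "bins",
                                           "strain_pairs", "orfs"), ...) {
  what <- match.arg(what)
  switch(what,
         segments = select(x$segments, -"seq"),
         termini = x$termini,
         bins = x$bins,
         strain_pairs = x$strain_pairs,
         orfs = if (nrow(x$annotation)) select(x$annotation, -"protein")
                else x$annotation)
}

#' One-row summary of a pipeline result
#'
#' @param x A `segvir_result`.
#' @param ... Unused.
#' @return One-row tibble with contig, segment, bin, strain-pair and ORF
#'   counts plus the overall SD fraction.
#' @export
glance.segvir_result <- function(x, ...) {
  tibble(
    n_contigs = nrow(x$segments),
    n_complete = sum(x$segments$status == "complete"),
    n_major = sum(x$segments$is_major),
    n_bins = dplyr::n_distinct(x$bins$bin_id),
    n_strain_pairs = nrow(x$strain_pairs),
    n_orfs = nrow(x$annotation),
    sd_fraction = if (nrow(x$annotation)) mean(x$annotation$sd_found)
                  else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
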