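#' Plot coverage and read-stop pileup for a contig
#'
#' Coverage as an area, alignment start/stop counts as spikes, and called
#' termini (if given) as dashed verticals — the visual evidence behind a
#' terminus call.
#'
#' @param profile Stop profile from [build_stop_profile()].
#' @param contig_id Contig to plot (default: first in the profile).
#' @param termini Optional terminus calls from [call_termini()].
#' @return A ggplot object.
#' @export
plot_stop_profile <- function(profile, contig_id = NULL, termini = NULL) {
  cid <- contig_id %||% profile$contig_id[1]
  p <- filter(profile, .data$contig_id == cid)
  stops <- p |>
    select("pos", "starts", "ends") |>
    pivot_longer(c("starts", "ends"), names_to = "kind", values_to = "count") |>
    filter(.data$count > 0)
  g <- ggplot2::ggplot(p, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$coverage), fill = "grey80") +
    ggplot2::geom_segment(data = stops,
                          ggplot2::aes(xend = .data$pos, y = 0,
                                       yend = .data$count,
                                       colour = .data$kind)) +
    ggplot2::labs(x = "position (nt)", y = "reads", colour = NULL,
                  title = cid) +
    ggplot2::theme_minimal()
  if (!is.null(termini)) {
    t <- filter(termini, .data$contig_id == cid)
    if (nrow(t)) {
      g <- g + ggplot2::geom_vline(xintercept = t$position,
                                   linetype = "dashed")
    }
  }
  g
}

#' Genome map of a bin's annotated segments
#'
#' ORFs as arrows along each member segment; SD-like motifs marked with a
#' point at the gene start, transmembrane-domain genes with an asterisk.
#'
#' @param annotation Annotation tibble from [annotate_bin()]/[run_pipeline()].
#' @param bin_id Bin to plot (default: first).
#' @return A ggplot object.
#' @export
plot_genome_map <- function(annotation, bin_id = NULL) {
  stopifnot(nrow(annotation) > 0L)
  b <- bin_id %||% annotation$bin_id[1]
  a <- filter(annotation, .data$bin_id == b)
  a$y <- as.integer(factor(a$segment_id))
  g <- ggplot2::ggplot(a) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 2, colour = "steelblue") +
    ggplot2::geom_point(data = filter(a, .data$sd_found),
                        ggplot2::aes(x = .data$start, y = .data$y + 0.18),
                        colour = "goldenrod", size = 2) +
    ggplot2::geom_text(data = filter(a, .data$tmd),
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$y + 0.3), label = "*",
                       size = 5) +
    ggplot2::scale_y_continuous(breaks = unique(a$y),
                                labels = unique(a$segment_id)) +
    ggplot2::labs(x = "position (nt)", y = NULL, title = b) +
    ggplot2::theme_minimal()
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a pipeline result
#'
#' Genome map of the first (or given) bin.
#'
#' @param object A `segvir_result`.
#' @param bin_id Optional bin id.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segvir_result <- function(object, bin_id = NULL, ...) {
  plot_genome_map(object$annotation, bin_id)
}
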