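# ggplot2 views of a scan: a genome map of islands, tDNAs and
# integrases, and a bar view of the filter attrition trace.

#' Genome map of an island scan
#'
#' One horizontal track per replicon: islands as wide bars, tDNAs as
#' upward ticks, admitted integrases as downward ticks. Origin-wrapping
#' islands are drawn as their two linear segments.
#'
#' @param object An `island_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.island_scan <- function(object, ...) {
  reps <- object$replicons
  seg_tbl <- function(tbl) {
    if (!nrow(tbl)) {
      return(tibble(replicon_id = character(), xstart = numeric(),
                    xend = numeric()))
    }
    map_dfr(seq_len(nrow(tbl)), function(i) {
      L <- reps$length[match(tbl$replicon_id[i], reps$replicon_id)]
      segs <- ivl_segments(tbl$start[i], tbl$end[i], L)
      tibble(replicon_id = tbl$replicon_id[i],
             xstart = segs[, 1], xend = segs[, 2],
             name = if ("name" %in% names(tbl)) tbl$name[i] else NA)
    })
  }
  isl <- seg_tbl(object$islands)
  td <- object$tdnas
  ig <- object$admitted_integrases
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = reps,
      ggplot2::aes(x = 0, xend = .data$length, y = .data$replicon_id,
                   yend = .data$replicon_id),
      linewidth = 0.4, colour = "grey40")
  if (nrow(isl)) {
    p <- p + ggplot2::geom_segment(
      data = isl,
      ggplot2::aes(x = .data$xstart, xend = .data$xend,
                   y = .data$replicon_id, yend = .data$replicon_id,
                   colour = .data$name),
      linewidth = 4, alpha = 0.8)
  }
  if (nrow(td)) {
    p <- p + ggplot2::geom_point(
      data = td,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = .data$replicon_id),
      shape = 17, size = 2, colour = "black")
  }
  if (nrow(ig)) {
    p <- p + ggplot2::geom_point(
      data = ig,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = .data$replicon_id),
      shape = 25, size = 1.6, fill = "firebrick", colour = "firebrick")
  }
  p +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "island") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Filter attrition plot
#'
#' Candidates entering and rejected at each filter of the cascade, in
#' cascade order.
#'
#' @param trace The `trace` tibble of [run_cascade()] or an
#'   `island_scan`.
#' @return A ggplot.
#' @export
plot_filter_trace <- function(trace) {
  if (inherits(trace, "island_scan")) trace <- trace$trace
  long <- trace %>%
    mutate(filter = factor(.data$filter, levels = .data$filter)) %>%
    tidyr::pivot_longer(c("entering", "rejected"), names_to = "what",
                        values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$filter, y = .data$n,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "candidates", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
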