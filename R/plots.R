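REGION_FILLS <- c(upstream = "grey80", primary = "#2166ac", insert = "#d6604d",
                  duplication = "#92c5de", downstream = "grey80")

#' Plot a coverage profile
#'
#' Depth along the genome; when a [dup_model()] is supplied the repeat
#' regions are shaded so coverage holes can be read against the repeat
#' structure (the characteristic signature of discarded multi-mappers).
#'
#' @param object a `coverage_profile` from [map_short_reads()].
#' @param model optional [dup_model()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coverage_profile <- function(object, model = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth))
  if (!is.null(model)) {
    rm_ <- region_map(model)
    rm_ <- rm_[rm_$region %in% c("primary", "insert", "duplication"), ]
    p <- p + ggplot2::geom_rect(
      data = rm_,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      inherit.aes = FALSE, alpha = 0.25) +
      ggplot2::scale_fill_manual(values = REGION_FILLS, name = "region")
  }
  p + ggplot2::geom_area(fill = "grey30") +
    ggplot2::labs(x = "position (nt)", y = "depth",
                  title = sprintf("policy: %s (%d/%d reads placed, %.1f%% covered)",
                                  object$policy, object$n_mapped, object$n_reads,
                                  100 * object$covered_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot the structure of a duplication model
#'
#' Two tracks: the reference with the duplicated interval marked, and the
#' derived genome with upstream/primary/insert/duplication/downstream
#' regions colored.
#'
#' @param object a [dup_model()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dup_model <- function(object, ...) {
  rm_ <- region_map(object)
  rm_$track <- "derived"
  ref <- tibble::tibble(
    region = c("upstream", "primary", "downstream"),
    start = c(1L, object$acceptor, object$donor + 1L),
    end = c(object$acceptor - 1L, object$donor, genome_length(object$reference)),
    track = "reference")
  df <- dplyr::bind_rows(rm_, ref)
  df$track <- factor(df$track, levels = c("reference", "derived"))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1, fill = .data$region)) +
    ggplot2::facet_wrap(~track, ncol = 1) +
    ggplot2::scale_fill_manual(values = REGION_FILLS) +
    ggplot2::labs(x = "position (nt)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' Plot junction candidate support
#'
#' Scatter of per-read junction candidates (donor vs acceptor), sized by
#' recurrence, with consensus calls overlaid.
#'
#' @param candidates tibble from [detect_backjumps()].
#' @param calls optional tibble from [cluster_junctions()].
#' @return a ggplot object.
#' @export
plot_junction_candidates <- function(candidates, calls = NULL) {
  df <- dplyr::count(candidates, .data$donor, .data$acceptor)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$donor, y = .data$acceptor)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::labs(x = "donor (reference nt)", y = "acceptor (reference nt)",
                  size = "reads") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_point(data = calls, shape = 4, size = 4,
                                 colour = "red")
  }
  p
}
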