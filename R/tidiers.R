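#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a warehouse into a per-contig property table
#'
#' @param x A warehouse.
#' @param ... Unused.
#' @return The [contig_properties()] tibble with assembly names joined in.
#' @export
tidy.warehouse <- function(x, ...) {
  props <- contig_properties(x)
  asm <- tibble(
    contig_id = x$contigs$id,
    assembly = x$assemblies$name[match(x$contigs$assembly_id, x$assemblies$id)]
  )
  dplyr::left_join(props, asm, by = "contig_id")
}

#' One-row warehouse overview
#'
#' @param x A warehouse.
#' @param ... Unused.
#' @return Tibble with entity counts and total assembled bases.
#' @export
glance.warehouse <- function(x, ...) {
  tibble(
    n_studies = nrow(x$studies),
    n_assemblies = nrow(x$assemblies),
    n_contigs = nrow(x$contigs),
    n_annotations = nrow(x$annotations),
    n_contig_sets = nrow(x$contig_sets),
    n_indexed_tokens = length(unique(x$index$token)),
    total_bases = sum(nchar(x$contigs$sequence))
  )
}

#' Tidy a contig report into its annotation table
#'
#' @param x A `contig_report`.
#' @param ... Unused.
#' @return The annotation detail tibble (one row per annotation).
#' @export
tidy.contig_report <- function(x, ...) as_tibble(x$tables)

#' Plot contig-set comparison series
#'
#' Scatter series are drawn as one point per contig and histogram series as
#' grouped columns on the shared bin edges; log-axis flags from the series
#' spec become log10 scales.
#'
#' @param object A `plot_series` from [scatter_data()] or [histogram_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plot_series <- function(object, ...) {
  axes <- attr(object, "axes")
  df <- as.data.frame(object)
  if (attr(object, "chart") == "scatter") {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$x, y = .data$y, colour = .data$set_label
    )) +
      ggplot2::geom_point(alpha = 0.6, size = 1) +
      ggplot2::labs(x = axes$x, y = axes$y, colour = "contig set")
    if (isTRUE(axes$log_x)) p <- p + ggplot2::scale_x_log10()
    if (isTRUE(axes$log_y)) p <- p + ggplot2::scale_y_log10()
    return(p)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2, y = .data$frequency,
    fill = .data$set_label
  )) +
    ggplot2::geom_col(position = "dodge",
      width = (df$bin_end - df$bin_start) * 0.9) +
    ggplot2::labs(
      x = axes$property,
      y = if (isTRUE(axes$relative)) "relative frequency" else "contigs",
      fill = "contig set"
    )
  if (isTRUE(axes$log_freq)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a single-contig overview
#'
#' A faceted rendering of the report tracks: per-base coverage and quality
#' (when present) as step lines, similarity hits, domains and read mappings
#' as horizontal interval bars, mirroring the overview page layout.
#'
#' @param object A `contig_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contig_report <- function(object, ...) {
  tr <- object$tracks
  panels <- list()
  if (!is.null(tr$coverage)) {
    panels$coverage <- tibble(
      panel = "coverage", pos = seq_along(tr$coverage) - 1L,
      value = as.double(tr$coverage)
    )
  }
  if (!is.null(tr$quality)) {
    panels$quality <- tibble(
      panel = "quality", pos = seq_along(tr$quality) - 1L,
      value = as.double(tr$quality)
    )
  }
  lines <- dplyr::bind_rows(panels)
  bars <- dplyr::bind_rows(
    if (nrow(tr$similarity_hits)) tibble(
      panel = "similarity hits", start = tr$similarity_hits$start,
      end = tr$similarity_hits$end,
      lane = seq_len(nrow(tr$similarity_hits))
    ),
    if (nrow(tr$domains)) tibble(
      panel = "domains", start = tr$domains$start, end = tr$domains$end,
      lane = seq_len(nrow(tr$domains))
    ),
    if (nrow(tr$read_mappings)) tibble(
      panel = "reads", start = tr$read_mappings$start,
      end = tr$read_mappings$end, lane = seq_len(nrow(tr$read_mappings))
    )
  )
  panel_levels <- c("coverage", "quality", "similarity hits", "domains", "reads")
  p <- ggplot2::ggplot()
  if (nrow(lines) > 0L) {
    lines$panel <- factor(lines$panel, panel_levels)
    p <- p + ggplot2::geom_step(
      data = lines, ggplot2::aes(x = .data$pos, y = .data$value)
    )
  }
  if (nrow(bars) > 0L) {
    bars$panel <- factor(bars$panel, panel_levels)
    p <- p + ggplot2::geom_segment(
      data = bars, linewidth = 2,
      ggplot2::aes(x = .data$start, xend = .data$end,
        y = .data$lane, yend = .data$lane)
    )
  }
  p +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::xlim(0, object$contig$length) +
    ggplot2::labs(
      x = sprintf("%s (bp)", object$contig$name), y = NULL
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
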