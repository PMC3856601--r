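# Renderer-agnostic report structures: the single-contig overview (scale
# bar, coverage/quality tracks, similarity and domain intervals, read
# mappings, annotation tables) and the contig-set comparison series
# (scatter / histogram). All are pure data, JSON-serializable; ggplot2
# rendering is a thin optional layer (see autoplot methods).

uniprot_url_template <- "https://www.uniprot.org/uniprotkb/%s/entry"
interpro_url_template <- "https://www.ebi.ac.uk/interpro/search/text/%s"

annotation_url <- function(source, accession) {
  ifelse(is.na(accession), NA_character_, sprintf(
    ifelse(source == "sequence_similarity",
      uniprot_url_template, interpro_url_template),
    accession
  ))
}

#' Single-contig overview report
#'
#' Gathers everything known about one contig into a fixed-order track list
#' (scale bar, per-base coverage, per-base quality, similarity-hit
#' intervals, domain intervals, read-mapping intervals) plus annotation
#' detail tables with external-resource URL templates. Coverage and quality
#' tracks are omitted when the contig was ingested without them (FASTA-only
#' workflow).
#'
#' @param wh A warehouse.
#' @param contig Contig id.
#' @return A `contig_report` list: `contig` (id, name, length), `tracks`
#'   (named list in fixed display order), `tables` (annotation rows).
#' @export
contig_report <- function(wh, contig) {
  i <- match(contig, wh$contigs$id)
  if (is.na(i)) cw_error("cw_not_found", sprintf("no contig %s", sQuote(contig)))
  row <- wh$contigs[i, ]
  len <- nchar(row$sequence)
  ann <- wh$annotations[wh$annotations$contig_id == contig, ]
  sim <- ann[ann$source == "sequence_similarity", ]
  sim <- sim[order(sim$rank), ]
  dom <- ann[ann$source == "protein_domain", ]
  mp <- wh$read_mappings[wh$read_mappings$contig_id == contig, ]

  tracks <- list(scale = list(length = len))
  if (!is.null(row$quality[[1]]) || !is.null(row$coverage[[1]])) {
    if (!is.null(row$coverage[[1]])) tracks$coverage <- row$coverage[[1]]
    if (!is.null(row$quality[[1]])) tracks$quality <- row$quality[[1]]
  }
  tracks$similarity_hits <- tibble(
    label = sim$description, accession = sim$subject_accession,
    start = sim$start, end = sim$end, evalue = sim$evalue, rank = sim$rank
  )
  tracks$domains <- tibble(
    label = dom$description, accession = dom$subject_accession,
    start = dom$start, end = dom$end, evalue = dom$evalue
  )
  tracks$read_mappings <- tibble(
    read_name = mp$read_name, strand = mp$strand,
    start = mp$start, end = mp$end
  )

  tables <- ann[, c("id", "source", "subject_accession", "description",
    "start", "end", "evalue", "rank")]
  tables$url <- annotation_url(tables$source, tables$subject_accession)

  structure(
    list(
      contig = list(id = row$id, name = row$name, length = len),
      tracks = tracks, tables = tables
    ),
    class = "contig_report"
  )
}

#' @export
print.contig_report <- function(x, ...) {
  cat(sprintf(
    "<contig report> %s (%d bp): tracks [%s], %d annotation rows\n",
    x$contig$name, x$contig$length, paste(names(x$tracks), collapse = ", "),
    nrow(x$tables)
  ))
  invisible(x)
}

set_label_for <- function(wh, set, fallback) {
  if (is.character(set) && length(set) == 1L) {
    row <- wh$contig_sets[wh$contig_sets$id == set | wh$contig_sets$name == set, ]
    if (nrow(row) == 1L) return(row$name)
  }
  lbl <- attr(set, "provenance")
  if (!is.null(lbl) && nzchar(lbl)) return(lbl)
  fallback
}

series_members <- function(wh, sets) {
  if (!is.list(sets)) sets <- list(sets)
  labels <- names(sets) %||% rep("", length(sets))
  lapply(seq_along(sets), function(k) {
    lbl <- if (nzchar(labels[k])) {
      labels[k]
    } else {
      set_label_for(wh, sets[[k]], sprintf("set %d", k))
    }
    list(label = lbl, ids = resolve_scope(wh, sets[[k]]))
  })
}

filter_props <- function(props, min_length, min_coverage) {
  keep <- props$length >= min_length
  if (min_coverage > 0) {
    keep <- keep & !is.na(props$mean_coverage) &
      props$mean_coverage >= min_coverage
  }
  props[keep, ]
}

check_property <- function(p) {
  if (!p %in% property_names()) {
    cw_error("cw_bad_property", sprintf(
      "unknown property %s; valid properties: %s",
      sQuote(p), paste(property_names(), collapse = ", ")
    ))
  }
}

#' Scatter-plot data for contig-set comparison
#'
#' One data series per contig set, in input order, each point one contig
#' (carrying its id for drill-down). Contigs failing the length/coverage
#' filters, lacking either axis property, or having non-positive values on
#' a log axis (log10; excluded, never offset) are dropped.
#'
#' @param wh A warehouse.
#' @param sets List of contig sets (ids/names or selections), optionally
#'   named for series labels.
#' @param x,y Property names (distinct), from `length`, `ungapped_length`,
#'   `gc`, `mean_coverage`, `mean_quality`.
#' @param log_x,log_y Logarithmic axis flags.
#' @param min_length,min_coverage Exclusion filters for very short or very
#'   low-coverage contigs.
#' @return A `plot_series` tibble: `set_label`, `colour_key`, `contig_id`,
#'   `x`, `y`, with the axis/filter spec in attributes.
#' @export
scatter_data <- function(wh, sets, x, y, log_x = FALSE, log_y = FALSE,
                         min_length = 0, min_coverage = 0) {
  check_property(x); check_property(y)
  if (identical(x, y)) cw_error("cw_bad_property", "x and y must differ")
  series <- series_members(wh, sets)
  rows <- lapply(seq_along(series), function(k) {
    s <- series[[k]]
    if (length(s$ids) == 0L) {
      return(tibble(set_label = character(), colour_key = integer(),
        contig_id = character(), x = double(), y = double()))
    }
    props <- filter_props(contig_properties(wh, s$ids), min_length, min_coverage)
    xv <- props[[x]]; yv <- props[[y]]
    keep <- !is.na(xv) & !is.na(yv)
    if (log_x) keep <- keep & xv > 0
    if (log_y) keep <- keep & yv > 0
    tibble(
      set_label = s$label, colour_key = k, contig_id = props$contig_id[keep],
      x = xv[keep], y = yv[keep]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "axes") <- list(x = x, y = y, log_x = log_x, log_y = log_y)
  attr(out, "filters") <- list(min_length = min_length, min_coverage = min_coverage)
  attr(out, "chart") <- "scatter"
  class(out) <- c("plot_series", class(out))
  out
}

#' Histogram data for contig-set comparison
#'
#' Shared bin edges across sets are computed from the pooled filtered value
#' range so overlays are comparable; `relative = TRUE` scales each set's
#' counts by its filtered size (frequencies then sum to 1 per non-empty
#' set). When all pooled values are identical a single width-1 bin centred
#' on the value is used.
#'
#' @inheritParams scatter_data
#' @param property Property to bin.
#' @param bins Number of bins (>= 1).
#' @param log_freq Logarithmic frequency axis flag (rendering hint only).
#' @param relative Scale frequencies relative to contig-set size.
#' @return A `plot_series` tibble: `set_label`, `colour_key`, `bin_start`,
#'   `bin_end`, `frequency`.
#' @export
histogram_data <- function(wh, sets, property, bins = 20L, log_freq = FALSE,
                           relative = FALSE, min_length = 0, min_coverage = 0) {
  check_property(property)
  stopifnot(bins >= 1L)
  series <- series_members(wh, sets)
  values <- lapply(series, function(s) {
    if (length(s$ids) == 0L) return(double())
    props <- filter_props(contig_properties(wh, s$ids), min_length, min_coverage)
    v <- props[[property]]
    v[!is.na(v)]
  })
  pooled <- unlist(values)
  if (length(pooled) == 0L) {
    edges <- c(0, 1)
  } else if (min(pooled) == max(pooled)) {
    edges <- c(pooled[1] - 0.5, pooled[1] + 0.5)
  } else {
    edges <- seq(min(pooled), max(pooled), length.out = bins + 1L)
  }
  rows <- lapply(seq_along(series), function(k) {
    v <- values[[k]]
    counts <- if (length(v) == 0L) {
      rep(0, length(edges) - 1L)
    } else {
      graphics::hist(v, breaks = edges, plot = FALSE,
        include.lowest = TRUE, right = FALSE)$counts
    }
    freq <- if (relative && length(v) > 0L) counts / length(v) else counts
    tibble(
      set_label = series[[k]]$label, colour_key = k,
      bin_start = edges[-length(edges)], bin_end = edges[-1],
      frequency = as.double(freq)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "axes") <- list(property = property, log_freq = log_freq,
    relative = relative)
  attr(out, "filters") <- list(min_length = min_length, min_coverage = min_coverage)
  attr(out, "chart") <- "histogram"
  class(out) <- c("plot_series", class(out))
  out
}

#' Assembly summary record
#'
#' @param wh A warehouse.
#' @param assembly Assembly id or name.
#' @return One-row tibble: contig count, annotation count, contigs with at
#'   least one similarity / domain annotation, and length/GC distribution
#'   summaries.
#' @export
assembly_summary <- function(wh, assembly) {
  as_id <- resolve_ref(wh, "assemblies", assembly)
  ctg <- wh$contigs[wh$contigs$assembly_id == as_id, ]
  ann <- wh$annotations[wh$annotations$contig_id %in% ctg$id, ]
  lens <- nchar(ctg$sequence)
  gc <- gc_content(ctg$sequence)
  tibble(
    assembly_id = as_id,
    name = wh$assemblies$name[wh$assemblies$id == as_id],
    n_contigs = nrow(ctg),
    n_annotations = nrow(ann),
    n_with_similarity = length(unique(
      ann$contig_id[ann$source == "sequence_similarity"])),
    n_with_domain = length(unique(
      ann$contig_id[ann$source == "protein_domain"])),
    length_min = if (nrow(ctg)) min(lens) else NA_integer_,
    length_median = if (nrow(ctg)) stats::median(lens) else NA_real_,
    length_max = if (nrow(ctg)) max(lens) else NA_integer_,
    length_total = sum(lens),
    gc_mean = if (nrow(ctg)) mean(gc, na.rm = TRUE) else NA_real_
  )
}

#' Serialize a report or plot series to JSON
#'
#' @param x A `contig_report` or `plot_series`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
report_json <- function(x, path = NULL) {
  doc <- if (inherits(x, "plot_series")) {
    list(
      chart = attr(x, "chart"), axes = attr(x, "axes"),
      filters = attr(x, "filters"), data = as.data.frame(x)
    )
  } else {
    unclass(x)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
    na = "null", dataframe = "columns")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
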