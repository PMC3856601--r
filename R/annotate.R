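# Evidence -> stored annotations. Sequence-similarity hits keep only the
# top `max_hits` per contig (E-value order, bitscore then accession as tie
# breaks); protein-domain matches are stored in full. Re-ingesting evidence
# of the same source for a contig replaces rather than duplicates.

index_tokens_for <- function(annotation_id, contig_id, description) {
  toks <- unique(tokenize(description))
  if (length(toks) == 0L) return(NULL)
  tibble(token = toks, annotation_id = annotation_id, contig_id = contig_id)
}

drop_annotations <- function(wh, contig_ids, source) {
  drop <- wh$annotations$contig_id %in% contig_ids &
    wh$annotations$source == source
  drop_ids <- wh$annotations$id[drop]
  wh$annotations <- wh$annotations[!drop, ]
  wh$index <- wh$index[!wh$index$annotation_id %in% drop_ids, ]
  wh
}

#' Ingest BLAST similarity hits for an assembly
#'
#' For every query contig the hits are ordered by best E-value (ascending),
#' with bitscore (descending) then subject accession (lexicographic) as
#' deterministic tie breaks, and the first `max_hits` are stored as
#' `sequence_similarity` annotations with ranks `1..k`. The stored region is
#' the best HSP's query interval, clipped to the contig; the remaining HSPs
#' are kept on the annotation. Queries naming unknown contigs are collected
#' into a skipped-queries report and do not stop the ingest. The full-text
#' index is updated incrementally.
#'
#' @param wh A warehouse.
#' @param report A `parsed_blast` tibble from [parse_blast_xml()].
#' @param assembly Assembly id or name whose contig names resolve the
#'   report's query names.
#' @param max_hits Retention cap per contig (default 10, the number of most
#'   similar protein entries kept).
#' @return The modified warehouse; `last_ingest()` reports `n_stored` and
#'   `skipped_queries`.
#' @export
ingest_blast_hits <- function(wh, report, assembly, max_hits = 10L) {
  stopifnot(max_hits >= 1L)
  as_id <- resolve_ref(wh, "assemblies", assembly)
  ctg <- wh$contigs[wh$contigs$assembly_id == as_id, ]
  name_to_id <- stats::setNames(ctg$id, ctg$name)
  known <- report$query %in% names(name_to_id)
  skipped <- unique(report$query[!known])
  report <- report[known, ]

  touched <- unname(name_to_id[unique(report$query)])
  wh <- drop_annotations(wh, touched, "sequence_similarity")

  n_stored <- 0L
  new_rows <- list()
  new_index <- list()
  for (q in unique(report$query)) {
    cid <- unname(name_to_id[[q]])
    len <- nchar(wh$contigs$sequence[wh$contigs$id == cid])
    hits <- report[report$query == q, ]
    ord <- order(hits$best_evalue, -hits$bitscore, hits$subject_accession)
    hits <- hits[ord, ][seq_len(min(max_hits, nrow(hits))), ]
    for (k in seq_len(nrow(hits))) {
      r <- new_id(wh, "an"); wh <- r$wh
      hsps <- hits$hsps[[k]]
      best <- order(hsps$evalue, -hsps$bitscore)[1]
      start <- max(0L, hsps$start[best])
      end <- min(len, hsps$end[best])
      new_rows[[length(new_rows) + 1L]] <- tibble(
        id = r$id, contig_id = cid, source = "sequence_similarity",
        subject_accession = hits$subject_accession[k],
        description = hits$subject_description[k],
        start = start, end = end,
        evalue = hits$best_evalue[k], rank = k, hsps = list(hsps)
      )
      new_index[[length(new_index) + 1L]] <-
        index_tokens_for(r$id, cid, hits$subject_description[k])
      n_stored <- n_stored + 1L
    }
  }
  wh$annotations <- dplyr::bind_rows(wh$annotations, dplyr::bind_rows(new_rows))
  wh$index <- dplyr::bind_rows(wh$index, dplyr::bind_rows(new_index))
  message(sprintf(
    "stored %d similarity annotations (%d queries skipped)",
    n_stored, length(skipped)
  ))
  ingest_summary(wh, list(n_stored = n_stored, skipped_queries = skipped))
}

#' Ingest InterProScan domain features for an assembly
#'
#' All features are stored (no retention cap) as `protein_domain`
#' annotations. The searchable description concatenates the recognizer
#' application, the signature accession and the signature description;
#' score-free applications (e.g. Coils, Phobius) store no E-value. Regions
#' extending past the contig end are clipped with a warning; features on
#' unknown contigs are collected into a skipped-features report.
#'
#' @param wh A warehouse.
#' @param features A `parsed_domains` tibble from [parse_interproscan_gff3()].
#' @param assembly Assembly id or name.
#' @return The modified warehouse; `last_ingest()` reports `n_stored` and
#'   `skipped_features`.
#' @export
ingest_domain_features <- function(wh, features, assembly) {
  as_id <- resolve_ref(wh, "assemblies", assembly)
  ctg <- wh$contigs[wh$contigs$assembly_id == as_id, ]
  name_to_id <- stats::setNames(ctg$id, ctg$name)
  known <- features$target_contig %in% names(name_to_id)
  skipped <- features[!known, ]
  features <- features[known, ]

  touched <- unname(name_to_id[unique(features$target_contig)])
  wh <- drop_annotations(wh, touched, "protein_domain")

  new_rows <- list()
  new_index <- list()
  for (k in seq_len(nrow(features))) {
    cid <- unname(name_to_id[[features$target_contig[k]]])
    len <- nchar(wh$contigs$sequence[wh$contigs$id == cid])
    start <- max(0L, features$start[k])
    end <- features$end[k]
    if (end > len) {
      warning(sprintf(
        "feature %s on %s: end %d clipped to contig length %d",
        features$accession[k], features$target_contig[k], end, len
      ))
      end <- len
    }
    desc <- paste(
      features$source_application[k], features$accession[k],
      features$description[k]
    )
    r <- new_id(wh, "an"); wh <- r$wh
    new_rows[[length(new_rows) + 1L]] <- tibble(
      id = r$id, contig_id = cid, source = "protein_domain",
      subject_accession = features$accession[k], description = desc,
      start = start, end = as.integer(end),
      evalue = features$evalue[k], rank = NA_integer_, hsps = list(NULL)
    )
    new_index[[length(new_index) + 1L]] <- index_tokens_for(r$id, cid, desc)
  }
  wh$annotations <- dplyr::bind_rows(wh$annotations, dplyr::bind_rows(new_rows))
  wh$index <- dplyr::bind_rows(wh$index, dplyr::bind_rows(new_index))
  message(sprintf(
    "stored %d domain annotations (%d features skipped)",
    nrow(features), nrow(skipped)
  ))
  ingest_summary(wh, list(n_stored = nrow(features), skipped_features = skipped))
}

#' Define an external-tool adapter
#'
#' The warehouse never interprets annotation-tool internals: an adapter
#' supplies a command template (with `{input}` and `{output}` placeholders),
#' the output format tag, and a working directory. For tests and stubs a
#' plain R function `fun(input, output)` returning an exit status can stand
#' in for the command.
#'
#' @param command Shell command template, or `NULL` when `fun` is given.
#' @param format One of `"blast_xml"`, `"gff3"`.
#' @param workdir Working directory (default a session temp dir).
#' @param fun Optional R function used instead of the shell command.
#' @return A `tool_adapter` object.
#' @export
tool_adapter <- function(command = NULL, format = c("blast_xml", "gff3"),
                         workdir = NULL, fun = NULL) {
  format <- match.arg(format)
  if (is.null(command) && is.null(fun)) {
    cw_error("cw_bad_args", "adapter needs a command template or a function")
  }
  structure(
    list(command = command, format = format,
         workdir = workdir %||% tempfile("adapter"), fun = fun),
    class = "tool_adapter"
  )
}

#' Run an external annotation tool through its adapter
#'
#' Writes the contigs to FASTA, invokes the adapter, and parses its output
#' with the matching format reader. A nonzero exit or missing output file is
#' an annotation-stage failure carrying the tool's diagnostics; partial
#' output is never ingested. An empty contig batch returns empty evidence
#' without invoking the tool.
#'
#' @param adapter A [tool_adapter()].
#' @param contigs Tibble with `name` and `sequence` columns.
#' @return Parsed evidence (`parsed_blast` or `parsed_domains`).
#' @export
run_external_annotator <- function(adapter, contigs) {
  if (!inherits(adapter, "tool_adapter")) {
    cw_error("cw_feature_unavailable", "no annotation adapter available")
  }
  empty <- if (adapter$format == "blast_xml") {
    parse_empty_blast()
  } else {
    parse_empty_domains()
  }
  if (is.null(contigs) || nrow(contigs) == 0L) return(empty)
  dir.create(adapter$workdir, showWarnings = FALSE, recursive = TRUE)
  input <- file.path(adapter$workdir, "input.fasta")
  output <- file.path(adapter$workdir, paste0("output.", adapter$format))
  write_fasta(contigs, input)
  status <- if (!is.null(adapter$fun)) {
    adapter$fun(input, output)
  } else {
    cmd <- gsub("{output}", output,
      gsub("{input}", input, adapter$command, fixed = TRUE),
      fixed = TRUE
    )
    system(cmd)
  }
  if (!identical(as.integer(status), 0L) || !file.exists(output)) {
    cw_error("cw_annotation_failure", sprintf(
      "annotation tool failed (exit %s, output %s)",
      as.character(status), if (file.exists(output)) "present" else "missing"
    ))
  }
  if (adapter$format == "blast_xml") parse_blast_xml(output)
  else parse_interproscan_gff3(output)
}

parse_empty_blast <- function() {
  out <- tibble(
    query = character(), subject_accession = character(),
    subject_description = character(), best_evalue = double(),
    bitscore = double(), hsps = list()
  )
  class(out) <- c("parsed_blast", class(out))
  out
}

parse_empty_domains <- function() {
  out <- tibble(
    target_contig = character(), source_application = character(),
    accession = character(), description = character(),
    start = integer(), end = integer(), evalue = double()
  )
  class(out) <- c("parsed_domains", class(out))
  out
}
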