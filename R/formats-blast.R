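# NCBI BLAST XML reader (single- and multi-query BlastOutput/Iteration
# dialect), built on xml2. Query coordinates are normalized to the internal
# 0-based half-open convention with the HSP frame retained.

#' Parse an NCBI BLAST XML report
#'
#' Hits are grouped per query; each hit carries its best (minimum) HSP
#' E-value and the full HSP list. HSP query intervals are normalized so
#' `start < end` regardless of frame, then converted to 0-based half-open.
#' The subject id is the accession token and the subject description the
#' definition line, as UniProt BLAST reports carry them.
#'
#' @param path BLAST XML file, optionally gzip-compressed.
#' @return A tibble of class `parsed_blast` with columns `query`,
#'   `subject_accession`, `subject_description`, `best_evalue`, `bitscore`
#'   (of the best HSP) and `hsps`, a list-column of tibbles
#'   (`start`, `end`, `evalue`, `bitscore`, `frame`). A report with zero
#'   iterations yields a zero-row tibble.
#' @export
parse_blast_xml <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no such file: %s", sQuote(path)))
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) cw_error(
      "cw_parse_error",
      sprintf("not well-formed XML (%s): %s", sQuote(path), conditionMessage(e))
    )
  )
  iterations <- xml2::xml_find_all(doc, ".//Iteration")
  rows <- lapply(iterations, function(it) {
    qdef <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
    query <- strsplit(qdef, "\\s+")[[1]][1]
    hits <- xml2::xml_find_all(it, "./Iteration_hits/Hit")
    if (length(hits) == 0L) return(NULL)
    dplyr::bind_rows(lapply(hits, function(hit) {
      acc <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_accession"))
      def <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
      hsps <- xml2::xml_find_all(hit, "./Hit_hsps/Hsp")
      num <- function(node, field) {
        as.double(xml2::xml_text(xml2::xml_find_first(node, field)))
      }
      hsp_tbl <- dplyr::bind_rows(lapply(hsps, function(h) {
        from <- num(h, "./Hsp_query-from")
        to <- num(h, "./Hsp_query-to")
        tibble(
          start = as.integer(min(from, to)) - 1L,
          end = as.integer(max(from, to)),
          evalue = num(h, "./Hsp_evalue"),
          bitscore = num(h, "./Hsp_bit-score"),
          frame = as.integer(num(h, "./Hsp_query-frame"))
        )
      }))
      best <- order(hsp_tbl$evalue, -hsp_tbl$bitscore)[1]
      tibble(
        query = query, subject_accession = acc, subject_description = def,
        best_evalue = hsp_tbl$evalue[best], bitscore = hsp_tbl$bitscore[best],
        hsps = list(hsp_tbl)
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      query = character(), subject_accession = character(),
      subject_description = character(), best_evalue = double(),
      bitscore = double(), hsps = list()
    )
  }
  class(out) <- c("parsed_blast", class(out))
  out
}
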