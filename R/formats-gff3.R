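# InterProScan GFF3 reader. rtracklayer does the parse; a pre-scan
# enforces the 9-column contract so malformed lines are reported by number.

#' Parse InterProScan domain features from GFF3
#'
#' One feature per GFF3 feature line: the recognizer application (`source`
#' column, e.g. `PfamA`, `SMART`, `Coils`, `Phobius`), the signature
#' accession, a description taken from attribute keys in priority order
#' `signature_desc` > `Name` > `ID`, the feature interval on the contig
#' (converted to 0-based half-open) and the E-value from the score column
#' (absent — `.` — for score-free applications such as Coils).
#'
#' @param path GFF3 file with a `##gff-version` directive, optionally
#'   gzip-compressed.
#' @return A tibble of class `parsed_domains` with columns `target_contig`,
#'   `source_application`, `accession`, `description`, `start`, `end`,
#'   `evalue`.
#' @export
parse_interproscan_gff3 <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no such file: %s", sQuote(path)))
  }
  lines <- readLines(path, warn = FALSE)
  in_fasta <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "##FASTA")) in_fasta <- TRUE
    if (in_fasta || startsWith(line, "#") || !nzchar(trimws(line))) next
    nfields <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (nfields != 9L) {
      cw_error("cw_parse_error", sprintf(
        "line %d: %d columns where GFF3 requires 9", ln, nfields
      ))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  empty <- tibble(
    target_contig = character(), source_application = character(),
    accession = character(), description = character(),
    start = integer(), end = integer(), evalue = double()
  )
  if (length(gr) == 0L) {
    class(empty) <- c("parsed_domains", class(empty))
    return(empty)
  }
  m <- as.data.frame(gr)
  get_attr <- function(key) {
    if (key %in% names(m)) as.character(m[[key]]) else rep(NA_character_, nrow(m))
  }
  sig_desc <- get_attr("signature_desc")
  name <- get_attr("Name")
  id <- get_attr("ID")
  description <- dplyr::coalesce(sig_desc, name, id)
  accession <- dplyr::coalesce(name, id)
  out <- tibble(
    target_contig = as.character(m$seqnames),
    source_application = as.character(m$source),
    accession = accession,
    description = description,
    start = as.integer(m$start) - 1L,
    end = as.integer(m$end),
    evalue = if ("score" %in% names(m)) as.double(m$score) else NA_real_
  )
  class(out) <- c("parsed_domains", class(out))
  out
}
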