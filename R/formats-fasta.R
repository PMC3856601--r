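# FASTA / FASTQ readers and writers. Biostrings does the FASTA heavy
# lifting; FASTQ is parsed as the 4-line Sanger dialect so that malformed
# records can be reported by name. All readers accept gzip input
# transparently (R connections decompress on read; Biostrings natively).

#' Read a FASTA file of contigs
#'
#' Record names are the first whitespace-delimited token of the header;
#' sequences are uppercased. Zero-length sequences are rejected.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return A tibble with columns `name`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no such file: %s", sQuote(path)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) cw_error(
      "cw_parse_error",
      sprintf("malformed FASTA in %s: %s", sQuote(path), conditionMessage(e))
    )
  )
  if (length(set) == 0L) {
    cw_error("cw_parse_error", sprintf("empty FASTA file: %s", sQuote(path)))
  }
  names <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    bad <- names[widths == 0L][1]
    cw_error("cw_parse_error", sprintf(
      "record %s has a zero-length sequence", sQuote(bad)
    ))
  }
  tibble(name = names, sequence = unname(toupper(as.character(set))))
}

#' Write records to FASTA
#'
#' @param records Tibble with `name` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Sanger / Phred+33)
#'
#' Only the 4-line-per-record Sanger dialect with Phred+33 quality encoding
#' is accepted; quality characters outside the Phred+33 range `[0, 93]`
#' (i.e. outside `!`..`~`) are rejected rather than silently misread.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return A tibble with columns `name`, `sequence` and a `quality`
#'   list-column of integer PHRED vectors.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no such file: %s", sQuote(path)))
  }
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    cw_error("cw_parse_error", sprintf("empty FASTQ file: %s", sQuote(path)))
  }
  if (length(lines) %% 4L != 0L) {
    cw_error("cw_parse_error", sprintf(
      "truncated FASTQ record at end of %s", sQuote(path)
    ))
  }
  head_l <- lines[seq(1L, length(lines), by = 4L)]
  seq_l <- lines[seq(2L, length(lines), by = 4L)]
  plus_l <- lines[seq(3L, length(lines), by = 4L)]
  qual_l <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(head_l, "@")) || any(!startsWith(plus_l, "+"))) {
    bad <- which(!startsWith(head_l, "@") | !startsWith(plus_l, "+"))[1]
    cw_error("cw_parse_error", sprintf(
      "malformed FASTQ record %d in %s", bad, sQuote(path)
    ))
  }
  names <- vapply(strsplit(sub("^@", "", head_l), "\\s+"), `[`, character(1), 1L)
  bad_len <- nchar(qual_l) != nchar(seq_l)
  if (any(bad_len)) {
    cw_error("cw_parse_error", sprintf(
      "record %s: quality length %d != sequence length %d",
      sQuote(names[bad_len][1]), nchar(qual_l[bad_len][1]),
      nchar(seq_l[bad_len][1])
    ))
  }
  quality <- lapply(seq_along(qual_l), function(i) {
    q <- utf8ToInt(qual_l[i]) - 33L
    if (any(q < 0L | q > 93L)) {
      cw_error("cw_parse_error", sprintf(
        "record %s: quality characters outside the Phred+33 range",
        sQuote(names[i])
      ))
    }
    q
  })
  tibble(name = names, sequence = toupper(seq_l), quality = quality)
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records Tibble with `name`, `sequence` and integer `quality`
#'   list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(lengths(records$quality) == nchar(records$sequence)))
  qual <- vapply(
    records$quality,
    function(q) intToUtf8(as.integer(q) + 33L),
    character(1)
  )
  writeLines(
    as.vector(rbind(paste0("@", records$name), records$sequence, "+", qual)),
    path
  )
  invisible(path)
}
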