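# Per-contig numeric properties: per-base read coverage, GC content,
# length, length excluding undefined bases, mean PHRED quality.

# Per-base depth from 0-based half-open intervals via a difference array.
coverage_from_intervals <- function(starts, ends, length) {
  delta <- integer(length + 1L)
  for (j in seq_along(starts)) {
    s <- starts[j]; e <- ends[j]
    if (e > s) {
      delta[s + 1L] <- delta[s + 1L] + 1L
      delta[e + 1L] <- delta[e + 1L] - 1L
    }
  }
  cumsum(delta)[seq_len(length)]
}

#' Compute and store a contig's per-base coverage track
#'
#' Coverage at position `i` is the number of reads whose aligned span,
#' projected to unpadded coordinates and clipped to the contig, covers `i`.
#' A contig with no read mappings gets an all-zero track.
#'
#' @param wh A warehouse.
#' @param contig Contig id.
#' @return The modified warehouse with the track stored on the contig.
#' @export
compute_coverage <- function(wh, contig) {
  i <- match(contig, wh$contigs$id)
  if (is.na(i)) cw_error("cw_not_found", sprintf("no contig %s", sQuote(contig)))
  len <- nchar(wh$contigs$sequence[i])
  mp <- wh$read_mappings[wh$read_mappings$contig_id == contig, ]
  wh$contigs$coverage[[i]] <- coverage_from_intervals(mp$start, mp$end, len)
  wh
}

#' GC content of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; `N` and other ambiguity
#' characters are excluded from both numerator and denominator. A sequence
#' with no unambiguous base yields `NA`.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' gc_content(c("ATGC", "ATGN", "NNN"))
#' @export
gc_content <- function(sequence) {
  up <- toupper(sequence)
  gc <- stringr::str_count(up, "[GC]")
  at <- stringr::str_count(up, "[AT]")
  out <- gc / (gc + at)
  out[gc + at == 0L] <- NA_real_
  out
}

#' Mean PHRED quality of a contig
#'
#' Arithmetic mean of the per-base consensus quality track. Contigs without
#' a track (FASTA-only ingestion) yield `NA`, never zero.
#'
#' @param wh A warehouse.
#' @param contig Contig id.
#' @return A single numeric value or `NA`.
#' @export
mean_quality <- function(wh, contig) {
  i <- match(contig, wh$contigs$id)
  if (is.na(i)) cw_error("cw_not_found", sprintf("no contig %s", sQuote(contig)))
  q <- wh$contigs$quality[[i]]
  if (is.null(q)) NA_real_ else mean(q)
}

#' Per-contig property table
#'
#' Computes the five scatter/histogram axis properties for every contig (or
#' a subset): `length`, `ungapped_length` (bases excluding undefined `N`),
#' `gc`, `mean_coverage` and `mean_quality`. Coverage and quality means are
#' `NA` for contigs ingested without tracks.
#'
#' @param wh A warehouse.
#' @param contigs Optional character vector of contig ids (default: all).
#' @return A tibble with one row per contig: `contig_id`, `name`, `length`,
#'   `ungapped_length`, `gc`, `mean_coverage`, `mean_quality`.
#' @export
contig_properties <- function(wh, contigs = NULL) {
  tbl <- wh$contigs
  if (!is.null(contigs)) {
    missing <- setdiff(contigs, tbl$id)
    if (length(missing) > 0L) {
      cw_error("cw_not_found", sprintf("no contig %s", sQuote(missing[1])))
    }
    tbl <- tbl[match(contigs, tbl$id), ]
  }
  tibble(
    contig_id = tbl$id,
    name = tbl$name,
    length = nchar(tbl$sequence),
    ungapped_length = stringr::str_count(toupper(tbl$sequence), "[ACGT]"),
    gc = gc_content(tbl$sequence),
    mean_coverage = vapply(
      tbl$coverage, function(v) if (is.null(v)) NA_real_ else mean(v), double(1)
    ),
    mean_quality = vapply(
      tbl$quality, function(v) if (is.null(v)) NA_real_ else mean(v), double(1)
    )
  )
}

property_names <- function() {
  c("length", "ungapped_length", "gc", "mean_coverage", "mean_quality")
}
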