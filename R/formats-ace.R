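# Consed-style ACE assembly parser (AS / CO / BQ / AF / RD / QA subset).
# The consensus is kept padded ('*' pad characters) at parse time; helpers
# below remove pads and project padded intervals into unpadded coordinates.
# Internal convention everywhere: 0-based, half-open intervals.

#' Parse an ACE assembly file
#'
#' Reads the consed ACE dialect: `AS` (declared totals), `CO` (padded
#' consensus), `BQ` (per-base qualities for unpadded positions), `AF` (read
#' placements), `RD` (padded read sequences) and `QA` (aligned/clipped
#' region per read). Other record types (`BS`, `DS`, `CT{`, `RT{`, `WA{`)
#' are skipped with a warning. Declared totals are cross-checked against the
#' parsed content and per-contig `BQ` counts against the unpadded consensus
#' length.
#'
#' Coordinates in the returned read mappings are converted to the internal
#' convention: `padded_start` is the 0-based offset of the read on the
#' padded consensus (negative when the read overhangs the contig 5' end) and
#' `clip_start`/`clip_end` the 0-based half-open aligned span in padded read
#' coordinates (from `QA`, the whole read when `QA` is absent or unaligned).
#'
#' @param path ACE file, optionally gzip-compressed.
#' @return A list of class `parsed_ace` with elements `contigs` (tibble:
#'   `name`, `padded_consensus`, `base_qualities` list-column,
#'   `read_mappings` list-column of tibbles) and `declared_contigs`,
#'   `declared_reads`.
#' @export
parse_ace <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no such file: %s", sQuote(path)))
  }
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  declared_contigs <- NA_integer_
  declared_reads <- NA_integer_
  contigs <- list()
  cur <- NULL
  skipped <- character()

  finish_contig <- function(cur) {
    if (is.null(cur)) return(NULL)
    unpadded_len <- sum(strsplit(cur$consensus, "")[[1]] != "*")
    if (length(cur$bq) != unpadded_len) {
      cw_error("cw_integrity_error", sprintf(
        "contig %s: %d BQ values for %d unpadded consensus bases",
        sQuote(cur$name), length(cur$bq), unpadded_len
      ))
    }
    af <- if (length(cur$af) > 0L) {
      tibble(
        read_name = vapply(cur$af, `[[`, character(1), 1L),
        orient = vapply(cur$af, `[[`, character(1), 2L),
        pos = as.integer(vapply(cur$af, `[[`, character(1), 3L))
      )
    } else {
      tibble(read_name = character(), orient = character(), pos = integer())
    }
    rd_len <- cur$rd_len
    missing_rd <- setdiff(af$read_name, names(rd_len))
    if (length(missing_rd) > 0L) {
      cw_error("cw_integrity_error", sprintf(
        "contig %s: AF references read %s with no RD record",
        sQuote(cur$name), sQuote(missing_rd[1])
      ))
    }
    qa <- cur$qa
    clip <- lapply(af$read_name, function(rn) {
      len <- rd_len[[rn]]
      q <- qa[[rn]]
      if (is.null(q) || q[3] < 0L || q[4] < 0L) c(0L, len)
      else c(q[3] - 1L, q[4])
    })
    mappings <- tibble(
      read_name = af$read_name,
      strand = c("reverse", "forward")[2L - (af$orient == "C")],
      padded_start = af$pos - 1L,
      clip_start = vapply(clip, `[`, integer(1), 1L),
      clip_end = vapply(clip, `[`, integer(1), 2L)
    )
    if (anyDuplicated(mappings$read_name)) {
      cw_error("cw_integrity_error", sprintf(
        "contig %s: duplicate read name %s", sQuote(cur$name),
        sQuote(mappings$read_name[duplicated(mappings$read_name)][1])
      ))
    }
    tibble(
      name = cur$name, padded_consensus = cur$consensus,
      base_qualities = list(cur$bq), read_mappings = list(mappings)
    )
  }

  read_block <- function(start) {
    # sequence/number lines until blank line or EOF
    j <- start
    while (j <= n && nzchar(trimws(lines[j]))) j <- j + 1L
    txt <- if (j > start) lines[start:(j - 1L)] else character()
    list(text = txt, next_i = j)
  }

  while (i <= n) {
    line <- lines[i]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    key <- if (length(tok) > 0L) tok[1] else ""
    if (key == "AS") {
      declared_contigs <- as.integer(tok[2])
      declared_reads <- as.integer(tok[3])
      i <- i + 1L
    } else if (key == "CO") {
      contigs[[length(contigs) + 1L]] <- finish_contig(cur)
      blk <- read_block(i + 1L)
      cur <- list(
        name = tok[2], consensus = toupper(paste(blk$text, collapse = "")),
        bq = integer(), af = list(),
        rd_len = list(), qa = list(), last_rd = NULL
      )
      i <- blk$next_i
    } else if (key == "BQ") {
      if (is.null(cur)) cw_error("cw_parse_error", "BQ before any CO record")
      blk <- read_block(i + 1L)
      cur$bq <- as.integer(unlist(strsplit(trimws(blk$text), "\\s+")))
      i <- blk$next_i
    } else if (key == "AF") {
      if (is.null(cur)) cw_error("cw_parse_error", "AF before any CO record")
      cur$af[[length(cur$af) + 1L]] <- tok[2:4]
      i <- i + 1L
    } else if (key == "RD") {
      if (is.null(cur)) cw_error("cw_parse_error", "RD before any CO record")
      blk <- read_block(i + 1L)
      cur$rd_len[[tok[2]]] <- sum(nchar(blk$text))
      cur$last_rd <- tok[2]
      i <- blk$next_i
    } else if (key == "QA") {
      if (is.null(cur) || is.null(cur$last_rd)) {
        cw_error("cw_parse_error", "QA with no preceding RD record")
      }
      cur$qa[[cur$last_rd]] <- as.integer(tok[2:5])
      i <- i + 1L
    } else if (key %in% c("BS", "DS") || key == "") {
      i <- i + 1L
    } else if (key %in% c("CT{", "RT{", "WA{")) {
      if (!key %in% skipped) {
        warning(sprintf("skipping ACE record type %s", sQuote(sub("\\{$", "", key))))
        skipped <- c(skipped, key)
      }
      while (i <= n && trimws(lines[i]) != "}") i <- i + 1L
      i <- i + 1L
    } else {
      if (!key %in% skipped) {
        warning(sprintf("skipping unknown ACE record type %s", sQuote(key)))
        skipped <- c(skipped, key)
      }
      i <- i + 1L
    }
  }
  contigs[[length(contigs) + 1L]] <- finish_contig(cur)
  contig_tbl <- dplyr::bind_rows(contigs)

  n_reads <- sum(vapply(contig_tbl$read_mappings, nrow, integer(1)))
  if (!is.na(declared_contigs) && declared_contigs != nrow(contig_tbl)) {
    cw_error("cw_integrity_error", sprintf(
      "AS declares %d contigs but file holds %d",
      declared_contigs, nrow(contig_tbl)
    ))
  }
  if (!is.na(declared_reads) && declared_reads != n_reads) {
    cw_error("cw_integrity_error", sprintf(
      "AS declares %d reads but file holds %d placements",
      declared_reads, n_reads
    ))
  }
  structure(
    list(
      contigs = contig_tbl,
      declared_contigs = declared_contigs, declared_reads = declared_reads
    ),
    class = "parsed_ace"
  )
}

#' Remove pads from a padded consensus
#'
#' @param padded Padded consensus string (`*` pads).
#' @return List with `sequence` (unpadded, uppercase) and `prefix_nonpad`,
#'   an integer vector where `prefix_nonpad[p + 1]` is the number of non-pad
#'   consensus characters strictly before 0-based padded position `p`
#'   (length `nchar(padded) + 1`). This is the pad-map used to project
#'   padded intervals to unpadded coordinates.
#' @export
unpad_consensus <- function(padded) {
  chars <- strsplit(toupper(padded), "")[[1]]
  nonpad <- chars != "*"
  list(
    sequence = paste(chars[nonpad], collapse = ""),
    prefix_nonpad = c(0L, cumsum(as.integer(nonpad)))
  )
}

#' Project a padded-consensus interval to unpadded coordinates
#'
#' The interval is clipped to the consensus before projection, so read
#' placements overhanging either contig end land inside `[0, unpadded
#' length)`. A span covering only pads projects to an empty interval.
#'
#' @param start,end 0-based half-open interval on the padded consensus.
#' @param prefix_nonpad Pad-map from [unpad_consensus()].
#' @return Integer vector `c(start, end)` in unpadded coordinates.
#' @export
project_padded_interval <- function(start, end, prefix_nonpad) {
  L <- length(prefix_nonpad) - 1L
  s <- min(max(start, 0L), L)
  e <- min(max(end, 0L), L)
  if (e < s) e <- s
  c(prefix_nonpad[s + 1L], prefix_nonpad[e + 1L])
}
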