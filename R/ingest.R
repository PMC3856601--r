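# Ingestion: files -> warehouse rows. FASTA-only ingestion stores bare
# sequences (no coverage, quality or read-mapping data); ACE ingestion
# unpads the consensus, attaches per-base qualities, projects read
# placements to unpadded coordinates and stores the computed coverage track.

ingest_summary <- function(wh, summary) {
  attr(wh, "ingest_summary") <- summary
  wh
}

#' Last ingest summary
#'
#' @param wh A warehouse returned by an ingest function.
#' @return Named list of counts from the most recent ingest.
#' @export
last_ingest <- function(wh) attr(wh, "ingest_summary")

#' Ingest contigs from a FASTA file
#'
#' Contigs arrive as bare consensus sequences: no coverage, quality or read
#' mapping data is stored, and downstream properties and reports omit those
#' tracks.
#'
#' @param wh A warehouse.
#' @param assembly Assembly id or name.
#' @param path FASTA file, or a tibble from [read_fasta()].
#' @return The modified warehouse; `last_ingest()` reports `n_contigs`.
#' @export
ingest_fasta <- function(wh, assembly, path) {
  as_id <- resolve_ref(wh, "assemblies", assembly)
  records <- if (is.data.frame(path)) path else read_fasta(path)
  existing <- wh$contigs$name[wh$contigs$assembly_id == as_id]
  clash <- intersect(records$name, existing)
  if (length(clash) > 0L || anyDuplicated(records$name)) {
    cw_error("cw_name_conflict", sprintf(
      "contig name %s not unique within assembly",
      sQuote(c(clash, records$name[duplicated(records$name)])[1])
    ))
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- new_id(wh, "ct"); wh <- r$wh
    rows[[i]] <- tibble(
      id = r$id, assembly_id = as_id, name = records$name[i],
      sequence = records$sequence[i], quality = list(NULL),
      coverage = list(NULL)
    )
  }
  wh$contigs <- dplyr::bind_rows(wh$contigs, dplyr::bind_rows(rows))
  message(sprintf("ingested %d contigs into assembly %s", nrow(records), as_id))
  ingest_summary(wh, list(n_contigs = nrow(records)))
}

#' Ingest an assembly from an ACE file
#'
#' Stores for every contig the unpadded consensus, the per-base PHRED
#' quality track, read placements projected to unpadded coordinates
#' (overhanging reads clipped to the contig), and the per-base read coverage
#' track computed from those placements.
#'
#' @param wh A warehouse.
#' @param assembly Assembly id or name.
#' @param path ACE file, or a `parsed_ace` object from [parse_ace()].
#' @return The modified warehouse; `last_ingest()` reports `n_contigs` and
#'   `n_reads`.
#' @export
ingest_ace <- function(wh, assembly, path) {
  as_id <- resolve_ref(wh, "assemblies", assembly)
  parsed <- if (inherits(path, "parsed_ace")) path else parse_ace(path)
  ace <- parsed$contigs
  existing <- wh$contigs$name[wh$contigs$assembly_id == as_id]
  clash <- intersect(ace$name, existing)
  if (length(clash) > 0L) {
    cw_error("cw_name_conflict", sprintf(
      "contig name %s not unique within assembly", sQuote(clash[1])
    ))
  }
  n_reads <- 0L
  contig_rows <- vector("list", nrow(ace))
  mapping_rows <- vector("list", nrow(ace))
  for (i in seq_len(nrow(ace))) {
    un <- unpad_consensus(ace$padded_consensus[i])
    len <- nchar(un$sequence)
    if (len < 1L) {
      cw_error("cw_integrity_error", sprintf(
        "contig %s has an empty unpadded consensus", sQuote(ace$name[i])
      ))
    }
    bq <- ace$base_qualities[[i]]
    if (any(bq < 0L | bq > 93L)) {
      cw_error("cw_integrity_error", sprintf(
        "contig %s: PHRED quality outside [0, 93]", sQuote(ace$name[i])
      ))
    }
    mp <- ace$read_mappings[[i]]
    proj <- lapply(seq_len(nrow(mp)), function(j) {
      project_padded_interval(
        mp$padded_start[j] + mp$clip_start[j],
        mp$padded_start[j] + mp$clip_end[j],
        un$prefix_nonpad
      )
    })
    r <- new_id(wh, "ct"); wh <- r$wh
    contig_rows[[i]] <- tibble(
      id = r$id, assembly_id = as_id, name = ace$name[i],
      sequence = un$sequence, quality = list(bq), coverage = list(NULL)
    )
    mapping_rows[[i]] <- tibble(
      contig_id = r$id, read_name = mp$read_name, strand = mp$strand,
      padded_start = mp$padded_start, clip_start = mp$clip_start,
      clip_end = mp$clip_end,
      start = vapply(proj, `[`, integer(1), 1L),
      end = vapply(proj, `[`, integer(1), 2L)
    )
    n_reads <- n_reads + nrow(mp)
  }
  contig_tbl <- dplyr::bind_rows(contig_rows)
  wh$contigs <- dplyr::bind_rows(wh$contigs, contig_tbl)
  wh$read_mappings <- dplyr::bind_rows(
    wh$read_mappings, dplyr::bind_rows(mapping_rows)
  )
  for (id in contig_tbl$id) wh <- compute_coverage(wh, id)
  message(sprintf(
    "ingested %d contigs (%d read placements) into assembly %s",
    nrow(ace), n_reads, as_id
  ))
  ingest_summary(wh, list(n_contigs = nrow(ace), n_reads = n_reads))
}

#' Store raw reads for a sequencing run
#'
#' Reads are stored verbatim (no trimming or cleaning); the run's
#' `read_count` and store reference are updated.
#'
#' @param wh A warehouse.
#' @param run Run id or name.
#' @param path FASTQ file, or a tibble from [read_fastq()].
#' @return The modified warehouse; `last_ingest()` reports `n_reads`.
#' @export
ingest_reads <- function(wh, run, path) {
  run_id <- resolve_ref(wh, "runs", run)
  records <- if (is.data.frame(path)) path else read_fastq(path)
  wh$reads <- dplyr::bind_rows(wh$reads, tibble(
    run_id = run_id, name = records$name, sequence = records$sequence,
    quality = records$quality
  ))
  sel <- wh$runs$id == run_id
  wh$runs$read_count[sel] <- sum(wh$reads$run_id == run_id)
  wh$runs$read_store_ref[sel] <- paste0("reads:", run_id)
  ingest_summary(wh, list(n_reads = nrow(records)))
}
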