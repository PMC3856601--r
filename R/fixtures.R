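# Synthetic-fixture generator: toy assemblies (ACE + FASTA), BLAST XML and
# InterProScan GFF3 with machine-readable ground truth, so the whole
# pipeline is testable with no downloads. All randomness flows from one
# explicit seed (withr::with_seed isolates and restores RNG state), so a
# fixed seed reproduces byte-identical files.

wrap_lines <- function(s, width) {
  if (nchar(s) == 0L) return(character())
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

default_vocabulary <- function() {
  c(
    "60S ribosomal protein L7",
    "40S ribosomal protein S12",
    "ribosomal RNA processing protein",
    "serine threonine protein kinase",
    "receptor tyrosine kinase",
    "cytochrome c oxidase subunit 1",
    "heat shock protein 70",
    "ATP synthase subunit beta",
    "elongation factor 1 alpha",
    "tubulin beta chain",
    "collagen alpha 1 chain",
    "myosin heavy chain",
    "zinc finger protein 91",
    "ubiquitin conjugating enzyme E2",
    "hypothetical protein"
  )
}

#' Generate a synthetic assembly fixture (ACE + FASTA + truth)
#'
#' Random transcripts are generated, reads are tiled over them with random
#' starts and strands at the stated mean depth, pad characters are inserted
#' into the consensus (to exercise padded-to-unpadded projection), and
#' per-base qualities are drawn from `quality_range`. Roughly a third of
#' reads get small end clips recorded in their `QA` region. The ACE and
#' FASTA files are written alongside a ground-truth JSON; the truth records
#' every read placement (padded and projected unpadded) and the expected
#' coverage track computed by direct position counting over the placements.
#'
#' @param dir Output directory (created if needed).
#' @param n_contigs Number of contigs (>= 1).
#' @param length_range Inclusive transcript length range in bases.
#' @param mean_depth Mean read depth (0 allowed: contigs with no reads).
#' @param n_rate Fraction of consensus bases replaced by `N`.
#' @param pad_rate Expected pads per base inserted into the consensus.
#' @param read_length Read length in bases (capped at the contig length).
#' @param quality_range Inclusive PHRED quality range for consensus bases.
#' @param seed Integer seed; the same seed reproduces identical bytes.
#' @return List with `ace`, `fasta`, `truth_json` paths and `truth`, a list
#'   with per-contig `name`, `sequence`, `qualities`, `reads` (tibble) and
#'   `expected_coverage`.
#' @export
generate_assembly <- function(dir, n_contigs = 10L,
                              length_range = c(200L, 2000L),
                              mean_depth = 10, n_rate = 0.01,
                              pad_rate = 0.02, read_length = 100L,
                              quality_range = c(20L, 60L), seed = 1L) {
  if (n_contigs < 1L) cw_error("cw_bad_args", "n_contigs must be >= 1")
  if (length_range[1] > length_range[2]) {
    cw_error("cw_bad_args", "length_range must be c(min, max) with min <= max")
  }
  if (mean_depth < 0) cw_error("cw_bad_args", "mean_depth must be >= 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  truth <- withr::with_seed(seed, {
    lapply(seq_len(n_contigs), function(i) {
      len <- sample(length_range[1]:length_range[2], 1L)
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      n_pos <- which(stats::runif(len) < n_rate)
      chars[n_pos] <- "N"
      qualities <- sample(quality_range[1]:quality_range[2], len, replace = TRUE)

      padded <- chars
      n_pads <- stats::rbinom(1L, len, pad_rate)
      for (p in seq_len(n_pads)) {
        at <- sample(length(padded) + 1L, 1L)
        padded <- append(padded, "*", after = at - 1L)
      }
      nonpad <- padded != "*"
      # padded 0-based position of each unpadded 0-based position
      padded_of <- which(nonpad) - 1L
      upos_cum <- cumsum(nonpad)

      rl <- min(read_length, len)
      n_reads <- if (mean_depth == 0) 0L else
        max(1L, round(mean_depth * len / rl))
      reads <- if (n_reads == 0L) {
        tibble(
          read_name = character(), strand = character(),
          padded_start = integer(), padded_length = integer(),
          clip_start = integer(), clip_end = integer(),
          unpadded_start = integer(), unpadded_end = integer()
        )
      } else {
        rows <- lapply(seq_len(n_reads), function(j) {
          s0 <- sample(0:(len - rl), 1L)
          pstart <- padded_of[s0 + 1L]
          pend <- padded_of[s0 + rl] + 1L   # half-open, padded
          plen <- pend - pstart
          clip <- if (stats::runif(1) < 0.3 && plen > 8L) {
            c(sample(0:3, 1L), sample(0:3, 1L))
          } else {
            c(0L, 0L)
          }
          span <- (pstart + clip[1] + 1L):(pstart + plen - clip[2])
          covered <- span[nonpad[span]]
          u_start <- if (length(covered)) upos_cum[covered[1]] - 1L else 0L
          u_end <- if (length(covered)) upos_cum[covered[length(covered)]] else 0L
          tibble(
            read_name = sprintf("c%03d_r%04d", i, j),
            strand = sample(c("forward", "reverse"), 1L),
            padded_start = pstart, padded_length = plen,
            clip_start = clip[1], clip_end = plen - clip[2],
            unpadded_start = u_start, unpadded_end = u_end
          )
        })
        dplyr::bind_rows(rows)
      }

      expected <- integer(len)
      for (j in seq_len(nrow(reads))) {
        s <- reads$unpadded_start[j]; e <- reads$unpadded_end[j]
        if (e > s) {
          idx <- (s + 1L):e
          expected[idx] <- expected[idx] + 1L
        }
      }
      list(
        name = sprintf("contig%03d", i),
        sequence = paste(chars, collapse = ""),
        padded_consensus = paste(padded, collapse = ""),
        qualities = qualities, reads = reads, expected_coverage = expected
      )
    })
  })

  total_reads <- sum(vapply(truth, function(t) nrow(t$reads), integer(1)))
  blocks <- list(c(sprintf("AS %d %d", n_contigs, total_reads), ""))
  for (t in truth) {
    blocks[[length(blocks) + 1L]] <- c(
      sprintf("CO %s %d %d 0 U", t$name, nchar(t$padded_consensus),
        nrow(t$reads)),
      wrap_lines(t$padded_consensus, 50L), "",
      "BQ",
      vapply(
        wrap_lines(paste(t$qualities, collapse = " "), 60L),
        trimws, character(1), USE.NAMES = FALSE
      ), ""
    )
    rd <- t$reads
    if (nrow(rd) > 0L) {
      blocks[[length(blocks) + 1L]] <- c(sprintf(
        "AF %s %s %d", rd$read_name,
        ifelse(rd$strand == "reverse", "C", "U"), rd$padded_start + 1L
      ), "")
      read_blocks <- lapply(seq_len(nrow(rd)), function(j) {
        read_seq <- substr(
          t$padded_consensus, rd$padded_start[j] + 1L,
          rd$padded_start[j] + rd$padded_length[j]
        )
        c(
          sprintf("RD %s %d 0 0", rd$read_name[j], rd$padded_length[j]),
          wrap_lines(read_seq, 50L), "",
          sprintf("QA %d %d %d %d", rd$clip_start[j] + 1L, rd$clip_end[j],
            rd$clip_start[j] + 1L, rd$clip_end[j]),
          "DS CHROMAT_FILE: none PHD_FILE: none TIME: none", ""
        )
      })
      blocks[[length(blocks) + 1L]] <- unlist(read_blocks)
    }
  }
  ace <- file.path(dir, sprintf("assembly_seed%d.ace", seed))
  writeLines(unlist(blocks), ace)
  fasta <- file.path(dir, sprintf("assembly_seed%d.fasta", seed))
  write_fasta(tibble(
    name = vapply(truth, `[[`, character(1), "name"),
    sequence = vapply(truth, `[[`, character(1), "sequence")
  ), fasta)
  truth_json <- file.path(dir, sprintf("assembly_seed%d.truth.json", seed))
  jsonlite::write_json(
    lapply(truth, function(t) {
      t$reads <- as.list(t$reads); t
    }),
    truth_json, auto_unbox = TRUE, digits = NA
  )
  list(ace = ace, fasta = fasta, truth_json = truth_json, truth = truth)
}

#' Generate a synthetic BLAST XML report with ground truth
#'
#' Emulates a protein similarity report (translated contig queries vs a
#' protein reference database): well-formed NCBI BLAST XML, E-values
#' log-uniform over `evalue_range`, bitscores anti-correlated with E-value,
#' 1-3 HSPs per hit. Give some contigs more than ten hits to exercise the
#' retention rule downstream.
#'
#' @param path Output XML path.
#' @param contigs Tibble with `name` and `length` columns, or a character
#'   vector of names (length then defaults to 1000).
#' @param hits_per_contig Integer vector recycled over contigs.
#' @param vocabulary Description strings to draw from (non-empty).
#' @param evalue_range Log-uniform E-value range.
#' @param seed Integer seed.
#' @return List with `path` and `truth` (tibble: `query`,
#'   `subject_accession`, `subject_description`, `best_evalue`, `bitscore`,
#'   per-hit best-HSP `start`/`end`).
#' @export
generate_blast_xml <- function(path, contigs, hits_per_contig = 5L,
                               vocabulary = default_vocabulary(),
                               evalue_range = c(1e-50, 1e-3), seed = 1L) {
  if (length(vocabulary) == 0L) {
    cw_error("cw_bad_args", "vocabulary must be non-empty")
  }
  contigs <- normalize_contig_arg(contigs)
  n <- nrow(contigs)
  hits_n <- rep_len(as.integer(hits_per_contig), max(n, 1L))
  truth <- withr::with_seed(seed, {
    acc_counter <- 0L
    rows <- list()
    for (i in seq_len(n)) {
      for (k in seq_len(hits_n[i])) {
        acc_counter <- acc_counter + 1L
        ev <- 10^stats::runif(1, log10(evalue_range[1]), log10(evalue_range[2]))
        bit <- round(-log10(ev) * 2 + stats::runif(1, 0, 5), 1)
        len <- contigs$length[i]
        s <- sample(0:max(0L, len - 30L), 1L)
        e <- min(len, s + sample(30:300, 1L))
        n_hsp <- sample(1:3, 1L)
        rows[[length(rows) + 1L]] <- tibble(
          query = contigs$name[i],
          subject_accession = sprintf("Q%05d", acc_counter),
          subject_description = sample(vocabulary, 1L),
          best_evalue = ev, bitscore = bit,
          start = s, end = e, n_hsp = n_hsp
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(truth) == 0L) {
    truth <- tibble(
      query = character(), subject_accession = character(),
      subject_description = character(), best_evalue = double(),
      bitscore = double(), start = integer(), end = integer(),
      n_hsp = integer()
    )
  }

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\"?>",
    "<BlastOutput>",
    "  <BlastOutput_program>blastx</BlastOutput_program>",
    "  <BlastOutput_version>synthetic</BlastOutput_version>",
    "  <BlastOutput_db>synthetic-proteins</BlastOutput_db>",
    "  <BlastOutput_iterations>"
  )
  for (i in seq_len(n)) {
    hits <- if (is.null(truth) || nrow(truth) == 0L) {
      truth
    } else {
      truth[truth$query == contigs$name[i], ]
    }
    lines <- c(lines,
      "    <Iteration>",
      sprintf("      <Iteration_iter-num>%d</Iteration_iter-num>", i),
      sprintf("      <Iteration_query-def>%s</Iteration_query-def>",
        esc(contigs$name[i])),
      sprintf("      <Iteration_query-len>%d</Iteration_query-len>",
        contigs$length[i]),
      "      <Iteration_hits>"
    )
    for (k in seq_len(nrow(hits))) {
      h <- hits[k, ]
      hsp_block <- character()
      for (j in seq_len(h$n_hsp)) {
        # subsidiary HSPs are strictly worse than the first
        ev_j <- h$best_evalue * 10^(j - 1)
        bit_j <- h$bitscore - (j - 1) * 3
        hsp_block <- c(hsp_block,
          "          <Hsp>",
          sprintf("            <Hsp_num>%d</Hsp_num>", j),
          sprintf("            <Hsp_bit-score>%s</Hsp_bit-score>",
            format(bit_j, scientific = FALSE)),
          sprintf("            <Hsp_evalue>%s</Hsp_evalue>",
            format(ev_j, scientific = TRUE, digits = 6)),
          sprintf("            <Hsp_query-from>%d</Hsp_query-from>", h$start + 1L),
          sprintf("            <Hsp_query-to>%d</Hsp_query-to>", h$end),
          "            <Hsp_query-frame>1</Hsp_query-frame>",
          "          </Hsp>"
        )
      }
      lines <- c(lines,
        "        <Hit>",
        sprintf("          <Hit_num>%d</Hit_num>", k),
        sprintf("          <Hit_id>sp|%s|SYN</Hit_id>", h$subject_accession),
        sprintf("          <Hit_def>%s</Hit_def>", esc(h$subject_description)),
        sprintf("          <Hit_accession>%s</Hit_accession>",
          h$subject_accession),
        "          <Hit_len>500</Hit_len>",
        "          <Hit_hsps>",
        hsp_block,
        "          </Hit_hsps>",
        "        </Hit>"
      )
    }
    lines <- c(lines,
      "      </Iteration_hits>",
      "    </Iteration>"
    )
  }
  lines <- c(lines, "  </BlastOutput_iterations>", "</BlastOutput>")
  writeLines(lines, path)
  list(path = path, truth = truth)
}

# Accept a character vector of names, or a tibble with name and length
# (length derived from a sequence column when present, else 1000).
normalize_contig_arg <- function(contigs) {
  if (is.character(contigs)) {
    return(tibble(name = contigs, length = rep(1000L, length(contigs))))
  }
  stopifnot(is.data.frame(contigs), "name" %in% names(contigs))
  if (!"length" %in% names(contigs)) {
    contigs$length <- if ("sequence" %in% names(contigs)) {
      nchar(contigs$sequence)
    } else {
      rep(1000L, nrow(contigs))
    }
  }
  contigs
}

ipr_applications <- function() {
  tibble(
    application = c("PfamA", "SMART", "TIGRFAM", "ProDom", "Gene3d",
      "Coils", "Phobius"),
    scored = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

ipr_descriptions <- function() {
  c(
    "Protein kinase domain", "Zinc finger C2H2 type", "WD40 repeat",
    "Ankyrin repeat", "EGF like domain", "Ribosomal protein L7 domain",
    "Coiled coil region", "Transmembrane region", "SH3 domain",
    "Ras family GTPase domain"
  )
}

#' Generate a synthetic InterProScan GFF3 file with ground truth
#'
#' Emulates the domain-recognizer application mix (`PfamA`, `SMART`,
#' `TIGRFAM`, `ProDom`, `Gene3d` scored; `Coils`, `Phobius` score-free,
#' emitting `.` in the score column).
#'
#' @param path Output GFF3 path.
#' @param contigs Tibble with `name` and `length`, or a character vector.
#' @param features_per_contig Integer vector recycled over contigs (zero
#'   total features yields a header-only valid GFF3).
#' @param seed Integer seed.
#' @return List with `path` and `truth` (tibble: `target_contig`,
#'   `source_application`, `accession`, `description`, 0-based half-open
#'   `start`/`end`, `evalue` with `NA` for score-free applications).
#' @export
generate_interproscan_gff3 <- function(path, contigs, features_per_contig = 2L,
                                       seed = 1L) {
  contigs <- normalize_contig_arg(contigs)
  n <- nrow(contigs)
  apps <- ipr_applications()
  truth <- withr::with_seed(seed, {
    acc_counter <- 0L
    feat_n <- rep_len(as.integer(features_per_contig), max(n, 1L))
    rows <- list()
    for (i in seq_len(n)) {
      for (k in seq_len(feat_n[i])) {
        acc_counter <- acc_counter + 1L
        a <- sample(nrow(apps), 1L)
        len <- contigs$length[i]
        s <- sample(0:max(0L, len - 20L), 1L)
        e <- min(len, s + sample(20:200, 1L))
        rows[[length(rows) + 1L]] <- tibble(
          target_contig = contigs$name[i],
          source_application = apps$application[a],
          accession = sprintf("DM%05d", acc_counter),
          description = sample(ipr_descriptions(), 1L),
          start = s, end = e,
          evalue = if (apps$scored[a]) {
            10^stats::runif(1, -40, -3)
          } else {
            NA_real_
          }
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  lines <- "##gff-version 3"
  if (!is.null(truth) && nrow(truth) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(truth)), function(k) {
      t <- truth[k, ]
      sprintf(
        "%s\t%s\tprotein_match\t%d\t%d\t%s\t+\t.\tID=match%05d;Name=%s;signature_desc=%s",
        t$target_contig, t$source_application, t$start + 1L, t$end,
        if (is.na(t$evalue)) "." else format(t$evalue, scientific = TRUE, digits = 4),
        k, t$accession, t$description
      )
    }, character(1)))
  }
  writeLines(lines, path)
  if (is.null(truth) || nrow(truth) == 0L) {
    truth <- parse_empty_domains()
  }
  list(path = path, truth = truth)
}

#' Build a fully-populated fixture warehouse
#'
#' Convenience wrapper used by examples, tests and the demonstration
#' scripts: generates an assembly fixture plus BLAST and InterProScan
#' evidence, creates a one-study hierarchy, ingests everything and returns
#' both the warehouse and the fixture truths.
#'
#' @param dir Working directory for the fixture files.
#' @param seed Integer seed driving all generators.
#' @param n_contigs,mean_depth,length_range Passed to [generate_assembly()].
#' @param hits_per_contig,features_per_contig Passed to the evidence
#'   generators (recycled).
#' @return List: `wh` (the warehouse), `assembly` (fixture), `blast`
#'   (fixture), `domains` (fixture), `assembly_id`, `study_id`.
#' @export
fixture_warehouse <- function(dir = tempfile("fixturewh"), seed = 1L,
                              n_contigs = 20L, mean_depth = 8,
                              length_range = c(200L, 1200L),
                              hits_per_contig = c(0L, 3L, 15L, 6L, 1L),
                              features_per_contig = c(2L, 0L, 3L)) {
  fx <- generate_assembly(
    dir, n_contigs = n_contigs, length_range = length_range,
    mean_depth = mean_depth, seed = seed
  )
  contigs <- tibble(
    name = vapply(fx$truth, `[[`, character(1), "name"),
    length = vapply(fx$truth, function(t) nchar(t$sequence), integer(1))
  )
  bx <- generate_blast_xml(
    file.path(dir, "hits.xml"), contigs,
    hits_per_contig = hits_per_contig, seed = seed + 1L
  )
  gx <- generate_interproscan_gff3(
    file.path(dir, "domains.gff3"), contigs,
    features_per_contig = features_per_contig, seed = seed + 2L
  )
  wh <- warehouse()
  wh <- create_hierarchy(wh, list(
    name = "fixture-study",
    compound_samples = list(list(name = "fixture-cs", samples = list(
      list(name = "whole-organism")
    )))
  ))
  wh <- create_assembly(wh, "fixture-cs", "fixture-assembly", "synthetic")
  as_id <- attr(wh, "created_assembly_id")
  suppressMessages({
    wh <- ingest_ace(wh, as_id, fx$ace)
    wh <- ingest_blast_hits(wh, parse_blast_xml(bx$path), as_id)
    wh <- ingest_domain_features(wh, parse_interproscan_gff3(gx$path), as_id)
  })
  list(
    wh = wh, assembly = fx, blast = bx, domains = gx,
    assembly_id = as_id,
    study_id = wh$studies$id[wh$studies$name == "fixture-study"]
  )
}
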