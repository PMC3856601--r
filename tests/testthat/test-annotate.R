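mk_report <- function(rows) {
  out <- dplyr::bind_rows(rows)
  class(out) <- c("parsed_blast", class(out))
  out
}

hit_row <- function(query, acc, ev, bit = 50, desc = "some protein",
                    s = 0L, e = 30L) {
  tibble::tibble(
    query = query, subject_accession = acc, subject_description = desc,
    best_evalue = ev, bitscore = bit,
    hsps = list(tibble::tibble(start = s, end = e, evalue = ev,
      bitscore = bit, frame = 1L))
  )
}

test_that("only the ten most similar hits are retained, ranked by E-value", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("ACGT", 25)))
  evs <- 10^-(30:16)   # 15 hits, best first
  report <- mk_report(lapply(seq_along(evs), function(i) {
    hit_row("c1", sprintf("A%02d", i), evs[i])
  }))
  # present them in shuffled order; storage order must not depend on it
  wh <- quiet(ingest_blast_hits(wh, report[sample(15), ], "asm1"))
  ann <- wh$annotations
  expect_equal(nrow(ann), 10L)
  expect_equal(ann$rank, 1:10)
  expect_equal(ann$evalue, sort(evs)[1:10])
  expect_equal(ann$subject_accession[1], "A01")
})

test_that("fewer hits than the cap are all stored with consecutive ranks", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("ACGT", 25)))
  report <- mk_report(list(
    hit_row("c1", "X1", 1e-5), hit_row("c1", "X2", 1e-9),
    hit_row("c1", "X3", 1e-7)
  ))
  wh <- quiet(ingest_blast_hits(wh, report, "asm1"))
  expect_equal(nrow(wh$annotations), 3L)
  expect_equal(wh$annotations$subject_accession, c("X2", "X3", "X1"))
  expect_equal(wh$annotations$rank, 1:3)
})

test_that("E-value ties break by bitscore then accession, deterministically", {
  make <- function(order) {
    wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("ACGT", 25)))
    rows <- list(
      hit_row("c1", "B", 0, bit = 80),
      hit_row("c1", "C", 0, bit = 90),
      hit_row("c1", "A", 0, bit = 80)
    )
    wh <- quiet(ingest_blast_hits(wh, mk_report(rows[order]), "asm1"))
    wh$annotations$subject_accession
  }
  expect_equal(make(1:3), c("C", "A", "B"))
  expect_equal(make(3:1), c("C", "A", "B"))
})

test_that("re-ingesting the identical report replaces rather than duplicates", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("ACGT", 25)))
  report <- mk_report(list(hit_row("c1", "X1", 1e-5), hit_row("c1", "X2", 1e-9)))
  wh <- quiet(ingest_blast_hits(wh, report, "asm1"))
  first <- wh$annotations
  wh <- quiet(ingest_blast_hits(wh, report, "asm1"))
  expect_equal(nrow(wh$annotations), 2L)
  expect_equal(wh$annotations$subject_accession, first$subject_accession)
  expect_equal(wh$annotations$rank, first$rank)
  # index rows were replaced too, not accumulated
  expect_equal(anyDuplicated(wh$index[, c("token", "annotation_id")]), 0L)
})

test_that("unknown queries are skipped and reported, ingest continues", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("ACGT", 25)))
  report <- mk_report(list(hit_row("c1", "X1", 1e-5), hit_row("ghost", "X2", 1e-9)))
  wh <- quiet(ingest_blast_hits(wh, report, "asm1"))
  expect_equal(nrow(wh$annotations), 1L)
  expect_equal(last_ingest(wh)$skipped_queries, "ghost")
})

test_that("the similarity-hit region is the best HSP's interval, clipped", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = strrep("AC", 20)))
  hsps <- tibble::tibble(
    start = c(5L, 10L), end = c(20L, 60L),
    evalue = c(1e-3, 1e-12), bitscore = c(20, 70), frame = c(1L, 1L)
  )
  report <- mk_report(list(tibble::tibble(
    query = "c1", subject_accession = "X", subject_description = "d",
    best_evalue = 1e-12, bitscore = 70, hsps = list(hsps)
  )))
  wh <- quiet(ingest_blast_hits(wh, report, "asm1"))
  expect_equal(wh$annotations$start, 10L)
  expect_equal(wh$annotations$end, 40L)   # clipped to contig length
  expect_equal(nrow(wh$annotations$hsps[[1]]), 2L)  # subsidiary HSPs kept
})

test_that("all domain features are stored, score-free ones without E-value", {
  wh <- tiny_wh(tibble::tibble(
    name = c("c1", "c2", "c3"), sequence = rep(strrep("ACGT", 50), 3)
  ))
  feats <- tibble::tibble(
    target_contig = c("c1", "c1", "c1", "c2", "c2", "c3", "c3"),
    source_application = c("PfamA", "SMART", "Coils", "PfamA", "Phobius",
      "TIGRFAM", "Gene3d"),
    accession = sprintf("D%d", 1:7),
    description = c("Protein kinase domain", "SH3 domain",
      "Coiled coil region", "WD40 repeat", "Transmembrane region",
      "Ankyrin repeat", "EGF like domain"),
    start = rep(0L, 7), end = rep(50L, 7),
    evalue = c(1e-10, 1e-8, NA, 1e-20, NA, 1e-5, 1e-6)
  )
  class(feats) <- c("parsed_domains", class(feats))
  wh <- quiet(ingest_domain_features(wh, feats, "asm1"))
  ann <- wh$annotations
  expect_equal(nrow(ann), 7L)          # no top-k filtering for domains
  expect_true(all(ann$source == "protein_domain"))
  coils <- ann[grepl("Coils", ann$description), ]
  expect_true(is.na(coils$evalue))
  # description carries application, accession and signature text
  expect_match(ann$description[1], "PfamA")
  expect_match(ann$description[1], "D1")
})

test_that("domain regions beyond the contig end are clipped with a warning", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = "ACGTACGT"))
  feats <- tibble::tibble(
    target_contig = "c1", source_application = "PfamA", accession = "D1",
    description = "x", start = 2L, end = 999L, evalue = 1e-5
  )
  expect_warning(
    wh <- suppressMessages(ingest_domain_features(wh, feats, "asm1")),
    "clipped"
  )
  expect_equal(wh$annotations$end, 8L)
})

test_that("every contig keeps at most ten similarity annotations", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 41L, n_contigs = 12L,
    hits_per_contig = c(0L, 4L, 15L, 12L, 11L, 2L))
  counts <- table(fx$wh$annotations$contig_id[
    fx$wh$annotations$source == "sequence_similarity"])
  expect_true(all(counts <= 10L))
})

test_that("index completeness: stored description tokens are all findable", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 43L, n_contigs = 8L)
  wh <- fx$wh
  for (k in sample(nrow(wh$annotations), 20L)) {
    cid <- wh$annotations$contig_id[k]
    for (tok in tokenize(wh$annotations$description[k])) {
      expect_true(cid %in% wh$index$contig_id[wh$index$token == tok],
        info = tok)
    }
  }
})

test_that("external annotator adapters pass evidence through atomically", {
  contigs <- tibble::tibble(name = c("c1", "c2"), sequence = c("ACGT", "GGCC"))
  canned <- generate_blast_xml(withr::local_tempfile(fileext = ".xml"),
    contigs, hits_per_contig = 2L, seed = 5L)
  stub <- tool_adapter(format = "blast_xml", fun = function(input, output) {
    file.copy(canned$path, output); 0L
  })
  ev <- run_external_annotator(stub, contigs)
  direct <- parse_blast_xml(canned$path)
  expect_equal(as.data.frame(ev), as.data.frame(direct))

  # nonzero exit: failure, nothing usable returned
  boom <- tool_adapter(format = "blast_xml", fun = function(...) 2L)
  expect_error(run_external_annotator(boom, contigs),
    class = "cw_annotation_failure")

  # empty batch: no invocation, empty evidence
  poison <- tool_adapter(format = "gff3", fun = function(...) stop("no"))
  ev0 <- run_external_annotator(poison, contigs[0, ])
  expect_equal(nrow(ev0), 0L)
})
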