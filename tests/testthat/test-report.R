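test_that("FASTA-only contigs report without coverage or quality tracks", {
  wh <- tiny_wh(tibble::tibble(name = "c1", sequence = "ACGTACGT"))
  rep <- contig_report(wh, wh$contigs$id[1])
  expect_false("coverage" %in% names(rep$tracks))
  expect_false("quality" %in% names(rep$tracks))
  expect_true(all(c("scale", "similarity_hits", "domains", "read_mappings")
    %in% names(rep$tracks)))
  expect_equal(nrow(rep$tables), 0L)
})

test_that("ACE contigs report all five track slots in display order", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 51L, n_contigs = 5L)
  wh <- fx$wh
  cid <- wh$contigs$id[1]
  rep <- contig_report(wh, cid)
  expect_equal(
    names(rep$tracks),
    c("scale", "coverage", "quality", "similarity_hits", "domains",
      "read_mappings")
  )
  len <- rep$contig$length
  expect_length(rep$tracks$coverage, len)
  expect_length(rep$tracks$quality, len)
  # every interval lies inside the contig
  for (tr in c("similarity_hits", "domains", "read_mappings")) {
    tbl <- rep$tracks[[tr]]
    if (nrow(tbl)) {
      expect_true(all(tbl$start >= 0 & tbl$end <= len), info = tr)
    }
  }
  # annotation table rows == similarity + domain annotations, with URLs
  n_ann <- sum(wh$annotations$contig_id == cid)
  expect_equal(nrow(rep$tables), n_ann)
  expect_true(all(grepl("^https://", rep$tables$url)))
  expect_equal(nrow(tidy(rep)), n_ann)
})

test_that("scatter series conserve filtered point counts per set", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 53L, n_contigs = 12L)
  wh <- fx$wh
  sd <- scatter_data(wh, list(all = "all:fixture-assembly"),
    x = "gc", y = "mean_coverage")
  props <- contig_properties(wh)
  expect_equal(nrow(sd), sum(!is.na(props$gc) & !is.na(props$mean_coverage)))
  # every emitted contig id resolves
  for (cid in sd$contig_id[1:5]) {
    expect_equal(resolve(wh, cid)$kind, "contig")
  }
  # log axis excludes non-positive values instead of offsetting
  zero_cov <- props$contig_id[props$mean_coverage == 0]
  sdl <- scatter_data(wh, list(all = "all:fixture-assembly"),
    x = "gc", y = "mean_coverage", log_y = TRUE)
  expect_false(any(sdl$contig_id %in% zero_cov))
  expect_true(all(sdl$y > 0))
  # impossible length filter: empty series
  sde <- scatter_data(wh, list(all = "all:fixture-assembly"),
    x = "gc", y = "length", min_length = 10^7)
  expect_equal(nrow(sde), 0L)
  expect_error(scatter_data(wh, list("all:fixture-assembly"), "gc", "gc"),
    class = "cw_bad_property")
})

test_that("histograms share bin edges and conserve counts", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 57L, n_contigs = 14L)
  wh <- fx$wh
  sel <- search_annotations(wh, "ribosomal")
  wh <- save_set(wh, sel, "ribo")
  hd <- histogram_data(wh, list(ribo = "ribo", all = "all:fixture-assembly"),
    property = "length", bins = 8L)
  for (lbl in unique(hd$set_label)) {
    expect_equal(sum(hd$set_label == lbl), 8L)
  }
  # shared edges across sets
  edges_a <- hd$bin_start[hd$set_label == "ribo"]
  edges_b <- hd$bin_start[hd$set_label == "all"]
  expect_equal(edges_a, edges_b)
  # absolute counts sum to filtered set sizes
  expect_equal(sum(hd$frequency[hd$set_label == "all"]), nrow(wh$contigs))
  expect_equal(sum(hd$frequency[hd$set_label == "ribo"]), length(sel))

  hr <- histogram_data(wh, list(ribo = "ribo", all = "all:fixture-assembly"),
    property = "length", bins = 8L, relative = TRUE)
  for (lbl in unique(hr$set_label)) {
    expect_equal(sum(hr$frequency[hr$set_label == lbl]), 1.0, tolerance = 1e-9)
  }
})

test_that("degenerate all-identical values fall back to a single width-1 bin", {
  wh <- tiny_wh(tibble::tibble(
    name = c("c1", "c2", "c3"), sequence = rep(strrep("AC", 10), 3)
  ))
  hd <- histogram_data(wh, list("all:asm1"), property = "length", bins = 5L)
  expect_equal(nrow(hd), 1L)
  expect_equal(hd$bin_end - hd$bin_start, 1)
  expect_equal(hd$frequency, 3)
})

test_that("the ribosomal-vs-species comparison behaves like the worked example", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 59L, n_contigs = 16L)
  wh <- fx$wh
  ribo <- search_annotations(wh, "ribosomal")
  wh <- save_set(wh, ribo, "ribosomal-matches")
  sd <- scatter_data(
    wh, list(ribosomal = "ribosomal-matches", species = "all:fixture-study"),
    x = "gc", y = "mean_coverage", log_y = TRUE
  )
  ribo_pts <- sd$contig_id[sd$set_label == "ribosomal"]
  all_pts <- sd$contig_id[sd$set_label == "species"]
  expect_true(all(ribo_pts %in% all_pts))  # subset relation of memberships
  expect_equal(length(unique(sd$colour_key)), 2L)
})

test_that("assembly summaries match generator ground truth and persist", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 61L, n_contigs = 10L,
    hits_per_contig = c(3L, 0L), features_per_contig = c(1L, 0L))
  wh <- fx$wh
  s <- assembly_summary(wh, fx$assembly_id)
  expect_equal(s$n_contigs, 10L)
  with_sim <- unique(fx$blast$truth$query)
  expect_equal(s$n_with_similarity, length(with_sim))
  with_dom <- unique(fx$domains$truth$target_contig)
  expect_equal(s$n_with_domain, length(with_dom))
  expect_equal(
    s$n_annotations,
    nrow(fx$domains$truth) + sum(pmin(table(fx$blast$truth$query), 10L))
  )
  path <- withr::local_tempfile(fileext = ".json")
  warehouse_save(wh, path)
  expect_equal(assembly_summary(warehouse_load(path), fx$assembly_id), s)

  wh2 <- tiny_wh()
  s2 <- assembly_summary(wh2, "asm1")
  expect_equal(s2$n_contigs, 0L)
  expect_equal(s2$n_annotations, 0L)
})

test_that("autoplot renders series and reports; JSON serialization works", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 63L, n_contigs = 6L)
  wh <- fx$wh
  sd <- scatter_data(wh, list(all = "all:fixture-assembly"),
    x = "gc", y = "length")
  expect_s3_class(autoplot(sd), "ggplot")
  hd <- histogram_data(wh, list(all = "all:fixture-assembly"), "gc", bins = 6L)
  expect_s3_class(autoplot(hd), "ggplot")
  rep <- contig_report(wh, wh$contigs$id[1])
  expect_s3_class(autoplot(rep), "ggplot")
  parsed <- jsonlite::fromJSON(report_json(sd))
  expect_equal(parsed$chart, "scatter")
  expect_equal(length(parsed$data$contig_id), nrow(sd))
  parsed_rep <- jsonlite::fromJSON(report_json(rep))
  expect_equal(parsed_rep$contig$length, rep$contig$length)
})
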