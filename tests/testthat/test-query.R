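# A small warehouse with hand-planted annotations for exact search checks.
planted_wh <- function() {
  wh <- tiny_wh(tibble::tibble(
    name = sprintf("c%d", 1:6),
    sequence = c("ACGTACGT", "GGGGCCCC", "ATATATAT", "ACGT", "GCGCGC", "TTTTAA")
  ))
  descs <- list(
    c1 = c("60S ribosomal protein L7", "serine threonine kinase"),
    c2 = "40S ribosomal protein S12",
    c3 = "receptor tyrosine kinase",
    c4 = "heat shock protein 70",
    c5 = character(),
    c6 = "ribosomal RNA binding kinase receptor"
  )
  report <- dplyr::bind_rows(lapply(names(descs), function(nm) {
    ds <- descs[[nm]]
    if (length(ds) == 0L) return(NULL)
    tibble::tibble(
      query = nm, subject_accession = sprintf("%s_h%d", nm, seq_along(ds)),
      subject_description = ds, best_evalue = 1e-10, bitscore = 50,
      hsps = lapply(seq_along(ds), function(i) {
        tibble::tibble(start = 0L, end = 4L, evalue = 1e-10, bitscore = 50,
          frame = 1L)
      })
    )
  }))
  quiet(ingest_blast_hits(wh, report, "asm1"))
}

cids <- function(wh, names) wh$contigs$id[match(names, wh$contigs$name)]

test_that("query grammar: terms, operators, precedence, grouping", {
  ast <- parse_query("ribosomal")
  expect_equal(ast$op, "term")
  expect_equal(ast$token, "ribosom")

  ast2 <- parse_query("kinase NOT receptor")
  expect_equal(ast2$op, "and")
  expect_equal(ast2$children[[1]]$token, "kinas")
  expect_equal(ast2$children[[2]]$op, "not")
  expect_equal(ast2$children[[2]]$child$token, "receptor")

  # OR binds loosest: a OR b AND c == Or(a, And(b, c))
  ast3 <- parse_query("shock OR ribosomal AND kinase")
  expect_equal(ast3$op, "or")
  expect_equal(ast3$children[[2]]$op, "and")

  ast4 <- parse_query("(shock OR ribosomal) AND kinase")
  expect_equal(ast4$op, "and")
  expect_equal(ast4$children[[1]]$op, "or")

  # implicit AND between adjacent bare terms
  ast5 <- parse_query("ribosomal protein")
  expect_equal(ast5$op, "and")
})

test_that("malformed queries raise syntax errors with a position", {
  expect_error(parse_query("(kinase"), "unbalanced", class = "cw_query_syntax")
  expect_error(parse_query("kinase AND"), "dangling", class = "cw_query_syntax")
  expect_error(parse_query("AND kinase"), class = "cw_query_syntax")
  expect_error(parse_query(""), class = "cw_query_syntax")
  expect_error(parse_query("the of"), class = "cw_query_syntax")
})

test_that("search matches planted annotations exactly", {
  wh <- planted_wh()
  expect_setequal(
    search_annotations(wh, "ribosomal"), cids(wh, c("c1", "c2", "c6"))
  )
  expect_setequal(
    search_annotations(wh, "kinase NOT receptor"), cids(wh, "c1")
  )
  expect_setequal(
    search_annotations(wh, "shock OR ribosomal"),
    cids(wh, c("c1", "c2", "c4", "c6"))
  )
  # stemmed query variants hit the same contigs
  expect_setequal(
    search_annotations(wh, "ribosomes"), cids(wh, c("c1", "c2", "c6"))
  )
  expect_length(search_annotations(wh, "flagellum"), 0L)
})

test_that("NOT is the scope-relative complement and results stay in scope", {
  wh <- planted_wh()
  scope <- cids(wh, c("c1", "c2", "c3"))
  res <- search_annotations(wh, "NOT ribosomal", scope = scope)
  expect_setequal(res, setdiff(scope, search_annotations(wh, "ribosomal", scope)))
  expect_true(all(res %in% scope))
  # restricting to a named automatic set also bounds the result
  res2 <- search_annotations(wh, "kinase", scope = "all:asm1")
  expect_true(all(res2 %in% set_members(wh, "all:asm1")))
})

test_that("random boolean queries agree with the brute-force scan oracle", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 31L, n_contigs = 15L)
  wh <- fx$wh
  vocab <- unique(wh$index$token)
  scope_all <- wh$contigs$id
  set.seed(101)
  for (i in 1:30) {
    ast <- structure(random_ast(vocab, depth = 3L), class = "query_ast")
    scope <- if (i %% 3 == 0) sample(scope_all, 8L) else scope_all
    got <- search_annotations(wh, ast, scope = scope)
    want <- oracle_search(wh, ast, scope)
    expect_setequal(as.character(got), want)
    expect_true(all(got %in% scope))
  }
})

test_that("De Morgan: NOT (a OR b) == NOT a AND NOT b over any scope", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 33L, n_contigs = 10L)
  wh <- fx$wh
  vocab <- unique(wh$index$token)
  set.seed(55)
  for (i in 1:10) {
    a <- sample(vocab, 1); b <- sample(vocab, 1)
    lhs <- search_annotations(wh, sprintf("NOT (%s OR %s)", a, b))
    rhs <- search_annotations(wh, sprintf("NOT %s AND NOT %s", a, b))
    expect_setequal(as.character(lhs), as.character(rhs))
  }
})

test_that("search soundness: every returned contig satisfies the query", {
  wh <- planted_wh()
  for (q in c("ribosomal", "kinase NOT receptor", "protein AND ribosomal")) {
    got <- search_annotations(wh, q)
    want <- oracle_search(wh, parse_query(q), wh$contigs$id)
    expect_setequal(as.character(got), want)
  }
})

test_that("property search filters by closed ranges and excludes trackless contigs", {
  wh <- planted_wh()
  all_ids <- wh$contigs$id
  expect_setequal(search_properties(wh, list(gc = c(0, 1))), all_ids)
  expect_setequal(
    search_properties(wh, list(length = c(4, 4))), cids(wh, "c4")
  )
  # mean_coverage constrained: FASTA-only contigs (no track) are excluded
  expect_length(search_properties(wh, list(mean_coverage = c(0, Inf))), 0L)
  expect_error(search_properties(wh, list(bogus = c(0, 1))),
    "valid properties", class = "cw_bad_property")
  expect_error(search_properties(wh, list(gc = c(1, 0))),
    class = "cw_bad_property")
})

test_that("random property rectangles agree with a brute-force filter", {
  fx <- fixture_warehouse(withr::local_tempdir(), seed = 37L, n_contigs = 12L)
  wh <- fx$wh
  props <- contig_properties(wh)
  set.seed(77)
  for (i in 1:15) {
    lo <- runif(1, 0.2, 0.5); hi <- runif(1, 0.5, 0.8)
    lmin <- sample(200:600, 1)
    got <- search_properties(wh, list(gc = c(lo, hi), length = c(lmin, Inf)))
    want <- props$contig_id[!is.na(props$gc) & props$gc >= lo &
      props$gc <= hi & props$length >= lmin]
    expect_setequal(as.character(got), want)
  }
  # conjunction of ranges == intersection of individual searches
  got2 <- search_properties(wh, list(gc = c(0.4, 0.6), length = c(300, Inf)))
  inter <- combine_sets(wh,
    search_properties(wh, list(gc = c(0.4, 0.6))),
    search_properties(wh, list(length = c(300, Inf))),
    "intersection"
  )
  expect_setequal(as.character(got2), as.character(inter))
})

test_that("set algebra follows standard identities", {
  wh <- planted_wh()
  a <- search_annotations(wh, "ribosomal")
  b <- search_annotations(wh, "kinase")
  expect_setequal(as.character(combine_sets(wh, a, a, "intersection")),
    as.character(a))
  expect_length(combine_sets(wh, a, a, "difference"), 0L)
  u <- combine_sets(wh, a, b, "union")
  i <- combine_sets(wh, a, b, "intersection")
  expect_equal(length(u), length(a) + length(b) - length(i))
})

test_that("saved sets freeze membership and record provenance verbatim", {
  wh <- planted_wh()
  sel <- search_annotations(wh, "ribosomal")
  wh <- save_set(wh, sel, "ribo", provenance = "ribosomal")
  sid <- attr(wh, "created_set_id")
  expect_setequal(set_members(wh, sid), as.character(sel))
  expect_equal(wh$contig_sets$provenance[wh$contig_sets$id == sid], "ribosomal")

  # frozen: later ingest does not change the saved set
  wh <- quiet(ingest_fasta(wh, "asm1", tibble::tibble(
    name = "late", sequence = "ACGTGGCC"
  )))
  expect_setequal(set_members(wh, sid), as.character(sel))

  # empty saved set is valid; duplicate names conflict
  wh <- save_set(wh, character(), "none")
  expect_length(set_members(wh, "none"), 0L)
  expect_error(save_set(wh, sel, "ribo"), class = "cw_name_conflict")
})

test_that("export_set writes newline-delimited members", {
  wh <- planted_wh()
  sel <- search_annotations(wh, "ribosomal")
  path <- withr::local_tempfile()
  export_set(wh, sel, path)
  expect_setequal(readLines(path), c("c1", "c2", "c6"))
})

test_that("similarity search is pure delegation with explicit unavailability", {
  wh <- planted_wh()
  expect_error(
    similarity_search(wh, "ACGT", "blastn", adapter = NULL),
    class = "cw_feature_unavailable"
  )
  # empty scope: no invocation at all
  poison <- tool_adapter(fun = function(...) stop("must not run"),
    format = "blast_xml")
  res <- similarity_search(wh, "ACGT", "blastn", scope = character(),
    adapter = poison)
  expect_equal(nrow(res), 0L)

  # stub adapter returning a canned report whose subjects are scope contigs:
  # the ranked list must match the canned E-values exactly
  canned_hit <- function(num, acc, ev) c(
    "<Hit>", sprintf("<Hit_num>%d</Hit_num>", num),
    sprintf("<Hit_id>lcl|%s</Hit_id>", acc),
    sprintf("<Hit_def>%s</Hit_def>", acc),
    sprintf("<Hit_accession>%s</Hit_accession>", acc),
    "<Hit_len>10</Hit_len>", "<Hit_hsps><Hsp>",
    "<Hsp_bit-score>50</Hsp_bit-score>",
    sprintf("<Hsp_evalue>%s</Hsp_evalue>", ev),
    "<Hsp_query-from>1</Hsp_query-from>",
    "<Hsp_query-to>4</Hsp_query-to>",
    "<Hsp_query-frame>1</Hsp_query-frame>",
    "</Hsp></Hit_hsps>", "</Hit>"
  )
  stub <- tool_adapter(format = "blast_xml", fun = function(input, output) {
    writeLines(c(
      "<?xml version=\"1.0\"?>", "<BlastOutput>", "<BlastOutput_iterations>",
      "<Iteration>",
      "<Iteration_query-def>query</Iteration_query-def>",
      "<Iteration_hits>",
      canned_hit(1L, "c3", "1e-8"), canned_hit(2L, "c1", "1e-20"),
      "</Iteration_hits>", "</Iteration>",
      "</BlastOutput_iterations>", "</BlastOutput>"
    ), output)
    0L
  })
  res2 <- similarity_search(wh, "ACGT", "blastn", adapter = stub)
  expect_equal(res2$name, c("c1", "c3"))   # ranked by E-value
  expect_equal(res2$evalue, c(1e-20, 1e-8))
  expect_equal(res2$contig_id, cids(wh, c("c1", "c3")))

  # nonzero exit is an annotation-stage failure
  failing <- tool_adapter(fun = function(...) 1L, format = "blast_xml")
  expect_error(
    similarity_search(wh, "ACGT", "blastn", adapter = failing),
    class = "cw_annotation_failure"
  )
})
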