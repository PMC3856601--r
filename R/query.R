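# Boolean annotation search, property range search, contig-set algebra and
# similarity-search delegation. Query grammar: uppercase AND / OR / NOT are
# operators, parentheses group, precedence NOT > AND > OR, adjacent bare
# terms are joined by an implicit AND. Terms are normalized with the same
# tokenizer used at indexing time.

query_lex <- function(raw) {
  spaced <- gsub("\\)", " ) ", gsub("\\(", " ( ", raw))
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a boolean search string
#'
#' @param raw Search string, e.g. `"kinase NOT receptor"`,
#'   `"(60S OR 40S) AND ribosomal"`.
#' @return A `query_ast` (nested nodes `term`/`and`/`or`/`not`).
#' @export
parse_query <- function(raw) {
  toks <- query_lex(raw)
  if (length(toks) == 0L) {
    cw_error("cw_query_syntax", "empty query")
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek(); pos <<- pos + 1L; t
  }
  syntax_error <- function(msg) {
    cw_error("cw_query_syntax", sprintf("%s at token %d", msg, min(pos, length(toks))))
  }

  parse_or <- function() {
    left <- parse_and()
    children <- list(left)
    while (!is.na(peek()) && peek() == "OR") {
      take()
      children[[length(children) + 1L]] <- parse_and()
    }
    if (length(children) == 1L) left else list(op = "or", children = children)
  }
  parse_and <- function() {
    children <- list(parse_unary())
    repeat {
      nxt <- peek()
      if (is.na(nxt) || nxt %in% c("OR", ")")) break
      if (nxt == "AND") take()
      children[[length(children) + 1L]] <- parse_unary()
    }
    children <- children[!vapply(children, is.null, logical(1))]
    if (length(children) == 0L) syntax_error("term removed by normalization")
    if (length(children) == 1L) children[[1]]
    else list(op = "and", children = children)
  }
  parse_unary <- function() {
    nxt <- peek()
    if (is.na(nxt)) syntax_error("dangling operator")
    if (nxt == "NOT") {
      take()
      child <- parse_unary()
      if (is.null(child)) syntax_error("NOT with no operand")
      return(list(op = "not", child = child))
    }
    parse_primary()
  }
  parse_primary <- function() {
    nxt <- peek()
    if (is.na(nxt)) syntax_error("dangling operator")
    if (nxt == "(") {
      take()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") syntax_error("unbalanced parentheses")
      take()
      return(node)
    }
    if (nxt %in% c(")", "AND", "OR")) syntax_error("dangling operator")
    term <- take()
    norm <- tokenize(term)
    if (length(norm) == 0L) return(NULL)
    if (length(norm) == 1L) return(list(op = "term", token = norm))
    list(op = "and", children = lapply(norm, function(t) list(op = "term", token = t)))
  }

  ast <- parse_or()
  if (!is.na(peek())) syntax_error("unexpected token")
  if (is.null(ast)) cw_error("cw_query_syntax", "query empty after normalization")
  structure(ast, class = "query_ast")
}

#' @export
#' @method format query_ast
format.query_ast <- function(x, ...) {
  fmt <- function(node) {
    switch(node$op,
      term = node$token,
      not = paste0("NOT ", fmt(node$child)),
      and = paste0("(", paste(vapply(node$children, fmt, character(1)),
        collapse = " AND "), ")"),
      or = paste0("(", paste(vapply(node$children, fmt, character(1)),
        collapse = " OR "), ")")
    )
  }
  fmt(x)
}

#' @export
print.query_ast <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Resolve a scope argument to a character vector of contig ids.
# NULL -> all contigs; a set id/name -> its members; a selection/character
# vector -> itself (validated).
resolve_scope <- function(wh, scope) {
  if (is.null(scope)) return(wh$contigs$id)
  if (inherits(scope, "contig_selection")) return(as.character(scope))
  if (is.character(scope) && length(scope) == 1L &&
      (scope %in% wh$contig_sets$id || scope %in% wh$contig_sets$name)) {
    return(set_members(wh, scope))
  }
  scope <- as.character(scope)
  unknown <- setdiff(scope, wh$contigs$id)
  if (length(unknown) > 0L) {
    cw_error("cw_not_found", sprintf(
      "scope contains unknown contig id %s", sQuote(unknown[1])
    ))
  }
  scope
}

new_selection <- function(ids, provenance) {
  structure(unique(ids), class = "contig_selection", provenance = provenance)
}

#' @export
print.contig_selection <- function(x, ...) {
  cat(sprintf(
    "<contig selection> %d contigs (%s)\n", length(x),
    attr(x, "provenance") %||% "ad hoc"
  ))
  invisible(x)
}

eval_query_ast <- function(wh, node, scope_ids) {
  switch(node$op,
    term = intersect(
      scope_ids, wh$index$contig_id[wh$index$token == node$token]
    ),
    and = Reduce(intersect, lapply(node$children, eval_query_ast, wh = wh,
      scope_ids = scope_ids)),
    or = unique(unlist(lapply(node$children, eval_query_ast, wh = wh,
      scope_ids = scope_ids))),
    not = setdiff(scope_ids, eval_query_ast(wh, node$child, scope_ids)),
    cw_error("cw_internal", sprintf("unknown AST op %s", node$op))
  )
}

#' Search annotations with a boolean query
#'
#' A term matches the contigs (within the scope) that have at least one
#' annotation whose description contains the token; `AND` intersects,
#' `OR` unites, and `NOT` is the scope-relative complement, so the result
#' is always a subset of the scope.
#'
#' @param wh A warehouse.
#' @param query A query string or a parsed `query_ast`.
#' @param scope `NULL` for the whole warehouse, a contig-set id/name, or a
#'   character vector of contig ids.
#' @return An unsaved contig selection (character vector of contig ids with
#'   a provenance attribute); persist it with [save_set()].
#' @export
search_annotations <- function(wh, query, scope = NULL) {
  ast <- if (inherits(query, "query_ast")) query else parse_query(query)
  scope_ids <- resolve_scope(wh, scope)
  hits <- eval_query_ast(wh, ast, scope_ids)
  new_selection(hits, sprintf("annotation search: %s",
    if (is.character(query)) query else format(ast)))
}

#' Search contigs by property ranges
#'
#' Conjunction of closed-interval constraints over the per-contig
#' properties (`length`, `ungapped_length`, `gc`, `mean_coverage`,
#' `mean_quality`) — the programmatic form of selecting a scatter-plot
#' region. Contigs lacking a constrained property (e.g. no coverage track)
#' are excluded.
#'
#' @param wh A warehouse.
#' @param ranges Named list of `c(min, max)` vectors, e.g.
#'   `list(gc = c(0.3, 0.6), length = c(500, Inf))`.
#' @param scope As in [search_annotations()].
#' @return An unsaved contig selection.
#' @export
search_properties <- function(wh, ranges, scope = NULL) {
  bad <- setdiff(names(ranges), property_names())
  if (length(bad) > 0L || is.null(names(ranges))) {
    cw_error("cw_bad_property", sprintf(
      "unknown property %s; valid properties: %s",
      sQuote(if (length(bad)) bad[1] else "<unnamed>"),
      paste(property_names(), collapse = ", ")
    ))
  }
  scope_ids <- resolve_scope(wh, scope)
  if (length(scope_ids) == 0L) return(new_selection(character(), "property search"))
  props <- contig_properties(wh, scope_ids)
  keep <- rep(TRUE, nrow(props))
  for (p in names(ranges)) {
    rng <- ranges[[p]]
    if (length(rng) != 2L || rng[1] > rng[2]) {
      cw_error("cw_bad_property", sprintf("range for %s must be c(min, max)", p))
    }
    v <- props[[p]]
    keep <- keep & !is.na(v) & v >= rng[1] & v <= rng[2]
  }
  desc <- paste(vapply(names(ranges), function(p) {
    sprintf("%s in [%g, %g]", p, ranges[[p]][1], ranges[[p]][2])
  }, character(1)), collapse = " & ")
  new_selection(props$contig_id[keep], sprintf("property search: %s", desc))
}

#' Combine two contig sets
#'
#' @param wh A warehouse.
#' @param a,b Contig sets: set ids/names, saved or unsaved selections.
#' @param op `"union"`, `"intersection"` or `"difference"` (a minus b).
#' @return An unsaved contig selection.
#' @export
combine_sets <- function(wh, a, b, op = c("union", "intersection", "difference")) {
  op <- match.arg(op)
  ma <- resolve_scope(wh, a)
  mb <- resolve_scope(wh, b)
  ids <- switch(op,
    union = union(ma, mb),
    intersection = intersect(ma, mb),
    difference = setdiff(ma, mb)
  )
  new_selection(ids, sprintf("set %s", op))
}

#' Persist a search result as a named contig set
#'
#' Saved sets freeze their membership (a snapshot, so shared results never
#' drift); automatic per-assembly/compound-sample/study sets remain live.
#'
#' @param wh A warehouse.
#' @param members A contig selection or character vector of contig ids.
#' @param name Set name, unique within the warehouse.
#' @param provenance Free text recording the query that produced the set;
#'   defaults to the selection's own provenance.
#' @return The modified warehouse, with `attr(, "created_set_id")`.
#' @export
save_set <- function(wh, members, name, provenance = NULL) {
  check_unique_name(wh$contig_sets$name, name, "contig-set")
  ids <- unique(as.character(members))
  unknown <- setdiff(ids, wh$contigs$id)
  if (length(unknown) > 0L) {
    cw_error("cw_not_found", sprintf(
      "member %s is not a contig in this warehouse", sQuote(unknown[1])
    ))
  }
  provenance <- provenance %||% attr(members, "provenance") %||% ""
  r <- new_id(wh, "set"); wh <- r$wh
  wh$contig_sets <- dplyr::bind_rows(wh$contig_sets, tibble(
    id = r$id, name = name, description = "",
    provenance = provenance, kind = "saved", ref_id = NA_character_
  ))
  if (length(ids) > 0L) {
    wh$set_members <- dplyr::bind_rows(
      wh$set_members, tibble(set_id = r$id, contig_id = ids)
    )
  }
  attr(wh, "created_set_id") <- r$id
  wh
}

#' Export a contig set as a newline-delimited list
#'
#' @param wh A warehouse.
#' @param set Set id/name or a contig selection.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @param what `"id"` or `"name"`.
#' @return The lines, invisibly when written to a file.
#' @export
export_set <- function(wh, set, path = NULL, what = c("name", "id")) {
  what <- match.arg(what)
  ids <- resolve_scope(wh, set)
  out <- if (what == "id") ids else wh$contigs$name[match(ids, wh$contigs$id)]
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Similarity search over a contig set (delegated)
#'
#' Pure delegation to an external aligner: the scope contigs are written as
#' a temporary database, the adapter is invoked with the query sequence,
#' and the parsed hits are returned ranked by E-value. No native alignment
#' is performed. Without an adapter this raises a `cw_feature_unavailable`
#' condition; an empty scope returns an empty result without invocation.
#'
#' @param wh A warehouse.
#' @param sequence Query DNA or protein sequence.
#' @param program One of `"blastn"`, `"tblastn"`, `"tblastx"` (passed to the
#'   adapter command as `{program}`).
#' @param scope As in [search_annotations()].
#' @param adapter A [tool_adapter()] with format `"blast_xml"`, or `NULL`.
#' @return Tibble `contig_id`, `name`, `evalue`, ranked by E-value.
#' @export
similarity_search <- function(wh, sequence, program = c("blastn", "tblastn", "tblastx"),
                              scope = NULL, adapter = NULL) {
  program <- match.arg(program)
  if (!inherits(adapter, "tool_adapter")) {
    cw_error("cw_feature_unavailable",
      "similarity search requires an external aligner adapter")
  }
  scope_ids <- resolve_scope(wh, scope)
  if (length(scope_ids) == 0L) {
    return(tibble(contig_id = character(), name = character(), evalue = double()))
  }
  dir.create(adapter$workdir, showWarnings = FALSE, recursive = TRUE)
  db <- file.path(adapter$workdir, "db.fasta")
  ctg <- wh$contigs[match(scope_ids, wh$contigs$id), ]
  write_fasta(ctg[, c("name", "sequence")], db)
  input <- file.path(adapter$workdir, "query.fasta")
  writeLines(c(">query", sequence), input)
  output <- file.path(adapter$workdir, "hits.xml")
  status <- if (!is.null(adapter$fun)) {
    adapter$fun(input, output)
  } else {
    cmd <- adapter$command
    subs <- c(input = input, output = output, db = db, program = program)
    for (key in names(subs)) {
      cmd <- gsub(paste0("{", key, "}"), subs[[key]], cmd, fixed = TRUE)
    }
    system(cmd)
  }
  if (!identical(as.integer(status), 0L) || !file.exists(output)) {
    cw_error("cw_annotation_failure", "similarity search tool failed")
  }
  report <- parse_blast_xml(output)
  hits <- report[report$subject_accession %in% ctg$name |
    report$subject_description %in% ctg$name, ]
  nm <- ifelse(hits$subject_accession %in% ctg$name,
    hits$subject_accession, hits$subject_description)
  out <- tibble(
    contig_id = ctg$id[match(nm, ctg$name)],
    name = nm, evalue = hits$best_evalue
  )
  out[order(out$evalue), ]
}
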