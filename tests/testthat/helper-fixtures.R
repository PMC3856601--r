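# Shared builders and independent brute-force oracles. The oracles
# deliberately avoid the package's own fast paths: coverage by per-position
# counting, search by scanning every annotation's token list.

# A warehouse with one study/compound-sample/assembly and contigs given as
# a tibble(name, sequence).
tiny_wh <- function(contigs = NULL) {
  wh <- warehouse()
  wh <- create_hierarchy(wh, list(
    name = "study1",
    compound_samples = list(list(name = "cs1", samples = list(
      list(name = "s1", experiments = list(
        list(name = "e1", runs = list(list(name = "r1")))
      ))
    )))
  ))
  wh <- create_assembly(wh, "cs1", "asm1")
  if (!is.null(contigs)) {
    wh <- suppressMessages(ingest_fasta(wh, "asm1", contigs))
  }
  wh
}

asm_id <- function(wh) wh$assemblies$id[wh$assemblies$name == "asm1"]

# Brute-force per-base coverage: increment a counter for every
# (read, position) pair.
oracle_coverage <- function(starts, ends, len) {
  track <- integer(len)
  for (j in seq_along(starts)) {
    for (pos in seq_len(len) - 1L) {
      if (pos >= starts[j] && pos < ends[j]) {
        track[pos + 1L] <- track[pos + 1L] + 1L
      }
    }
  }
  track
}

# Brute-force boolean search: per contig, scan every annotation's token
# list and evaluate the AST directly.
oracle_search <- function(wh, ast, scope_ids) {
  ann_tokens <- lapply(scope_ids, function(cid) {
    descs <- wh$annotations$description[wh$annotations$contig_id == cid]
    lapply(descs, tokenize)
  })
  names(ann_tokens) <- scope_ids
  matches <- function(node, cid) {
    switch(node$op,
      term = any(vapply(ann_tokens[[cid]], function(toks) {
        node$token %in% toks
      }, logical(1))),
      and = all(vapply(node$children, matches, logical(1), cid = cid)),
      or = any(vapply(node$children, matches, logical(1), cid = cid)),
      not = !matches(node$child, cid)
    )
  }
  scope_ids[vapply(scope_ids, function(cid) matches(ast, cid), logical(1))]
}

# Random boolean AST over a token vocabulary, depth-limited.
random_ast <- function(vocab, depth = 3L) {
  if (depth <= 0L || runif(1) < 0.4) {
    return(list(op = "term", token = sample(vocab, 1L)))
  }
  op <- sample(c("and", "or", "not"), 1L)
  if (op == "not") {
    list(op = "not", child = random_ast(vocab, depth - 1L))
  } else {
    n <- sample(2:3, 1L)
    list(op = op, children = lapply(seq_len(n), function(i) {
      random_ast(vocab, depth - 1L)
    }))
  }
}

# Minimal hand-built ACE file; returns the path.
write_tiny_ace <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny.ace")
  writeLines(lines, path)
  path
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
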