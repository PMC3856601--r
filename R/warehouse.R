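#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
NULL

# Table prototypes. Every warehouse table is a tibble with exactly these
# columns; save/load coerces back to these types so round-trips are lossless.
wh_schemas <- function() {
  list(
    studies = tibble(
      id = character(), name = character(), description = character(),
      visibility = character()
    ),
    compound_samples = tibble(
      id = character(), study_id = character(), name = character()
    ),
    samples = tibble(
      id = character(), compound_sample_id = character(), name = character(),
      biological_source_notes = character()
    ),
    experiments = tibble(
      id = character(), sample_id = character(), name = character(),
      rna_prep = character(), sequencing_technology = character()
    ),
    runs = tibble(
      id = character(), experiment_id = character(), name = character(),
      read_count = integer(), read_store_ref = character()
    ),
    assemblies = tibble(
      id = character(), compound_sample_id = character(), name = character(),
      assembler_metadata = character()
    ),
    contigs = tibble(
      id = character(), assembly_id = character(), name = character(),
      sequence = character(), quality = list(), coverage = list()
    ),
    read_mappings = tibble(
      contig_id = character(), read_name = character(), strand = character(),
      padded_start = integer(), clip_start = integer(), clip_end = integer(),
      start = integer(), end = integer()
    ),
    annotations = tibble(
      id = character(), contig_id = character(), source = character(),
      subject_accession = character(), description = character(),
      start = integer(), end = integer(), evalue = double(), rank = integer(),
      hsps = list()
    ),
    contig_sets = tibble(
      id = character(), name = character(), description = character(),
      provenance = character(), kind = character(), ref_id = character()
    ),
    set_members = tibble(set_id = character(), contig_id = character()),
    reads = tibble(
      run_id = character(), name = character(), sequence = character(),
      quality = list()
    ),
    index = tibble(
      token = character(), annotation_id = character(), contig_id = character()
    )
  )
}

#' Create an empty contig warehouse
#'
#' A warehouse is the in-memory form of one data store: a set of linked
#' tables holding the raw-sequence hierarchy (study, compound sample, sample,
#' experiment, run), the assembled-sequence hierarchy (assembly, contig, read
#' mapping), annotations with their full-text index, and contig sets.
#' All accessors return tibbles; mutating verbs return a modified copy of the
#' warehouse, so calls chain with the pipe.
#'
#' @return A `warehouse` object.
#' @examples
#' wh <- warehouse()
#' wh <- create_hierarchy(wh, list(name = "demo", compound_samples = list(
#'   list(name = "cs1"))))
#' list_studies(wh, include_private = TRUE)
#' @export
warehouse <- function() {
  wh <- wh_schemas()
  wh$counter <- 0L
  class(wh) <- "warehouse"
  wh
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse>\n")
  cat(sprintf(
    "  %d studies, %d assemblies, %d contigs, %d annotations, %d contig sets\n",
    nrow(x$studies), nrow(x$assemblies), nrow(x$contigs),
    nrow(x$annotations), nrow(x$contig_sets)
  ))
  invisible(x)
}

# Warehouse-scoped opaque identifiers: a type prefix, a counter, and a short
# mixing suffix so ids from different warehouses rarely collide on merge.
# Deterministic (no global RNG).
new_id <- function(wh, prefix) {
  wh$counter <- wh$counter + 1L
  n <- wh$counter
  suffix <- sprintf("%04x", (n * 48271L + 11L) %% 65521L)
  list(wh = wh, id = sprintf("%s-%06d-%s", prefix, n, suffix))
}

id_prefixes <- c(
  studies = "st", compound_samples = "cs", samples = "sa",
  experiments = "ex", runs = "rn", assemblies = "as", contigs = "ct",
  annotations = "an", contig_sets = "set"
)

cw_error <- function(class, message, ...) {
  abort(message, class = c(class, "cw_error"), ...)
}

check_unique_name <- function(existing, name, level) {
  if (name %in% existing) {
    cw_error("cw_name_conflict", sprintf(
      "name %s already exists at this %s level", sQuote(name), level
    ))
  }
}

add_row_checked <- function(tbl, row) {
  dplyr::bind_rows(tbl, row)
}

#' Create a study hierarchy
#'
#' Builds one study and its nested compound samples, samples, experiments and
#' runs from a nested list description, assigning fresh stable identifiers
#' throughout. A study is a collection of related compound samples; each
#' compound sample groups the samples (separate biological RNA sources) whose
#' reads feed its assemblies; an experiment is one library preparation on a
#' sample and may contain several sequencing runs. Automatic contig sets are
#' created for the study and for each compound sample (they track member
#' contigs live as assemblies are ingested). New studies start `private`.
#'
#' @param wh A warehouse.
#' @param spec A nested list: `list(name =, description =, compound_samples =
#'   list(list(name =, samples = list(list(name =, biological_source_notes =,
#'   experiments = list(list(name =, rna_prep =, sequencing_technology =,
#'   runs = list(list(name =)))))))))`. All levels below `name` are optional.
#' @return The modified warehouse. The new study id is attached as
#'   `attr(, "created_study_id")` and printed tables can retrieve it via
#'   [list_studies()].
#' @export
create_hierarchy <- function(wh, spec) {
  stopifnot(inherits(wh, "warehouse"))
  name <- spec$name
  if (is.null(name) || !nzchar(name)) {
    cw_error("cw_bad_args", "study name must be non-empty")
  }
  check_unique_name(wh$studies$name, name, "study")
  r <- new_id(wh, "st"); wh <- r$wh; study_id <- r$id
  wh$studies <- add_row_checked(wh$studies, tibble(
    id = study_id, name = name,
    description = spec$description %||% "",
    visibility = "private"
  ))
  wh <- add_auto_set(wh, "study", study_id, name)

  cs_specs <- spec$compound_samples %||% list()
  cs_names <- character()
  for (cs in cs_specs) {
    if (is.null(cs$name) || !nzchar(cs$name)) {
      cw_error("cw_bad_args", "compound sample name must be non-empty")
    }
    check_unique_name(cs_names, cs$name, "compound-sample")
    cs_names <- c(cs_names, cs$name)
    r <- new_id(wh, "cs"); wh <- r$wh; cs_id <- r$id
    wh$compound_samples <- add_row_checked(wh$compound_samples, tibble(
      id = cs_id, study_id = study_id, name = cs$name
    ))
    wh <- add_auto_set(wh, "compound_sample", cs_id, cs$name)

    sa_names <- character()
    for (sa in cs$samples %||% list()) {
      if (is.null(sa$name) || !nzchar(sa$name)) {
        cw_error("cw_bad_args", "sample name must be non-empty")
      }
      check_unique_name(sa_names, sa$name, "sample")
      sa_names <- c(sa_names, sa$name)
      r <- new_id(wh, "sa"); wh <- r$wh; sa_id <- r$id
      wh$samples <- add_row_checked(wh$samples, tibble(
        id = sa_id, compound_sample_id = cs_id, name = sa$name,
        biological_source_notes = sa$biological_source_notes %||% ""
      ))

      ex_names <- character()
      for (ex in sa$experiments %||% list()) {
        if (is.null(ex$name) || !nzchar(ex$name)) {
          cw_error("cw_bad_args", "experiment name must be non-empty")
        }
        check_unique_name(ex_names, ex$name, "experiment")
        ex_names <- c(ex_names, ex$name)
        r <- new_id(wh, "ex"); wh <- r$wh; ex_id <- r$id
        wh$experiments <- add_row_checked(wh$experiments, tibble(
          id = ex_id, sample_id = sa_id, name = ex$name,
          rna_prep = ex$rna_prep %||% "",
          sequencing_technology = ex$sequencing_technology %||% ""
        ))

        rn_names <- character()
        for (rn in ex$runs %||% list()) {
          if (is.null(rn$name) || !nzchar(rn$name)) {
            cw_error("cw_bad_args", "run name must be non-empty")
          }
          check_unique_name(rn_names, rn$name, "run")
          rn_names <- c(rn_names, rn$name)
          r <- new_id(wh, "rn"); wh <- r$wh; rn_id <- r$id
          wh$runs <- add_row_checked(wh$runs, tibble(
            id = rn_id, experiment_id = ex_id, name = rn$name,
            read_count = 0L, read_store_ref = NA_character_
          ))
        }
      }
    }
  }
  attr(wh, "created_study_id") <- study_id
  wh
}

add_auto_set <- function(wh, kind, ref_id, name) {
  r <- new_id(wh, "set"); wh <- r$wh
  wh$contig_sets <- add_row_checked(wh$contig_sets, tibble(
    id = r$id, name = paste0("all:", name),
    description = sprintf("automatic set tracking %s %s", kind, sQuote(name)),
    provenance = sprintf("auto:%s:%s", kind, ref_id),
    kind = kind, ref_id = ref_id
  ))
  wh
}

#' Create an assembly under a compound sample
#'
#' Registers an (initially empty) assembly and its automatic live contig set.
#' Contigs are attached by the ingest functions ([ingest_fasta()],
#' [ingest_ace()]).
#'
#' @param wh A warehouse.
#' @param compound_sample Id or name of the owning compound sample.
#' @param name Assembly name, unique within the compound sample.
#' @param assembler_metadata Free-text provenance (assembler name/version).
#' @return The modified warehouse, with `attr(, "created_assembly_id")`.
#' @export
create_assembly <- function(wh, compound_sample, name, assembler_metadata = "") {
  cs_id <- resolve_ref(wh, "compound_samples", compound_sample)
  sibling <- wh$assemblies$name[wh$assemblies$compound_sample_id == cs_id]
  check_unique_name(sibling, name, "assembly")
  r <- new_id(wh, "as"); wh <- r$wh; as_id <- r$id
  wh$assemblies <- add_row_checked(wh$assemblies, tibble(
    id = as_id, compound_sample_id = cs_id, name = name,
    assembler_metadata = assembler_metadata
  ))
  wh <- add_auto_set(wh, "assembly", as_id, name)
  attr(wh, "created_assembly_id") <- as_id
  wh
}

# Resolve an entity reference (id or unique name) within one table.
resolve_ref <- function(wh, table, ref) {
  tbl <- wh[[table]]
  if (ref %in% tbl$id) return(ref)
  hit <- tbl$id[tbl$name == ref]
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L) {
    cw_error("cw_ambiguous", sprintf("name %s is ambiguous in %s", sQuote(ref), table))
  }
  cw_error("cw_not_found", sprintf("no %s with id or name %s", sub("s$", "", table), sQuote(ref)))
}

entity_tables <- function() {
  c("studies", "compound_samples", "samples", "experiments", "runs",
    "assemblies", "contigs", "annotations", "contig_sets")
}

#' Resolve a stable identifier to its entity
#'
#' Identifiers are warehouse-scoped and stable across save/load, so any
#' entity (study, compound sample, sample, experiment, run, assembly, contig,
#' annotation or contig set) can be retrieved by id alone.
#'
#' @param wh A warehouse.
#' @param id A stable identifier.
#' @return A list with `kind` (singular entity kind) and the entity fields;
#'   contigs additionally carry `quality`/`coverage` tracks and contig sets
#'   their current `members`.
#' @export
resolve <- function(wh, id) {
  stopifnot(inherits(wh, "warehouse"), is.character(id), length(id) == 1L)
  for (table in entity_tables()) {
    tbl <- wh[[table]]
    i <- match(id, tbl$id)
    if (!is.na(i)) {
      entity <- as.list(tbl[i, ])
      entity$quality <- entity$quality[[1]] %||% NULL
      entity$coverage <- entity$coverage[[1]] %||% NULL
      entity$hsps <- entity$hsps[[1]] %||% NULL
      entity <- entity[!vapply(entity, is.null, logical(1))]
      entity$kind <- sub("s$", "", sub("ies$", "y", table))
      if (table == "contig_sets") {
        entity$kind <- "contig_set"
        entity$members <- set_members(wh, id)
      }
      if (table == "contigs") {
        entity$read_mappings <-
          wh$read_mappings[wh$read_mappings$contig_id == id, ]
      }
      class(entity) <- "cw_entity"
      return(entity)
    }
  }
  cw_error("cw_not_found", sprintf("no entity with id %s", sQuote(id)))
}

#' @export
print.cw_entity <- function(x, ...) {
  cat(sprintf("<%s> %s (%s)\n", x$kind, x$name %||% "", x$id))
  invisible(x)
}

#' Set study visibility
#'
#' Datasets remain private until explicitly made public; listing excludes
#' private studies unless the owner flag is passed.
#'
#' @param wh A warehouse.
#' @param study Study id or name.
#' @param public `TRUE` to publish, `FALSE` to make private. Idempotent.
#' @return The modified warehouse.
#' @export
set_visibility <- function(wh, study, public = TRUE) {
  id <- resolve_ref(wh, "studies", study)
  wh$studies$visibility[wh$studies$id == id] <-
    if (isTRUE(public)) "public" else "private"
  wh
}

#' List studies in a warehouse
#'
#' @param wh A warehouse.
#' @param include_private Owner flag; when `FALSE` (default) private studies
#'   are excluded, mirroring a public listing.
#' @return A tibble of studies.
#' @export
list_studies <- function(wh, include_private = FALSE) {
  tbl <- wh$studies
  if (!include_private) tbl <- tbl[tbl$visibility == "public", ]
  tbl
}

#' Current members of a contig set
#'
#' Automatic sets (one per assembly, compound sample and study) are live:
#' membership is derived from the hierarchy at call time. Saved sets are
#' frozen snapshots.
#'
#' @param wh A warehouse.
#' @param set Contig-set id or name.
#' @return Character vector of member contig ids.
#' @export
set_members <- function(wh, set) {
  id <- resolve_ref(wh, "contig_sets", set)
  row <- wh$contig_sets[wh$contig_sets$id == id, ]
  switch(row$kind,
    saved = wh$set_members$contig_id[wh$set_members$set_id == id],
    assembly = wh$contigs$id[wh$contigs$assembly_id == row$ref_id],
    compound_sample = {
      as_ids <- wh$assemblies$id[wh$assemblies$compound_sample_id == row$ref_id]
      wh$contigs$id[wh$contigs$assembly_id %in% as_ids]
    },
    study = {
      cs_ids <- wh$compound_samples$id[wh$compound_samples$study_id == row$ref_id]
      as_ids <- wh$assemblies$id[wh$assemblies$compound_sample_id %in% cs_ids]
      wh$contigs$id[wh$contigs$assembly_id %in% as_ids]
    },
    cw_error("cw_internal", sprintf("unknown set kind %s", row$kind))
  )
}

#' List contig sets
#'
#' @param wh A warehouse.
#' @return A tibble of contig sets with a `size` column (live membership for
#'   automatic sets, frozen for saved ones).
#' @export
list_sets <- function(wh) {
  tbl <- wh$contig_sets
  tbl$size <- vapply(tbl$id, function(i) length(set_members(wh, i)), integer(1))
  tbl
}

#' Export a hierarchy node as a JSON-ready document
#'
#' @param wh A warehouse.
#' @param id Entity id.
#' @return A named list (ids, names, metadata, membership) suitable for
#'   `jsonlite::toJSON()`.
#' @export
export_node <- function(wh, id) {
  e <- resolve(wh, id)
  doc <- unclass(e)
  doc$sequence <- NULL
  children <- switch(e$kind,
    study = list(compound_samples = wh$compound_samples$id[
      wh$compound_samples$study_id == id]),
    compound_sample = list(
      samples = wh$samples$id[wh$samples$compound_sample_id == id],
      assemblies = wh$assemblies$id[wh$assemblies$compound_sample_id == id]
    ),
    sample = list(experiments = wh$experiments$id[wh$experiments$sample_id == id]),
    experiment = list(runs = wh$runs$id[wh$runs$experiment_id == id]),
    assembly = list(contigs = wh$contigs$id[wh$contigs$assembly_id == id]),
    contig = list(annotations = wh$annotations$id[wh$annotations$contig_id == id]),
    list()
  )
  doc$read_mappings <- if (!is.null(doc$read_mappings)) {
    as.list(doc$read_mappings)
  }
  c(doc[!vapply(doc, is.null, logical(1))], children)
}

#' Save a warehouse to disk
#'
#' One plain-text JSON document per warehouse; the write is atomic (temp file
#' then rename) and identifiers are stable across save/load.
#'
#' @param wh A warehouse.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
warehouse_save <- function(wh, path) {
  stopifnot(inherits(wh, "warehouse"))
  doc <- list(format = "contig-warehouse", version = 1L, counter = wh$counter)
  for (nm in names(wh_schemas())) {
    tbl <- wh[[nm]]
    cols <- lapply(tbl, function(col) {
      if (is.list(col)) lapply(col, function(v) v %||% NULL) else col
    })
    doc[[nm]] <- c(list(.nrow = nrow(tbl)), cols)
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Load a warehouse from disk
#'
#' @param path Path written by [warehouse_save()].
#' @return A warehouse.
#' @export
warehouse_load <- function(path) {
  if (!file.exists(path)) {
    cw_error("cw_not_found", sprintf("no warehouse file at %s", sQuote(path)))
  }
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "contig-warehouse")) {
    cw_error("cw_parse_error", sprintf("%s is not a warehouse file", sQuote(path)))
  }
  wh <- warehouse()
  wh$counter <- as.integer(doc$counter)
  for (nm in names(wh_schemas())) {
    proto <- wh_schemas()[[nm]]
    stored <- doc[[nm]]
    n <- as.integer(stored$.nrow %||% 0L)
    cols <- lapply(names(proto), function(cn) {
      col <- stored[[cn]]
      if (is.list(proto[[cn]])) {
        if (n == 0L) return(list())
        if (cn == "hsps") {
          lapply(col, function(v) {
            if (is.null(v) || length(v) == 0L) return(NULL)
            dplyr::bind_rows(lapply(v, function(row) {
              tibble(
                start = as.integer(row$start), end = as.integer(row$end),
                evalue = as.double(row$evalue), bitscore = as.double(row$bitscore),
                frame = as.integer(row$frame %||% NA)
              )
            }))
          })
        } else {
          lapply(col, function(v) if (is.null(v)) NULL else as.integer(unlist(v)))
        }
      } else {
        if (n == 0L) return(proto[[cn]])
        # a one-row table stores scalars; a fully-null column reads as NULL
        if (is.null(col)) col <- vector("list", n)
        if (n == 1L && !is.list(col)) col <- list(col)
        v <- unlist(lapply(col, function(x) x %||% NA), use.names = FALSE)
        mode_fun <- switch(class(proto[[cn]])[1],
          character = as.character, integer = as.integer, numeric = as.double
        )
        mode_fun(v)
      }
    })
    names(cols) <- names(proto)
    wh[[nm]] <- as_tibble(cols)
  }
  wh
}
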