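---
title: "Methods: the contig warehouse model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the contig warehouse model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigwarehouse)
```

## The data model

A warehouse holds two overlapping hierarchies. The raw-sequence side
mirrors how sequencing projects are organized: a *study* collects
*compound samples* (one organism or project axis), each of which groups
*samples* (separate biological RNA sources), *experiments* (one library
preparation, with its RNA prep and sequencing technology) and *runs* (one
sequencing run, whose reads are stored verbatim — read cleaning is an
external-tool concern). The assembled side hangs *assemblies* off compound
samples, and *contigs* off assemblies; a contig carries its unpadded
consensus sequence, optional per-base quality and coverage tracks, its read
placements, and its annotations. *Contig sets* are the only many-to-many
link: a contig may belong to any number of named sets.

Identifiers are warehouse-scoped opaque strings (type prefix, counter,
mixing suffix) rather than integers, so exported documents and merged
warehouses do not collide, and every entity can be retrieved by id alone
with `resolve()`. Persistence is a single JSON document per warehouse,
written atomically (temp file, then rename); identifiers and all table
content are stable across `warehouse_save()`/`warehouse_load()`. A
relational embedded store would serve equally; a single text document keeps
local deployment dependency-free and diffable.

One open modelling question was whether a sample's reads may feed
assemblies in other compound samples. We take the hierarchy at face value:
assemblies belong to exactly one compound sample, and read/assembly
provenance below that level is free text.

Studies start `private` and are excluded from listings until explicitly
published — the single visibility flag is the whole access-control model
(no user accounts).

## Coordinates and the pad map

Assemblers emit a *padded* consensus in ACE files: `*` characters mark
alignment gaps, and read placements (`AF`), read sequences (`RD`) and
aligned regions (`QA`) are all expressed in padded coordinates, 1-based and
inclusive. Internally everything is converted at the parser boundary to one
convention: **0-based, half-open intervals on the unpadded consensus**.
`unpad_consensus()` retains a prefix-count pad map (`prefix_nonpad[p + 1]` =
non-pad characters strictly before padded position `p`), and
`project_padded_interval()` clips a padded interval to the consensus and
projects it. Reads overhanging either contig end (a negative `AF` start is
legal) are clipped to `[0, length)`; a span covering only pads projects to
an empty interval and contributes nothing. BLAST and GFF3 1-based inclusive
`[s, e]` intervals become `[s - 1, e)` at parse time; writing back inverts
the shift.

The parser accepts the consed-standard record subset `AS`, `CO`, `BQ`,
`AF`, `RD`, `QA`. `BS` base segments and `DS` descriptors carry nothing we
store and are skipped silently; tag blocks (`CT{`, `RT{`, `WA{`) and any
unknown record types are skipped with a warning rather than rejected, since
assemblers vary in which optional records they emit. Integrity is enforced
where it matters: `BQ` count must equal the unpadded length, every `AF`
must have its `RD`, and the `AS` totals must match the parsed content.

## Coverage and contig properties

Coverage at unpadded position $i$ is the number of reads whose aligned span
covers $i$, where the aligned span is the `QA`-clipped region when present
and the whole read otherwise (aligned-region coverage is what assembly
viewers display). The implementation accumulates interval endpoints in a
difference array and takes the cumulative sum; the test suite and the
acceptance script re-derive every fixture track with a deliberately naive
per-(read, position) counter and require equality at every position, plus
the conservation law `sum(track) == sum of clipped span lengths`.

The five plot/search properties per contig are `length`,
`ungapped_length` (bases excluding undefined `N`), `gc` (computed over
unambiguous bases only, `NA` when none), `mean_coverage` and
`mean_quality`. Quality is the consensus `BQ` track in PHRED units
($q = -10 \log_{10} p_{err}$), bounded to $[0, 93]$; the per-contig scalar
used on plot axes is the arithmetic mean of the track, the natural choice
when each contig is one point. Contigs ingested from FASTA have no tracks:
their coverage and quality are *absent* (`NA`), never zero, and reports
omit those panels entirely.

## Annotation retention

Sequence-similarity evidence is filtered to the `max_hits = 10` most
similar subjects per contig. "Most similar" is E-value ascending; because
synthetic and real reports both contain exact ties (E-value 0 is common),
the order is made total with bitscore (descending) then subject accession
(lexicographic), so stored ranks are identical regardless of input order.
The stored region is the best HSP's query interval (one bar per hit in the
overview); the remaining HSPs stay attached to the annotation as subsidiary
intervals. Each XML `Hit` element is one retention candidate — we do not
deduplicate subjects across hits, matching what the report states.

Domain matches are stored in full, with no cap: the searchable description
concatenates the recognizer application, signature accession and signature
description, and score-free applications (Coils, Phobius) store no E-value.
Regions past the contig end are clipped with a warning (translated-domain
coordinates off-by-slightly are routine); features naming unknown contigs
go into a skipped-record report and never abort an ingest.

Re-ingesting evidence of the same source for a contig *replaces* the prior
annotations (and their index rows), so re-running an annotation pipeline is
idempotent rather than additive.

## Text search

Indexing and querying share a single normalization: lowercase, split on
non-alphanumeric characters, drop a fixed English stopword list (~130
function words), then stem with the Porter (1980) algorithm, implemented in
full in the package. Two deliberate choices:

- Tokens containing digits (`60s`, `l7`, `hsp70`) pass through unstemmed.
  Porter's consonant/vowel rules are defined only for letters, and
  stripping the `s` from `60s` would conflate a ribosomal-subunit name with
  the number 60.
- The stopword list and stemmer are fixed and documented rather than
  configurable; token-level parity with any particular database's full-text
  engine is a non-goal — the observable contract is that morphological
  variants (`ribosomal`/`ribosome`, `binding`/`binds`) collapse to one
  token.

The query grammar gives `NOT` the highest precedence, then `AND`, then
`OR`; parentheses group; adjacent bare terms are joined by an implicit
`AND` (the behaviour users expect from web search boxes). A term matches
the contigs having at least one annotation whose description contains the
token. `NOT` is the *scope-relative* complement: an unscoped complement
would be unbounded, so a bare `NOT x` is evaluated against the search's
scope set, and every result is a subset of its scope by construction. The
evaluator works on an inverted token → contig index maintained
incrementally at ingest; tests compare it against a naive evaluator that
rescans every annotation, over randomly generated ASTs, and check the
De Morgan identity as a property.

Saved sets freeze their membership — a shared result must not drift as more
data arrives — while the automatic per-assembly/compound-sample/study sets
stay live and always equal the hierarchy's current contigs.

## Plot data

Scatter and histogram structures are pure data (tibbles plus an axis/filter
spec), JSON-serializable for any renderer; `autoplot()` is a thin ggplot2
layer. Log axes use log10 and **exclude** non-positive values rather than
offsetting them — offsets silently distort, exclusion is visible in the
point counts. Histograms compute shared bin edges from the pooled filtered
range of all sets so overlays are comparable (the pooled-range policy also
covers sets with disjoint ranges); when every pooled value is identical the
fallback is a single width-1 bin centred on the value. With
`relative = TRUE` each set's counts are divided by its filtered size, so
frequencies sum to 1 per non-empty set; absolute counts sum to the filtered
set size.

## The synthetic-fixture generator

`generate_assembly()`, `generate_blast_xml()` and
`generate_interproscan_gff3()` produce standard-format files together with
machine-readable ground truth, so every downstream computation can be
checked against planted values without downloads. Defaults describe a small
but structurally complete EST-style assembly: contig lengths 200–2,000 bp,
mean read depth ~10 with 100 bp reads, 1% undefined bases, ~2% consensus
pad rate, consensus qualities uniform in PHRED 20–60, about a third of
reads carrying small QA end-clips; BLAST E-values log-uniform over
$[10^{-50}, 10^{-3}]$ with bitscores anti-correlated, 1–3 HSPs per hit and
some contigs given more than ten hits so the retention rule is exercised;
domain features drawn from the real recognizer application mix including
the score-free ones. The description vocabulary includes "ribosomal", so
the saved-set comparison scenario (search, save, scatter of GC against log
coverage for the matching set versus the whole study) is reproducible end
to end.

All randomness flows from one explicit seed through an isolated RNG state
(`withr::with_seed`), so a fixed seed reproduces byte-identical files and
the generators never perturb the session RNG. What the fixtures do *not*
emulate: sequencing error models, chimeric contigs, realistic coverage
autocorrelation, or assembler-specific quirks beyond the record subset
above — so green tests demonstrate the correctness of parsing, projection,
counting, retention, search and reporting logic, not robustness to
pathological real-world files.

## Problem sizes and tolerances

The default verification sizes are chosen to finish in minutes on one CPU
while still exercising every code path at meaningful scale: coverage
equivalence over 50 contigs spanning depths 0–30 with pads injected; search
equivalence over 200 contigs carrying 1,000 annotations, against 50 random
boolean queries of depth ≤ 4; round trips over 8-contig assemblies with
~370 read placements. Equality checks are exact (integer tracks, set
membership); the only tolerances in use are $10^{-9}$ on relative
histogram sums and a $10^{-4}$ relative tolerance on E-values that pass
through XML text with six significant digits.

## Limitations

- Similarity search over a contig set is pure delegation to an external
  aligner adapter; without one it reports `cw_feature_unavailable`. No
  native alignment is implemented, and adapters are stubbed in tests.
- Text search returns sets, not ranked matches; no phrase queries or fuzzy
  matching.
- SAM/BAM read mappings, ACE tag records, GO/KEGG mapping and ORF calling
  are out of scope.
- The single-file JSON store is designed for the tens-of-thousands-of-
  contigs scale of typical de novo transcriptomes on a laptop; it loads
  eagerly and is single-writer.
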