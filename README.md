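# contigwarehouse

A searchable, set-oriented warehouse for assembled transcriptome contigs.

After a de novo transcriptome assembly, a biologist working on a non-model
organism typically holds a FASTA or ACE file of contigs, a BLASTX report
against a protein reference database, and an InterProScan domain scan — and
no genome database to browse them in. `contigwarehouse` turns those files
into a structured local resource that can be searched, sliced into named
contig sets, and summarized graphically:

- **Ingestion** of FASTA contigs, consed-style ACE assemblies (padded
  consensus `*`, per-base `BQ` qualities, `AF`/`RD`/`QA` read placements),
  FASTQ reads (Phred+33), NCBI BLAST XML and InterProScan GFF3. All readers
  accept gzip input and convert to one internal convention: 0-based,
  half-open intervals on the unpadded consensus.
- **Per-base coverage** computed from read placements: the coverage at
  position *i* is the number of reads whose QA-clipped aligned span,
  projected from padded to unpadded coordinates, covers *i*. Per-contig
  properties are length, length excluding undefined bases, GC content
  (G+C)/(A+C+G+T), mean coverage and mean PHRED quality.
- **Annotation retention**: for each contig the 10 most similar protein hits
  (E-value ascending, bitscore and accession as tie-breaks) are stored with
  ranks 1–10; all protein-domain matches are stored, E-value-free
  recognizers (Coils, Phobius) included.
- **Boolean full-text search** over annotation descriptions with uppercase
  `AND`/`OR`/`NOT` operators, parentheses, implicit AND between bare terms,
  English stopword removal and Porter stemming, evaluated against an
  inverted token index. Property-range search and contig-set algebra
  (union/intersection/difference) compose with it; results can be saved as
  frozen named sets, while per-assembly/sample/study sets stay live.
- **Reports and plot data**: a per-contig overview (scale bar, coverage,
  quality, similarity hits, domains, read mappings plus annotation tables
  with UniProt/InterPro links) and renderer-agnostic scatter/histogram
  series for contig-set comparison, with `autoplot()` methods.
- A **synthetic-fixture generator** (toy assemblies and annotation evidence
  with machine-readable ground truth) and a **CLI** tying the workflows
  together.

## Worked example

```r
library(contigwarehouse)

fx <- fixture_warehouse(tempfile("demo"), seed = 42, n_contigs = 20)
wh <- fx$wh
glance(wh)
#> # A tibble: 1 × 7
#>   n_studies n_assemblies n_contigs n_annotations n_contig_sets n_indexed_tokens
#> 1         1            1        20           112             3               93

ribo <- search_annotations(wh, "ribosomal NOT mitochondrial")
ribo
#> <contig selection> 13 contigs (annotation search: ribosomal NOT mitochondrial)

wh <- save_set(wh, ribo, "ribosomal-matches")
long_ribo <- combine_sets(wh, ribo,
  search_properties(wh, list(length = c(500, Inf))), "intersection")
length(long_ribo)
#> [1] 10

sd <- scatter_data(wh, list(ribosomal = "ribosomal-matches",
  species = "all:fixture-study"), x = "gc", y = "mean_coverage", log_y = TRUE)
dplyr::count(tibble::as_tibble(sd), set_label)
#> # A tibble: 2 × 2
#>   set_label     n
#> 1 ribosomal    13
#> 2 species      20
autoplot(sd)   # one point per contig, one colour per set, log10 y axis
```

The 20-contig fixture carries 112 stored annotations (the 10-hit retention
cap applied to the planted 15-hit contigs, plus all domain matches); 13
contigs match `ribosomal NOT mitochondrial`, 10 of them at least 500 bp
long; the scatter series hold one point per set member with positive
coverage, so the `ribosomal` series is a subset of the `species` series.

The same workflows run from the shell:

```sh
CLI=$(Rscript -e 'cat(contigwarehouse::cli_path())')
Rscript $CLI init   --warehouse wh.json --study demo --compound-sample cs1
Rscript $CLI ingest --warehouse wh.json --assembly asm1 \
    --compound-sample cs1 --ace assembly.ace
Rscript $CLI annotate-import --warehouse wh.json --assembly asm1 \
    --blast-xml hits.xml --gff3 domains.gff3
Rscript $CLI search --warehouse wh.json --query "kinase NOT receptor" \
    --save kinases --names
Rscript $CLI plotdata --warehouse wh.json --sets kinases,all:asm1 \
    --chart scatter --x gc --y mean_coverage --log-y --out scatter.json
```

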