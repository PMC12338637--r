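# foldannot

Structure-informed functional annotation of phage proteins from FoldSeek
hit tables.

Most proteins encoded on phage genomes carry no informative label — the
"viral dark matter". Because structure is conserved longer than sequence,
searching *predicted* structures of unannotated proteins against structure
databases (PDB, AlphaFold database, the Phold phage databases) with
FoldSeek recovers function where sequence search fails. This package
implements everything downstream of the searches, for bioinformaticians
post-processing such screens:

* readers/writers for the formats involved: FASTA, the 15-column FoldSeek
  tab format (`query, target, fident, alnlen, mismatch, gapopen, qstart,
  qend, tstart, tend, evalue, bits, prob, lddt, lddtfull`), PDB/mmCIF
  structures carrying per-residue pLDDT in the B-factor field, A3M
  alignments, MMseqs2 cluster tables, annotation and identifier-map tables;
* dataset curation: unannotated-name detection, the 100–850 aa size
  window, exact-sequence deduplication, and the split of cluster
  representatives into sequence-annotated vs *truly unannotated*;
* structure QC: mean pLDDT, per-position MSA depth, the depth-10
  tipping-point contrast, and binned/resampled length–pLDDT correlations;
* two-stage hit filtering — significance (E < 0.001) then quality
  (alignment lDDT > 0.5, aligned-query mean pLDDT > 70, same-SCOP-class
  probability > 0.5, all strict) — and canonical bitscore sorting;
* four annotation-transfer policies per database — best hit (BH), best
  annotated hit (BAH), tier-preferring best annotated hit (BAH_3T), and
  UniProt-supplemented best annotated hit (BAH_UP) — under a three-tier
  label classification (HIGH / LOW / NONE), plus multi-database joint
  calls and UpSet-style complementarity accounting;
* one-sided Mann–Whitney U contrasts (exact for small tie-free samples)
  and r² correlation summaries for the report;
* a synthetic-data generator, `simulate_bundle()`, that writes a complete
  input bundle with a ground-truth manifest from which `expected_report()`
  derives every report number in closed form — the whole pipeline is
  validated by exact equality against it.

## Worked example

Simulate a 500-cluster study bundle and run the full pipeline on the files
it wrote:

```r
library(foldannot)

dir <- file.path(tempdir(), "bundle")
man <- simulate_bundle(simulation_config(n_clusters = 500, seed = 3), dir)
rep <- run_pipeline(dir)
identical(rep, expected_report(man))
#> [1] TRUE
rep
#> Structure-informed annotation report
#>   500 clusters (1845 proteins); 365 truly unannotated, 135 sequence-annotated
#>   mean per-protein pLDDT 76.84 +/- 15.21; median MSA depth 71
#>   hit presence (truly unannotated): PDB 9.0%, AFDB 47.1%, PHOLD 66.0%; any database 80.0% of clusters (91.9% of proteins)
#>   BAH     AFDB 16.2%, JOINT 32.3%, PDB 4.9%, PHOLD 18.4%
#>   BAH_3T  AFDB 16.2%, JOINT 32.3%, PDB 4.9%, PHOLD 18.4%
#>   BAH_UP  AFDB 21.9%, JOINT 35.6%, PDB 4.9%, PHOLD 18.4%
#>   BH      AFDB 5.2%, JOINT 16.2%, PDB 4.9%, PHOLD 7.7%
```

Reading the output: of 500 protein clusters, 135 (27%) already receive an
informative sequence-based annotation; the remaining 365 are truly
unannotated. Among those, 9% / 47% / 66% have at least one significant
structural match in the PDB / AlphaFold / Phold databases. The best-hit
policy annotates few clusters (many database entries are themselves
unlabelled); skipping to the best *annotated* hit raises the rates, the
three databases jointly annotate ~32%, and supplementing database headers
with UniProt protein names lifts the joint rate to ~36%. The per-call
detail (labels, tiers, source targets, UniParc caution flags) is in
`rep$calls`, rate tables in `rep$annotation$rates`, and group contrasts
(e.g. annotated proteins being longer, with deeper MSAs and better
structures) in `rep$contrasts`.

Individual stages are exported, e.g.:

```r
hits <- read_foldseek_tsv("foldseek_afdb.tsv")
prof <- read_plddt("structures/REP00001.pdb")
kept <- quality_filter(significance_filter(hits), list(REP00001 = prof$plddt))
best_annotated_hit_tiered(sort_hits(kept), read_header_table("headers_afdb.tsv", "AFDB"))
```

A thin command-line front end (`inst/cli/foldannot`) exposes `simulate`,
`filter` and `annotate` subcommands over the same functions.

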