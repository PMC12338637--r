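---
title: "Structure-informed annotation of phage proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-informed annotation of phage proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most open reading frames on phage genomes encode proteins with no useful
functional label — the "viral dark matter". Sequence-similarity search often
fails on these proteins because phage proteins diverge quickly, but
predicted structure is better conserved than sequence. The workflow this
package implements transfers function annotations through structural
similarity: predicted structures of protein-cluster representatives are
searched with FoldSeek against structure databases (the PDB, the AlphaFold
database, and the Phold phage-specific databases), the hits are filtered,
and the surviving hits' database labels are transferred back to the query
clusters under several selection policies.

The package does not run the upstream tools (MMseqs2 clustering, ColabFold
structure prediction, FoldSeek search, Pharokka sequence annotation); it
consumes their standard output formats, and ships a synthetic-data generator
that emulates all of them with known ground truth.

## Pipeline stages

**Curation.** A protein counts as *unannotated* when its NCBI-style name
contains `hypothetical protein` or `phage protein` (case-insensitive
substring match; the matching mode is a package choice, since name
conventions in public records are inconsistent in case and qualifiers).
Proteins are kept when their length lies in the inclusive window 100–850
residues; the window bounds are read inclusively from "between 100 and 850".
Deduplication is exact string identity on the amino-acid sequence — the
mildest defensible notion, since any fuzzier rule would need parameters the
upstream record does not provide. Cluster representatives that a
sequence-based annotator (Pharokka-style table) labels informatively are
separated from the *truly unannotated* ones. "Informatively" is a compound
condition: the representative must be present in the table, its PHROG
category must not be `unknown function`, and the label itself must not be an
unannotated-name match. Each clause has real counterexamples in practice
(hits to PHROGs of unknown function; labels that literally read
"hypothetical protein"), which is why all three are required.

**Structure QC.** Per-protein prediction confidence is the arithmetic mean
of the per-residue pLDDT profile, read from the B-factor field of the
CA atom of each residue (the AlphaFold convention; a mean-over-atoms variant
is available and agrees on AlphaFold-style files, which write uniform
per-residue values). MSA depth at a query position is the number of aligned
sequences, query included, with a residue at that position; the
*maximum per-protein MSA depth* is the maximum of that per-position
coverage. Whether depth should count sequences or per-position coverage is
genuinely ambiguous in common usage; both are implemented
(`msa_depth_profile(mode =)`), coverage is the default, and the two agree
whenever one column is fully occupied. A depth of 10 sequences is treated as
the tipping point between the low-confidence and high-confidence regimes and
`depth_contrast()` tests that contrast with a one-sided Mann–Whitney U.
Length–confidence association is measured as squared Pearson correlation,
pooled, within half-open length bins `[100 + 50k, 100 + 50(k+1))` (left
edge at the size-filter minimum), or pooled after balancing bin occupancy by
undersampling (without replacement, to the smallest bin) or oversampling
(with replacement, to the largest bin). Resampling takes a single integer
seed and restores the caller's RNG state, so results are reproducible
bit for bit.

**Hit filtering.** Two stages, both strict on their boundaries: a
significance stage retaining E-value `< 0.001`, then a quality stage
retaining alignment lDDT `> 0.5` **and** mean query pLDDT over the aligned
residues (`qstart..qend`, 1-based inclusive) `> 70` **and** same-SCOP-class
probability `> 0.5`. Strictness is forced by the phrasing of the upstream
protocol, which removes hits *at* the boundary. The aligned-fraction pLDDT
is computed from the query structure's own profile rather than from the
alignment's per-position lDDT string; an `lddtfull`-based variant sits
behind a flag. The two filters commute and are idempotent, so their order
cannot change results. Canonical ordering is by descending bitscore, with
ties broken by ascending E-value and then target identifier — the
tie-break is a package invention (FoldSeek's output order is not guaranteed
stable) chosen to make every downstream selection deterministic.

**Annotation transfer.** Labels are classified into three totally ordered
tiers: `NONE` (non-informative: hypothetical/uncharacterized/unannotated
names), `LOW` (named but uninformative: DUF domains, bare
"domain-containing protein" or "putative protein" labels) and `HIGH`
(everything else). The tier patterns are configurable from a plain-text
file (`TIER<TAB>regex` lines); the defaults are the package's own, since no
canonical public regex set exists for this discrimination. One subtlety:
`unknown function` is a non-informative marker *except* inside "domain of
unknown function", which must stay `LOW`; the default pattern uses a
lookbehind to keep the two pattern sets disjoint in effect.

Four single-hit selection policies operate on the filtered, sorted hits of
one query:

* **BH** (best hit): transfer the top hit's label whatever its tier; a
  non-informative top label is recorded but the cluster counts unannotated.
* **BAH** (best annotated hit): transfer the top hit whose label is
  informative (tier ≠ `NONE`).
* **BAH_3T** (tier-preferring): transfer the top `HIGH` hit if any exists,
  else the top `LOW` hit. Relative to BAH this never changes *whether* a
  cluster is annotated, only *how informatively*.
* **BAH_UP** (UniProt-supplemented): every hit's header label is first
  replaced by its UniProt-mapped protein name where the identifier map has
  an `active` or `removed_uniparc` entry, then BAH selection runs on the
  supplemented labels. Supplementing *before* selection (rather than
  relabelling the hit BAH already chose) is deliberate: hits whose database
  header is empty but whose UniProt record is informative become eligible,
  which is what lets this policy raise annotation rates. Names recovered
  through UniParc after removal of the UniProt entry carry a `caution` flag
  that propagates into reports as a separate column — they count as
  annotations, but deserve scrutiny.

Per-database calls combine into a joint call by maximum tier; when several
databases offer the same tier the label follows the precedence
PDB > Phold > AlphaFold database (experimental evidence first, then curated
phage families), then bitscore. Only the joint annotated/unannotated status
feeds the headline rates, so the precedence affects which label is shown,
never how many clusters count annotated.

**Statistics.** Group contrasts use a one-sided Mann–Whitney U with a fixed
contract: exact null distribution when `min(n, m) <= 8` and the pooled
sample is tie-free, tie-corrected normal approximation (with continuity
correction) otherwise. The computation delegates to `stats::wilcox.test()`;
the test suite checks the exact path against an independent exhaustive
enumeration over rank assignments. Correlations are squared
Pearson/Spearman coefficients; constant input is an error, not a zero.
P-values below `1e-300` are printed as bounds rather than as a misleading
`0`. No multiple-testing correction is applied, matching the upstream
protocol.

## The synthetic-data generator

`simulate_bundle()` writes a complete input bundle — FASTA, MMseqs2-style
cluster table, CA-only PDB files with pLDDT in the B-factor column, A3M
alignments, three FoldSeek hit tables, three header-annotation tables, a
UniProt identifier map and a sequence-annotation table — and returns a
truth manifest from which `expected_report()` computes, in closed form,
every number the pipeline must produce. The central validation property is
exact equality: `run_pipeline(dir)` must be `identical()` to
`expected_report(manifest)` for any configuration and seed. To make that
equality achievable at double precision, every numeric value that passes
through a text format is quantized through the writer's own format string
before use, so the generator's in-memory value is bit-identical to what the
reader recovers.

Defaults encode the study conditions the generator emulates: a
singleton-heavy cluster-size law (singleton fraction 6978/10498, zipf-like
non-singleton tail matched to an overall mean of 4), per-group truncated
log-normal length laws moment-matched to 159 ± 166 aa (truly unannotated)
and 343 ± 288 aa (sequence-annotated) within the 100–850 window, a 27%
sequence-annotated fraction, per-database significant-hit probabilities of
0.09 / 0.47 / 0.66 (PDB / AlphaFold / Phold) for truly unannotated
clusters, pLDDT regimes of 82 ± 12 above versus 55 ± 16 below MSA depth 10,
a 21% low-outranks-high fraction among annotated calls of which 13/21 carry
a lower-scoring proper annotation, and an identifier-map status mixture of
0.7 active / 0.2 UniParc-recovered / 0.1 unmapped. The MSA-depth law
(18% shallow, log-normal deep component with median ≈ 131 capped at 250)
was chosen once so that the shallow regime is well populated while the
depth distribution stays in the hundreds-of-sequences range typical of
viral MSAs. Group-level fractions are planted as exact counts (rounded),
which is what makes small planted contrasts — 21 low-information calls per
100 annotated, 13 of them rescued — deterministic rather than merely
expected.

A single latent "annotatability" score per cluster couples hit presence
across databases with MSA depth, cluster size and length (Gaussian copulas,
coupling strength 0.5 by default). This reproduces, qualitatively, the
partial complementarity of the databases and the observed pattern that
annotatable clusters are larger, longer, deeper-MSA'd and better predicted.
Bitscores are assigned strictly decreasing along each query's intended
sorted order, so planted selection outcomes cannot be disturbed by ties.

Two honest limitations. First, sequences and structures are format-valid
placeholders with controlled metadata, not physically meaningful models:
passing tests demonstrate correctness of the *post-processing* arithmetic,
not robustness to pathological real-world files. Second, planted
annotated-given-hit probabilities are conditional on a cluster having hits,
while the quality filter additionally removes all hits of queries whose
realized mean pLDDT falls at or below 70; realized annotation rates
therefore sit somewhat below the planted conditionals (as in real data,
where poorly predicted proteins also lose their hits). The truth manifest
records realized outcomes, so the exact-equality property is unaffected.

## Numerical choices and degenerate inputs

* All threshold comparisons are strict; boundary rows are removed, and the
  test suite plants rows exactly on every boundary to pin this down.
* String ordering everywhere uses C-locale radix sorting, so reports do not
  depend on `LC_COLLATE`.
* Empty pLDDT profiles, empty samples, constant correlation input, a
  missing query profile, a missing header target, a member in two clusters,
  and a lowercase A3M query are all hard errors naming the offending
  entity; silent pass-through is never allowed.
* Group contrasts with fewer than two observations on a side are recorded
  as degenerate entries instead of failing whole-report generation.
* `lddtfull` strings shorter than `alnlen` are tolerated (gapped positions
  omitted); longer ones are an error.
* FoldSeek tables are headerless by convention; a deposited table with a
  header row is read with `header = TRUE`, and an unexpected header row is
  rejected (its E-value field fails numeric parsing), never skipped.

## Problem sizes used in validation

The end-to-end equivalence property is exercised on twenty random
configuration/seed pairs at 500 clusters each, the filter oracle on 10,000
hits, the tier-scheme contrast on a 250-cluster bundle planted to yield
exactly 100 annotated calls, the type-I-error simulation on 1,000 null
replicates of 200-per-group samples, and the distribution-law checks on a
5,000-cluster bundle; these sizes make every planted fraction land on whole
counts while keeping the full suite quick to run.
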