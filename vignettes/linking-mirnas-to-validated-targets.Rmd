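---
title: "Linking miRNAs to validated targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking miRNAs to validated targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The problem

MicroRNAs repress their target mRNAs post-transcriptionally, and a single
miRNA can regulate many targets (and vice versa). Several curated databases
collect *experimentally validated* miRNA–target interactions (MTIs), but they
disagree on miRNA spelling, on target naming (symbols, synonyms, assorted
accession types), and on which validation evidence they record. `mirlink`
pools such databases behind a harmonized interchange format, links
user-supplied miRNA and/or target lists to the pooled interactions, and
optionally scores each miRNA's target set against a user-ranked target list.

The package operates on whatever snapshot of the source databases the user
supplies in the interchange format; none of the numbers it produces are tied
to a particular database release.

## Identifier semantics

A miRNA identifier is parsed as *species prefix* (3–4 letters, e.g. `hsa`),
*core* (e.g. `miR-301b`, `let-7a`), and *hairpin arm* (`-3p`/`-5p`). Three
choices matter:

* A leading 3–4 letter token only counts as a species prefix when the
  remainder starts with a known core stem (`miR`, `mir`, `let`, `lin`,
  `bantam`, case-insensitive). Without this rule `let-7a` would parse as
  prefix `let` + core `7a`.
* Trailing copy-number suffixes (`miR-302a-1`) stay in the core; only a
  literal trailing `-3p`/`-5p` is an arm.
* Matching treats an omitted component as a wildcard **on either side**: the
  query `miR-301b` matches the reference `hsa-miR-301b-3p`, and a query
  `miR-301b-3p` matches a reference stored arm-less as `hsa-miR-301b`.
  Whether the original databases intended the second direction is not
  documented anywhere we know of; symmetric wildcarding is the simplest rule
  that makes matching well-behaved (symmetric for full identifiers,
  consistent with cluster keys), so the package adopts it and states it here.

Core comparison is case-insensitive by default because the source databases
mix capitalization (`miR-1` vs `mir-1`); an exact-case mode exists for users
who need it. Unparseable lines are never fatal: they are dropped and reported
in a skipped-input table, so arbitrary text files can be fed in safely.

## Harmonization and occurrence counting

Target symbols are mapped to UniProt accessions by exact, case-insensitive
token equality against each entry's gene symbol, synonyms, and
cross-references. No fuzzy matching is attempted — approximate string
matching would silently inflate apparent homology. In species-agnostic mode
the species constraint is dropped, which is how homologous targets of
validated interactions enter the result for niche model organisms; the cost
is that same-named genes with different functions are conflated (a symbol
is not a protein), which is the method's main known limitation.

Cross-database agreement is recorded per `(miRNA key, UniProt accession)`
pair as a 4-bit occurrence string in the fixed order tarbase, mirtarbase,
mirecords, starbase. The occurrence count is computed **after** UniProt
mapping, not on raw symbols: the entire point of mapping to one accession
space is to make the databases comparable, and counting on heterogeneous raw
symbols would undercount agreement. The workflow diagrams of comparable
tools order filtering before mapping, so this is a genuine design choice;
it is parameter-free and documented here. In agnostic mode the count is kept
per accession (not per symbol cluster), so interactions reported for
different species reinforce exactly the accessions they both map to.

## Filters

Four user-adjustable criteria select interactions: source databases,
minimal database occurrence (popcount of the occurrence string), species
(or `any`), validation methods (free strings, compared case-insensitively
after trimming — the fixtures use a controlled vocabulary, real databases do
not), and the minimal CLIP-Seq support for starBase records (other databases
are unaffected). Defaults: all four databases, occurrence ≥ 1, any species,
all methods, CLIP support ≥ 1.

All filters are pure subset operations — idempotent, commuting, and monotone
under relaxation — and the test suite asserts exactly those algebraic
properties on randomized fixtures. One caveat is worth stating: per-stage
miRNA counts are *not* globally non-increasing, because a shortened user
identifier is a wildcard and can match several distinct database keys under a
strict policy. Counts are non-increasing from the database-matching stage
onward, and the raw input count dominates the deduplicated one; the step-count
table and its tests reflect precisely that.

## The enrichment analysis

Each eligible MTI set is scored against the ranked list by a weighted
running sum: hits step up by $|r_i|^p / N_R$ (with $N_R = \sum_{hits}
|r_i|^p$), misses step down by $1/(N - N_H)$; the enrichment score (ES) is
the signed extremum. The null distribution is built by gene-set resampling:
each permutation draws $N_H$ accessions uniformly without replacement from
the ranked list, keeping the set size constant. This is the documented
permutation scheme of the method; phenotype-label permutation is deliberately
out of scope. NES divides ES by the mean |ES| of same-sign permutations, and
the FDR q-value compares the pooled same-sign permutation NES tail with the
observed NES tail, clipped to [0, 1].

Parameter defaults, with reasons:

| parameter | default | why |
|---|---|---|
| `weight_p` | 1 | the weighted statistic; 0 gives the classic unweighted form |
| `n_perm` | 1000 | resolves q-values to ~0.001 at acceptable cost |
| `min_set_size` | 3 | sets of 1–2 targets produce quasi-binary scores with no useful null |
| ranking order | NES desc, then q, then set size, then key | NES is the primary result; the remaining keys make output deterministic |

Numerical and edge-case choices:

* The running sum's increments cancel by construction, so the walk ends at 0;
  tests assert $|{\rm final}| < 10^{-9}$ everywhere.
* Extremum ties are resolved to the **earliest** position, with a $10^{-12}$
  tolerance. At $p = 0$ the running sums are small rationals and exact
  $\pm x$ ties occur with appreciable probability; without the tolerance the
  winner would be decided by floating-point accumulation noise.
* If every hit weight is zero at $p \ge 1$ (all ranking values 0 among the
  hits), $N_R = 0$ leaves the hit step undefined; the implementation falls
  back to equal hit weights (the unweighted statistic) with a warning.
* An ES of exactly 0 takes the positive-ES leading-edge rule and gets NES 0.
* A set with no same-sign permutation ES has an undefined NES; it is reported
  missing and excluded from the FDR strata.
* A zero denominator in the q-value ratio yields q = 0 by convention.
* Ranked-list ties keep input order (stable sort); duplicated accessions keep
  the first occurrence with a warning; set members absent from the ranked
  list are dropped before scoring and the reported set size is the
  post-intersection one. Negative ranking values are allowed (hits weight by
  $|r|^p$).
* Sets covering the entire ranked list are skipped (the miss step is
  undefined), as are sets with no members in the list.

All permutations flow from one seed; a fixed seed gives bit-identical NES and
q-values, and the run manifest records it.

## What the synthetic fixtures emulate — and what they don't

The generator builds the four interchange databases, the UniProt mapping,
and the miRBase accession table with *planted, exactly known* structure:
the database-occurrence histogram of the planted pairs, symbol→accession
fan-outs (one accession per species per symbol), deliberately malformed rows,
unmappable miRBase accessions, duplicated rows, and synonym-referencing
records. Ranked-list fixtures plant enriched sets at a chosen top-quantile
loading among uniform null sets. Every planted quantity is written to a
manifest, and the tests recover each one exactly from the corresponding
pipeline stage.

The fixtures mimic real-world *shapes* (organism codes such as `hsa`,
`P#####`-style accessions, a controlled method vocabulary) but make no
attempt to mimic the species, method, or set-size distributions of the real
databases, nor the many-to-many messiness of real synonym tables (each
fixture symbol maps to exactly one accession per species). Passing tests
therefore demonstrate that the *mechanics* — parsing, mapping, counting,
filtering, scoring, and their algebraic properties — are correct; they say
nothing about recall against any particular database release, which depends
entirely on the snapshot the user supplies.

Test and acceptance problem sizes are chosen to exercise the method while
keeping a full run fast: enrichment simulations use ranked lists of
$N = 200$ with a planted set of 10 fully loaded into the top decile among 20
null sets of 10, 1000 permutations, and 20 seeded replicates; the
oracle-equivalence checks use 1000 random instances with $N \le 50$; the
reference fixtures use tens of miRNAs and targets over 2–3 species. These
sizes already produce stable results (the planted set is recovered as the
top hit with q < 0.05 in every replicate, and well under 10% of pure-null
sets reach q < 0.05).

## Output conventions

The tested surface is tabular: `matrix.tsv` (accessions × miRNA keys with
binary occurrence strings; a non-empty cell *is* a linked interaction),
`info.tsv` (one row per accession with aggregated miRNA keys and UniProt
annotation), `overlap_matrix.tsv` (pairwise Jaccard index between MTI sets —
the metric is this package's choice, since symmetric and size-normalized;
an intersection-count mode is available — with leading edges substituted for
full sets when the enrichment ran), `step_counts.tsv`, `ranking.tsv` (set
size ranking without enrichment, NES ranking with it), and per-set trace
tables (one row per in-list member: list index, running ES at that index,
leading-edge flag). Figures — the step-count bar graph, the overlap heatmap,
and the per-set enrichment plot (running-score curve, hit rug, extremum
marker) — are rendered strictly from those tables and a rendering failure
only warns, never fails a run.

## Known limitations

* Homology via shared gene symbols only; no protein-sequence similarity
  check backs up the species-agnostic mapping.
* No parsers for the native database dump formats and no network retrieval —
  inputs must be in the interchange format.
* No phenotype-permutation mode and no per-method reliability weighting
  (occurrence is a count, not a score).
* No mature↔precursor resolution beyond arm handling, and no validation
  against a live miRBase release.
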