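---
title: "Methods: genome catalogs, novelty and co-occurrence with magcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome catalogs, novelty and co-occurrence with magcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcat)
```

## Overview

Large MAG (metagenome-assembled genome) collections are turned into usable
catalogs by a chain of decisions: which bins are good enough to keep, which
genomes are the same species or the same strain, which clusters are already
known to reference databases, which secondary-metabolite loci and peptide
products they encode, and how the resulting species co-occur across samples.
`magcat` implements that chain as a set of small, testable stages, and ships
a synthetic-community generator that plants the ground truth every stage is
supposed to recover. This vignette explains the models behind each stage,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic tests do and do not establish about real data.

## The synthetic community generator

`simulate_genomes()` draws one ancestral sequence uniformly over A/C/G/T and
derives lineages by independent per-site substitutions to a uniformly chosen
different base, with no indels. Substitution-only divergence keeps true ANI
analytic — `ANI = 1 - mismatch fraction` — which is exactly the regime the
Mash distance estimator assumes, so recovery targets can be stated in closed
form.

The two divergence parameters are *expected pairwise* divergences between
sibling lineages. Each sibling branch mutates at the rate `r` solving
`2r - (4/3) r^2 = d` (the quadratic accounts for sites hit on both branches,
including coincident substitutions to the same base), so the expected
pairwise mismatch fraction equals `d` exactly. Defaults:

| parameter | default | meaning |
|---|---|---|
| `between_species_divergence` | 0.08 | pairwise divergence between two species (well above the 5% species boundary) |
| `within_species_divergence` | 0.005 | pairwise divergence between two strains of one species |
| `genome_length` | 100 kb | long enough that binomial noise on divergence is ~0.1% |
| `n_species`, `strains_per_species` | 20, 3 | community size used throughout the packaged experiments |
| `reference_overlap_fraction` | 0.5 | fraction of species that also have a synthetic reference genome |

With the default within-species divergence of 0.5%, all strains of a species
sit within 1% of each other, i.e. above 99% ANI: the expected strain-level
partition coincides with the species partition, and a species' planted
strains are non-novel exactly when the species has a reference genome. The
generator derives this expected partition analytically from the config and
warns when a planted divergence lands within 25% of a clustering threshold —
in that regime recovery is genuinely undetermined (the realized divergence of
a 100 kb pair fluctuates by ~±0.1% and the Mash estimate by a similar
amount), so no truth label is defensible there. To exercise visible strain
substructure, raise `within_species_divergence` above ~1.5% pairwise while
staying below the species threshold.

References planted inside a covered species are generated exactly like an
additional strain; the remainder of the reference set are unrelated decoy
genomes. Covered references alternate between a GTDB isolate and a
MAG-derived (UHGG-style) entry, which plants the three species types the
typing stage must distinguish: *isolate*, *uncultivated* and *novel*.

The abundance generator draws per-sample basis abundances log-normally
(`abundance_log_sd`, default 1, around per-taxon means spread with SD 1.5 on
the log scale) and closes them to relative abundances. Planted correlations
are injected on the log-basis scale through a bivariate normal. Two
deliberate choices: one taxon is always forced far below the 0.1% median
filter so the network stage's abundance floor is exercised, and planted
pairs are placed on taxa of typical (community-average) abundance — a
correlation planted on a taxon below the sequencing depth would be
unrecoverable by construction and would test nothing but shot noise.

What the generator does *not* emulate: real phylogenies, recombination and
gene content variation, indels, assembly fragmentation and chimerism,
sequencing error, or taxon interactions beyond pairwise log-scale
correlation. Passing the planted-recovery tests therefore shows the
*algorithms* are correct under their stated models, not that the thresholds
(95%/99% ANI, MIMAG boundaries, 0.05% presence) are optimal for any
particular real data set.

## Sketching and ANI

`build_sketch()` keeps the `s` smallest 64-bit-mixed hash values (bottom-s
MinHash) of the canonical k-mer set, with `k = 21`, `s = 10000` — standard
genome-scale settings. Canonicalization takes the lexicographic minimum of a
k-mer and its reverse complement; windows containing non-ACGT characters are
skipped; lowercase is accepted. The hash is the splitmix64 finalizer applied
to the 2-bit-packed k-mer with a fixed salt, truncated to its top 53 bits so
every hash is exactly representable as an R double (collision probability at
genome scale is ~1e-7 and a collision would perturb one Jaccard estimate by
~1e-4 at most).

`jaccard_estimate()` uses the merged bottom-`s'` estimator: take the
`s' = min(s, |union|)` smallest values of the merged hash streams and count
the fraction present in both sketches. When `s` covers the whole union the
estimate *equals* the exact Jaccard index — the basis of the exact-oracle
tests. `mash_distance()` converts Jaccard to a mutation-rate estimate,
`d = -(1/k) log(2j/(1+j))`, with `j = 0` mapped to `d = 1` (capped) so
distance matrices stay bounded for clustering; `1 - d` is reported as ANI.
For a pairwise substitution rate `p`, `d` estimates `-log(1-p)`, which stays
within 0.005 of `p` for `p <= 0.1` at the default `k` — hence the planted
rates used in the recovery experiments (1–8%).

## Dereplication

`single_linkage_cluster()` places two genomes in one cluster exactly when a
path of edges with `d < threshold` connects them (strict inequality,
matching distance-threshold agglomerative clustering; configurable). The
implementation is a union-find over threshold edges, and the test suite
checks it against an independent connected-components computation on
thousands of random matrices. Species use `d < 0.05` (95% ANI), strains
`d < 0.01` (99% ANI); since the strain edge set is a subset of the species
edge set, the strain partition provably refines the species partition.
Cluster ids are assigned in order of each cluster's smallest member, and
member lists are kept sorted, so outputs are diffable and independent of
input order.

Representatives maximise eigenvector centrality on the complete weighted
graph over cluster members with edge weight `1 - d` (ANI similarity; the
natural choice where only "a weighted network graph" is conventional).
Centrality is computed by power iteration with tolerance 1e-10 and at most
10,000 iterations; the iteration runs on `W + I`, which leaves the
eigenvector unchanged but makes the Perron eigenvalue strictly dominant even
on bipartite weight patterns (a star-shaped cluster would otherwise
oscillate). Centrality ties within 1e-9 — including the fully symmetric
equal-weight case — resolve to the lexicographically smallest genome id.

## Quality tiers, reference matching, typing, novelty

`assign_quality_tier()` applies MIMAG-style rules with every printed
inequality strict: *medium* needs contamination < 10 and completeness > 50;
*near-complete* contamination < 5 and completeness > 90; *high* additionally
needs complete 5S/16S/23S rRNA genes and >= 18 unique tRNAs (inclusive, "at
least 18"). Low-tier bins are removed before clustering. N50 uses the
cumulative >= total/2 convention.

`match_reference()` keeps reference hits with Mash distance <= 0.05
(inclusive) and returns the minimum, ties to the smaller id.
`classify_slc()` types a species cluster from the union of its members'
matches — *isolate* if any match is an isolate, *uncultivated* if matches
exist but none is an isolate, *novel* otherwise — and names it by majority
vote over matched species names, count ties broken in favour of GTDB-backed
names, then lexicographically. Using "any member" rather than
"representative only" is the permissive reading of per-cluster typing from
per-MAG matches; it is the default and the alternative is a one-line change
at the call site. `classify_strain_novelty()` clusters queries jointly with
the species-matched references at the strain threshold; a strain cluster is
novel exactly when it contains no reference.

## BGC catalog curation

Records are normalised internally to 0-based half-open coordinates. The
curation cascade: (1) `filter_basic()` removes records with exactly one gene
AND length < 2 kb — the literal conjunction; a disjunction switch exists
because the prose rule is ambiguous; (2) `filter_deep_candidates()` keeps
deep-learning calls only with a known product class and >= 1 biosynthetic
domain; (3) `dedup_overlap()` drops a secondary call when its overlap with
any primary call on the same genome and contig reaches >= 30% of either
interval's length (inclusive, strand ignored). Every filter returns both
partitions with machine-readable reasons, so record counts are conserved at
each stage. Product classes are unified through an editable mapping table;
labels whose `;`-separated parts map to two distinct classes become
*hybrid*. GCF membership computation is out of scope (an input table); the
family representative is the smallest member, ties lexicographic. Novelty is
the two-step 80% rule: curated databases first, then the annotated reference
collection.

## AMP screening

The screen applies to peptides from RiPP BGCs with length strictly between
10 and 200 residues. The ensemble rule is
`core1 AND core2 AND (aux1 OR aux2) AND transporter-in-BGC`; the four
predictor votes are inputs (the external models are trained artifacts, not
reimplemented here). Physicochemical annotations: percentage hydrophobicity
over a configurable residue set (default {A, C, F, I, L, M, V, W}, an
APD-style convention) and net charge `(#K + #R) - (#D + #E)` with histidine
excluded by default and available as an option — the upstream calculator's
exact conventions are not published, so both are parameters rather than
guesses. `evaluate_ensemble()` reports precision/recall/F1 with `NA` (never
silently 0) on degenerate denominators.

## Rarefaction

`to_incidence()` scores presence strictly above 0.05% relative abundance.
Interpolation uses the exact hypergeometric form
`S(t) = S_obs - sum_i C(T - Y_i, t) / C(T, t)`, computed through `lchoose`
for stability (terms with `t > T - Y_i` vanish exactly). Extrapolation uses
the incidence-based Chao2 estimate of undetected richness with the
small-sample correction, and is flat at `S_obs` when no singletons exist.
`coverage_at(t)` is the self-ratio `S(t)/S(endpoint)` (endpoint 300 by
default). The interpolated curve is checked against exhaustive subset
enumeration for `T <= 8` at 1e-9 and against an independent exact
species-accumulation computation.

## Compositional correlations and the network

Relative abundances are compositional: closure alone induces spurious
negative correlation, so Pearson correlation on proportions is biased. The
estimator here is the SparCC family's: per iteration, resample fractions
from a Dirichlet posterior with pseudocount 1; form the variation matrix
`t_ij = Var(log x_i/x_j)`; solve the linear system (diagonal `p-1`,
off-diagonal 1) that expresses the row sums of `t` in terms of basis
variances under a sparsity assumption; convert to correlations and clamp to
[-1, 1]; then up to 20 exclusion rounds remove the currently strongest
`|rho| > 0.1` pair from the system and re-solve, protecting the sparsity
assumption from a few strong correlations. The final estimate is the
element-wise median over 100 iterations. Pairs whose basis variance turns
non-positive (a degenerate system — expected near the 4-taxon identifiability
floor) are zeroed with a warning, never reported silently.

p-values come from permutation: each taxon's column is permuted
independently (destroying association, preserving marginals), the estimator
re-run with identical settings, and two-sided add-one p-values reported, so
the smallest attainable p is `1/(n_boot + 1)`. The resampling uses the
package's own counter-seeded generator, making results bit-reproducible
across platforms and independent of R's global RNG state. Networks drop
taxa with median relative abundance <= 0.1% (inclusive, as conventionally
stated) before keeping edges with `p < 0.05` (strict). Calibration on
independent synthetic data is approximately nominal; the estimator family is
known to run slightly anticonservative under strong compositional closure,
which the calibration check's binomial band accommodates.

## Problem sizes and determinism

The packaged experiments use 20 species x 3 strains at 100 kb for catalog
recovery, 50 taxa x 200 samples with 200 permutation replicates for network
calibration, and 1000 random 30x30 matrices for the clustering oracle —
sizes at which every planted quantity is comfortably identified while a full
run of the suite and the acceptance script stays in the minutes range on one
core. All stages draw from per-stage child streams of one root seed
(`child_seed()`), so any stage can be re-run alone and still reproduce the
full-pipeline output byte for byte; the boundary battery emitted by
`simulate_quality_table()` (ids `BOUND_*`) is a pure classifier fixture and
is not fed to the sequence stages.

## Known limitations

* Mash distance estimates `-log(1 - p)`, so planted-rate recovery degrades
  above ~10% divergence; the species threshold itself (0.05) is unaffected.
* Strain-level truth is undefined when planted divergences straddle the 99%
  boundary; the generator warns rather than guessing.
* The SparCC basis solve assumes sparse correlations; dense strong
  correlation structures violate it and are only partially rescued by the
  exclusion rounds.
* The rarefaction extrapolation inherits Chao2's behaviour: it is a lower
  bound on richness and is driven entirely by singleton/doubleton counts.
* The catalog stages trust their input tables (quality metrics, BGC calls,
  predictor votes, GCF memberships); none of the upstream tools are
  re-implemented or validated here.
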