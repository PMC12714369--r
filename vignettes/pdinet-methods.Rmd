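---
title: "Methods: statistics and benchmarks behind pdinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and benchmarks behind pdinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdinet)
```

`pdinet` analyses directed protein–DNA interaction (PDI) networks: graphs
whose edges run from a transcription factor (TF) to a promoter it binds,
as established by enhanced yeast one-hybrid screens or projected across
species through ortholog maps. This vignette records the statistical
model behind each stage, the defaults and why they were chosen, what the
synthetic generators do and do not emulate, and the package's known
limitations.

## Network model

A network (`grn`) is a node table plus a deduplicated edge table. Roles
are inferred from participation — a gene appearing only as a regulator is
a `TF`, only as a bound target a `promoter`, on both sides a
`TF_and_promoter` — and can be overridden from a node-attribute file,
since a screen may know a node is a TF even when it caught no outgoing
edge. Design choices worth stating explicitly:

* **Duplicates collapse.** PDIs are unique (TF, promoter) pairs; repeated
  assay rows collapse to one edge with the collapsed count logged, so a
  reader can see when a deposited table disagrees with its printed total.
* **Self-binding edges are retained** in the network and in degree
  counts. Nothing in the assay excludes autoregulation; they are only
  barred from feed-forward loops, whose three nodes must be distinct.
* **Identifiers match exactly** (case-sensitive) after trimming
  surrounding whitespace: deposited gene identifiers are canonical
  strings, and silent fuzzy matching would hide curation errors.

Indegree counts distinct TFs bound to a node's promoter, outdegree the
distinct promoters its TF binds; hub reports use strict thresholds
("more than 35 TFs" means indegree > 35).

## TF-family enrichment

Under a null in which regulatory interactions distribute over TFs in
proportion to family size, a family with $m$ of the network's $T$ TFs is
expected to emit $E = \frac{m}{T} M$ of the $M$ edges. The departure of
the observed family outdegree $O$ is scored with a two-cell goodness-of-fit
statistic — family versus all other TFs —

$$\chi^2 = \frac{(O - E)^2}{E} + \frac{((M - O) - (M - E))^2}{M - E},
\qquad p = P(\chi^2_1 \ge \chi^2),$$

on one degree of freedom (a single comparison category). The two-cell
form, rather than a bare one-cell sum, is what reproduces published
p-values from published counts; the complementary cell is required for
the statistic to have its nominal distribution. Significance is flagged
at raw $p < \alpha$ (default 0.05), matching the common reporting
convention for this test; a Benjamini–Hochberg column is emitted
alongside for users who prefer a corrected view, and p-values are kept in
full double precision because strongly over-represented families reach
the $10^{-59}$ range. A family containing every TF has no comparison cell
and returns `NA`.

## Gini correlation and edge polarity

The Gini correlation coefficient (GCC) is an asymmetric rank-weighted
association measure, robust for skewed expression data:

$$\mathrm{GCC}(x; y) =
\frac{\sum_{i=1}^{n} (2i - n - 1)\, x_{\pi_y(i)}}
     {\sum_{i=1}^{n} (2i - n - 1)\, x_{\pi_x(i)}},$$

where $\pi_y$ orders samples by ascending $y$ and $\pi_x$ by ascending
$x$. This equals the covariance of $x$ with the ranks of $y$, normalised
by the covariance of $x$ with its own ranks — the form used as an
independent oracle in the tests. Numerical choices:

* **Ties break by original sample index** (a stable sort), making results
  deterministic and documented; with heavily tied data the choice can
  matter, which is why both the estimator and its tie rule are fixed.
* **Both directions are computed per edge** (`gcc_tf_ranks` weighs target
  values by TF ranks; `gcc_target_ranks` the reverse). The estimator is
  asymmetric and neither direction is canonically "the" edge value, so
  the polarity-determining `gcc` is the direction of larger magnitude
  (ties favour `gcc_tf_ranks`) and both are recorded for audit.
* **All in-context samples enter the correlation** — every phase, time
  point and replicate of the chosen tissue. Rank statistics need $n$;
  averaging replicates would discard half the sample.
* **Thresholds are strict**: activating iff GCC > 0.5, repressing iff
  GCC < −0.5, else undetermined with a reason code (`missing_gene`,
  `constant_profile`, `below_threshold`). A constant profile makes the
  denominator vanish, so such edges are reported rather than scored.

## Feed-forward loops

An FFL is an ordered triple (tf1, tf2, target) of pairwise-distinct nodes
with edges tf1→tf2, tf1→target and tf2→target. Conventions:

* **Ordered triples.** "tf1 regulates tf2" is directional; when both
  TF→TF edges exist, (A, B, p) and (B, A, p) are distinct instances. An
  `unordered = TRUE` flag collapses mirror pairs for comparison against
  counts that may use the other convention.
* **Classification** follows the canonical eight-type taxonomy, pinned as
  a single authoritative table (`ffl_type_table()`) with ordering
  (s1, s2, s3) = (tf1→tf2, tf2→target, tf1→target): coherent types
  c1 (+,+,+), c2 (−,+,−), c3 (+,−,−), c4 (−,−,+) satisfy
  $s_1 s_2 = s_3$; incoherent types i1 (+,−,+), i2 (−,−,−), i3 (+,+,−),
  i4 (−,+,+) violate it. Unit tests verify the table exhaustively over
  all eight sign triples.
* **Significance is the strictest reading**: a loop is retained only when
  all three edges have determined polarity in the requested context;
  loops with any undetermined edge are reported `unclassified`.

Enumeration is adjacency-intersection based and is checked against an
independent brute-force scan over all ordered node triples on hundreds of
random networks.

## Cross-species projection and conservation

Projection expands each edge over the Cartesian product of its endpoints'
orthologs (so one-to-many relations fan out, as expected for a species
with genome duplications), collapses duplicates, drops and counts edges
with unmapped endpoints, and defaults to syntenic ortholog pairs — the
appropriate set for building a projected network. Conservation scoring
between two experimentally tested networks uses all ortholog pairs by
default and defines, per direction:

* **tested** — both endpoints have at least one ortholog among the
  partner network's nodes, i.e. the interaction was assayable in both
  screens. This is the only denominator under which "conserved fraction"
  compares like with like.
* **conserved** — any ortholog combination of the endpoints is an edge of
  the partner network. Requiring all paralog combinations would penalise
  duplicated genomes for their duplications.

The conserved edge sets found in the two directions translate into each
other exactly on one-to-one maps (a tested invariant).

## Expression overlay and clustering

Differential-expression status is a pure function of (log2FC, adjusted p)
with strict thresholds, default padj < 0.05 and log2FC > 1; the
down-regulation threshold mirrors the up threshold at −1, the only
reading under which a "greater than 1" rule can produce the
down-regulated genes it is routinely paired with. Boundary values are
not differentially expressed.

Tissue specificity uses the classical Gini inequality index over
per-group mean TPM, $G = \sum_{ij} |m_i - m_j| / (2 g^2 \bar m)$ — zero
for uniform expression, $(g-1)/g$ when one group carries everything, and
scale-invariant.

Temporal clustering averages replicates per (tissue, phase, time),
z-scores each gene's mean profile, and runs k-means (Euclidean distance,
10 restarts, seeded; k = 10 by default, a conventional resolution for
temporal response classes). k-means was chosen as the simplest standard
method for partitioning z-scored profiles and is recorded in the output
so the choice is visible; constant profiles cannot be z-scored and are
excluded with their identifiers reported.

## Synthetic data: what is emulated, what is not

The generators exist so every stage has a parameter-recovery test with
known truth. They emulate the *structure* of a nutrient-stress screen:

* networks with a heavy-tailed outdegree mix (a configurable fraction of
  hub TFs drawing ~5× the mean outdegree), dual-role TFs enabling FFLs,
  and Zipf-skewed family sizes;
* two tissues, time points 0, 0.5, 3, 24 (deprivation) and 24.5, 48 h
  (recovery), three replicates — the defaults mirror a short-term
  deprivation/recovery design;
* expression in which each planted TF→target relationship is monotone
  with its planted sign: targets are weighted sums (log-normal weights)
  of their regulators' profiles plus iid replicate noise, shifted
  positive (TPM-like) with any post-noise negatives clipped at zero and
  counted. Regulated TFs keep a 50% intrinsic component, standing for
  upstream inputs outside the assayed network; pure targets are fully
  regulator-determined, per the cleanest recoverable construction.
  Profiles are random smooth curves built on an orthonormal polynomial
  basis with equal-weight coefficients, so the effective dimension — and
  hence the chance correlation between unrelated genes — is governed by
  the time-grid density (capped at 12). Targets with mixed-sign
  regulators partially cancel their own signal and are flagged, as are
  edges inside regulatory cycles, so recovery tests can condition on
  identifiable configurations;
* DEG tables drawn at planted up/down rates with values consistent with
  the strict thresholds, and ortholog maps with a planted per-edge
  conservation probability whose noise edges deliberately avoid every
  ortholog image of a source edge, so the planted conserved set is exactly
  what conservation scoring should find.

They do **not** simulate read counts, library-size or dispersion effects,
assay false positives/negatives, or regulatory dynamics (delays,
saturation); passing recovery tests therefore demonstrates correctness of
the analysis machinery, not that real networks are recoverable at these
rates.

## Benchmark problem sizes and what recovery means

Three seeded benchmarks back the package-level claims:

* **Polarity recovery**: 100 single-regulator edges (50 activating, 50
  repressing) at replicate noise σ = 0.05 on the six-point study grid;
  all 100 polarities are recovered. Single-regulator construction is
  deliberate: pairwise correlation can only be guaranteed to reflect an
  edge's sign when that edge dominates its target.
* **Conservation recovery**: planted fractions 0.1/0.3/0.5 on networks of
  ~1500 edges; recovered fractions land within binomial error (< 0.05).
* **End-to-end FFL-type recovery**: 50 node-disjoint planted loops
  (100 TFs) with uniform random signs, a dense 2-hourly time grid for
  statistical power, σ = 0.05. Recovery is scored over *classifiable*
  loops — those whose three edges all pass |GCC| > 0.5. This conditioning
  is principled: an incoherent loop's indirect path opposes its direct
  edge by definition, so part of its own signal cancels in observational
  co-expression and such loops frequently (and correctly) come back
  unclassified rather than mislabelled. Among classifiable loops, type
  recovery exceeds 90% at the suite's seed; with only ~25–30 classifiable
  loops the per-seed binomial spread is several points, so individual
  seeds range roughly 83–96%.

## Known limitations

* Edge polarity from co-expression degrades with target indegree: a
  promoter integrating ten TFs rarely yields |GCC| > 0.5 for any single
  edge, so dense hub networks keep many edges undetermined. This mirrors
  the behaviour of the method on real screens and is a property of the
  statistic, not of the implementation.
* Incoherent FFL arms are partially confounded by construction (above);
  their recovery is bounded no matter the noise level.
* The chi-square enrichment evaluated from rounded published member
  counts reproduces published p-values to order of magnitude only; exact
  agreement needs the unrounded per-family tallies.
* Verifying published structural totals (edge, TF, promoter and loop
  counts of the deposited maize and sorghum networks) requires those
  deposited tables, which are not redistributable here; the two
  acceptance tests covering them report the missing inputs until a copy
  is placed under `inst/extdata/`.
* The pipeline clusters one expression matrix at a time; cross-species
  joint clustering is out of scope, as are DEG calling, ortholog
  inference and network visualisation.
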