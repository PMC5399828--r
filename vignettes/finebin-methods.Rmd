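---
title: "Sub-bin resolution analysis of metagenome functions: models and methods"
author: "finebin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-bin resolution analysis of metagenome functions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finebin)
```

## The problem

Gene-centric analysis quantifies a shotgun metagenome by the functions its
reads carry: reads are assigned to annotated genes on reference contigs and
pooled into *bins*, one per functional domain (a TIGRFAM, PFAM or COG
family), whose counts are then compared between conditions. Domain families
are deliberately broad, so one bin typically pools many distinct gene
variants. When only a subset of those variants responds to a condition — or
two subsets respond in opposite directions — the pooled bin count changes
little and the effect is *diluted* away. finebin addresses this by
interposing an unsupervised step between annotation and testing: the
amino-acid sequences of each domain's annotated instances are clustered at a
sequence-identity cutoff, splitting each bin into *sub-bins* that are
quantified and tested separately. The package also ships a resampling
framework that measures, on data with planted effects, exactly how much
signal and statistical power are lost when fine-level effects are read out
at coarser levels.

## Workflow and coordinate conventions

The pipeline is: six-frame translation of the reference contigs, profile-HMM
hit tables parsed per domain (`parse_domtblout()`), overlap resolution,
projection of amino-acid hit coordinates back onto nucleotide reference
coordinates (`project_to_nucleotides()`), clustering of each domain's
instances (`cluster_domains()`), read counting against the annotated regions
(`count_overlaps()`), roll-up into bin/sub-bin matrices (`build_matrix()`),
representativeness filtering, and per-feature testing
(`run_differential_abundance()`).

All internal coordinates are 0-based half-open on the forward strand; text
formats keep their native conventions (GFF/TSV 1-based inclusive). For frame
$+k$ and 1-based amino-acid positions $s..e$, the projected interval is
$[(k-1)+3(s-1),\,(k-1)+3e)$; for $-k$ the same interval on the reverse
complement is mapped back to forward coordinates. A trailing partial codon
is dropped in translation, codons containing `N` translate to `X`, stop
codons translate to `*`, and a hit spanning a stop is kept whole — the hit
table, not the translation, decides what is a domain instance. Translated
query names carry a `_frame<+k|-k>` suffix; the hit-table parser requires
that convention and recovers the frame from it.

When two hits on the same reference overlap by more than a fraction $p$
(`max_acceptable_overlap`) of the *shorter* annotation, only the
better-scoring hit is kept; resolution is greedy in decreasing bitscore
(ties: lower independent e-value, then coordinates). $p = 1$ reports
everything. The shorter-annotation denominator is the conservative reading —
it flags containment — and the rule is applied to all pairs, including
repeated hits of the same domain. The filtering e-value is the per-domain
independent e-value (default cutoff `1e-10`).

## Sequence identity and clustering

Pairwise identity is computed from a global (Needleman–Wunsch/Gotoh)
alignment with fixed scoring — match $+1$, mismatch $-1$, a gap of length
$L$ costs $5 + L$ — as

$$\mathrm{id}(a,b) = \frac{\#\text{identical aligned pairs}}
{\#\text{alignment columns}},$$

with all columns counted, terminal gap columns included. Two deliberate
choices are buried here. First, identity rather than similarity drives the
threshold, so no substitution matrix is used. Second, co-optimal alignments
can disagree on the number of identical pairs; finebin resolves this by
maximizing, among all maximum-score alignments, first the number of
identical pairs and then the negative column count. That makes the identity
a deterministic function of the sequence pair — it can be recomputed
independently and compared exactly, which is how the test suite validates
the C++ kernel against a separate dynamic-programming implementation.
Counting terminal gap columns in the denominator is part of the same
decision: a denominator that excluded them would depend on which co-optimal
traceback was taken. The practical consequence is that sequences of very
different lengths get low identity, which is appropriate here because the
clustered sequences are domain instances already clipped to the HMM match.

`greedy_centroid_cluster()` reproduces centroid-clustering semantics in the
style of UCLUST: sequences are processed in decreasing length order (ties by
id) and each joins the *first* centroid with identity at or above the
cutoff, else founds a new cluster (`assign = "best"` switches to best-hit
assignment). No k-mer prefilter is used; correctness and determinism take
precedence over speed at the package's design scale (at most a few thousand
sequences per bin). `hierarchical_cluster()` offers complete-linkage
agglomeration on $1 - \mathrm{id}$, cut at $1 - \text{cutoff}$, so every
cluster's diameter is bounded by construction; it recomputes cluster
distances exactly and breaks ties by smallest cluster indices, and is
intended for small bins (quadratic memory, cubic time). Centroid clustering
is not hierarchical: sub-bins at a strict cutoff need not nest inside
sub-bins at a loose one, and `subset_consistency()` quantifies how often
they do.

## Counting and filtering

Reads are quality-filtered first: a read is removed when at least 50% of its
bases are below Phred 10 (both thresholds configurable; the comparison is
inclusive). Counting follows coverageBed semantics — a read increments every
region its aligned interval overlaps by at least one base, strand ignored
(shotgun reads are unstranded), one increment per read-region pair. Because
a read can overlap two regions, bin totals can exceed the number of mapped
reads when domains overlap (with `max_acceptable_overlap = 1`); that is a
property of the counting definition, not an error. Sub-bin counts are sums
of member-region counts, so at every level and in every sample the bin
count equals the sum of its sub-bin counts — an exact conservation law the
tests assert.

The built-in `naive_map()` exists so that desk-scale analyses and the test
suite need no external aligner: exact 31-mer seeding (sparse offsets first,
then every offset) plus ungapped extension, best placement per read at
identity $\ge 0.9$ over the read. Exact seeding means a read is mappable
only if it contains one error-free 31-mer, which caps the tolerable error
rate at roughly 2–3 substitutions per 100-base read; production use goes
through SAM/BAM (or blast8 best-hits) from a real mapper.

Before testing, features are kept only when present (count $> 0$) in at
least 75% of samples, compared inclusively (6 of 8 passes). Presence is
evaluated on the full sample set, not per condition.

## The statistical model

For one feature with counts $y_j$ across samples, finebin fits

$$\log E[y_j] = \beta_0 + \beta_1 x_j + o_j,$$

where $x_j$ is the condition indicator and $o_j$ a normalization offset —
by default the log of the sample's total count over the tested features at
that level, computed before representativeness filtering when the pipeline
wrappers are used. The mean parameters come from iteratively reweighted
least squares (relative deviance change below $10^{-8}$, at most 50
iterations; the fit is delegated to `stats::glm` with the Poisson family).
Overdispersion is per-feature quasi-likelihood:
$\hat\varphi = \chi^2_{\text{Pearson}} / (n - 2)$, floored at 1 so that
apparent underdispersion never shrinks a standard error. Then
$\mathrm{se}(\hat\beta_1) = \sqrt{\hat\varphi}\,
\mathrm{se}_{\text{Pois}}(\hat\beta_1)$ and the p-value is a two-sided t
test with $n - 2$ degrees of freedom — a small-sample honesty choice over
the normal reference. No information is shared across features; that would
be a different estimator family. Log fold changes are reported in natural
log (with a `log2FC` convenience column).

When one group is all zeros the MLE is infinite; finebin then computes
$\hat\beta_1$ from group totals with a 0.5 continuity correction (only in
that case) and flags the row in a `separated` column, because an infinite
estimate is unusable downstream. All-zero features are an error by design —
the representativeness filter removes them before fitting. P-values are
adjusted by Benjamini–Hochberg step-up across all features tested at one
level.

Two properties worth knowing: estimates are exactly invariant to rescaling a
whole group's counts with matching offsets (the score equations match group
totals to group exposures), but only approximately invariant to rescaling a
single sample; and the group-total structure admits a closed form
($\hat\beta_1 = \log(T_1/O_1) - \log(T_0/O_0)$) that the tests use as an
independent oracle for the IRLS path.

## The downsampling power framework

To measure dilution, effects are planted by binomial thinning: in one group,
each affected region's count $Y$ is replaced by a $\mathrm{Binomial}(Y, p)$
draw, giving an expected between-group fold change of $1/p$ while preserving
the data's variance structure. The default $p = 1/7$ targets a 7-fold
change; the acceptance script verifies the realized mean fold change by
Monte-Carlo simulation. Each iteration of `run_power_experiment()` draws a
fresh two-group split (without replacement) and a fresh affected set —
`effect_fraction` (default 10%) of the sub-bins at the chosen effect level —
then thins the member regions' counts, rebuilds matrices at every evaluated
level, recomputes offsets (mimicking a real dataset's library sizes),
filters, and tests. A feature at any level counts as affected when it
contains at least one affected region, so effects propagate upward through
cluster membership.

Power at a level is the detected fraction of affected features *that
survived the representativeness filter at that level*: features filtered out
are undetectable by construction and excluded from the denominator (a
definitional choice, stated here because it changes the numbers when
filtering is aggressive). Alongside power, the mean $|\log\text{FC}|$ of
affected features tracks the signal itself; on nested structures it
decreases from the effect level toward the bin level, which is the dilution
phenomenon in its purest form. With $p = 1$ the whole machinery is
distribution-preserving and the reported "power" is an empirical type-I
error at the chosen $\alpha$.

## What the generator emulates — and what it does not

The synthetic-data module is first-class, tested code; every pipeline stage
is validated against its truth manifests.

* `make_domain_families()` plants domain families: per family a random
  ancestor (120–300 residues) and members carrying substitutions at a
  fraction $(1 - \text{within\_id})/2$ of positions, so within-family
  pairwise identity lands near the target (realized values are recorded in
  the manifest; the generator refuses targets at or below 0.5, which
  substitution-only mutation cannot reliably hit). Families of one domain are mutually unrelated, so a
  cutoff between the within- and between-family identities recovers the
  families exactly.
* `make_reference_and_reads()` reverse-translates members with uniform codon
  choice (codon bias is irrelevant to everything tested), embeds each in its
  own contig between random flanks on a random strand and frame offset, and
  draws per-sample reads: Poisson-many 100-base reads per region, uniform
  within the region, plus background reads confined to the flanks so that
  region counts are uncontaminated at zero error rate. Planted low-quality
  reads get 60% of their bases at Q2, safely past the inclusive 50%-below-Q10
  removal rule; everything else is Q35.
* `make_count_matrix()` produces negative-binomial feature-by-sample counts
  (variance $\mu + \phi\mu^2$; $\phi = 0$ is Poisson) around log-normal
  size factors, with an optional planted fold change in one group and a
  truth table.

All generators take a seed, use an isolated RNG stream, and are
byte-reproducible. What they deliberately do not emulate: realistic
taxonomic composition or GC content, insertion/deletion sequencing errors,
chimeric or fragmented assemblies, paired-end structure, and
position-dependent quality profiles. Passing tests therefore demonstrate
the correctness of the algorithms under the stated model, not robustness to
every artifact of real gut-metagenome data.

## Problem sizes and numerical choices in the checks

The shipped checks run at deliberately modest scale, chosen as the package's
own test design: oracle-equivalence tests use a few hundred random instances
with sequences up to ~40 residues; GLM calibration uses 50 replicates of 500
null negative-binomial features at 15 + 15 samples (expected type-I fraction
near 0.05), plus a planted 7-fold panel for sensitivity; the dilution
experiment uses 10 bins × 4 fine sub-bins × 3 regions, 5 + 5 samples and 20
iterations; the fold-change calibration averages over 12,000 thinned
features. Determinism is checked by hashing every pipeline output file
across two runs from the same seed.

## Known limitations

* The identity definition (all alignment columns, fixed scoring) is one of
  several defensible conventions; thresholds are not numerically
  interchangeable with those of other tools, even where the algorithmic
  semantics match.
* Greedy centroid clustering is input-order dependent by construction
  (length, then id); it is deterministic but not order-free, and sub-bins
  across cutoffs need not nest.
* The naive mapper is for toy data; its exact-seeding geometry caps the
  tolerable error rate well below what production mappers handle.
* Per-feature dispersion estimated from 28 degrees of freedom is noisy; the
  floor at 1 protects size but costs a little power on truly Poisson data.
* Sub-bins inherit their parent's functional annotation; finding that a
  sub-bin responds says *which sequences* respond, not what they do —
  downstream sequence comparison is needed for that.
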