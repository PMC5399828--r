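# finebin

High-resolution functional binning and differential abundance analysis for
shotgun metagenomes.

## The problem

Gene-centric metagenome analysis pools sequence reads into *bins* — one per
annotated functional domain (TIGRFAM, PFAM, COG) — and compares bin counts
between conditions. Domain families are broad by design, so a single bin
typically mixes many distinct gene variants. When only some variants respond
to a condition, or different variants respond in opposite directions, the
pooled count barely moves and the effect is **diluted** out of reach of the
statistical test. finebin inserts an unsupervised step between annotation
and testing: the amino-acid sequences of each domain's annotated instances
are clustered at a sequence-identity cutoff, splitting each bin into
**sub-bins** that are quantified and tested separately. A resampling
framework with planted effects measures how much fold change and power are
lost when a fine-level effect is read out at coarser levels.

It is aimed at researchers analysing assembled metagenomes (contigs +
per-sample FASTQ reads) who already run a profile-HMM annotation and a read
mapper, and want sub-domain resolution in the downstream statistics.

## What it computes

For one feature (bin or sub-bin) with counts $y_j$ over samples, finebin
fits the overdispersed Poisson GLM

$$\log E[y_j] = \beta_0 + \beta_1 x_j + o_j,$$

with $x_j$ the condition indicator and $o_j$ a log library-size offset.
Dispersion is per-feature Pearson $\chi^2/(n-2)$, floored at 1;
$\mathrm{se}(\hat\beta_1)$ is the Poisson standard error inflated by
$\sqrt{\hat\varphi}$; p-values come from a two-sided t test with $n-2$
degrees of freedom and are Benjamini–Hochberg adjusted across the level.
Sub-bins are produced by greedy centroid clustering (UCLUST-style
first-qualifying-centroid assignment, complete-linkage agglomeration as an
alternative) on global-alignment identity with fixed scoring. Effects for
power evaluation are planted by binomial thinning: replacing counts $Y$ by
$\mathrm{Binomial}(Y, p)$ in one group yields an expected fold change of
$1/p$ (the default $p = 1/7$ targets 7-fold).

See `vignettes/finebin-methods.Rmd` for the full model description and
design decisions.

## Worked example

Everything below is synthetic and self-contained: the generator plants two
domains with three sequence families each, embeds them in contigs, simulates
reads, and we thin one sub-bin's counts 4-fold in the second group.

```r
library(finebin)
library(dplyr)

fam <- make_domain_families(n_domains = 2, families_per_domain = 3,
                            members_per_family = 4, within_id = 0.9, seed = 1)
sim <- make_reference_and_reads(fam, n_samples = 8, reads_per_region_mean = 40,
                                lowq_read_fraction = 0.05, seed = 2)

tbl <- tempfile(fileext = ".domtblout")
write_domtblout(sim$hits, tbl)
regions  <- annotate_reference(sim$refs, domtblout = tbl)   # supervised binning
clusters <- cluster_domains(regions, cutoff = 0.75)         # sub-binning

counts <- bind_rows(lapply(names(sim$reads), function(s) {
  aln <- naive_map(quality_filter(sim$reads[[s]]), sim$refs)
  count_overlaps(aln, regions, s)
}))

# plant a 4-fold drop in the first sub-bin for samples S05-S08
set.seed(3)
target <- clusters$region_id[clusters$subbin_id == clusters$subbin_id[1]]
for (s in sprintf("S%02d", 5:8)) {
  idx <- counts$sample_id == s
  y <- setNames(counts$count[idx], counts$region_id[idx])
  counts$count[idx] <- unname(downsample_counts(y, target, 1/4))
}

m <- build_matrix(counts, clusters) |> representativeness_filter(0.75)
design <- make_design(sprintf("S%02d", 1:8),
                      factor(rep(c("ctrl", "case"), each = 4),
                             levels = c("ctrl", "case")))
res <- run_differential_abundance(m, design, alpha = 0.05)
tidy(res) |> select(feature_id, logFC, se, p, fdr, significant)
```

```
# A tibble: 6 × 6
  feature_id       logFC     se          p       fdr significant
  <chr>            <dbl>  <dbl>      <dbl>     <dbl> <lgl>
1 DOM0001_0.75_1 -1.32   0.0912 0.00000667 0.0000400 TRUE
2 DOM0001_0.75_2  0.216  0.0559 0.00834    0.0250    TRUE
3 DOM0002_0.75_3  0.165  0.0561 0.0261     0.0523    FALSE
4 DOM0001_0.75_3  0.180  0.0668 0.0357     0.0536    FALSE
5 DOM0002_0.75_2  0.103  0.0566 0.120      0.144     FALSE
6 DOM0002_0.75_1  0.0336 0.102  0.752      0.752     FALSE
```

The thinned sub-bin is recovered with $\widehat{\log\mathrm{FC}} = -1.32$,
close to the planted $-\ln 4 = -1.39$, at FDR $4\times10^{-5}$. The small
positive estimates elsewhere are the compositional shadow of normalization:
removing most of one large sub-bin's reads shrinks the affected samples'
library sizes, so unchanged features drift slightly up — one of them past
the 0.05 threshold here, a reminder that library-size offsets redistribute,
rather than remove, large compositional shifts.

`run_power_experiment()` wraps the same machinery in a resampling loop
(random splits, planted binomial effects, per-level testing) and
`autoplot()` draws power and mean $|\log\mathrm{FC}|$ per clustering level;
`autoplot()` on a test result gives a volcano plot.

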