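# lobeconcord

Does the small airway epithelium of a smoker's upper and lower lobes respond
to cigarette smoke in the same way?  `lobeconcord` implements the analysis
pipeline for answering that question from paired probe-by-sample expression
data: if each subject's two samples carry the same individual response
signature, the two samples should be each other's nearest neighbours when
samples are clustered over the smoking-responsive genes — and that degree of
pairing should be unattainable by chance gene sets.

The package is aimed at transcriptomics analysts working with paired-site
bulk expression (classically MAS5-summarized microarray intensities, but any
probe-by-sample table fits), and at methodologists who want a tested,
reproducible implementation of the sibling-pairing statistic and its
random-gene-list null.

## The statistics at the core

**Sibling-pairing count.** Samples are clustered by agglomerative
hierarchical clustering (average linkage by default) on the correlation
distance `d(i, j) = 1 - cor(x_i, x_j)` (Pearson or Spearman) computed over a
probe list.  For each subject with one upper and one lower sample, the pair
counts as *clustered together* when the two samples are dendrogram
**siblings** — their first merge is with each other.  The statistic `k` is
the number of paired subjects out of `n` whose samples are siblings.

**Random gene-list null.** The same count is recomputed on `B` probe lists
of identical size drawn uniformly without replacement from the
present-filtered probe universe with the signature excluded.  The empirical
p-value uses the add-one convention

```
p = (1 + #{null k >= observed k}) / (B + 1)
```

so that `B = 100` lists and zero exceedances give `p = 1/101 ≈ 0.0099`.

**Supporting machinery**, each exposed as a pipe-friendly function:
per-chip / per-gene median normalization, present-call filtering (a probe is
kept when called present in ≥ 20 % of at least one sample group), classical
paired t-tests, an empirical-Bayes moderated t-test with posterior variance
`(d0*s0² + d*s²)/(d0 + d)`, Benjamini–Hochberg and Storey q-value FDR
control, signature derivation (fold change ≥ 1.5 and BH-adjusted p < 0.01),
PCA scores in signature space, and the paired vector-length statistic
(Euclidean distance between a subject's two samples over a probe list) with
its own random-list null.  A synthetic-cohort generator reproduces the
structure such a study assumes — 11 paired smokers, 60 nonsmokers, and a
planted block of smoking-responsive probes with subject-specific response
magnitudes *and* patterns — so the full pipeline is testable without any
data download.

## Worked example

```r
library(lobeconcord)

co <- generate_cohort(synthetic_config(), seed = 1)
#> Synthetic cohort: 11 paired smokers + 60 nonsmokers, 5000 probes
#> (529 responsive, 50 always-absent)

ann        <- co$annotation
paired_ids <- ann$sample_id[ann$group == "smoker"]
lin        <- co$expression[c("probe_id", paired_ids)]
attr(lin, "scale") <- "linear"

lg <- lin |> normalize_per_chip() |> normalize_per_gene() |> log2_transform()

universe <- present_filter(
  lin, co$detection[c("probe_id", paired_ids)],
  groups = list(upper = ann$sample_id[ann$site == "upper" & ann$group == "smoker"],
                lower = ann$sample_id[ann$site == "lower" & ann$group == "smoker"]))
length(universe)
#> [1] 4950

res <- pairing_permutation_test(lg, ann, co$signature, universe,
                                B = 100, method = "pearson", seed = 2)
res
#> Sibling pairing: 11 of 11 pairs (signature of 529 probes, pearson/average)
#> Null over 100 random lists: max 4, empirical p = 0.009901
```

All 11 subjects' upper/lower samples are siblings on the signature probes,
no random list of 529 probes pairs more than 4 of 11, and the add-one
empirical p is 1/101: the within-subject response signature, not chance,
drives the pairing.  The vector-length analysis on the same cohort shows the
complementary null behaviour — with no extra site variation planted outside
the signature, the observed median paired distance (8.30) sits in the middle
of the random-list medians (5 %–95 % range 8.15–8.46, `P(null <= obs)` =
0.49):

```r
vector_length_null(lg, ann, co$signature, universe, B = 100, seed = 3)
#> Median paired vector length: 8.298 over 11 pairs (signature of 529 probes)
#> Null medians over 100 random lists: median 8.299 [5%: 8.149, 95%: 8.46];
#> P(null <= obs) = 0.495
```

`tidy()`, `glance()` and `autoplot()` methods exist for every result object,
and `run_pipeline(config, out_dir, seed)` executes the whole chain
(simulate/read → normalize → signature → concordance → PCA and vector
lengths) and writes per-stage files plus a deterministic `report.json`.

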