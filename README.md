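# repclone

Clonal overlap analysis of TCR-β CDR3 repertoires across paired tissues.

## What it is for

When T cell subsets are sorted from two sites of the same donor — for
example human lung and lung-draining lymph node (LDLN) — each sorted
sample yields a table of TCR-β CDR3 clonotypes with read counts. The
scientific question is whether phenotypically identical memory subsets
(CM, EM, TRM) at the two sites descend from shared expanded clones or
from separate progenitor pools. `repclone` is for immunologists and
computational biologists who have such clone tables (MiXCR- or
AIRR-style exports) and want the standard quantitative battery:

- **clonotyping**: productive-rearrangement filtering and collapse of
  reads into clonotypes by CDR3 *nucleotide* identity;
- **diversity**: clonality (1 − Pielou evenness) and analytic
  rarefaction, E[S<sub>m</sub>] = Σ<sub>i</sub> (1 −
  C(N−n<sub>i</sub>, m)/C(N, m));
- **overlap**: sample × clonotype frequency matrices restricted to
  shared clones, donor inclusion rules, top-overlap clone ranking for
  heatmaps;
- **tissue concordance**: per-donor hierarchical clustering of subset
  frequency vectors (Euclidean, complete linkage), a cluster-majority
  concordance tally of memory subsets, and an exact two-sided binomial
  test of the pooled tally against p₀ = 0.5;
- **MDS**: pooled classical (Torgerson) multidimensional scaling with
  per-donor distance-group summaries and Wilcoxon rank-sum comparisons;
- **V-J usage**: frequency-independent segment-usage tables (each clone
  counted once) with Pearson-residual and exact-binomial
  over/under-representation scores;
- **simulation**: a seeded generator of multi-donor two-tissue cohorts
  with controllable within-/cross-tissue sharing, power-law clone sizes
  and planted V-J bias, so every stage runs and is testable without
  sequencing data.

## Worked example

Simulate a cohort under the default study conditions — 6 donors, CD4
naive/CM/EM/TRM in lung and LDLN, 5,000 reads per sample, within-tissue
sharing 0.3 versus cross-tissue 0.02 — and test whether memory subsets
cluster by tissue:

```r
library(repclone)

cfg    <- synthetic_config(n_donors = 6, lineages = "CD4", seed = 1)
cohort <- generate_cohort(cfg)

cohort_concordance(cohort)
#> Tissue concordance: 36 of 36 memory subsets (6/6 donors included)
#> Exact binomial test (p0 = 0.5): P = 2.91e-11
#> Linkage: complete; rule: top2_majority

cen <- unique_clone_census(cohort)
sprintf("unique clones: %d; in >1 sample: %.1f%%",
        cen$total_unique, 100 * cen$fraction_multi_sample)
#> "unique clones: 123483; in >1 sample: 4.3%"
```

All six donors pass the inclusion rule (≥3 CD4 subsets per tissue, >150
shared clones) and all 36 memory subsets fall in the cluster dominated
by their own tissue, so the pooled binomial test is decisive. Only ~4%
of the 123k unique clonotypes recur in more than one sample — sharing is
the exception, which is exactly why restricting analyses to shared
clones matters.

The binomial test itself is desk-checkable; a tally of 32 concordant
memory subsets out of 35 gives

```r
binomial_concordance_test(32, 35)$p_value
#> [1] 4.176982e-07
```

i.e. 4.2 × 10⁻⁷ at two significant figures.

`run_pipeline(cfg, "out/")` executes every stage in order and writes
TSV/JSON/newick artifacts with a checksum manifest;
`summarize_run("out/")` prints a one-page summary. Real data enters the
same way: `run_pipeline(c("donor1.tsv", ...), "out/", dialect =
"mixcr-like")`.

See `vignettes/repertoire-overlap.Rmd` for the models, parameter
meanings and design choices.

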