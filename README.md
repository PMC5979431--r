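# txdrift

Fold-change and transcriptional drift-variance analysis of replicate
bulk RNA-seq expression matrices (RPKM), for three-arm aging designs:
a **young** reference cohort, an **aged** cohort, and an aged cohort
under an **intermittent-fasting (IF) style treatment**, measured in one
or more tissues with 2–3 replicates each.

The package is for researchers who have per-gene RPKM tables from such a
design (or want to prototype one) and need the two complementary
readouts of transcriptome aging:

1. **Fold-change classification.** With cohort means
   $\bar x_{gc}$, the aging fold change is
   $\mathrm{FC}^{\text{age}}_g = \bar x_{g,\text{aged}}/\bar x_{g,\text{young}}$
   and the treatment fold change
   $\mathrm{FC}^{\text{IF}}_g = \bar x_{g,\text{aged}}/\bar x_{g,\text{treated}}$.
   Genes are called at strict symmetric cutoffs
   ($\mathrm{FC} > 1.4$ or $< 1/1.4$ for age; $1.3$ for treatment);
   "youthful" genes are those whose treatment response reverses their
   age direction. Note the denominator convention: a gene restored
   *upward* by treatment has $\mathrm{FC}^{\text{IF}} < 1/1.3$.
2. **Drift-variance statistics.** Per-gene, per-sample drift
   $d_{gs} = \log_{10}(x_{gs}/\bar x_{g,\text{young}})$; the
   transcriptional drift-variance (TD) of a cohort is the variance of
   its pooled drift values, compared between cohorts with a gene-block
   permutation test. Per-gene variance Z scores
   $\mathrm{VZ} = \mathrm{SD}/\text{mean}$ (the replicate coefficient of
   variation) and variance changes
   $\mathrm{VC} = \mathrm{VZ}_A/\mathrm{VZ}_B$ flag genes whose
   replicate dispersion inflates with age and is suppressed by treatment
   ($\mathrm{VC} > 3.75$, strict).

Around these sit the standard supports: a strict $>1$ RPKM expression
filter defining the per-tissue gene universe, Welch tests on log2 values
with BH-adjusted columns, PCA quality control, hypergeometric gene-set
over-representation (GMT input), volcano/drift-plot/heatmap builders that
always emit their plotted values as TSV, and a deterministic synthetic
replicate-RPKM generator with a per-gene truth table so the whole
pipeline is testable without any external data.

## Worked example

```r
library(txdrift)

spec <- synthetic_spec(n_genes = 10000, seed = 42)   # head-like: 3+3+3 replicates
res  <- run_pipeline(spec, "txdrift_demo",
                     config = analysis_config(permutations = 999),
                     tissues = "head")

res$head$category_counts
#>   change_with_age age_down age_up change_with_if age_down_if_up age_up_if_down
#> 1            1925     1036    889           1829            500            363
#>   if_more_youthful
#> 1              863

res$head$drift_summaries[, c("cohort", "n_values", "drift_variance")]
#>         cohort n_values drift_variance
#> 1        young    28539    0.004935266
#> 2         aged    28539    0.033797528
#> 3 aged_treated    28539    0.019809010

res$head$drift_tests
#>           contrast   observed     p permutations
#> 1    aged_vs_young 0.02886226 0.001          999
#> 2  aged_vs_treated 0.01398852 0.001          999
#> 3 treated_vs_young 0.01487374 0.001          999
```

Reading the output: 9513 of 10,000 simulated genes exceed 1 RPKM in all
nine samples and form the analysis universe. 1925 genes cross the
1.4-fold age cutoff (the generator planted 1200 true 2-fold effects; the
surplus reflects replicate noise at CV 0.2 with n = 3, visible as such
because the truth table is available). The drift variance of the aged
cohort (0.0338) is ~7× the young value (0.0049), with the treated cohort
in between (0.0198) — the young < treated < aged ordering that defines
partial drift suppression by treatment — and each pairwise difference is
significant at the permutation floor p = 0.001. Every table is also
written under `txdrift_demo/head/`, with a `manifest.json` echoing the
full configuration.

A thin command-line wrapper for the same flows is installed at
`system.file("cli", "txdrift.R", package = "txdrift")`
(subcommands `simulate` and `run-all`).

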