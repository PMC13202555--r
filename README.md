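# mobindex

Contig-level co-localization indices for resistance and virulence genes
in soil metagenomes, with the statistical layer needed to analyze them.

## The science

In metal-contaminated soils, metal-resistance genes (MRGs), antibiotic
resistance genes (ARGs), and virulence factor genes (VFGs) are
co-selected: metal stress maintains resistance determinants even
without antibiotic exposure, and when those determinants sit next to
mobile genetic elements (MGEs) — plasmids, phages, insertion sequences,
transposons, integrons, ICEs — they can move between bacteria by
horizontal gene transfer. Assembled contigs make this physical linkage
observable: two genes on one contig are genuinely co-located on one DNA
molecule, and a resistance gene on a plasmid-like or MGE-carrying
contig is plausibly mobile.

`mobindex` quantifies this with three per-sample indices computed from
filtered annotation tables (E-value ≤ 1e-5 and identity ≥ 80%, best
hit per contig-gene pair):

- **Carrying rate** — CR(c) = N_contigs(c) / N_contigs: the fraction of
  contigs carrying at least one gene of class c (MRG, ARG, or VFG). At
  the study scale of 100,000 contigs, one extra carrier changes CR by
  exactly 1 × 10⁻⁵.
- **Co-occurrence rate** — CoR(S) = N_contigs(all classes in S) /
  N_contigs: the fraction of contigs on which two or three classes are
  physically co-located.
- **Mobility potential** — MP(c) = N_genes(c, MGE-associated) /
  N_genes(c): the fraction of class-c *genes* on contigs that carry an
  MGE marker or are classified as plasmid/phage. A sample with no
  class-c genes has MP missing (0/0 = `NA`), never zero.

Around the indices the package provides alpha diversity (Shannon,
richness, Pielou), Bray–Curtis and Morisita–Horn dissimilarity with
PCoA and permutation-exact PERMANOVA, Spearman screens, and an
environmental driver regression cascade — VIF screen, then OLS if its
residuals pass normality and homoscedasticity tests, Huber M-estimation
if not, and Bayesian linear regression (priors normal(0, 0.5) and
exponential(5) on standardized scales, Gibbs sampling with split R-hat
/ ESS diagnostics) for small or ill-behaved samples. A seeded synthetic
generator with closed-form expected indices makes every layer testable
end to end. See the vignette `vignettes/colocalization-methods.Rmd` for
the full methods.

## Worked example

Simulate the default study design — 12 samples (8 metal-contaminated,
4 control), 5,000 contigs each, with vanadium raising ARG carriage by
5 × 10⁻⁵ per mg/kg — then recover that effect from the synthetic
annotation tables:

```r
library(mobindex)

cfg <- synth_config(seed = 101)
ds  <- generate_dataset(cfg)
sets <- build_dataset(ds$contigs, ds$hits, ds$metadata)
idx  <- index_table(sets)
idx[1:4, c("sample_id", "cr_mrg", "cr_arg", "cr_vfg", "cor_all3", "mp_arg")]
#>   sample_id cr_mrg cr_arg cr_vfg cor_all3 mp_arg
#> 1       S01 0.0224 0.0168 0.0172        0 0.0238
#> 2       S02 0.0228 0.0128 0.0164        0 0.1719
#> 3       S03 0.0218 0.0156 0.0164        0 0.1026
#> 4       S04 0.0234 0.0142 0.0178        0 0.0986

# community distance between groups (ARG composition, Morisita-Horn)
mat <- abundance_from_hits(resolve_best_hit(filter_hits(ds$hits)), "ARG")
d   <- dissimilarity_matrix(mat, "horn")
groups <- ds$metadata$group[match(rownames(as.matrix(d)),
                                  ds$metadata$sample_id)]
permanova(d, groups, seed = 1)
#> PERMANOVA: pseudo-F = 0.9426  R2 = 0.08614  p = 0.4505 (exhaustive)

# driver analysis: which metals move the ARG carrying rate?
merged <- merge(idx, ds$metadata, by = "sample_id")
auto_cascade("cr_arg", c("V", "Ni", "Zn", "pH"), merged, seed = 1)
#> regression_result (mlr)
#>          term   estimate      lower     upper
#> 1 (Intercept)  2.137e-02 -1.453e-03 4.420e-02
#> 2           V  4.783e-05  1.572e-05 7.994e-05
#> 3          Ni -3.912e-05 -1.387e-04 6.049e-05
#> 4          Zn  1.692e-06 -3.517e-05 3.855e-05
#> 5          pH -1.330e-03 -4.337e-03 1.678e-03
```

The cascade stays on ordinary least squares (residual checks pass) and
the 95% interval for V, [1.6 × 10⁻⁵, 8.0 × 10⁻⁵], covers the configured
truth of 5 × 10⁻⁵; the null Ni/Zn/pH intervals all cover their true
values too (−6 × 10⁻⁵, −1 × 10⁻⁵, 0). The whole run is reproducible
from the single seed, including the Gibbs sampler had it been selected.

A complete pipeline run (`run_all()` / `mobindex run --config run.yaml`)
writes `indices.tsv`, diversity tables, `regression_results.json`, and a
manifest whose rerun is byte-identical.

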