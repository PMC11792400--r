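# decomplex

Decomposer–exploiter dynamics in plant residue decomposition: CAZyme
scoring, trophic-role classification, and community flux balance
analysis with cross-feeding.

## The problem this package addresses

Plant residue decomposition — the process feeding the largest
terrestrial soil organic carbon pool — is carried out jointly by fungi
and bacteria, but not symmetrically. Fungal genomes are rich in the
residue-attacking enzymes (cellulases, xylanases, ligninolytic enzymes:
CXLs), while bacterial genomes typically carry only one or two such
genes alongside large repertoires of oligosaccharide and
polysaccharide-branch hydrolases (OHs/PBHs) that consume the *products*
of decomposition. Communities therefore organize into fungal
**decomposers** and bacterial **exploiters**. `decomplex` is an R
toolkit for microbial ecologists studying this division of labour from
genome annotations, amplicon tables, homology hits, and small
constraint-based metabolic models.

At its core are three pieces of machinery:

**1. The plant residue decomposition index (PDI).** For genome *i* in
a pool with per-term totals *T*, with *D* terms counting cellulase,
xylanase, ligninolytic, OH+PBH, and total non-GT CAZyme genes plus two
family diversities:

    PDI_i = 0.30 D_ci/T_c + 0.30 D_xi/T_x + 0.05 D_li/T_l
          + 0.10 D_opi/T_op + 0.10 D_gci/T_gc + 0.10 D_fi/T_f
          + 0.05 D_di/T_d

Pool normalization makes PDIs sum to exactly 1 over any pool.

**2. Flux balance analysis and carbon utilization breadth (CUB).**
Growth is the solution of `maximize biomass s.t. S v = 0, lb ≤ v ≤ ub`;
a carbon source counts as utilized only when it yields both growth and
CO2 release; CUB is the number of utilizable sources. Alternate optima
are resolved by minimizing total absolute flux so secretion sets are
deterministic.

**3. Community simulation across an uptake-flux ladder** (0.01 → 1000
mmol·gDW⁻¹·h⁻¹) with pooled cross-feeding: secreted byproducts are
pooled (floored at 0.01), capped so that pooled secreted carbon never
exceeds community uptake carbon times the community secretion
efficiency (CCSE), and fed back in a second FBA pass. Reported
statistics: ANAC (mean absorbed sources), CST (distinct secreted
types), CSE/CCSE (carbon-weighted secretion efficiency), CGRV (growth
slope across ladder rungs), growth-rate skewness, and the relative
divergence RD of growth with vs without cross-feeding.

Every input can also be *generated*: seeded synthetic CAZyme profiles,
toy metabolic models, abundance tables, hit tables, and expression
records with the statistical structure the analysis assumes, so the
full pipeline runs offline.

## Worked example

Score a two-genome pool and classify trophic roles:

```r
library(decomplex)
p <- data.frame(
  genome_id = rep(c("Trichoderma_sp", "Bacillus_sp"), times = c(4, 3)),
  kingdom   = rep(c("fungi", "bacteria"), times = c(4, 3)),
  family    = c("GH7", "GH10", "AA2", "GH3", "GH1", "GH3", "GH5-2"),
  count     = c(9, 4, 6, 7, 12, 9, 1)
)
pdi <- compute_pdi(p)
print(pdi, digits = 3)
#>        genome_id  kingdom d_c d_x d_l d_op d_gc d_f d_d   pdi
#> 1 Trichoderma_sp    fungi   9   4   6    7   26   3   4 0.778
#> 2    Bacillus_sp bacteria   1   0   0   21   22   3   3 0.222

ohpbh_cxl_ratio(pdi)
#> [1]  0.368 21.000

classify_trophic_role(c(0, 7), c(0.03, 5e-5), "observational")
#> [1] "exploiter"  "decomposer"
```

The fungus holds 78% of the pool's degradative weight; the bacterium's
OH+PBH-to-CXL ratio of 21 is the exploiter signature, and the
observational thresholds (≤ 2 CXL genes at ≥ 1% abundance vs ≥ 5 genes
at ≤ 0.1‰) classify accordingly.

Simulate a 40-model synthetic community across the flux ladder:

```r
cfg    <- generator_config(seed = 1)       # 2000+200 genomes, 40 models
models <- gen_toy_models(cfg)
med    <- base_medium(cfg)
res    <- simulate_with_crossfeeding(models, med, flux_level = 10)
community_metrics(res$individuals, 10)
#>   flux_level  anac cst       ccse mean_growth  skewness
#> 1         10  8.55   8 0.05288338    9.918824 0.9358857
res$rd
#> [1] 0.06441829
```

At starvation (flux 0.01) the same community absorbs ~16 sources each
with zero secretion; under plenty (flux 1000) it narrows to ~8 rich
sources and secretes measurably — cross-feeding gains peak in between.
The end-to-end pipeline (`run_pipeline()`, or `exec/decomplex run-all`)
writes per-stage TSVs and a reproducibility manifest.

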