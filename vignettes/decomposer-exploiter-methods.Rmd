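---
title: "Models and methods: decomposer-exploiter dynamics in plant residue decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: decomposer-exploiter dynamics in plant residue decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decomplex)
```

## The scientific problem

During plant residue decomposition, fungi and bacteria divide labour:
fungi carry and express the residue-attacking enzymes — cellulases,
xylanases, and ligninolytic enzymes, collectively CXLs — while bacteria
disproportionately carry oligosaccharide hydrolases (OHs) and
polysaccharide-branch hydrolases (PBHs), enzymes that consume the
*products* of decomposition rather than the polymer backbone. That
asymmetry defines two trophic roles: *decomposers*, which attack the
residue, and *exploiters*, which free-ride on the released sugars. This
package provides the quantitative machinery for studying that division:
a genome-level degradative score (the PDI), trophic-role classification
rules, and a community flux-balance-analysis framework that explains
when exploiters can outgrow decomposers and how cross-feeding shapes
community growth under carbon limitation.

## The plant residue decomposition index

A genome's CAZyme families are classified into functional groups by the
shipped catalog (29 cellulase, 10 xylanase, 4 ligninolytic, and 50
OH/PBH families, with subfamily resolution such as `GH5-1` versus
`GH5-21`); glycosyltransferases (`GT*`) are excluded from all
degradative statistics. Seven per-genome quantities are computed: gene
counts of the four groups ($D_c$, $D_x$, $D_l$, $D_{op}$), the total
non-GT CAZyme count ($D_{gc}$), and two family diversities — distinct
cellulase/xylanase/OH+PBH families present ($D_f$) and distinct non-GT
families present ($D_d$). For genome $i$ scored in a pool with term
totals $T_k$,

$$\mathrm{PDI}_i = 0.30\frac{D_{ci}}{T_c} + 0.30\frac{D_{xi}}{T_x}
  + 0.05\frac{D_{li}}{T_l} + 0.10\frac{D_{opi}}{T_{op}}
  + 0.10\frac{D_{gci}}{T_{gc}} + 0.10\frac{D_{fi}}{T_f}
  + 0.05\frac{D_{di}}{T_d}.$$

Cellulase and xylanase carry the highest weights because cellulose and
xylan are the dominant residue polysaccharides; ligninolytic enzymes
carry the lowest because lignin attack releases little usable carbon.
Because every term is pool-normalized, PDI values sum to exactly 1 over
any pool — a property the test suite asserts to $10^{-12}$.

Two design points were genuinely open and are decided here:

* **Zero pool totals.** If some term's pool total is zero the ratio is
  undefined; we define such a term to contribute 0 for every genome
  (with a warning). This keeps the sum invariant meaningful on
  degenerate pools rather than failing.
* **"Exceeding semi-range."** Enrichment against the semi-range line is
  computed as the fraction of values *strictly above*
  $\min + (\max - \min)/2$; "exceeding" reads as strict. Both the
  semi-range and the percent-of-maximum conventions are implemented in
  `pdi_enrichment()`.
* **Family diversity counts presence, not abundance** — $D_f$ and
  $D_d$ count families with at least one gene, since they measure
  repertoire breadth, which is how a "families of" quantity reads.

Trophic roles follow two schemes in `classify_trophic_role()`. The
*observational* scheme combines the matched genome's
cellulase+xylanase count with the taxon's mean relative abundance:
exploiters have $\le 2$ genes and abundance $\ge 1\%$; decomposers have
$\ge 5$ genes and abundance $\le 0.1\unicode{x2030}$. The
*synthetic-community* scheme uses counts alone (0 genes: exploiter;
1–2: intermediate; $> 2$: decomposer). Abundance is averaged across
samples because a role is a property of a taxon, not of one sample.

## Flux balance analysis

Models are small carbon-only stoichiometric networks: metabolites carry
integer carbon-atom counts, exchange reactions touch exactly one
metabolite (negative flux = uptake), and one biomass reaction is the
objective. `solve_fba()` maximizes biomass flux subject to
$S v = 0$ and the bounds, with the medium setting each allowed
exchange's lower bound to $-L$ for uptake limit $L$; unlisted
exchanges are secretion-only. Mineral nutrients are not modelled: every
community statistic here depends on carbon exchanges alone.

FBA problems are degenerate linear programs with many alternate
optima, and the secretion sets we extract from flux vectors would
otherwise be solver-dependent. Two numerical decisions address this:

* **Parsimonious resolution.** Among optimal solutions the reported
  flux vector additionally minimizes total absolute flux (a second LP
  on the split $v = p - n$), making uptake and secretion sets
  deterministic.
* **The LP core** is a bounded-variable two-phase primal simplex
  written for this package. It recomputes the basic solution from a
  fresh factorization at every iteration and falls back from Dantzig
  to Bland's pivoting rule when progress stalls, which guarantees
  termination on the highly degenerate bases these problems produce.
  The suite verifies it against a brute-force vertex-enumeration
  oracle on hundreds of random small models to $10^{-9}$.

A model *utilizes* a carbon source when, with only that source allowed
at an unrestricted uptake of 1000 mmol·gDW⁻¹·h⁻¹, it achieves growth
**and** CO2 release above a noise floor of $\varepsilon = 10^{-6}$
(growth without respiration does not count). Carbon utilization breadth
(CUB) is the number of such sources out of the shared catalog.

## Community simulation and cross-feeding

Communities are simulated member-by-member across an uptake-flux ladder
(0.01 to 1000 mmol·gDW⁻¹·h⁻¹ in 14 steps); no spatial structure and no
resource depletion between members is modelled, so community statistics
are aggregates of independent individual solutions. Per level we
report: ANAC, the mean number of absorbed sources; CST, the number of
distinct secreted carbon types (CO2 excluded); CSE, each member's
carbon-atom-weighted secretion/uptake ratio, and CCSE, its
growth-weighted community average; the adjusted Fisher–Pearson
skewness of growth rates; and CGRV, the finite-difference slope of
community mean growth between adjacent ladder levels (the pairing
between adjacent rungs is a package decision — only the quotient's
form is fixed by its definition).

Cross-feeding is a two-pass scheme. Pass 1 runs every model on the
base sources; secreted byproducts are pooled per metabolite, entries
below 0.01 mmol·gDW⁻¹·h⁻¹ are discarded (floor first, then scaling,
following the order in which the rules are stated), and the pool is
capped so that

$$\beta \sum_p \text{pooled}_p \, C_p \;\le\; \mathrm{CCSE} \times
  \sum_t \text{uptake}_t \, C_t,$$

i.e. the community cannot collectively consume more secreted carbon
than it actually secreted. Three open points are decided here: $\beta$
defaults to 1 (the rule's verbal gloss — pooled secretion carbon "does
not exceed" uptake carbon times CCSE — implies unit scaling, and it is
exposed as a config knob); the right-hand side uses *realized* pass-1
uptake fluxes, not nominal bounds; and when the pool exceeds the cap
all pooled fluxes are scaled down proportionally to meet it with
equality. Pass 2 re-runs every model with the pooled secretions added
as uptake-limited sources (each capped by the smaller of its pooled
flux and the ladder flux). Since pass 2 only relaxes the feasible set,
every member's growth is non-decreasing, and the relative divergence

$$\mathrm{RD} = \frac{G_{\text{cross}} - G_{\text{non}}}
  {(G_{\text{cross}} + G_{\text{non}})/2} \in [0, 2]$$

of community mean growth is non-negative (0 when both means are 0, by
definition). For decomposer/exploiter contrasts the reported growth
ratio is the ratio of group means; the group means themselves are also
returned so users preferring other composites can form them.

## What the synthetic generator emulates

All inputs can be generated offline under a single seeded config, and
the defaults are fixed study conditions, not tuning knobs:

* **CAZyme profiles.** Per-group gene totals are negative binomial
  (dispersion size 2 — family counts across genomes are strongly
  overdispersed) with bacterial means 1.59/0.72/0.86/16.36 for
  cellulase/xylanase/ligninolytic/OH+PBH and fungal means
  25.84/6.04/14.25 for the CXL groups, following published
  genome-survey averages. Values that surveys do not publish as means
  (fungal OH+PBH, GT and other non-GT counts) are set once to
  realistic magnitudes (40; 15/30; 5/15). Within a group, genes are
  allocated uniformly across families — the per-family distribution is
  not documented empirically, so uniformity is a declared assumption,
  not evidence.
* **Toy metabolic models.** 35 abstract carbon sources `C01..C35`
  carry 2–6 carbon atoms (only atom counts matter to the statistics;
  source identities are not reproduced). Each model draws a niche of
  4–28 sources (real CUB spans roughly 1–32) and, per source, an
  efficient pathway (1 source → (C−1) biomass precursor + 1 CO2)
  capped at 3 mmol·gDW⁻¹·h⁻¹, plus, with probability 0.6, an
  uncapped overflow pathway that diverts part of the carbon into one
  of 8 shared byproducts. Biomass is capped by a lognormal maximum
  growth rate (meanlog $\log 8$, sdlog 0.6). This is the smallest
  family in which FBA, CUB, CSE, and cross-feeding are all
  non-trivial, and it reproduces the qualitative ladder structure:
  at low flux every source is needed (ANAC high) and the capped
  efficient pathway carries everything (secretion exactly zero below
  3 mmol·gDW⁻¹·h⁻¹); at high flux few rich sources suffice (ANAC
  low) and overflow secretion appears (CST and CCSE rise), with
  cross-feeding gains peaking at intermediate flux.
* **Abundances and hits.** One OTU per bacterial genome; 76% of total
  abundance sits on low-CXL genomes (the exploiter-dominant regime);
  hit tables span the matching decision boundaries (97/95 strict band,
  95–97 relaxed band, rejects, near-tie decoys).

What passing tests on these data do **not** show: real genomes have
correlated family repertoires and phylogenetic structure; real
metabolic networks share pathways and cofactors across sources; real
communities deplete resources and interact spatially. The generator
validates the *rules and statistics*, not ecological realism.

## Tabular decision rules

OTU-to-genome matching is two-pass: identity ≥ 97% and coverage ≥ 95%,
then unmatched queries retried at identity ≥ 95%; exactly one genome is
kept per query ("highest similarity" is resolved identity → coverage →
bitscore → lexicographic subject id, since no tie rule is stated), and
strict matches are never displaced by relaxed ones. Kingdom votes
retain hits within 95% of the best bitscore and require a strict
majority (a 50/50 retained set is unclassified). CAZyme-to-genome
assignment keeps hits at ≥ 70% identity and ≥ 70% coverage, one best
hit per query, idempotently. Residue complexity is defined as the
cellulose + lignin mass fraction — the definition names the two
recalcitrant polymers without fixing a formula, so the additive
composite is the package's choice and the formula argument is
pluggable.

## Problem sizes and reproducibility

The default study conditions are 2000 bacterial + 200 fungal genomes,
40 models, and the 14-level ladder; a full pipeline run takes well
under a minute on one core, and the test suite's community checks use
6–8 model communities at a handful of ladder rungs. Every generator is
a pure function of its config (seed included) and restores the
caller's RNG state; `run_pipeline()` writes a manifest (seed, package
version, config hash) from which byte-identical numeric outputs can be
re-derived.

```{r}
cfg <- generator_config(seed = 1, n_bacteria = 120, n_fungi = 30,
                        n_models = 8)
models <- gen_toy_models(cfg)
med <- base_medium(cfg)
do.call(rbind, lapply(c(0.1, 5, 1000), function(fl) {
  res <- simulate_with_crossfeeding(models, med, fl)
  cbind(community_metrics(res$individuals, fl), rd = res$rd)
}))
```

## Known limitations

* The simplex core is dense and refactorizes each iteration: right for
  models with tens of reactions, wrong for genome-scale networks with
  thousands.
* Models are carbon-only; nitrogen or mineral co-limitation, explicit
  maintenance ATP, and thermodynamic constraints are out of scope.
* Community statistics assume independent members (no depletion, no
  spatial structure); cross-feeding is a one-shot two-pass scheme, not
  a dynamic equilibrium.
* The PDI is a repertoire score: it weights gene counts and family
  breadth, not expression or enzyme kinetics.
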