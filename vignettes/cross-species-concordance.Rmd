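---
title: "Methods: differential expression and cross-species gene-set concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and cross-species gene-set concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdeg)
```

## The problem

Mouse models of lupus nephritis differ widely in which immune pathways they
engage, and none reproduces human SLE kidney disease in full. To choose a
model for a given target, one wants to know — pathway by pathway — whether
the model's transcriptional response *moves in the same direction* as the
human response. `crossdeg` implements that comparison for targeted count
panels: per-gene differential expression in each mouse model, pathway-level
DEG burden, and a directional concordance analysis against a human
differential-expression profile (bulk tissue or a per-cell-type contrast
from single-cell data).

## Differential expression on targeted panels

The input is a gene × sample matrix of normalized counts (the package
accepts pre-normalized matrices as its primary contract; a transparent
geometric-mean scaler, `normalize_geomean()`, is available when only raw
counts are at hand). For each gene, expression is log2-transformed with a
pseudocount and a classical one-way ANOVA compares the diseased and naive
groups. With exactly two groups the F statistic is the square of the
pooled-variance t statistic, and the implementation exploits this identity
for a fully vectorized per-gene computation; the test suite checks it
against a textbook sum-of-squares oracle and against `stats::oneway.test`
to 1e-10.

Assumptions: log2 counts approximately Gaussian within group, equal
variances across the two groups (classical ANOVA, no Welch correction by
default), and no covariates — the targeted-panel study design here is a
single two-group contrast per model.

Multiplicity is handled with Benjamini–Hochberg across the panel,
separately per model (each model is its own experiment with its own
ANOVA family). A gene is a DEG when

* adjusted p < `q_threshold` (default **0.1**, strict inequality), and
* |log2FC| ≥ log2(`fc_threshold`) (default **1.5-fold**, inclusive —
  "at least a 1.5-fold change" admits exactly 1.5), symmetric for up- and
  down-regulation.

The signed fold change reports ratios below one as negative reciprocals
(0.25 → −4), the display convention of panel-analysis reports.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `pseudocount` | 1 | counts | keeps log2 defined at zero counts; negligible at panel-typical expression (counts ≥ 16) |
| `q_threshold` | 0.1 | adjusted p | conventional FDR target for exploratory panel screens |
| `fc_threshold` | 1.5 | linear ratio | filters statistically significant but biologically trivial shifts |

### Degenerate inputs

A gene with zero within-group variance and equal group means gets F = 0,
p = 1. Zero variance with *unequal* means (possible in near-noiseless
synthetic data after count rounding) would make F infinite; the package
reports p at the smallest positive double and raises a warning rather than
failing, so batch simulation runs survive degenerate genes while leaving a
visible trace.

## Pathway DEG summaries

`pathway_deg_summary()` reports, per (model, pathway), the number of
pathway genes **measured on the panel** that are DEGs, and the percentage
with that intersection as the denominator. Using pathway∩panel rather than
the full curated pathway is deliberate and changes every percentage: a
44-gene denominator on a panel is typically much smaller than the curated
pathway, and the "x% (k/n)" display makes the denominator explicit.
Percentages are shown rounded half-up to whole percent next to the exact
fraction. A pathway disjoint from the panel yields a row with n = 0 and a
missing percentage, plus a warning.

## Cross-species association

### Ortholog pairing

Mouse and human profiles are paired on a shared symbol universe. The
default rule is case-insensitive symbol equality (*Stat1* ↔ *STAT1*),
which resolves the overwhelming majority of one-to-one orthologs on
immunology panels; a user-supplied two-column table overrides the rule
where it fails (true renamings, many-to-one families). A user table mapping
two mouse genes onto one human symbol is an error by default — the map must
be a function — unless `collapse = "mean"` is requested, which averages the
mouse changes. Unmapped genes are dropped and counted in a message.

### Signed ranks and the score

Within the common universe of N genes, each gene's log2 fold change Δ gets
a signed rank r = sign(Δ) · rank(|Δ|), ranks ascending in |Δ| from 1 to N
with average ranks at ties. For a pathway G the association score is

$$S \;=\; \frac{\sum_{g\in G} r_m(g)\, r_h(g)}{\sum_{g\in G} |r_m(g)|\,|r_h(g)|}.$$

Three design choices deserve explanation, because the score admits several
constructions:

* **Normalizer.** Dividing by $\sum |r_m||r_h|$ over the *same* pathway
  genes is the unique simple constant that both bounds S in [−1, 1] and
  makes the endpoints exact: S = +1 iff every used gene pair agrees in
  sign, S = −1 iff every pair disagrees. A Spearman-style normalization
  over the global universe would bound the score but could not reach ±1 on
  a pathway subset, breaking the "perfectly mimics / perfectly reverses"
  endpoint semantics.
* **Rank scope.** Ranks are computed over the full common universe and then
  subset to the pathway (the GSEA-like convention). This keeps S sensitive
  to whether a pathway's changes are large *relative to the rest of the
  response*; per-pathway re-ranking is available via
  `rank_scope = "pathway"` for sensitivity analysis.
* **Which genes enter.** All common genes with finite changes are ranked —
  not only significant ones. The score measures concordance of the whole
  response profile; DEG status enters only through the optional
  `require_degs` flag, which drops models with zero DEGs from the analysis
  entirely (a model with no detectable response has no direction to
  compare).

Ties in |Δ| get average ranks; a gene with Δ = 0 carries sign +. Both are
logged. These conventions only matter on discretized or thresholded
profiles — with continuous log2 fold changes, ties and exact zeros have
probability zero.

The score inherits useful invariances, all property-tested: it is exactly
antisymmetric under negating one profile; it is invariant to any strictly
increasing transform of |Δ| in either species (only signs and rank order
matter); and under independent random signs its mean over many pathways is
statistically indistinguishable from 0.

### Proportional association

P = k/n is the fraction of pathway genes whose change direction agrees
between species. Genes with an exactly zero change in either species carry
no direction and are excluded from the denominator (with a message) — a
convention the "(k/n)" display makes auditable. For display, P is rounded
half-up to 2 decimals ("1.0" at unity), e.g. "0.77 (27/35)". Half-up
rather than R's default round-half-even matches how such fractions are
conventionally printed.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every calibration claim in the test suite is made.

`simulate_panel_counts()` emulates a targeted autoimmunity panel: 770
genes, 2–9 replicates per group (the defaults, 5 naive vs 7 diseased,
match a typical model cohort). Per-gene baseline log2 means are drawn
Uniform(4, 12) — counts from ~16 to ~4000, the working range of a count
panel — sample values add Gaussian noise on the log2 scale (default SD
0.5, a realistic between-animal biological CV), diseased samples are
shifted by the planted log2 fold change, and counts are `round(2^x)`. The
Gaussian-on-log2 generative model matches the downstream ANOVA's
assumptions by construction, which is the point: calibration tests isolate
the statistics from distributional mismatch.

What it does **not** emulate: NanoString technical structure (lane
effects, positive-control titrations, background thresholding),
overdispersed count noise, or correlated genes. Passing calibration tests
therefore demonstrates that the statistical machinery is correct under its
own assumptions, not that real panel data satisfy those assumptions.

`simulate_paired_profiles()` plants directional concordance: for each
pathway of size n with target fraction ρ, **exactly** `round(ρ·n)` genes
are made sign-concordant — a deterministic assignment via a seeded shuffle,
not a Bernoulli draw — so recovery of the planted fraction is exact and
testable with equality rather than approximately. Magnitudes are drawn
independently per species (lognormal by default, strictly positive), since
directional concordance is a statement about signs only.

All randomness flows through R's Mersenne-Twister stream from a single
integer seed; replicate ensembles (`simulate_null_panel()`) derive
per-replicate seeds deterministically from the master seed, so every
generated object is bit-reproducible from (parameters, seed).

## Calibration and recovery: the problem sizes used

The acceptance-level tests run at the study's own scale, chosen to make
Monte-Carlo error small relative to the quantities checked while keeping a
default test run fast:

* **FDR calibration**: 500 replicate all-null 770-gene panels at n = 5/7;
  the realized false-discovery proportion at q < 0.1 (no fold-change
  filter) must not exceed 0.1 by more than 3 Monte-Carlo standard errors.
* **DEG sensitivity**: 500 replicates with 50 genes per panel planted at
  4-fold (log2FC 2), within-group SD 0.25; pooled sensitivity must exceed
  0.9.
* **Null score behavior**: 1000 random-sign 50-gene pathways; the mean
  score must lie within 3 standard errors of 0.
* **Oracle agreement**: ANOVA against a brute-force sum-of-squares oracle
  at 1e-10; BH against an independent step-up implementation on 1000
  random p-vectors at 1e-12.

## The pipeline driver

`run_pipeline()` consumes a strict YAML config (unknown keys rejected by
name — silent typos in a config are a classic reproducibility failure),
runs whichever stages its inputs support, and writes all stage TSVs plus a
`manifest.json` recording the config hash, package version, seed, and
per-stage row counts. Outputs are deliberately timestamp-free so a rerun
with the same config is byte-identical.

## Known limitations

* The ortholog case rule is a heuristic; genuinely divergent symbols and
  many-to-many families need a user table.
* Classical ANOVA without variance moderation is noisy at n = 3 per group;
  an empirical-Bayes moderated test would gain power on real panels but is
  out of scope here, where the target is the plain two-group ANOVA chain.
* The association score comes with no permutation p-value; it is a
  descriptive connectivity measure, and its null behavior is characterized
  by simulation rather than analytically.
* Proprietary panel normalization and pathway annotations are treated as
  user inputs; the geometric-mean normalizer is a transparent stand-in,
  not a reimplementation of any vendor pipeline.
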