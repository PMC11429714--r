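---
title: "Kinase-substrate network inference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase-substrate network inference: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnet)
```

phosnet infers which kinases drive the phosphorylation changes observed in a
differential phosphoproteomics experiment, and scores candidate
kinase-substrate relationships into a weighted network. This vignette is the
package's own account of the underlying procedure: the model, the tunable
parameters, the synthetic-data generator used for validation, the numerical
conventions, and the design decisions that were genuinely open.

## The procedure

The pipeline starts from a quantified, localization-resolved phosphosite
table: one row per phosphosite per treatment comparison, carrying the
protein, the 1-based acceptor position, the acceptor residue (S/T/Y), a
sequence window over positions $-5..+4$ around the acceptor, a log2 fold
change and a BH-adjusted p-value. Upstream peptide-level processing
(search, quantification, site localization, moderated statistics) is out of
scope; those quantities are inputs.

**1. Differential calling.** A site is called *up* when
$\log_2\mathrm{FC} \ge 1.5$ and adjusted $p \le 0.05$, *down* when
$\log_2\mathrm{FC} \le -1.5$ and adjusted $p \le 0.05$ (boundaries
inclusive), otherwise *ns*.

**2. Signed regulation score.** Per comparison, each site receives
$r = w \cdot \log_2\mathrm{FC}$ where $w$ is the min-max-normalized
significance over all quantified sites of the comparison. The significance
transform is the central interpretive choice of this stage: normalizing the
adjusted p-values directly would give the *least* significant sites the
largest weight, contradicting the score's use downstream, so the default
transform is min-max of $-\log_{10}(\text{adj } p)$ (most significant site
$\to w = 1$). The alternative `one_minus_p` reading is available via
`run_config(significance_transform =)`.

**3. Motif scoring and the top-25 filter.** Each kinase is a
position-specific scoring matrix (PSSM) of additive log2-odds over window
positions and the 20-residue alphabet, plus an S/T acceptor preference
(scored as $\log_2(\mathrm{pref}/0.5)$ so an indifferent kinase contributes
0). Terminus pads (`_`) contribute nothing. A site's raw score against a
kinase is converted to an empirical percentile within that kinase's
background score distribution; by default the background is
*dataset-internal* — the kinase's scores over all windows of the analyzed
dataset — because no external reference distribution is bundled (an
external sample can be supplied to `score_phosphosites()`). Each site
retains its 25 top-percentile kinases ("top 25 scoring kinases by
percentile" is read as the 25 best-ranked kinases, not the 25th percentile;
the count is `top_kinase_percentile_count` in the config). Ties at the
boundary break by raw score, then kinase name, so outputs are
deterministic. Tyrosine sites are excluded from scoring: the library models
serine/threonine kinases.

**4. Kinase-motif enrichment and relative activity.** For each direction of
each comparison, a kinase's 2x2 table counts top-25 membership among the
called sites (foreground) versus all other quantified sites of the
comparison (background). The test is the one-sided Fisher exact test
(upper-tail hypergeometric), the effect size is the log2 *frequency factor*
$\log_2\frac{fg_{\mathrm{hits}}/fg}{bg_{\mathrm{hits}}/bg}$ (Haldane +0.5 on
all four cells only when a cell is zero), and BH correction runs over the
family of all kinases x both directions within the comparison. Directions
with an empty foreground are untestable and leave the BH family. The signed
*relative kinase activity* takes the kinase's most significant direction
(smaller adjusted p; ties by larger |frequency factor|, then up), and
multiplies the min-max-normalized significance (over the chosen adjusted
p-values of all kinases of the comparison) by that direction's frequency
factor; down-direction activities carry a negative sign.

**5. Interaction scoring (KLS).** For every differentially expressed site
and each of its retained kinases:

* base KLS $=$ percentile (rescaled 0-1) $\times$ |activity|;
* $+0.5$ per level of curated evidence (in vitro, in vivo), with a
  site-level record taking precedence over a protein-level one;
* $+\,n/(n+1)$ where $n$ is the interaction reference count (protein-pair
  level; $n = 0$ adds nothing);
* final score $=$ augmented KLS $\times$ the site's signed regulation score.

Each site then keeps its top `top_interactions_per_site = 3` kinases by
|final score| (ties by augmented KLS, then name). The kinase-substrate
score is the signed sum of final scores over the substrate's sites; the
pathway interaction score is (sum of the member phosphoproteins'
score-sums) x (fraction of members carrying any score). The per-site top-3
filter is applied *before* aggregation. The scored bipartite graph is
exportable as GraphML (full attributes) or SIF (identity only), with
substrate nodes annotated by Chronos dependency score and the
essential/non-essential call at $\le -0.5$.

**6. Overrepresentation with dependency partitioning.** Co-regulated
phosphoproteins (at least one up- and one down-regulated site in the same
comparison) are split by gene dependency (Chronos $\le -0.5$ essential,
boundary inclusive) and each subset is tested for gene-set
overrepresentation by the one-tailed hypergeometric test against the
background of all detected phosphoproteins, skipping sets with fewer than
`min_background = 3` background members (skipped sets leave the BH family
and are reported as skipped, not as $p = 1$).

**7. Metabolic arithmetic.** Mitochondrial stress-test metrics follow the
standard reading of an OCR trace: non-mitochondrial respiration is the
post-rotenone/antimycin minimum and maximal respiration the post-FCCP
maximum minus non-mitochondrial (both vendor-standard conventions recorded
as assumptions); basal, ATP-linked, proton leak and spare capacity follow
by subtraction. Glycolysis stress metrics read the ECAR trace analogously;
the glycolytic reserve is capacity minus glycolysis and may legitimately be
negative (no clamping). Isotopologue fractional abundances divide each peak
area by the metabolite's total; total-intensity normalization divides each
sample row by its sum and is idempotent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `log2fc_min` | 1.5 | minimum \|log2FC\| for a differential call (log2 units) |
| `adjp_max` | 0.05 | maximum BH-adjusted p for a call |
| `top_kinase_percentile_count` | 25 | kinases retained per site after percentile ranking |
| `top_interactions_per_site` | 3 | interaction scores retained per called site |
| `min_background` | 3 | minimum background members for an ORA set |
| `chronos_essential_max` | -0.5 | essentiality cutoff (Chronos units) |
| `significance_transform` | `"neglog10"` | p-value transform inside min-max weights |
| `pathway_fraction_scale` | `"unit"` | pathway-score fraction on 0-1 (or x100) |

The first six are the procedure's published operating constants and should
not normally be changed; the last two are interpretive conventions exposed
for sensitivity analysis.

## The synthetic-data generator

No deposited dataset at desk scale exercises every stage of this pipeline,
so the package ships a generator (`simulate_experiment()`) that produces
every input with planted ground truth, and the test suite validates each
stage by recovery. The reference conditions, fixed once, are: 50 kinases,
2000 phosphosites on 800 proteins, 2 up-active and 2 down-active kinases,
regulated-site effect size 3 log2 units with noise SD 0.3, 12% of sites
regulated, and 30 co-regulated proteins. These sizes keep a full 20-seed
recovery experiment within a couple of minutes on one CPU while leaving
each enrichment test with foregrounds of ~120 sites, comparable in power to
a real acute-treatment comparison.

Design of the generator:

* **Kinase library.** Each kinase's PSSM is Normal(0, 0.1) noise with 2-3
  strongly preferred (position, residue) cells at log-odds 5-7 — the scale
  of the strong favorite-residue preferences seen in peptide-array-derived
  specificity matrices. One kinase (`AMPK_SYN`) carries the literal AMPK
  consensus (hydrophobic at -5/+4, basic at -4/-3) and one (`ROCK_SYN`) the
  ROCK consensus (basic at -2/-3).
* **Identifiability.** Preferred cells are drawn *without replacement*
  across the library, and each kinase's background noise is zeroed at the
  other kinases' signature cells. Without this, two artifacts break
  single-kinase recovery: a competitor whose preferred cell coincides with
  a planted kinase's cell piggybacks on its windows, and — more subtly —
  a competitor's background noise at a planted kinase's cells is presented
  coherently by *every* planted window, shifting the competitor's
  percentile by a fixed offset comparable to the window-to-window score SD
  (the effect is scale-invariant in the noise SD, so it cannot be removed
  by shrinking the noise). Real kinomes have overlapping specificities;
  the generator deliberately does not emulate that, so passing recovery
  tests demonstrate correctness of the scoring chain, not the ability to
  disambiguate closely related kinases in real data.
* **Windows.** Planted substrates sample their windows from the owning
  kinase's PSSM as a per-position categorical distribution
  ($p \propto 2^{\text{log-odds}}$), acceptors from the kinase's S/T
  preference; null windows are uniform with a fair S/T acceptor. This is
  the simplest model that makes motif enrichment detectable.
* **Statistics.** Planted sites get $\log_2\mathrm{FC} \sim
  \mathcal{N}(\pm 3, 0.3)$ and raw $p \sim U(0, 10^{-6})$; null sites
  $\mathcal{N}(0, 0.3)$ and $U(0, 1)$. Adjusted p-values are produced by
  the pipeline's own BH over the simulated raw p-values so the
  p-value/fold-change joint structure is internally consistent. A
  consequence worth noting: under a pure null, BH-adjusted calling yields
  essentially *zero* calls (BH controls the FDR, not the per-test rate),
  so the null calibration checks assert that the raw-p exceedance rate
  matches the nominal 0.05 within binomial error while the adjusted call
  rate stays at or below it.
* **Annotations.** 60% of planted kinase-substrate pairs receive curated
  evidence flags (each level Bernoulli(0.7), at least one set; half the
  records site-level, half protein-level), 50% receive an interaction
  record with Geometric(0.5)+1 references, Chronos scores are
  $\mathcal{N}(0, 0.3)$ with designated essential genes at
  $\mathcal{N}(-1, 0.15)$ capped at $-0.55$ (so the $\le -0.5$ rule holds
  with margin), and one planted pathway collects the essential half of the
  co-regulated proteins so that dependency-partitioned ORA has a known
  positive.

What the generator does **not** emulate: TMT reporter-ion noise structure,
missing values, peptide-to-site roll-up, overlapping kinase specificities,
correlated pathway membership, or realistic gene-dependency covariance.
Recovery results on synthetic data therefore validate the implementation,
not the biological error rates to expect on real experiments.

## Numerical choices

* Percentiles use the empirical midpoint rule for ties
  ($100\,(\#\{<\!x\} + \tfrac12 \#\{=\!x\})/n$), which makes percentile a
  monotone function of raw score with equal scores mapping to equal
  percentiles.
* Min-max of a constant vector is defined as all zeros.
* An adjusted p of exactly 0 is clamped to the smallest positive double
  before $\log_{10}$, with a warning.
* The frequency-factor continuity rule (+0.5 on all four cells) triggers
  only when some cell is zero, leaving exact ratios untouched otherwise.
* All rank-based filters (top-25, top-3, direction choice) carry total,
  documented tie-break orders ending in lexicographic kinase name, so
  every output is reproducible byte-for-byte from the config and seed.
* Percentiles are rescaled 0-100 $\to$ 0-1 before entering products so KLS
  and activity share scale; the "percentage of phosphoproteins" factor in
  pathway scores is likewise a 0-1 fraction by default (a literal-percent
  switch only rescales all pathway scores by 100).

## Open design decisions

Several points of the procedure are not pinned down by its published
description; each was fixed as follows and exposed in the configuration
where reasonable:

* the enrichment background (all quantified non-foreground sites of the
  same comparison, per direction);
* the BH family (all kinases x both directions, per comparison);
* the percentile background (dataset-internal by default, external sample
  accepted);
* the window length ($-5..+4$ covers every consensus position the
  procedure uses: $-5, -4, -3, -2, 0, +4$);
* the AMPK consensus in strict mode requires basic residues at both $-4$
  and $-3$ (the consensus string), while relaxed mode — covering the
  reported motif variants — requires a hydrophobic residue at $-5$ *or*
  $+4$ plus a basic $-3$; strict is the default;
* the per-site top-3 filter runs before kinase/pathway aggregation;
* the glycolysis formula's missing operator is read as subtraction
  (anything else is dimensionally meaningless).

## Limitations

The package scores serine/threonine kinase motifs only; tyrosine sites are
carried through differential calling but dropped from kinase scoring. The
dataset-internal percentile background makes percentiles relative to the
analyzed experiment, so absolute percentile values are not comparable
across datasets scored against different backgrounds. Pathway interaction
scores mix positive and negative site contributions; a pathway with
balanced up/down regulation can legitimately score near zero. The flux
metrics implement the standard stress-test readings; instrument-specific
report-generator conventions may differ in how they window "after
injection" measurements.
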