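# phosnet

Kinase–substrate network inference from differential phosphoproteomics.

Acute drug perturbations — for instance combined inhibition of oxidative
phosphorylation and ROCK kinases in lung cancer cells — rewire thousands of
phosphosites within hours. phosnet is for computational biologists who have
such a differential phosphosite table (protein, site, ±5-residue sequence
window, log2 fold change, adjusted p per treatment comparison) and want to
know **which kinases drive the changes** and **which kinase–substrate
relationships carry them**, scored into an exportable network.

## The method

1. **Motif scoring.** Every phosphosite window (positions −5..+4, acceptor
   at 0) is scored against each kinase's position-specific scoring matrix
   (additive log2-odds plus an S/T acceptor preference) and converted to an
   empirical percentile within that kinase's background score distribution;
   each site retains its top-25 kinases by percentile.
2. **Differential calling.** Sites with |log2FC| ≥ 1.5 and BH-adjusted
   p ≤ 0.05 (inclusive) are called up/down; each site also gets a signed
   regulation score `r = minmax(−log10 adj p) × log2FC` per comparison.
3. **Kinase-motif enrichment.** Per direction, a one-sided Fisher exact
   test of top-25 membership among called sites versus the remaining
   quantified sites, BH-corrected over all kinases × both directions;
   summarized as the log2 frequency factor and the signed
   **relative kinase activity**
   `a = ± minmax(−log10 adj p) × frequency factor` of the most significant
   direction.
4. **Interaction scoring.** For each called site and retained kinase, the
   kinase library score `KLS = percentile × |a|` is augmented by +0.5 per
   curated evidence level (in vitro / in vivo) and by `n/(n+1)` for `n`
   interaction references, then multiplied by the site's signed regulation
   score. Each site keeps its top-3 kinases by |final score|;
   kinase–substrate scores are the signed sums over a substrate's sites,
   pathway interaction scores multiply each pathway's score-sum by its
   fraction of scored members.
5. **Dependency-partitioned ORA.** Co-regulated phosphoproteins (≥1 up and
   ≥1 down site) are split at Chronos ≤ −0.5 into essential/non-essential
   and tested for gene-set overrepresentation (one-tailed hypergeometric,
   BH, minimum background 3) against all detected phosphoproteins.

Companion modules compute Seahorse-style mitochondrial/glycolysis
stress-test metrics, isotopologue fractional abundances, and
total-intensity normalization, and a synthetic-data generator produces
every input with planted ground truth so the whole pipeline is validated by
recovery. See `vignettes/kinase-network-inference.Rmd` for the full methods
account.

## Worked example

```r
library(phosnet)

sim <- simulate_experiment(seed = 42)   # 50 kinases, 2000 sites, planted truth
res <- run_pipeline(sim$sites, sim$library,
                    evidence     = sim$annotations$evidence,
                    interactions = sim$annotations$interactions,
                    gene_sets    = sim$annotations$gene_sets,
                    dependency   = sim$annotations$dependency)[[1]]

act <- res$activities
head(act[order(-abs(act$activity)), ], 5)
#>    kinase    comparison direction frequency_factor    adj_p activity
#>    KIN047 combo_vs_ctrl        up            0.686 2.03e-07   0.6859
#>    KIN023 combo_vs_ctrl      down            0.575 3.51e-06  -0.4686
#>  AMPK_SYN combo_vs_ctrl      down            0.560 3.51e-06  -0.4564
#>    KIN035 combo_vs_ctrl        up            0.389 1.27e-02   0.1103
#>    KIN045 combo_vs_ctrl      down            0.242 5.21e-01  -0.0103
```

The four kinases planted as active (`sim$truth$active_kinases_up` =
KIN047, KIN035; `sim$truth$active_kinases_down` = AMPK_SYN, KIN023) head
the activity ranking with the planted signs; activities are the product of
a 0–1 significance weight and the log2 frequency factor, so |activity| is
bounded by |frequency factor|.

```r
ks <- res$kinase_substrate_scores
head(ks[order(-abs(ks$score)), ], 3)
#>    kinase  protein    comparison  score n_sites
#>    KIN023 PROT0196 combo_vs_ctrl -10.26       2
#>  AMPK_SYN PROT0196 combo_vs_ctrl  -9.98       3
#>    KIN047 PROT0027 combo_vs_ctrl   7.97       2
```

Edge weights are signed sums of final interaction scores over a substrate's
sites — negative for substrates of down-active kinases. The planted
essential pathway is recovered by dependency-partitioned ORA:

```r
head(res$ora$essential[order(res$ora$essential$adj_p), ], 1)
#>           gene_set fg_hits bg_hits enrichment_ratio    adj_p
#>  PLANTED_ESSENTIAL      15      25            29.72 8.49e-24
```

`build_network()` / `write_network()` export the scored graph as GraphML or
SIF for Cytoscape.

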