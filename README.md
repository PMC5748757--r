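# gutnet

Detecting weak, masked dietary impacts on the gut ecosystem by combining
random-forest feature importance with correlation-network modules.

## The problem

Feeding studies that measure the gut ecosystem broadly — fecal and urinary
NMR metabolite profiles, 16S microbial composition, urinary elements —
produce wide multi-assay tables (hundreds of features) over few subjects.
A food that is not a strong pre/probiotic perturbs this system only
slightly, and the perturbation is buried under per-animal differences and
day-to-day physiological noise: on a PCA score plot the treatment groups
simply do not separate. `gutnet` packages an integrated detection strategy
for exactly this regime, intended for microbiome/metabolome researchers
evaluating candidate functional foods, together with a synthetic study
generator that makes every stage testable without animal data.

## The method

For a combined samples-by-features table **X** (unit-variance scaled;
microbial counts as per-sample percentages):

1. **Random-forest screening.** A forest (500 trees, Gini splits,
   `mtry = ⌊√p⌋`) classifies samples into {pre-period, control food,
   test food 1, test food 2}. Features are ranked by permutation
   importance — mean decrease in out-of-bag accuracy (MDA) — and the top
   30 become *important factors*. OOB error, stratified k-fold
   cross-validation and an MDS embedding of the forest proximity matrix
   (d = √(1 − proximity)) guard against over-training.
2. **Correlation-network modules.** Pairwise-complete Spearman
   correlations over all features define a network with edges where
   |ρ| ≥ 0.6; greedy modularity maximisation (Clauset–Newman–Moore on
   weights |ρ|, deterministic tie-breaks) partitions it into communities,
   maximising Q = Σ_c [w_c/W − (s_c/2W)²].
3. **Module-level inference.** Every community containing an important
   factor is selected; its factors are compared between each pair of
   treatment arms with two-sided Mann–Whitney U tests, Holm-corrected over
   all (factor × pair) tests of the run (stars: \*\*\* p<0.001,
   \*\* p<0.01, \* p<0.05).

The interpretable output is the selected community — a block of co-varying
metabolites, taxa and host markers — rather than any single feature, which
is what rescues effects too weak and too redundant for per-feature
rankings.

## A worked example

```r
library(gutnet)

run <- run_pipeline(pipeline_config(study = study_config(seed = 1),
                                    out_dir = "results", seed = 1))
print(run)
#> <gutnet_run>
#>   status: modules_detected (30 significant factor(s))
#>   OOB error 0.398 | PCA silhouette 0.071 | 20 edges, Q = 0.499
#>   23 selected module(s)

mean(run$truth$planted_feature_ids %in% run$top_factors)
#> [1] 0.9
```

This simulates the reference design (3 arms × 4 subjects × 18 days; 216
fecal and 183 urinary collections; 490 features with 10 planted into 2
correlated blocks at δ = 1 within-condition SD) and runs the full
pipeline. Here the PCA silhouette of the treatment groups on PC1–PC2 is
0.071 — the arms do not separate in the unsupervised view — while 9 of the
10 planted features reach the top-30 importance list, and both planted
blocks are recovered as network communities exactly (Jaccard 1.0, part of
the 20-edge network with modularity 0.499). `results/` receives the run
manifest, score/importance/partition tables, the annotated GraphML network
(node attributes `assay`, `community`, `is_important` for Cytoscape-style
rendering) and the module report (JSON + TSV).

The methods vignette (`vignettes/gutnet-methods.Rmd`) documents the model
behind the generator, every tunable with its default, and the measured
statistical limits of the methodology — in particular that the end-to-end
false-report rate under the null is far above the nominal Holm level, so
the stars are descriptive flags rather than confirmatory inference.

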