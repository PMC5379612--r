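# DefenseFlux

Phylogenetic reconstruction of gene gain and loss dynamics of microbial
defense systems.

Prokaryotic anti-virus defense systems — restriction-modification (RM),
toxin-antitoxin (TA), CRISPR-Cas, abortive infection (Abi) and others — are
gained and lost at striking rates as genomes adapt to shifting phage
pressure. DefenseFlux quantifies that turnover: given per-genome copy numbers
of each gene family (phyletic profiles) in a cluster of closely related
genomes and a rooted species tree, it fits a stochastic birth-death-gain
model of family size, infers where on the tree families were gained, lost,
expanded or reduced, and compares the per-family event rates of defense
systems against the all-gene background. It also tests whether defense genes
cluster into chromosomal islands, and ships an exact simulator so every piece
can be validated against known ground truth.

## The model

Family size `n` evolves along each branch as a continuous-time Markov chain
with up-rate `κ + nλ` and down-rate `nμ`:

* `κ` — gain of a new copy by horizontal transfer (independent of `n`),
* `λ` — per-copy duplication,
* `μ` — per-copy loss.

The root is drawn from the stationary distribution (negative binomial with
size `κ/λ` and success probability `λ/μ`; requires `λ < μ`). Likelihoods are
computed by pruning over size states with controlled truncation, conditioned
on families being observable, with up to four discrete gamma rate categories
across families. Event posteriors per family and tree edge come from
inside–outside decoding: gain (`0 → ≥1`), loss (`≥1 → 0`), expansion
(`b > a ≥ 1`), reduction (`a > b ≥ 1`).

## Worked example

Simulate a synthetic genome cluster with a defense subset evolving 1.5× faster
and mildly clustered on the chromosome, then run the full analysis:

```r
library(DefenseFlux)

cfg <- SimConfig(seed = 1, nLeaves = 6, nFamilies = 400,
                 defenseFraction = 0.08,
                 defenseMultiplier = c(1.5, 1.5, 1.5),
                 islandConcentration = 0.6)
runSimulate(cfg, "atgc_sim")

res <- runAnalyze("atgc_sim/tree.nwk", "atgc_sim/counts.tsv",
                  "atgc_sim/annotations.tsv", "atgc_sim/genemap.tsv",
                  outDir = "atgc_out", atgcId = "SYN001",
                  fit = fitConfig(maxCategories = 2), nReps = 2000, seed = 1)

res$model
#> Fitted birth-death-gain model (6 tips, 10 edges, M = 20)
#>   log-likelihood = -1164.6954  (converged, 2 fitting rounds)
#> Birth-death-gain rates
#>   kappa (gain) = 0.6439  lambda (duplication) = 0.03175  mu (loss) = 1.246

res$relativeRates
#>     atgc genus gain_ratio loss_ratio expansion_ratio reduction_ratio all_gde_ratio
#> 1 SYN001             0.84       1.92            1.45           0.704          1.21

res$colocalization$gene[[1]]
#> Co-localization test (gene level): observed median = 1, p = 0.002999 (2000 reps, seed 1)
```

The package also includes the published table of defense-versus-all relative
rates across 36 clusters of closely related genomes:

```r
t1 <- loadTable1()
round(meanRatios(t1), 2)
#>       gain_ratio       loss_ratio  expansion_ratio  reduction_ratio    all_gde_ratio
#>             1.28             1.46             1.04             1.52             1.40
table(classifyFlux(t1)$flux_class)
#> average    high     low
#>      18       9       9
round(pcaRelativeRates(t1)$varianceExplained, 1)
#> [1] 54.2 25.2 14.7  5.9
```

A command-line front-end (`simulate`, `analyze`, `table1-stats` subcommands)
is installed at `system.file("scripts", "defenseflux.R", package = "DefenseFlux")`.

## Documentation

See the vignette source `vignettes/defenseflux-methods.Rmd` for the model,
the estimation and decoding algorithms, the randomization tests, the
simulator, and the reasoning behind the main design choices (including the
PCA variant used for the packaged table and why event-count ratios are
attenuated readouts of the underlying rate multipliers).
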