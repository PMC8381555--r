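# finemapDO

Empirical-Bayes fine-mapping of Diversity Outbred (DO) mouse cis-eQTLs to
single candidate regulatory variants, by integrating founder-strain
multi-omics summaries.

## The problem

An eQTL scan in DO mice yields, per gene, a marker and an 8-founder
allelic-effect vector — but the founders' long high-LD blocks leave tens of
candidate SNPs per marker. This package scores the candidates that lie
inside founder ATAC-seq peaks and whose genotype associates with local
accessibility (local ATAC multi-omic variants), asking which candidate's
founder genotype-effect pattern best explains the DO allelic pattern.

## The model

Effect vectors are trinarized into allelic patterns in {-1, 0, +1} relative
to the reference strain B6. For gene *g* with *p_g* candidates:

* *V_g* ~ Bernoulli(γ) — does any candidate drive the eQTL?
* Θ_g ~ Dirichlet(Π_g), *Z_g* | *V_g* = 1 ~ Multinomial(1, Θ_g) — which one;
* per-strain edit distances between the DO pattern Ỹ_g and either the causal
  SNP's genotype-effect pattern R̃_g (causal branch) or the founder
  expression pattern B̃_g (null branch) are tallied over the 5 classical
  strains, n_g ~ Multinomial(5, a₁ or a₀), and the 3 wild-derived strains,
  m_g ~ Multinomial(3, b₁ or b₀);
* the multi-omics prior weight is
  Π_{g,k} = F_{g,k} + D_{g,k} + |cor(A_{g,k}, E_{g,k})| + |cor(A_{g,k}, B_g)| + 1
  (footprint impact, distance score, accessibility-effect and
  accessibility-expression correlations).

The fit is a multi-restart EM with pseudocounted multinomial updates,
Dirichlet-MAP updates of Θ_g, direct-posterior-probability FDR calls,
and credible sets. A footprint module derives F from Tn5 cut profiles
(footprint depth, comparative ΔFPD against motif-specific empirical nulls,
gain/loss rules) and a per-peak permutation test identifies
accessibility-associated SNPs. A simulation harness generates full
synthetic inputs and samples from the plate model under non-, moderately-,
and highly-informative priors. See `vignettes/finemapping-model.Rmd` for
the complete account.

## Worked example

```r
library(finemapDO)
cfg <- sim_config(G = 200, informativeness = "HI", seed = 1)
sim <- simulate_from_plate(generate_fixture(cfg))
data <- build_model_data(sim$instances, sim$expr)
fit <- fit_model(data, sim$priors, fit_control(restarts = 4, seed = 2))
fit
#>   genes: 200, candidates: 7933
#>   gamma = 0.4093
#>   a1 = (0.916, 0.084, 0.000)   b1 = (0.903, 0.097, 0.000)
#>   a0 = (0.914, 0.081, 0.004)   b0 = (0.910, 0.086, 0.004)
#>   objective = 25547.6415 (restart 3/4, converged in 17 iterations)
```

γ̂ ≈ 0.41 recovers the generative causal fraction (0.4); the count
parameters sit near their concordance-dominated truths. Downstream:

```r
evaluate_power(fit$resp$v_hat, sim$truth)
#> $power      0.974026
#> $fdr        0.09638554
#> $n_selected 83
round(evaluate_fine_mapping(fit, data, sim$truth), 4)
#>    most_likely   least_likely         random closest_marker   closest_gene
#>         0.0820         0.9535         0.4582         0.5411         0.5587
```

97% of truly causal genes are recovered at the 0.05 posterior-FDR cut, and
the model's most-likely SNP needs on average only 8% of the ranked
candidates to cover the true causal variant, versus ~46-56% for
random/closest baselines (the least-likely ranking is, as it should be,
worse than every baseline). `posterior_results(fit, data)` turns the fit
into per-gene calls, credible sets, and strategy selections;
`write_results_tsv()` / `write_fit_json()` export them.

A thin CLI wraps the same functions:

```sh
inst/cli/finemapdo simulate --out-dir sim --G 200 --setting HI --seed 7
inst/cli/finemapdo fit --eqtl sim/eqtl.tsv --snps sim/snps.tsv \
    --expr sim/expression.tsv --out-dir results --seed 7
```

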