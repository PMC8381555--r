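---
title: "Fine-mapping DO mouse eQTLs with founder multi-omics: model and methods"
author: "finemapDO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping DO mouse eQTLs with founder multi-omics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapDO)
```

## The problem

Expression QTL mapping in Diversity Outbred (DO) mice localizes regulatory
signal to a marker with an 8-founder allelic-effect vector, but the long
high-LD blocks of the DO founders leave dozens of candidate variants per
marker. `finemapDO` fine-maps each gene-marker association to candidate SNPs
that reside inside founder-strain ATAC-seq peaks and whose genotype
associates with the local accessibility signal ("local ATAC multi-omic
variants"). The model asks: which candidate SNP's founder genotype-effect
pattern best explains the DO allelic expression pattern, and is any
candidate needed at all?

## The generative model

All 8-strain vectors are reduced to trinary allelic patterns in
\{-1, 0, +1\} relative to the reference strain B6 (`trinarize_effects()`,
`trinarize_genotype_effects()`). For a gene $g$ with $p_g$ candidates:

* $V_g \sim \mathrm{Bernoulli}(\gamma)$ indicates whether some candidate is
  causal (at most one per association).
* $\Theta_g \sim \mathrm{Dirichlet}(\Pi_g)$ are per-candidate causal
  probabilities; $Z_g \mid V_g = 1 \sim \mathrm{Multinomial}(1, \Theta_g)$
  picks the causal SNP.
* The observed DO pattern $\tilde Y_g$ enters through per-strain edit
  distances $d_s = |\tilde Y_{g,s} - \tilde R_{g,s}|$ against the causal
  SNP's genotype-effect pattern $\tilde R_g$ (causal branch), or against the
  trinarized founder expression $\tilde B_g$ (null branch). Distances are
  tallied separately over the 5 classical strains — a 3-cell multinomial
  with 5 trials, probabilities $a_1$ (causal) or $a_0$ (null) — and over the
  3 wild-derived strains (3 trials, $b_1$ / $b_0$). The null branch encodes
  the expectation that, absent a causal variant, DO allelic effects still
  track founder expression.

The multi-omics prior weight of candidate $k$ is the equal-weight sum

$$\Pi_{g,k} = F_{g,k} + D_{g,k} + |\mathrm{cor}(A_{g,k}, E_{g,k})| +
|\mathrm{cor}(A_{g,k}, B_g)| + 1,$$

with $F$ the comparative-footprint impact flag, $D \in (0, 0.5]$ the
distance score, and the two Pearson correlations (across the 8 strains, in
absolute value) linking peak accessibility to the SNP's expression effect
and to the gene's founder expression. The distance score is 0.5 up to
0.25 Mb and $(5/12)/(10x - 5/3)$ beyond, continuous and decreasing, so that
distance acts as a tie-breaker rather than dominating: chromatin-contact
signal decays with distance, but penalizing proximity too hard would simply
re-derive the "closest SNP" heuristic the model is meant to beat.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window (`window_mb`) | 1 Mb | half-width of the candidate window around the marker (closed interval) |
| trinarization cutoff | 0.2 | threshold on standardized, B6-centered effects (strict inequalities) |
| effect significance | 0.05 | marginal genotype-effect p-value gate for $\tilde E$ |
| pseudocounts $\lambda$ | (0.1, 0.01, 0) | per-gene tilt of all four count sums toward low edit distances |
| restarts / tol | 10 / 1e-8 | EM restarts and relative objective tolerance |

## Fitting

The fit maximizes a penalized observed-data objective by EM
(`fit_model()`): the marginal log-likelihood of each gene's mixture, plus
the Dirichlet prior density of $\Theta_g$ at $\Pi_g$, plus the pseudocount
regularizers on $(a_0, a_1, b_0, b_1)$. The E-step (`estep()`) computes
per-gene responsibilities over the null state and the $p_g$ causal states
in log space with max-subtraction. The M-step (`mstep()`) applies the
closed-form multinomial updates with pseudocounts $\lambda_i p_g$ added per
gene to each of the four sums, the Dirichlet MAP update
$\theta_{g,k} \propto \Pi_{g,k} + w_{g,k} - 1$, and
$\hat\gamma = \bar v$, clipped to $[10^{-6}, 1 - 10^{-6}]$ to keep the
objective finite.

Design choices made where the procedure was genuinely open:

* **Soft EM.** The latent indicators are imputed as posterior expectations
  rather than hard assignments; this is the standard mixture EM and keeps
  the ascent property exact. A hard mode (`em_mode = "hard"`) is available
  for comparison.
* **Initialization.** $a_1, b_1$ start near (0.7, 0.2, 0.1) (concordance
  expected under causality), $a_0, b_0$ near uniform, $\gamma$ near 0.5,
  $\Theta_g \propto \Pi_g$, with per-restart jitter from the seeded
  generator. Restart ties (within 1e-12) keep the lowest index; the fit is
  bitwise deterministic given the seed.
* **Objective for restart comparison** includes the Dirichlet prior term,
  so restarts are compared on the same penalized surface the M-step
  ascends.
* **Degeneracies.** A constant raw effect vector trinarizes to all-zero
  (no information); a zero-variance vector zeroes its correlation term in
  the prior; the MAP denominator is floored at 1e-12 and falls back to a
  uniform $\Theta_g$ (reachable only under a flat prior); a gene whose
  every mixture component has zero likelihood gets uniform
  responsibilities with a warning.

## Calls, credible sets, attribution

Gene-level calls use the direct-posterior-probability rule
(`fdr_select()`): sort by $\hat V_g$ descending and take the largest prefix
whose mean null posterior stays at or below the target FDR; ties at the cut
enter or leave as a block so the call is order-free. Credible sets
(`credible_set()`) are minimal posterior-descending prefixes reaching
cumulative 0.80, flagged informative when smaller than half the candidates
(strict; a single-candidate gene is trivially informative). SNP-level
posteriors are responsibilities renormalized by $\hat V_g$ (the posterior
of $Z$ given $V = 1$); we rank by responsibilities rather than
$\hat\Theta_g$ because they incorporate the likelihood. Prior-component
attribution (`contributor_rank_scores()`) ranks each component of the
causal SNP across its competitors (ascending, average ranks for ties,
normalized by $p_g$).

## Footprint features

The footprint flag $F$ is derived upstream of the mixture
(`footprint_flags()`). Footprint depth is the proportional depletion of
depth-normalized Tn5 5'-cut counts at a binding site relative to its
flanks; because no closed form is standard, we fix
$\mathrm{FPD} = (\bar f - \bar s)/\bar f$ with $\bar f$ the average of the
pooled 1-25 bp and pooled 26-50 bp flank means. $\Delta\mathrm{FPD}$
contrasts pooled alternative- vs reference-allele strain profiles; its
significance comes from a motif-specific empirical null (in-silico
insignificant SNP-motif pairs), one-sided in the direction of the
candidate's gain/loss class, add-one convention, requiring at least 20 null
values. Gain requires pval_ref > 0.05, pval_snp <= 0.05,
$\Delta\mathrm{FPD} > 0$; loss is the mirror. Per SNP the minimum
footprint p-value is adjusted across SNPs by Benjamini-Hochberg. The
accessibility-association screen (`local_atac_mv_test()`) uses the squared
Pearson correlation between genotype and strain-level peak signal with a
within-peak max-statistic permutation null (this controls best-SNP
selection; with binary genotypes any permutation restoring the carrier
partition ties the maximum, so p-values are conservative by construction),
retaining exact ties and adjusting across peaks by Benjamini-Hochberg.
In-silico motif-match p-values are consumed as inputs, never computed.

## The simulation harness

`generate_fixture()` builds a synthetic multi-omics dataset and
`simulate_from_plate()` draws $(V, Z, \tilde Y)$ from the model above. The
generator's defaults are the package's study conditions and are not tuned
per run:

* **Scale.** Candidate counts are $1 + \mathrm{NegBin}(2.5, \mu = 40)$
  (median 36, sd about 26, right-skewed). Markers sit 3 Mb apart with
  candidates within $\pm 1$ Mb.
* **Genotypes.** Candidates copy one of 3-8 shared haplotype patterns per
  window with 5% per-strain flips, emulating the founders' long high-LD
  blocks; wild-derived strains are enriched for alternative alleles (0.55
  vs 0.2); B6 always carries the reference allele.
* **Signals.** Peak accessibility is baseline + genotype effect + noise;
  each SNP carries a genotype-driven expression trait whose marginal
  regression supplies its effect and p-value (candidate sets emulate
  significant variant-expression associations); founder gene expression is
  the designated regulatory SNP's genotype effect attenuated (0.4) with
  extra noise (0.5), so the gene's expression pattern only partially
  matches that SNP's effect pattern.
* **Generative parameters.** $\gamma = 0.4$, $a_1 = (0.95, 0.04, 0.01)$,
  $b_1 = (0.90, 0.08, 0.02)$, $a_0 = (0.92, 0.06, 0.02)$,
  $b_0 = (0.88, 0.09, 0.03)$. Both branches are concordance-dominated —
  the null premise is that DO patterns still track founder expression —
  with the causal branch tighter. With many candidates per gene this
  tightness is also what keeps the two-component mixture identifiable: if
  null concordance is weak, some incidental candidate pairing explains
  null genes better than their own null pairing and the causal component
  absorbs everything.
* **Informativeness.** NI fixes $\Pi \equiv 1$; MI uses the computed
  multi-omics prior; HI sets $F = 10$ on one uniformly chosen SNP per gene
  and 0 elsewhere.
* **Materialization.** The model is defined on counts, so drawn counts are
  assigned to strains uniformly at random subject to feasibility (distance
  2 needs a nonzero base code; distance 1 from 0 picks a direction
  uniformly, from $\pm 1$ moves to 0), resampling counts when infeasible.
  B6 is treated like any classical strain, so simulated patterns can carry
  a nonzero B6 code that real trinarized data cannot; exported TSVs
  round-trip exactly only under `reference_zero = TRUE`, which conditions
  on a zero edit distance at B6.

What passing tests on this fixture do **not** show about real data: the
generator has no trans effects, no shared markers across genes, a single
chromosome's worth of independent windows, Gaussian noise, and genotype LD
far simpler than real founder haplotypes; parameter-recovery results
certify the estimator under the model's own assumptions, not robustness to
their violation.

### Problem sizes used by the checks

The packaged checks run parameter recovery at $G = 5000$ (HI, 10
restarts), FDR calibration with oracle-parameter posteriors over 50
replicates at $G = 2000$, and strategy comparisons over 20 replicates per
informativeness setting at $G = 300$ with 3 restarts — sizes chosen as the
smallest at which the Monte-Carlo error is comfortably below the margins
being tested.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(G = 200, informativeness = "HI", seed = 1)
sim <- simulate_from_plate(generate_fixture(cfg))
data <- build_model_data(sim$instances, sim$expr)
fit <- fit_model(data, sim$priors,
                 fit_control(restarts = 4, seed = 2))
fit
evaluate_power(fit$resp$v_hat, sim$truth)
evaluate_fine_mapping(fit, data, sim$truth)
```

## Known limitations

* One causal variant per gene-marker association; genes under several
  markers can still receive several variants, but multi-causal loci within
  one association are out of scope, as are trans-eQTLs.
* The edit-distance likelihood discards effect magnitudes beyond the
  trinary codes; two candidates with identical genotype patterns and
  effect signs are indistinguishable to the likelihood and are separated
  only by the prior.
* The estimator shows a small upward bias in $\gamma$ when many candidates
  compete (incidental near-matches), visible in the recovery checks as an
  error well inside, but not far from, the tolerance.
* Footprint-depth conventions (flank pooling, sidedness of the empirical
  p-value) follow the definitions above; other reasonable conventions
  shift $\Delta$FPD slightly.
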