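# Data-driven simulation harness: a synthetic multi-omics fixture generator
# (genotype-driven ATAC signal, founder expression, marginal genotype
# effects, footprint flags) and plate-model sampling of (V, Z, Y~) under
# three levels of prior informativeness, plus power / fine-mapping
# evaluation.

#' Simulation configuration
#'
#' Defaults emulate the scale and structure of the real DO islet application:
#' a right-skewed candidate count per association (1 + negative binomial,
#' median 36, sd about 26), wild-derived strains enriched for alternative
#' alleles, genotype-driven ATAC signal, and founder expression coupled to
#' the designated causal SNP's accessibility. The generative parameter
#' defaults (`gamma`, `a1`, `b1`, `a0`, `b0`) concentrate causal edit
#' distances near zero and leave null distances closer to uniform.
#'
#' @param G Number of gene-marker associations.
#' @param informativeness `"NI"` (flat prior), `"MI"` (observed multi-omics
#'   prior), or `"HI"` (footprint component set to `hi_f_value` on one
#'   uniformly chosen SNP per gene, 0 elsewhere).
#' @param gamma Prior causal probability in (0, 1).
#' @param a1,b1 Causal multinomial probability triples (classical, wild).
#' @param a0,b0 Null triples.
#' @param seed Integer seed; generation is deterministic given it.
#' @param p_size,p_mu Negative-binomial size and mean for the candidate
#'   count minus 1.
#' @param p_max Optional cap on candidates per gene (desk-scale tests).
#' @param hi_f_value Footprint override in the HI setting (default 10).
#' @param wild_enrichment Added alt-allele probability for wild-derived
#'   strains (classical 0.2, wild 0.2 + enrichment).
#' @param noise_sd Noise standard deviation for ATAC signal and SNP-level
#'   expression traits.
#' @param expr_coupling,expr_noise Attenuation and noise of founder gene
#'   expression relative to the designated SNP's genotype effect.
#' @param ld_noise Per-strain flip probability applied to the shared
#'   haplotype patterns that candidate genotypes are drawn from (3-8
#'   patterns per window, emulating high founder LD).
#' @param reference_zero If `TRUE`, plate sampling conditions on a zero edit
#'   distance at the reference strain so that materialized patterns always
#'   round-trip through raw-effect trinarization.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(G = 2000,
                       informativeness = c("HI", "MI", "NI"),
                       gamma = 0.4,
                       a1 = c(0.95, 0.04, 0.01), b1 = c(0.90, 0.08, 0.02),
                       a0 = c(0.92, 0.06, 0.02), b0 = c(0.88, 0.09, 0.03),
                       seed = 1, p_size = 2.5, p_mu = 40, p_max = Inf,
                       hi_f_value = 10, wild_enrichment = 0.35,
                       noise_sd = 0.3, expr_coupling = 0.4,
                       expr_noise = 0.5, ld_noise = 0.05,
                       reference_zero = FALSE) {
  informativeness <- match.arg(informativeness)
  for (v in list(a1, b1, a0, b0))
    stopifnot(length(v) == 3, all(v >= 0), abs(sum(v) - 1) < 1e-12)
  stopifnot(gamma > 0, gamma < 1)
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-omics fixture
#'
#' Builds a full input dataset emulating the summarized founder data: per
#' association a marker, a gene promoter, and candidate SNPs within 1 Mb of
#' the marker; per SNP 8-strain genotypes (reference strain fixed at 0, wild
#' strains enriched for alternative alleles), ATAC signal driven by
#' genotype plus noise, and a marginal genotype-effect (effect size and
#' p-value) from regressing a founder-expression trait on genotype. Founder
#' expression is correlated with the designated causal SNP's ATAC signal,
#' and footprint flags follow the configured informativeness (in HI, the
#' designated SNP carries `hi_f_value`).
#'
#' @param config A [sim_config()].
#' @param panel A [strain_panel()].
#' @return A list of class `"sim_fixture"`: `instances` (eQTL instances with
#'   candidates attached; allelic effects unset until plate sampling),
#'   `expr` (founder expression matrix), `designated` (per-gene feature
#'   causal SNP index), `config`, `panel`.
#' @export
generate_fixture <- function(config = sim_config(), panel = strain_panel()) {
  with_seed(config$seed, {
    G <- config$G
    p_alt <- ifelse(seq_len(8) %in% panel$wild_idx,
                    0.2 + config$wild_enrichment, 0.2)
    p_alt[panel$reference_idx] <- 0
    pvec <- pmin(1L + stats::rnbinom(G, size = config$p_size,
                                     mu = config$p_mu), config$p_max)
    designated <- integer(G)
    expr <- matrix(0, G, 8, dimnames = list(sprintf("gene%04d", seq_len(G)),
                                            panel$strains))
    instances <- vector("list", G)
    for (g in seq_len(G)) {
      p <- pvec[g]
      marker_pos <- g * 3e6
      promoter_pos <- marker_pos + round(stats::runif(1, -5e5, 5e5))
      pos <- sort(marker_pos + round(stats::runif(p, -1e6, 1e6)))
      # haplotype-block LD: candidate genotypes are noisy copies of a few
      # shared founder haplotype patterns, emulating the long high-LD
      # blocks of the DO founders
      n_hap <- min(p, sample.int(6L, 1L) + 2L)
      hap <- matrix(stats::rbinom(n_hap * 8L, 1L, rep(p_alt, each = n_hap)),
                    n_hap, 8)
      geno <- hap[sample.int(n_hap, p, replace = TRUE), , drop = FALSE]
      flip <- matrix(stats::runif(p * 8L) < config$ld_noise, p, 8) &
        rep(p_alt > 0, each = p)
      geno[flip] <- 1L - geno[flip]
      while (any(zero <- rowSums(geno) == 0L))
        geno[zero, ] <- matrix(stats::rbinom(sum(zero) * 8L, 1L,
                                             rep(p_alt, each = sum(zero))),
                               sum(zero), 8)
      kstar <- sample.int(p, 1)
      designated[g] <- kstar
      # genotype-driven ATAC signal of the harboring peak
      eff_a <- sample(c(-1, 1), p, replace = TRUE) *
        stats::runif(p, 0.8, 1.5)
      A <- matrix(stats::runif(p, 1, 3), p, 8) + eff_a * geno +
        matrix(stats::rnorm(p * 8, 0, config$noise_sd), p, 8)
      # per-SNP genotype-driven expression traits; candidate sets emulate
      # variant-expression associations, so most marginal effects are real
      eff_e <- sample(c(-1, 1), p, replace = TRUE) *
        stats::runif(p, 0.8, 1.5)
      traits <- eff_e * geno +
        matrix(stats::rnorm(p * 8, 0, config$noise_sd), p, 8)
      # founder expression of the gene: driven by the designated SNP's
      # genotype (so |cor(A, B)| is elevated at a genuinely regulatory
      # variant) but attenuated and noisier than the SNP-level trait --
      # expression is a separate modality, so its trinarized pattern only
      # partially matches the designated genotype-effect pattern
      B <- config$expr_coupling * eff_e[kstar] * geno[kstar, ] +
        stats::rnorm(8, 0, config$expr_noise)
      expr[g, ] <- B
      # marginal regression of the trait on genotype, per SNP
      # (closed-form simple regression across the 8 strains)
      xbar <- rowMeans(geno)
      sxx <- rowSums((geno - xbar)^2)
      ybar <- rowMeans(traits)
      sxy <- rowSums((geno - xbar) * (traits - ybar))
      effect <- sxy / sxx
      resid <- traits - ybar - effect * (geno - xbar)
      se <- sqrt(rowSums(resid^2) / 6 / sxx)
      pvalue <- 2 * stats::pt(abs(effect / se), df = 6, lower.tail = FALSE)
      Fv <- if (config$informativeness == "HI") {
        f <- numeric(p); f[kstar] <- config$hi_f_value; f
      } else {
        f <- as.numeric(stats::runif(p) < 0.1)
        f[kstar] <- as.numeric(stats::runif(1) < 0.8)
        f
      }
      cand <- c(list(snp_id = sprintf("g%04d_s%02d", g, seq_len(p)),
                     chrom = rep("chr1", p), pos = pos,
                     peak_id = sprintf("peak%04d_%02d", g, seq_len(p)),
                     dist_to_promoter = abs(pos - promoter_pos),
                     dist_to_marker = abs(pos - marker_pos),
                     footprint_flag = Fv,
                     effect = effect, effect_pvalue = pvalue),
                stats::setNames(lapply(1:8, function(s) geno[, s]),
                                paste0("geno_", panel$strains)),
                stats::setNames(lapply(1:8, function(s) A[, s]),
                                paste0("atac_", panel$strains)))
      attr(cand, "row.names") <- seq_len(p)
      class(cand) <- "data.frame"
      instances[[g]] <- structure(
        list(gene_id = rownames(expr)[g], gene_chrom = "chr1",
             gene_promoter_pos = promoter_pos, marker_chrom = "chr1",
             marker_pos = marker_pos,
             effects = stats::setNames(rep(NA_real_, 8), panel$strains),
             candidates = cand),
        class = "eqtl_instance")
    }
    structure(list(instances = instances, expr = expr,
                   designated = designated, config = config, panel = panel),
              class = "sim_fixture")
  })
}

#' Prior list for a fixture under its informativeness setting
#'
#' NI overrides every gene's weights to a flat Dirichlet; MI and HI compute
#' the multi-omics prior from the fixture's features (HI features already
#' carry the dominant footprint component).
#'
#' @param fixture A `"sim_fixture"`.
#' @return List of `"gene_prior"` objects.
#' @export
fixture_priors <- function(fixture) {
  if (fixture$config$informativeness == "NI")
    return(lapply(fixture$instances, function(x)
      flat_prior(x$gene_id, nrow(x$candidates), x$candidates$snp_id)))
  lapply(fixture$instances, function(x)
    compute_prior(x, fixture$expr[x$gene_id, ], fixture$panel))
}

# Assign drawn edit distances to strains around a base trinary pattern.
# d = 2 requires a nonzero base entry (flip sign); d = 1 moves 0 -> +/-1
# (uniform direction) or +/-1 -> 0; d = 0 copies. Returns NULL if the drawn
# counts are infeasible for this base pattern.
materialize_group <- function(base, counts, force_zero_at = NULL) {
  n_strains <- length(base)
  stopifnot(sum(counts) == n_strains)
  avail <- seq_len(n_strains)
  d <- integer(n_strains)
  if (!is.null(force_zero_at)) {
    if (counts[1] == 0L) return(NULL)
    d[force_zero_at] <- 0L
    counts[1] <- counts[1] - 1L
    avail <- setdiff(avail, force_zero_at)
  }
  eligible2 <- intersect(avail, which(base != 0))
  if (counts[3] > length(eligible2)) return(NULL)
  idx2 <- eligible2[sample.int(length(eligible2), counts[3])]
  avail <- setdiff(avail, idx2)
  idx1 <- avail[sample.int(length(avail), counts[2])]
  idx0 <- setdiff(avail, idx1)
  y <- base
  y[idx2] <- -base[idx2]
  y[idx1] <- ifelse(base[idx1] == 0,
                    sample(c(-1L, 1L), length(idx1), replace = TRUE),
                    0L)
  y[idx0] <- base[idx0]
  y
}

materialize_pattern <- function(base, n, m, panel, reference_zero = FALSE,
                                max_reject = 100L) {
  ref_in_classical <- match(panel$reference_idx, panel$classical_idx)
  for (try in seq_len(max_reject)) {
    yn <- materialize_group(base[panel$classical_idx], n,
                            if (reference_zero) ref_in_classical else NULL)
    if (is.null(yn)) return(NULL)
    yw <- materialize_group(base[panel$wild_idx], m)
    if (is.null(yw)) return(NULL)
    y <- integer(8)
    y[panel$classical_idx] <- yn
    y[panel$wild_idx] <- yw
    return(y)
  }
  NULL
}

#' Sample associations from the plate model
#'
#' For each fixture gene: draws the causal indicator `V ~ Bernoulli(gamma)`,
#' the causal simplex `Theta ~ Dirichlet(Pi)` under the configured
#' informativeness, the causal SNP `Z ~ Multinomial(1, Theta)` when V = 1,
#' then edit-distance counts from the causal (`a1`, `b1`) or null (`a0`,
#' `b0`) multinomials, and materializes a trinary DO allelic pattern
#' consistent with those counts around the causal SNP's genotype-effect
#' pattern (causal) or the founder-expression pattern (null). Infeasible
#' count draws (e.g. a distance of 2 where the base pattern is 0) are
#' resampled.
#'
#' @param fixture A `"sim_fixture"` from [generate_fixture()].
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return A list of class `"sim_data"`: `instances` (with `effects_tri`
#'   set, and raw `effects` equal to the trinary codes), `expr`, `priors`
#'   (the `"gene_prior"` list used), `truth` (data frame gene_id, v_true,
#'   z_true index, z_true_snp), `counts_drawn` (G x 6, the drawn edit
#'   counts), `config`, `panel`.
#' @export
simulate_from_plate <- function(fixture, seed = NULL) {
  config <- fixture$config
  panel <- fixture$panel
  priors <- fixture_priors(fixture)
  if (is.null(seed)) seed <- config$seed + 1L
  with_seed(seed, {
    gcols <- paste0("geno_", panel$strains)
    truth <- vector("list", length(fixture$instances))
    counts_drawn <- matrix(0L, length(fixture$instances), 6,
                           dimnames = list(NULL, c("n0", "n1", "n2",
                                                   "m0", "m1", "m2")))
    instances <- fixture$instances
    for (g in seq_along(instances)) {
      inst <- instances[[g]]
      cand <- inst$candidates
      p <- nrow(cand)
      v <- stats::rbinom(1, 1, config$gamma)
      z <- NA_integer_
      theta <- rdirichlet1(priors[[g]]$pi)
      if (v == 1L) z <- sample.int(p, 1, prob = theta)
      base <- if (v == 1L)
        trinarize_genotype_effects(cand$effect[z], cand$effect_pvalue[z],
                                   as.numeric(cand[z, gcols]))
      else trinarize_effects(fixture$expr[inst$gene_id, ], panel)
      probs <- if (v == 1L) list(config$a1, config$b1) else
        list(config$a0, config$b0)
      repeat {
        n <- drop(stats::rmultinom(1, 5, probs[[1]]))
        m <- drop(stats::rmultinom(1, 3, probs[[2]]))
        y <- materialize_pattern(base, n, m, panel, config$reference_zero)
        if (!is.null(y)) break
      }
      inst$effects_tri <- y
      inst$effects <- stats::setNames(as.numeric(y), panel$strains)
      instances[[g]] <- inst
      counts_drawn[g, ] <- c(n, m)
      truth[[g]] <- data.frame(gene_id = inst$gene_id, v_true = v,
                               z_true = z,
                               z_true_snp = if (is.na(z)) NA_character_
                               else cand$snp_id[z])
    }
    structure(list(instances = instances, expr = fixture$expr,
                   priors = priors, truth = do.call(rbind, truth),
                   counts_drawn = counts_drawn,
                   config = config, panel = panel),
              class = "sim_data")
  })
}

#' Oracle responsibilities under the true generative parameters
#'
#' E-step posteriors computed with the simulator's true parameters and the
#' prior-mean causal simplex (`Theta = Pi / sum(Pi)`). Used to benchmark
#' FDR calibration independently of EM estimation error.
#'
#' @param data A `"model_data"` built from simulated instances.
#' @param priors The `"gene_prior"` list used in generation.
#' @param config The `"sim_config"` holding the true parameters.
#' @return [estep()] responsibilities.
#' @export
oracle_responsibilities <- function(data, priors, config) {
  pi <- unlist(lapply(priors, `[[`, "pi"), use.names = FALSE)
  sumpi <- drop(rowsum(pi, data$gene_index))
  params <- list(a0 = config$a0, a1 = config$a1, b0 = config$b0,
                 b1 = config$b1, gamma = config$gamma,
                 theta = pi / sumpi[data$gene_index])
  estep(data, params)
}

#' Power and realized FDR of gene-level causal calls
#'
#' Applies [fdr_select()] at `alpha` and compares with the simulation truth.
#'
#' @param v_hat Posterior causal probabilities per gene.
#' @param truth Truth table from [simulate_from_plate()].
#' @param alpha Nominal FDR (default 0.05).
#' @return List with `power` (TP / causal genes), `fdr` (FP over selected,
#'   0 if none selected), `n_selected`.
#' @export
evaluate_power <- function(v_hat, truth, alpha = 0.05) {
  stopifnot(length(v_hat) == nrow(truth))
  sel <- fdr_select(v_hat, alpha)
  tp <- sum(sel & truth$v_true == 1)
  fp <- sum(sel & truth$v_true == 0)
  list(power = if (sum(truth$v_true) > 0) tp / sum(truth$v_true) else NA,
       fdr = fp / max(1, sum(sel)),
       n_selected = sum(sel))
}

#' Mean credible proportions of the five selection strategies
#'
#' For each simulated causal gene, ranks the candidates under each strategy
#' (posterior-descending for the model's Most Likely, posterior-ascending
#' for Least Likely, uniform random order for Random, distance-ascending for
#' the two Closest baselines; ties by genomic coordinate) and records the
#' credible proportion of the true causal SNP ([credible_proportion()]).
#'
#' @param fit A `"finemap_fit"` (or any object with `resp$w`).
#' @param data The `"model_data"` fit.
#' @param truth Truth table from [simulate_from_plate()].
#' @return Named numeric vector of mean credible proportions:
#'   `most_likely`, `least_likely`, `random`, `closest_marker`,
#'   `closest_gene`.
#' @export
evaluate_fine_mapping <- function(fit, data, truth) {
  gi <- data$gene_index
  causal <- which(truth$v_true == 1)
  stopifnot(length(causal) > 0)
  acc <- matrix(NA_real_, length(causal), 5,
                dimnames = list(NULL, c("most_likely", "least_likely",
                                        "random", "closest_marker",
                                        "closest_gene")))
  for (j in seq_along(causal)) {
    g <- causal[j]
    rows <- which(gi == g)
    ids <- data$snp_id[rows]
    pos <- data$snp_pos[rows]
    w <- fit$resp$w[rows]
    true_snp <- truth$z_true_snp[g]
    rk <- function(key, decreasing = FALSE)
      ids[order(key, pos, decreasing = c(decreasing, FALSE),
                method = "radix")]
    acc[j, "most_likely"] <- credible_proportion(rk(w, TRUE), true_snp)
    acc[j, "least_likely"] <- credible_proportion(rk(w, FALSE), true_snp)
    acc[j, "random"] <- credible_proportion(ids[sample.int(length(ids))],
                                            true_snp)
    acc[j, "closest_marker"] <-
      credible_proportion(rk(data$dist_to_marker[rows]), true_snp)
    acc[j, "closest_gene"] <-
      credible_proportion(rk(data$dist_to_promoter[rows]), true_snp)
  }
  colMeans(acc)
}

#' Write a simulated dataset in the input TSV formats
#'
#' Emits `eqtl.tsv`, `snps.tsv`, `expression.tsv`, and `truth.tsv` into
#' `dir`, readable by the corresponding `read_*` functions. Allelic-effect
#' columns hold the materialized trinary codes; patterns whose reference
#' (B6) code is nonzero do not round-trip through trinarization exactly
#' (generate with `reference_zero = TRUE` for exact round trips).
#'
#' @param sim A `"sim_data"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_tsv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim$panel
  meta <- c(seed = as.character(sim$config$seed),
            informativeness = sim$config$informativeness)
  eqtl <- do.call(rbind, lapply(sim$instances, function(x) {
    eff <- as.data.frame(as.list(x$effects))
    names(eff) <- panel$strains
    cbind(data.frame(gene_id = x$gene_id, gene_chrom = x$gene_chrom,
                     gene_promoter_pos = x$gene_promoter_pos,
                     marker_chrom = x$marker_chrom,
                     marker_pos = x$marker_pos), eff)
  }))
  write_tsv_output(eqtl, file.path(dir, "eqtl.tsv"), meta)
  snps <- do.call(rbind, lapply(sim$instances, `[[`, "candidates"))
  write_tsv_output(snps, file.path(dir, "snps.tsv"), meta)
  expr <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                     check.names = FALSE)
  write_tsv_output(expr, file.path(dir, "expression.tsv"), meta)
  write_tsv_output(sim$truth, file.path(dir, "truth.tsv"), meta)
  invisible(dir)
}
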