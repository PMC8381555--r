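# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

panel <- strain_panel()

# A minimal association instance with hand-set candidate features.
# geno/atac are p x 8 matrices in panel order.
make_instance <- function(gene_id = "g1", effects = rep(0, 8),
                          pos = NULL, marker_pos = 10e6,
                          promoter_pos = 10.1e6,
                          geno, atac, effect, effect_pvalue,
                          footprint = NULL) {
  p <- nrow(geno)
  if (is.null(pos)) pos <- marker_pos + seq_len(p) * 1e4
  if (is.null(footprint)) footprint <- rep(0, p)
  cand <- data.frame(snp_id = paste0("s", seq_len(p)), chrom = "chr1",
                     pos = pos, peak_id = paste0("pk", seq_len(p)),
                     dist_to_promoter = abs(pos - promoter_pos),
                     dist_to_marker = abs(pos - marker_pos),
                     footprint_flag = footprint,
                     effect = effect, effect_pvalue = effect_pvalue)
  gdf <- as.data.frame(geno)
  names(gdf) <- paste0("geno_", panel$strains)
  adf <- as.data.frame(atac)
  names(adf) <- paste0("atac_", panel$strains)
  structure(list(gene_id = gene_id, gene_chrom = "chr1",
                 gene_promoter_pos = promoter_pos, marker_chrom = "chr1",
                 marker_pos = marker_pos,
                 effects = stats::setNames(effects, panel$strains),
                 candidates = cbind(cand, gdf, adf)),
            class = "eqtl_instance")
}

# random trinary vector with reference entry 0 (as real data produces)
random_trinary <- function(ref_zero = TRUE) {
  y <- sample(c(-1L, 0L, 1L), 8, replace = TRUE)
  if (ref_zero) y[panel$reference_idx] <- 0L
  y
}

# brute-force per-gene posterior by enumerating (V = 0) and (V = 1, Z = k)
# with plain product arithmetic -- the independent oracle for estep
enumerate_posterior <- function(counts_k, null_counts, theta, gamma,
                                a0, a1, b0, b1) {
  lik1 <- apply(counts_k, 1, function(cc)
    prod(a1^cc[1:3]) * prod(b1^cc[4:6]))
  lik0 <- prod(a0^null_counts[1:3]) * prod(b0^null_counts[4:6])
  un <- c(gamma * theta * lik1, (1 - gamma) * lik0)
  un / sum(un)
}

# grid-search maximizer of the Dirichlet(alpha) log density on the
# 2-simplex, the oracle for the MAP theta update at p = 2; coarse pass
# then local refinement so the maximizer is resolved well below 1e-6
grid_map_dirichlet2 <- function(alpha) {
  ld <- function(th) (alpha[1] - 1) * log(th) + (alpha[2] - 1) * log(1 - th)
  th <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  best <- th[which.max(ld(th))]
  th2 <- seq(max(1e-9, best - 2e-4), min(1 - 1e-9, best + 2e-4),
             by = 1e-9)
  th2[which.max(ld(th2))]
}

# tiny model_data with explicit counts (bypasses trinarization)
make_model_data <- function(counts, null_counts, p, snp_pos = NULL) {
  G <- length(p)
  gi <- rep(seq_len(G), p)
  K <- sum(p)
  if (is.null(snp_pos)) snp_pos <- seq_len(K) * 1e4
  structure(list(
    gene_id = paste0("g", seq_len(G)), p = as.integer(p), gene_index = gi,
    snp_id = paste0("s", seq_len(K)), snp_pos = snp_pos,
    dist_to_marker = abs(snp_pos - 5e4),
    dist_to_promoter = abs(snp_pos - 8e4),
    counts = counts, null_counts = null_counts,
    y_tri = NULL, r_tri = NULL, b_tri = NULL),
    class = "model_data")
}
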