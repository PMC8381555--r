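#' Multi-omics Dirichlet prior weights for one association
#'
#' The per-SNP prior weight combines four equally weighted sources of
#' multi-omics evidence plus a baseline of 1:
#'
#'   pi_k = F_k + D(x_k) + |cor(A_k, E_k)| + |cor(A_k, B)| + 1
#'
#' where `F_k` is the comparative-footprint impact flag, `D` the distance
#' score ([distance_score()]), `A_k` the 8-strain ATAC signal of the peak
#' harboring SNP k, `E_k` the 8-strain genotype-effect vector of SNP k on
#' founder expression, and `B` the 8-strain founder expression of the gene.
#' Pearson correlations are taken across the 8 strains and in absolute value.
#' These weights parameterize the Dirichlet prior on the per-gene causal
#' probability simplex.
#'
#' A zero-variance vector makes a correlation undefined; that term
#' contributes 0 (no evidence) with a warning.
#'
#' @param instance An `"eqtl_instance"` with candidates attached
#'   ([assemble_instances()]).
#' @param expr 8-vector of normalized founder expression for the gene
#'   (panel order), or `NULL` if unavailable (the cor(A,B) term is then 0).
#' @param panel A [strain_panel()].
#' @param distance_mode Distance used for D: `"promoter"` (SNP to gene
#'   promoter, default) or `"marker"` (SNP to eQTL marker).
#' @return A list of class `"gene_prior"` with `gene_id`, `pi` (length p_g,
#'   each > 1 in real-data mode), and `components`, a p_g x 4 matrix with
#'   columns `F`, `D`, `cor_AE`, `cor_AB` kept for diagnostics and
#'   contributor attribution.
#' @export
compute_prior <- function(instance, expr = NULL, panel = strain_panel(),
                          distance_mode = c("promoter", "marker")) {
  distance_mode <- match.arg(distance_mode)
  cand <- instance$candidates
  p <- nrow(cand)
  stopifnot(p >= 1L)
  acols <- paste0("atac_", panel$strains)
  gcols <- paste0("geno_", panel$strains)
  A <- as.matrix(cand[acols])
  G <- as.matrix(cand[gcols])
  dist_bp <- if (distance_mode == "promoter") cand$dist_to_promoter else
    cand$dist_to_marker
  D <- distance_score(dist_bp / 1e6)
  Fv <- as.numeric(cand$footprint_flag)
  if (any(Fv < 0)) stop("footprint flag must be nonnegative")

  # row-wise |Pearson| across the 8 strains, vectorized over candidates;
  # E_k = effect_k * genotype_k, so |cor(A_k, E_k)| = |cor(A_k, geno_k)|
  # whenever effect_k != 0
  Ac <- A - rowMeans(A)
  ssA <- rowSums(Ac^2)
  Gc <- G - rowMeans(G)
  ssG <- rowSums(Gc^2)
  okE <- ssA > 0 & ssG > 0 & cand$effect != 0
  cor_AE <- ifelse(okE,
                   abs(rowSums(Ac * Gc)) / sqrt(pmax(ssA * ssG, 1e-300)), 0)
  if (is.null(expr)) {
    cor_AB <- numeric(p)
    okB <- rep(TRUE, p)
  } else {
    Bc <- expr - mean(expr)
    ssB <- sum(Bc^2)
    okB <- ssA > 0 & ssB > 0
    cor_AB <- ifelse(okB,
                     abs(drop(Ac %*% Bc)) / sqrt(pmax(ssA * ssB, 1e-300)), 0)
  }
  if (!all(okE) || !all(okB))
    warning("zero-variance vector in prior correlation; term set to 0",
            call. = FALSE)
  comp <- cbind(F = Fv, D = D, cor_AE = cor_AE, cor_AB = cor_AB)
  rownames(comp) <- cand$snp_id
  structure(list(gene_id = instance$gene_id,
                 pi = unname(rowSums(comp)) + 1,
                 components = comp),
            class = "gene_prior")
}

#' Non-informative prior override
#'
#' Returns a `"gene_prior"` with all weights set to 1 (flat Dirichlet),
#' the non-informative setting of the simulation study.
#'
#' @param gene_id Gene identifier.
#' @param p Number of candidate SNPs.
#' @param snp_ids Optional SNP identifiers for the component rownames.
#' @return A `"gene_prior"` with `pi` identically 1 and zero components.
#' @export
flat_prior <- function(gene_id, p, snp_ids = NULL) {
  comp <- matrix(0, p, 4,
                 dimnames = list(snp_ids, c("F", "D", "cor_AE", "cor_AB")))
  structure(list(gene_id = gene_id, pi = rep(1, p), components = comp),
            class = "gene_prior")
}

#' Export prior diagnostics as a long table
#'
#' @param priors List of `"gene_prior"` objects.
#' @return Data frame with gene_id, snp_id, the four components, and pi.
#' @export
prior_diagnostics <- function(priors) {
  do.call(rbind, lapply(priors, function(pr) {
    data.frame(gene_id = pr$gene_id,
               snp_id = rownames(pr$components) %||%
                 as.character(seq_along(pr$pi)),
               F = pr$components[, "F"],
               D = pr$components[, "D"],
               cor_AE = pr$components[, "cor_AE"],
               cor_AB = pr$components[, "cor_AB"],
               pi = pr$pi,
               row.names = NULL)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
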