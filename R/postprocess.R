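# Turning fitted posteriors into calls: direct-posterior-probability FDR
# selection, credible sets, selection strategies, and prior-component
# attribution.

#' Direct-posterior-probability FDR selection
#'
#' Sorts genes by descending posterior causal probability and selects the
#' largest prefix whose mean null posterior (1 - v_hat) does not exceed
#' `alpha`. Genes tied at the cut value are included together if the prefix
#' including all of them still satisfies the bound, and excluded together
#' otherwise, so the call does not depend on input order.
#'
#' @param v_hats Posterior probabilities of a causal SNP, one per gene.
#' @param alpha Target FDR (default 0.05).
#' @return Logical vector aligned with `v_hats`.
#' @export
#'
#' @examples
#' fdr_select(c(0.99, 0.97, 0.90, 0.50))
fdr_select <- function(v_hats, alpha = 0.05) {
  n <- length(v_hats)
  if (n == 0L) return(logical(0))
  stopifnot(all(v_hats >= 0 & v_hats <= 1))
  ord <- order(v_hats, decreasing = TRUE)
  cmean <- cumsum(1 - v_hats[ord]) / seq_len(n)
  k <- if (any(cmean <= alpha)) max(which(cmean <= alpha)) else 0L
  if (k == 0L) return(rep(FALSE, n))
  cut_val <- v_hats[ord[k]]
  # expand or contract to treat ties at the cut as a block
  k_hi <- max(which(v_hats[ord] >= cut_val))
  if (k_hi > k) {
    if (cmean[k_hi] <= alpha) k <- k_hi else k <- min(which(v_hats[ord] ==
                                                              cut_val)) - 1L
  }
  sel <- rep(FALSE, n)
  if (k > 0L) sel[ord[seq_len(k)]] <- TRUE
  sel
}

#' Credible set of candidate SNPs for one gene
#'
#' The smallest prefix of posterior-descending SNPs whose cumulative causal
#' posterior reaches `threshold`. The set is flagged informative when it
#' comprises fewer than `max_fraction` of the candidates (strict
#' comparison).
#'
#' @param snp_posteriors Per-SNP causal posteriors summing to 1.
#' @param threshold Cumulative posterior target (default 0.80).
#' @param max_fraction Informative-set size limit as a fraction of p_g
#'   (default 0.5, strict comparison); a single-candidate gene is always
#'   informative.
#' @param snp_ids Optional identifiers; defaults to indices.
#' @return List with `snp_ids` (ordered), `cumulative` posterior,
#'   `fraction` of candidates used, and `informative` flag.
#' @export
credible_set <- function(snp_posteriors, threshold = 0.80,
                         max_fraction = 0.5, snp_ids = NULL) {
  p <- length(snp_posteriors)
  stopifnot(p >= 1L, abs(sum(snp_posteriors) - 1) < 1e-6)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(p))
  ord <- order(snp_posteriors, decreasing = TRUE)
  cum <- cumsum(snp_posteriors[ord])
  size <- which(cum >= threshold - 1e-12)[1]
  if (is.na(size)) size <- p
  list(snp_ids = snp_ids[ord[seq_len(size)]],
       cumulative = cum[size],
       fraction = size / p,
       # a single candidate is trivially fine-mapped; otherwise the set
       # must cover strictly less than max_fraction of the candidates
       informative = p == 1L || (size / p) < max_fraction)
}

#' Causal-SNP selection strategies for one gene
#'
#' Five selections compared throughout the benchmark: the model's most and
#' least likely SNPs (highest/lowest posterior), a random SNP, and the SNPs
#' closest to the eQTL marker and to the gene promoter. Posterior and
#' distance ties are broken by lower genomic coordinate; Random consumes the
#' current seeded generator stream.
#'
#' @param snp_posteriors Per-SNP causal posteriors.
#' @param snp_pos SNP coordinates (bp).
#' @param dist_to_marker,dist_to_promoter Distances (bp) per SNP.
#' @param snp_ids Optional identifiers; defaults to indices.
#' @return Named list mapping strategy to the selected SNP id:
#'   `most_likely`, `least_likely`, `random`, `closest_marker`,
#'   `closest_gene`.
#' @export
select_strategies <- function(snp_posteriors, snp_pos, dist_to_marker,
                              dist_to_promoter, snp_ids = NULL) {
  p <- length(snp_posteriors)
  stopifnot(p >= 1L)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(p))
  pick <- function(key, decreasing) {
    ord <- order(key, snp_pos, decreasing = c(decreasing, FALSE),
                 method = "radix")
    snp_ids[ord[1]]
  }
  list(most_likely = pick(snp_posteriors, TRUE),
       least_likely = pick(snp_posteriors, FALSE),
       random = snp_ids[sample.int(p, 1)],
       closest_marker = pick(dist_to_marker, FALSE),
       closest_gene = pick(dist_to_promoter, FALSE))
}

#' Smallest credible proportion of a ranking
#'
#' The rank of the true causal SNP in a strategy's candidate ranking divided
#' by the number of candidates: the minimum proportion of ranked candidates
#' that must be taken to encompass the causal variant.
#'
#' @param ranking Vector of SNP ids (or indices) in the strategy's order,
#'   best first.
#' @param true_snp The causal SNP's id (or index).
#' @return The proportion, in (0, 1\].
#' @export
credible_proportion <- function(ranking, true_snp) {
  r <- match(true_snp, ranking)
  if (is.na(r)) stop("true causal SNP is not among the candidates")
  r / length(ranking)
}

#' Rank-score attribution of prior components
#'
#' For the causal SNP of a gene, each of the four prior components (F, D,
#' |cor(A,E)|, |cor(A,B)|) is ranked in ascending order across the gene's
#' p_g candidates (average ranks for ties) and normalized by p_g. The
#' leading contributor is the component with the highest rank score.
#'
#' @param components p_g x 4 matrix with columns `F`, `D`, `cor_AE`,
#'   `cor_AB` (as in a `"gene_prior"`).
#' @param causal_index Row index of the causal SNP.
#' @return List with `scores` (named numeric, one per component) and
#'   `leading` (component name; first of the tied maxima).
#' @export
contributor_rank_scores <- function(components, causal_index) {
  p <- nrow(components)
  stopifnot(causal_index >= 1L, causal_index <= p)
  scores <- apply(components, 2, function(v)
    rank(v, ties.method = "average")[causal_index] / p)
  list(scores = scores, leading = names(scores)[which.max(scores)])
}

#' Summarize a fit into per-gene fine-mapping results
#'
#' Applies [fdr_select()] to the posterior causal probabilities, normalizes
#' per-SNP responsibilities into causal posteriors (`w_k / v_hat`, the
#' posterior of Z given V = 1), and builds credible sets and strategy
#' selections per gene. Genes with `v_hat = 0` get no credible set.
#'
#' @param fit A `"finemap_fit"`.
#' @param data The `"model_data"` it was fit to.
#' @param alpha FDR level for gene calls (default 0.05).
#' @param threshold Credible-set cumulative posterior (default 0.80).
#' @param max_fraction Informative-set fraction limit (default 0.5).
#' @return A list of class `"posterior_result"`: data frame `genes`
#'   (gene_id, p, v_hat, fdr_called, credible_set, credible_fraction,
#'   credible_informative, most_likely, least_likely), data frame `snps`
#'   (gene_id, snp_id, w, posterior), and the per-gene `strategies` list.
#' @export
posterior_results <- function(fit, data, alpha = 0.05, threshold = 0.80,
                              max_fraction = 0.5) {
  gi <- data$gene_index
  v <- fit$resp$v_hat
  called <- fdr_select(v, alpha)
  post <- ifelse(v[gi] > 0, fit$resp$w / v[gi], 0)
  genes <- vector("list", length(v))
  strategies <- vector("list", length(v))
  for (g in seq_along(v)) {
    rows <- which(gi == g)
    pg <- post[rows]
    has_set <- v[g] > 0
    cs <- if (has_set)
      credible_set(pg / sum(pg), threshold, max_fraction,
                   snp_ids = data$snp_id[rows]) else NULL
    st <- select_strategies(fit$resp$w[rows], data$snp_pos[rows],
                            data$dist_to_marker[rows],
                            data$dist_to_promoter[rows],
                            snp_ids = data$snp_id[rows])
    strategies[[g]] <- st
    genes[[g]] <- data.frame(
      gene_id = data$gene_id[g], p = data$p[g], v_hat = v[g],
      fdr_called = called[g],
      credible_set = if (has_set) paste(cs$snp_ids, collapse = ",") else "",
      credible_fraction = if (has_set) cs$fraction else NA_real_,
      credible_informative = if (has_set) cs$informative else NA,
      most_likely = st$most_likely, least_likely = st$least_likely)
  }
  structure(list(genes = do.call(rbind, genes),
                 snps = data.frame(gene_id = data$gene_id[gi],
                                   snp_id = data$snp_id,
                                   w = fit$resp$w, posterior = post),
                 strategies = strategies),
            class = "posterior_result")
}

#' Write fine-mapping results as TSVs
#'
#' @param res A `"posterior_result"`.
#' @param gene_path,snp_path Output paths for the per-gene and per-SNP
#'   tables.
#' @param meta Extra header metadata for [write_tsv_output()].
#' @return Invisibly, the two paths.
#' @export
write_results_tsv <- function(res, gene_path, snp_path,
                              meta = character(0)) {
  write_tsv_output(res$genes, gene_path, meta)
  write_tsv_output(res$snps, snp_path, meta)
  invisible(c(gene_path, snp_path))
}
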