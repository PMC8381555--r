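# Footprint-depth statistics from per-base Tn5 cut profiles, comparative
# footprint analysis across allele groups, and the per-peak permutation test
# identifying accessibility-associated variants.

#' Build a dense cut profile from a bedGraph window
#'
#' Expands interval records (0-based half-open) into a per-base-pair vector
#' of depth-normalized 5' Tn5 cut counts over a contig window. Positions not
#' covered by any record are 0.
#'
#' @param bg bedGraph data frame ([read_bedgraph()]).
#' @param chrom Contig name.
#' @param start,end Window bounds (0-based half-open).
#' @param norm Normalization factor already applied to the counts (recorded
#'   for provenance, default 1).
#' @return A list of class `"cut_profile"`: `chrom`, `start`, `counts`
#'   (length `end - start`), `norm`.
#' @export
cut_profile <- function(bg, chrom, start, end, norm = 1) {
  stopifnot(end > start)
  counts <- numeric(end - start)
  rows <- bg[bg$chrom == chrom & bg$end > start & bg$start < end, ,
             drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    a <- max(rows$start[i], start) - start + 1L
    b <- min(rows$end[i], end) - start
    counts[a:b] <- counts[a:b] + rows$value[i]
  }
  if (any(counts < 0)) stop("cut counts must be nonnegative")
  structure(list(chrom = chrom, start = start, counts = counts, norm = norm),
            class = "cut_profile")
}

profile_window_mean <- function(profile, from, to) {
  # from/to 0-based half-open genomic coordinates
  i <- (from - profile$start + 1L):(to - profile$start)
  if (min(i) < 1L || max(i) > length(profile$counts))
    stop("requested window lies outside the cut profile")
  mean(profile$counts[i])
}

#' Footprint depth (FPD) of a binding site
#'
#' The proportional decrease in Tn5 cut sites at the binding site relative
#' to its flanks: `FPD = (flank_mean - site_mean) / flank_mean`, where
#' `flank_mean` averages two flank summaries, the mean cut count over the
#' 1-25 bp flanks (both sides pooled) and over the 26-50 bp flanks (both
#' sides pooled). FPD is at most 1, can be negative (accessibility higher at
#' the site than around it), and is undefined (`NA`) when the flanks carry
#' no cuts.
#'
#' @param profile A `"cut_profile"` covering the site plus 50 bp flanks.
#' @param site_start,site_end Binding-site interval (0-based half-open,
#'   positive width).
#' @return Scalar FPD, or `NA` if the flank mean is zero.
#' @export
footprint_depth <- function(profile, site_start, site_end) {
  stopifnot(site_end > site_start)
  site_mean <- profile_window_mean(profile, site_start, site_end)
  flank1 <- mean(c(
    profile$counts[idx_range(profile, site_start - 25L, site_start)],
    profile$counts[idx_range(profile, site_end, site_end + 25L)]))
  flank2 <- mean(c(
    profile$counts[idx_range(profile, site_start - 50L, site_start - 25L)],
    profile$counts[idx_range(profile, site_end + 25L, site_end + 50L)]))
  flank_mean <- (flank1 + flank2) / 2
  if (flank_mean == 0) return(NA_real_)
  (flank_mean - site_mean) / flank_mean
}

idx_range <- function(profile, from, to) {
  i <- (from - profile$start + 1L):(to - profile$start)
  if (min(i) < 1L || max(i) > length(profile$counts))
    stop("flank window lies outside the cut profile")
  i
}

#' Comparative footprint depth between allele groups
#'
#' Pools the normalized cut profiles of the strains carrying the reference
#' allele and of those carrying the alternative allele, computes the FPD of
#' the site within each pooled profile, and reports
#' `delta = FPD_SNP - FPD_REF`. A deeper footprint in the alternative-allele
#' group (binding enhanced by the SNP) gives `delta > 0`.
#'
#' @param profiles Named list of `"cut_profile"` objects, one per strain,
#'   all over the same window.
#' @param site_start,site_end Binding-site interval (0-based half-open).
#' @param genotypes Named 0/1 vector (alt-allele carriage) over the same
#'   strains.
#' @return List with `fpd_ref`, `fpd_snp`, `delta`, or `NULL` (with a
#'   message) when either allele group is empty.
#' @export
delta_fpd <- function(profiles, site_start, site_end, genotypes) {
  stopifnot(length(profiles) == length(genotypes),
            all(genotypes %in% c(0, 1)))
  ref <- which(genotypes == 0)
  alt <- which(genotypes == 1)
  if (length(ref) == 0L || length(alt) == 0L) {
    message("empty allele group; SNP-motif record skipped")
    return(NULL)
  }
  pool <- function(ix) {
    p <- profiles[[ix[1]]]
    counts <- Reduce(`+`, lapply(profiles[ix], `[[`, "counts"))
    structure(list(chrom = p$chrom, start = p$start, counts = counts,
                   norm = p$norm), class = "cut_profile")
  }
  fpd_ref <- footprint_depth(pool(ref), site_start, site_end)
  fpd_snp <- footprint_depth(pool(alt), site_start, site_end)
  list(fpd_ref = fpd_ref, fpd_snp = fpd_snp, delta = fpd_snp - fpd_ref)
}

#' Empirical p-value for a footprint-depth change
#'
#' One-sided add-one empirical p-value of an observed `delta` FPD against a
#' motif-specific null set (the delta FPDs of SNP-motif pairs whose motif
#' match is not affected in silico). The direction follows the candidate's
#' class: gains test `null >= delta`, losses test `null <= delta`. Fewer
#' than `min_null` null values give a missing p-value.
#'
#' @param delta Observed delta FPD.
#' @param null_deltas Numeric vector of null delta FPDs for the motif.
#' @param direction `"gain"` or `"loss"`.
#' @param min_null Minimum null-set size (default 20).
#' @return The p-value in (0, 1\], or `NA` when the null set is too small.
#' @export
empirical_fpd_pvalue <- function(delta, null_deltas,
                                 direction = c("gain", "loss"),
                                 min_null = 20L) {
  direction <- match.arg(direction)
  null_deltas <- null_deltas[is.finite(null_deltas)]
  if (length(null_deltas) < min_null) return(NA_real_)
  extreme <- if (direction == "gain") sum(null_deltas >= delta) else
    sum(null_deltas <= delta)
  (1 + extreme) / (1 + length(null_deltas))
}

#' Classify a SNP-motif record as gain/loss of function
#'
#' Gain: the reference allele does not match the motif (`pval_ref > 0.05`),
#' the alternative allele does (`pval_snp <= 0.05`), and the footprint
#' deepens (`delta > 0`). Loss is the mirror image. Anything else
#' (including a sign inconsistent with the in-silico change) is `"none"`.
#'
#' @param pval_ref,pval_snp In-silico motif-match p-values for the two
#'   alleles.
#' @param delta Observed delta FPD.
#' @param alpha Match-significance level (default 0.05).
#' @return `"gain"`, `"loss"`, or `"none"` (vectorized).
#' @export
classify_fpd <- function(pval_ref, pval_snp, delta, alpha = 0.05) {
  ifelse(pval_ref > alpha & pval_snp <= alpha & delta > 0, "gain",
         ifelse(pval_ref <= alpha & pval_snp > alpha & delta < 0, "loss",
                "none"))
}

#' Footprint-impact flags from comparative footprint records
#'
#' Filters SNP-motif records to those with a significant in-silico rank
#' change (`pval_rank < 0.05`), a consistent gain/loss classification, and a
#' significant footprint change (`pval_fpd < alpha`); takes each SNP's
#' minimum `pval_fpd` as its p-value for affecting any TF binding site;
#' adjusts across SNPs by Benjamini-Hochberg at level `fdr`. Surviving SNPs
#' receive footprint flag F = 1.
#'
#' @param records Data frame with columns `snp_id`, `motif_id`, `pval_rank`,
#'   `pval_ref`, `pval_snp`, `delta`, `pval_fpd`.
#' @param alpha Per-record significance level (default 0.05).
#' @param fdr SNP-level FDR (default 0.05).
#' @return List with `flags` (named 0/1 vector over all input SNPs),
#'   `snp_table` (snp_id, min pval_fpd, BH-adjusted p, flag), and
#'   `significant_pairs` (the retained SNP-motif records with their class).
#' @export
footprint_flags <- function(records, alpha = 0.05, fdr = 0.05) {
  required <- c("snp_id", "motif_id", "pval_rank", "pval_ref", "pval_snp",
                "delta", "pval_fpd")
  stopifnot(all(required %in% names(records)))
  records$class <- classify_fpd(records$pval_ref, records$pval_snp,
                                records$delta, alpha)
  keep <- records$pval_rank < alpha & records$class != "none" &
    !is.na(records$pval_fpd) & records$pval_fpd < alpha
  retained <- records[keep, , drop = FALSE]
  all_snps <- sort(unique(records$snp_id))
  flags <- stats::setNames(rep(0, length(all_snps)), all_snps)
  if (nrow(retained) == 0L)
    return(list(flags = flags,
                snp_table = data.frame(snp_id = character(0),
                                       min_pval_fpd = numeric(0),
                                       p_adj = numeric(0), flag = integer(0)),
                significant_pairs = retained))
  minp <- tapply(retained$pval_fpd, retained$snp_id, min)
  p_adj <- stats::p.adjust(minp, method = "BH")
  hit <- names(minp)[p_adj <= fdr]
  flags[hit] <- 1
  snp_table <- data.frame(snp_id = names(minp),
                          min_pval_fpd = as.numeric(minp),
                          p_adj = as.numeric(p_adj),
                          flag = as.integer(names(minp) %in% hit),
                          row.names = NULL)
  sig_pairs <- retained[retained$snp_id %in% hit, , drop = FALSE]
  list(flags = flags, snp_table = snp_table, significant_pairs = sig_pairs)
}

#' Per-peak permutation test for accessibility-associated SNPs
#'
#' Within one ATAC-seq peak, associates each SNP's 8-strain genotype with
#' the peak's 8-strain accessibility signal using the squared Pearson
#' correlation, and assesses the best (maximum) statistic against a null of
#' permuted strain labels. Permuting the signal once per iteration and
#' taking the within-peak maximum controls the selection of the best SNP.
#' All SNPs tied at the exact best statistic are retained.
#'
#' @param signal 8-strain peak accessibility signal.
#' @param genotypes Matrix (SNPs x 8) of 0/1 genotypes; rownames are SNP
#'   ids. SNPs with constant genotype are uninformative and ignored.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed applied locally for reproducibility.
#' @return List with `best_snps` (ids of the tied best SNPs), `statistic`
#'   (their shared squared correlation), `p_value` (add-one permutation p
#'   for the peak), `stats` (per informative SNP), or `NULL` (with a
#'   message) when no SNP is informative.
#' @export
local_atac_mv_test <- function(signal, genotypes, n_perm = 10000,
                               seed = NULL) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(signal))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
  }
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  informative <- apply(genotypes, 1, function(g) stats::sd(g) > 0)
  if (stats::sd(signal) == 0 || !any(informative)) {
    message("no informative SNP in peak; skipped")
    return(NULL)
  }
  gmat <- genotypes[informative, , drop = FALSE]
  stat <- drop(stats::cor(t(gmat), signal))^2
  obs <- max(stat)
  perm_max <- vapply(seq_len(n_perm), function(i) {
    s <- sample(signal)
    max(drop(stats::cor(t(gmat), s))^2)
  }, numeric(1))
  p <- (1 + sum(perm_max >= obs)) / (1 + n_perm)
  tied <- which(stat == obs)
  list(best_snps = ids[informative][tied], statistic = obs, p_value = p,
       stats = stats::setNames(stat, ids[informative]))
}

#' Scan peaks for accessibility-associated SNPs
#'
#' Runs [local_atac_mv_test()] on every peak and adjusts the per-peak
#' permutation p-values across peaks with Benjamini-Hochberg.
#'
#' @param peaks Named list; each element has `signal` (8-vector) and
#'   `genotypes` (SNP x 8 matrix).
#' @param n_perm Permutations per peak (default 10000).
#' @param fdr Across-peak FDR (default 0.05).
#' @param seed Optional seed applied locally.
#' @return Data frame with one row per retained best SNP: `peak_id`,
#'   `snp_id`, `statistic`, `p_value`, `p_adj`, `selected`.
#' @export
local_atac_mv_scan <- function(peaks, n_perm = 10000, fdr = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
  }
  res <- lapply(names(peaks), function(pid) {
    r <- local_atac_mv_test(peaks[[pid]]$signal, peaks[[pid]]$genotypes,
                            n_perm = n_perm)
    if (is.null(r)) return(NULL)
    data.frame(peak_id = pid, snp_id = r$best_snps,
               statistic = r$statistic, p_value = r$p_value)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  peak_p <- tapply(out$p_value, out$peak_id, `[`, 1)
  p_adj <- stats::p.adjust(peak_p, method = "BH")
  out$p_adj <- as.numeric(p_adj[out$peak_id])
  out$selected <- out$p_adj <= fdr
  out
}
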