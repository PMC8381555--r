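#' The eight-founder strain panel
#'
#' The Diversity Outbred (DO) mouse population descends from eight founder
#' strains: five classical inbred strains (129, AJ, B6, NOD, NZO) and three
#' wild-derived strains (CAST, PWK, WSB). B6 is the reference strain: all
#' allelic patterns are coded relative to it, and by construction it carries
#' the reference allele at every SNP.
#'
#' All 8-vectors in the package (allelic effects, ATAC-seq signal, genotypes,
#' founder expression) are ordered as `panel$strains`.
#'
#' @param strains Character vector of 8 strain names. The default order is
#'   alphabetical: 129, AJ, B6, CAST, NOD, NZO, PWK, WSB.
#' @param classical Names of the five classical inbred strains.
#' @param wild Names of the three wild-derived strains.
#' @param reference The reference strain (must be classical).
#'
#' @return An object of class `"strain_panel"`: a list with `strains`,
#'   `classical`, `wild`, `reference`, and the integer index sets
#'   `classical_idx`, `wild_idx`, `reference_idx`.
#' @export
#'
#' @examples
#' panel <- strain_panel()
#' panel$wild
strain_panel <- function(strains = c("129", "AJ", "B6", "CAST", "NOD",
                                     "NZO", "PWK", "WSB"),
                         classical = c("129", "AJ", "B6", "NOD", "NZO"),
                         wild = c("CAST", "PWK", "WSB"),
                         reference = "B6") {
  strains <- as.character(strains)
  if (length(strains) != 8L || anyDuplicated(strains))
    stop("`strains` must be 8 distinct strain names")
  if (length(classical) != 5L || length(wild) != 3L)
    stop("panel requires 5 classical and 3 wild-derived strains")
  if (!setequal(c(classical, wild), strains))
    stop("classical and wild strains must partition the panel")
  if (!reference %in% classical)
    stop("reference strain must be one of the classical strains")
  structure(
    list(strains = strains,
         classical = classical,
         wild = wild,
         reference = reference,
         classical_idx = match(classical, strains),
         wild_idx = match(wild, strains),
         reference_idx = match(reference, strains)),
    class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("Founder strain panel (", length(x$strains), " strains)\n", sep = "")
  cat("  classical:", paste(x$classical, collapse = ", "), "\n")
  cat("  wild-derived:", paste(x$wild, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

#' Standardize and trinarize an 8-strain effect vector
#'
#' Converts a continuous 8-strain allelic-effect (or normalized expression)
#' vector into a trinary allelic pattern in \{-1, 0, +1\}: the vector is
#' min-max scaled to \[0, 1\], the scaled value of the reference strain (B6)
#' is subtracted, and each centered entry is coded +1 if it exceeds `cutoff`,
#' -1 if below `-cutoff`, and 0 otherwise (strict inequalities). The reference
#' entry is 0 by construction. A constant vector (max = min) carries no
#' information and is coded all-zero.
#'
#' Because min-max scaling removes location and scale, the result is invariant
#' to affine transforms `a*x + b` (a > 0) of the raw vector.
#'
#' @param effects Numeric vector of 8 finite values, in panel order.
#' @param panel A [strain_panel()].
#' @param cutoff Trinarization cutoff on the centered \[0,1\]-scaled values
#'   (default 0.2).
#' @return Integer vector of 8 codes in \{-1, 0, +1\}.
#' @export
#'
#' @examples
#' trinarize_effects(c(2, 2, 2, 2, 2, 2, 0, 2), strain_panel())
trinarize_effects <- function(effects, panel = strain_panel(), cutoff = 0.2) {
  if (length(effects) != 8L || !all(is.finite(effects)))
    stop("`effects` must be 8 finite values")
  rng <- range(effects)
  if (rng[1] == rng[2]) return(integer(8L))
  scaled <- (effects - rng[1]) / (rng[2] - rng[1])
  centered <- scaled - scaled[panel$reference_idx]
  as.integer((centered > cutoff) - (centered < -cutoff))
}

#' Trinarize a marginal genotype-effect into a founder pattern
#'
#' Expands the scalar effect of a single SNP from the marginal regression of
#' founder gene expression on genotype into an 8-strain trinary pattern: if
#' the effect is significant at `alpha`, strains carrying the alternative
#' allele receive `sign(effect)` and reference-allele strains receive 0;
#' otherwise the pattern is all-zero. This yields one row of the trinarized
#' genotype-effect matrix; the row of the causal SNP is the causal allelic
#' pattern the mixture model compares against.
#'
#' @param effect Scalar regression effect size.
#' @param pvalue Its p-value, in \[0, 1\].
#' @param genotypes 8-vector of alt-allele carriage in \{0, 1\}, panel order.
#' @param alpha Significance level (default 0.05; significance is
#'   `pvalue < alpha`).
#' @return Integer vector of 8 codes in \{-1, 0, +1\}.
#' @export
trinarize_genotype_effects <- function(effect, pvalue, genotypes,
                                       alpha = 0.05) {
  if (length(genotypes) != 8L || !all(genotypes %in% c(0, 1)))
    stop("`genotypes` must be 8 values in {0, 1}")
  if (!is.finite(pvalue) || pvalue < 0 || pvalue > 1)
    stop("`pvalue` must be in [0, 1]")
  code <- if (is.finite(pvalue) && pvalue < alpha) sign(effect) else 0
  as.integer(genotypes * code)
}

#' Distance score for the multi-omics prior
#'
#' Piecewise score on the genomic distance `x` (in Mb) between a candidate
#' SNP and the gene promoter (or eQTL marker, depending on configuration).
#' Distances up to 0.25 Mb are not penalized (score 0.5); beyond the knee the
#' score is (5/12) / (10 x - 5/3), continuous at x = 0.25 and strictly
#' decreasing, so that closer variants are slightly favored without distance
#' overwhelming the other prior components (the maximum is 0.5).
#'
#' @param x Distance(s) in Mb, nonnegative. Vectorized.
#' @return Numeric score(s) in (0, 0.5] for x in (0, 1]; x = 0 gives 0.5.
#' @export
#'
#' @examples
#' distance_score(c(0.1, 0.25, 0.5))
distance_score <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("distance must be finite and nonnegative")
  ifelse(x <= 0.25, 0.5, (5 / 12) / (10 * x - 5 / 3))
}

#' Edit-distance counts between two trinary allelic patterns
#'
#' For each strain, the edit distance is the absolute difference of the two
#' trinary codes, in \{0, 1, 2\}. These are tallied separately over the five
#' classical strains (counts `n`, a 3-cell multinomial with 5 trials) and the
#' three wild-derived strains (counts `m`, 3 trials). The same operation
#' serves the causal pairing (DO pattern vs candidate genotype-effect
#' pattern) and the null pairing (DO pattern vs founder-expression pattern).
#'
#' @param y,r Trinary vectors of 8 codes in \{-1, 0, +1\}, panel order.
#' @param panel A [strain_panel()].
#' @return A list of class `"edit_counts"` with integer triples `n`
#'   (classical, sums to 5) and `m` (wild, sums to 3), each named
#'   `c("d0","d1","d2")`.
#' @export
#'
#' @examples
#' y <- c(0, 0, 0, 1, 0, 0, 1, 1)
#' edit_distance_counts(y, y)
edit_distance_counts <- function(y, r, panel = strain_panel()) {
  stopifnot(length(y) == 8L, length(r) == 8L,
            all(y %in% -1:1), all(r %in% -1:1))
  d <- abs(y - r)
  n <- tabulate(d[panel$classical_idx] + 1L, nbins = 3L)
  m <- tabulate(d[panel$wild_idx] + 1L, nbins = 3L)
  structure(list(n = stats::setNames(n, c("d0", "d1", "d2")),
                 m = stats::setNames(m, c("d0", "d1", "d2"))),
            class = "edit_counts")
}

#' Restrict candidate SNPs to the window around an eQTL marker
#'
#' Keeps SNPs on the marker's chromosome within `window_mb` megabases of the
#' marker position (closed interval, i.e. marker +/- W), sorted by position.
#'
#' @param marker_chrom Marker chromosome.
#' @param marker_pos Marker position (bp).
#' @param snps Data frame with columns `chrom` and `pos` (bp).
#' @param window_mb Half-width W of the window in Mb (default 1).
#' @return The subset of `snps` inside the window, position-sorted.
#' @export
candidate_window <- function(marker_chrom, marker_pos, snps, window_mb = 1) {
  w <- window_mb * 1e6
  keep <- snps$chrom == marker_chrom & abs(snps$pos - marker_pos) <= w
  out <- snps[keep, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}
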