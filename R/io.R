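# Readers for the tab-separated input tables. Conventions: TSV positions are
# 1-based; BED/bedGraph intervals are 0-based half-open (native); lines
# starting with "#" are headers/comments and are skipped.

read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

check_strain_cols <- function(df, panel, path, suffix = "") {
  cols <- paste0(panel$strains, suffix)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing strain column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  dup <- cols[cols %in% names(df)[duplicated(names(df))]]
  if (length(dup) > 0L)
    stop(sprintf("%s: duplicated strain column(s): %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  cols
}

#' Read a DO-eQTL association table
#'
#' One row per gene-marker association, with the 8-founder allelic-effect
#' vector in strain-named columns. Required columns: `gene_id`, `gene_chrom`,
#' `gene_promoter_pos`, `marker_chrom`, `marker_pos`, plus one numeric column
#' per strain (panel names). A gene may appear under several markers and a
#' marker under several genes; each row becomes its own association instance.
#' Rows with missing or non-numeric effects are rejected with a message
#' naming the offending line.
#'
#' @param path Path to the TSV file.
#' @param panel A [strain_panel()].
#' @return A list of `"eqtl_instance"` objects, each with `gene_id`,
#'   `gene_chrom`, `gene_promoter_pos`, `marker_chrom`, `marker_pos`,
#'   `effects` (named 8-vector in panel order) and an initially empty
#'   `candidates` table (filled by [assemble_instances()]).
#' @export
read_eqtl_table <- function(path, panel = strain_panel()) {
  df <- read_tsv_table(path)
  required <- c("gene_id", "gene_chrom", "gene_promoter_pos",
                "marker_chrom", "marker_pos")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  cols <- check_strain_cols(df, panel, path)
  eff <- df[cols]
  bad <- integer(0)
  for (j in seq_along(eff)) {
    v <- eff[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- union(bad, which(is.na(vn) & !is.na(v)))
      eff[[j]] <- vn
    }
    bad <- union(bad, which(is.na(eff[[j]])))
  }
  if (length(bad) > 0L) {
    message(sprintf(
      "%s: rejected %d row(s) with missing/non-numeric effects (line %s)",
      path, length(bad),
      paste(sort(bad) + 1L, collapse = ", ")))  # +1: header line
    df <- df[-sort(bad), , drop = FALSE]
    eff <- eff[-sort(bad), , drop = FALSE]
  }
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(gene_id = as.character(df$gene_id[i]),
           gene_chrom = as.character(df$gene_chrom[i]),
           gene_promoter_pos = as.numeric(df$gene_promoter_pos[i]),
           marker_chrom = as.character(df$marker_chrom[i]),
           marker_pos = as.numeric(df$marker_pos[i]),
           effects = stats::setNames(as.numeric(eff[i, ]), panel$strains),
           candidates = NULL),
      class = "eqtl_instance")
  })
}

#' Read the candidate-SNP multi-omics feature table
#'
#' One row per candidate SNP with columns `snp_id`, `chrom`, `pos`,
#' `peak_id`, `dist_to_promoter`, `dist_to_marker`, `footprint_flag`,
#' `effect`, `effect_pvalue`, then 8 genotype columns (`geno_<strain>`, in
#' \{0,1\}, reference strain all 0) and 8 ATAC-signal columns
#' (`atac_<strain>`, normalized peak signal).
#'
#' @inheritParams read_eqtl_table
#' @return A data frame with genotype and ATAC columns reordered to panel
#'   order.
#' @export
read_snp_features <- function(path, panel = strain_panel()) {
  df <- read_tsv_table(path)
  required <- c("snp_id", "chrom", "pos", "peak_id", "dist_to_promoter",
                "dist_to_marker", "footprint_flag", "effect", "effect_pvalue")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  gcols <- paste0("geno_", panel$strains)
  acols <- paste0("atac_", panel$strains)
  for (cc in c(gcols, acols))
    if (!cc %in% names(df))
      stop(sprintf("%s: missing strain column(s): %s", path, cc),
           call. = FALSE)
  ref_g <- df[[paste0("geno_", panel$reference)]]
  if (any(ref_g != 0))
    stop(sprintf("%s: reference strain (%s) must carry genotype 0",
                 path, panel$reference), call. = FALSE)
  df[c(required, gcols, acols)]
}

#' Read the founder gene-expression table
#'
#' `gene_id` plus 8 strain-named columns of normalized founder expression.
#'
#' @inheritParams read_eqtl_table
#' @return A numeric matrix (genes x 8, panel order) with gene_id rownames.
#' @export
read_founder_expression <- function(path, panel = strain_panel()) {
  df <- read_tsv_table(path)
  if (!"gene_id" %in% names(df))
    stop(sprintf("%s: missing column(s): gene_id", path), call. = FALSE)
  cols <- check_strain_cols(df, panel, path)
  m <- as.matrix(df[cols])
  if (anyNA(m)) stop(sprintf("%s: missing expression values", path),
                     call. = FALSE)
  rownames(m) <- as.character(df$gene_id)
  m
}

#' Read an ATAC-seq peak BED file
#'
#' BED3+ with the peak identifier in column 4; 0-based half-open intervals.
#'
#' @param path Path to the BED file.
#' @return Data frame with `chrom`, `start`, `end`, `peak_id`.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop(sprintf("%s: BED needs >= 4 columns", path))
  stats::setNames(df[1:4], c("chrom", "start", "end", "peak_id"))
}

#' Read motif-site intervals (BED6, motif id in the name field)
#' @param path Path to the BED file.
#' @return Data frame with `chrom`, `start`, `end`, `motif_id`, `score`,
#'   `strand`.
#' @export
read_motif_sites <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop(sprintf("%s: BED needs >= 4 columns", path))
  if (ncol(df) < 6L) { df$score <- 0; df$strand <- "." }
  stats::setNames(df[1:6],
                  c("chrom", "start", "end", "motif_id", "score", "strand"))
}

#' Read a per-strain bedGraph of normalized Tn5 cut counts
#' @param path Path to the bedGraph file.
#' @return Data frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop(sprintf("%s: bedGraph needs 4 columns", path))
  stats::setNames(df[1:4], c("chrom", "start", "end", "value"))
}

#' Read precomputed in-silico motif-match p-values
#'
#' TSV with `snp_id`, `motif_id`, `pval_rank`, `pval_ref`, `pval_snp`
#' (atSNP-style p-values, consumed as input).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those five columns.
#' @export
read_snp_motif_pvalues <- function(path) {
  df <- read_tsv_table(path)
  required <- c("snp_id", "motif_id", "pval_rank", "pval_ref", "pval_snp")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Attach candidate SNPs to eQTL association instances
#'
#' For each association, candidates are the feature-table SNPs inside the
#' window around the eQTL marker (see [candidate_window()]). Associations
#' with no candidate cannot be fine-mapped and are dropped with a logged
#' count.
#'
#' @param instances List of instances from [read_eqtl_table()].
#' @param snps Feature table from [read_snp_features()].
#' @param window_mb Window half-width in Mb (default 1).
#' @return The instances with `$candidates` filled, empty ones removed.
#' @export
assemble_instances <- function(instances, snps, window_mb = 1) {
  out <- lapply(instances, function(inst) {
    inst$candidates <- candidate_window(inst$marker_chrom, inst$marker_pos,
                                        snps, window_mb)
    inst
  })
  empty <- vapply(out, function(x) nrow(x$candidates) == 0L, logical(1))
  if (any(empty))
    message(sprintf(
      "%d association(s) had no candidate SNP in the window and were dropped",
      sum(empty)))
  out[!empty]
}

#' Write a TSV with commented metadata header lines
#'
#' All tabular outputs carry `#`-prefixed header lines recording at least the
#' package version and, where applicable, the seed and configuration hash, so
#' that two runs with identical configuration produce byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named character vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(df, path, meta = character(0)) {
  meta <- c(version = as.character(utils::packageVersion("finemapDO")), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
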