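## Quality control: per-SNP statistics, the standard case-control GWAS filters
## (sample and SNP missingness, minor allele frequency, Hardy-Weinberg
## equilibrium among controls, imputation quality), assignment of SNPs to
## padded gene regions, and candidate-gene selection.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts that are no more probable than the
#' observed one.  Computed with the standard recurrence on the conditional
#' distribution of the heterozygote count, so it is exact for any sample size.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return the exact two-sided p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 100) < 1e-6
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!vapply(counts, is_count, logical(1))) || any(counts < 0)) {
    stop_config("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop_config("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa  # minor allele count
  if (n_rare == 0 || n_rare == 2 * n) return(1)

  # conditional distribution of the heterozygote count given allele counts:
  # P(het+2)/P(het) = 4*hom_r*hom_c / ((het+2)*(het+1)), walked from the
  # smallest admissible het count (same parity as n_rare) upward.
  het0 <- n_rare %% 2
  hets <- seq(het0, n_rare, by = 2)
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    het <- hets[i - 1]
    hom_r <- (n_rare - het) / 2
    hom_c <- n - het - hom_r
    logp[i] <- logp[i - 1] + log(4 * hom_r * hom_c) - log((het + 2) * (het + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (length(obs) != 1) {
    stop_config("genotype counts inconsistent: heterozygote count %d has wrong parity", n_Aa)
  }
  # ties count toward the tail (p <= p_obs), with a small relative guard
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Per-SNP summary statistics
#'
#' Computes, for every SNP column, the folded minor allele frequency from mean
#' dosage, the missingness fraction, and the exact Hardy-Weinberg p-value among
#' controls.  Genotypes for the HWE test are hard-called by rounding dosage to
#' the nearest integer (halves away from zero).  SNPs with no non-missing
#' values are flagged monomorphic-missing and their statistics set `NA`.
#'
#' @param dosages samples x SNPs matrix of minor-allele dosages.
#' @param samples sample table (sample_id, status, site) aligned by id.
#' @param snps optional SNP-table skeleton (chrom/pos/alleles/imputation_r2)
#'   to be carried through.
#' @return a SNP table data frame with snp_id, chrom, pos, minor, major, maf,
#'   missingness, hwe_p_controls, imputation_r2, monomorphic.
#' @export
compute_snp_stats <- function(dosages, samples, snps = NULL) {
  assert_dosage_matrix(dosages)
  samples <- align_samples(samples, rownames(dosages))
  ctl <- samples$status == 0L

  n <- nrow(dosages)
  miss <- colSums(is.na(dosages)) / n
  mean_d <- colMeans(dosages, na.rm = TRUE)
  af <- mean_d / 2
  maf <- pmin(af, 1 - af)
  all_missing <- miss >= 1

  hwe <- vapply(seq_len(ncol(dosages)), function(j) {
    d <- dosages[ctl, j]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    g <- round_half_up(d)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  mono <- !is.na(maf) & maf == 0
  out <- data.frame(
    snp_id = colnames(dosages),
    chrom = NA_character_, pos = NA_integer_,
    minor = NA_character_, major = NA_character_,
    maf = ifelse(all_missing, NA_real_, maf),
    missingness = miss,
    hwe_p_controls = hwe,
    imputation_r2 = NA_real_,
    monomorphic = mono | all_missing,
    stringsAsFactors = FALSE
  )
  if (!is.null(snps)) {
    m <- match(out$snp_id, snps$snp_id)
    for (cl in intersect(c("chrom", "pos", "minor", "major", "imputation_r2"),
                         colnames(snps))) {
      out[[cl]] <- snps[[cl]][m]
    }
  }
  rownames(out) <- NULL
  out
}

#' Default GWAS QC thresholds
#'
#' Samples with >= 5% missing dosages are dropped; then SNPs with >= 5%
#' missingness, minor allele frequency < 1%, Hardy-Weinberg p < 1e-6 among
#' controls, or imputation r-squared < 0.3 are dropped.
#'
#' @param sample_miss,snp_miss,maf,hwe,r2 the five cutoffs.
#' @return a named list of thresholds for [apply_qc()].
#' @export
qc_thresholds <- function(sample_miss = 0.05, snp_miss = 0.05, maf = 0.01,
                          hwe = 1e-6, r2 = 0.3) {
  list(sample_miss = sample_miss, snp_miss = snp_miss, maf = maf,
       hwe = hwe, r2 = r2)
}

#' Apply sample and SNP quality-control filters
#'
#' Samples failing the missingness cutoff are dropped first; SNP statistics
#' are then recomputed on the surviving samples and SNPs are filtered in a
#' fixed attribution order (missingness, MAF, HWE, imputation r2): each
#' dropped SNP is counted under the first rule it fails.  Boundary semantics
#' follow the conventional filters: missingness drops at `>=` the cutoff, MAF
#' drops strictly below 1% (a SNP at exactly 0.01 is retained), HWE and r2
#' drop strictly below their cutoffs.
#'
#' @param dosages samples x SNPs dosage matrix.
#' @param samples sample table.
#' @param snps optional SNP-table skeleton carrying imputation_r2 and
#'   chrom/pos/allele metadata.
#' @param thresholds list from [qc_thresholds()].
#' @return a list of class `qc_result`: `dosages`, `samples`, `snps` (the
#'   post-QC SNP table with recomputed statistics), and `report` (a
#'   `qc_report` itemizing drops per rule).
#' @export
apply_qc <- function(dosages, samples, snps = NULL, thresholds = qc_thresholds()) {
  assert_dosage_matrix(dosages)
  samples <- align_samples(samples, rownames(dosages))
  n0 <- nrow(dosages); m0 <- ncol(dosages)

  smiss <- rowSums(is.na(dosages)) / ncol(dosages)
  drop_samples <- rownames(dosages)[smiss >= thresholds$sample_miss]
  keep_s <- setdiff(rownames(dosages), drop_samples)
  if (length(keep_s) == 0) stop_config("QC removed every sample")
  dosages <- dosages[keep_s, , drop = FALSE]
  samples <- samples[samples$sample_id %in% keep_s, , drop = FALSE]

  stats <- compute_snp_stats(dosages, samples, snps)
  fail_miss <- stats$missingness >= thresholds$snp_miss
  fail_maf <- is.na(stats$maf) | stats$maf < thresholds$maf
  fail_hwe <- !is.na(stats$hwe_p_controls) & stats$hwe_p_controls < thresholds$hwe
  fail_r2 <- !is.na(stats$imputation_r2) & stats$imputation_r2 < thresholds$r2

  # first-failing-rule attribution, in the fixed order
  rule <- rep(NA_character_, nrow(stats))
  rule[fail_r2] <- "imputation_r2"
  rule[fail_hwe] <- "hwe"
  rule[fail_maf] <- "maf"
  rule[fail_miss] <- "missingness"
  keep_snp <- is.na(rule)

  report <- structure(list(
    n_samples_in = n0, n_snps_in = m0,
    samples_dropped = drop_samples,
    snps_dropped = split(stats$snp_id[!keep_snp], rule[!keep_snp]),
    counts = c(samples_missingness = length(drop_samples),
               snp_missingness = sum(rule == "missingness", na.rm = TRUE),
               snp_maf = sum(rule == "maf", na.rm = TRUE),
               snp_hwe = sum(rule == "hwe", na.rm = TRUE),
               snp_imputation_r2 = sum(rule == "imputation_r2", na.rm = TRUE)),
    surviving_samples = keep_s,
    surviving_snps = stats$snp_id[keep_snp],
    thresholds = thresholds
  ), class = "qc_report")

  structure(list(
    dosages = dosages[, keep_snp, drop = FALSE],
    samples = samples,
    snps = stats[keep_snp, , drop = FALSE],
    report = report
  ), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_samples_in, "samples,", x$n_snps_in, "SNPs in\n")
  cat("  dropped:",
      sprintf("%d samples (missingness), %d SNPs (miss %d / maf %d / hwe %d / r2 %d)\n",
              x$counts[["samples_missingness"]], sum(x$counts[-1]),
              x$counts[["snp_missingness"]], x$counts[["snp_maf"]],
              x$counts[["snp_hwe"]], x$counts[["snp_imputation_r2"]]))
  cat("  surviving:", length(x$surviving_samples), "samples,",
      length(x$surviving_snps), "SNPs\n")
  invisible(x)
}

#' Assign SNPs to a padded gene region
#'
#' A SNP belongs to the gene if its (1-based) position falls inside the
#' 0-based half-open interval `[start - pad, end + pad)`.  With the default
#' 10 kb pad this includes a SNP exactly 10,000 bp upstream of the transcript
#' start and excludes one 10,001 bp upstream.
#'
#' @param snps SNP table with snp_id, chrom, pos.
#' @param region one-row gene-region table (gene, chrom, start, end; 0-based
#'   half-open transcript union).
#' @param pad flank in bp added on both sides (default 10,000, covering
#'   proximal regulatory sequence).
#' @return SNP ids inside the padded region, ordered by position.
#' @export
assign_snps_to_gene <- function(snps, region, pad = 10000) {
  if (pad < 0) stop_config("pad must be non-negative")
  if (nrow(region) != 1) stop_config("region must be a single gene")
  on_chrom <- snps$chrom == region$chrom
  pos0 <- snps$pos - 1L  # 1-based SNP position -> 0-based coordinate
  hit <- on_chrom & pos0 >= region$start - pad & pos0 < region$end + pad
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) warning(sprintf("no SNPs in region of gene %s", region$gene))
  ids <- snps$snp_id[hit]
  ids[order(snps$pos[hit])]
}

#' Select candidate partner genes
#'
#' Keeps genes whose protein-interaction confidence score is at least
#' `min_score` (default 0.7, the conventional "high confidence" cutoff) and,
#' by default, removes sex-chromosome genes, since X/Y dosages are not
#' comparable between sexes under the autosomal dosage model.
#'
#' @param candidates data frame with gene, chrom, score.
#' @param min_score minimum confidence score, inclusive.
#' @param autosomes_only drop chr X/Y entries.
#' @return the filtered candidate table, ordered by decreasing score.
#' @export
select_candidate_genes <- function(candidates, min_score = 0.7,
                                   autosomes_only = TRUE) {
  if (nrow(candidates) == 0) return(candidates)
  if (any(!is.na(candidates$score) & (candidates$score < 0 | candidates$score > 1))) {
    stop_config("confidence scores must lie in [0, 1]")
  }
  keep <- !is.na(candidates$score) & candidates$score >= min_score
  if (autosomes_only) keep <- keep & !(as.character(candidates$chrom) %in% SEX_CHROMS)
  out <- candidates[keep, , drop = FALSE]
  out[order(-out$score, out$gene), , drop = FALSE]
}
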