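## Family-wise error control by case-control label permutation (min-p / max-T),
## empirical p-values, the rank-based significance threshold, replication of
## surviving pairs in an independent cohort, and the driving-SNP
## allelic-heterogeneity rescan.

#' Permute case-control labels
#'
#' Returns a random rearrangement of `y`: the multiset of labels is exactly
#' preserved, and genotypes/covariates stay attached to individuals (only the
#' outcome moves), which breaks every genotype-outcome and covariate-outcome
#' association while keeping the genotype and covariate structure intact.
#'
#' @param y binary label vector.
#' @param seed integer seed (fully determines the permutation).
#' @param strata optional factor for stratified permutation (labels shuffled
#'   within levels, e.g. within study site).
#' @return permuted label vector.
#' @export
permute_labels <- function(y, seed, strata = NULL) {
  if (!all(y %in% c(0, 1))) stop_config("labels must be binary 0/1")
  with_seed(seed, {
    if (is.null(strata)) {
      sample(y)
    } else {
      out <- y
      for (lev in unique(strata)) {
        i <- which(strata == lev)
        out[i] <- sample(y[i])
      }
      out
    }
  })
}

#' Build the permutation min-p null distribution
#'
#' For each of `B` replicates the case-control labels are permuted once and
#' every interaction scan (all index-gene x partner-gene SNP pairs, all
#' partner genes) is recomputed with the covariates held fixed; the replicate
#' contributes the experiment-wide minimum p over all OK tests.  This is the
#' min-p / max-T family-wise correction: each gene's observed minimum p is
#' referred to the single experiment-wide null.  `null_type = "per-gene"`
#' instead keeps one null per partner gene (each replicate's minimum taken
#' within that gene's pairs only).
#'
#' @param dosages samples x SNPs dosage matrix (post-QC).
#' @param samples sample table aligned to `dosages` rows (supplies the
#'   case-control labels).
#' @param covariates adjustment matrix aligned to `dosages` rows.
#' @param snps_index index-gene SNP ids.
#' @param partner_snp_lists named list of partner-gene SNP id vectors.
#' @param B number of permutation replicates (default 1,000).
#' @param master_seed master seed; per-replicate seeds are derived from it by
#'   fixed offsets and recorded.
#' @param alpha nominal family-wise level carried into the object.
#' @param null_type `"experiment"` (default) or `"per-gene"`.
#' @param strata optional stratification factor for the permutations.
#' @return object of class `perm_null`: `B`, `alpha`, `null_min_p` (length-B
#'   experiment-wide minima), `per_gene` (B x genes matrix of per-gene
#'   minima), `n_ok` per replicate, `seeds`, `null_type`.
#' @export
build_null <- function(dosages, samples, covariates = NULL, snps_index,
                       partner_snp_lists, B = 1000, master_seed = 1,
                       alpha = 0.05, null_type = c("experiment", "per-gene"),
                       strata = NULL) {
  null_type <- match.arg(null_type)
  assert_dosage_matrix(dosages)
  if (B < 20) stop_config("B must be at least 20")
  if (!is.list(partner_snp_lists) || is.null(names(partner_snp_lists))) {
    stop_config("partner_snp_lists must be a named list of SNP id vectors")
  }
  samples <- align_samples(samples, rownames(dosages))
  y <- samples$status
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)

  snps_partner <- unlist(partner_snp_lists, use.names = FALSE)
  gene_index <- rep(seq_along(partner_snp_lists),
                    lengths(partner_snp_lists))
  miss <- setdiff(c(snps_index, snps_partner), colnames(dosages))
  if (length(miss)) stop_config("SNPs absent from dosage matrix: %s",
                                paste(head(miss, 5), collapse = ", "))

  seeds <- vapply(seq_len(B), function(b) derive_seed(master_seed, b), integer(1))
  Yperm <- vapply(seeds, function(s) as.numeric(permute_labels(y, s, strata)),
                  numeric(n))

  m <- cpp_null_min_p(dosages[, snps_index, drop = FALSE],
                      dosages[, snps_partner, drop = FALSE],
                      as.integer(gene_index),
                      as.matrix(covariates), Yperm)
  G <- length(partner_snp_lists)
  per_gene <- m[, seq_len(G), drop = FALSE]
  colnames(per_gene) <- names(partner_snp_lists)
  n_ok <- as.integer(m[, G + 1])
  if (any(n_ok == 0)) {
    stop_config("replicate(s) with zero testable pairs: %s",
                paste(head(which(n_ok == 0), 5), collapse = ", "))
  }
  null_min_p <- if (null_type == "experiment") {
    apply(per_gene, 1, min, na.rm = TRUE)
  } else NULL
  structure(list(B = B, alpha = alpha, null_min_p = null_min_p,
                 per_gene = per_gene, n_ok = n_ok, seeds = seeds,
                 null_type = null_type, master_seed = master_seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("Permutation null (%s-wide): B = %d replicates, %d gene(s)\n",
              x$null_type, x$B, ncol(x$per_gene)))
  if (!is.null(x$null_min_p)) {
    cat("experiment-wide min-p quantiles:\n")
    print(stats::quantile(x$null_min_p, c(0.01, 0.05, 0.5)))
  }
  invisible(x)
}

null_values <- function(null, gene = NULL) {
  if (null$null_type == "experiment") return(null$null_min_p)
  if (is.null(gene)) stop_config("per-gene null requires a gene name")
  null$per_gene[, gene]
}

#' Empirical permutation p-value
#'
#' The fraction of null replicates whose minimum p is at least as significant
#' as the observed value: `#(null_min_p <= observed) / B`, ties counting as
#' exceedances.  Values live on the grid `{0, 1/B, ..., 1}`.  The
#' `"add-one"` estimator `( # + 1 ) / (B + 1)` (never exactly zero) is
#' available via `estimator`.
#'
#' @param observed_min_p observed gene-level minimum p (vectorized).
#' @param null a `perm_null`.
#' @param gene partner-gene name, required for a per-gene null.
#' @param estimator `"count"` (default) or `"add-one"`.
#' @return numeric vector of empirical p-values.
#' @export
empirical_p <- function(observed_min_p, null, gene = NULL,
                        estimator = c("count", "add-one")) {
  estimator <- match.arg(estimator)
  nv <- null_values(null, gene)
  cnt <- vapply(observed_min_p, function(o) sum(nv <= o), numeric(1))
  if (estimator == "count") cnt / null$B else (cnt + 1) / (null$B + 1)
}

#' Rank-based family-wise significance threshold
#'
#' The `floor(alpha * B)`-th smallest null minimum p: an observed minimum p
#' at or below this value has empirical family-wise significance `alpha`
#' (with B = 1,000 and alpha = 0.05, the 50th most significant permuted
#' value).
#'
#' @param null a `perm_null`.
#' @param alpha nominal family-wise level.
#' @param gene partner-gene name for a per-gene null.
#' @return the threshold p-value.
#' @export
significance_threshold <- function(null, alpha = 0.05, gene = NULL) {
  k <- floor(alpha * null$B)
  if (k < 1) stop_config("alpha * B = %.2f < 1: no attainable rank", alpha * null$B)
  sort(null_values(null, gene))[k]
}

#' Empirical gene-level results
#'
#' Combines observed gene-level minimum p-values with a permutation null into
#' the per-gene empirical summary: observed min p, empirical p, and the
#' pass/fail flag against the rank threshold (`observed <= threshold`).
#'
#' @param scans named list of `gene_pair_scan` objects (one per partner gene).
#' @param null a `perm_null` built over the same gene family.
#' @param alpha nominal family-wise level.
#' @return data frame of class `empirical_result`: gene, observed_min_p,
#'   empirical_p, passes.
#' @export
empirical_results <- function(scans, null, alpha = null$alpha) {
  thr <- if (null$null_type == "experiment") significance_threshold(null, alpha) else NA
  rows <- lapply(names(scans), function(g) {
    obs <- scans[[g]]$min_p
    th <- if (null$null_type == "experiment") thr else
      significance_threshold(null, alpha, gene = g)
    data.frame(gene = g, observed_min_p = obs,
               empirical_p = empirical_p(obs, null,
                                         gene = if (null$null_type == "per-gene") g),
               passes = !is.na(obs) & obs <= th,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$observed_min_p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_result", "data.frame")
  out
}

#' Select SNP pairs passing the permutation threshold
#'
#' All converged pairs across the given scans with observed `p <= threshold`
#' (ties at the threshold included), ordered by p and annotated with their
#' partner gene.
#'
#' @param scans named list of `gene_pair_scan` objects.
#' @param threshold p-value threshold from [significance_threshold()].
#' @return data frame: gene, snp_a, snp_b, beta3, se3, wald_z, p.
#' @export
select_significant_pairs <- function(scans, threshold) {
  rows <- lapply(names(scans), function(g) {
    res <- scans[[g]]$results
    hit <- res$status == "OK" & !is.na(res$p) & res$p <= threshold
    if (!any(hit)) return(NULL)
    cbind(gene = g, res[hit, c("snp_a", "snp_b", "beta3", "se3", "wald_z", "p")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), snp_a = character(),
                      snp_b = character(), beta3 = numeric(), se3 = numeric(),
                      wald_z = numeric(), p = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$p), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Re-test selected SNP pairs in a replication cohort
#'
#' Runs the same dosage-interaction Wald test for each discovery-significant
#' pair in an independent cohort.  A pair is flagged significant at the
#' nominal two-sided level `alpha` (no permutation correction at this stage:
#' the replication family is the pre-selected pair list); sign agreement of
#' the interaction coefficient with discovery is always reported.  Pairs with
#' a SNP absent from the replication data get status `MISSING` and are
#' excluded from counts.
#'
#' @param pairs data frame with snp_a, snp_b and (optionally) discovery
#'   `beta3` for the direction-consistency report.
#' @param dosages,samples,covariates replication-cohort data (post-QC),
#'   aligned as in [scan_gene_pair()].
#' @param alpha nominal replication level.
#' @return data frame of class `replication_result`: snp_a, snp_b, beta3,
#'   se3, p, status, significant, sign_consistent.
#' @export
replicate_pairs <- function(pairs, dosages, samples, covariates = NULL,
                            alpha = 0.05) {
  if (nrow(pairs) == 0) {
    out <- data.frame(snp_a = character(), snp_b = character(),
                      beta3 = numeric(), se3 = numeric(), p = numeric(),
                      status = character(), significant = logical(),
                      sign_consistent = logical(), stringsAsFactors = FALSE)
    class(out) <- c("replication_result", "data.frame")
    return(out)
  }
  assert_dosage_matrix(dosages)
  samples <- align_samples(samples, rownames(dosages))
  y <- samples$status
  disc_b3 <- if ("beta3" %in% colnames(pairs)) pairs$beta3 else rep(NA_real_, nrow(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$snp_a[i]; b <- pairs$snp_b[i]
    if (!(a %in% colnames(dosages)) || !(b %in% colnames(dosages))) {
      return(data.frame(snp_a = a, snp_b = b, beta3 = NA_real_, se3 = NA_real_,
                        p = NA_real_, status = "MISSING", significant = NA,
                        sign_consistent = NA, stringsAsFactors = FALSE))
    }
    r <- interaction_test(dosages[, a], dosages[, b], covariates, y, a, b)
    data.frame(snp_a = a, snp_b = b, beta3 = r$beta3, se3 = r$se3, p = r$p,
               status = r$status,
               significant = if (r$status == "OK") r$p < alpha else NA,
               sign_consistent = if (r$status == "OK" && !is.na(disc_b3[i]))
                 sign(r$beta3) == sign(disc_b3[i]) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("replication_result", "data.frame")
  out
}

#' Driving-SNP allelic-heterogeneity rescan
#'
#' Exploratory follow-up for a cohort in which the discovery pairs fail to
#' replicate: tests every (driving SNP, partner-gene SNP) combination in the
#' replication cohort at the nominal level, to detect the same gene pair
#' signalling through different variants (allelic heterogeneity).  No
#' permutation correction is applied and the output is labelled exploratory.
#'
#' @param driving_snps ids of the driving SNPs (must be present in the
#'   replication dosages).
#' @param partner_gene_snps ids of the partner-gene SNPs to rescan against.
#' @param dosages,samples,covariates replication-cohort data.
#' @param alpha nominal flagging level.
#' @return data frame: snp_a (driving), snp_b, beta3, se3, p, status,
#'   significant; attribute `exploratory = TRUE`.
#' @export
cross_gene_rescan <- function(driving_snps, partner_gene_snps, dosages,
                              samples, covariates = NULL, alpha = 0.05) {
  assert_dosage_matrix(dosages)
  miss <- setdiff(driving_snps, colnames(dosages))
  if (length(miss)) stop_config("driving SNP(s) absent from replication data: %s",
                                paste(miss, collapse = ", "))
  samples <- align_samples(samples, rownames(dosages))
  y <- samples$status
  grid <- expand.grid(snp_a = driving_snps, snp_b = partner_gene_snps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # deterministic order: driving SNP outer, partner inner
  grid <- grid[order(match(grid$snp_a, driving_snps),
                     match(grid$snp_b, partner_gene_snps)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$snp_a[i]; b <- grid$snp_b[i]
    if (!(b %in% colnames(dosages))) {
      return(data.frame(snp_a = a, snp_b = b, beta3 = NA_real_, se3 = NA_real_,
                        p = NA_real_, status = "MISSING", significant = NA,
                        stringsAsFactors = FALSE))
    }
    r <- interaction_test(dosages[, a], dosages[, b], covariates, y, a, b)
    data.frame(snp_a = a, snp_b = b, beta3 = r$beta3, se3 = r$se3, p = r$p,
               status = r$status,
               significant = if (r$status == "OK") r$p < alpha else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exploratory") <- TRUE
  attr(out, "alpha") <- alpha
  out
}
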