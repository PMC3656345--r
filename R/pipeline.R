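## End-to-end driver: simulate -> serialize -> QC -> ancestry PCA ->
## interaction scans -> permutation null -> replication -> driving-SNP rescan,
## with every stage's result written as a TSV so a fixed master seed
## reproduces the output byte for byte.

#' Run the full synthetic-study interaction pipeline
#'
#' Simulates a two-cohort study from `config`, applies QC, computes ancestry
#' PCs and site covariates per cohort, scans all index x partner SNP pairs in
#' the discovery cohort, builds the label-permutation min-p null, selects
#' pairs passing the rank threshold, re-tests them in the replication cohort,
#' and runs the driving-SNP allelic-heterogeneity rescan.  All results are
#' written under `out_dir` as TSVs plus a YAML run manifest (seeds,
#' thresholds, counts); given the same `config` and `seed` the files are
#' byte-identical across runs.
#'
#' @param config a [sim_config()].
#' @param seed master seed for the whole run.
#' @param out_dir output directory.
#' @param B permutation replicates.
#' @param alpha nominal family-wise level.
#' @param k_pcs ancestry PCs per cohort.
#' @return (invisibly) a list with the scans, null, empirical results,
#'   selected pairs, replication and rescan tables, and file paths.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         out_dir, B = 1000, alpha = 0.05, k_pcs = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_study(config, seed)
  write_study(bundle, file.path(out_dir, "data"))

  prep <- function(cohort) {
    qc <- apply_qc(cohort$dosages, cohort$samples, cohort$snps)
    pca <- eigenstrat_pca(qc$dosages, k = k_pcs)
    covs <- build_covariates(qc$samples, pca, k = k_pcs)
    list(qc = qc, pca = pca, covariates = covs)
  }
  disc <- prep(bundle$discovery)
  repl <- prep(bundle$replication)

  regions <- layout_gene_regions(bundle$truth$layout)
  cand <- select_candidate_genes(
    read_candidate_genes(file.path(out_dir, "data", "candidates.tsv")))
  index_gene <- config$index_gene
  snp_lists <- function(prepd) {
    g <- lapply(c(index_gene, cand$gene), function(gn) {
      assign_snps_to_gene(prepd$qc$snps, regions[regions$gene == gn, , drop = FALSE])
    })
    names(g) <- c(index_gene, cand$gene)
    g
  }
  lists_d <- snp_lists(disc)

  scans <- lapply(cand$gene, function(gn) {
    scan_gene_pair(disc$qc$dosages, lists_d[[index_gene]], lists_d[[gn]],
                   disc$covariates, disc$qc$samples$status,
                   gene_a = index_gene, gene_b = gn)
  })
  names(scans) <- cand$gene
  scan_tab <- do.call(rbind, lapply(cand$gene, function(gn) {
    cbind(gene = gn, scans[[gn]]$results)
  }))
  write.table(scan_tab, file.path(out_dir, "scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  null <- build_null(disc$qc$dosages, disc$qc$samples, disc$covariates,
                     lists_d[[index_gene]], lists_d[cand$gene],
                     B = B, master_seed = derive_seed(seed, 500), alpha = alpha)
  write.table(data.frame(replicate = seq_len(B), seed = null$seeds,
                         min_p = null$null_min_p),
              file.path(out_dir, "null.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  thr <- significance_threshold(null, alpha)
  emp <- empirical_results(scans, null, alpha)
  write.table(as.data.frame(emp), file.path(out_dir, "empirical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pairs <- select_significant_pairs(scans, thr)
  write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rep_res <- replicate_pairs(pairs, repl$qc$dosages, repl$qc$samples,
                             repl$covariates, alpha = 0.05)
  write.table(as.data.frame(rep_res), file.path(out_dir, "replication.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # driving SNPs: the partner-gene SNPs carrying the most selected pairs
  rescan <- NULL
  if (nrow(pairs) > 0) {
    tab <- sort(table(pairs$snp_b), decreasing = TRUE)
    driving <- names(tab)[tab == max(tab)]
    driving <- driving[driving %in% colnames(repl$qc$dosages)]
    lists_r <- snp_lists(repl)
    if (length(driving) > 0 && length(lists_r[[index_gene]]) > 0) {
      rescan <- cross_gene_rescan(driving, lists_r[[index_gene]],
                                  repl$qc$dosages, repl$qc$samples,
                                  repl$covariates)
      write.table(rescan, file.path(out_dir, "rescan.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    master_seed = as.integer(seed), B = as.integer(B), alpha = alpha,
    k_pcs = as.integer(k_pcs),
    qc_thresholds = qc_thresholds(),
    permutation_master_seed = derive_seed(seed, 500),
    threshold = thr,
    n_candidate_genes = nrow(cand),
    n_significant_pairs = nrow(pairs),
    n_replicated = if (nrow(rep_res) > 0) sum(rep_res$significant, na.rm = TRUE) else 0L,
    package_version = as.character(utils::packageVersion("episnp"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(bundle = bundle, discovery = disc, replication = repl,
                 scans = scans, null = null, threshold = thr, empirical = emp,
                 pairs = pairs, replication_result = rep_res, rescan = rescan,
                 manifest = manifest, out_dir = out_dir))
}

#' Demonstration pipeline configuration
#'
#' A down-sized study configuration for the end-to-end demo and determinism
#' checks: 2,000+2,000 discovery and 1,500+1,500 replication samples, an
#' 8-SNP index gene against two 5-SNP partner genes, 60 background SNPs, two
#' sites, and the default planted interaction (odds ratio 2) -- sized so the
#' planted pair clears the family-wise permutation threshold with high
#' probability (its Wald z is ~5 at this n).
#'
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
demo_config <- function(...) {
  sim_config(n_cases = 2000, n_controls = 2000,
             n_replication_cases = 1500, n_replication_controls = 1500,
             snps_index = 8, snps_partner = 5,
             partner_genes = c("GENEB", "GENEC"), partner_chroms = c("20", "14"),
             n_background = 60, n_haplotypes = 1000, n_low_r2 = 1, ...)
}
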