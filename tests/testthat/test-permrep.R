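# Label permutation, the min-p null, empirical p-values and thresholds,
# replication, and the driving-SNP rescan.

fake_null <- function(values, alpha = 0.05) {
  structure(list(B = length(values), alpha = alpha, null_min_p = values,
                 per_gene = matrix(values, ncol = 1,
                                   dimnames = list(NULL, "G")),
                 n_ok = rep(1L, length(values)),
                 seeds = seq_along(values), null_type = "experiment",
                 master_seed = 0L), class = "perm_null")
}

test_that("label permutation preserves the multiset and is seed-deterministic", {
  y <- c(rep(1, 7), rep(0, 13))
  for (s in 1:20) expect_equal(sum(permute_labels(y, s)), 7)
  expect_equal(permute_labels(y, 99), permute_labels(y, 99))
  expect_false(all(permute_labels(y, 1) == permute_labels(y, 2)) &&
                 all(permute_labels(y, 2) == permute_labels(y, 3)))
  # stratified: counts preserved within strata
  strata <- rep(c("a", "b"), each = 10)
  py <- permute_labels(y, 5, strata = strata)
  expect_equal(sum(py[strata == "a"]), sum(y[strata == "a"]))
})

test_that("every distinct label arrangement is reachable across seeds", {
  y <- c(1, 1, 1, 0, 0, 0)
  seen <- character(0)
  for (s in 1:5000) {
    seen <- union(seen, paste(permute_labels(y, s), collapse = ""))
    if (length(seen) == 20) break
  }
  expect_equal(length(seen), choose(6, 3))
})

test_that("empirical p follows the count/B convention with ties as exceedances", {
  nul <- fake_null(seq(0.001, 1, length.out = 1000))
  expect_equal(empirical_p(1e-9, nul), 0)
  expect_equal(empirical_p(2, nul), 1)
  expect_equal(empirical_p(nul$null_min_p[5], nul), 0.005)  # 5 of 1,000
  expect_equal(empirical_p(0.0005, nul, estimator = "add-one"), 1 / 1001)
  # monotone in the observed value
  obs <- sort(runif(20))
  expect_true(all(diff(empirical_p(obs, nul)) >= 0))
})

test_that("the significance threshold is the floor(alpha*B)-th smallest null value", {
  set.seed(31)
  vals <- runif(1000)
  nul <- fake_null(sample(vals))
  expect_equal(significance_threshold(nul, 0.05), sort(vals)[50])
  nul20 <- fake_null(runif(20))
  expect_equal(significance_threshold(nul20, 0.05), min(nul20$null_min_p))
  cnst <- fake_null(rep(0.3, 100))
  expect_equal(significance_threshold(cnst, 0.05), 0.3)
  expect_error(significance_threshold(fake_null(runif(10)), 0.05), "rank")
})

test_that("build_null returns B in-range minima, bit-reproducibly", {
  set.seed(32)
  n <- 120
  d <- cbind(vapply(1:3, function(i) rbinom(n, 2, 0.3), numeric(n)),
             vapply(1:4, function(i) rbinom(n, 2, 0.4), numeric(n)))
  colnames(d) <- c(paste0("i", 1:3), paste0("p", 1:4))
  rownames(d) <- sprintf("S%03d", 1:n)
  samp <- data.frame(sample_id = rownames(d), status = rep(c(0L, 1L), n / 2),
                     site = "s1", stringsAsFactors = FALSE)
  nul <- build_null(d, samp, NULL, paste0("i", 1:3),
                    list(G1 = paste0("p", 1:2), G2 = paste0("p", 3:4)),
                    B = 20, master_seed = 5)
  expect_length(nul$null_min_p, 20)
  expect_true(all(nul$null_min_p > 0 & nul$null_min_p <= 1))
  expect_equal(ncol(nul$per_gene), 2)
  expect_equal(nul$null_min_p, apply(nul$per_gene, 1, min))
  nul2 <- build_null(d, samp, NULL, paste0("i", 1:3),
                     list(G1 = paste0("p", 1:2), G2 = paste0("p", 3:4)),
                     B = 20, master_seed = 5)
  expect_identical(nul$null_min_p, nul2$null_min_p)
  # a different master seed gives a different null
  nul3 <- build_null(d, samp, NULL, paste0("i", 1:3),
                     list(G1 = paste0("p", 1:2), G2 = paste0("p", 3:4)),
                     B = 20, master_seed = 6)
  expect_false(identical(nul$null_min_p, nul3$null_min_p))
})

test_that("per-gene nulls reference each gene to its own distribution", {
  set.seed(33)
  n <- 100
  d <- cbind(i1 = rbinom(n, 2, 0.3), p1 = rbinom(n, 2, 0.4),
             p2 = rbinom(n, 2, 0.2))
  rownames(d) <- sprintf("S%03d", 1:n)
  samp <- data.frame(sample_id = rownames(d), status = rep(c(0L, 1L), n / 2),
                     site = "s1", stringsAsFactors = FALSE)
  nul <- build_null(d, samp, NULL, "i1", list(G1 = "p1", G2 = "p2"),
                    B = 40, master_seed = 2, null_type = "per-gene")
  expect_null(nul$null_min_p)
  t1 <- significance_threshold(nul, 0.05, gene = "G1")
  expect_equal(t1, sort(nul$per_gene[, "G1"])[2])
  expect_error(significance_threshold(nul, 0.05), "gene")
})

test_that("pair selection honours <= threshold semantics including exact ties", {
  res <- data.frame(snp_a = "a", snp_b = c("1", "2", "3"),
                    beta3 = 1, se3 = 1, wald_z = 1,
                    p = c(0.01, 0.05, 0.2), status = "OK", n = 10,
                    stringsAsFactors = FALSE)
  sc <- structure(list(gene_a = "A", gene_b = "B", results = res,
                       min_p = 0.01, best_pairs = NULL, n_skipped = 0),
                  class = "gene_pair_scan")
  got <- select_significant_pairs(list(B = sc), 0.05)
  expect_equal(got$snp_b, c("1", "2"))    # tie at the threshold included
  expect_equal(nrow(select_significant_pairs(list(B = sc), 1e-6)), 0)
})

test_that("replication re-tests pairs, flags missing SNPs, and reports sign agreement", {
  set.seed(34)
  n <- 400
  dA <- rbinom(n, 2, 0.3); dB <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.4 + log(2.5) * dA * dB))
  d <- cbind(a1 = dA, b1 = dB)
  rownames(d) <- sprintf("S%03d", 1:n)
  samp <- data.frame(sample_id = rownames(d), status = as.integer(y),
                     site = "s1", stringsAsFactors = FALSE)
  pairs <- data.frame(snp_a = c("a1", "a1"), snp_b = c("b1", "absent"),
                      beta3 = c(0.8, 0.5), stringsAsFactors = FALSE)
  rep_res <- replicate_pairs(pairs, d, samp, NULL)
  expect_equal(rep_res$status, c("OK", "MISSING"))
  expect_true(rep_res$significant[1])
  expect_true(rep_res$sign_consistent[1])
  expect_true(is.na(rep_res$significant[2]))
  empty <- replicate_pairs(pairs[0, ], d, samp, NULL)
  expect_equal(nrow(empty), 0)
})

test_that("the driving-SNP rescan covers the full grid and flags nominal hits", {
  set.seed(35)
  n <- 500
  dr <- cbind(vapply(1:2, function(i) rbinom(n, 2, 0.3), numeric(n)))
  pt <- vapply(1:16, function(i) rbinom(n, 2, 0.3), numeric(n))
  d <- cbind(dr, pt)
  colnames(d) <- c(paste0("dr", 1:2), sprintf("pt%02d", 1:16))
  rownames(d) <- sprintf("S%03d", 1:n)
  y <- rbinom(n, 1, 0.5)
  samp <- data.frame(sample_id = rownames(d), status = y, site = "s1",
                     stringsAsFactors = FALSE)
  rs <- cross_gene_rescan(paste0("dr", 1:2), sprintf("pt%02d", 1:16), d, samp)
  expect_equal(nrow(rs), 32)
  expect_true(attr(rs, "exploratory"))
  expect_true(all(rs$status == "OK"))
  expect_error(cross_gene_rescan("missing_snp", "pt01", d, samp), "absent")
})

test_that("a strong planted interaction is found and survives the permutation threshold", {
  # odds-ratio 2.5 interaction, n = 3,000, B = 200: the planted pair should
  # be the best pair and be selected in the large majority of runs
  found_best <- found_sig <- 0
  runs <- 5
  for (i in seq_len(runs)) {
    cfg <- sim_config(n_cases = 1500, n_controls = 1500,
                      snps_index = 10, snps_partner = 10,
                      partner_genes = "GENEB", partner_chroms = "20",
                      n_background = 0, n_haplotypes = 1000,
                      beta3 = log(2.5), maf_range = c(0.15, 0.35),
                      site_count = 1, site_effects = 0,
                      ancestry_effect = c(0, 0), duplicate_pair = FALSE,
                      n_low_r2 = 0, n_replication_cases = 50,
                      n_replication_controls = 50, seed = 400 + i)
    lay <- make_snp_layout(cfg)
    pool <- simulate_haplotype_pool(cfg$n_haplotypes, lay, cfg$ld_block_size,
                                    cfg$ld_rho, seed = 400 + i)
    coh <- episnp:::simulate_cohort(pool, cfg, 1500, 1500, 500 + i, "D")
    pp <- episnp:::planted_pair_ids(cfg)
    idx <- lay$snp_id[lay$gene == "GENEA"]
    prt <- lay$snp_id[lay$gene == "GENEB"]
    sc <- scan_gene_pair(coh$dosages, idx, prt, NULL, coh$samples$status,
                         "GENEA", "GENEB")
    best <- sc$best_pairs
    if (nrow(best) == 1 && best$snp_a == pp[["index"]] &&
        best$snp_b == pp[["partner"]]) found_best <- found_best + 1
    nul <- build_null(coh$dosages, coh$samples, NULL, idx, list(GENEB = prt),
                      B = 200, master_seed = 600 + i)
    sel <- select_significant_pairs(list(GENEB = sc),
                                    significance_threshold(nul, 0.05))
    if (any(sel$snp_a == pp[["index"]] & sel$snp_b == pp[["partner"]])) {
      found_sig <- found_sig + 1
    }
  }
  expect_gte(found_best, runs - 1)
  expect_gte(found_sig, runs - 1)
})

test_that("allelic heterogeneity is detectable by the driving-SNP rescan", {
  # in the 'replication' cohort the interaction acts through a different
  # partner SNP; the rescan should flag the new partner while the original
  # pair stays quiet
  hits_new <- 0; quiet_old <- 0
  runs <- 5
  for (i in seq_len(runs)) {
    set.seed(700 + i)
    n <- 2000
    dA <- rbinom(n, 2, 0.3)
    dB_old <- rbinom(n, 2, 0.3)   # original partner: no effect here
    dB_new <- rbinom(n, 2, 0.3)   # effect moved here
    y <- rbinom(n, 1, plogis(-0.5 + log(2.5) * dA * dB_new))
    d <- cbind(drv = dA, old = dB_old, new = dB_new)
    rownames(d) <- sprintf("S%04d", 1:n)
    samp <- data.frame(sample_id = rownames(d), status = as.integer(y),
                       site = "s1", stringsAsFactors = FALSE)
    rs <- cross_gene_rescan("drv", c("old", "new"), d, samp)
    if (isTRUE(rs$significant[rs$snp_b == "new"])) hits_new <- hits_new + 1
    if (!isTRUE(rs$significant[rs$snp_b == "old"])) quiet_old <- quiet_old + 1
  }
  expect_gte(hits_new, runs - 1)    # >= ~70% detection at this effect size
  expect_gte(quiet_old, runs - 2)
})

test_that("under a null cohort the rescan flags about 5% of pairs", {
  set.seed(710)
  n <- 1500
  d <- vapply(1:40, function(j) rbinom(n, 2, 0.3), numeric(n))
  colnames(d) <- c("drv", paste0("p", 1:39))
  rownames(d) <- sprintf("S%04d", 1:n)
  samp <- data.frame(sample_id = rownames(d),
                     status = rep(c(0L, 1L), n / 2), site = "s1",
                     stringsAsFactors = FALSE)
  rs <- cross_gene_rescan("drv", paste0("p", 1:39), d, samp)
  rate <- mean(rs$significant, na.rm = TRUE)
  # 99% binomial bounds around 0.05 with 39 tests are wide: [0, 0.15]
  expect_lte(rate, 0.16)
})
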