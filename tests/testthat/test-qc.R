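# Per-SNP statistics, the Hardy-Weinberg exact test against an enumeration
# oracle, the QC filter cascade, gene-region assignment, candidate selection.

test_that("HWE exact test matches the enumeration oracle on random counts", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:166, 1)
    counts <- as.vector(rmultinom(1, n, prob = runif(3, 0.05, 1)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 oracle_hwe(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12,
                 label = paste("counts", paste(counts, collapse = "/")))
  }
  # totals up to 500
  expect_equal(hwe_exact_test(120, 210, 170), oracle_hwe(120, 210, 170),
               tolerance = 1e-12)
})

test_that("HWE exact test handles the canonical cases", {
  expect_equal(hwe_exact_test(0, 0, 50), 1)       # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(100, 0, 100), 1e-6)    # total heterozygote deficit
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("per-SNP statistics: MAF folding, missingness, control-only HWE", {
  d <- cbind(flat = c(0, 1, 2, 1), zero = c(0, 0, 0, 0), part = c(NA, 1, 1, 0))
  rownames(d) <- paste0("S", 1:4)
  samp <- data.frame(sample_id = paste0("S", 1:4), status = c(0L, 0L, 0L, 1L),
                     site = "s1", stringsAsFactors = FALSE)
  st <- compute_snp_stats(d, samp)
  expect_equal(st$maf[st$snp_id == "flat"], 0.5)
  expect_equal(st$maf[st$snp_id == "zero"], 0)
  expect_true(st$monomorphic[st$snp_id == "zero"])
  expect_equal(st$missingness[st$snp_id == "part"], 0.25)
  # HWE computed on the three controls only
  expect_equal(st$hwe_p_controls[st$snp_id == "flat"], hwe_exact_test(1, 1, 1))
})

test_that("dosage hard-calling rounds halves away from zero", {
  d <- cbind(s = c(0.5, 1.5, 0.4, 1.0))
  rownames(d) <- paste0("S", 1:4)
  samp <- data.frame(sample_id = paste0("S", 1:4), status = 0L, site = "s1",
                     stringsAsFactors = FALSE)
  st <- compute_snp_stats(d, samp)
  # hard calls are 1, 2, 0, 1 -> counts (1, 2, 1)
  expect_equal(st$hwe_p_controls, hwe_exact_test(1, 2, 1))
})

test_that("QC drops one SNP per rule with first-failing-rule attribution", {
  set.seed(7)
  n <- 200
  # enough clean SNPs that one missing genotype keeps a sample under the
  # 5% sample-missingness cutoff
  clean <- vapply(1:24, function(i) rbinom(n, 2, 0.3), numeric(n))
  colnames(clean) <- sprintf("clean%02d", 1:24)
  low_maf <- rbinom(n, 2, 0.003)              # maf < 1%
  missy <- rbinom(n, 2, 0.3); missy[1:20] <- NA   # 10% missing
  hwe_bad <- c(rep(0, 100), rep(2, 100))      # no heterozygotes
  low_r2 <- rbinom(n, 2, 0.25)
  d <- cbind(clean, low_maf = low_maf, missy = missy, hwe_bad = hwe_bad,
             low_r2 = low_r2)
  rownames(d) <- sprintf("S%03d", seq_len(n))
  samp <- data.frame(sample_id = rownames(d),
                     status = rep(c(0L, 1L), n / 2), site = "s1",
                     stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = colnames(d), chrom = "1",
                     pos = seq_len(ncol(d)) * 100L, minor = "A", major = "B",
                     imputation_r2 = c(rep(0.9, 24), 0.9, 0.9, 0.9, 0.2),
                     stringsAsFactors = FALSE)
  qc <- apply_qc(d, samp, snps)
  expect_setequal(qc$report$surviving_snps, colnames(clean))
  expect_equal(unname(qc$report$counts[c("snp_missingness", "snp_maf",
                                         "snp_hwe", "snp_imputation_r2")]),
               c(1, 1, 1, 1))
  # idempotence: nothing more to drop
  qc2 <- apply_qc(qc$dosages, qc$samples, qc$snps)
  expect_equal(sum(qc2$report$counts), 0)
  expect_equal(qc2$dosages, qc$dosages)
})

test_that("samples failing missingness are dropped before SNP statistics", {
  set.seed(8)
  d <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30,
              dimnames = list(sprintf("S%02d", 1:40), sprintf("snp%02d", 1:30)))
  d[1, 1:3] <- NA                      # 10% missing for sample 1
  samp <- data.frame(sample_id = rownames(d), status = rep(c(0L, 1L), 20),
                     site = "s1", stringsAsFactors = FALSE)
  qc <- apply_qc(d, samp)
  expect_equal(qc$report$samples_dropped, "S01")
  expect_false("S01" %in% rownames(qc$dosages))
  # SNP missingness recomputed after the drop: nothing left missing
  expect_equal(sum(qc$report$counts[-1]), 0)
})

test_that("MAF filter is strict: a SNP at exactly 1% survives", {
  # 200 samples, 4 minor alleles -> maf exactly 0.01
  d <- cbind(border = c(rep(1, 4), rep(0, 196)),
             clean = rbinom(200, 2, 0.3))
  rownames(d) <- sprintf("S%03d", 1:200)
  samp <- data.frame(sample_id = rownames(d), status = rep(c(0L, 1L), 100),
                     site = "s1", stringsAsFactors = FALSE)
  qc <- apply_qc(d, samp)
  expect_true("border" %in% qc$report$surviving_snps)
  expect_equal(qc$snps$maf[qc$snps$snp_id == "border"], 0.01)
})

test_that("gene assignment uses the padded half-open interval", {
  # transcript occupies 0-based [50000, 60000); pad 10 kb
  region <- data.frame(gene = "G", chrom = "10", start = 50000L, end = 60000L,
                       stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = c("up_edge", "up_out", "inside", "down_edge", "down_out", "other_chr"),
    chrom = c("10", "10", "10", "10", "10", "11"),
    pos = c(50001L - 10000L,   # exactly 10,000 bp upstream of the first base
            50000L - 10000L,   # 10,001 bp upstream
            55000L,
            60000L + 10000L,   # last included base downstream
            60001L + 10000L,
            55000L),
    stringsAsFactors = FALSE)
  got <- assign_snps_to_gene(snps, region)
  expect_equal(got, c("up_edge", "inside", "down_edge"))
  expect_warning(
    assign_snps_to_gene(snps[snps$chrom == "11", , drop = FALSE][0, ], region),
    "no SNPs")
})

test_that("candidate selection keeps high-confidence autosomal genes", {
  cand <- read_candidate_genes(
    system.file("extdata", "string_candidates.tsv", package = "episnp"))
  sel <- select_candidate_genes(cand)
  expect_equal(nrow(sel), 14)
  expect_false(any(sel$chrom %in% c("X", "Y")))
  # a score of exactly 0.7000 is retained ('at least high confidence')
  edge <- data.frame(gene = c("E1", "E2"), chrom = c("2", "2"),
                     score = c(0.7, 0.6999), stringsAsFactors = FALSE)
  expect_equal(select_candidate_genes(edge)$gene, "E1")
  expect_equal(nrow(select_candidate_genes(cand[0, , drop = FALSE])), 0)
})
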