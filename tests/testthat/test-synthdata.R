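# The synthetic-study generator: haplotype pools with block LD, genotype and
# phenotype simulation, imputation-dosage noise, and the two-cohort bundle.

test_that("block size 1 removes LD and duplicate SNPs are perfectly correlated", {
  lay <- data.frame(snp_id = sprintf("s%02d", 1:10), gene = "G", chrom = "1",
                    pos = 1000L * (1:10), maf = rep(0.3, 10),
                    stringsAsFactors = FALSE)
  pool <- simulate_haplotype_pool(1000, lay, ld_block_size = 1, seed = 41)
  r2 <- cor(pool$haplotypes$A)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.05)

  lay$duplicate_of <- c(NA, "s01", rep(NA, 8))
  pool2 <- simulate_haplotype_pool(500, lay, ld_block_size = 1, seed = 41)
  expect_identical(pool2$haplotypes$A[, "s02"], pool2$haplotypes$A[, "s01"])
  expect_equal(cor(pool2$haplotypes$A[, "s01"], pool2$haplotypes$A[, "s02"])^2, 1)
})

test_that("pool allele frequencies hit their targets and LD decays within blocks", {
  lay <- data.frame(snp_id = sprintf("s%02d", 1:8), gene = "G", chrom = "1",
                    pos = 1000L * (1:8), maf = rep(0.3, 8),
                    stringsAsFactors = FALSE)
  pool <- simulate_haplotype_pool(2000, lay, ld_block_size = 8, ld_rho = 0.9,
                                  seed = 42)
  freq <- colMeans(pool$haplotypes$A)
  expect_true(all(freq >= 0.25 & freq <= 0.35))
  # genotype-scale r2 decreases with index distance inside the block
  g <- pool$haplotypes$A[1:1000, ] + pool$haplotypes$A[1001:2000, ]
  r2 <- cor(g)^2
  expect_gt(r2[1, 2], r2[1, 5])
  expect_gt(r2[1, 5], r2[1, 8])
  expect_error(simulate_haplotype_pool(1, lay, 2, seed = 1), ">= 2")
})

test_that("genotypes are haplotype sums in {0,1,2} with Hardy-Weinberg proportions", {
  lay <- data.frame(snp_id = c("s1", "s2"), gene = "G", chrom = "1",
                    pos = c(1000L, 2000L), maf = c(0.3, 0.15),
                    stringsAsFactors = FALSE)
  pool <- simulate_haplotype_pool(4000, lay, ld_block_size = 1, seed = 43)
  d <- simulate_genotypes(pool, 5000, seed = 44)
  expect_true(all(d %in% 0:2))
  f <- colMeans(pool$haplotypes$A)
  expect_equal(unname(colMeans(d) / 2), unname(f), tolerance = 0.02)
  # genotype counts consistent with HWE at the pool frequency
  for (j in 1:2) {
    counts <- tabulate(d[, j] + 1, 3)
    expected <- 5000 * c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
    expect_gt(chisq.test(counts, p = expected / sum(expected))$p.value, 1e-4)
  }
  expect_identical(simulate_genotypes(pool, 100, seed = 9),
                   simulate_genotypes(pool, 100, seed = 9))
  expect_error(simulate_genotypes(pool, 0, seed = 1), "positive")
})

test_that("an all-zero haplotype pool yields all-zero dosages", {
  lay <- data.frame(snp_id = "s1", gene = "G", chrom = "1", pos = 1000L,
                    maf = 0.3, stringsAsFactors = FALSE)
  pool <- simulate_haplotype_pool(100, lay, 1, seed = 1)
  pool$haplotypes$A[] <- 0L
  pool$haplotypes$B[] <- 0L
  expect_true(all(simulate_genotypes(pool, 50, seed = 2) == 0))
})

test_that("imputation noise hits the target r2 and records the realized value", {
  set.seed(45)
  d <- cbind(a = rbinom(2000, 2, 0.3), b = rbinom(2000, 2, 0.4),
             flat = rep(1L, 2000))
  rownames(d) <- sprintf("S%04d", 1:2000)
  out <- add_imputation_noise(d, c(0.3, 1, 0.5), seed = 46)
  expect_true(all(out$dosages >= 0 & out$dosages <= 2))
  realized <- cor(out$dosages[, "a"], d[, "a"])^2
  expect_gt(realized, 0.25); expect_lt(realized, 0.35)
  expect_equal(unname(out$imputation_r2["a"]), realized)
  expect_equal(unname(out$dosages[, "b"]), unname(as.numeric(d[, "b"])))  # target 1: untouched
  expect_equal(unname(out$imputation_r2["flat"]), 0)          # undefined -> flagged
  expect_equal(out$flagged, "flat")
  expect_error(add_imputation_noise(d, c(0, 1, 1), seed = 1), "\\(0, 1\\]")
})

test_that("phenotypes follow the logistic model and are seed-deterministic", {
  cfg <- small_config(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                      site_count = 1, site_effects = 0,
                      ancestry_effect = c(0, 0))
  lay <- make_snp_layout(cfg)
  pool <- simulate_haplotype_pool(800, lay, cfg$ld_block_size, seed = 47)
  d <- simulate_genotypes(pool, 5000, seed = 48)
  ph <- simulate_phenotypes(d, cfg, seed = 49)
  expect_equal(mean(ph$status), 0.5, tolerance = 2 * sqrt(0.25 / 5000) / 0.5)
  expect_identical(ph$status, simulate_phenotypes(d, cfg, seed = 49)$status)
  expect_error(simulate_phenotypes(d[, 1:2], cfg, seed = 1), "planted")
})

test_that("refitting the generative model recovers the planted interaction", {
  cfg <- small_config(beta3 = log(2))
  lay <- make_snp_layout(cfg)
  pool <- simulate_haplotype_pool(2000, lay, cfg$ld_block_size, seed = 50)
  pp <- episnp:::planted_pair_ids(cfg)
  hits <- 0
  for (i in 1:20) {
    d <- simulate_genotypes(pool, 2500, seed = 50 + i)
    ph <- simulate_phenotypes(d, cfg, seed = 150 + i)
    cv <- cbind(site2 = as.numeric(ph$site == "site2"),
                a1 = ph$ancestry1, a2 = ph$ancestry2)
    r <- interaction_test(d[, pp["index"]], d[, pp["partner"]], cv, ph$status)
    if (r$status == "OK" && abs(r$beta3 - log(2)) < 3 * r$se3) hits <- hits + 1
  }
  expect_gte(hits, 16)   # ~95% nominal; allows a couple of misses at 20 reps
})

test_that("a simulated study has independent cohorts and a faithful truth record", {
  cfg <- small_config()
  b <- simulate_study(cfg, seed = 51)
  expect_s3_class(b, "cohort_bundle")
  expect_equal(nrow(b$discovery$dosages), 300)
  expect_equal(nrow(b$replication$dosages), 240)
  expect_equal(table(b$discovery$samples$status)[["1"]], 150)
  expect_equal(colnames(b$discovery$dosages), colnames(b$replication$dosages))
  # independence: per-SNP correlation between cohorts is near zero
  m <- min(nrow(b$discovery$dosages), nrow(b$replication$dosages))
  cors <- vapply(seq_len(ncol(b$discovery$dosages)), function(j) {
    suppressWarnings(cor(b$discovery$dosages[1:m, j], b$replication$dosages[1:m, j]))
  }, numeric(1))
  expect_lt(mean(abs(cors), na.rm = TRUE), 0.08)
  expect_equal(b$truth$planted_pair[["partner"]], "GENEB_s02")
  # determinism: same config and seed give bit-identical cohorts
  b2 <- simulate_study(cfg, seed = 51)
  expect_identical(b$discovery$dosages, b2$discovery$dosages)
  expect_identical(b$replication$samples, b2$replication$samples)
})

test_that("a study round-trips through the exchange formats", {
  cfg <- small_config()
  b <- simulate_study(cfg, seed = 52)
  dir <- file.path(tempdir(), "study_rt")
  unlink(dir, recursive = TRUE)
  write_study(b, dir)
  back <- read_study(dir)
  expect_equal(back$discovery$dosages, b$discovery$dosages, tolerance = 1e-4)
  expect_equal(back$replication$samples$status, b$replication$samples$status)
  expect_equal(back$truth$config$beta3, b$truth$config$beta3)
  expect_equal(back$truth$planted_pair, b$truth$planted_pair)
  regions <- read_gene_regions(file.path(dir, "genes.bed"))
  expect_setequal(regions$gene, c("GENEA", "GENEB", "GENEC"))
})

test_that("frequency conservation: mean dosage tracks the target MAF", {
  cfg <- small_config()
  b <- simulate_study(cfg, seed = 53)
  lay <- b$truth$layout
  unshifted <- lay$snp_id[lay$shift == 0]
  got <- colMeans(b$discovery$dosages[, unshifted]) / 2
  target <- lay$maf[match(unshifted, lay$snp_id)]
  # 99% binomial bound on the frequency estimate (n = 600 chromosomes),
  # slightly widened for the dosage noise
  bound <- 2.58 * sqrt(target * (1 - target) / 600) + 0.03
  expect_true(all(abs(got - target) < bound + 0.05))
})

test_that("the perfect-LD twin pair survives imputation noise with r2 = 1", {
  cfg <- small_config()
  b <- simulate_study(cfg, seed = 54)
  lay <- b$truth$layout
  twin <- lay$snp_id[!is.na(lay$duplicate_of)]
  template <- lay$duplicate_of[!is.na(lay$duplicate_of)]
  expect_length(twin, 1)
  expect_identical(b$discovery$dosages[, twin], b$discovery$dosages[, template])
  expect_equal(cor(b$replication$dosages[, twin],
                   b$replication$dosages[, template])^2, 1)
})
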