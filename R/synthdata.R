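## Synthetic case-control GWAS cohorts for end-to-end testing of the
## interaction pipeline without controlled-access genotypes.  The generator
## emulates: LD-blocked SNPs inside two (or more) gene regions, including one
## perfectly correlated SNP pair; fractional imputed dosages with a per-SNP
## quality r2; study-site structure; two latent ancestry coordinates, with
## allele frequencies shifting linearly along the first for a configurable
## SNP subset (so genotype PCA has signal to find); and a planted two-locus
## interaction effect on case status under a logistic model.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-study generator, with defaults sized
#' to emulate a mid-size imputed candidate-gene case-control study: cohorts
#' of ~2,000 samples, an index gene of 16 SNPs scanned against three partner
#' genes of 10 SNPs each, ~200 genome-background SNPs for the ancestry PCA,
#' two study sites, and a planted interaction of odds-ratio 2 between one
#' index SNP and one partner SNP (the partner SNP having a perfect-LD twin,
#' so the planted signal is carried by a correlated SNP pair, as seen in real
#' imputed data).
#'
#' @param n_cases,n_controls discovery cohort sizes.
#' @param n_replication_cases,n_replication_controls replication cohort sizes.
#' @param index_gene,index_chrom index-gene symbol and chromosome.
#' @param partner_genes,partner_chroms partner-gene symbols and chromosomes.
#' @param snps_index,snps_partner SNPs per index / per partner gene.
#' @param n_background genome-background SNPs (ancestry signal, PCA input).
#' @param maf_range minor-allele-frequency range; per-SNP targets are spaced
#'   evenly across it.
#' @param ld_block_size SNPs per LD block within a gene (1 = no LD).
#' @param ld_rho latent AR(1) correlation between adjacent SNPs in a block.
#' @param n_haplotypes haplotypes per population pool.
#' @param duplicate_pair plant one perfect-LD (r2 = 1) SNP pair in the first
#'   partner gene.
#' @param beta0,beta1,beta2,beta3 log-odds intercept, the two planted main
#'   effects, and the planted interaction effect.
#' @param site_count,site_effects number of study sites and their log-odds
#'   offsets (first site is the reference, offset 0).
#' @param ancestry_effect log-odds effect of the two latent ancestry
#'   coordinates on case status.
#' @param ancestry_maf_shift allele-frequency shift between the two ancestry
#'   extremes for shifted SNPs.
#' @param background_shift_frac,gene_shift_frac fraction of background / gene
#'   SNPs whose frequency shifts along ancestry coordinate 1 (gene SNPs shift
#'   at half amplitude).
#' @param site_ancestry_shift offset of ancestry coordinate 1 per study site
#'   (makes site a genetic confounder, not only a phenotypic one).
#' @param imputation_r2_range per-SNP imputation-quality targets are spaced
#'   across this range.
#' @param n_low_r2 number of background SNPs given a poor target r2 (0.25,
#'   below the conventional 0.3 filter) so QC has something to drop.
#' @param seed master seed stored with the configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1000, n_controls = 1000,
                       n_replication_cases = 800, n_replication_controls = 1200,
                       index_gene = "GENEA", index_chrom = "10",
                       partner_genes = c("GENEB", "GENEC", "GENED"),
                       partner_chroms = c("20", "14", "1"),
                       snps_index = 16, snps_partner = 10,
                       n_background = 200,
                       maf_range = c(0.05, 0.45),
                       ld_block_size = 4, ld_rho = 0.9,
                       n_haplotypes = 2000,
                       duplicate_pair = TRUE,
                       beta0 = -0.4, beta1 = 0.1, beta2 = 0.1, beta3 = log(2),
                       site_count = 2, site_effects = c(0, 0.2),
                       ancestry_effect = c(0.3, 0.15),
                       ancestry_maf_shift = 0.1,
                       background_shift_frac = 0.5, gene_shift_frac = 0.5,
                       site_ancestry_shift = 0.3,
                       imputation_r2_range = c(0.7, 0.99),
                       n_low_r2 = 2,
                       seed = 1) {
  if (n_cases <= 0 || n_controls <= 0) stop_config("cohort sizes must be positive")
  if (length(partner_genes) != length(partner_chroms)) {
    stop_config("partner_genes and partner_chroms must have equal length")
  }
  if (length(site_effects) != site_count) stop_config("need one site effect per site")
  if (length(ancestry_effect) != 2) stop_config("ancestry_effect must have length 2")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) stop_config("MAFs must lie in (0, 0.5]")
  if (snps_index < 1 || snps_partner < 1) stop_config("need at least one SNP per gene")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d+%d discovery, %d+%d replication (cases+controls)\n",
              x$n_cases, x$n_controls, x$n_replication_cases, x$n_replication_controls))
  cat(sprintf("  genes: %s (%d SNPs) x [%s] (%d SNPs each), %d background SNPs\n",
              x$index_gene, x$snps_index, paste(x$partner_genes, collapse = ", "),
              x$snps_partner, x$n_background))
  cat(sprintf("  planted: beta3 = %.3f (plus mains %.2f/%.2f), %d site(s), seed %d\n",
              x$beta3, x$beta1, x$beta2, x$site_count, x$seed))
  invisible(x)
}

#' SNP layout for a simulation configuration
#'
#' Deterministically lays out per-SNP metadata: id, gene, chromosome,
#' position (evenly spaced within each gene region), target MAF (evenly
#' spaced across `maf_range`), ancestry frequency shift, the perfect-LD
#' duplicate designation, and per-SNP imputation-quality target.
#'
#' @param config a [sim_config()].
#' @return data frame with snp_id, gene, chrom, pos, maf, shift,
#'   duplicate_of, imputation_r2_target.
#' @export
make_snp_layout <- function(config) {
  genes <- data.frame(
    gene = c(config$index_gene, config$partner_genes, "background"),
    chrom = c(config$index_chrom, config$partner_chroms, "2"),
    n = c(config$snps_index, rep(config$snps_partner, length(config$partner_genes)),
          config$n_background),
    start = c(61500000, 100000 + 500000 * seq_along(config$partner_genes), 20000000),
    stringsAsFactors = FALSE
  )
  spacing <- 2000L
  genes <- genes[genes$n > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    n <- genes$n[i]
    data.frame(
      snp_id = sprintf("%s_s%02d", genes$gene[i], seq_len(n)),
      gene = genes$gene[i], chrom = genes$chrom[i],
      pos = genes$start[i] + spacing * (seq_len(n) - 1L),
      maf = seq(config$maf_range[1], config$maf_range[2], length.out = max(n, 2))[seq_len(n)],
      stringsAsFactors = FALSE
    )
  })
  layout <- do.call(rbind, rows)
  layout$shift <- 0
  # ancestry-shifted subsets: deterministic (every other SNP up to the quota)
  bg <- which(layout$gene == "background")
  n_bg_shift <- round(config$background_shift_frac * length(bg))
  if (n_bg_shift > 0) layout$shift[bg[seq_len(n_bg_shift)]] <- config$ancestry_maf_shift
  in_gene <- which(layout$gene != "background")
  n_g_shift <- round(config$gene_shift_frac * length(in_gene))
  if (n_g_shift > 0) {
    pick <- in_gene[seq(1, length(in_gene), by = 2)][seq_len(min(n_g_shift, ceiling(length(in_gene) / 2)))]
    layout$shift[pick] <- config$ancestry_maf_shift / 2
  }
  # the perfect-LD twin shadows the planted partner SNP, which sits mid-gene
  # so the planted variants have representative (mid-range) frequencies
  layout$duplicate_of <- NA_character_
  if (isTRUE(config$duplicate_pair) && config$snps_partner >= 2) {
    g1 <- config$partner_genes[1]
    mid <- max(1, config$snps_partner %/% 2)
    twin <- if (mid < config$snps_partner) mid + 1 else mid - 1
    layout$duplicate_of[layout$snp_id == sprintf("%s_s%02d", g1, twin)] <-
      sprintf("%s_s%02d", g1, mid)
    # the twin copies its template exactly, frequency included
    layout$maf[layout$snp_id == sprintf("%s_s%02d", g1, twin)] <-
      layout$maf[layout$snp_id == sprintf("%s_s%02d", g1, mid)]
  }
  r2 <- seq(config$imputation_r2_range[1], config$imputation_r2_range[2],
            length.out = nrow(layout))
  layout$imputation_r2_target <- r2
  if (config$n_low_r2 > 0 && length(bg) >= config$n_low_r2) {
    layout$imputation_r2_target[bg[seq_len(config$n_low_r2)]] <- 0.25
  }
  layout
}

planted_pair_ids <- function(config) {
  c(index = sprintf("%s_s%02d", config$index_gene, max(1, config$snps_index %/% 2)),
    partner = sprintf("%s_s%02d", config$partner_genes[1],
                      max(1, config$snps_partner %/% 2)))
}

#' Simulate a haplotype pool with block LD
#'
#' Builds two population pools of binary haplotypes (0 = major, 1 = minor
#' allele).  Within each LD block, alleles are thresholded latent Gaussian
#' AR(1) variables with correlation `ld_rho^|i - j|`, so genotype correlation
#' decays with index distance inside a block and is zero across blocks.
#' Population B's allele frequencies are shifted by the layout's `shift`
#' column (ancestry structure); SNPs marked `duplicate_of` copy their
#' template column exactly (r2 = 1).
#'
#' @param n_haplotypes haplotypes per population pool (>= 2).
#' @param layout SNP layout (see [make_snp_layout()]); only snp_id, gene,
#'   maf, and optionally shift / duplicate_of are used.
#' @param ld_block_size SNPs per block within a gene (1 = independent SNPs).
#' @param ld_rho adjacent-SNP latent correlation within a block.
#' @param seed integer seed.
#' @return object of class `haplotype_pool`: `haplotypes` (list of two 0/1
#'   matrices, populations A and B), `block_assignments`, `target_mafs`,
#'   `layout`.
#' @export
simulate_haplotype_pool <- function(n_haplotypes, layout, ld_block_size = 4,
                                    ld_rho = 0.9, seed = 1) {
  if (!is_count(n_haplotypes) || n_haplotypes < 2) stop_config("n_haplotypes must be >= 2")
  if (!is_count(ld_block_size) || ld_block_size < 1) stop_config("ld_block_size must be >= 1")
  if (any(layout$maf <= 0 | layout$maf > 0.5)) stop_config("MAFs must lie in (0, 0.5]")
  m <- nrow(layout)
  # consecutive blocks within each gene
  block <- integer(m)
  nb <- 0L
  for (g in unique(layout$gene)) {
    i <- which(layout$gene == g)
    block[i] <- nb + ((seq_along(i) - 1L) %/% ld_block_size) + 1L
    nb <- max(block[i])
  }
  dup <- if ("duplicate_of" %in% colnames(layout)) layout$duplicate_of else rep(NA, m)
  shift <- if ("shift" %in% colnames(layout)) layout$shift else rep(0, m)

  draw_pool <- function(mafs) {
    H <- matrix(0L, n_haplotypes, m)
    for (b in unique(block)) {
      j <- which(block == b)
      k <- length(j)
      Z <- matrix(0, n_haplotypes, k)
      Z[, 1] <- rnorm(n_haplotypes)
      if (k > 1) {
        for (t in 2:k) {
          Z[, t] <- ld_rho * Z[, t - 1] + sqrt(1 - ld_rho^2) * rnorm(n_haplotypes)
        }
      }
      for (t in seq_len(k)) {
        H[, j[t]] <- as.integer(Z[, t] < qnorm(mafs[j[t]]))
      }
    }
    for (j in which(!is.na(dup))) {
      H[, j] <- H[, match(dup[j], layout$snp_id)]
    }
    colnames(H) <- layout$snp_id
    H
  }
  with_seed(seed, {
    HA <- draw_pool(layout$maf)
    HB <- draw_pool(pmin(pmax(layout$maf + shift, 0.01), 0.99))
    structure(list(haplotypes = list(A = HA, B = HB),
                   block_assignments = setNames(block, layout$snp_id),
                   target_mafs = setNames(layout$maf, layout$snp_id),
                   layout = layout),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("Haplotype pool: 2 x %d haplotypes, %d SNPs, %d LD block(s)\n",
              nrow(x$haplotypes$A), ncol(x$haplotypes$A),
              length(unique(x$block_assignments))))
  invisible(x)
}

#' Simulate integer genotype dosages from a haplotype pool
#'
#' Each sample is the sum of two haplotypes drawn independently (with
#' replacement) from the pool, giving dosages in `{0, 1, 2}` with no
#' missingness and Hardy-Weinberg genotype proportions at the pool allele
#' frequencies.  `pop_weight` gives each sample's probability of drawing each
#' haplotype from population B instead of A (`NULL` = all from A), which is
#' how ancestry admixture enters.
#'
#' @param pool a `haplotype_pool`.
#' @param n_samples number of samples (> 0).
#' @param seed integer seed.
#' @param pop_weight optional per-sample probability in `[0, 1]` of drawing
#'   from population B.
#' @return integer matrix (samples x SNPs) with SNP ids as colnames.
#' @export
simulate_genotypes <- function(pool, n_samples, seed = 1, pop_weight = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (!is_count(n_samples) || n_samples <= 0) stop_config("n_samples must be positive")
  nh <- nrow(pool$haplotypes$A)
  if (is.null(pop_weight)) pop_weight <- rep(0, n_samples)
  if (length(pop_weight) != n_samples || any(pop_weight < 0 | pop_weight > 1)) {
    stop_config("pop_weight must be n_samples probabilities in [0, 1]")
  }
  with_seed(seed, {
    D <- matrix(0L, n_samples, ncol(pool$haplotypes$A))
    for (copy in 1:2) {
      from_b <- runif(n_samples) < pop_weight
      idx <- sample.int(nh, n_samples, replace = TRUE)
      take_a <- which(!from_b)
      take_b <- which(from_b)
      if (length(take_a)) D[take_a, ] <- D[take_a, , drop = FALSE] + pool$haplotypes$A[idx[take_a], , drop = FALSE]
      if (length(take_b)) D[take_b, ] <- D[take_b, , drop = FALSE] + pool$haplotypes$B[idx[take_b], , drop = FALSE]
    }
    colnames(D) <- colnames(pool$haplotypes$A)
    D
  })
}

#' Add imputation-style dosage noise
#'
#' Perturbs integer dosages into the fractional dosages an imputation program
#' would output: per SNP, Gaussian noise is added and the result clipped to
#' `[0, 2]`, with the noise scale calibrated (against the realized, clipped
#' values) so that the squared correlation between noisy and true dosage hits
#' the target r2.  The *realized* squared correlation is recorded, since
#' downstream QC filters on the estimated quality, not the target.
#' Constant SNPs have no defined r2: they are flagged and recorded as 0.
#'
#' @param dosages samples x SNPs integer dosage matrix.
#' @param r2_targets per-SNP targets in `(0, 1]`, recycled if scalar; a
#'   target of 1 leaves the SNP untouched.
#' @param seed integer seed.
#' @return list: `dosages` (fractional, clipped), `imputation_r2` (named
#'   realized values), `flagged` (constant SNP ids).
#' @export
add_imputation_noise <- function(dosages, r2_targets, seed = 1) {
  m <- ncol(dosages)
  if (length(r2_targets) == 1) r2_targets <- rep(r2_targets, m)
  if (length(r2_targets) != m) stop_config("need one r2 target per SNP")
  if (any(r2_targets <= 0 | r2_targets > 1)) stop_config("r2 targets must lie in (0, 1]")
  out <- dosages * 1.0
  realized <- setNames(rep(NA_real_, m), colnames(dosages))
  flagged <- character(0)
  with_seed(seed, {
    for (j in seq_len(m)) {
      d <- dosages[, j]
      v <- var(d)
      if (is.na(v) || v == 0) {
        flagged <- c(flagged, colnames(dosages)[j])
        realized[j] <- 0
        next
      }
      if (r2_targets[j] == 1) {
        realized[j] <- 1
        next
      }
      sd0 <- sqrt(v * (1 - r2_targets[j]) / r2_targets[j])
      e <- rnorm(length(d))
      obj <- function(s) {
        noisy <- pmin(pmax(d + s * sd0 * e, 0), 2)
        cor(noisy, d)^2 - r2_targets[j]
      }
      # clipping pushes the realized r2 above target at the nominal scale, so
      # expand the bracket upward until the root is enclosed
      hi <- 1
      while (obj(hi) > 0 && hi < 64) hi <- hi * 2
      s <- if (obj(hi) > 0) hi else uniroot(obj, c(0, hi), tol = 1e-4)$root
      noisy <- pmin(pmax(d + s * sd0 * e, 0), 2)
      out[, j] <- noisy
      realized[j] <- cor(noisy, d)^2
    }
  })
  list(dosages = out, imputation_r2 = realized, flagged = flagged)
}

#' Simulate case-control status under the logistic interaction model
#'
#' Case probability for sample i is
#' `logistic(b0 + b1 dA + b2 dB + b3 dA dB + site offset + a' ancestry_effect)`
#' where `dA`, `dB` are the planted pair's dosages.  Site labels and the two
#' latent ancestry coordinates are drawn here unless supplied via
#' `sample_info` (as [simulate_study()] does, because the same coordinates
#' must also drive the genotype frequencies).
#'
#' @param dosages samples x SNPs dosage matrix containing the planted SNPs.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param sample_info optional data frame with columns site (integer),
#'   ancestry1, ancestry2.
#' @return sample table data frame: sample_id, status, site, ancestry1,
#'   ancestry2.
#' @export
simulate_phenotypes <- function(dosages, config, seed = 1, sample_info = NULL) {
  pp <- planted_pair_ids(config)
  if (!all(pp %in% colnames(dosages))) {
    stop_config("planted SNP(s) %s missing from dosage matrix",
                paste(setdiff(pp, colnames(dosages)), collapse = ", "))
  }
  n <- nrow(dosages)
  with_seed(seed, {
    if (is.null(sample_info)) {
      site <- sample.int(config$site_count, n, replace = TRUE)
      a1 <- runif(n, -1, 1) + config$site_ancestry_shift * (site - (config$site_count + 1) / 2)
      a2 <- runif(n, -1, 1)
    } else {
      site <- sample_info$site
      a1 <- sample_info$ancestry1
      a2 <- sample_info$ancestry2
    }
    dA <- dosages[, pp["index"]]
    dB <- dosages[, pp["partner"]]
    eta <- config$beta0 + config$beta1 * dA + config$beta2 * dB +
      config$beta3 * dA * dB + config$site_effects[site] +
      config$ancestry_effect[1] * a1 + config$ancestry_effect[2] * a2
    y <- rbinom(n, 1, plogis(eta))
    ids <- rownames(dosages)
    if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
    data.frame(sample_id = ids, status = as.integer(y),
               site = paste0("site", site),
               ancestry1 = a1, ancestry2 = a2, stringsAsFactors = FALSE)
  })
}

# One population batch: genotypes with ancestry admixture plus phenotypes.
simulate_batch <- function(pool, config, n, seed) {
  with_seed(derive_seed(seed, 1), {
    site <- sample.int(config$site_count, n, replace = TRUE)
    a1 <- runif(n, -1, 1) + config$site_ancestry_shift * (site - (config$site_count + 1) / 2)
    a2 <- runif(n, -1, 1)
  })
  w <- pmin(pmax((a1 + 1) / 2, 0), 1)  # pop-B weight, linear in ancestry1
  D <- simulate_genotypes(pool, n, seed = derive_seed(seed, 2), pop_weight = w)
  info <- data.frame(site = site, ancestry1 = a1, ancestry2 = a2)
  samp <- simulate_phenotypes(D, config, seed = derive_seed(seed, 3),
                              sample_info = info)
  list(dosages = D, samples = samp)
}

# Retrospective ascertainment: simulate population batches, keep the first
# n_cases cases and n_controls controls encountered.
simulate_cohort <- function(pool, config, n_cases, n_controls, seed, id_prefix) {
  need <- n_cases + n_controls
  got_case <- NULL; got_ctl <- NULL
  info_case <- NULL; info_ctl <- NULL
  for (batch in seq_len(60)) {
    bs <- ceiling(1.5 * need)
    b <- simulate_batch(pool, config, bs, derive_seed(seed, 100 + batch))
    is_case <- b$samples$status == 1L
    got_case <- rbind(got_case, b$dosages[is_case, , drop = FALSE])
    info_case <- rbind(info_case, b$samples[is_case, , drop = FALSE])
    got_ctl <- rbind(got_ctl, b$dosages[!is_case, , drop = FALSE])
    info_ctl <- rbind(info_ctl, b$samples[!is_case, , drop = FALSE])
    if (nrow(got_case) >= n_cases && nrow(got_ctl) >= n_controls) break
  }
  if (nrow(got_case) < n_cases || nrow(got_ctl) < n_controls) {
    stop_config("could not ascertain %d cases / %d controls; check beta0", n_cases, n_controls)
  }
  D <- rbind(got_case[seq_len(n_cases), , drop = FALSE],
             got_ctl[seq_len(n_controls), , drop = FALSE])
  samp <- rbind(info_case[seq_len(n_cases), , drop = FALSE],
                info_ctl[seq_len(n_controls), , drop = FALSE])
  ids <- sprintf("%s%05d", id_prefix, seq_len(nrow(D)))
  rownames(D) <- ids
  samp$sample_id <- ids
  rownames(samp) <- NULL

  noise <- add_imputation_noise(D, pool$layout$imputation_r2_target,
                                seed = derive_seed(seed, 7))
  # perfect-LD twins share their template's imputed dosages exactly, so the
  # r2 = 1 pair survives into the fractional data (as in real imputed panels
  # where both members are imputed from the same haplotype background)
  dup <- pool$layout$duplicate_of
  for (j in which(!is.na(dup))) {
    noise$dosages[, pool$layout$snp_id[j]] <- noise$dosages[, dup[j]]
    noise$imputation_r2[pool$layout$snp_id[j]] <- noise$imputation_r2[dup[j]]
  }
  skel <- data.frame(snp_id = pool$layout$snp_id, chrom = pool$layout$chrom,
                     pos = pool$layout$pos, minor = "B", major = "A",
                     imputation_r2 = unname(noise$imputation_r2),
                     stringsAsFactors = FALSE)
  snps <- compute_snp_stats(noise$dosages, samp, skel)
  list(dosages = noise$dosages, samples = samp, snps = snps)
}

#' Simulate a two-cohort interaction study
#'
#' Draws a discovery and an independent replication cohort from the same
#' generative process (shared haplotype pools and planted effect, independent
#' samples and noise), each ascertained retrospectively to the requested
#' case/control counts.  The returned bundle carries the full truth record.
#'
#' @param config a [sim_config()].
#' @param seed master seed (default: the one stored in `config`); child seeds
#'   for the pool, batches, phenotypes and noise are derived from it by fixed
#'   offsets and recorded in `truth$seeds`.
#' @return object of class `cohort_bundle`: `discovery` and `replication`
#'   (each a list `dosages`, `samples`, `snps`) and `truth` (config, layout,
#'   planted pair, seeds).
#' @export
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  layout <- make_snp_layout(config)
  pool <- simulate_haplotype_pool(config$n_haplotypes, layout,
                                  config$ld_block_size, config$ld_rho,
                                  seed = derive_seed(seed, 11))
  disc <- simulate_cohort(pool, config, config$n_cases, config$n_controls,
                          derive_seed(seed, 20), "D")
  repl <- simulate_cohort(pool, config, config$n_replication_cases,
                          config$n_replication_controls,
                          derive_seed(seed, 30), "R")
  truth <- list(config = config, layout = layout,
                planted_pair = planted_pair_ids(config),
                master_seed = seed,
                seeds = c(pool = derive_seed(seed, 11),
                          discovery = derive_seed(seed, 20),
                          replication = derive_seed(seed, 30)))
  structure(list(discovery = disc, replication = repl, truth = truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Simulated study: discovery %d samples, replication %d samples, %d SNPs\n",
              nrow(x$discovery$dosages), nrow(x$replication$dosages),
              ncol(x$discovery$dosages)))
  cat(sprintf("  planted pair: %s x %s (beta3 = %.3f), master seed %d\n",
              x$truth$planted_pair["index"], x$truth$planted_pair["partner"],
              x$truth$config$beta3, x$truth$master_seed))
  invisible(x)
}

#' Gene regions implied by a simulated layout
#'
#' One 0-based half-open interval per gene (background excluded), covering
#' the gene's SNPs; the stand-in for a transcript-union BED in synthetic
#' studies.
#'
#' @param layout SNP layout.
#' @return gene-region data frame (gene, chrom, start, end).
#' @export
layout_gene_regions <- function(layout) {
  genes <- setdiff(unique(layout$gene), "background")
  rows <- lapply(genes, function(g) {
    i <- layout$gene == g
    data.frame(gene = g, chrom = layout$chrom[i][1],
               start = min(layout$pos[i]) - 1L, end = max(layout$pos[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / reload a simulated study
#'
#' Writes each cohort in the pipeline's exchange formats (dosage TSV +
#' companion SNP TSV, sample TSV), the gene-region BED, a synthetic
#' candidate-gene TSV (every partner gene at confidence 0.9), the SNP layout,
#' and the truth record as YAML.  `read_study()` reloads the lot.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study <- function(bundle, dir) {
  for (cohort in c("discovery", "replication")) {
    cd <- file.path(dir, cohort)
    dir.create(cd, recursive = TRUE, showWarnings = FALSE)
    co <- bundle[[cohort]]
    write_dosages(co$dosages, co$snps, file.path(cd, "cohort"))
    write_samples(co$samples, file.path(cd, "samples.tsv"))
  }
  regions <- layout_gene_regions(bundle$truth$layout)
  write_gene_regions(regions, file.path(dir, "genes.bed"))
  cand <- data.frame(gene = bundle$truth$config$partner_genes,
                     chrom = bundle$truth$config$partner_chroms,
                     score = 0.9, stringsAsFactors = FALSE)
  write.table(cand, file.path(dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$layout, file.path(dir, "layout.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$layout <- NULL
  truth$config <- unclass(truth$config)
  truth$planted_pair <- as.list(truth$planted_pair)  # keep names in YAML
  truth$seeds <- as.list(truth$seeds)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  read_cohort <- function(cd) {
    d <- read_dosages(file.path(cd, "cohort.dosages.tsv"), format = "tsv")
    samples <- read_samples(file.path(cd, "samples.tsv"))
    list(dosages = d$dosages, samples = samples,
         snps = compute_snp_stats(d$dosages, samples, d$snps))
  }
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  truth$config <- do.call(sim_config, truth$config[names(formals(sim_config))[
    names(formals(sim_config)) %in% names(truth$config)]])
  truth$layout <- read.table(file.path(dir, "layout.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  truth$planted_pair <- unlist(truth$planted_pair)
  structure(list(discovery = read_cohort(file.path(dir, "discovery")),
                 replication = read_cohort(file.path(dir, "replication")),
                 truth = truth),
            class = "cohort_bundle")
}
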