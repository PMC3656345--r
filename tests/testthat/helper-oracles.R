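# Independent oracles used across the suite.  These deliberately avoid the
# package's IRLS / recurrence code paths.

# Brute-force maximum-likelihood logistic fit via quasi-Newton on the
# (stable) negative log-likelihood with analytic gradient.
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta)))) - sum(y * eta)
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    drop(crossprod(X, mu - y))
  }
  o <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-16))
  o2 <- optim(o$par, nll, gr, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-16))
  list(beta = o2$par, loglik = -o2$value)
}

# Exact Hardy-Weinberg test by direct enumeration: the conditional
# probability of each admissible heterozygote count given the allele counts,
# from the closed-form expression with log-factorials.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_AA + n_Aa   # one allele's count
  n_b <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, n_b)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# Small deterministic dosage fixture: n samples, the named SNPs as columns.
toy_dosages <- function(n, snp_mafs, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  d <- withr_seed(
    vapply(snp_mafs, function(m) rbinom(n, 2, m), numeric(n))
  )
  rownames(d) <- sprintf("S%03d", seq_len(n))
  d
}

toy_samples <- function(dosages, case_fraction = 0.5, seed = 2, site = "s1") {
  n <- nrow(dosages)
  set.seed(seed)
  data.frame(sample_id = rownames(dosages),
             status = as.integer(runif(n) < case_fraction),
             site = site, stringsAsFactors = FALSE)
}

# A small simulated study shared by several files (built fresh per call).
small_config <- function(...) {
  sim_config(n_cases = 150, n_controls = 150,
             n_replication_cases = 120, n_replication_controls = 120,
             snps_index = 6, snps_partner = 4,
             partner_genes = c("GENEB", "GENEC"), partner_chroms = c("20", "14"),
             n_background = 40, n_haplotypes = 500, n_low_r2 = 1, ...)
}
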