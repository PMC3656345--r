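## Ancestry principal components in the Eigenstrat normalization, and the
## covariate matrix (study-site indicators + leading PCs) shared by all
## interaction regressions.

#' Ancestry principal components (Eigenstrat normalization)
#'
#' Standardizes each SNP column by centering at `2 * p_hat` and scaling by
#' `sqrt(p_hat * (1 - p_hat))`, where `p_hat` is by default the shrunk allele
#' frequency estimate `(1 + sum d) / (2 + 2n)`; missing dosages are
#' mean-imputed per SNP before the decomposition.  The top `k` eigenvectors of
#' the resulting sample-sample covariance are returned as ancestry
#' coordinates.  Constant SNPs carry no information and are skipped with a
#' warning.
#'
#' @param dosages samples x SNPs dosage matrix (post-QC).
#' @param k number of components (default 2).
#' @param shrink use the shrunk allele-frequency estimator (default); set
#'   `FALSE` for the plain MLE `mean(d) / 2`.
#' @param ld_prune optional list `(window, step, r2)` for greedy LD pruning of
#'   the SNP set before the decomposition; `NULL` (default) disables pruning.
#' @return object of class `pc_result`: `coordinates` (samples x k,
#'   unit-norm columns), `eigenvalues` (non-increasing), `snps_used`.
#' @export
eigenstrat_pca <- function(dosages, k = 2, shrink = TRUE, ld_prune = NULL) {
  assert_dosage_matrix(dosages)
  n <- nrow(dosages)
  if (n < k + 1) stop_config("need at least k + 1 = %d samples", k + 1)

  use <- colnames(dosages)
  if (!is.null(ld_prune)) use <- ld_prune_snps(dosages, ld_prune)
  d <- dosages[, use, drop = FALSE]

  const <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || all(x == x[1])
  })
  if (any(const)) {
    warning(sprintf("skipping %d constant SNP(s) in PCA", sum(const)))
    d <- d[, !const, drop = FALSE]
  }
  if (ncol(d) == 0) stop_config("no variable SNPs available for PCA")

  nn <- colSums(!is.na(d))
  sums <- colSums(d, na.rm = TRUE)
  p_hat <- if (shrink) (1 + sums) / (2 + 2 * nn) else sums / (2 * nn)
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) {          # mean-impute, then standardize
    x <- d[, j]
    x[is.na(x)] <- mu[j]
    d[, j] <- (x - 2 * p_hat[j]) / sqrt(p_hat[j] * (1 - p_hat[j]))
  }

  grm <- tcrossprod(d) / ncol(d)
  ev <- eigen(grm, symmetric = TRUE)
  rank <- sum(ev$values > max(ev$values) * 1e-10)
  if (k > rank) stop_config("k = %d exceeds the rank (%d) of the genotype matrix", k, rank)

  coords <- ev$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(dosages)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = ev$values[seq_len(k)],
                 snps_used = colnames(d)),
            class = "pc_result")
}

# greedy window-based LD pruning on dosage correlation
ld_prune_snps <- function(dosages, ld_prune) {
  window <- ld_prune$window %||% 50
  step <- ld_prune$step %||% 5
  r2max <- ld_prune$r2 %||% 0.2
  ids <- colnames(dosages)
  keep <- rep(TRUE, length(ids))
  start <- 1
  while (start <= length(ids)) {
    idx <- seq(start, min(start + window - 1, length(ids)))
    idx <- idx[keep[idx]]
    if (length(idx) > 1) {
      cc <- suppressWarnings(cor(dosages[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      cc[!is.finite(cc)] <- 0
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        drop <- which(cc[a, ] > r2max & seq_along(idx) > a & keep[idx])
        keep[idx[drop]] <- FALSE
      }
    }
    start <- start + step
  }
  ids[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("Ancestry PCA: %d samples, %d SNPs, %d component(s)\n",
              nrow(x$coordinates), length(x$snps_used), ncol(x$coordinates)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Build the regression covariate matrix
#'
#' Assembles the per-sample adjustment columns used by every interaction
#' model: reference-coded study-site indicators (the first site is the
#' reference, so a single-site cohort contributes no site columns) followed by
#' the first `k` ancestry PCs.  Rows are aligned to the sample-table order.
#'
#' @param samples sample table (sample_id, status, site).
#' @param pcs `pc_result` from [eigenstrat_pca()], or `NULL` for no PC
#'   adjustment.
#' @param k number of PC columns to include (default 2).
#' @return numeric matrix (samples x columns) with rownames = sample ids.
#' @export
build_covariates <- function(samples, pcs = NULL, k = 2) {
  sites <- sort(unique(samples$site))
  cols <- list()
  if (length(sites) > 1) {
    for (s in sites[-1]) {
      cols[[paste0("site", s)]] <- as.numeric(samples$site == s)
    }
  }
  if (!is.null(pcs) && k > 0) {
    if (k > ncol(pcs$coordinates)) stop_config("k = %d PCs requested but only %d available",
                                               k, ncol(pcs$coordinates))
    if (!all(samples$sample_id %in% rownames(pcs$coordinates))) {
      stop_config("PC result is missing some samples")
    }
    pc <- pcs$coordinates[match(samples$sample_id, rownames(pcs$coordinates)),
                          seq_len(k), drop = FALSE]
    for (j in seq_len(k)) cols[[colnames(pc)[j]]] <- pc[, j]
  }
  out <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(samples), ncol = 0)
  rownames(out) <- samples$sample_id
  out
}
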