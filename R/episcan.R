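## The interaction scan: maximum-likelihood logistic regression (IRLS, C++
## backend), the single-pair dosage-interaction Wald test, and the exhaustive
## scan of all SNP pairs between the index gene and one partner gene.

STATUS_LEVELS <- c("OK", "NON_CONVERGED", "COLLINEAR")

status_label <- function(code) STATUS_LEVELS[code + 1L]

#' Maximum-likelihood logistic regression
#'
#' Fits `P(y = 1 | x) = logistic(x' beta)` by iteratively reweighted least
#' squares (Newton steps with step-halving).  Convergence is declared when the
#' maximum absolute score falls below `tol_score` or the relative
#' log-likelihood change falls below `tol_ll`; standard errors come from the
#' inverse observed information at the optimum.  A coefficient escaping
#' `beta_bound` in absolute value, or failure to converge within `maxit`
#' iterations, marks the fit `NON_CONVERGED` (the usual symptom of complete
#' or quasi-complete separation); a rank-deficient design is `COLLINEAR`.
#'
#' @param y binary 0/1 outcome vector (both classes must be present).
#' @param X design matrix including the intercept column.
#' @param maxit maximum Newton iterations.
#' @param tol_score,tol_ll convergence tolerances.
#' @param beta_bound divergence bound on |beta| (dosage scale).
#' @param start optional starting coefficient vector.
#' @return object of class `logistic_fit`: coefficients, se, vcov, loglik,
#'   converged, n_iterations, status, n.
#' @examples
#' set.seed(1)
#' X <- cbind(1, rnorm(200))
#' y <- rbinom(200, 1, plogis(X %*% c(-0.3, 0.8)))
#' fit <- fit_logistic(y, X)
#' coef(fit)
#' @export
fit_logistic <- function(y, X, maxit = 50, tol_score = 1e-8, tol_ll = 1e-10,
                         beta_bound = 15, start = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_config("length(y) != nrow(X)")
  if (anyNA(y) || anyNA(X)) stop_config("fit_logistic does not accept missing values")
  if (!all(y %in% c(0, 1))) stop_config("y must be binary 0/1")
  if (all(y == 0) || all(y == 1)) stop_config("outcome has a single class")

  f <- cpp_logistic_fit(X, y, maxit, tol_score, tol_ll, beta_bound, start)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("b", seq_len(ncol(X)) - 1L)
  beta <- setNames(as.numeric(f$coefficients), nms)
  se <- setNames(as.numeric(f$se), nms)
  vc <- f$vcov
  dimnames(vc) <- list(nms, nms)
  structure(list(coefficients = beta, se = se, vcov = vc,
                 loglik = f$loglik, converged = f$status == 0L,
                 n_iterations = f$iterations,
                 status = status_label(f$status),
                 n = length(y), X = X, y = y),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' @export
residuals.logistic_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  mu <- predict(object)
  if (type == "response") return(object$y - mu)
  sign(object$y - mu) * sqrt(-2 * (object$y * log(mu) + (1 - object$y) * log1p(-mu)))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s): n = %d, logLik = %.4f, %d iteration(s)\n",
              x$status, x$n, x$loglik, x$n_iterations))
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(table = tab, status = object$status,
                 loglik = object$loglik, n = object$n),
            class = "summary.logistic_fit")
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s), n = %d, logLik = %.4f\n", x$status, x$n, x$loglik))
  printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Dosage-interaction Wald test for one SNP pair
#'
#' Fits `logit P(case) = b0 + b1 dA + b2 dB + b3 dA*dB + gamma' covariates`
#' and tests `b3 = 0` with the two-sided Wald statistic `z = b3 / se(b3)`,
#' `p = 2 (1 - Phi(|z|))`.  Samples with a missing value in either dosage, any
#' covariate, or the outcome are dropped (pairwise complete case).
#'
#' @param dos_a,dos_b dosage vectors for the two SNPs.
#' @param covariates numeric matrix of adjustment columns (may have 0 columns).
#' @param y binary outcome vector.
#' @param snp_a,snp_b SNP identifiers for the result record.
#' @return object of class `interaction_result`: snp_a, snp_b, beta3, se3,
#'   wald_z, p (NA unless status is OK), status, n.
#' @export
interaction_test <- function(dos_a, dos_b, covariates = NULL, y,
                             snp_a = "snp_a", snp_b = "snp_b") {
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  if (length(dos_a) != n || length(dos_b) != n || nrow(covariates) != n) {
    stop_config("dosages, covariates and outcome must have equal length")
  }
  keep <- !is.na(dos_a) & !is.na(dos_b) & !is.na(y) & complete.cases(covariates)
  dA <- dos_a[keep]; dB <- dos_b[keep]; yy <- y[keep]
  C <- covariates[keep, , drop = FALSE]
  if (length(unique(yy)) < 2) stop_config("single outcome class after missing-data drop")

  X <- cbind(`(Intercept)` = 1, dos_a = dA, dos_b = dB, interaction = dA * dB, C)
  f <- cpp_logistic_fit(X, as.numeric(yy))
  st <- status_label(f$status)
  if (st == "OK") {
    b3 <- f$coefficients[4]; s3 <- f$se[4]
    z <- b3 / s3
    p <- 2 * pnorm(-abs(z))
  } else {
    b3 <- s3 <- z <- p <- NA_real_
  }
  structure(list(snp_a = snp_a, snp_b = snp_b, beta3 = b3, se3 = s3,
                 wald_z = z, p = p, status = st, n = sum(keep)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  if (x$status == "OK") {
    cat(sprintf("%s x %s: beta3 = %.4f (se %.4f), z = %.3f, p = %.3g [n = %d]\n",
                x$snp_a, x$snp_b, x$beta3, x$se3, x$wald_z, x$p, x$n))
  } else {
    cat(sprintf("%s x %s: %s [n = %d]\n", x$snp_a, x$snp_b, x$status, x$n))
  }
  invisible(x)
}

#' Scan all SNP pairs between the index gene and one partner gene
#'
#' Runs [interaction_test()] for every (index SNP, partner SNP) combination,
#' in deterministic order (index SNPs outer, partner SNPs inner, both in the
#' order given, which callers should make positional).  Pairs whose four
#' SNP design columns are rank-deficient (e.g. the same SNP, or two SNPs in
#' perfect LD) are reported `COLLINEAR`; non-converged fits are reported
#' `NON_CONVERGED`; neither contributes to the gene minimum p.
#'
#' @param dosages samples x SNPs dosage matrix.
#' @param snps_index,snps_partner SNP id vectors for the two genes (non-empty,
#'   present in `dosages`).
#' @param covariates adjustment matrix aligned to `dosages` rows.
#' @param y binary outcome aligned to `dosages` rows.
#' @param gene_a,gene_b gene labels for the report.
#' @return object of class `gene_pair_scan`: `gene_a`, `gene_b`, `results`
#'   (data frame: snp_a, snp_b, beta3, se3, wald_z, p, status, n), `min_p`,
#'   `best_pairs`, `n_skipped`.
#' @export
scan_gene_pair <- function(dosages, snps_index, snps_partner, covariates = NULL,
                           y, gene_a = "index", gene_b = "partner") {
  assert_dosage_matrix(dosages)
  if (length(snps_index) == 0) stop_config("no SNPs for index gene %s", gene_a)
  if (length(snps_partner) == 0) stop_config("no SNPs for partner gene %s", gene_b)
  miss <- setdiff(c(snps_index, snps_partner), colnames(dosages))
  if (length(miss)) stop_config("SNPs absent from dosage matrix: %s",
                                paste(head(miss, 5), collapse = ", "))
  n <- nrow(dosages)
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  keep <- !is.na(y) & complete.cases(covariates)
  DA <- dosages[keep, snps_index, drop = FALSE]
  DB <- dosages[keep, snps_partner, drop = FALSE]
  C <- covariates[keep, , drop = FALSE]
  yy <- as.numeric(y[keep])
  if (length(unique(yy)) < 2) stop_config("single outcome class in scan")

  m <- cpp_scan_pairs(DA, DB, C, yy)
  res <- data.frame(
    snp_a = rep(snps_index, each = length(snps_partner)),
    snp_b = rep(snps_partner, times = length(snps_index)),
    beta3 = m[, "beta3"], se3 = m[, "se3"], wald_z = m[, "z"],
    p = ifelse(m[, "status"] == 0, 2 * pnorm(-abs(m[, "z"])), NA_real_),
    status = status_label(as.integer(m[, "status"])),
    n = as.integer(m[, "n"]),
    stringsAsFactors = FALSE
  )
  ok <- res$status == "OK"
  min_p <- if (any(ok)) min(res$p[ok]) else NA_real_
  best <- if (any(ok)) res[ok & res$p <= min_p, c("snp_a", "snp_b"), drop = FALSE] else
    res[0, c("snp_a", "snp_b")]
  structure(list(gene_a = gene_a, gene_b = gene_b, results = res,
                 min_p = min_p, best_pairs = best,
                 n_skipped = sum(!ok)),
            class = "gene_pair_scan")
}

#' @export
print.gene_pair_scan <- function(x, ...) {
  cat(sprintf("Interaction scan %s x %s: %d pairs (%d skipped), min p = %s\n",
              x$gene_a, x$gene_b, nrow(x$results), x$n_skipped,
              format(x$min_p, digits = 4)))
  invisible(x)
}

#' @export
summary.gene_pair_scan <- function(object, n_top = 5, ...) {
  res <- object$results
  ok <- res[res$status == "OK", , drop = FALSE]
  ok <- ok[order(ok$p), , drop = FALSE]
  cat(sprintf("Scan %s x %s: %d tests OK, %d skipped\n", object$gene_a,
              object$gene_b, nrow(ok), object$n_skipped))
  print(head(ok, n_top), row.names = FALSE)
  invisible(object)
}

#' Gene-level minimum p-value
#'
#' The smallest two-sided interaction p over the converged (`OK`) pairs of a
#' scan, with all pairs attaining it (exact ties included) in deterministic
#' scan order.
#'
#' @param scan a `gene_pair_scan`.
#' @return list with `min_p`, `best_pairs`, `untestable` (TRUE when the scan
#'   produced no OK result, with a warning).
#' @export
gene_min_p <- function(scan) {
  stopifnot(inherits(scan, "gene_pair_scan"))
  res <- scan$results
  ok <- res$status == "OK"
  if (!any(ok)) {
    warning(sprintf("gene %s has no testable pair", scan$gene_b))
    return(list(min_p = NA_real_, best_pairs = res[0, c("snp_a", "snp_b")],
                untestable = TRUE))
  }
  mp <- min(res$p[ok])
  list(min_p = mp,
       best_pairs = res[ok & res$p <= mp, c("snp_a", "snp_b"), drop = FALSE],
       untestable = FALSE)
}
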