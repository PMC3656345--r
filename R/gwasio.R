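## Readers and writers for the pipeline's exchange formats:
##   - dosage matrices: VCF v4.2 with a per-genotype DS FORMAT field, or a
##     dosage-TSV dialect (header `snp_id<TAB>sample...`, one row per SNP,
##     missing = ".") with a companion SNP-metadata TSV
##   - sample tables (TSV: sample_id, status, site, optional PCs)
##   - gene regions (BED, 0-based half-open, gene symbol in column 4)
##   - candidate-gene tables (TSV: gene, chrom, score)
## All positions in SNP tables are 1-based (VCF convention); BED coordinates
## are converted in exactly one place (read_gene_regions / write_gene_regions).

#' Read a genotype-dosage matrix
#'
#' Reads fractional allelic dosages from a VCF with a per-genotype `DS` FORMAT
#' field (falling back to hard `GT` genotypes when `DS` is absent) or from the
#' package's dosage-TSV dialect.  After reading, orientation is normalized so
#' that every dosage counts the dataset-minor allele: any SNP whose stored
#' allele has frequency > 0.5 is flipped (`d -> 2 - d`, alleles swapped) and
#' the flip is recorded in the returned SNP table.
#'
#' @param path path to the VCF or dosage TSV.
#' @param format `"vcf"` or `"tsv"`.
#' @param snp_meta for `format = "tsv"`, path to the companion SNP-metadata
#'   TSV (columns snp_id, chrom, pos, minor, major, imputation_r2); defaults
#'   to `<path minus .dosages.tsv>.snps.tsv`.
#' @param r2_key INFO key holding per-SNP imputation quality in a VCF.
#' @return a list with `dosages` (samples x SNPs numeric matrix, `NA` for
#'   missing) and `snps` (a SNP-table skeleton data frame with snp_id, chrom,
#'   pos, minor, major, imputation_r2, flipped).
#' @seealso [write_dosages()], [compute_snp_stats()]
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"), snp_meta = NULL,
                         r2_key = "R2") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("no such file: %s", path)
  parsed <- if (format == "vcf") read_dosages_vcf(path, r2_key) else {
    if (is.null(snp_meta)) snp_meta <- sub("\\.dosages\\.tsv$", ".snps.tsv", path)
    read_dosages_tsv(path, snp_meta)
  }
  normalize_minor_allele(parsed$dosages, parsed$snps)
}

read_dosages_vcf <- function(path, r2_key) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop_config("multi-allelic VCF records are not supported (line with ALT: %s)",
                alt[grepl(",", alt, fixed = TRUE)][1])
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(g) {
      g <- gsub("|", "/", g, fixed = TRUE)
      vapply(strsplit(g, "/", fixed = TRUE), function(a) {
        if (length(a) == 0 || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@gt), dimnames = dimnames(gt))
  }
  bad <- which(!is.na(ds) & (ds < 0 | ds > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_config("dosage outside [0,2] at SNP %s", rownames(ds)[bad[1, 1]])
  }
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = r2_key)))
  snps <- data.frame(
    snp_id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    minor = alt,          # dosage counts ALT copies before normalization
    major = fix[, "REF"],
    imputation_r2 = if (length(r2) == nrow(fix)) r2 else NA_real_,
    stringsAsFactors = FALSE
  )
  list(dosages = t(ds), snps = snps)
}

read_dosages_tsv <- function(path, snp_meta) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = ".", stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "snp_id") {
    stop_config("dosage TSV must start with an `snp_id` column (line 1)")
  }
  d <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(d)) stop_config("non-numeric dosage value in %s", path)
  rownames(d) <- tab$snp_id
  snps <- NULL
  if (!is.null(snp_meta) && file.exists(snp_meta)) {
    snps <- read.table(snp_meta, header = TRUE, sep = "\t",
                       colClasses = c(snp_id = "character", chrom = "character",
                                      minor = "character", major = "character"),
                       stringsAsFactors = FALSE)
    snps <- snps[match(tab$snp_id, snps$snp_id), , drop = FALSE]
  } else {
    snps <- data.frame(snp_id = tab$snp_id, chrom = NA_character_,
                       pos = NA_integer_, minor = NA_character_,
                       major = NA_character_, imputation_r2 = NA_real_,
                       stringsAsFactors = FALSE)
  }
  if (any(!is.na(d) & (d < 0 | d > 2))) {
    stop_config("dosage outside [0,2] in %s", path)
  }
  list(dosages = t(d), snps = snps)
}

# Flip any SNP whose counted allele is actually the major allele, so that
# downstream effects are always on the minor-allele scale.
normalize_minor_allele <- function(dosages, snps) {
  assert_dosage_matrix(dosages)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    swap <- snps$minor[flip]
    snps$minor[flip] <- snps$major[flip]
    snps$major[flip] <- swap
  }
  snps$flipped <- as.logical(flip[match(snps$snp_id, colnames(dosages))])
  list(dosages = dosages, snps = snps)
}

#' Write a dosage matrix in the dosage-TSV dialect
#'
#' Writes `<stem>.dosages.tsv` (header `snp_id<TAB>sample...`, one row per
#' SNP, missing values as `.`) and the companion `<stem>.snps.tsv`.
#'
#' @param dosages samples x SNPs numeric matrix.
#' @param snps SNP table with at least snp_id, chrom, pos, minor, major,
#'   imputation_r2 (missing columns are filled with `NA`).
#' @param stem output path stem.
#' @param digits decimal digits for dosages.
#' @return invisibly, the two file paths.
#' @export
write_dosages <- function(dosages, snps, stem, digits = 6) {
  assert_dosage_matrix(dosages)
  d <- t(dosages)  # rows = SNPs
  txt <- formatC(round(d, digits), format = "fg", digits = digits)
  txt[is.na(d)] <- "."
  out <- data.frame(snp_id = rownames(d), txt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("snp_id", rownames(dosages))
  f_dos <- paste0(stem, ".dosages.tsv")
  write.table(out, f_dos, sep = "\t", quote = FALSE, row.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "minor", "major", "imputation_r2")
  for (cl in setdiff(need, colnames(snps))) snps[[cl]] <- NA
  meta <- snps[match(rownames(d), snps$snp_id), need, drop = FALSE]
  f_meta <- paste0(stem, ".snps.tsv")
  write.table(meta, f_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosages = f_dos, snps = f_meta))
}

#' Write a dosage matrix as a VCF with DS genotypes
#'
#' Minimal single-allelic VCF v4.2 writer used for interoperability and
#' round-trip testing against the VCF reader.
#'
#' @inheritParams write_dosages
#' @param path output path (plain text, not bgzipped).
#' @param r2_key INFO key for per-SNP imputation quality.
#' @return invisibly, `path`.
#' @export
write_dosages_vcf <- function(dosages, snps, path, r2_key = "R2", digits = 6) {
  assert_dosage_matrix(dosages)
  snps <- snps[match(colnames(dosages), snps$snp_id), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation r-squared\">", r2_key),
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dosages)), function(j) {
    ds <- dosages[, j]
    dtxt <- formatC(round(ds, digits), format = "fg", digits = digits)
    dtxt[is.na(ds)] <- "."
    info <- if (is.na(snps$imputation_r2[j])) "." else
      sprintf("%s=%s", r2_key, formatC(snps$imputation_r2[j], format = "fg", digits = 6))
    paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j], snps$major[j],
            snps$minor[j], ".", "PASS", info, "DS", dtxt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write a sample table
#'
#' TSV with columns sample_id, status (1 = case, 0 = control), site, and any
#' optional extra columns (ancestry coordinates, PCs).
#'
#' @param path TSV path.
#' @return a data frame with sample_id, status (integer 0/1), site.
#' @export
read_samples <- function(path) {
  s <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "status", "site")
  if (!all(need %in% colnames(s))) {
    stop_config("sample TSV must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(s$sample_id)) stop_config("duplicate sample ids in %s", path)
  if (!all(s$status %in% c(0L, 1L))) stop_config("status must be 0/1 in %s", path)
  s$sample_id <- as.character(s$sample_id)
  s$status <- as.integer(s$status)
  s$site <- as.character(s$site)
  s
}

#' @rdname read_samples
#' @param samples sample table to write.
#' @export
write_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write gene regions (BED)
#'
#' BED is 0-based half-open; the returned table keeps that convention in
#' `start`/`end`, with the gene symbol taken from BED column 4.
#'
#' @param path BED path.
#' @return data frame with gene, chrom, start, end (0-based half-open).
#' @export
read_gene_regions <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(b) < 4) stop_config("BED file must have at least 4 columns (chrom, start, end, gene)")
  out <- data.frame(gene = as.character(b[[4]]), chrom = as.character(b[[1]]),
                    start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop_config("BED interval with start >= end")
  out
}

#' @rdname read_gene_regions
#' @param regions gene-region table to write.
#' @export
write_gene_regions <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a candidate-gene table
#'
#' TSV with columns gene, chrom, score; `score` is a protein-interaction
#' confidence in `[0, 1]` (a STRING-style joint evidence probability).  Lines
#' starting with `#` are comments.
#'
#' @param path TSV path.  The packaged table of index-gene interaction
#'   partners lives at
#'   `system.file("extdata", "string_candidates.tsv", package = "episnp")`.
#' @return data frame with gene, chrom, score.
#' @export
read_candidate_genes <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "score")
  if (!all(need %in% colnames(g))) {
    stop_config("candidate-gene TSV must have columns %s", paste(need, collapse = ", "))
  }
  g$score <- as.numeric(g$score)
  if (any(!is.na(g$score) & (g$score < 0 | g$score > 1))) {
    stop_config("confidence scores must lie in [0, 1]")
  }
  g[, need]
}
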