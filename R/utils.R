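#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state, so seeded package functions never disturb the session
#' stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Child seeds from a master seed by fixed offsets, folded into the 32-bit
# signed range so any user-supplied integer master seed is safe.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + as.numeric(offset)) %% 2147483629)
}

# round half away from zero (dosage 0.5 -> 1, 1.5 -> 2); base round() would
# round to even
round_half_up <- function(x) floor(x + 0.5)

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)

# sex chromosome labels in both plain and 'chr'-prefixed, numeric-coded styles
SEX_CHROMS <- c("X", "Y", "chrX", "chrY", "23", "24")

assert_dosage_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d)) stop_config("dosages must be a numeric matrix (samples x SNPs)")
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    stop_config("dosage matrix must carry sample ids as rownames and SNP ids as colnames")
  }
  if (anyDuplicated(rownames(d))) stop_config("duplicate sample ids in dosage matrix")
  if (anyDuplicated(colnames(d))) stop_config("duplicate SNP ids in dosage matrix")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop_config("dosage values outside [0, 2]")
  }
  invisible(d)
}

align_samples <- function(samples, sample_ids) {
  if (!all(sample_ids %in% samples$sample_id)) {
    missing <- setdiff(sample_ids, samples$sample_id)
    stop_config("sample table is missing ids: %s", paste(head(missing, 5), collapse = ", "))
  }
  samples[match(sample_ids, samples$sample_id), , drop = FALSE]
}
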