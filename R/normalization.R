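#' Median-of-ratios size factors
#'
#' Per-sample size factors computed as the median, over genes with positive
#' counts in every sample, of the ratio of the gene's count to its
#' across-sample geometric mean. This is the classical size-factor estimator
#' for bulk RNA-seq count matrices.
#'
#' @param counts Count tibble (see [validate_counts()]).
#' @return Tibble with columns `sample_id`, `factor`, `method`
#'   (`"median_ratios"`) and `reference_sample` (`"geometric_mean"`).
#' @examples
#' cts <- tibble::tibble(gene_id = paste0("g", 1:3),
#'                       s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
#' estimate_size_factors(cts)
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort("median-of-ratios needs at least one gene with positive counts in every sample.")
  }
  mp <- m[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(mp)))
  f <- apply(mp / geo, 2, median)
  tibble(sample_id = colnames(m), factor = unname(f),
         method = "median_ratios", reference_sample = "geometric_mean")
}

#' Trimmed-mean-of-M-values (TMM) size factors
#'
#' Library-composition normalization: for each sample against a reference
#' sample, gene-wise log2 ratios (M) and average log2 abundances (A) are
#' computed on library-size-scaled counts, the most extreme 30% of M values
#' and 5% of A values are trimmed, and the factor is the precision-weighted
#' mean of the remaining M values. Factors are centred so their geometric
#' mean is 1.
#'
#' @param counts Count tibble.
#' @param ref Reference sample id, or `NULL` to pick the sample whose
#'   upper-quartile (of library-size-scaled counts) is closest to the mean
#'   upper-quartile.
#' @param logratio_trim,abundance_trim Two-sided trim fractions for M and A.
#' @return Tibble with columns `sample_id`, `factor`, `method` (`"tmm"`) and
#'   `reference_sample`.
#' @export
estimate_tmm_factors <- function(counts, ref = NULL,
                                 logratio_trim = 0.3, abundance_trim = 0.05) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("all counts are zero in sample(s): ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  if (is.null(ref)) {
    uq <- apply(m, 2, quantile, probs = 0.75) / lib
    ref <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% colnames(m)) abort(paste0("reference sample not found: ", ref))
  f <- vapply(colnames(m), function(s) {
    tmm_pair_factor(m[, s], m[, ref], lib[[s]], lib[[ref]],
                    logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), factor = unname(f),
         method = "tmm", reference_sample = ref)
}

# single-pair TMM factor (obs vs ref), doubly trimmed, precision-weighted
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # delta-method variance of M, used as precision weight
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & A > -1e10
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

# Per-sample log offsets. Median-of-ratios factors are full size factors
# (they already carry relative depth), so the offset is log(factor); TMM
# factors are composition corrections on top of depth, so the offset is
# log(library size * factor).
norm_offsets <- function(counts, norm) {
  m <- counts_matrix(counts)
  f <- setNames(norm$factor, norm$sample_id)[colnames(m)]
  if (anyNA(f)) abort("normalization factors missing for some samples.")
  if (unique(norm$method)[1] == "median_ratios") {
    log(unname(f))
  } else {
    log(colSums(m) * unname(f))
  }
}
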