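#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up procedure. `NA`/`NaN` entries (e.g.
#' filtered genes) are excluded from the number of tests `m` and returned as
#' `NA`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

# contrast vector aligned to design coefficients (named or positional)
align_contrast <- function(contrast, coef_names) {
  p <- length(coef_names)
  if (!is.null(names(contrast)) && any(names(contrast) != "")) {
    cv <- setNames(rep(0, p), coef_names)
    unknown <- setdiff(names(contrast), coef_names)
    if (length(unknown)) {
      abort(paste0("contrast names not in design: ", paste(unknown, collapse = ", ")))
    }
    cv[names(contrast)] <- contrast
    return(unname(cv))
  }
  if (length(contrast) != p) abort("contrast length must equal the coefficient count.")
  as.numeric(contrast)
}

#' Wald contrast test on fitted NB GLMs
#'
#' Tests `contrast' beta = 0` per gene with a normal-approximation Wald
#' statistic, using the observed Fisher information at the optimum. Reported
#' effects are on the log2 scale.
#'
#' @param fit An [fit_nb_glm()] object.
#' @param contrast Numeric contrast over the design coefficients (named by
#'   coefficient, or positional of full length).
#' @return Tibble with columns `gene_id`, `log2fc`, `stat`, `pvalue`, `fdr`,
#'   `class` (`"filtered"` for degenerate/untestable genes, `"ns"`
#'   otherwise; classification against thresholds is applied downstream).
#' @export
wald_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "nbglm_fit"))
  cv <- align_contrast(contrast, colnames(fit$design))
  G <- length(fit$gene_id)
  est <- as.numeric(fit$coefficients %*% cv)
  se <- vapply(seq_len(G), function(g) {
    V <- tryCatch(solve(fit$info[g, , ]), error = function(e) NULL)
    if (is.null(V)) return(NA_real_)
    v <- as.numeric(t(cv) %*% V %*% cv)
    if (v < 0) NA_real_ else sqrt(v)
  }, numeric(1))

  stat <- est / se
  pval <- 2 * pnorm(-abs(stat))
  null_contrast <- all(cv == 0)
  if (null_contrast) {
    stat[] <- 0
    pval[] <- 1
  }
  flagged <- fit$degenerate | (!null_contrast & (is.na(se) | se == 0))
  stat[flagged] <- NA_real_
  pval[flagged] <- NA_real_
  tibble(gene_id = fit$gene_id,
         log2fc = est / log(2),
         stat = stat,
         pvalue = pval,
         fdr = bh_adjust(pval),
         class = ifelse(flagged, "filtered", "ns"))
}

# invertible map T with first row = contrast; remaining rows orthonormal
contrast_reparam <- function(contrast) {
  p <- length(contrast)
  if (all(contrast == 0)) abort("contrast must be a nonzero vector.")
  Qfull <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)
  rbind(contrast, t(Qfull[, -1, drop = FALSE]))
}

#' Likelihood-ratio test of a coefficient contrast
#'
#' Reparameterizes the design so the contrast becomes a single coefficient
#' (first row of an invertible map, completed orthonormally), fits the full
#' model and the reduced model with that coefficient dropped, and compares
#' `2 * (ll_full - ll_reduced)` to a chi-square with 1 df. The reported
#' effect is the full-model Wald estimate of the same contrast, so the two
#' routes agree on the effect size.
#'
#' @param counts Count tibble.
#' @param design Samples-by-coefficients design matrix.
#' @param norm Normalization-factor tibble.
#' @param dispersions Dispersion estimates or numeric dispersion(s).
#' @param contrast Contrast vector over the design coefficients.
#' @return Tibble with `gene_id`, `log2fc`, `stat`, `pvalue`, `fdr`, `class`.
#' @export
lrt_contrast_test <- function(counts, design, norm, dispersions, contrast) {
  validate_counts(counts)
  y <- counts_matrix(counts)
  design <- align_design(design, colnames(y))
  cv <- align_contrast(contrast, colnames(design))
  Tm <- contrast_reparam(cv)
  Xfull <- design %*% solve(Tm)
  colnames(Xfull) <- c("contrast", paste0("nuisance", seq_len(ncol(design) - 1)))
  Xred <- Xfull[, -1, drop = FALSE]
  if (ncol(Xred) == 0) abort("contrast spans the whole design; no reduced model exists.")
  if (qr(Xred)$rank < ncol(Xred)) abort("reduced design is rank deficient.")

  alpha <- dispersion_vector(dispersions, rownames(y))
  offset <- norm_offsets(counts, norm)
  full <- nbglm_irls(y, Xfull, offset, alpha)
  red <- nbglm_irls(y, Xred, offset, alpha)

  stat <- pmax(2 * (full$loglik - red$loglik), 0)
  pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  flagged <- full$degenerate
  stat[flagged] <- NA_real_
  pval[flagged] <- NA_real_
  tibble(gene_id = rownames(y),
         log2fc = unname(full$beta[, 1]) / log(2),
         stat = stat,
         pvalue = pval,
         fdr = bh_adjust(pval),
         class = ifelse(flagged, "filtered", "ns"))
}
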