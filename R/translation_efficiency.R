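#' Four-condition polysome-profiling design
#'
#' Maps each sample's (genotype, fraction) pair onto one of the four
#' conditions `WT_Input`, `KO_Input`, `WT_Polysomes`, `KO_Polysomes`, builds
#' the one-hot condition design, and encodes the translational-efficiency
#' interaction contrast `(KO_Polysomes - KO_Input) - (WT_Polysomes - WT_Input)`,
#' which captures changes in polysome association beyond changes in input
#' abundance.
#'
#' @param metadata Sample metadata tibble (`sample_id`, `genotype`,
#'   `fraction` with values `"input"`/`"polysome"`).
#' @param wt,ko Genotype labels treated as wild type and knockdown.
#' @return A `te_design` list: `design` (samples x 4 one-hot matrix),
#'   `contrast` (named numeric), `condition` (per-sample tibble).
#' @export
build_te_design <- function(metadata, wt = "WT", ko = "KO") {
  need <- c("sample_id", "genotype", "fraction")
  if (!all(need %in% names(metadata))) {
    abort("metadata needs columns sample_id, genotype, fraction.")
  }
  meta <- dplyr::filter(metadata, .data$genotype %in% c(wt, ko),
                        .data$fraction %in% c("input", "polysome"))
  cond <- paste0(ifelse(meta$genotype == wt, "WT", "KO"), "_",
                 ifelse(meta$fraction == "input", "Input", "Polysomes"))
  levels <- c("WT_Input", "KO_Input", "WT_Polysomes", "KO_Polysomes")
  missing <- setdiff(levels, cond)
  if (length(missing)) {
    abort(paste0("missing condition(s): ", paste(missing, collapse = ", ")))
  }
  meta$condition <- cond
  X <- condition_design(meta, by = "condition", levels = levels)
  contrast <- setNames(c(1, -1, -1, 1),
                       c("WT_Input", "KO_Input", "WT_Polysomes", "KO_Polysomes"))
  structure(list(design = X, contrast = contrast,
                 condition = tibble(sample_id = meta$sample_id,
                                    condition = cond)),
            class = "te_design")
}

#' Differential translational efficiency from polysome profiling
#'
#' Applies the low-count filter jointly across fractions, TMM-normalizes,
#' estimates dispersions, fits the four-condition NB GLM and tests the
#' translational-efficiency interaction contrast with a 1-df
#' likelihood-ratio test. Both the raw p-value (used for classification by
#' default) and the BH-adjusted FDR are reported.
#'
#' @param counts Count tibble covering the four conditions.
#' @param design A [build_te_design()] object.
#' @param alpha Significance level applied to the classification column.
#' @param use_fdr Classify on the BH-adjusted values instead of raw p.
#' @param min_total_reads Low-count filter threshold (pooled across fractions).
#' @return A `te_result` tibble: `gene_id`, `delta_te_log2`, `stat`,
#'   `pvalue`, `fdr`, `class` in `{te_up, te_down, ns, filtered}`.
#' @export
run_te_analysis <- function(counts, design, alpha = 0.05, use_fdr = FALSE,
                            min_total_reads = 5) {
  stopifnot(inherits(design, "te_design"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  validate_counts(counts)
  keep_cols <- c(names(counts)[1], design$condition$sample_id)
  sub <- counts[, keep_cols, drop = FALSE]

  flt <- filter_low_counts(sub, min_total_reads)
  tested <- flt$counts
  norm <- estimate_tmm_factors(tested)
  disp <- estimate_dispersions(tested, design$design, norm)
  tab <- lrt_contrast_test(tested, design$design, norm, disp, design$contrast)

  out <- dplyr::bind_rows(
    dplyr::rename(tab, delta_te_log2 = "log2fc"),
    tibble(gene_id = flt$removed, delta_te_log2 = NA_real_, stat = NA_real_,
           pvalue = NA_real_, fdr = NA_real_, class = "filtered"))
  out <- out[match(counts[[1]], out$gene_id), ]

  crit <- if (use_fdr) out$fdr else out$pvalue
  tested_gene <- out$class != "filtered" & !is.na(crit)
  out$class[tested_gene] <- "ns"
  sig <- tested_gene & crit < alpha
  out$class[sig & out$delta_te_log2 > 0] <- "te_up"
  out$class[sig & out$delta_te_log2 < 0] <- "te_down"
  structure(out, class = c("te_result", class(tibble())),
            alpha = alpha, use_fdr = use_fdr,
            summary = classify_te(out))
}

#' Summarize translational classification
#'
#' @param result A `te_result` tibble (or any tibble with a `class` column
#'   using the `te_up`/`te_down` vocabulary).
#' @return List with `n_te_up` and `n_te_down`.
#' @export
classify_te <- function(result) {
  list(n_te_up = sum(result$class == "te_up", na.rm = TRUE),
       n_te_down = sum(result$class == "te_down", na.rm = TRUE))
}

#' @export
print.te_result <- function(x, ...) {
  s <- classify_te(x)
  cat(sprintf("Translational efficiency result: %d up, %d down (alpha = %g, %s)\n",
              s$n_te_up, s$n_te_down, attr(x, "alpha"),
              if (isTRUE(attr(x, "use_fdr"))) "BH FDR" else "raw p"))
  NextMethod()
}

#' @rdname run_te_analysis
#' @param x A `te_result`.
#' @param ... Unused.
#' @method glance te_result
#' @export
glance.te_result <- function(x, ...) {
  s <- classify_te(x)
  tibble(n_te_up = s$n_te_up, n_te_down = s$n_te_down,
         n_tested = sum(x$class != "filtered"),
         n_filtered = sum(x$class == "filtered"),
         alpha = attr(x, "alpha"),
         use_fdr = isTRUE(attr(x, "use_fdr")))
}
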