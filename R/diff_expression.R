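#' Differential-expression configuration
#'
#' @param min_total_reads Genes with fewer total reads than this across all
#'   samples are excluded before testing (default 5).
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (>= 1); under `fold2` mode a
#'   gene must change `fc_threshold`-fold, i.e. `|log2fc| >= log2(fc_threshold)`.
#' @param log2fc_mode `"fold2"` (twofold-or-higher change, `|log2fc| >= 1`
#'   at the default threshold) or `"log2fc2"` (`|log2fc| >= 2`). Both
#'   conventions appear in practice; the mode used is recorded in outputs.
#' @return A `de_config` list.
#' @export
de_config <- function(min_total_reads = 5, fdr_threshold = 0.05,
                      fc_threshold = 2, log2fc_mode = c("fold2", "log2fc2")) {
  log2fc_mode <- match.arg(log2fc_mode)
  if (min_total_reads < 0) abort("`min_total_reads` must be >= 0.")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) abort("`fdr_threshold` must be in (0, 1).")
  if (fc_threshold < 1) abort("`fc_threshold` must be >= 1.")
  structure(list(min_total_reads = min_total_reads,
                 fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold,
                 log2fc_mode = log2fc_mode),
            class = "de_config")
}

de_log2_cutoff <- function(cfg) {
  switch(cfg$log2fc_mode,
         fold2 = log2(cfg$fc_threshold),
         log2fc2 = cfg$fc_threshold)
}

#' Remove genes with low total counts
#'
#' Genes with fewer than `min_total` reads summed across all samples are
#' excluded from downstream testing.
#'
#' @param counts Count tibble.
#' @param min_total Minimum total reads a gene must reach to be kept.
#' @return List with `counts` (kept genes) and `removed` (character vector
#'   of removed gene ids).
#' @export
filter_low_counts <- function(counts, min_total = 5) {
  validate_counts(counts)
  if (min_total < 0) abort("`min_total` must be >= 0.")
  totals <- rowSums(counts_matrix(counts))
  keep <- totals >= min_total
  list(counts = counts[keep, , drop = FALSE],
       removed = counts[[1]][!keep])
}

#' Differential expression between one case genotype and a control
#'
#' Low-count filtering, median-of-ratios normalization, empirical-Bayes
#' dispersions, NB GLM group-means fit, Wald test of case minus control,
#' BH adjustment over tested genes, and up/down/ns classification.
#'
#' @param counts Count tibble covering both genotypes.
#' @param metadata Sample metadata tibble.
#' @param case,control Genotype labels to compare (effect is case - control).
#' @param cfg A [de_config()].
#' @return A `de_result` tibble: `gene_id`, `log2fc`, `stat`, `pvalue`,
#'   `fdr`, `class` for every input gene (filtered genes carry `NA`
#'   statistics and class `"filtered"`); attributes record the config and
#'   summary counts.
#' @export
run_de_comparison <- function(counts, metadata, case, control,
                              cfg = de_config()) {
  validate_counts(counts, metadata)
  for (lab in c(case, control)) {
    if (!lab %in% metadata$genotype) abort(paste0("genotype not in metadata: ", lab))
  }
  meta <- dplyr::filter(metadata, .data$genotype %in% c(case, control))
  n_rep <- table(meta$genotype)
  if (any(n_rep < 2)) {
    warn("fewer than 2 replicates in a group; estimates will be unstable.")
  }
  keep_cols <- c(names(counts)[1], meta$sample_id)
  sub <- counts[, keep_cols, drop = FALSE]

  flt <- filter_low_counts(sub, cfg$min_total_reads)
  tested <- flt$counts
  norm <- estimate_size_factors(tested)
  design <- condition_design(meta, by = "genotype", levels = c(control, case))
  disp <- estimate_dispersions(tested, design, norm)
  fit <- fit_nb_glm(tested, design, norm, disp)
  contrast <- setNames(c(-1, 1), c(control, case))
  tab <- wald_test(fit, contrast)
  tab <- classify_de(tab, cfg)

  out <- dplyr::bind_rows(
    tab,
    tibble(gene_id = flt$removed, log2fc = NA_real_, stat = NA_real_,
           pvalue = NA_real_, fdr = NA_real_, class = "filtered"))
  out <- out[match(counts[[1]], out$gene_id), ]
  new_de_result(out, cfg = cfg, case = case, control = control)
}

new_de_result <- function(tab, cfg, case = NULL, control = NULL) {
  structure(tab, class = c("de_result", class(tibble())),
            cfg = cfg, case = case, control = control,
            summary = de_summary_counts(tab))
}

de_summary_counts <- function(tab) {
  cls <- factor(tab$class, levels = c("up", "down", "ns", "filtered"))
  as.list(setNames(as.integer(table(cls)),
                   c("n_up", "n_down", "n_ns", "n_filtered")))
}

#' Classify genes as up, down or not significant
#'
#' A tested gene is `up` when `fdr < fdr_threshold` and `log2fc` exceeds the
#' positive cutoff implied by the configured mode, `down` for the negative
#' counterpart, `ns` otherwise; filtered genes keep class `"filtered"`.
#'
#' @param table Test-table tibble (`gene_id`, `log2fc`, `pvalue`, `fdr`, ...).
#' @param cfg A [de_config()].
#' @return The table with its `class` column set; attribute `summary` holds
#'   `n_up`, `n_down`, `n_ns`, `n_filtered`.
#' @export
classify_de <- function(table, cfg = de_config()) {
  cut <- de_log2_cutoff(cfg)
  if (!"class" %in% names(table)) {
    table$class <- ifelse(is.na(table$pvalue), "filtered", "ns")
  }
  tested <- table$class != "filtered" & !is.na(table$pvalue)
  cls <- table$class
  cls[tested] <- "ns"
  sig <- tested & !is.na(table$fdr) & table$fdr < cfg$fdr_threshold
  cls[sig & table$log2fc >= cut] <- "up"
  cls[sig & table$log2fc <= -cut] <- "down"
  table$class <- cls
  new_de_result(table, cfg = cfg)
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  cfg <- attr(x, "cfg")
  cat("Differential expression result (mode: ", cfg$log2fc_mode, ")\n", sep = "")
  cat(sprintf("  up: %d  down: %d  ns: %d  filtered: %d\n",
              s$n_up, s$n_down, s$n_ns, s$n_filtered))
  NextMethod()
}

#' @rdname run_de_comparison
#' @param x A `de_result`.
#' @param ... Unused.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  cfg <- attr(x, "cfg")
  tibble(n_up = s$n_up, n_down = s$n_down, n_ns = s$n_ns,
         n_filtered = s$n_filtered, fdr_threshold = cfg$fdr_threshold,
         log2fc_mode = cfg$log2fc_mode)
}
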