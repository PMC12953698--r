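#' Negative-binomial regression of signature-gene TPM across groups
#'
#' Models the TPM of each signature gene (rounded to the nearest integer, as
#' NB regression needs counts) as the dependent variable with the library
#' group (stage or genotype) as the sole predictor, genes serving as the
#' observational units. Each requested contrast is tested with a Wald test
#' on the fitted coefficients and the family is BH-adjusted.
#'
#' @param table Stage-expression tibble: `gene_id` column plus one numeric
#'   TPM column per library, or long format with columns `gene_id`, `group`,
#'   `tpm`.
#' @param signature [gene_set()] or character vector of signature genes.
#' @param contrasts List of 2-element character vectors `c(case, control)`;
#'   each is tested as `log mean(case) - log mean(control)`.
#' @param groups Optional named vector mapping library columns to group
#'   labels (defaults to the column names themselves for wide input).
#' @return A `signature_fit` with `contrasts` tibble (`contrast`, `estimate`
#'   on the natural-log scale, `se`, `stat`, `pvalue`, `fdr`), the fitted
#'   `model`, and the long `data`.
#' @export
fit_stage_nb_regression <- function(table, signature, contrasts,
                                    groups = NULL) {
  sig <- set_members(signature)
  if (!length(sig)) abort("signature gene set is empty.")
  long <- stage_table_long(table, groups)
  long <- dplyr::filter(long, .data$gene_id %in% sig)
  if (!nrow(long)) abort("no signature genes found in the expression table.")
  long$response <- as.integer(round(long$tpm))
  long$group <- factor(long$group)

  model <- tryCatch(
    suppressWarnings(MASS::glm.nb(response ~ 0 + group, data = long)),
    error = function(e) {
      warn(paste0("glm.nb failed (", conditionMessage(e),
                  "); falling back to a Poisson fit."))
      stats::glm(response ~ 0 + group, data = long, family = stats::poisson())
    })
  est <- coef(model)
  V <- vcov(model)
  lev <- levels(long$group)
  names(est) <- lev

  res <- purrr::map_dfr(contrasts, function(ct) {
    if (length(ct) != 2) abort("each contrast must be c(case, control).")
    missing <- setdiff(ct, lev)
    if (length(missing)) {
      abort(paste0("contrast references absent group(s): ",
                   paste(missing, collapse = ", ")))
    }
    L <- setNames(rep(0, length(lev)), lev)
    L[ct[1]] <- 1
    L[ct[2]] <- -1
    e <- sum(L * est)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    z <- e / se
    tibble(contrast = paste0(ct[1], " vs ", ct[2]),
           estimate = e, se = se, stat = z,
           pvalue = 2 * pnorm(-abs(z)))
  })
  res$fdr <- bh_adjust(res$pvalue)
  structure(list(contrasts = res, model = model, data = long),
            class = "signature_fit")
}

stage_table_long <- function(table, groups = NULL) {
  if (all(c("gene_id", "group", "tpm") %in% names(table))) {
    long <- tibble(gene_id = table$gene_id, group = table$group, tpm = table$tpm)
  } else {
    names(table)[1] <- "gene_id"
    long <- tidyr::pivot_longer(table, -"gene_id", names_to = "library",
                                values_to = "tpm")
    long$group <- if (is.null(groups)) long$library else {
      mapped <- groups[long$library]
      if (anyNA(mapped)) abort("`groups` must map every library column.")
      unname(mapped)
    }
  }
  if (any(long$tpm < 0, na.rm = TRUE)) abort("TPM values must be >= 0.")
  long
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Stage-signature NB regression (", length(unique(x$data$gene_id)),
      " genes)\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' @rdname fit_stage_nb_regression
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @method tidy signature_fit
#' @export
tidy.signature_fit <- function(x, ...) x$contrasts

#' @rdname fit_stage_nb_regression
#' @method glance signature_fit
#' @export
glance.signature_fit <- function(x, ...) {
  tibble(n_genes = length(unique(x$data$gene_id)),
         n_groups = length(levels(x$data$group)),
         n_contrasts = nrow(x$contrasts),
         theta = if (inherits(x$model, "negbin")) x$model$theta else NA_real_)
}

#' Classify per-gene stage profiles
#'
#' A gene is `germ_cell_like` when its mean TPM over the undifferentiated
#' stages (GSC, CB, cyst) is at least `ratio` times the whole-ovary TPM,
#' `maternal_like` for the reverse, `flat` when neither direction exceeds
#' the ratio and the profile is roughly even, otherwise `other`.
#'
#' @param table Stage-expression tibble (wide: columns `GSC`, `CB`, `cyst`,
#'   `whole_ovary`; or long with `group` in that vocabulary).
#' @param ratio Fold-ratio defining a profile (default 2).
#' @return Tibble `gene_id`, `early_mean`, `ovary_tpm`, `profile`.
#' @export
classify_stage_profile <- function(table, ratio = 2) {
  long <- stage_table_long(table)
  stages <- c("GSC", "CB", "cyst", "whole_ovary")
  missing <- setdiff(stages, unique(long$group))
  if (length(missing)) {
    abort(paste0("missing stage(s): ", paste(missing, collapse = ", ")))
  }
  wide <- long |>
    dplyr::group_by(.data$gene_id, .data$group) |>
    dplyr::summarise(tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "tpm")
  early <- rowMeans(cbind(wide$GSC, wide$CB, wide$cyst))
  ovary <- wide$whole_ovary
  profile <- dplyr::case_when(
    early == 0 & ovary == 0 ~ "flat",
    early >= ratio * ovary ~ "germ_cell_like",
    ovary >= ratio * early ~ "maternal_like",
    TRUE ~ "flat")
  tibble(gene_id = wide$gene_id, early_mean = early,
         ovary_tpm = ovary, profile = profile)
}
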