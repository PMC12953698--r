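te_meta <- function(n_rep = 2, wt = "WT", ko = "KO") {
  grid <- expand.grid(replicate = seq_len(n_rep),
                      fraction = c("input", "polysome"),
                      genotype = c(wt, ko), stringsAsFactors = FALSE)
  tibble::tibble(sample_id = paste(grid$genotype, grid$fraction,
                                   grid$replicate, sep = "_"),
                 genotype = grid$genotype, fraction = grid$fraction,
                 stage = "whole_ovary", replicate = grid$replicate)
}

test_that("the TE design is one-hot with the interaction contrast", {
  meta <- te_meta()
  d <- build_te_design(meta)
  expect_equal(dim(d$design), c(8, 4))
  expect_equal(unname(colSums(d$design)), rep(2, 4))
  expect_true(all(rowSums(d$design) == 1))
  # orthogonal to the intercept
  expect_equal(sum(d$contrast), 0)
  # applied to condition means (a, b, c, d) = (WT_I, KO_I, WT_P, KO_P)
  means <- c(WT_Input = 5, KO_Input = 7, WT_Polysomes = 11, KO_Polysomes = 17)
  expect_equal(sum(d$contrast * means), (17 - 7) - (11 - 5))
  expect_error(build_te_design(meta[meta$fraction == "input", ]),
               "missing condition")
})

test_that("a gene with matched polysome/input ratios shows no TE change", {
  # KO polysome = KO input * r with the same r as WT: interaction is null
  meta <- te_meta()
  counts <- c(WT_input = 100, WT_polysome = 300,
              KO_input = 200, KO_polysome = 600)
  m <- matrix(rep(c(100, 100, 300, 300, 200, 200, 600, 600) * 10, 1), nrow = 1)
  colnames(m) <- meta$sample_id
  cts <- as_counts(m, "g1")
  d <- build_te_design(meta)
  norm <- unit_norm(cts)
  tab <- lrt_contrast_test(cts, d$design, norm, 0, d$contrast)
  expect_equal(tab$log2fc, 0, tolerance = 1e-6)
  expect_gt(tab$pvalue, 0.999)
})

test_that("swapping the genotype labels negates delta TE", {
  cfg <- sim_config(n_genes = 200, te_cohort_size = 40, delta_te_log2 = 1.5,
                    seed = 18)
  sim <- simulate_polysome_experiment(cfg)
  a <- run_te_analysis(sim$counts,
                       build_te_design(sim$metadata, wt = "nosGAL4",
                                       ko = "zfrp8_GKD"))
  b <- run_te_analysis(sim$counts,
                       build_te_design(sim$metadata, wt = "zfrp8_GKD",
                                       ko = "nosGAL4"))
  expect_equal(a$delta_te_log2, -b$delta_te_log2, tolerance = 1e-8)
})

test_that("a fraction-wide polysome scaling is absorbed by the design", {
  cfg <- sim_config(n_genes = 300, te_cohort_size = 60, seed = 19)
  sim <- simulate_polysome_experiment(cfg)
  d <- build_te_design(sim$metadata, wt = "nosGAL4", ko = "zfrp8_GKD")
  base <- run_te_analysis(sim$counts, d)

  scaled <- sim$counts
  poly <- sim$metadata$sample_id[sim$metadata$fraction == "polysome"]
  scaled[poly] <- scaled[poly] * 3

  # for Poisson fits at fixed offsets the interaction estimate is exactly
  # scale-free: the factor cancels between the two polysome condition means
  t1 <- lrt_contrast_test(sim$counts, d$design, unit_norm(sim$counts), 0,
                          d$contrast)
  t2 <- lrt_contrast_test(scaled, d$design, unit_norm(scaled), 0, d$contrast)
  expect_lt(max(abs(t1$log2fc - t2$log2fc), na.rm = TRUE), 1e-6)

  # the full NB pipeline (TMM + estimated dispersions) absorbs the shift up
  # to the precision weighting of the rescaled counts
  res <- run_te_analysis(scaled, d)
  expect_gt(mean(res$class == base$class), 0.99)
  expect_lt(max(abs(res$delta_te_log2 - base$delta_te_log2), na.rm = TRUE),
            0.05)
  keep <- !is.na(res$pvalue)
  expect_gt(stats::cor(log10(res$pvalue[keep] + 1e-300),
                       log10(base$pvalue[keep] + 1e-300)), 0.995)
})

test_that("delta TE equals the Wald estimate of the same contrast", {
  cfg <- sim_config(n_genes = 200, te_cohort_size = 40, seed = 20)
  sim <- simulate_polysome_experiment(cfg)
  d <- build_te_design(sim$metadata, wt = "nosGAL4", ko = "zfrp8_GKD")
  res <- run_te_analysis(sim$counts, d)
  norm <- estimate_tmm_factors(sim$counts)
  disp <- estimate_dispersions(sim$counts, d$design, norm)
  fit <- fit_nb_glm(sim$counts, d$design, norm, disp)
  wt <- wald_test(fit, d$contrast)
  m <- match(res$gene_id, wt$gene_id)
  expect_equal(res$delta_te_log2, wt$log2fc[m], tolerance = 1e-6)
})

test_that("TE summaries count classes and respect gene order", {
  all_null <- structure(
    tibble::tibble(gene_id = paste0("g", 1:5), delta_te_log2 = 0,
                   stat = 0, pvalue = 1, fdr = 1, class = "ns"),
    class = c("te_result", class(tibble::tibble())))
  s <- classify_te(all_null)
  expect_equal(s, list(n_te_up = 0, n_te_down = 0))

  cfg <- sim_config(n_genes = 500, te_cohort_size = 100, delta_te_log2 = 3,
                    baseline_meanlog = log(300), seed = 21)
  sim <- simulate_polysome_experiment(cfg)
  d <- build_te_design(sim$metadata, wt = "nosGAL4", ko = "zfrp8_GKD")
  res <- run_te_analysis(sim$counts, d)
  s2 <- classify_te(res)
  s3 <- classify_te(res[sample(nrow(res)), ])
  expect_equal(s2, s3)
  # planted 50 up / 50 down at strong effect
  expect_lte(abs(s2$n_te_up - 50), 15)
  expect_lte(abs(s2$n_te_down - 50), 15)
})
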