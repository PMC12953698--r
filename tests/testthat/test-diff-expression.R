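test_that("the low-count filter removes exactly the genes under the threshold", {
  m <- rbind(c(1L, 1L, 1L, 1L),   # sum 4: removed
             c(2L, 1L, 1L, 1L),   # sum 5: kept
             c(2L, 2L, 1L, 1L))   # sum 6: kept
  cts <- as_counts(m, c("low", "edge", "high"))
  flt <- filter_low_counts(cts, 5)
  expect_equal(flt$removed, "low")
  expect_equal(flt$counts$gene_id, c("edge", "high"))
  expect_equal(sort(c(flt$removed, flt$counts$gene_id)), sort(cts$gene_id))

  ident <- filter_low_counts(cts, 0)
  expect_equal(ident$counts, cts)
  expect_length(ident$removed, 0)
})

test_that("fold-change modes classify the same gene differently", {
  tab <- tibble::tibble(gene_id = "g1", log2fc = 1.2, stat = 2.5,
                        pvalue = 0.01, fdr = 0.04, class = "ns")
  up <- classify_de(tab, de_config(log2fc_mode = "fold2"))
  expect_equal(up$class, "up")
  ns <- classify_de(tab, de_config(log2fc_mode = "log2fc2"))
  expect_equal(ns$class, "ns")
})

test_that("classification summaries are exhaustive and order-invariant", {
  set.seed(13)
  tab <- tibble::tibble(gene_id = paste0("g", 1:100),
                        log2fc = rnorm(100, 0, 2), stat = rnorm(100),
                        pvalue = runif(100), fdr = runif(100),
                        class = "ns")
  cls <- classify_de(tab, de_config())
  s <- attr(cls, "summary")
  expect_equal(s$n_up + s$n_down + s$n_ns + s$n_filtered, 100)
  perm <- sample(100)
  s2 <- attr(classify_de(tab[perm, ], de_config()), "summary")
  expect_equal(s, s2)

  all_null <- tibble::tibble(gene_id = paste0("g", 1:10), log2fc = rnorm(10),
                             stat = 0, pvalue = 1, fdr = 1, class = "ns")
  s3 <- attr(classify_de(all_null, de_config()), "summary")
  expect_equal(s3$n_up, 0)
  expect_equal(s3$n_down, 0)
})

test_that("a planted twofold-up cohort is recovered with few false calls", {
  cfg <- sim_config(genotypes = c("nosGAL4", "zfrp8_GKD"),
                    germ_cohort_size = 100, maternal_cohort_size = 0,
                    seed = 14)
  sim <- simulate_bulk_counts(cfg)
  res <- run_de_comparison(sim$counts, sim$metadata, "zfrp8_GKD", "nosGAL4")
  m <- match(sim$truth$gene_id, res$gene_id)
  cohort <- sim$truth$cohort == "germ_cell"
  expect_gte(mean(res$class[m][cohort] == "up"), 0.7)
  expect_lte(mean(res$class[m][!cohort] %in% c("up", "down")), 0.1)
})

test_that("a planted 50-up/50-down design yields balanced class counts", {
  # well-expressed baseline so the designed effect is strong for every gene
  cfg <- sim_config(genotypes = c("nosGAL4", "mio_GKD"),
                    baseline_meanlog = log(300), baseline_sdlog = 0.5,
                    germ_cohort_size = 50, germ_effect_log2fc = 3,
                    maternal_cohort_size = 50, maternal_effect_log2fc = -3,
                    seed = 15)
  sim <- simulate_bulk_counts(cfg)
  res <- run_de_comparison(sim$counts, sim$metadata, "mio_GKD", "nosGAL4")
  s <- attr(res, "summary")
  expect_lte(abs(s$n_up - 50), 15)
  expect_lte(abs(s$n_down - 50), 15)
})

test_that("filtered genes carry no p-values and BH m equals the tested count", {
  set.seed(16)
  m <- rbind(matrix(rpois(40 * 4, 50), ncol = 4),
             matrix(rpois(5 * 4, 0.2), ncol = 4))
  cts <- as_counts(m)
  meta <- two_group_meta(names(cts)[-1], labels = c("ctl", "kd"))
  res <- run_de_comparison(cts, meta, "kd", "ctl")
  filt <- res$class == "filtered"
  expect_true(any(filt))
  expect_true(all(is.na(res$pvalue[filt])))
  tested <- !filt
  expect_equal(res$fdr[tested], bh_adjust(res$pvalue[tested]))
})

test_that("swapping case and control negates effects and preserves p-values", {
  set.seed(17)
  m <- matrix(rnbinom(200 * 4, mu = 80, size = 10), ncol = 4)
  m[1:20, 3:4] <- m[1:20, 3:4] * 4
  cts <- as_counts(m)
  meta <- two_group_meta(names(cts)[-1], labels = c("ctl", "kd"))
  a <- run_de_comparison(cts, meta, "kd", "ctl")
  b <- run_de_comparison(cts, meta, "ctl", "kd")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
})

test_that("unknown genotype labels are rejected", {
  cts <- as_counts(matrix(rpois(40, 30), ncol = 4))
  meta <- two_group_meta(names(cts)[-1])
  expect_error(run_de_comparison(cts, meta, "missing", "A"), "genotype")
})
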