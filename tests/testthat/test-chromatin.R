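toy_track <- function(values, bin_width = 100, chrom = "chr1",
                      total_reads = NULL) {
  n <- length(values)
  binned_track(tibble::tibble(chrom = chrom,
                              start = (seq_len(n) - 1) * bin_width,
                              end = seq_len(n) * bin_width,
                              value = values),
               bin_width, total_reads = total_reads)
}

test_that("RPKM normalization applies the formula and its scale property", {
  tr <- toy_track(c(10, 0, 5), total_reads = 1e6)
  r <- rpkm_bin_track(tr)
  expect_equal(r$value, c(100, 0, 50))   # 10 * 1e9 / (1e6 * 100)

  tr2 <- toy_track(c(10, 0, 5), total_reads = 2e6)
  expect_equal(rpkm_bin_track(tr2)$value, r$value / 2)
  expect_error(rpkm_bin_track(toy_track(c(1, 2), total_reads = 0)), "positive")
})

test_that("binarization bounds only improbably high bins", {
  uniform <- toy_track(rep(2, 100))
  expect_false(any(binarize_track(uniform)$bound))

  spike <- toy_track(c(rep(2, 99), 100))
  b <- binarize_track(spike)
  expect_true(b$bound[100])
  expect_false(any(b$bound[1:99]))

  empty <- toy_track(rep(0, 10))
  expect_false(any(binarize_track(empty)$bound))
})

test_that("gene quantification is overlap-weighted and strand-aware", {
  uniform <- toy_track(rep(7, 50))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1000,
                          end = 3000, strand = "+")
  q <- quantify_gene_marks(uniform, genes)
  expect_equal(q$promoter_mean, 7)
  expect_equal(q$body_mean, 7)

  # signal confined to the upstream promoter half leaves the body at zero
  v <- rep(0, 50); v[10] <- 20   # [900, 1000): upstream of the TSS at 1000
  conc <- toy_track(v)
  q2 <- quantify_gene_marks(conc, genes, promoter_up = 100, promoter_down = 100)
  expect_equal(q2$promoter_mean, 10)
  expect_equal(q2$body_mean, 0)

  # hand-computed 3-bin partial overlap: [150, 450) over bins of 100
  hand <- toy_track(c(1, 2, 3, 4, 5))
  g3 <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 150, end = 450,
                       strand = "+")
  q3 <- quantify_gene_marks(hand, g3, promoter_up = 50, promoter_down = 50)
  expect_equal(q3$body_mean, (2 * 50 + 3 * 100 + 4 * 100 + 5 * 50) / 300)

  # a promoter window crossing the chromosome start is clipped, with notice
  expect_warning(quantify_gene_marks(hand, g3), "clipped")

  expect_error(quantify_gene_marks(hand, dplyr::mutate(g3, chrom = "chrX")),
               "absent")
})

test_that("differential calls follow the threshold-and-background rule", {
  q <- function(p, b) tibble::tibble(gene_id = c("g1", "g2"),
                                     promoter_mean = p, body_mean = b)
  same <- differential_mark_call(q(c(10, 20), c(5, 5)), q(c(10, 20), c(5, 5)),
                                 background = 1)
  expect_true(all(same$call == "stable"))

  halved <- differential_mark_call(q(c(40, 40), c(5, 5)), q(c(19, 40), c(5, 5)),
                                   background = 1, pseudocount = 1)
  expect_equal(halved$call, c("loss", "stable"))

  below <- differential_mark_call(q(c(0.5, 40), c(1, 1)), q(c(0.1, 40), c(1, 1)),
                                  background = 1, pseudocount = 0.1)
  expect_equal(below$call[1], "below_background")
})

test_that("a planted loss/gain design is recovered from the tracks", {
  mk <- simulate_marks_and_tads(sim_config(seed = 27))
  tab <- differential_marks(mk$wt_track, mk$kd_track, mk$genes)
  m <- match(mk$truth$gene_id, tab$gene_id)
  loss <- mk$truth$mark_class == "loss"
  gain <- mk$truth$mark_class == "gain"
  stable <- mk$truth$mark_class == "stable"
  expect_gte(mean(tab$call[m][loss] == "loss"), 0.95)
  expect_gte(mean(tab$call[m][gain] == "gain"), 0.95)
  expect_lte(mean(tab$call[m][stable] == "loss"), 0.02)

  # the loss cohort is enriched among loss calls (module's own test)
  called_loss <- tab$gene_id[tab$call == "loss"]
  hyper <- hypergeometric_overlap_test(called_loss,
                                       mk$truth$gene_id[loss],
                                       mk$truth$gene_id)
  expect_lt(hyper$p_value, 1e-10)
})

test_that("redistribution counts conserve bins and reach the symmetric limit", {
  mk_bound <- function(bound) tibble::tibble(
    chrom = "chr1", start = (seq_along(bound) - 1) * 100,
    end = seq_along(bound) * 100, bound = bound)
  ident <- redistribution_summary(mk_bound(c(TRUE, FALSE, TRUE)),
                                  mk_bound(c(TRUE, FALSE, TRUE)))
  expect_equal(ident$n_lost, 0)
  expect_equal(ident$n_gained, 0)
  expect_equal(ident$redistribution_index, 0)

  swap <- redistribution_summary(mk_bound(c(TRUE, TRUE, FALSE, FALSE)),
                                 mk_bound(c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(swap$redistribution_index, 1)

  # hand-built 10-bin case: 2 lost, 3 gained
  wt <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  kd <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r <- redistribution_summary(mk_bound(wt), mk_bound(kd))
  expect_equal(r$n_lost, 2)
  expect_equal(r$n_gained, 3)
  expect_equal(r$redistribution_index, 2 / 3)
  expect_equal(r$n_lost + r$n_gained + r$n_stable_bound + r$n_stable_unbound, 10)

  expect_error(redistribution_summary(mk_bound(wt), mk_bound(wt[1:5])),
               "binning")
})

test_that("RPKM normalization commutes with quantification", {
  set.seed(28)
  tr <- toy_track(rpois(100, 5), total_reads = 1e5)
  genes <- tibble::tibble(gene_id = paste0("g", 1:3), chrom = "chr1",
                          start = c(600, 2000, 5000),
                          end = c(1500, 4000, 9000), strand = c("+", "-", "+"))
  q_then_n <- quantify_gene_marks(tr, genes)
  scale <- 1e9 / (1e5 * 100)
  n_then_q <- quantify_gene_marks(rpkm_bin_track(tr), genes)
  expect_equal(q_then_n$promoter_mean * scale, n_then_q$promoter_mean,
               tolerance = 1e-9)
  expect_equal(q_then_n$body_mean * scale, n_then_q$body_mean,
               tolerance = 1e-9)
})

test_that("the TAD meta-region matrix has the declared layout and membership", {
  # toy genome: 2 TADs, 6 genes placed by hand, 4 inside
  tads <- tibble::tibble(tad_id = c("tad1", "tad2"), chrom = "chr1",
                         start = c(10000, 50000), end = c(30000, 80000))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:6), chrom = "chr1",
    start = c(12000, 20000, 55000, 70000, 35000, 90000),
    end = c(14000, 22000, 57000, 72000, 37000, 92000),
    strand = "+")
  values <- tibble::tibble(gene_id = genes$gene_id,
                           log2fc = c(3, 2, -2, 0.1, 4, 0),
                           class = c("up", "up", "down", "ns", "up", "ns"))
  mm <- tad_metaregion_matrix(values, tads, genes = genes,
                              flank = 3000, flank_bins = 10, body_bins = 20)
  expect_equal(ncol(mm$matrix), 2 * 10 + 20)
  expect_equal(nrow(mm$matrix), 2)
  # DE genes: g1, g2, g3 inside; g5 outside -> 3/4
  expect_equal(mm$within_tad_fraction, 3 / 4)
  inside <- mm$gene_tad_membership
  expect_equal(inside$inside_tad, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(mean(inside$inside_tad), 4 / 6)

  # short region collapses with a warning
  tiny <- tibble::tibble(tad_id = "t", chrom = "chr1", start = 100, end = 150)
  expect_warning(tad_metaregion_matrix(values, tiny, genes = genes),
                 "shorter than one bin")
})

test_that("rows are sorted by cluster and effect size", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), chrom = "chr1",
                          start = c(1000, 5000, 9000),
                          end = c(2000, 6000, 10000), strand = "+")
  values <- tibble::tibble(gene_id = c("a", "b", "c"),
                           log2fc = c(-3, 2, 4), class = c("down", "up", "up"))
  mm <- tad_metaregion_matrix(values, genes, genes = genes,
                              flank = 500, flank_bins = 5, body_bins = 10)
  expect_equal(mm$rows$region_id, c("c", "b", "a"))
  expect_equal(as.character(mm$rows$cluster),
               c("upregulated", "upregulated", "downregulated"))
})

test_that("bedGraph and BED round-trip through files", {
  tr <- toy_track(c(3, 0, 8, 1))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, bin_width = 100)
  expect_equal(back$value, tr$value)
  expect_equal(back$start, tr$start)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1\t0\t+", "chr2\t0\t50\tg2\t0\t-"), bed)
  b <- read_bed(bed)
  expect_equal(b$chrom, c("chr1", "chr2"))
  expect_equal(b$strand, c("+", "-"))
})
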