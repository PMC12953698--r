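test_that("k-way intersections are exact", {
  expect_equal(intersect_sets(list(c("a", "b"), c("c", "d")))$n, 0)
  expect_equal(intersect_sets(list(c("a", "b", "c"), c("a", "b", "c")))$n, 3)
  r <- intersect_sets(list(c("a", "b", "c"), c("b", "c", "d"), c("c", "e")))
  expect_equal(r$n, 1)
  expect_equal(r$members, "c")
})

test_that("sets equal to the universe saturate the randomization test", {
  uni <- paste0("g", 1:50)
  r <- overlap_randomization_test(list(uni, uni, uni), uni, n_iter = 1000,
                                  seed = 1)
  expect_equal(r$empirical_p, 1)
  expect_equal(r$n_exceedances, 1000)
})

test_that("a planted core unattainable by chance hits the add-one floor", {
  uni <- paste0("g", 1:2000)
  core <- uni[1:200]
  sets <- list(gene_set("a", c(core, uni[201:300])),
               gene_set("b", c(core, uni[301:500])),
               gene_set("c", c(core, uni[501:800])))
  n_iter <- 1e5
  r <- overlap_randomization_test(sets, uni, n_iter = n_iter, seed = 2)
  expect_equal(r$observed_intersection, 200)
  expect_equal(r$n_exceedances, 0)
  expect_equal(r$empirical_p, 1 / (n_iter + 1))
})

test_that("the randomization test matches exhaustive enumeration on a tiny universe", {
  uni <- letters[1:8]
  set_a <- uni[1:3]
  set_b <- uni[c(1, 2, 4, 5)]
  obs <- 2
  exact <- enumerate_overlap_p(8, 3, 4, obs)
  n_iter <- 1e5
  r <- overlap_randomization_test(list(set_a, set_b), uni, n_iter = n_iter,
                                  seed = 3)
  expect_equal(r$observed_intersection, obs)
  mc_sd <- sqrt(exact * (1 - exact) / n_iter)
  expect_lt(abs(r$empirical_p - exact), 3 * mc_sd)
})

test_that("empirical p is non-increasing in the observed intersection", {
  uni <- paste0("g", 1:300)
  p_for_core <- function(core_n) {
    core <- uni[seq_len(core_n)]
    # fillers keep both set sizes fixed (50 and 60) as the core grows
    s1 <- c(core, uni[151 + seq_len(50 - core_n) - 1])
    s2 <- c(core, uni[201 + seq_len(60 - core_n) - 1])
    overlap_randomization_test(list(s1, s2), uni, n_iter = 2e4,
                               seed = 4)$empirical_p
  }
  ps <- vapply(c(2, 10, 30), p_for_core, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("hypergeometric overlap has closed-form and enumeration oracles", {
  uni <- paste0("g", 1:10)
  r <- hypergeometric_overlap_test(uni[1:5], uni[1:5], uni)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  r0 <- hypergeometric_overlap_test(uni[1:4], uni[5:10], uni)
  expect_equal(r0$p_value, 1)

  # enumeration oracle on |U| = 12
  uni12 <- paste0("g", 1:12)
  a <- uni12[1:5]; b <- uni12[c(1:3, 6, 7)]
  r12 <- hypergeometric_overlap_test(a, b, uni12)
  exact <- enumerate_overlap_p(12, 5, 5, r12$observed_intersection)
  expect_equal(r12$p_value, exact, tolerance = 1e-12)

  # symmetric in the two sets
  expect_equal(hypergeometric_overlap_test(a, b, uni12)$p_value,
               hypergeometric_overlap_test(b, a, uni12)$p_value)
  expect_error(hypergeometric_overlap_test("a", "b", character(0)), "empty")
})

test_that("Venn-region fractions partition the union", {
  ident <- overlap_fraction_summary(list(c("a", "b"), c("a", "b")))
  expect_equal(ident$core_fraction, 1)
  disj <- overlap_fraction_summary(list(c("a", "b"), c("c", "d")))
  expect_equal(disj$core_fraction, 0)

  r <- overlap_fraction_summary(list(c("a", "b", "c", "d"),
                                     c("b", "c", "d", "e"),
                                     c("c", "d", "f")))
  expect_equal(r$core_fraction, 1 / 3)
  expect_equal(sum(r$regions$fraction), 1)
  expect_equal(sum(r$regions$n), 6)
})

test_that("set membership outside the universe is rejected", {
  expect_error(overlap_randomization_test(list(c("a", "z"), c("a", "b")),
                                          c("a", "b", "c"), n_iter = 10,
                                          seed = 1),
               "subset")
  expect_error(gene_set("s", c("a", "z"), universe = c("a", "b")), "universe")
})

test_that("the randomization stream is reproducible and label-invariant", {
  uni <- paste0("g", 1:100)
  sets <- list(uni[1:30], uni[21:60])
  r1 <- overlap_randomization_test(sets, uni, n_iter = 5e3, seed = 7)
  r2 <- overlap_randomization_test(sets, uni, n_iter = 5e3, seed = 7)
  expect_equal(r1, r2)
  # relabel every gene consistently
  relab <- setNames(paste0("x", 1:100), uni)
  r3 <- overlap_randomization_test(lapply(sets, function(s) unname(relab[s])),
                                   unname(relab), n_iter = 5e3, seed = 7)
  expect_equal(r1$empirical_p, r3$empirical_p)
})
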