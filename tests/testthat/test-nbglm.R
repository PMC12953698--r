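test_that("one-factor fits with equal offsets recover exact group means", {
  cts <- as_counts(matrix(c(10, 10, 20, 20), nrow = 1),
                   gene_ids = "g1")
  meta <- two_group_meta(names(cts)[-1])
  X <- condition_design(meta, "genotype")
  fit <- fit_nb_glm(cts, X, unit_norm(cts), 0.1)
  expect_equal(unname(exp(fit$coefficients[1, ])), c(10, 20), tolerance = 1e-7)
  expect_true(all(fit$converged))
})

test_that("all-zero genes are flagged degenerate with bounded coefficients", {
  m <- rbind(c(5L, 6L, 7L, 8L), c(0L, 0L, 0L, 0L))
  cts <- as_counts(m)
  meta <- two_group_meta(names(cts)[-1])
  X <- condition_design(meta, "genotype")
  fit <- fit_nb_glm(cts, X, unit_norm(cts), 0.1)
  expect_true(fit$degenerate[2])
  expect_false(fit$degenerate[1])
  expect_true(all(fit$coefficients[2, ] <= -29))
})

test_that("the IRLS optimum beats a grid-search oracle on 2-coefficient toys", {
  set.seed(5)
  for (rep in 1:3) {
    y <- matrix(rnbinom(8, mu = rep(c(15, 40), each = 4), size = 10), nrow = 1)
    cts <- as_counts(y, "g1")
    meta <- two_group_meta(names(cts)[-1])
    X <- condition_design(meta, "genotype")
    alpha <- 0.1
    fit <- fit_nb_glm(cts, X, unit_norm(cts), alpha)
    ll_opt <- fit$loglik[1]
    grid <- seq(log(1), log(100), length.out = 101)
    ll_grid <- outer(grid, grid, Vectorize(function(b1, b2) {
      mu <- exp(as.numeric(X %*% c(b1, b2)))
      sum(dnbinom(y[1, ], size = 1 / alpha, mu = mu, log = TRUE))
    }))
    expect_gte(ll_opt + 1e-8, max(ll_grid))
  }
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(6)
  G <- 2000
  base <- rlnorm(G, log(100), 1)
  meta <- two_group_meta(paste0("s", 1:8))
  X <- condition_design(meta, "genotype")

  y_pois <- sapply(1:8, function(j) rpois(G, base))
  colnames(y_pois) <- meta$sample_id
  cts_p <- as_counts(y_pois)
  d_p <- estimate_dispersions(cts_p, X, estimate_size_factors(cts_p))
  expect_lt(median(d_p$per_gene$dispersion), 0.01)

  y_nb <- sapply(1:8, function(j) rnbinom(G, mu = base, size = 1 / 0.2))
  colnames(y_nb) <- meta$sample_id
  cts_n <- as_counts(y_nb)
  d_n <- estimate_dispersions(cts_n, X, estimate_size_factors(cts_n))
  med <- median(d_n$per_gene$dispersion)
  expect_gt(med, 0.1)
  expect_lt(med, 0.4)
  expect_true(all(d_n$per_gene$dispersion >= 0))
})

test_that("full shrinkage returns the common dispersion for every gene", {
  set.seed(7)
  m <- sapply(1:6, function(j) rnbinom(50, mu = 60, size = 10))
  cts <- as_counts(m)
  meta <- tibble::tibble(sample_id = names(cts)[-1],
                         genotype = rep(c("A", "B"), 3), fraction = "none")
  X <- condition_design(meta, "genotype")
  d <- estimate_dispersions(cts, X, estimate_size_factors(cts),
                            shrinkage_weight = 1)
  expect_equal(d$per_gene$dispersion, rep(d$common_dispersion, 50))
})

test_that("shrunk dispersions lie between gene-wise and common estimates", {
  set.seed(8)
  m <- sapply(1:8, function(j) rnbinom(200, mu = 80, size = 8))
  cts <- as_counts(m)
  meta <- two_group_meta(names(cts)[-1])
  X <- condition_design(meta, "genotype")
  d <- estimate_dispersions(cts, X, estimate_size_factors(cts))
  lo <- pmin(d$per_gene$dispersion_raw, d$common_dispersion)
  hi <- pmax(d$per_gene$dispersion_raw, d$common_dispersion)
  expect_true(all(d$per_gene$dispersion >= lo - 1e-12 &
                    d$per_gene$dispersion <= hi + 1e-12))
})

test_that("rank-deficient designs are rejected", {
  m <- matrix(rpois(40, 20), nrow = 10)
  cts <- as_counts(m)
  X <- cbind(a = rep(1, 4), b = rep(1, 4))
  rownames(X) <- colnames(m)
  expect_error(fit_nb_glm(cts, X, unit_norm(cts), 0.1), "full rank")
  expect_error(estimate_dispersions(cts, X, unit_norm(cts)), "full rank")
})

test_that("tidy and glance expose coefficients and convergence", {
  cts <- as_counts(matrix(c(10, 12, 22, 18), nrow = 1), "g1")
  meta <- two_group_meta(names(cts)[-1])
  X <- condition_design(meta, "genotype")
  fit <- fit_nb_glm(cts, X, unit_norm(cts), 0.05)
  td <- tidy(fit)
  expect_named(td, c("gene_id", "term", "estimate"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n_genes, 1)
  expect_equal(gl$n_converged, 1)
})
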