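#' One-hot condition design matrix
#'
#' Builds a samples-by-conditions indicator design from sample metadata, one
#' column per condition level (no intercept), suitable for group-means NB
#' GLM fits.
#'
#' @param metadata Sample metadata tibble with a `sample_id` column.
#' @param by Metadata column(s) defining the condition; multiple columns are
#'   pasted with `_`.
#' @param levels Optional explicit level order for the columns.
#' @return Numeric matrix, rownames sample ids, colnames condition labels.
#' @export
condition_design <- function(metadata, by = "genotype", levels = NULL) {
  missing_cols <- setdiff(by, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  lab <- do.call(paste, c(unname(metadata[by]), sep = "_"))
  lev <- levels %||% unique(lab)
  bad <- setdiff(lab, lev)
  if (length(bad)) abort(paste0("labels outside declared levels: ", paste(unique(bad), collapse = ", ")))
  X <- vapply(lev, function(l) as.numeric(lab == l), numeric(length(lab)))
  rownames(X) <- metadata$sample_id
  colnames(X) <- lev
  X
}

# NB log-likelihood per gene (rows of y); alpha scalar or per-gene
nb_loglik <- function(y, mu, alpha) {
  G <- nrow(y)
  alpha <- rep_len(alpha, G)
  ll <- numeric(G)
  pois <- alpha < 1e-10
  if (any(pois)) {
    ll[pois] <- rowSums(dpois(y[pois, , drop = FALSE],
                              lambda = mu[pois, , drop = FALSE], log = TRUE))
  }
  if (any(!pois)) {
    size <- 1 / alpha[!pois]
    ll[!pois] <- rowSums(dnbinom(y[!pois, , drop = FALSE], size = size,
                                 mu = mu[!pois, , drop = FALSE], log = TRUE))
  }
  ll
}

# NB deviance per gene (2 * (saturated ll - model ll), Poisson limit at alpha=0)
nb_deviance <- function(y, mu, alpha) {
  G <- nrow(y)
  alpha <- rep_len(alpha, G)
  ylogy <- y * log(ifelse(y > 0, y / mu, 1))
  pois <- alpha < 1e-10
  dev <- numeric(G)
  if (any(pois)) {
    d <- ylogy[pois, , drop = FALSE] -
      (y[pois, , drop = FALSE] - mu[pois, , drop = FALSE])
    dev[pois] <- 2 * rowSums(d)
  }
  if (any(!pois)) {
    a <- alpha[!pois]
    ys <- y[!pois, , drop = FALSE]
    ms <- mu[!pois, , drop = FALSE]
    d <- ylogy[!pois, , drop = FALSE] -
      (ys + 1 / a) * log((1 + a * ys) / (1 + a * ms))
    dev[!pois] <- 2 * rowSums(d)
  }
  pmax(dev, 0)
}

# Batch IRLS for NB log-link GLMs across genes.
# y: G x S counts; X: S x p design; offset: length-S log offsets;
# alpha: scalar or per-gene dispersion. Returns beta (natural log scale),
# fitted means, deviance, convergence/degeneracy flags, and the per-gene
# Fisher information blocks X'WX at the optimum.
nbglm_irls <- function(y, X, offset, alpha, maxit = 100, tol = 1e-8,
                       beta_init = NULL) {
  G <- nrow(y); S <- ncol(y); p <- ncol(X)
  if (qr(X)$rank < p) abort("design matrix is not full rank.")
  alpha <- rep_len(alpha, G)
  off <- matrix(offset, nrow = G, ncol = S, byrow = TRUE)
  cap <- 30
  degenerate <- rowSums(y) == 0
  # disjoint column supports => X'WX diagonal for any diagonal W (one-hot designs)
  xtx_cross <- crossprod(abs(X))
  diag_path <- all(xtx_cross[upper.tri(xtx_cross)] == 0)

  if (is.null(beta_init)) {
    z0 <- log(pmax(y, 0.5)) - off
    beta <- t(qr.solve(X, t(z0)))
  } else {
    beta <- beta_init
  }
  beta <- pmin(pmax(beta, -cap), cap)

  eta_of <- function(b) off + tcrossprod(b, X)
  dev_of <- function(b) {
    mu <- exp(pmin(eta_of(b), cap))
    nb_deviance(y, pmax(mu, 1e-10), alpha)
  }
  dev <- dev_of(beta)
  converged <- rep(FALSE, G)
  converged[degenerate] <- TRUE
  beta[degenerate, ] <- -cap

  xx_pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  active <- which(!converged)
  iter <- 0
  while (length(active) && iter < maxit) {
    iter <- iter + 1
    ba <- beta[active, , drop = FALSE]
    ya <- y[active, , drop = FALSE]
    ofa <- off[active, , drop = FALSE]
    aa <- alpha[active]
    eta <- pmin(ofa + tcrossprod(ba, X), cap)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + mu * aa)
    z <- (eta - ofa) + (ya - mu) / mu
    wz <- w * z
    bvec <- wz %*% X                        # G x p
    if (diag_path) {
      Adiag <- w %*% (X * X) + 1e-12
      beta_new <- bvec / Adiag
    } else {
      Aflat <- matrix(0, length(active), nrow(xx_pairs))
      for (k in seq_len(nrow(xx_pairs))) {
        j <- xx_pairs[k, 1]; l <- xx_pairs[k, 2]
        Aflat[, k] <- w %*% (X[, j] * X[, l])
      }
      beta_new <- ba
      for (g in seq_along(active)) {
        A <- matrix(0, p, p)
        A[upper.tri(A, diag = TRUE)] <- Aflat[g, ]
        A <- A + t(A) - diag(diag(A), p)
        diag(A) <- diag(A) + 1e-12
        beta_new[g, ] <- tryCatch(solve(A, bvec[g, ]),
                                  error = function(e) ba[g, ])
      }
    }
    beta_new <- pmin(pmax(beta_new, -cap), cap)
    # step-halving where deviance worsened
    mu_new <- pmax(exp(pmin(ofa + tcrossprod(beta_new, X), cap)), 1e-10)
    dev_new <- nb_deviance(ya, mu_new, aa)
    worse <- which(dev_new > dev[active] + 1e-10)
    halvings <- 0
    while (length(worse) && halvings < 12) {
      halvings <- halvings + 1
      beta_new[worse, ] <- (beta_new[worse, , drop = FALSE] +
                              ba[worse, , drop = FALSE]) / 2
      mu_w <- pmax(exp(pmin(ofa[worse, , drop = FALSE] +
                              tcrossprod(beta_new[worse, , drop = FALSE], X), cap)), 1e-10)
      dev_new[worse] <- nb_deviance(ya[worse, , drop = FALSE], mu_w, aa[worse])
      worse <- worse[dev_new[worse] > dev[active][worse] + 1e-10]
    }
    done <- abs(dev_new - dev[active]) / (abs(dev_new) + 0.1) < tol
    beta[active, ] <- beta_new
    dev[active] <- dev_new
    converged[active[done]] <- TRUE
    active <- active[!done]
  }

  eta <- pmin(eta_of(beta), cap)
  mu <- pmax(exp(eta), 1e-10)
  w <- mu / (1 + mu * alpha)
  info <- array(0, dim = c(G, p, p))
  for (k in seq_len(nrow(xx_pairs))) {
    j <- xx_pairs[k, 1]; l <- xx_pairs[k, 2]
    v <- as.numeric(w %*% (X[, j] * X[, l]))
    info[, j, l] <- v
    info[, l, j] <- v
  }
  list(beta = beta, mu = mu, deviance = nb_deviance(y, mu, alpha),
       loglik = nb_loglik(y, mu, alpha), converged = converged,
       degenerate = degenerate, info = info, iterations = iter)
}

#' Fit per-gene negative-binomial GLMs
#'
#' Fits one NB GLM per gene with a log link, a shared design matrix and
#' log(library size x normalization factor) offsets, by iteratively
#' reweighted least squares with deviance-based step halving. Coefficients
#' are on the natural-log scale. Genes that fail to converge within
#' `maxit` iterations are flagged, not dropped; all-zero genes are flagged
#' degenerate with coefficients at the lower bound.
#'
#' @param counts Count tibble.
#' @param design Numeric design matrix (samples x coefficients) with rownames
#'   matching the count columns, e.g. from [condition_design()].
#' @param norm Normalization-factor tibble from [estimate_size_factors()] or
#'   [estimate_tmm_factors()].
#' @param dispersions Dispersion estimates from [estimate_dispersions()], or
#'   a numeric scalar/per-gene vector.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return An object of class `nbglm_fit` with elements `gene_id`, `design`,
#'   `coefficients`, `fitted`, `deviance`, `loglik`, `converged`,
#'   `degenerate`, `dispersion`, `offsets`.
#' @export
fit_nb_glm <- function(counts, design, norm, dispersions,
                       maxit = 100, tol = 1e-8) {
  validate_counts(counts)
  y <- counts_matrix(counts)
  design <- align_design(design, colnames(y))
  offset <- norm_offsets(counts, norm)
  alpha <- dispersion_vector(dispersions, rownames(y))
  fit <- nbglm_irls(y, design, offset, alpha, maxit = maxit, tol = tol)
  dimnames(fit$beta) <- list(rownames(y), colnames(design))
  structure(list(gene_id = rownames(y), design = design,
                 coefficients = fit$beta, fitted = fit$mu,
                 deviance = fit$deviance, loglik = fit$loglik,
                 converged = fit$converged, degenerate = fit$degenerate,
                 info = fit$info, dispersion = alpha, offsets = offset),
            class = "nbglm_fit")
}

align_design <- function(design, sample_ids) {
  if (!is.matrix(design)) abort("`design` must be a numeric matrix.")
  if (!is.null(rownames(design))) {
    missing <- setdiff(sample_ids, rownames(design))
    if (length(missing)) {
      abort(paste0("design lacks rows for sample(s): ", paste(missing, collapse = ", ")))
    }
    design <- design[sample_ids, , drop = FALSE]
  } else if (nrow(design) != length(sample_ids)) {
    abort("design row count does not match sample count.")
  }
  design
}

dispersion_vector <- function(dispersions, gene_ids) {
  if (inherits(dispersions, "gc2mat_dispersions")) {
    d <- setNames(dispersions$per_gene$dispersion, dispersions$per_gene$gene_id)
    out <- d[gene_ids]
    if (anyNA(out)) abort("dispersion estimates missing for some genes.")
    return(unname(out))
  }
  if (!is.numeric(dispersions)) abort("`dispersions` must be numeric or an estimate object.")
  if (any(dispersions < 0)) abort("dispersions must be >= 0.")
  rep_len(dispersions, length(gene_ids))
}

#' @export
print.nbglm_fit <- function(x, ...) {
  cat("Negative-binomial GLM fits\n")
  cat("  genes:       ", length(x$gene_id), "\n")
  cat("  coefficients:", paste(colnames(x$design), collapse = ", "), "\n")
  cat("  converged:   ", sum(x$converged), "/", length(x$converged), "\n")
  invisible(x)
}

#' @rdname fit_nb_glm
#' @param x An `nbglm_fit` object.
#' @param ... Unused.
#' @method tidy nbglm_fit
#' @export
tidy.nbglm_fit <- function(x, ...) {
  co <- as_tibble(as.data.frame(x$coefficients))
  co$gene_id <- x$gene_id
  out <- tidyr::pivot_longer(co, -"gene_id", names_to = "term",
                             values_to = "estimate")
  dplyr::arrange(out, match(.data$gene_id, x$gene_id))
}

#' @rdname fit_nb_glm
#' @method glance nbglm_fit
#' @export
glance.nbglm_fit <- function(x, ...) {
  tibble(n_genes = length(x$gene_id),
         n_coefficients = ncol(x$design),
         n_converged = sum(x$converged),
         n_degenerate = sum(x$degenerate),
         median_dispersion = median(x$dispersion),
         total_deviance = sum(x$deviance))
}
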