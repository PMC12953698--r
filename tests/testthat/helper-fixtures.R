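# matrix -> count tibble with gene ids
as_counts <- function(m, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, gene_id = gene_ids, .before = 1)
}

# normalization factors making all offsets zero (factor = 1 / library size)
unit_norm <- function(counts) {
  m <- as.matrix(counts[, -1])
  tibble::tibble(sample_id = colnames(m), factor = 1 / colSums(m),
                 method = "tmm", reference_sample = colnames(m)[1])
}

two_group_meta <- function(sample_ids, labels = c("A", "B")) {
  tibble::tibble(sample_id = sample_ids,
                 genotype = rep(labels, each = length(sample_ids) / 2),
                 fraction = "none", stage = "whole_ovary",
                 replicate = rep(seq_len(length(sample_ids) / 2), 2))
}

# independently coded TMM reference: straight transcription of the
# doubly-trimmed weighted mean of M-values, structured around explicit
# sorting rather than ranks
reference_tmm <- function(m, logratio_trim = 0.3, abundance_trim = 0.05) {
  lib <- colSums(m)
  uq <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(m)), function(j) {
    o <- m[, j]; r <- m[, ref]
    keep0 <- o > 0 & r > 0
    o <- o[keep0]; r <- r[keep0]
    M <- log2(o / lib[j]) - log2(r / lib[ref])
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    v <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  })
  f / exp(mean(log(f)))
}

# independently coded BH step-up, straight from the definition
reference_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# exact distribution of the overlap of two uniform random subsets by
# exhaustive enumeration (small universes only)
enumerate_overlap_p <- function(N, n1, n2, obs) {
  u <- seq_len(N)
  sets1 <- utils::combn(u, n1, simplify = FALSE)
  sets2 <- utils::combn(u, n2, simplify = FALSE)
  hits <- 0; total <- 0
  for (a in sets1) for (b in sets2) {
    total <- total + 1
    if (length(intersect(a, b)) >= obs) hits <- hits + 1
  }
  hits / total
}
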