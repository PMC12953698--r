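#' Gene-set construction and I/O
#'
#' A gene set is a named list with unique members. Sets are read and written
#' as newline-delimited text files.
#'
#' @param name Set name.
#' @param members Character vector of gene ids (de-duplicated).
#' @param universe Optional universe; membership outside it is an error.
#' @return A `gene_set` list with elements `name` and `members`.
#' @export
gene_set <- function(name, members, universe = NULL) {
  members <- unique(as.character(members))
  if (!is.null(universe)) {
    out <- setdiff(members, universe)
    if (length(out)) {
      abort(paste0("set '", name, "' has members outside the universe, e.g. ",
                   paste(head(out, 3), collapse = ", ")))
    }
  }
  structure(list(name = name, members = members), class = "gene_set")
}

#' @rdname gene_set
#' @param path Newline-delimited text file of gene ids.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  gene_set(name, readLines(path, warn = FALSE))
}

set_members <- function(x) if (inherits(x, "gene_set")) x$members else unique(as.character(x))

#' k-way intersection of gene sets
#'
#' @param sets List of two or more [gene_set()]s (or character vectors).
#' @return List with `n` (intersection size) and `members`.
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2) abort("need at least two sets.")
  members <- Reduce(intersect, lapply(sets, set_members))
  list(n = length(members), members = members)
}

#' Empirical randomization test for multi-set overlap
#'
#' Assesses whether the observed k-way intersection is larger than expected
#' for independent uniformly drawn sets of the same sizes from the universe.
#' The intersection size of k independent uniform fixed-size subsets follows
#' a chain of hypergeometric draws (the overlap of each new random set with
#' the running intersection), which is sampled directly; this is
#' distributionally identical to drawing the sets and intersecting them.
#' Significance uses the add-one estimator
#' `(exceedances + 1) / (iterations + 1)`, with exceedance defined as a
#' randomized intersection `>=` the observed one.
#'
#' @param sets List of [gene_set()]s (or character vectors), all within the
#'   universe.
#' @param universe [gene_set()] or character vector of eligible genes.
#' @param n_iter Number of randomization iterations (default 1e6).
#' @param seed Integer seed making the test reproducible.
#' @return Tibble with `observed_intersection`, `n_iterations`,
#'   `n_exceedances`, `empirical_p`, `expected_intersection` (Monte-Carlo
#'   mean) and `shared_fraction` (core / union).
#' @export
overlap_randomization_test <- function(sets, universe, n_iter = 1e6, seed = 1L) {
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  uni <- set_members(universe)
  N <- length(uni)
  member_list <- lapply(sets, set_members)
  for (i in seq_along(member_list)) {
    out <- setdiff(member_list[[i]], uni)
    if (length(out)) abort("all sets must be subsets of the universe.")
  }
  sizes <- lengths(member_list)
  obs <- intersect_sets(member_list)$n

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  inter <- rep.int(sizes[1], n_iter)
  for (k in seq_along(sizes)[-1]) {
    inter <- rhyper(n_iter, m = inter, n = N - inter, k = sizes[k])
  }
  exceed <- sum(inter >= obs)

  union_n <- length(Reduce(union, member_list))
  tibble(observed_intersection = obs,
         n_iterations = as.integer(n_iter),
         n_exceedances = exceed,
         empirical_p = (exceed + 1) / (n_iter + 1),
         expected_intersection = mean(inter),
         shared_fraction = if (union_n > 0) obs / union_n else 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= observed)` where `X` is the overlap of two uniformly drawn sets
#' of the given sizes from the universe.
#'
#' @param set_a,set_b [gene_set()]s or character vectors.
#' @param universe Universe of eligible genes.
#' @return Tibble with `observed_intersection`, set sizes, universe size and
#'   `p_value`.
#' @export
hypergeometric_overlap_test <- function(set_a, set_b, universe) {
  uni <- set_members(universe)
  if (!length(uni)) abort("universe is empty.")
  a <- set_members(set_a); b <- set_members(set_b)
  if (length(setdiff(a, uni)) || length(setdiff(b, uni))) {
    abort("both sets must be subsets of the universe.")
  }
  obs <- length(intersect(a, b))
  p <- phyper(obs - 1, m = length(a), n = length(uni) - length(a),
              k = length(b), lower.tail = FALSE)
  tibble(observed_intersection = obs, size_a = length(a),
         size_b = length(b), universe_size = length(uni), p_value = p)
}

#' Venn-region sizes and shared fraction
#'
#' Decomposes the union of k sets into its 2^k - 1 exclusive regions
#' (labelled by membership bitmask, e.g. `"110"` = in sets 1 and 2 only)
#' and reports the core-intersection fraction of the union.
#'
#' @param sets List of >= 2 [gene_set()]s or character vectors.
#' @return List with `regions` (tibble: `region`, `sets`, `n`, `fraction`)
#'   and `core_fraction` (= |core| / |union|).
#' @export
overlap_fraction_summary <- function(sets) {
  if (length(sets) < 2) abort("need at least two sets.")
  member_list <- lapply(sets, set_members)
  set_names <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s$name else paste0("set", i)
  }, character(1))
  all_genes <- Reduce(union, member_list)
  k <- length(member_list)
  mask <- vapply(member_list, function(m) all_genes %in% m, logical(length(all_genes)))
  mask <- matrix(mask, ncol = k)
  key <- apply(mask, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(key)
  regions <- tibble(
    region = names(counts),
    sets = vapply(names(counts), function(kk) {
      paste(set_names[strsplit(kk, "")[[1]] == "1"], collapse = "&")
    }, character(1)),
    n = as.integer(counts),
    fraction = as.integer(counts) / length(all_genes))
  core <- sum(rowSums(mask) == k)
  list(regions = regions,
       core_fraction = if (length(all_genes)) core / length(all_genes) else 0)
}
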