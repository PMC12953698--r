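#' Binned genomic signal tracks
#'
#' A binned track is a tibble with columns `chrom`, `start`, `end`, `value`
#' whose bins tile each chromosome contiguously with a fixed width
#' (0-based, half-open coordinates). Attributes record the bin width, the
#' total read count and the normalization state (`"raw"` or `"rpkm"`).
#'
#' @param df Tibble with `chrom`, `start`, `end`, `value` (value >= 0).
#' @param bin_width Bin width in bp.
#' @param total_reads Total reads behind the track (defaults to the value
#'   sum for raw tracks).
#' @param normalization `"raw"` or `"rpkm"`.
#' @return A `binned_track` tibble.
#' @export
binned_track <- function(df, bin_width, total_reads = NULL,
                         normalization = c("raw", "rpkm")) {
  normalization <- match.arg(normalization)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(df))) abort("track needs columns chrom, start, end, value.")
  if (any(df$value < 0)) abort("track values must be >= 0.")
  df <- dplyr::arrange(df, .data$chrom, .data$start)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (any(d$end - d$start != bin_width)) {
      abort(paste0("bins on ", ch, " are not all ", bin_width, " bp wide."))
    }
    if (d$start[1] != 0 || (nrow(d) > 1 && any(diff(d$start) != bin_width))) {
      abort(paste0("bins on ", ch, " do not tile the chromosome contiguously from 0."))
    }
  }
  if (is.null(total_reads)) {
    total_reads <- if (normalization == "raw") sum(df$value) else NA_real_
  }
  structure(as_tibble(df), class = c("binned_track", class(tibble())),
            bin_width = bin_width, total_reads = total_reads,
            normalization = normalization)
}

track_bin_width <- function(track) attr(track, "bin_width")
track_total_reads <- function(track) attr(track, "total_reads")

#' Read / write bedGraph tracks
#'
#' bedGraph is 4-column (`chrom`, `start`, `end`, `value`), 0-based
#' half-open; bins absent from the file are filled with 0 so the returned
#' track tiles each chromosome.
#'
#' @param path File path.
#' @param bin_width Bin width of the track.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the largest `end` seen per chromosome.
#' @param total_reads Total read count (defaults to the value sum).
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, bin_width, chrom_lengths = NULL,
                          total_reads = NULL) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         comment = "#", show_col_types = FALSE,
                         col_types = "ciid")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(raw$end, raw$chrom, max)
  }
  full <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    n_bins <- ceiling(chrom_lengths[[ch]] / bin_width)
    tibble(chrom = ch, start = (seq_len(n_bins) - 1) * bin_width,
           end = seq_len(n_bins) * bin_width)
  })
  full <- dplyr::left_join(full, raw, by = c("chrom", "start", "end"))
  full$value[is.na(full$value)] <- 0
  binned_track(full, bin_width, total_reads = total_reads)
}

#' @rdname read_bedgraph
#' @param track A [binned_track()].
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads BED3/BED6 into a tibble (`chrom`, `start`, `end`, and `name`,
#' `score`, `strand` when present), keeping 0-based half-open coordinates.
#'
#' @param path File path.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw) <- cols[seq_len(min(ncol(raw), 6))]
  as_tibble(raw)
}

#' Gene interval table with strand-aware TSS
#'
#' @param df Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @return The tibble with a `tss` column (`start` on `+`, `end - 1` on `-`).
#' @export
gene_intervals <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    abort("gene intervals need columns gene_id, chrom, start, end, strand.")
  }
  if (any(df$start >= df$end)) abort("gene intervals must satisfy start < end.")
  if (any(!df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  as_tibble(df)
}

#' RPKM-normalize a binned track
#'
#' `rpkm = raw * 1e9 / (total_reads * bin_width)`.
#'
#' @param raw A raw [binned_track()].
#' @return The track with values in RPKM units.
#' @export
rpkm_bin_track <- function(raw) {
  if (attr(raw, "normalization") == "rpkm") return(raw)
  total <- track_total_reads(raw)
  if (is.null(total) || is.na(total) || total <= 0) {
    abort("total_reads must be positive for RPKM normalization.")
  }
  out <- raw
  out$value <- raw$value * 1e9 / (total * track_bin_width(raw))
  attr(out, "normalization") <- "rpkm"
  out
}

#' Binarize a raw track against a Poisson background
#'
#' A bin is called bound when its count is improbably high under a Poisson
#' background whose rate is the genome-wide mean count per bin:
#' upper-tail `P(X >= x) < p_threshold`.
#'
#' @param track Raw [binned_track()] of counts.
#' @param p_threshold Poisson upper-tail threshold (default 1e-4).
#' @return Tibble `chrom`, `start`, `end`, `bound` (logical).
#' @export
binarize_track <- function(track, p_threshold = 1e-4) {
  rate <- mean(track$value)
  p <- ppois(track$value - 1, lambda = rate, lower.tail = FALSE)
  bound <- if (rate == 0) rep(FALSE, nrow(track)) else p < p_threshold
  tibble(chrom = track$chrom, start = track$start, end = track$end,
         bound = bound)
}

# per-chromosome value vectors for fast interval means
track_by_chrom <- function(track) {
  split(track$value, track$chrom)
}

# overlap-weighted mean of a uniformly binned signal over [a, b); intervals
# are clipped to the chromosome
interval_mean <- function(values, bin_width, a, b) {
  chrom_len <- length(values) * bin_width
  a <- max(a, 0); b <- min(b, chrom_len)
  if (b <= a) return(0)
  i0 <- floor(a / bin_width) + 1
  i1 <- floor((b - 1e-9) / bin_width) + 1
  idx <- i0:i1
  ov <- pmin(b, idx * bin_width) - pmax(a, (idx - 1) * bin_width)
  sum(values[idx] * ov) / (b - a)
}

#' Promoter and gene-body mark levels
#'
#' Overlap-weighted mean track signal over each gene's promoter window
#' (strand-aware around the TSS) and gene body. Intervals extending past
#' chromosome ends are clipped with a warning.
#'
#' @param track A [binned_track()] (raw or RPKM).
#' @param genes [gene_intervals()] tibble.
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS in bp (default 500/500).
#' @return Tibble `gene_id`, `promoter_mean`, `body_mean`.
#' @export
quantify_gene_marks <- function(track, genes, promoter_up = 500,
                                promoter_down = 500) {
  genes <- gene_intervals(genes)
  w <- track_bin_width(track)
  vals <- track_by_chrom(track)
  missing <- setdiff(unique(genes$chrom), names(vals))
  if (length(missing)) {
    abort(paste0("gene(s) on chromosome absent from track: ",
                 paste(missing, collapse = ", ")))
  }
  clipped <- FALSE
  res <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    v <- vals[[g$chrom]]
    chrom_len <- length(v) * w
    if (g$strand == "+") {
      pa <- g$tss - promoter_up; pb <- g$tss + promoter_down
    } else {
      pa <- g$tss - promoter_down + 1; pb <- g$tss + promoter_up + 1
    }
    if (pa < 0 || pb > chrom_len || g$start < 0 || g$end > chrom_len) {
      clipped <<- TRUE
    }
    tibble(gene_id = g$gene_id,
           promoter_mean = interval_mean(v, w, pa, pb),
           body_mean = interval_mean(v, w, g$start, g$end))
  })
  if (clipped) warn("some intervals extended past chromosome ends and were clipped.")
  res
}

#' Differential mark calls per gene
#'
#' Compares knockdown to wild-type mark levels with a pseudocounted log2
#' ratio: `loss` when the ratio drops below `-lfc_threshold` and the
#' wild-type level exceeds background, `gain` for the mirror case,
#' `below_background` when both conditions sit under background, `stable`
#' otherwise.
#'
#' @param wt,kd Quantification tibbles from [quantify_gene_marks()] over the
#'   same genes.
#' @param lfc_threshold Absolute log2-ratio threshold (default 1).
#' @param background Background signal level (same units as the tracks;
#'   typically the genome-wide median).
#' @param pseudocount Added to both conditions before the ratio (default 1).
#' @param region `"promoter"` (default) or `"body"`: which mean drives the
#'   ratio and call.
#' @return `mark_table` tibble: `gene_id`, promoter/body means per
#'   condition, `log2_ratio`, `call`.
#' @export
differential_mark_call <- function(wt, kd, lfc_threshold = 1, background = 0,
                                   pseudocount = 1,
                                   region = c("promoter", "body")) {
  region <- match.arg(region)
  if (!identical(wt$gene_id, kd$gene_id)) {
    abort("wt and kd quantifications must cover the same genes in the same order.")
  }
  wv <- if (region == "promoter") wt$promoter_mean else wt$body_mean
  kv <- if (region == "promoter") kd$promoter_mean else kd$body_mean
  lr <- log2((kv + pseudocount) / (wv + pseudocount))
  call <- dplyr::case_when(
    lr <= -lfc_threshold & wv > background ~ "loss",
    lr >= lfc_threshold & kv > background ~ "gain",
    wv <= background & kv <= background ~ "below_background",
    TRUE ~ "stable")
  structure(tibble(gene_id = wt$gene_id,
                   wt_promoter = wt$promoter_mean, kd_promoter = kd$promoter_mean,
                   wt_body = wt$body_mean, kd_body = kd$body_mean,
                   log2_ratio = lr, call = call),
            class = c("mark_table", class(tibble())),
            lfc_threshold = lfc_threshold, background = background,
            region = region)
}

#' Differential marks straight from a pair of tracks
#'
#' Convenience wrapper: RPKM-normalizes both tracks, quantifies promoter and
#' body levels, sets the background to the genome-wide median RPKM of the
#' wild-type track, and calls gains and losses. The pseudocount is the RPKM
#' equivalent of one read per bin in the wild-type library, the classic
#' add-one-read damping of log ratios at low coverage.
#'
#' @param wt_track,kd_track Raw [binned_track()]s.
#' @param genes [gene_intervals()] tibble.
#' @inheritParams differential_mark_call
#' @inheritParams quantify_gene_marks
#' @return A `mark_table` (see [differential_mark_call()]).
#' @export
differential_marks <- function(wt_track, kd_track, genes, lfc_threshold = 1,
                               pseudocount = NULL, region = "promoter",
                               promoter_up = 500, promoter_down = 500) {
  wt_r <- rpkm_bin_track(wt_track)
  kd_r <- rpkm_bin_track(kd_track)
  bg <- median(wt_r$value)
  if (is.null(pseudocount)) {
    pseudocount <- 1e9 / (track_total_reads(wt_track) * track_bin_width(wt_track))
  }
  differential_mark_call(
    quantify_gene_marks(wt_r, genes, promoter_up, promoter_down),
    quantify_gene_marks(kd_r, genes, promoter_up, promoter_down),
    lfc_threshold = lfc_threshold, background = bg,
    pseudocount = pseudocount, region = region)
}

#' Genome-wide redistribution of bound bins
#'
#' Cross-classifies the binarized wild-type and knockdown tracks bin by bin.
#' The redistribution index is `min(n_lost, n_gained) / max(n_lost,
#' n_gained)` (0 when nothing is lost or gained): 1 means every loss is
#' balanced by a gain elsewhere.
#'
#' @param wt_bound,kd_bound Binarizations from [binarize_track()] on the
#'   same binning.
#' @return Tibble with `n_lost`, `n_gained`, `n_stable_bound`,
#'   `n_stable_unbound`, `redistribution_index`.
#' @export
redistribution_summary <- function(wt_bound, kd_bound) {
  same <- identical(wt_bound$chrom, kd_bound$chrom) &&
    identical(wt_bound$start, kd_bound$start) &&
    identical(wt_bound$end, kd_bound$end)
  if (!same) abort("wt and kd binarizations use different binnings.")
  w <- wt_bound$bound; k <- kd_bound$bound
  n_lost <- sum(w & !k)
  n_gained <- sum(!w & k)
  tibble(n_lost = n_lost, n_gained = n_gained,
         n_stable_bound = sum(w & k), n_stable_unbound = sum(!w & !k),
         redistribution_index = if (n_lost == 0 || n_gained == 0) 0 else
           min(n_lost, n_gained) / max(n_lost, n_gained))
}

# paint per-gene values onto a uniform track (mean over overlapping genes)
paint_value_track <- function(genes, values, chrom_lengths, paint_bin = 100) {
  v <- setNames(values$log2fc, values$gene_id)[genes$gene_id]
  v[is.na(v)] <- 0
  full <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    n_bins <- ceiling(chrom_lengths[[ch]] / paint_bin)
    acc <- numeric(n_bins); cnt <- numeric(n_bins)
    idx <- which(genes$chrom == ch)
    for (i in idx) {
      b0 <- floor(genes$start[i] / paint_bin) + 1
      b1 <- min(floor((genes$end[i] - 1) / paint_bin) + 1, n_bins)
      if (b1 < b0) next
      acc[b0:b1] <- acc[b0:b1] + v[i]
      cnt[b0:b1] <- cnt[b0:b1] + 1
    }
    tibble(chrom = ch, start = (seq_len(n_bins) - 1) * paint_bin,
           end = seq_len(n_bins) * paint_bin,
           value = ifelse(cnt > 0, acc / pmax(cnt, 1), 0))
  })
  structure(as_tibble(full), class = c("binned_track", class(tibble())),
            bin_width = paint_bin, total_reads = NA_real_,
            normalization = "raw")
}

#' Meta-region matrix over TADs or genes
#'
#' Samples a signal over each region as fixed-width upstream flank bins, a
#' body rescaled to a fixed number of bins, and downstream flank bins
#' (scale-regions layout, default 3 kb flanks). When no track is supplied,
#' the per-gene `log2fc` values are first painted onto the genome so the
#' matrix shows expression change around each region. Rows are clustered
#' into `upregulated` / `nontarget` / `downregulated` and sorted by
#' decreasing `log2fc` within cluster.
#'
#' @param values Tibble with `gene_id`, `log2fc` and optionally `class`
#'   (`up`/`down`/other as from [run_de_comparison()]).
#' @param regions Region tibble (`chrom`, `start`, `end`, plus `gene_id` for
#'   gene regions) — TAD intervals or gene intervals.
#' @param track Optional [binned_track()] sampled over the regions; if
#'   `NULL`, `genes` must be given and the painted log2FC signal is used.
#' @param genes [gene_intervals()] tibble (needed to paint log2FC and for
#'   the within-TAD fraction).
#' @param flank Flank size in bp either side (default 3000).
#' @param flank_bins,body_bins Number of flank and scaled-body bins.
#' @param paint_bin Bin width used when painting log2FC onto the genome.
#' @return `metaregion_matrix` object: `matrix` (rows sorted), `rows`
#'   (tibble `region_id`, `log2fc`, `cluster`), `within_tad_fraction`
#'   (fraction of up/down genes whose midpoint lies inside a region;
#'   `NA` without `genes`), and the layout parameters.
#' @export
tad_metaregion_matrix <- function(values, regions, track = NULL, genes = NULL,
                                  flank = 3000, flank_bins = 30,
                                  body_bins = 100, paint_bin = 100) {
  if (is.null(track)) {
    if (is.null(genes)) abort("supply either a track or gene intervals to paint.")
    genes <- gene_intervals(genes)
    chrom_lengths <- tapply(c(genes$end, regions$end + flank),
                            c(genes$chrom, regions$chrom), max)
    track <- paint_value_track(genes, values, as.list(chrom_lengths), paint_bin)
  }
  w <- track_bin_width(track)
  vals <- track_by_chrom(track)
  missing <- setdiff(unique(regions$chrom), names(vals))
  if (length(missing)) {
    abort(paste0("region(s) on chromosome absent from track: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(regions$end - regions$start < w)) {
    warn("region(s) shorter than one bin; their body collapses to a single bin.")
  }
  ncol_total <- 2L * flank_bins + body_bins
  mat <- matrix(0, nrow(regions), ncol_total)
  for (i in seq_len(nrow(regions))) {
    v <- vals[[regions$chrom[i]]]
    a <- regions$start[i]; b <- regions$end[i]
    up_edges <- seq(a - flank, a, length.out = flank_bins + 1)
    body_edges <- seq(a, b, length.out = body_bins + 1)
    dn_edges <- seq(b, b + flank, length.out = flank_bins + 1)
    edges <- cbind(c(up_edges[-length(up_edges)], body_edges[-length(body_edges)],
                     dn_edges[-length(dn_edges)]),
                   c(up_edges[-1], body_edges[-1], dn_edges[-1]))
    mat[i, ] <- vapply(seq_len(ncol_total), function(j) {
      interval_mean(v, w, edges[j, 1], edges[j, 2])
    }, numeric(1))
  }

  region_id <- if ("gene_id" %in% names(regions)) regions$gene_id else
    if ("tad_id" %in% names(regions)) regions$tad_id else
      paste0("region", seq_len(nrow(regions)))
  body_cols <- (flank_bins + 1):(flank_bins + body_bins)
  if ("gene_id" %in% names(regions) && all(region_id %in% values$gene_id)) {
    rows_fc <- setNames(values$log2fc, values$gene_id)[region_id]
    cls <- if ("class" %in% names(values)) {
      setNames(values$class, values$gene_id)[region_id]
    } else rep(NA_character_, length(region_id))
  } else {
    rows_fc <- rowMeans(mat[, body_cols, drop = FALSE])
    cls <- rep(NA_character_, length(region_id))
  }
  cluster <- dplyr::case_when(
    !is.na(cls) & cls == "up" ~ "upregulated",
    !is.na(cls) & cls == "down" ~ "downregulated",
    is.na(cls) & rows_fc > 0.5 ~ "upregulated",
    is.na(cls) & rows_fc < -0.5 ~ "downregulated",
    TRUE ~ "nontarget")
  rows <- tibble(region_id = region_id, log2fc = unname(rows_fc),
                 cluster = factor(cluster, levels = c("upregulated",
                                                      "nontarget",
                                                      "downregulated")))
  ord <- order(rows$cluster, -rows$log2fc)
  rows <- rows[ord, ]
  mat <- mat[ord, , drop = FALSE]
  rownames(mat) <- rows$region_id

  within_frac <- NA_real_
  per_gene_inside <- NULL
  if (!is.null(genes)) {
    inside <- within_tad_indicator(genes, regions)
    per_gene_inside <- inside
    de <- values$gene_id[values$class %in% c("up", "down")]
    de <- intersect(de, inside$gene_id)
    if (length(de)) {
      within_frac <- mean(inside$inside_tad[match(de, inside$gene_id)])
    }
  }
  structure(list(matrix = mat, rows = rows,
                 within_tad_fraction = within_frac,
                 gene_tad_membership = per_gene_inside,
                 flank = flank, flank_bins = flank_bins,
                 body_bins = body_bins),
            class = "metaregion_matrix")
}

#' Gene midpoint membership in TADs
#'
#' @param genes [gene_intervals()] tibble.
#' @param tads Interval tibble (`chrom`, `start`, `end`).
#' @return Tibble `gene_id`, `inside_tad` (logical).
#' @export
within_tad_indicator <- function(genes, tads) {
  mid <- (genes$start + genes$end) / 2
  inside <- vapply(seq_len(nrow(genes)), function(i) {
    any(tads$chrom == genes$chrom[i] & tads$start <= mid[i] & mid[i] < tads$end)
  }, logical(1))
  tibble(gene_id = genes$gene_id, inside_tad = inside)
}

#' @export
print.metaregion_matrix <- function(x, ...) {
  cat("Meta-region matrix: ", nrow(x$matrix), " regions x ", ncol(x$matrix),
      " bins (", x$flank_bins, " flank + ", x$body_bins, " body + ",
      x$flank_bins, " flank)\n", sep = "")
  print(table(x$rows$cluster))
  if (!is.na(x$within_tad_fraction)) {
    cat("fraction of DE genes inside regions:",
        signif(x$within_tad_fraction, 4), "\n")
  }
  invisible(x)
}

#' @rdname tad_metaregion_matrix
#' @param x A `metaregion_matrix`.
#' @param ... Unused.
#' @method tidy metaregion_matrix
#' @export
tidy.metaregion_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$matrix))
  names(out) <- paste0("bin", seq_len(ncol(x$matrix)))
  dplyr::bind_cols(x$rows, out)
}
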