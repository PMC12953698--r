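#' Simulation configuration
#'
#' Parameters for the synthetic-data generators. Counts are negative
#' binomial with variance `mu + dispersion * mu^2`; baseline gene means are
#' log-normal. Defaults mirror a two-replicate bulk ovary RNA-seq design
#' with a planted germ-cell cohort upregulated in knockdowns, a smaller
#' maternal cohort downregulated, a translational-efficiency cohort for the
#' polysome design, TOP/non-TOP 5' termini with CAGE profiles peaked at the
#' planted TSS, and promoter-peaked mark tracks with designed loss and gain
#' cohorts over a TAD-carrying toy genome.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per condition.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   gene means (counts per library).
#' @param dispersion NB dispersion (scalar).
#' @param genotypes Genotype labels; the first is the control.
#' @param germ_cohort_size,germ_effect_log2fc Size and knockdown log2
#'   fold-change of the germ-cell cohort (up in KD).
#' @param maternal_cohort_size,maternal_effect_log2fc Size and effect of the
#'   maternal cohort (down in KD).
#' @param te_cohort_size,delta_te_log2 Size and true log2 TE change of the
#'   translational cohort (half up, half down).
#' @param te_base_sd SD of gene-level baseline log2 TE (shared across
#'   genotypes, cancels in the interaction).
#' @param polysome_scale Fraction-wide multiplicative scaling of polysome
#'   libraries (exercises normalization).
#' @param stage_fold Fold separating early-stage and whole-ovary expression
#'   for the stage cohorts.
#' @param top_fraction Fraction of transcripts given a TOP 5' terminus.
#' @param top_run_range Pyrimidine run-length range for TOP termini.
#' @param cage_reads CAGE reads per transcript profile.
#' @param cage_window Half-width of the CAGE window around the TSS.
#' @param bin_width,genome_length Mark-track bin width and toy chromosome
#'   length (bp).
#' @param background_rate Poisson background rate per bin of the mark
#'   tracks.
#' @param peak_rate Promoter peak rate per bin (added to background).
#' @param kd_reduction Factor by which knockdown reduces loss-cohort peaks.
#' @param loss_cohort_size,gain_cohort_size Mark-change cohort sizes.
#' @param n_marked_genes Number of genes on the toy chromosome.
#' @param n_tads,tad_size_range Number of TADs and their size range (bp).
#' @param seed Integer seed; every generator is a pure function of the
#'   config including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates = 2,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       dispersion = 0.05,
                       genotypes = c("nosGAL4", "zfrp8_GKD", "mio_GKD", "raptor_GKD"),
                       germ_cohort_size = 100,
                       germ_effect_log2fc = 2,
                       maternal_cohort_size = 50,
                       maternal_effect_log2fc = -2,
                       te_cohort_size = 100,
                       delta_te_log2 = 2,
                       te_base_sd = 0.25,
                       polysome_scale = 1.5,
                       stage_fold = 8,
                       top_fraction = 0.5,
                       top_run_range = c(5, 14),
                       cage_reads = 100,
                       cage_window = 50,
                       bin_width = 200,
                       genome_length = 2e6,
                       background_rate = 5,
                       peak_rate = 45,
                       kd_reduction = 4,
                       loss_cohort_size = 100,
                       gain_cohort_size = 100,
                       n_marked_genes = 600,
                       n_tads = 20,
                       tad_size_range = c(20000, 80000),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$germ_cohort_size + cfg$maternal_cohort_size > cfg$n_genes) {
    abort("cohort sizes exceed n_genes.")
  }
  if (cfg$te_cohort_size > cfg$n_genes) abort("te_cohort_size exceeds n_genes.")
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("a seed is mandatory.")
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(seed, offset, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion < 1e-10) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a bulk RNA-seq count matrix with genotype effects
#'
#' NB counts for one control and one or more knockdown genotypes: the
#' germ-cell cohort goes up in every knockdown by the configured log2FC,
#' the maternal cohort goes down.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts` (tibble), `metadata` (tibble), `truth` (tibble
#'   `gene_id`, `cohort`, `true_log2fc`).
#' @export
simulate_bulk_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 101L, {
    G <- cfg$n_genes
    gene_id <- sprintf("gene%04d", seq_len(G))
    base <- rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
    cohort <- rep("null", G)
    cohort[seq_len(cfg$germ_cohort_size)] <- "germ_cell"
    cohort[cfg$germ_cohort_size + seq_len(cfg$maternal_cohort_size)] <- "maternal"
    lfc <- ifelse(cohort == "germ_cell", cfg$germ_effect_log2fc,
                  ifelse(cohort == "maternal", cfg$maternal_effect_log2fc, 0))
    control <- cfg$genotypes[1]
    samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                           genotype = cfg$genotypes,
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste0(samples$genotype, "_rep", samples$replicate)
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      mu <- if (samples$genotype[j] == control) base else base * 2^lfc
      rnb(G, mu, cfg$dispersion)
    }, numeric(G))
    colnames(counts) <- samples$sample_id
    rownames(counts) <- gene_id
    list(counts = matrix_to_counts(counts),
         metadata = tibble(sample_id = samples$sample_id,
                           genotype = samples$genotype,
                           fraction = "none", stage = "whole_ovary",
                           replicate = samples$replicate),
         truth = tibble(gene_id = gene_id, cohort = cohort, true_log2fc = lfc))
  })
}

#' Simulate a four-condition polysome-profiling experiment
#'
#' Input libraries are NB around the baseline means in both genotypes;
#' polysome means are the input means times
#' `2^(te_base + delta_te * KO)` for the translational cohort, times a
#' fraction-wide polysome scaling that normalization must absorb.
#'
#' @param cfg A [sim_config()]. `delta_te_log2 = 0` with
#'   `te_cohort_size = 0` gives a null experiment.
#' @return List: `counts`, `metadata`, `truth` (`gene_id`,
#'   `true_delta_te_log2`), `design_labels` (`wt`, `ko`).
#' @export
simulate_polysome_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 202L, {
    G <- cfg$n_genes
    gene_id <- sprintf("gene%04d", seq_len(G))
    base <- rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
    te_base <- rnorm(G, 0, cfg$te_base_sd)
    delta <- rep(0, G)
    if (cfg$te_cohort_size > 0) {
      half <- floor(cfg$te_cohort_size / 2)
      delta[seq_len(half)] <- cfg$delta_te_log2
      delta[half + seq_len(cfg$te_cohort_size - half)] <- -cfg$delta_te_log2
    }
    wt <- "nosGAL4"; ko <- "zfrp8_GKD"
    grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        fraction = c("input", "polysome"),
                        genotype = c(wt, ko), stringsAsFactors = FALSE)
    grid$sample_id <- paste(grid$genotype, grid$fraction, grid$replicate,
                            sep = "_")
    counts <- vapply(seq_len(nrow(grid)), function(j) {
      is_ko <- grid$genotype[j] == ko
      mu <- base
      if (grid$fraction[j] == "polysome") {
        mu <- mu * 2^(te_base + delta * is_ko) * cfg$polysome_scale
      }
      rnb(G, mu, cfg$dispersion)
    }, numeric(G))
    colnames(counts) <- grid$sample_id
    rownames(counts) <- gene_id
    list(counts = matrix_to_counts(counts),
         metadata = tibble(sample_id = grid$sample_id,
                           genotype = grid$genotype,
                           fraction = grid$fraction, stage = "whole_ovary",
                           replicate = grid$replicate),
         truth = tibble(gene_id = gene_id, true_delta_te_log2 = delta),
         design_labels = list(wt = wt, ko = ko))
  })
}

#' Simulate stage-graded TPM profiles
#'
#' Germ-cell cohort genes are expressed in GSC/CB/cyst libraries and reduced
#' `stage_fold`-fold in whole ovary; the maternal cohort is reversed; null
#' genes are flat. NB noise is applied around the stage means.
#'
#' @param cfg A [sim_config()].
#' @return List: `tpm` (wide tibble with columns `GSC`, `CB`, `cyst`,
#'   `whole_ovary`), `truth` (`gene_id`, `cohort`).
#' @export
simulate_stage_tpm <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 303L, {
    G <- cfg$n_genes
    gene_id <- sprintf("gene%04d", seq_len(G))
    base <- rlnorm(G, log(50), 0.8)
    cohort <- rep("null", G)
    cohort[seq_len(cfg$germ_cohort_size)] <- "germ_cell"
    cohort[cfg$germ_cohort_size + seq_len(cfg$maternal_cohort_size)] <- "maternal"
    stages <- c("GSC", "CB", "cyst", "whole_ovary")
    mu <- sapply(stages, function(st) {
      m <- base
      late <- st == "whole_ovary"
      m[cohort == "germ_cell"] <- if (late) base[cohort == "germ_cell"] / cfg$stage_fold
        else base[cohort == "germ_cell"]
      m[cohort == "maternal"] <- if (late) base[cohort == "maternal"]
        else base[cohort == "maternal"] / cfg$stage_fold
      m
    })
    tpm <- apply(mu, 2, function(m) rnb(G, m, cfg$dispersion))
    tpm <- as_tibble(as.data.frame(tpm))
    tpm <- tibble::add_column(tpm, gene_id = gene_id, .before = 1)
    list(tpm = tpm, truth = tibble(gene_id = gene_id, cohort = cohort))
  })
}

#' Simulate CAGE profiles and 5' termini with planted TOP motifs
#'
#' TOP transcripts get a C/U first base followed by a pyrimidine run of
#' sampled length (at least the conventional minimum); non-TOP transcripts
#' start with a purine. CAGE 5'-end counts are multinomial around the
#' planted TSS with the modal position at the TSS.
#'
#' @param cfg A [sim_config()]; `n_genes` is the transcript count here.
#' @param utr_length Length of the emitted 5'-terminal sequence.
#' @return List: `profiles` (tibble `transcript_id`, `strand`, `pos`,
#'   `count`), `sequences` (named character), `truth` (`transcript_id`,
#'   `is_top`, `run_length`, `tss`).
#' @export
simulate_cage_utrs <- function(cfg = sim_config(), utr_length = 30) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 404L, {
    n <- cfg$n_genes
    tx <- sprintf("tx%04d", seq_len(n))
    is_top <- seq_len(n) <= round(cfg$top_fraction * n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- sample(1000:2000, n, replace = TRUE)
    pyr <- c("C", "T"); pur <- c("A", "G"); all4 <- c("A", "C", "G", "T")
    run_len <- integer(n)
    seqs <- vapply(seq_len(n), function(i) {
      if (is_top[i]) {
        r <- sample(cfg$top_run_range[1]:cfg$top_run_range[2], 1)
        run_len[i] <<- r
        head_part <- sample(pyr, r, replace = TRUE)
        rest <- c(sample(pur, 1), sample(all4, utr_length - r - 1, replace = TRUE))
      } else {
        run_len[i] <<- 0L
        head_part <- sample(pur, 1)
        rest <- sample(all4, utr_length - 1, replace = TRUE)
      }
      paste(c(head_part, rest), collapse = "")
    }, character(1))
    # peaked profile: mode at the TSS, geometric decay into the window
    offs <- -cfg$cage_window:cfg$cage_window
    prob <- 0.5^abs(offs)
    prob[offs == 0] <- 2           # dominant modal position
    prob <- prob / sum(prob)
    profiles <- purrr::map_dfr(seq_len(n), function(i) {
      cnt <- as.integer(rmultinom(1, cfg$cage_reads, prob))
      tibble(transcript_id = tx[i], strand = strand[i],
             pos = tss[i] + offs, count = cnt)
    })
    list(profiles = profiles,
         sequences = setNames(seqs, tx),
         truth = tibble(transcript_id = tx, is_top = is_top,
                        run_length = run_len, tss = tss, strand = strand))
  })
}

#' Simulate WT/KD mark tracks, gene intervals and TADs
#'
#' Poisson bin counts at a uniform background rate on a toy chromosome;
#' promoter peaks over the loss cohort in the wild type (reduced
#' `kd_reduction`-fold in the knockdown) and over the gain cohort in the
#' knockdown only, so marks are redistributed, not merely lost. Genes are
#' laid out on a regular grid; TADs are non-overlapping intervals covering
#' part of the chromosome.
#'
#' @param cfg A [sim_config()].
#' @return List: `wt_track`, `kd_track` ([binned_track()]s), `genes`
#'   ([gene_intervals()]), `tads` (tibble `tad_id`, `chrom`, `start`,
#'   `end`), `truth` (`gene_id`, `mark_class` in
#'   `{loss, gain, stable}`, `inside_tad`).
#' @export
simulate_marks_and_tads <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 505L, {
    w <- cfg$bin_width
    L <- cfg$genome_length
    n_bins <- ceiling(L / w)
    chrom <- "chrSim"
    nG <- cfg$n_marked_genes
    if (cfg$loss_cohort_size + cfg$gain_cohort_size > nG) {
      abort("mark cohorts exceed the gene count.")
    }
    # genes on a regular grid, 2 kb long, away from chromosome ends
    pitch <- floor((L - 20000) / nG)
    start <- 10000 + (seq_len(nG) - 1) * pitch
    genes <- gene_intervals(tibble(
      gene_id = sprintf("mgene%04d", seq_len(nG)),
      chrom = chrom, start = start, end = start + 2000,
      strand = rep(c("+", "-"), length.out = nG)))
    cls <- rep("stable", nG)
    idx <- sample.int(nG)
    cls[idx[seq_len(cfg$loss_cohort_size)]] <- "loss"
    cls[idx[cfg$loss_cohort_size + seq_len(cfg$gain_cohort_size)]] <- "gain"

    peak_bins <- function(tss) {
      b0 <- max(floor((tss - 400) / w), 0) + 1
      b1 <- min(floor((tss + 400) / w), n_bins - 1) + 1
      b0:b1
    }
    rate_wt <- rep(cfg$background_rate, n_bins)
    rate_kd <- rep(cfg$background_rate, n_bins)
    for (i in seq_len(nG)) {
      pb <- peak_bins(genes$tss[i])
      if (cls[i] == "loss") {
        rate_wt[pb] <- rate_wt[pb] + cfg$peak_rate
        rate_kd[pb] <- rate_kd[pb] + cfg$peak_rate / cfg$kd_reduction
      } else if (cls[i] == "gain") {
        rate_kd[pb] <- rate_kd[pb] + cfg$peak_rate
      }
    }
    mk_track <- function(rate) {
      binned_track(tibble(chrom = chrom,
                          start = (seq_len(n_bins) - 1) * w,
                          end = seq_len(n_bins) * w,
                          value = rpois(n_bins, rate)), w)
    }
    wt_track <- mk_track(rate_wt)
    kd_track <- mk_track(rate_kd)

    # non-overlapping TADs tiled left to right with random sizes and gaps
    sizes <- round(runif(cfg$n_tads, cfg$tad_size_range[1], cfg$tad_size_range[2]))
    gaps <- round(runif(cfg$n_tads, 5000, 20000))
    starts <- cumsum(gaps + dplyr::lag(sizes, default = 0))
    ok <- starts + sizes < L
    tads <- tibble(tad_id = sprintf("tad%02d", seq_len(sum(ok))),
                   chrom = chrom, start = starts[ok], end = (starts + sizes)[ok])

    inside <- within_tad_indicator(genes, tads)
    list(wt_track = wt_track, kd_track = kd_track, genes = genes, tads = tads,
         truth = tibble(gene_id = genes$gene_id, mark_class = cls,
                        inside_tad = inside$inside_tad))
  })
}
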