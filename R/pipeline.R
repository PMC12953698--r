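#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. A
#' configuration may also be read from a YAML file with the same flat
#' schema. Every stochastic stage derives its stream from the single
#' top-level seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param stages Stages to run, in dependency order, from
#'   `c("simulate", "de", "te", "overlap", "signature", "top", "marks")`.
#' @param simulate Named list of [sim_config()] overrides.
#' @param inputs Optional named list of input paths (`counts`, `metadata`)
#'   used instead of simulation for the expression stages; files must exist.
#' @param de,te,overlap,signature,top,marks Named lists of stage parameters
#'   (see the stage functions for meanings).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "gc2mat_out", seed = 1L,
                            stages = c("simulate", "de", "te", "overlap",
                                       "signature", "top", "marks"),
                            simulate = list(), inputs = list(),
                            de = list(), te = list(), overlap = list(),
                            signature = list(), top = list(), marks = list()) {
  known <- c("simulate", "de", "te", "overlap", "signature", "top", "marks")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- known[known %in% stages]
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      abort(paste0("input file does not exist: ", inputs[[nm]]))
    }
  }
  if (!length(inputs) && !"simulate" %in% stages) {
    abort("without input files the 'simulate' stage is required.")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 simulate = simulate, inputs = inputs, de = de, te = te,
                 overlap = overlap, signature = signature, top = top,
                 marks = marks),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the configuration schema above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate or load,
#' filter + differential expression per knockdown genotype, translational
#' efficiency, gene-set overlaps, stage signature, TOP classification,
#' chromatin marks), writes per-stage outputs under the configured output
#' directory, and returns a run manifest recording package version, seed,
#' parameters, timings and output checksums. A failing stage aborts the run
#' with the stage named; files it had written are kept with a `.partial`
#' suffix.
#'
#' @param cfg A [pipeline_config()] (or a YAML path).
#' @return List with `manifest` (tibble), `results` (per-stage objects) and
#'   `summary` (the written report list), invisibly returned components
#'   available for inspection.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list()
  msg <- function(...) message("[gc2mat] ", ...)

  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    written <- character()
    note_file <- function(p) { written <<- c(written, p); p }
    res <- tryCatch(fn(note_file), error = function(e) {
      for (p in written) if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    results[[name]] <<- res
    manifest[[name]] <<- tibble(
      stage = name, status = "completed",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      n_outputs = length(written),
      outputs = paste(basename(written), collapse = ";"))
    msg("stage ", name, " completed")
    invisible(res)
  }

  scfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))

  run_stage("simulate", function(note) {
    sim <- list(bulk = simulate_bulk_counts(scfg),
                polysome = simulate_polysome_experiment(scfg),
                stages = simulate_stage_tpm(scfg),
                cage = simulate_cage_utrs(scfg),
                marks = simulate_marks_and_tads(scfg))
    readr::write_tsv(sim$bulk$counts, note(file.path(cfg$out_dir, "bulk_counts.tsv")))
    readr::write_tsv(sim$bulk$metadata, note(file.path(cfg$out_dir, "bulk_metadata.tsv")))
    readr::write_tsv(sim$bulk$truth, note(file.path(cfg$out_dir, "bulk_truth.tsv")))
    readr::write_tsv(sim$polysome$counts, note(file.path(cfg$out_dir, "polysome_counts.tsv")))
    readr::write_tsv(sim$polysome$metadata, note(file.path(cfg$out_dir, "polysome_metadata.tsv")))
    readr::write_tsv(sim$stages$tpm, note(file.path(cfg$out_dir, "stage_tpm.tsv")))
    write_fasta(sim$cage$sequences, note(file.path(cfg$out_dir, "five_prime_utrs.fa")))
    write_bedgraph(sim$marks$wt_track, note(file.path(cfg$out_dir, "marks_wt.bedgraph")))
    write_bedgraph(sim$marks$kd_track, note(file.path(cfg$out_dir, "marks_kd.bedgraph")))
    readr::write_tsv(sim$marks$tads, note(file.path(cfg$out_dir, "tads.bed")),
                     col_names = FALSE)
    sim
  })

  get_bulk <- function() {
    if (length(cfg$inputs)) {
      list(counts = read_counts(cfg$inputs$counts),
           metadata = read_sample_metadata(cfg$inputs$metadata))
    } else {
      if (is.null(results$simulate)) abort("no inputs and the simulate stage did not run.")
      results$simulate$bulk
    }
  }

  run_stage("de", function(note) {
    bulk <- get_bulk()
    decfg <- do.call(de_config, cfg$de)
    control <- unique(bulk$metadata$genotype)[1]
    cases <- setdiff(unique(bulk$metadata$genotype), control)
    out <- lapply(cases, function(case) {
      res <- run_de_comparison(bulk$counts, bulk$metadata, case, control, decfg)
      write_test_table(res, note(file.path(cfg$out_dir, paste0("de_", case, ".tsv"))),
                       header_comment = paste0("log2fc_mode=", decfg$log2fc_mode))
      res
    })
    setNames(out, cases)
  })

  run_stage("te", function(note) {
    sim <- results$simulate
    if (is.null(sim)) abort("the te stage requires the simulate stage.")
    poly <- sim$polysome
    design <- build_te_design(poly$metadata, wt = poly$design_labels$wt,
                              ko = poly$design_labels$ko)
    tecfg <- cfg$te
    res <- run_te_analysis(poly$counts, design,
                           alpha = tecfg$alpha %||% 0.05,
                           use_fdr = isTRUE(tecfg$use_fdr))
    write_test_table(res, note(file.path(cfg$out_dir, "te_results.tsv")))
    res
  })

  run_stage("overlap", function(note) {
    de <- results$de
    if (is.null(de) || length(de) < 2) abort("overlap needs >= 2 DE comparisons.")
    universe <- de[[1]]$gene_id[de[[1]]$class != "filtered"]
    up_sets <- lapply(names(de), function(g) {
      gene_set(g, de[[g]]$gene_id[de[[g]]$class == "up"], universe)
    })
    rand <- overlap_randomization_test(up_sets, universe,
                                       n_iter = cfg$overlap$n_iter %||% 1e6,
                                       seed = cfg$seed)
    hyper <- hypergeometric_overlap_test(up_sets[[1]], up_sets[[2]], universe)
    venn <- overlap_fraction_summary(up_sets)
    out <- list(randomization = rand, hypergeometric = hyper, venn = venn)
    jsonlite::write_json(
      list(randomization = as.list(rand), hypergeometric = as.list(hyper),
           regions = venn$regions, core_fraction = venn$core_fraction),
      note(file.path(cfg$out_dir, "overlap.json")),
      auto_unbox = TRUE, digits = NA)
    out
  })

  run_stage("signature", function(note) {
    sim <- results$simulate
    if (is.null(sim)) abort("the signature stage requires the simulate stage.")
    tpm <- sim$stages$tpm
    signature <- if (!is.null(results$overlap)) {
      core <- intersect_sets(lapply(names(results$de), function(g) {
        results$de[[g]]$gene_id[results$de[[g]]$class == "up"]
      }))$members
      if (length(core) >= 5) core else sim$stages$truth$gene_id[
        sim$stages$truth$cohort == "germ_cell"]
    } else {
      sim$stages$truth$gene_id[sim$stages$truth$cohort == "germ_cell"]
    }
    contrasts <- list(c("GSC", "whole_ovary"), c("CB", "whole_ovary"),
                      c("cyst", "whole_ovary"))
    fit <- fit_stage_nb_regression(tpm, signature, contrasts)
    profiles <- classify_stage_profile(tpm)
    readr::write_tsv(fit$contrasts, note(file.path(cfg$out_dir, "signature_contrasts.tsv")))
    readr::write_tsv(profiles, note(file.path(cfg$out_dir, "stage_profiles.tsv")))
    list(fit = fit, profiles = profiles)
  })

  run_stage("top", function(note) {
    sim <- results$simulate
    if (is.null(sim)) abort("the top stage requires the simulate stage.")
    tss <- call_tss_from_cage(sim$cage$profiles)
    calls <- classify_top_motif(sim$cage$sequences,
                                min_run = cfg$top$min_run %||% 5,
                                transcript_id = names(sim$cage$sequences))
    res <- dplyr::left_join(tss, calls, by = "transcript_id")
    readr::write_tsv(res, note(file.path(cfg$out_dir, "top_calls.tsv")))
    res
  })

  run_stage("marks", function(note) {
    sim <- results$simulate
    if (is.null(sim)) abort("the marks stage requires the simulate stage.")
    mk <- sim$marks
    tab <- differential_marks(mk$wt_track, mk$kd_track, mk$genes,
                              lfc_threshold = cfg$marks$lfc_threshold %||% 1)
    redist <- redistribution_summary(binarize_track(mk$wt_track),
                                     binarize_track(mk$kd_track))
    de_first <- results$de[[1]]
    values <- if (!is.null(de_first)) {
      tibble(gene_id = mk$genes$gene_id,
             log2fc = tab$log2_ratio,
             class = ifelse(tab$call == "loss", "down",
                            ifelse(tab$call == "gain", "up", "ns")))
    } else {
      tibble(gene_id = mk$genes$gene_id, log2fc = tab$log2_ratio,
             class = "ns")
    }
    meta <- tad_metaregion_matrix(values, mk$tads, track = NULL,
                                  genes = mk$genes)
    readr::write_tsv(tab, note(file.path(cfg$out_dir, "mark_calls.tsv")))
    readr::write_tsv(redist, note(file.path(cfg$out_dir, "redistribution.tsv")))
    readr::write_tsv(tidy(meta), note(file.path(cfg$out_dir, "tad_metaregions.tsv")))
    list(calls = tab, redistribution = redist, metaregions = meta)
  })

  manifest <- dplyr::bind_rows(manifest)
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest|summary", files)]
  checks <- tools::md5sum(files)
  manifest_meta <- tibble(
    stage = "run", status = "completed",
    elapsed_s = sum(manifest$elapsed_s), n_outputs = length(files),
    outputs = paste0("package=", as.character(utils::packageVersion("gc2mat")),
                     ";seed=", cfg$seed))
  manifest <- dplyr::bind_rows(manifest, manifest_meta)
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  readr::write_tsv(tibble(file = basename(names(checks)), md5 = unname(checks)),
                   file.path(cfg$out_dir, "checksums.tsv"))
  summary <- write_reports(results, cfg$out_dir)
  list(manifest = manifest, results = results, summary = summary,
       checksums = setNames(unname(checks), basename(names(checks))))
}

#' Write the cross-stage report bundle
#'
#' Aggregates stage results into a summary JSON (DE counts per genotype,
#' TE up/down counts, overlap statistics, signature classes, TOP calls,
#' mark-call counts and redistribution index). Stages that did not run are
#' absent from the JSON, not null.
#'
#' @param results Named list of stage results from [run_pipeline()].
#' @param out_dir Output directory.
#' @return The summary list, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  if (!length(results)) abort("no stage results to report.")
  summary <- list()
  if (!is.null(results$de)) {
    summary$de <- lapply(results$de, function(r) attr(r, "summary"))
  }
  if (!is.null(results$te)) {
    summary$te <- classify_te(results$te)
  }
  if (!is.null(results$overlap)) {
    summary$overlap <- c(as.list(results$overlap$randomization),
                         list(hypergeometric_p = results$overlap$hypergeometric$p_value,
                              core_fraction = results$overlap$venn$core_fraction))
  }
  if (!is.null(results$signature)) {
    summary$signature <- list(
      profiles = as.list(table(results$signature$profiles$profile)),
      n_significant = sum(results$signature$fit$contrasts$fdr < 0.05, na.rm = TRUE))
  }
  if (!is.null(results$top)) {
    summary$top <- list(n_top = sum(results$top$is_top),
                        n_non_top = sum(!results$top$is_top))
  }
  if (!is.null(results$marks)) {
    summary$marks <- c(as.list(table(results$marks$calls$call)),
                       list(redistribution_index =
                              results$marks$redistribution$redistribution_index,
                            within_tad_fraction =
                              results$marks$metaregions$within_tad_fraction))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
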