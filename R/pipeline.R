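## End-to-end orchestration: simulate -> preprocess -> correct -> segment ->
## call -> annotate/permtest -> enrich, with every intermediate persisted in
## standard formats and a run manifest sufficient to re-run any stage.

#' Pipeline configuration
#'
#' Builds and validates the configuration for \code{\link{run_pipeline}}.
#' Unknown keys are rejected so typos fail fast, before any stage runs.
#'
#' @param outdir output directory.
#' @param seed global seed; all stage randomness derives from it.
#' @param genome a \code{genome_config} list (see \code{\link{genome_config}}).
#' @param simulate list: \code{n_per_sample}, \code{samples},
#'   \code{length_range}, \code{shared_fraction}, \code{noise_sd},
#'   \code{bias_sd}, \code{bias_frac_large}, \code{bias_large_mean},
#'   \code{target_spacing}, \code{probe_length}, \code{replicate_fraction}.
#' @param preprocess list: \code{span}, \code{qc_window},
#'   \code{qc_outlier_frac}.
#' @param correct list: \code{alpha_level}.
#' @param segment list: \code{alpha}, \code{nperm}, \code{merge_tol}.
#' @param call list: \code{threshold}, \code{min_probes}, \code{flank}.
#' @param permtest list: \code{n_rounds}, \code{tail}.
#' @param enrich list: \code{n_sets}, \code{set_size} (synthetic gene-set
#'   collection drawn from the genome's genes).
#' @param de list: \code{enabled} (default FALSE), \code{n_test},
#'   \code{n_control}, \code{frac_de}, \code{lfc}, \code{fdr_threshold} —
#'   a simulated expression matrix over the genome's genes, collapsed,
#'   tested and compared against the CNV gene directions.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            genome = genome_config(),
                            simulate = list(), preprocess = list(),
                            correct = list(), segment = list(),
                            call = list(), permtest = list(),
                            enrich = list(), de = list(),
                            log_level = "info") {
  defaults <- list(
    simulate = list(n_per_sample = 40L, samples = c("GK1", "GK2", "GK3"),
                    length_range = c(5e4, 5e5), shared_fraction = 0.7,
                    noise_sd = 0.15, bias_sd = 0.05, bias_frac_large = 0.25,
                    bias_large_mean = 0.4, target_spacing = 7900,
                    probe_length = 60, replicate_fraction = 0),
    preprocess = list(span = 0.3, qc_window = 10L, qc_outlier_frac = 0.4),
    correct = list(alpha_level = 0.05),
    segment = list(alpha = 0.01, nperm = 10000, merge_tol = 0.05),
    call = list(threshold = 0.5, min_probes = 3L, flank = 5000),
    permtest = list(n_rounds = 1000, tail = "depletion"),
    enrich = list(n_sets = 20L, set_size = 50L),
    de = list(enabled = FALSE, n_test = 5L, n_control = 5L, frac_de = 0.1,
              lfc = 2, fdr_threshold = 0.2))
  stages <- list(simulate = simulate, preprocess = preprocess,
                 correct = correct, segment = segment, call = call,
                 permtest = permtest, enrich = enrich, de = de)
  for (st in names(stages)) {
    unknown <- setdiff(names(stages[[st]]), names(defaults[[st]]))
    if (length(unknown) > 0)
      stop("unknown ", st, " config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[[st]][names(stages[[st]])] <- stages[[st]]
  }
  if (!log_level %in% c("info", "quiet"))
    stop("log_level must be 'info' or 'quiet'", call. = FALSE)
  cfg <- c(list(outdir = outdir, seed = as.integer(seed), genome = genome,
                log_level = log_level), defaults)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys match the arguments of
#'   \code{\link{pipeline_config}}.
#' @param outdir,seed overrides for the file's values (optional).
#' @return a validated \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(raw$genome)) {
    gc <- raw$genome
    if (!is.null(gc$chrom_lengths)) gc$chrom_lengths <- unlist(gc$chrom_lengths)
    raw$genome <- do.call(genome_config, gc)
  }
  do.call(pipeline_config, raw)
}

plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "info"))
    message(format(Sys.time(), "%H:%M:%S"), " [swapCGH] ", ...)
}

#' Run the full pipeline on simulated data
#'
#' Executes every stage in order, persisting each stage's outputs under
#' \code{outdir} (BED, TSV, Newick, JSON) and writing a \code{manifest.json}
#' that records per-stage parameters and output files. Identical config and
#' seed produce byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the run manifest (list), invisibly; its \code{results} entry
#'   holds in-memory stage results (genome, truth, cnvrs, permtest,
#'   enrichment, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage_seeds <- as.list(sample.int(.Machine$integer.max %/% 2L, 7))
  names(stage_seeds) <- c("genome", "truth", "layout", "scans", "segment",
                          "permtest", "de")
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      parameters = params, outputs = files,
      md5 = unname(tools::md5sum(files)))
  }
  out <- function(...) file.path(config$outdir, ...)

  ## --- simulate ----------------------------------------------------------
  sim <- config$simulate
  genome <- make_genome(config$genome, seed = stage_seeds$genome)
  truth <- plant_cnvs(genome, n_per_sample = sim$n_per_sample,
                      samples = sim$samples, length_range = sim$length_range,
                      shared_fraction = sim$shared_fraction,
                      seed = stage_seeds$truth)
  layout <- tile_probes(genome, target_spacing = sim$target_spacing,
                        probe_length = sim$probe_length,
                        replicate_fraction = sim$replicate_fraction,
                        seed = stage_seeds$layout)
  bias <- make_dye_bias(layout, sd = sim$bias_sd,
                        frac_large = sim$bias_frac_large,
                        large_mean = sim$bias_large_mean,
                        seed = stage_seeds$layout)
  expt <- simulate_dyeswap_experiment(layout, truth, bias = bias,
                                      noise_sd = sim$noise_sd,
                                      seed = stage_seeds$scans)
  write_chrom_sizes(genome, out("chrom.sizes"))
  write_bed(genome$features$genes, out("genes.bed"))
  write_tsv(as.data.frame(truth), out("truth.tsv"))
  write_tsv(as.data.frame(layout), out("layout.tsv"))
  write_tsv(expt$design, out("design.tsv"))
  scan_files <- character(0)
  for (a in names(expt$scans)) {
    f <- out(paste0("scan_", a, ".tsv"))
    write_scan(expt$scans[[a]], f)
    scan_files <- c(scan_files, f)
  }
  plog(config, "simulate: ", nrow(layout), " probes, ",
       length(expt$scans), " arrays, ", nrow(truth), " CNV assignments")
  note("simulate", sim, c(out(c("chrom.sizes", "genes.bed", "truth.tsv",
                                "layout.tsv", "design.tsv")), scan_files))

  ## --- preprocess --------------------------------------------------------
  pp <- config$preprocess
  spots <- lapply(expt$scans, preprocess_scan, span = pp$span,
                  qc_window = pp$qc_window, qc_outlier_frac = pp$qc_outlier_frac)
  n_flagged <- sum(vapply(spots, function(s) sum(s$qc_flag == "fail"), numeric(1)))
  for (a in names(spots)) write_tsv(spots[[a]], out(paste0("spots_", a, ".tsv")))
  plog(config, "preprocess: ", n_flagged, " spots flagged across arrays")
  note("preprocess", pp, out(paste0("spots_", names(spots), ".tsv")))

  ## --- correct -----------------------------------------------------------
  M <- build_m_matrix(spots, expt$design)
  fits <- fit_dye_model(M, expt$design)
  clust_before <- cluster_arrays(M)
  Mc <- correct_dye_bias(M, fits, expt$design)
  clust_after <- cluster_arrays(Mc)
  pmv <- merge_samples(Mc, expt$design, layout)
  bias_frac <- dye_bias_fraction(fits, config$correct$alpha_level)
  write_tsv(as.data.frame(fits), out("dye_fits.tsv"))
  write_tsv(data.frame(probe_id = rownames(Mc), Mc, check.names = FALSE),
            out("corrected_m.tsv"))
  writeLines(clust_before$newick, out("cluster_before.nwk"))
  writeLines(clust_after$newick, out("cluster_after.nwk"))
  write_tsv(as.data.frame(pmv), out("sample_m.tsv"))
  plog(config, "correct: ", sprintf("%.1f%%", 100 * bias_frac),
       " spots with significant dye bias")
  note("correct", config$correct,
       out(c("dye_fits.tsv", "corrected_m.tsv", "cluster_before.nwk",
             "cluster_after.nwk", "sample_m.tsv")))

  ## --- segment -----------------------------------------------------------
  sg <- config$segment
  segs <- segment_all(pmv, alpha = sg$alpha, nperm = sg$nperm,
                      merge_tol = sg$merge_tol, seed = stage_seeds$segment)
  seg_tab <- do.call(rbind, lapply(segs, `[[`, "segments"))
  write_tsv(seg_tab, out("segments.tsv"))
  plog(config, "segment: ", nrow(seg_tab), " segments over ",
       length(segs), " samples")
  note("segment", sg, out("segments.tsv"))

  ## --- call --------------------------------------------------------------
  cl <- config$call
  per_sample <- lapply(names(segs), function(s)
    call_cores(segs[[s]]$smoothed, s, genome, threshold = cl$threshold,
               min_probes = cl$min_probes, flank = cl$flank))
  names(per_sample) <- names(segs)
  cnvrs <- merge_to_nonredundant(per_sample)
  for (s in names(per_sample))
    if (nrow(per_sample[[s]]) > 0) {
      ps <- per_sample[[s]]
      ps$name <- sprintf("%s.cnv.%d", s, seq_len(nrow(ps)))
      ps$score <- round(pmin(1000 * abs(ps$mean_smoothed_M), 1000))
      write_bed(ps, out(paste0("cnvr_", s, ".bed")),
                extra_cols = c("status", "sample_id"))
    }
  if (nrow(cnvrs) > 0) {
    cb <- cnvrs
    cb$score <- 0
    write_bed(cb, out("cnvr_nonredundant.bed"),
              extra_cols = c("status", "supporting_samples"))
  }
  plog(config, "call: ", nrow(cnvrs), " non-redundant CNVRs (",
       sum(cnvrs$status == "gain"), " gain / ", sum(cnvrs$status == "loss"),
       " loss)")
  note("call", cl, out(c(paste0("cnvr_", names(per_sample), ".bed"),
                         "cnvr_nonredundant.bed")))

  ## --- annotate / permtest ------------------------------------------------
  pt <- config$permtest
  cov_tab <- coverage_table(cnvrs, genome$features$genes, genome)
  cnv_genes <- genes_overlapping(cnvrs, genome$features$genes)
  perm <- random_interval_test(cnvrs, genome$features$genes, genome,
                               n_rounds = pt$n_rounds, tail = pt$tail,
                               seed = stage_seeds$permtest)
  write_tsv(cov_tab, out("coverage_table.tsv"))
  jsonlite::write_json(
    perm[c("observed", "expected", "null_sd", "z", "p_value", "tail",
           "n_rounds", "seed")],
    out("permtest.json"), auto_unbox = TRUE, digits = NA)
  plog(config, "annotate: ", length(cnv_genes$gain), " gain / ",
       length(cnv_genes$loss), " loss CNV genes; depletion p = ",
       signif(perm$p_value, 3))
  note("permtest", pt, out(c("coverage_table.tsv", "permtest.json")))

  ## --- enrich -------------------------------------------------------------
  en <- config$enrich
  universe <- genome$features$genes$id
  query <- unique(unlist(cnv_genes))
  enr <- NULL
  if (length(universe) > 0 && length(query) > 0) {
    sets <- lapply(seq_len(en$n_sets), function(i)
      sample(universe, min(en$set_size, length(universe))))
    names(sets) <- sprintf("set%03d", seq_len(en$n_sets))
    coll <- gene_set_collection(universe, sets)
    enr <- enrich_sets(query, coll)
    write_tsv(as.data.frame(enr), out("enrichment.tsv"))
    write_gmt(sets, out("gene_sets.gmt"))
    note("enrich", en, out(c("enrichment.tsv", "gene_sets.gmt")))
  }

  ## --- de (optional) ------------------------------------------------------
  de_res <- NULL; consistency <- NULL
  if (isTRUE(config$de$enabled) && length(universe) > 0) {
    dc <- config$de
    sim <- simulate_expression(n_genes = length(universe),
                               n_test = dc$n_test, n_control = dc$n_control,
                               frac_de = dc$frac_de, lfc = dc$lfc,
                               seed = stage_seeds$de)
    sim$map$gene_id <- universe[match(sim$map$gene_id, sim$truth$gene_id)]
    gmat <- collapse_probesets(sim$mat, sim$map)
    de_res <- de_test(gmat, sim$groups, fdr_threshold = dc$fdr_threshold)
    consistency <- consistency_call(cnv_genes, de_res)
    write_tsv(as.data.frame(de_res), out("de_results.tsv"))
    write_tsv(consistency, out("cnv_expression_consistency.tsv"))
    plog(config, "de: ", sum(de_res$direction != "ns"), " genes called; ",
         sum(consistency$consistency == "consistent"), " CNV genes consistent")
    note("de", dc, out(c("de_results.tsv", "cnv_expression_consistency.tsv")))
  }

  manifest$results <- list(genome = genome, truth = truth, layout = layout,
                           design = expt$design, fits = fits, pmv = pmv,
                           segments = seg_tab, per_sample_cnvrs = per_sample,
                           cnvrs = cnvrs, coverage = cov_tab,
                           cnv_genes = cnv_genes, permtest = perm,
                           enrichment = enr, de = de_res,
                           consistency = consistency,
                           dye_bias_fraction = bias_frac,
                           cluster_before = clust_before,
                           cluster_after = clust_after)
  mf <- manifest
  mf$results <- NULL
  jsonlite::write_json(mf, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(manifest)
}
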