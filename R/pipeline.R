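#' Pipeline configuration
#'
#' Bundles input locations, analysis thresholds and the seed for a full run
#' of the discovery chain. Defaults are the package-wide analysis constants:
#' FDR 0.05, |log2FC| 1.5, GS 0.7 at p 0.05, housekeeper expression floor
#' log2(RPKM) 5 with the 10\% low-variance quantile, GS abundance floor mean
#' RPKM 2, 12 expression clusters, in-stage z-score floor 1. Configs
#' round-trip losslessly through YAML (\code{\link{readPipelineConfig}} /
#' \code{\link{writePipelineConfig}}).
#'
#' @param out_dir run directory for result tables and the manifest.
#' @param counts_path,sheet_path,annotation_path,cq_path optional input
#'   files; when \code{counts_path} is NULL the synthetic generator supplies
#'   the data.
#' @param sim a \code{\link{simulationConfig}} (used when simulating).
#' @param alpha,lfc DE thresholds.
#' @param gs_min,gs_alpha,min_mean_rpkm gene-significance thresholds.
#' @param min_log2rpkm,low_var_quantile housekeeper thresholds.
#' @param k_clusters expression clusters to cut.
#' @param z_min marker in-stage z-score floor.
#' @param relax_stage stage whose all-pairwise DE criterion is relaxed
#'   (default \code{"ATT"}; NULL for none).
#' @param n_panel markers per stage and \code{n_references} housekeepers
#'   carried into the qPCR arm.
#' @param seed integer seed for every random step.
#' @return Validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir,
                           counts_path = NULL, sheet_path = NULL,
                           annotation_path = NULL, cq_path = NULL,
                           sim = simulationConfig(),
                           alpha = 0.05, lfc = 1.5,
                           gs_min = 0.7, gs_alpha = 0.05, min_mean_rpkm = 2,
                           min_log2rpkm = 5, low_var_quantile = 0.10,
                           k_clusters = 12L, z_min = 1,
                           relax_stage = "ATT",
                           n_panel = 3L, n_references = 5L,
                           seed = 1L) {
  cfg <- list(out_dir = out_dir, counts_path = counts_path,
              sheet_path = sheet_path, annotation_path = annotation_path,
              cq_path = cq_path, sim = sim, alpha = alpha, lfc = lfc,
              gs_min = gs_min, gs_alpha = gs_alpha,
              min_mean_rpkm = min_mean_rpkm, min_log2rpkm = min_log2rpkm,
              low_var_quantile = low_var_quantile,
              k_clusters = as.integer(k_clusters), z_min = z_min,
              relax_stage = relax_stage, n_panel = as.integer(n_panel),
              n_references = as.integer(n_references),
              seed = as.integer(seed))
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  if (cfg$gs_alpha <= 0 || cfg$gs_alpha > 1) stop("gs_alpha must lie in (0, 1]")
  if (cfg$gs_min < 0 || cfg$gs_min > 1) stop("gs_min must lie in [0, 1]")
  if (cfg$lfc < 0) stop("lfc must be >= 0")
  if (cfg$low_var_quantile <= 0 || cfg$low_var_quantile > 1)
    stop("low_var_quantile must lie in (0, 1]")
  if (cfg$k_clusters < 1L) stop("k_clusters must be >= 1")
  if (!is.null(cfg$relax_stage)) .checkStage(cfg$relax_stage)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(simulationConfig, raw$sim)
         else simulationConfig()
  raw$sim <- NULL
  do.call(pipelineConfig, c(raw, list(sim = sim)))
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$n_markers_per_stage <- as.list(x$sim$n_markers_per_stage)
  yaml::write_yaml(x, path)
  invisible(path)
}

.writeTab <- function(d, dir, name) {
  utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full discovery pipeline
#'
#' Orchestrates the chain: ingest or simulate a staged count matrix; filter
#' to expressed transcripts; all pairwise exact-test contrasts; Venn overlap
#' of the infective stages against niS; complete-linkage clustering of
#' z-scored log2(CPM+1) profiles of transcripts significant in at least one
#' contrast; optional functional-bin enrichment of that set; gene
#' significance; housekeeper and marker selection; and (for simulated runs,
#' or when a Cq table is supplied) the RT-qPCR arm -- reference-gene
#' stability ranking, reference normalization and marker-based stage calls.
#' Every stage's output is written as TSV into \code{config$out_dir} together
#' with a YAML manifest of the thresholds used and the dimensions retained at
#' each step; a failing stage aborts with its name and leaves a FAILED
#' marker.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(config)[!(names(config) %in%
                     c("out_dir", "sim"))],
                   sim = if (is.null(config$counts_path)) unclass(config$sim),
                   stages = list())
  if (!is.null(manifest$sim))
    manifest$sim$n_markers_per_stage <- as.list(manifest$sim$n_markers_per_stage)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  sc <- step("ingest", {
    if (is.null(config$counts_path)) {
      simcfg <- config$sim
      simcfg$seed <- config$seed
      sim <- simulateCounts(simcfg)
      truth <- sim$truth
      .writeTab(sim$truth, config$out_dir, "truth.tsv")
      writeCounts(sim$counts, file.path(config$out_dir, "counts.tsv"),
                  file.path(config$out_dir, "sheet.tsv"))
      sim$counts
    } else readCounts(config$counts_path, config$sheet_path)
  })
  manifest$stages$ingest <- list(transcripts = nrow(sc), samples = ncol(sc))

  fc <- step("filter", filterExpressed(sc))
  manifest$stages$filter <- list(retained = nrow(fc))

  de <- step("diffexp", allPairwiseContrasts(fc, config$alpha, config$lfc))
  for (nm in names(de)) .writeTab(de[[nm]], config$out_dir,
                                  paste0("de_", nm, ".tsv"))
  manifest$stages$diffexp <- lapply(de, function(d)
    list(up = sum(d$direction == "up"), down = sum(d$direction == "down")))

  venn <- step("overlap", {
    vs_nis <- de[grep("^niS_vs_", names(de))]
    if (length(vs_nis) == 3L) stageOverlapSets(vs_nis) else NULL
  })
  if (!is.null(venn)) {
    .writeTab(data.frame(region = names(venn$regions),
                         n = lengths(venn$regions)),
              config$out_dir, "venn_regions.tsv")
    manifest$stages$overlap <- as.list(lengths(venn$regions))
  }

  clus <- step("cluster", {
    deg <- unique(unlist(lapply(de, function(d)
      d$transcript_id[d$direction != "ns"])))
    if (length(deg) < max(2L, config$k_clusters)) NULL else {
      z <- zscoreRows(log2p(toCPM(fc)))[deg, ]
      tree <- hierarchicalCluster(z, axis = "rows")
      asg <- cutToK(tree, config$k_clusters)
      prof <- clusterProfiles(asg, z)
      .writeTab(data.frame(transcript_id = names(asg), cluster = asg),
                config$out_dir, "clusters.tsv")
      .writeTab(data.frame(cluster = rownames(prof), prof),
                config$out_dir, "cluster_profiles.tsv")
      ape::write.tree(ape::as.phylo(tree),
                      file.path(config$out_dir, "transcript_dendrogram.nwk"))
      list(deg = deg, assignment = asg)
    }
  })
  manifest$stages$cluster <- list(clustered = if (is.null(clus)) 0L
                                  else length(clus$assignment))

  if (!is.null(config$annotation_path) && !is.null(clus)) {
    step("enrich", {
      annot <- readAnnotation(config$annotation_path)
      enr <- enrichBins(clus$deg, rownames(fc), annot, alpha = config$alpha)
      .writeTab(enr, config$out_dir, "enrichment.tsv")
      manifest$stages$enrich <- list(bins_tested = nrow(enr),
                                      enriched = sum(enr$enriched))
    })
  }

  gs <- step("gene_significance",
             geneSignificance(fc, config$min_mean_rpkm, config$gs_min,
                              config$gs_alpha))
  .writeTab(gs, config$out_dir, "gene_significance.tsv")

  hk <- step("housekeepers",
             selectHousekeepers(fc, de, config$min_log2rpkm,
                                config$low_var_quantile, config$alpha,
                                config$lfc))
  .writeTab(hk, config$out_dir, "housekeepers.tsv")
  manifest$stages$housekeepers <- list(selected = nrow(hk))

  mk <- step("markers",
             selectMarkers(fc, de, gs, config$z_min, config$relax_stage,
                           alpha = config$alpha, lfc = config$lfc))
  .writeTab(mk, config$out_dir, "markers.tsv")
  manifest$stages$markers <- as.list(table(as.character(mk$stage)))

  qpcr_ok <- nrow(hk) >= 3L && all(table(as.character(mk$stage)) >= 1L) &&
    nlevels(droplevels(mk$stage)) == 4L
  if (qpcr_ok) step("qpcr_staging", {
    refs <- utils::head(hk$transcript_id, config$n_references)
    panel <- lapply(split(mk, mk$stage), function(d)
      utils::head(d$transcript_id[order(-d$GS)], config$n_panel))
    panel_genes <- unique(c(refs, unlist(panel)))
    cqt <- if (!is.null(config$cq_path)) readCq(config$cq_path) else {
      expr <- log2p(toRPKM(fc))[panel_genes, ]
      simcfg <- config$sim
      simcfg$seed <- config$seed
      simulateCq(expr, simcfg)
    }
    writeCq(cqt, file.path(config$out_dir, "cq.tsv"))
    groups <- as.character(stageOf(fc))[match(unique(cqData(cqt)$sample_id),
                                              colnames(fc))]
    stab <- rankStability(cqt, groups = groups, candidates = refs)
    .writeTab(stabilityTable(stab), config$out_dir, "stability.tsv")
    best2 <- utils::head(stabilityTable(stab)$candidate, 2L)
    rq <- relativeAbundance(cqt, efficiency = config$sim$efficiency)
    nrq <- normalizeToReferences(rq, best2)
    calls <- classifyStages(nrq, panel)
    .writeTab(calls, config$out_dir, "stage_calls.tsv")
    manifest$stages$qpcr_staging <- list(
      references_used = best2,
      calls = as.list(table(as.character(calls$call))))
  })

  manifest$stages$seed <- config$seed
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
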