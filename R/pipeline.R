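#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: masking thresholds
#' (expression 8, IP+Input count 50), missing-value cap (15), neighbour
#' window (<= 100 bp) and correlation (0.8), MAD threshold (0.4), edge rank
#' fraction (0.10 per tail) and alpha (0.05), hub degree (>= 4), MCL
#' inflation (1.4) and module size (>= 10), the PV/GN evaluation grids, the
#' rewiring mode and the global seed.
#'
#' @param ... overrides by name.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(expr_min = 8, count_min = 50, max_na = 15L,
              neighbor_dist = 100L, neighbor_rho = 0.8, mad_min = 0.4,
              top_frac = 0.10, alpha = 0.05, min_pairs = 10L,
              hub_min_degree = 4L, pv_prefilter = 0.05,
              inflation = 1.4, module_min_size = 10L,
              pv_grid = c(1e-1, 1e-2, 1e-3), gn_grid = c(4L, 8L, 12L, 16L),
              swaps = "auto", seed = 1L, run_baseline = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config parameter(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
  assertScalarNumber(cfg$alpha, "alpha", 0, 1)
  assertScalarNumber(cfg$top_frac, "top_frac", 0, 0.5)
  assertScalarNumber(cfg$neighbor_rho, "neighbor_rho", -1, 1)
  assertScalarNumber(cfg$inflation, "inflation", lower = 1)
  assertScalarNumber(cfg$hub_min_degree, "hub_min_degree", lower = 1)
  assertScalarNumber(cfg$module_min_size, "module_min_size", lower = 2)
  assertScalarNumber(cfg$seed, "seed", lower = 0)
  if (!length(cfg$pv_grid) || !length(cfg$gn_grid))
    stopf("pv_grid and gn_grid must be non-empty")
  cfg
}

#' Run the full annotation pipeline
#'
#' Orchestrates the stages in their fixed order: site filtering and
#' quantile normalisation, network construction, hub-based prediction with
#' its (PV, GN) performance sweep, MCL module detection and module-based
#' enrichment, cross-method overlap, and (optionally) the rewired-network
#' baseline. When `outDir` is given, all result tables plus a manifest
#' (parameters, seed, input checksums) are written there.
#'
#' @param meth [MethylationSet-class] or matrix.
#' @param sites site table.
#' @param dag [OntologyDAG-class].
#' @param annotation [GeneAnnotation-class].
#' @param config list from [pipelineConfig()].
#' @param expression,ipInputCounts optional evidence matrices for the
#'   masking stage (see [maskLowEvidence()]).
#' @param outDir optional output directory.
#' @return list with `filter_report`, `network`, `hub_annotations`,
#'   `performance`, `modules`, `module_annotations`, `overlap`, and (when
#'   `run_baseline`) `baseline` (from [randomBaseline()]) and
#'   `baseline_overlap`.
#' @export
runPipeline <- function(meth, sites, dag, annotation,
                        config = pipelineConfig(),
                        expression = NULL, ipInputCounts = NULL,
                        outDir = NULL) {
  config <- validatePipelineConfig(config)
  filt <- filterSites(meth, sites, expression, ipInputCounts,
                      exprMin = config$expr_min, countMin = config$count_min,
                      maxNA = config$max_na, maxDist = config$neighbor_dist,
                      rhoMin = config$neighbor_rho, madMin = config$mad_min)
  net <- buildNetwork(filt$meth, sites, topFrac = config$top_frac,
                      alpha = config$alpha, minPairs = config$min_pairs)
  hubAnn <- hubPredict(net, annotation, dag,
                       minDegree = config$hub_min_degree,
                       pvPrefilter = config$pv_prefilter)
  perf <- pvGnSweep(hubAnn, config$pv_grid, config$gn_grid)
  part <- mclCluster(net, inflation = config$inflation)
  modules <- significantModules(part, config$module_min_size)
  modAnn <- moduleAnnotate(modules, net, annotation, dag)
  ovl <- overlapTerms(hubAnn, modAnn)
  out <- list(filter_report = filt$report, meth = filt$meth, network = net,
              hub_annotations = hubAnn, performance = perf,
              partition = part, modules = modules,
              module_annotations = modAnn, overlap = ovl,
              config = config)
  if (isTRUE(config$run_baseline)) {
    bl <- randomBaseline(net, annotation, dag,
                         minDegree = config$hub_min_degree,
                         pvPrefilter = config$pv_prefilter,
                         seed = config$seed, nSwaps = config$swaps,
                         pvGrid = config$pv_grid, gnGrid = config$gn_grid)
    blPart <- mclCluster(bl$network, inflation = config$inflation)
    blModules <- significantModules(blPart, config$module_min_size)
    blModAnn <- moduleAnnotate(blModules, bl$network, annotation, dag)
    out$baseline <- bl
    out$baseline_overlap <- overlapTerms(bl$hubAnnotations, blModAnn)
  }
  if (!is.null(outDir)) writePipelineOutputs(out, sites, outDir)
  out
}

writePipelineOutputs <- function(res, sites, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeFilterReport(res$filter_report, file.path(outDir, "filter_report.json"))
  writeEdgeList(res$network, file.path(outDir, "edges.tsv"))
  writeGraphML(res$network, file.path(outDir, "network.graphml"))
  writeSif(res$network, file.path(outDir, "network.sif"))
  writeClusters(res$partition, file.path(outDir, "clusters.txt"))
  write.table(res$performance, file.path(outDir, "performance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- annotationTable(res$hub_annotations, sites, res$module_annotations)
  write.table(tab, file.path(outDir, "site_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$baseline)) {
    write.table(res$baseline$performance,
                file.path(outDir, "performance_random.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("comethnet")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = res$config,
    n_sites_final = nrow(res$meth),
    n_nodes = igraph::vcount(siteGraph(res$network)),
    n_edges = igraph::ecount(siteGraph(res$network)),
    n_hubs = length(res$hub_annotations),
    n_modules = length(res$modules))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
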