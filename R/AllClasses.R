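#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MethylationSet: site-by-condition methylation levels
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one assay,
#' `"level"`, with one row per m6A site and one column per experimental
#' condition. Values are log2 IP/Input fold enrichments; `NA` marks cells
#' masked for low evidence. Row metadata may carry `gc_fraction` (GC content
#' of the quantification window, in \[0,1\]) and the host-gene labels
#' `gene_entrez` / `gene_symbol` used downstream for annotation.
#'
#' @slot .Data inherited SummarizedExperiment machinery.
#' @seealso [MethylationSet()] for construction, [buildNetwork()] for the
#'   downstream network.
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  if (!"level" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'level' is required")
  rd <- SummarizedExperiment::rowData(object)
  if ("gc_fraction" %in% colnames(rd)) {
    gc <- rd$gc_fraction
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
      msg <- c(msg, "gc_fraction must lie within [0, 1]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "site ids (rownames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param level numeric matrix, sites x conditions; rownames are site ids and
#'   colnames condition labels. `NA` encodes missing values.
#' @param siteData optional `data.frame`/`DataFrame` of per-site metadata
#'   (e.g. `gc_fraction`, `gene_entrez`, `gene_symbol`), rows parallel to
#'   `level`.
#' @return a [MethylationSet-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("c", 1:5)))
#' ms <- MethylationSet(m)
#' dim(ms)
#' @export
MethylationSet <- function(level, siteData = NULL) {
  if (!is.matrix(level) || !is.numeric(level))
    stopf("'level' must be a numeric matrix")
  if (is.null(rownames(level)))
    rownames(level) <- paste0("site_", seq_len(nrow(level)))
  if (is.null(colnames(level)))
    colnames(level) <- paste0("cond_", seq_len(ncol(level)))
  if (is.null(siteData))
    siteData <- S4Vectors::DataFrame(row.names = rownames(level))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(level = level),
    rowData = siteData)
  new("MethylationSet", se)
}

#' Extract the methylation-level matrix
#' @param x a [MethylationSet-class]
#' @return numeric matrix sites x conditions.
#' @export
methLevels <- function(x) {
  stopifnot(is(x, "MethylationSet"))
  SummarizedExperiment::assay(x, "level")
}

#' MeripCountSet: IP/Input read counts over site windows
#'
#' A SummarizedExperiment with a `"counts"` assay (sites x samples,
#' non-negative integers) and per-sample metadata columns `condition`,
#' `assay` (one of `"IP"`, `"Input"`), `seq_type` (`"single"`/`"paired"`,
#' informational) and `replicate_group`. Every condition must provide at
#' least one IP and one Input sample.
#'
#' @export
setClass("MeripCountSet", contains = "SummarizedExperiment")

setValidity("MeripCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  need <- c("condition", "assay")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, sprintf("missing sample metadata column(s): %s",
                          paste(miss, collapse = ", ")))
  } else {
    if (!all(cd$assay %in% c("IP", "Input")))
      msg <- c(msg, "assay labels must be 'IP' or 'Input'")
    tab <- table(cd$condition, cd$assay)
    if (!all(c("IP", "Input") %in% colnames(tab)) || any(tab == 0))
      msg <- c(msg, "every condition needs at least one IP and one Input sample")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MeripCountSet
#'
#' @param counts integer matrix, sites x samples.
#' @param sampleData data.frame with one row per sample; columns `condition`,
#'   `assay` ("IP"/"Input"), optionally `seq_type` and `replicate_group`.
#' @return a [MeripCountSet-class].
#' @export
MeripCountSet <- function(counts, sampleData) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("site_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  sampleData <- S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  if (is.null(sampleData$replicate_group) && !is.null(sampleData$condition))
    sampleData$replicate_group <- sampleData$condition
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData)
  new("MeripCountSet", se)
}

#' CoMethNetwork: the RNA co-methylation network
#'
#' An undirected simple graph whose nodes are m6A sites (with host-gene
#' attributes `gene_entrez`, `gene_symbol`) and whose edges mark strongly
#' correlated or anti-correlated methylation profiles. Each edge carries the
#' Spearman coefficient `scc`, the raw Fisher asymptotic p-value `p_raw`, the
#' Bonferroni-adjusted `p_adj`, the correlation `sign`, and `weight = |scc|`
#' (used as MCL input). Isolated annotated sites are retained as nodes.
#'
#' @slot graph the underlying \pkg{igraph} object.
#' @slot nConditions integer, the number of conditions behind the p-values.
#' @slot params list of construction parameters (top_frac, alpha, min_pairs,
#'   rank thresholds, number of tested pairs).
#' @export
setClass("CoMethNetwork",
         representation(graph = "ANY", nConditions = "integer",
                        params = "list"))

setValidity("CoMethNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("slot 'graph' must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must have no self-loops")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "graph must be simple")
  if (igraph::ecount(g) > 0) {
    ea <- igraph::edge_attr_names(g)
    need <- c("scc", "p_raw", "p_adj", "sign")
    if (!all(need %in% ea)) {
      msg <- c(msg, "edges must carry scc, p_raw, p_adj, sign")
    } else {
      scc <- igraph::E(g)$scc
      if (any(abs(scc) > 1)) msg <- c(msg, "scc out of [-1, 1]")
      if (any(igraph::E(g)$sign != ifelse(scc >= 0, "+", "-")))
        msg <- c(msg, "edge sign must match sign(scc)")
      p <- c(igraph::E(g)$p_raw, igraph::E(g)$p_adj)
      if (any(p < 0 | p > 1)) msg <- c(msg, "p-values out of [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CoMethNetwork-class underlying igraph object.
#' @param x,object a `CoMethNetwork`.
#' @export
siteGraph <- function(x) {
  stopifnot(is(x, "CoMethNetwork"))
  x@graph
}

#' @describeIn CoMethNetwork-class number of conditions used for p-values.
#' @export
nConditions <- function(x) {
  stopifnot(is(x, "CoMethNetwork"))
  x@nConditions
}

#' @describeIn CoMethNetwork-class edges as a data.frame
#'   (site_a, site_b, scc, p_raw, p_adj, sign).
#' @export
edgeTable <- function(x) {
  g <- siteGraph(x)
  if (igraph::ecount(g) == 0) {
    return(data.frame(site_a = character(), site_b = character(),
                      scc = numeric(), p_raw = numeric(), p_adj = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(site_a = el[, 1], site_b = el[, 2],
             scc = igraph::E(g)$scc, p_raw = igraph::E(g)$p_raw,
             p_adj = igraph::E(g)$p_adj, sign = igraph::E(g)$sign,
             stringsAsFactors = FALSE)
}

setMethod("show", "CoMethNetwork", function(object) {
  g <- object@graph
  cat(sprintf("CoMethNetwork: %d sites, %d co-methylation edges (n = %d conditions)\n",
              igraph::vcount(g), igraph::ecount(g), object@nConditions))
  if (igraph::ecount(g) > 0) {
    cat(sprintf("  |scc| range %.3f..%.3f; %d positive, %d negative edges\n",
                min(abs(igraph::E(g)$scc)), max(abs(igraph::E(g)$scc)),
                sum(igraph::E(g)$sign == "+"), sum(igraph::E(g)$sign == "-")))
  }
  invisible(NULL)
})

#' OntologyDAG: a GO biological-process is_a DAG with a slim subset
#'
#' Parsed from OBO (see [readObo()]); only `is_a` relations are honoured.
#' Ancestor sets are precomputed at construction, which also certifies
#' acyclicity.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list: term id -> character vector of direct parents.
#' @slot ancestors named list: term id -> all transitive is_a ancestors
#'   (excluding the term itself).
#' @slot slimIds character, the GO-slim subset.
#' @slot rootId character(1), the namespace root (GO:0008150 for BP).
#' @export
setClass("OntologyDAG",
         representation(terms = "data.frame", parents = "list",
                        ancestors = "list", slimIds = "character",
                        rootId = "character"))

setValidity("OntologyDAG", function(object) {
  msg <- character()
  ids <- object@terms$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate term ids")
  if (!all(object@slimIds %in% ids))
    msg <- c(msg, "slimIds must be a subset of term ids")
  if (length(object@rootId) != 1L || !object@rootId %in% ids)
    msg <- c(msg, "rootId must name a single known term")
  bad <- setdiff(unlist(object@parents), ids)
  if (length(bad))
    msg <- c(msg, sprintf("is_a parent(s) not in term set: %s",
                          paste(head(bad, 3), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms (%d slim), root %s\n",
              nrow(object@terms), length(object@slimIds), object@rootId))
  invisible(NULL)
})

#' @describeIn OntologyDAG-class term ids in the DAG.
#' @param x,object an `OntologyDAG`.
#' @export
termIds <- function(x) {
  stopifnot(is(x, "OntologyDAG"))
  x@terms$id
}

#' @describeIn OntologyDAG-class the GO-slim term ids.
#' @export
slimIds <- function(x) {
  stopifnot(is(x, "OntologyDAG"))
  x@slimIds
}

#' GeneAnnotation: gene-to-GO-term assignments
#'
#' Holds the direct gene -> term table and its propagation (closure under
#' is_a ancestors), the form in which all enrichment is computed.
#'
#' @slot direct named list: gene id -> character vector of directly
#'   annotated term ids.
#' @slot propagated named list: gene id -> direct terms plus all ancestors.
#' @export
setClass("GeneAnnotation",
         representation(direct = "list", propagated = "list"))

setValidity("GeneAnnotation", function(object) {
  if (!identical(sort(names(object@direct)), sort(names(object@propagated))))
    return("direct and propagated must cover the same genes")
  for (g in names(object@direct)) {
    if (!all(object@direct[[g]] %in% object@propagated[[g]]))
      return(sprintf("direct terms of gene %s missing from propagated set", g))
  }
  TRUE
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes, %d direct / %d propagated assignments\n",
              length(object@direct), length(unlist(object@direct)),
              length(unlist(object@propagated))))
  invisible(NULL)
})

#' @describeIn GeneAnnotation-class annotated gene ids.
#' @param x,object a `GeneAnnotation`.
#' @export
annotatedGenes <- function(x) {
  stopifnot(is(x, "GeneAnnotation"))
  names(x@direct)
}

#' @describeIn GeneAnnotation-class propagated term set of one gene
#'   (character(0) for unknown genes).
#' @param gene gene identifier.
#' @export
geneTerms <- function(x, gene) {
  stopifnot(is(x, "GeneAnnotation"))
  out <- x@propagated[[as.character(gene)]]
  if (is.null(out)) character(0) else out
}
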