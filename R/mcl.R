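#' Markov Cluster algorithm (MCL)
#'
#' From-scratch dense implementation of MCL, the stochastic-flow graph
#' clustering used to find co-methylation modules. Self loops are added,
#' the weighted adjacency matrix is column-normalised, and expansion
#' (matrix power), inflation (elementwise power + renormalisation) and
#' pruning alternate until the flow matrix stops changing. Clusters are
#' read off the attractor rows of the limit matrix; a node supported by
#' several attractors is assigned to the attractor with the smallest node
#' index (deterministic tie-break).
#'
#' @param graph igraph object (undirected; non-negative `weight` edge
#'   attribute used if present, else unit weights) or a
#'   [CoMethNetwork-class] (uses `|scc|` weights).
#' @param inflation inflation exponent > 1 controlling granularity,
#'   default 1.4.
#' @param expansion integer matrix-power >= 2, default 2.
#' @param selfLoopWeight weight of the added self loops, default 1.
#' @param pruneThreshold flow entries below this are zeroed each iteration
#'   (default 1e-5); set 0 to disable.
#' @param maxIter iteration cap, default 200.
#' @param convergenceTol convergence threshold on the max absolute change,
#'   default 1e-8.
#' @return list with `clusters` (list of character vectors of node names,
#'   decreasing size, ties broken by smallest member), `membership` (named
#'   integer vector) and `converged` (logical).
#' @export
mclCluster <- function(graph, inflation = 1.4, expansion = 2L,
                       selfLoopWeight = 1, pruneThreshold = 1e-5,
                       maxIter = 200L, convergenceTol = 1e-8) {
  if (is(graph, "CoMethNetwork")) graph <- siteGraph(graph)
  assertScalarNumber(inflation, "inflation", lower = 1)
  if (inflation <= 1) stopf("'inflation' must exceed 1")
  assertScalarNumber(expansion, "expansion", lower = 2)
  assertScalarNumber(selfLoopWeight, "selfLoopWeight", lower = 0)
  w <- igraph::edge_attr(graph, "weight")
  if (!is.null(w) && any(w < 0)) stopf("edge weights must be non-negative")
  A <- as.matrix(igraph::as_adjacency_matrix(
    graph, attr = if (is.null(w)) NULL else "weight", sparse = TRUE))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(A)))
  lim <- mclIterate(A, inflation, expansion, selfLoopWeight,
                    pruneThreshold, maxIter, convergenceTol)
  part <- mclInterpret(lim$M, nodes)
  c(part, list(converged = lim$converged, iterations = lim$iterations))
}

# Core flow iteration on a dense matrix; shared contract with the naive
# oracle used in the tests (which runs without pruning).
mclIterate <- function(A, inflation, expansion, selfLoopWeight,
                       pruneThreshold, maxIter, convergenceTol) {
  n <- nrow(A)
  diag(A) <- selfLoopWeight
  M <- normalizeCols(A)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ inflation
    Minf <- normalizeCols(Minf)
    if (pruneThreshold > 0) {
      Minf[Minf < pruneThreshold] <- 0
      Minf <- normalizeCols(Minf)
    }
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < convergenceTol) { converged <- TRUE; break }
  }
  list(M = M, converged = converged, iterations = it)
}

normalizeCols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

# Attractors are rows with positive diagonal mass; each attractor's cluster
# is its row support. Nodes claimed by several attractors go to the one
# with the smallest node index; attractors sharing members are merged
# transitively through that assignment.
mclInterpret <- function(M, nodes) {
  n <- nrow(M)
  eps <- .Machine$double.eps * 100
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- which(apply(M, 1, max) > eps)
  membership <- integer(n)
  owner <- rep(NA_integer_, n)
  for (a in attractors) {
    support <- which(M[a, ] > eps)
    for (j in support) {
      if (is.na(owner[j]) || a < owner[j]) owner[j] <- a
    }
  }
  # attractors claimed by a smaller attractor inherit its cluster
  root <- function(a) {
    while (!is.na(owner[a]) && owner[a] != a) a <- owner[a]
    a
  }
  for (j in seq_len(n)) {
    owner[j] <- if (is.na(owner[j])) j else root(owner[j])
  }
  ids <- sort(unique(owner))
  membership <- match(owner, ids)
  names(membership) <- nodes
  clusters <- split(nodes, membership)
  sizes <- lengths(clusters)
  firstMember <- vapply(clusters, function(cl) min(match(cl, nodes)), 0)
  ord <- order(-sizes, firstMember)
  clusters <- unname(clusters[ord])
  relabel <- match(seq_along(ord), ord)
  membership <- relabel[membership]
  names(membership) <- nodes
  list(clusters = clusters, membership = membership)
}

#' Select significant modules from an MCL partition
#'
#' Modules are clusters with at least `minSize` members (default 10,
#' i.e. "more than 9 sites"), ordered by decreasing size with ties broken
#' by smallest member id.
#'
#' @param partition result of [mclCluster()] (or any list with a
#'   `clusters` component).
#' @param minSize minimum module size, default 10.
#' @return list of character vectors (module member ids).
#' @export
significantModules <- function(partition, minSize = 10L) {
  cl <- partition$clusters
  cl <- cl[lengths(cl) >= minSize]
  if (!length(cl)) return(list())
  ord <- order(-lengths(cl), vapply(cl, function(x) sort(x)[1], ""))
  cl[ord]
}

#' Write an MCL edge-list input file
#'
#' Tab-separated `node_a node_b weight` rows, the native input shape of
#' the mcl tool; the co-methylation network exports `|scc|` as weight.
#'
#' @param net [CoMethNetwork-class].
#' @param path output path.
#' @param weights `"abs"` (default, `|scc|`) or `"unit"`.
#' @export
writeMclInput <- function(net, path, weights = c("abs", "unit")) {
  weights <- match.arg(weights)
  et <- edgeTable(net)
  w <- if (weights == "abs") abs(et$scc) else rep(1, nrow(et))
  write.table(data.frame(et$site_a, et$site_b, w), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an MCL partition in mcl's native output shape
#' @param partition result of [mclCluster()].
#' @param path output path (one cluster per line, tab-separated members).
#' @export
writeClusters <- function(partition, path) {
  lines <- vapply(partition$clusters, paste, "", collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}
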