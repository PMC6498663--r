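#' Pairwise-complete Spearman correlation between all site pairs
#'
#' Correlations are computed per pair on the conditions where both sites are
#' observed, with average ranks for ties; pairs with fewer than `minPairs`
#' complete observations are set undefined (`NA`) and excluded from edge
#' ranking downstream.
#'
#' @param meth [MethylationSet-class] or matrix, sites x conditions.
#' @param minPairs minimum complete observations per pair, default 10.
#' @return list with `rho` (sites x sites, diagonal `NA`) and `nObs`
#'   (integer matrix of complete-pair counts).
#' @export
spearmanMatrix <- function(meth, minPairs = 10L) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  if (nrow(x) < 2) stopf("at least 2 sites are required")
  rho <- suppressWarnings(
    cor(t(x), method = "spearman", use = "pairwise.complete.obs"))
  obs <- !is.na(x)
  nObs <- obs %*% t(obs)
  storage.mode(nObs) <- "integer"
  rho[nObs < minPairs] <- NA_real_
  diag(rho) <- NA_real_
  list(rho = rho, nObs = nObs)
}

#' Fisher asymptotic p-value for a Spearman correlation
#'
#' Under the null, the Fisher transform `z = atanh(rho)` scaled by
#' `sqrt(n - 3)` is approximately standard normal; the two-sided tail gives
#' the p-value. Monotone decreasing in `|rho|` at fixed `n`.
#'
#' @param rho correlation(s) in \[-1, 1\] (vectorised).
#' @param n number of paired observations (>= 4), scalar or parallel vector.
#' @return p-values in \[0, 1\]; `|rho| = 1` yields 0 with attribute
#'   `underflow = TRUE`.
#' @examples
#' fisherPvalue(0.6, 32)
#' @export
fisherPvalue <- function(rho, n) {
  if (any(n < 4, na.rm = TRUE)) stopf("'n' must be at least 4")
  if (any(abs(rho) > 1, na.rm = TRUE)) stopf("'rho' must lie in [-1, 1]")
  z <- atanh(pmin(pmax(rho, -1), 1))
  p <- 2 * pnorm(-abs(z) * sqrt(n - 3))
  exact <- !is.na(rho) & abs(rho) == 1
  if (any(exact)) {
    p[exact] <- 0
    attr(p, "underflow") <- TRUE
  }
  p
}

#' Bonferroni adjustment
#'
#' @param p p-values in \[0, 1\].
#' @param m number of tests (>= `length(p)` of defined tests); defaults to
#'   `length(p)`.
#' @return `pmin(1, m * p)`, order preserving.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#' @inheritParams bonferroniAdjust
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Build the co-methylation network
#'
#' A site pair becomes an edge when its Spearman coefficient ranks in the
#' highest or lowest `topFrac` of all defined off-diagonal pair
#' correlations (boundary ties included) AND its Bonferroni-adjusted Fisher
#' p-value is below `alpha`. Sites without gene annotation are removed
#' before ranking; annotated isolated sites are kept as nodes.
#'
#' @param meth [MethylationSet-class] or matrix (filtered, normalised).
#' @param sites site table with `site_id`, `gene_entrez`, `gene_symbol`.
#' @param topFrac tail fraction for the rank gate, default 0.10 per side.
#' @param alpha significance level on the adjusted p, default 0.05 (strict).
#' @param minPairs see [spearmanMatrix()].
#' @return a [CoMethNetwork-class].
#' @export
buildNetwork <- function(meth, sites, topFrac = 0.10, alpha = 0.05,
                         minPairs = 10L) {
  assertScalarNumber(topFrac, "topFrac", 0, 0.5)
  assertScalarNumber(alpha, "alpha", 0, 1)
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  sites <- sites[match(rownames(x), sites$site_id), ]
  annotated <- !is.na(sites$gene_entrez)
  if (any(!annotated)) {
    message(sprintf("%d site(s) dropped: no gene annotation", sum(!annotated)))
    x <- x[annotated, , drop = FALSE]
    sites <- sites[annotated, , drop = FALSE]
  }
  sm <- spearmanMatrix(x, minPairs)
  rho <- sm$rho
  nUse <- ncol(x)
  ut <- upper.tri(rho)
  defined <- ut & !is.na(rho)
  m <- sum(defined)
  if (m == 0) {
    warnf("no defined site pairs; returning an edgeless network")
    g <- igraph::make_empty_graph(n = nrow(x), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = rownames(x))
  } else {
    rhos <- rho[defined]
    hi <- quantile(rhos, 1 - topFrac, names = FALSE)
    lo <- quantile(rhos, topFrac, names = FALSE)
    idx <- which(defined & (rho >= hi | rho <= lo), arr.ind = TRUE)
    nPair <- sm$nObs[idx]
    pRaw <- fisherPvalue(rho[idx], pmax(nPair, 4L))
    pAdj <- bonferroniAdjust(as.numeric(pRaw), m)
    keep <- pAdj < alpha
    idx <- idx[keep, , drop = FALSE]
    ed <- data.frame(from = rownames(x)[idx[, 1]],
                     to = rownames(x)[idx[, 2]],
                     scc = rho[idx],
                     p_raw = as.numeric(pRaw)[keep],
                     p_adj = pAdj[keep],
                     stringsAsFactors = FALSE)
    ed$sign <- ifelse(ed$scc >= 0, "+", "-")
    ed$weight <- abs(ed$scc)
    g <- igraph::graph_from_data_frame(
      ed, directed = FALSE,
      vertices = data.frame(name = rownames(x), stringsAsFactors = FALSE))
  }
  g <- igraph::set_vertex_attr(g, "gene_entrez", value = sites$gene_entrez)
  g <- igraph::set_vertex_attr(g, "gene_symbol", value = sites$gene_symbol)
  params <- list(top_frac = topFrac, alpha = alpha, min_pairs = minPairs,
                 n_pairs_tested = m)
  if (m > 0) params <- c(params, list(rho_hi = hi, rho_lo = lo))
  new("CoMethNetwork", graph = g, nConditions = as.integer(nUse),
      params = params)
}

#' Fit a power law to the degree distribution
#'
#' Least-squares fit of log10 frequency on log10 degree over positive
#' degrees; scale-free networks show an approximately linear trend with
#' exponent (negative slope) near 2-3.
#'
#' @param net [CoMethNetwork-class] or igraph object.
#' @return list with `degrees` (frequency table), `exponent` and
#'   `fit_range` (degree bounds used).
#' @export
degreeFit <- function(net) {
  g <- if (is(net, "CoMethNetwork")) siteGraph(net) else net
  deg <- igraph::degree(g)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3)
    stopf("degree fit needs at least 3 distinct positive degrees")
  d <- as.numeric(names(tab))
  f <- as.numeric(tab)
  fit <- lm(log10(f) ~ log10(d))
  list(degrees = tab, exponent = -unname(coef(fit)[2]),
       fit_range = range(d))
}

#' Degree-preserving random rewiring
#'
#' The null network is obtained by repeated double edge swaps: two edges
#' (a,b) and (c,d) are replaced by (a,d) and (c,b) provided neither new
#' edge already exists and no self-loop arises; otherwise the proposal is
#' rejected and does not count as a performed swap. Every node keeps its
#' exact degree. Graphs admitting no valid swap (e.g. a triangle) are
#' returned unchanged once the attempt budget is exhausted.
#'
#' @param net [CoMethNetwork-class] or igraph object.
#' @param nSwaps number of successful swaps to perform; the default
#'   `"auto"` uses 100 x |E| (adequate mixing); `"literal"` performs 100
#'   total swaps (the historical count); or give an integer.
#' @param seed integer seed; same seed, same output.
#' @param maxTries attempt budget (default `50 * nSwaps + 1000`).
#' @return object of the same type with rewired edges; edge attributes are
#'   dropped except a unit weight (correlation statistics do not transfer to
#'   randomised pairs).
#' @export
rewireNetwork <- function(net, nSwaps = "auto", seed = 1L, maxTries = NULL) {
  g <- if (is(net, "CoMethNetwork")) siteGraph(net) else net
  m <- igraph::ecount(g)
  if (identical(nSwaps, "auto")) nSwaps <- 100L * m
  if (identical(nSwaps, "literal")) nSwaps <- 100L
  nSwaps <- as.integer(nSwaps)
  if (nSwaps < 0) stopf("'nSwaps' must be non-negative")
  if (is.null(maxTries)) maxTries <- 50L * max(nSwaps, 1L) + 1000L
  if (m < 2 || nSwaps == 0) return(rewrapRewired(net, g))
  el <- igraph::as_edgelist(g, names = FALSE)
  nV <- igraph::vcount(g)
  # unordered-pair membership as an indexed logical vector: O(1) lookups
  pk <- function(a, b) (pmin(a, b) - 1) * nV + pmax(a, b)
  adj <- logical(nV * nV)
  adj[pk(el[, 1], el[, 2])] <- TRUE
  withSeed(seed, {
    done <- 0L; tries <- 0L
    batch <- 0L; bSize <- 16384L
    E1 <- E2 <- integer(0); FL <- logical(0)
    while (done < nSwaps && tries < maxTries) {
      batch <- batch + 1L
      if (batch > length(E1)) {  # draw proposals in bulk: loop stays scalar
        E1 <- sample.int(m, bSize, replace = TRUE)
        E2 <- sample.int(m - 1L, bSize, replace = TRUE)
        FL <- runif(bSize) < 0.5
        batch <- 1L
      }
      tries <- tries + 1L
      e1 <- E1[batch]; e2 <- E2[batch]
      if (e2 >= e1) e2 <- e2 + 1L
      a <- el[e1, 1L]; b <- el[e1, 2L]
      c <- el[e2, 1L]; d <- el[e2, 2L]
      # random orientation of the second edge covers both re-pairings
      if (FL[batch]) { tmp <- c; c <- d; d <- tmp }
      if (a == d || c == b) next
      k1 <- (min(a, d) - 1) * nV + max(a, d)
      k2 <- (min(c, b) - 1) * nV + max(c, b)
      if (k1 == k2 || adj[k1] || adj[k2]) next
      adj[(min(a, b) - 1) * nV + max(a, b)] <- FALSE
      adj[(min(c, d) - 1) * nV + max(c, d)] <- FALSE
      adj[k1] <- TRUE; adj[k2] <- TRUE
      el[e1, 1L] <- a; el[e1, 2L] <- d
      el[e2, 1L] <- c; el[e2, 2L] <- b
      done <- done + 1L
    }
  })
  g2 <- igraph::make_empty_graph(n = igraph::vcount(g), directed = FALSE)
  g2 <- igraph::add_edges(g2, t(el))
  igraph::vertex_attr(g2) <- igraph::vertex_attr(g)
  igraph::E(g2)$weight <- 1
  rewrapRewired(net, g2)
}

rewrapRewired <- function(net, g) {
  if (is(net, "CoMethNetwork")) {
    igraph::E(g)$scc <- rep(0, igraph::ecount(g))
    igraph::E(g)$p_raw <- rep(1, igraph::ecount(g))
    igraph::E(g)$p_adj <- rep(1, igraph::ecount(g))
    igraph::E(g)$sign <- rep("+", igraph::ecount(g))
    new("CoMethNetwork", graph = g, nConditions = net@nConditions,
        params = c(net@params, list(rewired = TRUE)))
  } else g
}

#' Constrain neighbour-gene counts of a rewired network
#'
#' Hub sites in the real network whose neighbours collapse onto few genes
#' would otherwise gain artificially many neighbour genes after rewiring;
#' for each real-network hub, the rewired network's neighbour genes are
#' subsampled (seeded, uniform) to the hub's real neighbour-gene count, or
#' kept entirely if fewer.
#'
#' @param randomNet,realNet [CoMethNetwork-class] objects over the same
#'   node set.
#' @param minDegree hub threshold on the real network, default 4.
#' @param seed integer seed.
#' @return named list: hub site id -> character vector of neighbour genes
#'   to use for random-baseline annotation.
#' @export
constrainNeighborGenes <- function(randomNet, realNet, minDegree = 4L,
                                   seed = 1L) {
  gr <- siteGraph(realNet); gq <- siteGraph(randomNet)
  if (!setequal(igraph::V(gr)$name, igraph::V(gq)$name))
    stopf("networks must share the same node set")
  hubs <- findHubs(realNet, minDegree)
  seeds <- childSeeds(seed, max(length(hubs), 1L))
  out <- vector("list", length(hubs))
  names(out) <- hubs
  for (i in seq_along(hubs)) {
    h <- hubs[i]
    realGenes <- neighborGenes(gr, h)
    randGenes <- neighborGenes(gq, h)
    k <- length(realGenes)
    out[[i]] <- if (length(randGenes) > k) {
      withSeed(seeds[i], sort(sample(randGenes, k)))
    } else randGenes
  }
  out
}

neighborGenes <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  genes <- igraph::vertex_attr(g, "gene_entrez", nb)
  sort(unique(as.character(genes[!is.na(genes)])))
}

#' Leave-one-condition-out network stability
#'
#' For each condition, the network is rebuilt without it and compared with
#' the all-condition network through the odds ratio of the 2x2 edge
#' presence/absence table over all node pairs (Haldane-Anscombe +0.5 when
#' any cell is zero). Conditions whose removal collapses the odds ratio are
#' influential outlier candidates.
#'
#' @param meth [MethylationSet-class] or matrix with >= 4 conditions.
#' @param builder function(meth_subset) returning a [CoMethNetwork-class];
#'   defaults to [buildNetwork()] with `sites`.
#' @param sites site table (used by the default builder).
#' @param ... passed to [buildNetwork()] by the default builder.
#' @return named numeric vector of per-condition odds ratios.
#' @export
leaveOneOutInfluence <- function(meth, builder = NULL, sites = NULL, ...) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  if (ncol(x) < 4) stopf("at least 4 conditions are required")
  if (is.null(builder)) {
    if (is.null(sites)) stopf("provide 'sites' or a custom 'builder'")
    builder <- function(mm) buildNetwork(mm, sites, ...)
  }
  full <- builder(meth)
  adjFull <- adjVector(full)
  ors <- vapply(colnames(x), function(cond) {
    sub <- if (is(meth, "MethylationSet")) meth[, colnames(x) != cond]
           else x[, colnames(x) != cond, drop = FALSE]
    adjSub <- adjVector(builder(sub))
    oddsRatio2x2(adjFull, adjSub)
  }, numeric(1))
  ors
}

adjVector <- function(net) {
  g <- siteGraph(net)
  n <- igraph::vcount(g)
  a <- matrix(FALSE, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = TRUE)
    a[el] <- TRUE
    a[el[, c(2, 1), drop = FALSE]] <- TRUE
  }
  a[upper.tri(a)]
}

oddsRatio2x2 <- function(u, v) {
  n11 <- sum(u & v); n10 <- sum(u & !v)
  n01 <- sum(!u & v); n00 <- sum(!u & !v)
  if (min(n11, n10, n01, n00) == 0) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  (n11 * n00) / (n10 * n01)
}

#' Collapse the site network to a gene network
#'
#' Two genes are co-methylated when any site pair across them is an edge;
#' edges between sites of the same gene do not create self-loops.
#'
#' @param net [CoMethNetwork-class].
#' @return igraph object over gene ids.
#' @export
siteToGeneNetwork <- function(net) {
  g <- siteGraph(net)
  gene <- as.character(igraph::V(g)$gene_entrez)
  genes <- sort(unique(gene[!is.na(gene)]))
  if (igraph::ecount(g) == 0)
    return(igraph::make_empty_graph(length(genes), directed = FALSE) |>
             igraph::set_vertex_attr("name", value = genes))
  el <- igraph::as_edgelist(g, names = FALSE)
  g1 <- gene[el[, 1]]; g2 <- gene[el[, 2]]
  ok <- !is.na(g1) & !is.na(g2) & g1 != g2
  ge <- unique(data.frame(a = pmin(g1[ok], g2[ok]), b = pmax(g1[ok], g2[ok])))
  igraph::graph_from_data_frame(ge, directed = FALSE,
                                vertices = data.frame(name = genes))
}

#' Correlation between two networks' adjacency structures
#'
#' Pearson correlation of the vectorised upper-triangle adjacency
#' indicators over a shared node set; near-zero values mean the two
#' networks share essentially no edges beyond chance.
#'
#' @param netA,netB [CoMethNetwork-class] or igraph objects with identical
#'   node sets.
#' @return correlation; 0 with attribute `degenerate = TRUE` when either
#'   network is edgeless or complete.
#' @export
compareNetworks <- function(netA, netB) {
  ga <- if (is(netA, "CoMethNetwork")) siteGraph(netA) else netA
  gb <- if (is(netB, "CoMethNetwork")) siteGraph(netB) else netB
  if (!setequal(igraph::V(ga)$name, igraph::V(gb)$name))
    stopf("networks must share the same node set")
  nm <- sort(igraph::V(ga)$name)
  va <- adjVectorNamed(ga, nm); vb <- adjVectorNamed(gb, nm)
  if (length(unique(va)) < 2 || length(unique(vb)) < 2) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cor(as.numeric(va), as.numeric(vb))
}

adjVectorNamed <- function(g, nm) {
  n <- length(nm)
  a <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = TRUE)
    a[el] <- TRUE
    a[el[, c(2, 1), drop = FALSE]] <- TRUE
  }
  a[upper.tri(a)]
}

#' Export the network
#'
#' @param net [CoMethNetwork-class].
#' @param path output path.
#' @describeIn exportNetwork edge list TSV
#'   (site_a, site_b, scc, p_raw, p_adj).
#' @export
writeEdgeList <- function(net, path) {
  write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @describeIn exportNetwork GraphML (for igraph/Cytoscape import).
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(stripNullAttrs(siteGraph(net)), path, format = "graphml")
  invisible(path)
}

#' @describeIn exportNetwork SIF interaction file for Cytoscape; the
#'   interaction type is the correlation sign.
#' @export
writeSif <- function(net, path) {
  et <- edgeTable(net)
  sif <- data.frame(a = et$site_a,
                    type = ifelse(et$sign == "+", "pos", "neg"),
                    b = et$site_b)
  write.table(sif, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# graphml export chokes on NA-typed attributes; coerce to character
stripNullAttrs <- function(g) {
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (!is.numeric(v)) igraph::vertex_attr(g, a) <- as.character(ifelse(is.na(v), "", v))
    else if (anyNA(v)) igraph::vertex_attr(g, a) <- ifelse(is.na(v), -1, v)
  }
  g
}
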