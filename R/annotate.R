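#' Hub sites of the co-methylation network
#'
#' Hubs are sites with more than three immediate neighbours
#' (degree >= `minDegree`, default 4).
#'
#' @param net [CoMethNetwork-class] or igraph object.
#' @param minDegree minimum degree, default 4.
#' @return character vector of hub site ids.
#' @export
findHubs <- function(net, minDegree = 4L) {
  g <- if (is(net, "CoMethNetwork")) siteGraph(net) else net
  deg <- igraph::degree(g)
  names(deg)[deg >= minDegree]
}

#' Guilt-by-association annotation of hub sites
#'
#' For each hub, the distinct host genes of its immediate neighbours form
#' the study set (the hub's own gene excluded by default, to avoid
#' self-confirmation); GO-BP enrichment against the background yields the
#' predicted terms (prefiltered at `pvPrefilter` on the raw p), which are
#' reduced to slim terms, each slim term carrying the minimum p of its
#' source terms. The hub's "known" terms are the slim reduction of its own
#' gene's propagated annotation — a soft benchmark, since site-level
#' functional truth is unavailable. GO:0008150 is excluded throughout.
#'
#' @param net [CoMethNetwork-class].
#' @param annotation [GeneAnnotation-class].
#' @param dag [OntologyDAG-class] with its slim set.
#' @param background gene universe; default all genes hosting a network
#'   site.
#' @param minDegree hub threshold, default 4.
#' @param pvPrefilter raw-p prefilter on enriched terms, default 0.05.
#' @param excludeOwnGene drop the hub's host gene from its study set,
#'   default TRUE.
#' @param neighborGeneSets optional named list overriding each hub's
#'   neighbour-gene study set (used by the constrained random baseline).
#' @param hubs optional explicit hub id vector (default [findHubs()]).
#' @return list of per-hub records (class `hubAnnotation`): `hub_site_id`,
#'   `degree`, `neighbor_site_ids`, `neighbor_gene_ids`,
#'   `known_slim_terms`, `predicted` (data.frame `term`, `p`),
#'   `enriched_terms` (pre-slim data.frame), `hit_terms`,
#'   `known_annotated` (FALSE when the hub gene has no annotation).
#' @export
hubPredict <- function(net, annotation, dag, background = NULL,
                       minDegree = 4L, pvPrefilter = 0.05,
                       excludeOwnGene = TRUE, neighborGeneSets = NULL,
                       hubs = NULL) {
  g <- siteGraph(net)
  geneOf <- setNames(as.character(igraph::V(g)$gene_entrez),
                     igraph::V(g)$name)
  if (is.null(background))
    background <- sort(unique(geneOf[!is.na(geneOf)]))
  if (is.null(hubs)) hubs <- findHubs(net, minDegree)
  slim <- setdiff(slimIds(dag), dag@rootId)
  out <- lapply(hubs, function(h) {
    nb <- igraph::neighbors(g, h)$name
    nbGenes <- sort(unique(geneOf[nb]))
    nbGenes <- nbGenes[!is.na(nbGenes)]
    hubGene <- geneOf[[h]]
    study <- if (!is.null(neighborGeneSets)) neighborGeneSets[[h]] %||% character(0)
             else nbGenes
    if (excludeOwnGene) study <- setdiff(study, hubGene)
    study <- intersect(study, background)
    enr <- if (length(study)) {
      hypergeomEnrich(study, background, annotation, dag)
    } else {
      hypergeomEnrich(character(0), background, annotation, dag)
    }
    enr <- enr[enr$p_raw < pvPrefilter & enr$term_id != dag@rootId, ,
               drop = FALSE]
    predicted <- slimReduceEnrichment(dag, enr)
    knownProp <- geneTerms(annotation, hubGene)
    known <- if (length(knownProp)) mapToSlim(dag, knownProp) else character(0)
    known <- setdiff(intersect(known, c(slim, character(0))), dag@rootId)
    structure(list(hub_site_id = h,
                   degree = length(nb),
                   neighbor_site_ids = nb,
                   neighbor_gene_ids = nbGenes,
                   known_slim_terms = known,
                   predicted = predicted,
                   enriched_terms = enr,
                   hit_terms = intersect(known, predicted$term),
                   known_annotated = length(knownProp) > 0),
              class = "hubAnnotation")
  })
  names(out) <- hubs
  out
}

# Reduce an enrichment table to slim terms; each slim term inherits the
# minimum p over the enriched source terms mapping to it.
slimReduceEnrichment <- function(dag, enr) {
  if (!nrow(enr))
    return(data.frame(term = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  hits <- lapply(seq_len(nrow(enr)), function(i) {
    st <- mapToSlim(dag, enr$term_id[i])
    if (!length(st)) return(NULL)
    data.frame(term = st, p = enr$p_raw[i], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(term = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(p ~ term, hits, min)
  agg <- agg[order(agg$p, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Micro-averaged recall and precision at one (PV, GN) cutoff
#'
#' Per hub, the predicted slim terms are restricted to those with
#' enrichment p <= `pvCutoff` (PV) and truncated to the `gnCutoff` (GN)
#' smallest-p terms (ties broken by term id); hits are predictions also
#' present in the hub's known set. Sums are taken across hubs before
#' dividing: `recall = sum(hits) / sum(known)`,
#' `precision = sum(hits) / sum(predicted)`; an empty denominator yields 0
#' with attribute `undefined`.
#'
#' @param hubAnnotations result of [hubPredict()].
#' @param pvCutoff enrichment p-value cutoff.
#' @param gnCutoff maximum number of predicted slim terms per hub.
#' @return one-row data.frame: `pv_cutoff`, `gn_cutoff`, `recall`,
#'   `precision`, `n_hubs_contributing`, `sum_hits`, `sum_known`,
#'   `sum_predicted`.
#' @export
evaluatePerformance <- function(hubAnnotations, pvCutoff, gnCutoff) {
  assertScalarNumber(pvCutoff, "pvCutoff", lower = 0)
  assertScalarNumber(gnCutoff, "gnCutoff", lower = 1)
  sumHits <- sumKnown <- sumPred <- 0L
  contrib <- 0L
  for (ha in hubAnnotations) {
    pred <- ha$predicted
    pred <- pred[pred$p <= pvCutoff, , drop = FALSE]
    pred <- pred[order(pred$p, pred$term), , drop = FALSE]
    predTerms <- head(pred$term, gnCutoff)
    hits <- intersect(predTerms, ha$known_slim_terms)
    sumHits <- sumHits + length(hits)
    sumKnown <- sumKnown + length(ha$known_slim_terms)
    sumPred <- sumPred + length(predTerms)
    if (length(predTerms) || length(ha$known_slim_terms))
      contrib <- contrib + 1L
  }
  recall <- if (sumKnown > 0) sumHits / sumKnown else 0
  precision <- if (sumPred > 0) sumHits / sumPred else 0
  out <- data.frame(pv_cutoff = pvCutoff, gn_cutoff = gnCutoff,
                    recall = recall, precision = precision,
                    n_hubs_contributing = contrib,
                    sum_hits = sumHits, sum_known = sumKnown,
                    sum_predicted = sumPred)
  if (sumKnown == 0 || sumPred == 0) attr(out, "undefined") <- TRUE
  out
}

#' Recall/precision over a grid of PV and GN cutoffs
#'
#' @inheritParams evaluatePerformance
#' @param pvGrid PV cutoffs, default `c(1e-1, 1e-2, 1e-3)`.
#' @param gnGrid GN cutoffs, default `c(4, 8, 12, 16)`.
#' @return data.frame with one row per (PV, GN) combination.
#' @export
pvGnSweep <- function(hubAnnotations, pvGrid = c(1e-1, 1e-2, 1e-3),
                      gnGrid = c(4L, 8L, 12L, 16L)) {
  if (!length(pvGrid) || !length(gnGrid)) stopf("cutoff grids must be non-empty")
  grid <- expand.grid(pv = pvGrid, gn = gnGrid)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    evaluatePerformance(hubAnnotations, grid$pv[i], grid$gn[i])
  }))
}

#' Random-network baseline for the hub-based method
#'
#' Rewires the network degree-preservingly, constrains each hub's
#' neighbour-gene count to its real-network value, and re-runs the
#' hub-based prediction with the same hubs and the same known sets; the
#' resulting (PV, GN) performance grid is the null against which the real
#' network is compared.
#'
#' @inheritParams hubPredict
#' @param seed integer seed driving rewiring and gene subsampling.
#' @param nSwaps see [rewireNetwork()].
#' @param pvGrid,gnGrid see [pvGnSweep()].
#' @return list with `performance` (grid data.frame), `hubAnnotations`
#'   (per-hub records on the rewired network) and `network` (the rewired
#'   [CoMethNetwork-class]).
#' @export
randomBaseline <- function(net, annotation, dag, background = NULL,
                           minDegree = 4L, pvPrefilter = 0.05,
                           seed = 1L, nSwaps = "auto",
                           pvGrid = c(1e-1, 1e-2, 1e-3),
                           gnGrid = c(4L, 8L, 12L, 16L)) {
  seeds <- childSeeds(seed, 2)
  rnd <- rewireNetwork(net, nSwaps = nSwaps, seed = seeds[1])
  geneSets <- constrainNeighborGenes(rnd, net, minDegree, seed = seeds[2])
  hubs <- findHubs(net, minDegree)
  ha <- hubPredict(rnd, annotation, dag, background = background,
                   minDegree = minDegree, pvPrefilter = pvPrefilter,
                   neighborGeneSets = geneSets, hubs = hubs)
  # known sets come from the hub's own gene, which rewiring does not touch
  list(performance = pvGnSweep(ha, pvGrid, gnGrid),
       hubAnnotations = ha, network = rnd)
}

#' Annotate MCL modules by within-module GO enrichment
#'
#' The study set of a module is the distinct host genes of its member
#' sites; p-values are BH-adjusted across the terms tested within each
#' module, and a module is significant when any adjusted p falls below
#' `alpha`. Every member site inherits its module's enriched terms.
#'
#' @param modules list of site-id vectors (see [significantModules()]).
#' @param net [CoMethNetwork-class] (source of site-to-gene labels and the
#'   default background).
#' @param annotation [GeneAnnotation-class].
#' @param dag [OntologyDAG-class].
#' @param background gene universe; default all network genes.
#' @param alpha significance level on adjusted p, default 0.05.
#' @return list of per-module records: `module_id`, `member_site_ids`,
#'   `member_gene_ids`, `enrichment` (data.frame with `p_raw`, `p_adj`),
#'   `significant`.
#' @export
moduleAnnotate <- function(modules, net, annotation, dag,
                           background = NULL, alpha = 0.05) {
  g <- siteGraph(net)
  geneOf <- setNames(as.character(igraph::V(g)$gene_entrez),
                     igraph::V(g)$name)
  if (is.null(background))
    background <- sort(unique(geneOf[!is.na(geneOf)]))
  lapply(seq_along(modules), function(i) {
    members <- modules[[i]]
    genes <- sort(unique(geneOf[members]))
    genes <- intersect(genes[!is.na(genes)], background)
    enr <- hypergeomEnrich(genes, background, annotation, dag)
    enr <- enr[enr$term_id != dag@rootId, , drop = FALSE]
    if (nrow(enr)) enr$p_adj <- bhAdjust(enr$p_raw)
    list(module_id = i,
         member_site_ids = members,
         member_gene_ids = genes,
         enrichment = enr,
         annotated = nrow(enr) > 0,
         significant = nrow(enr) > 0 && any(enr$p_adj < alpha))
  })
}

#' Cross-method overlap of predicted terms per site
#'
#' For every site annotated by both methods (a hub site belonging to an
#' annotated module), counts the GO BP terms present in both its hub-based
#' enriched set (pre-slim terms with p < `pvCutoff`) and its module's
#' enriched set (p < `pvCutoff`); reports the per-site counts and their
#' mean. Agreement between the two methods on the real network, against
#' near-zero overlap on the rewired null, is the cross-validation of the
#' framework.
#'
#' @param hubAnnotations result of [hubPredict()].
#' @param moduleAnnotations result of [moduleAnnotate()].
#' @param pvCutoff raw-p threshold on both term sets, default 0.05.
#' @return list with `per_site` (named integer vector over doubly
#'   annotated sites) and `mean_overlap`.
#' @export
overlapTerms <- function(hubAnnotations, moduleAnnotations,
                         pvCutoff = 0.05) {
  moduleOf <- list()
  for (ma in moduleAnnotations) {
    terms <- ma$enrichment$term_id[ma$enrichment$p_raw < pvCutoff]
    for (s in ma$member_site_ids) moduleOf[[s]] <- terms
  }
  perSite <- integer(0)
  for (ha in hubAnnotations) {
    s <- ha$hub_site_id
    mterms <- moduleOf[[s]]
    if (is.null(mterms)) next
    hterms <- ha$enriched_terms$term_id[ha$enriched_terms$p_raw < pvCutoff]
    if (!length(hterms) && !length(mterms)) next
    perSite[s] <- length(intersect(hterms, mterms))
  }
  list(per_site = perSite,
       mean_overlap = if (length(perSite)) mean(perSite) else NA_real_)
}

#' Per-site annotation summary table
#'
#' One row per hub site mirroring the columns of the public results table:
#' position/strand/gene labels, neighbour counts, known and predicted term
#' counts, hit counts, and module-based term counts.
#'
#' @param hubAnnotations result of [hubPredict()].
#' @param sites site table.
#' @param moduleAnnotations optional result of [moduleAnnotate()].
#' @param pvCutoff raw-p cutoff used for the module term counts.
#' @return data.frame, one row per hub site.
#' @export
annotationTable <- function(hubAnnotations, sites,
                            moduleAnnotations = NULL, pvCutoff = 0.05) {
  moduleCount <- list()
  if (!is.null(moduleAnnotations)) {
    for (ma in moduleAnnotations) {
      nterm <- sum(ma$enrichment$p_raw < pvCutoff)
      for (s in ma$member_site_ids) moduleCount[[s]] <- nterm
    }
  }
  rows <- lapply(hubAnnotations, function(ha) {
    i <- match(ha$hub_site_id, sites$site_id)
    data.frame(site_id = ha$hub_site_id,
               chrom = sites$chrom[i], position = sites$position[i],
               strand = sites$strand[i],
               gene_symbol = sites$gene_symbol[i],
               gene_entrez = sites$gene_entrez[i],
               n_neighbor_sites = ha$degree,
               n_neighbor_genes = length(ha$neighbor_gene_ids),
               n_known_slim = length(ha$known_slim_terms),
               n_predicted_slim = nrow(ha$predicted),
               n_hit = length(ha$hit_terms),
               n_module_terms = moduleCount[[ha$hub_site_id]] %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
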