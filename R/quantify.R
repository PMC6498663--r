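#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed as the median, over sites
#' with all-positive counts, of the ratio of each sample's count to the
#' per-site geometric mean. This is the classical median-of-ratios
#' normalisation used by RNA-seq count models; no dispersion shrinkage is
#' performed here (see the package vignette for the quantification model).
#'
#' @param counts non-negative integer matrix, sites x samples, or a
#'   [MeripCountSet-class].
#' @return positive numeric vector of length `ncol(counts)`, named by sample.
#' @examples
#' m <- rbind(c(10, 20), c(30, 60))
#' medianRatioSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianRatioSizeFactors <- function(counts) {
  if (is(counts, "MeripCountSet"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (any(counts < 0)) stopf("counts must be non-negative")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep))
    stopf(paste("no site has positive counts in every sample;",
                "add a pseudocount or drop empty samples"))
  logc <- log(counts[keep, , drop = FALSE])
  logGeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - logGeo)))
  names(sf) <- colnames(counts)
  sf
}

#' Per-site methylation level from IP and Input counts
#'
#' The methylation level of a site is the log2 fold enrichment of
#' depth-normalised IP reads over Input reads in the quantification window,
#' with a symmetric pseudocount keeping the value finite:
#' `log2((ip/sfIp + pc) / (input/sfInput + pc))`.
#'
#' @param ip,input non-negative count vectors (parallel).
#' @param sfIp,sfInput positive size factors for the two samples.
#' @param pseudocount added to both normalised counts, default 0.5.
#' @return numeric vector of log2 fold enrichments.
#' @export
methylationLevel <- function(ip, input, sfIp = 1, sfInput = 1,
                             pseudocount = 0.5) {
  if (sfIp <= 0 || sfInput <= 0) stopf("size factors must be positive")
  if (any(ip < 0) || any(input < 0)) stopf("counts must be non-negative")
  log2((ip / sfIp + pseudocount) / (input / sfInput + pseudocount))
}

#' Quantify a full MeripCountSet into per-condition methylation levels
#'
#' For each condition, IP and Input replicate counts are depth-normalised
#' with [medianRatioSizeFactors()] (computed across all samples jointly),
#' per-replicate-pair log2 enrichments are computed with
#' [methylationLevel()], and biological replicates are averaged. Also emits
#' the per-site expression proxy (mean normalised Input count) and the raw
#' IP+Input count totals consumed by the low-evidence mask of the filtering
#' stage.
#'
#' @param mcs a [MeripCountSet-class].
#' @param pseudocount see [methylationLevel()].
#' @param excludeSamples character vector of sample names dropped before
#'   quantification (explicit outlier list; no automatic detection).
#' @param gcFraction optional numeric vector of per-site GC content carried
#'   into the result's row metadata.
#' @return list with components `meth` ([MethylationSet-class], sites x
#'   conditions), `expression` (matrix, mean normalised Input counts) and
#'   `ipInputCounts` (matrix, raw IP+Input totals per condition).
#' @export
quantifyMethylation <- function(mcs, pseudocount = 0.5,
                                excludeSamples = character(0),
                                gcFraction = NULL) {
  stopifnot(is(mcs, "MeripCountSet"))
  if (length(excludeSamples)) {
    keep <- !colnames(mcs) %in% excludeSamples
    mcs <- mcs[, keep]
    validObject(mcs)
  }
  counts <- SummarizedExperiment::assay(mcs, "counts")
  cd <- SummarizedExperiment::colData(mcs)
  sf <- medianRatioSizeFactors(counts)
  conds <- unique(as.character(cd$condition))
  meth <- expr <- tot <- matrix(NA_real_, nrow(counts), length(conds),
                                dimnames = list(rownames(counts), conds))
  for (cond in conds) {
    ipIdx <- which(cd$condition == cond & cd$assay == "IP")
    inIdx <- which(cd$condition == cond & cd$assay == "Input")
    nPair <- min(length(ipIdx), length(inIdx))
    lev <- sapply(seq_len(nPair), function(k) {
      methylationLevel(counts[, ipIdx[k]], counts[, inIdx[k]],
                       sf[ipIdx[k]], sf[inIdx[k]], pseudocount)
    })
    meth[, cond] <- rowMeans(as.matrix(lev))
    normInput <- sweep(counts[, inIdx, drop = FALSE], 2, sf[inIdx], "/")
    expr[, cond] <- rowMeans(normInput)
    tot[, cond] <- rowSums(counts[, c(ipIdx, inIdx), drop = FALSE])
  }
  siteData <- NULL
  if (!is.null(gcFraction))
    siteData <- S4Vectors::DataFrame(gc_fraction = gcFraction,
                                     row.names = rownames(counts))
  list(meth = MethylationSet(meth, siteData),
       expression = expr, ipInputCounts = tot)
}

#' Remove the GC-content trend from methylation levels
#'
#' Technical GC bias is removed per condition by local regression: a loess
#' curve of level on GC fraction is fitted, its prediction subtracted, and
#' the condition mean added back, so column means are preserved. This is a
#' local-regression detrending of the GC effect (the package's own
#' normalisation step; see the vignette for scope).
#'
#' @param meth a [MethylationSet-class] whose rowData carries `gc_fraction`.
#' @param span loess span, default 0.75.
#' @return a corrected [MethylationSet-class].
#' @export
correctGCBias <- function(meth, span = 0.75) {
  stopifnot(is(meth, "MethylationSet"))
  rd <- SummarizedExperiment::rowData(meth)
  if (!"gc_fraction" %in% colnames(rd))
    stopf("correctGCBias requires rowData column 'gc_fraction'")
  gc <- rd$gc_fraction
  x <- methLevels(meth)
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j]) & !is.na(gc)
    if (sum(ok) < 30)
      stopf("condition '%s' has fewer than 30 non-missing sites", colnames(x)[j])
    mu <- mean(x[ok, j])
    if (stats::var(gc[ok]) == 0) next  # constant GC: nothing to detrend
    fit <- stats::loess(y ~ g, data = data.frame(y = x[ok, j], g = gc[ok]),
                        span = span, degree = 1,
                        control = stats::loess.control(surface = "direct"))
    resid <- x[ok, j] - predict(fit, data.frame(g = gc[ok]))
    x[ok, j] <- resid - mean(resid) + mu  # recentre: column mean preserved
  }
  out <- meth
  SummarizedExperiment::assay(out, "level") <- x
  out
}

#' Average biological replicates into per-condition columns
#'
#' Replicate columns from the same cell line / laboratory are merged by the
#' arithmetic mean, ignoring missing values; a cell missing in every
#' replicate stays missing.
#'
#' @param x numeric matrix, sites x samples.
#' @param groups character/factor of length `ncol(x)` mapping each sample to
#'   its replicate group (the output condition label).
#' @return matrix sites x groups.
#' @export
mergeReplicates <- function(x, groups) {
  if (length(groups) != ncol(x))
    stopf("'groups' must assign every sample to exactly one group")
  groups <- as.character(groups)
  if (any(is.na(groups) | groups == "")) stopf("empty replicate group label")
  ug <- unique(groups)
  out <- sapply(ug, function(g) {
    rowMeans(x[, groups == g, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(x), ug)
  out
}

#' Hierarchical clustering of conditions
#'
#' Agglomerative clustering of condition columns under Euclidean distance
#' (average linkage), the QC view used to verify that conditions from the
#' same cell line group together after GC correction. Missing cells are
#' imputed by their row mean for the distance computation only.
#'
#' @param meth a [MethylationSet-class] or numeric matrix (sites x
#'   conditions).
#' @param newickPath optional path; when given, the dendrogram is also
#'   written as a Newick tree.
#' @return an [stats::hclust] object over conditions.
#' @export
sampleDendrogram <- function(meth, newickPath = NULL) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  if (ncol(x) < 2) stopf("at least 2 conditions are required")
  rmu <- rowMeans(x, na.rm = TRUE)
  for (i in seq_len(nrow(x))) {
    nai <- is.na(x[i, ])
    if (any(nai)) x[i, nai] <- rmu[i]
  }
  x <- x[!is.na(rowMeans(x)), , drop = FALSE]
  hc <- hclust(dist(t(x), method = "euclidean"), method = "average")
  if (!is.null(newickPath)) {
    ape::write.tree(ape::as.phylo(hc), file = newickPath)
  }
  hc
}
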