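#' Mask methylation levels with insufficient read evidence
#'
#' A cell is set to missing when the expression value for the site under
#' that condition is lower than `exprMin` (default 8) or the total IP+Input
#' read count is lower than `countMin` (default 50). Both thresholds are
#' strict: cells exactly at the threshold are kept.
#'
#' @param meth [MethylationSet-class] or matrix, sites x conditions.
#' @param expression numeric matrix with the same dimnames (expression
#'   proxy, e.g. normalised Input coverage of the site window).
#' @param ipInputCounts numeric matrix with the same dimnames (raw IP+Input
#'   totals).
#' @param exprMin,countMin masking thresholds.
#' @return object of the same type as `meth` with masked cells set `NA`.
#' @export
maskLowEvidence <- function(meth, expression, ipInputCounts,
                            exprMin = 8, countMin = 50) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  if (!identical(dimnames(x), dimnames(expression)) ||
      !identical(dimnames(x), dimnames(ipInputCounts)))
    stopf("meth, expression and ipInputCounts must share dimnames")
  mask <- (expression < exprMin) | (ipInputCounts < countMin)
  x[which(mask)] <- NA_real_
  replaceLevels(meth, x)
}

replaceLevels <- function(meth, x) {
  if (is(meth, "MethylationSet")) {
    SummarizedExperiment::assay(meth, "level") <- x
    meth
  } else x
}

subsetSites <- function(meth, keep) {
  if (is(meth, "MethylationSet")) meth[keep, ] else meth[keep, , drop = FALSE]
}

#' Drop sites with too many missing values
#'
#' @param meth [MethylationSet-class] or matrix.
#' @param maxNA maximum tolerated NA count per site (row), default 15 of the
#'   32 conditions; rows with more are dropped.
#' @return filtered object; dropped site ids in attribute `"dropped"`.
#' @export
dropHighNA <- function(meth, maxNA = 15L) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  nNA <- rowSums(is.na(x))
  keep <- nNA <= maxNA
  out <- subsetSites(meth, keep)
  attr(out, "dropped") <- rownames(x)[!keep]
  out
}

#' Collapse near-duplicate neighbouring sites
#'
#' Two sites on the same chromosome closer than 101 bp whose methylation
#' profiles have pairwise-complete Spearman correlation above `rhoMin` are
#' taken to be one site captured twice (the resolution limit of m6A-seq);
#' the member with the lower mean methylation level is dropped. Pairs are
#' resolved greedily in ascending genomic position until no qualifying pair
#' remains, which makes the outcome deterministic for chains of neighbours.
#'
#' @param meth [MethylationSet-class] or matrix.
#' @param sites site table (data.frame with `site_id`, `chrom`, `position`)
#'   covering the rows of `meth`.
#' @param maxDist neighbours are pairs with `|delta position| <= maxDist`
#'   (default 100, i.e. "closer than 101 bp").
#' @param rhoMin Spearman threshold, strict (default 0.8).
#' @return filtered object; dropped ids in attribute `"dropped"`.
#' @export
collapseNeighbors <- function(meth, sites, maxDist = 100L, rhoMin = 0.8) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  sites <- sites[match(rownames(x), sites$site_id), ]
  if (any(is.na(sites$site_id)))
    stopf("every methylation row needs a row in 'sites'")
  key <- paste(sites$chrom, sites$position, sites$strand)
  if (anyDuplicated(key))
    warnf("duplicated (chrom, position, strand); treating as distance-0 neighbours")
  ord <- order(sites$chrom, sites$position)
  alive <- setNames(rep(TRUE, nrow(x)), rownames(x))
  rowMean <- rowMeans(x, na.rm = TRUE)
  dropped <- character(0)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!alive[rownames(x)[i]]) next
    b <- a + 1L
    while (b <= length(ord)) {
      j <- ord[b]
      if (sites$chrom[j] != sites$chrom[i] ||
          sites$position[j] - sites$position[i] > maxDist) break
      if (alive[rownames(x)[j]]) {
        rho <- suppressWarnings(
          cor(x[i, ], x[j, ], method = "spearman",
              use = "pairwise.complete.obs"))
        if (!is.na(rho) && rho > rhoMin) {
          loser <- if (rowMean[i] <= rowMean[j]) i else j
          alive[rownames(x)[loser]] <- FALSE
          dropped <- c(dropped, rownames(x)[loser])
          if (loser == i) break  # current anchor gone; move on
        }
      }
      b <- b + 1L
    }
  }
  out <- subsetSites(meth, alive[rownames(x)])
  attr(out, "dropped") <- dropped
  out
}

#' Keep variably methylated sites
#'
#' Sites whose median absolute deviation of methylation level across
#' conditions exceeds `madMin` carry usable biological signal and are
#' retained; the MAD is raw (no 1.4826 normal-consistency constant) and the
#' threshold is strict.
#'
#' @param meth [MethylationSet-class] or matrix.
#' @param madMin strict MAD threshold, default 0.4.
#' @param constant consistency constant passed to [stats::mad()]; default 1
#'   (raw MAD).
#' @return filtered object; dropped ids in attribute `"dropped"`.
#' @export
madFilter <- function(meth, madMin = 0.4, constant = 1) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  nOk <- rowSums(!is.na(x))
  if (any(nOk < 2))
    warnf("%d site(s) with < 2 non-missing values dropped", sum(nOk < 2))
  m <- apply(x, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) return(NA_real_)
    stats::mad(r, constant = constant)
  })
  keep <- !is.na(m) & m > madMin
  out <- subsetSites(meth, keep)
  attr(out, "dropped") <- rownames(x)[!keep]
  out
}

#' Quantile-normalise conditions
#'
#' Forces every condition column onto the common reference distribution
#' (the mean of sorted columns), removing residual batch effects before
#' correlation. Missing cells stay missing: per column, ranks are computed
#' among non-missing entries and mapped onto the reference via linear
#' interpolation on the common quantile grid; ties receive the mean of
#' their quantile values.
#'
#' @param meth [MethylationSet-class] or matrix with >= 2 conditions.
#' @return normalised object of the same type.
#' @export
quantileNormalize <- function(meth) {
  x <- if (is(meth, "MethylationSet")) methLevels(meth) else meth
  if (ncol(x) < 2) stopf("at least 2 conditions are required")
  grid <- seq(0, 1, length.out = nrow(x))
  colQ <- sapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][!is.na(x[, j])]
    if (length(v) < 2) return(rep(NA_real_, length(grid)))
    quantile(v, probs = grid, names = FALSE, type = 7)
  })
  ref <- rowMeans(colQ, na.rm = TRUE)
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    if (sum(ok) < 2) next
    p <- (rank(x[ok, j], ties.method = "average") - 1) / (sum(ok) - 1)
    out[ok, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  replaceLevels(meth, out)
}

#' Run the full site-filtering pipeline
#'
#' Applies, in fixed order: low-evidence masking, missing-value row drop,
#' neighbour collapse, MAD filter, quantile normalisation. Stage-by-stage
#' site counts and dropped ids are collected in a filter report.
#'
#' @param meth [MethylationSet-class] or matrix.
#' @param sites site table (see [collapseNeighbors()]).
#' @param expression,ipInputCounts see [maskLowEvidence()]; skip masking by
#'   passing `NULL`.
#' @param exprMin,countMin,maxNA,maxDist,rhoMin,madMin stage parameters with
#'   the pipeline defaults.
#' @return list with `meth` (filtered, normalised object) and `report`
#'   (list: `n_input_sites`, `n_after_masking`, `n_after_na_drop`,
#'   `n_after_neighbor_collapse`, `n_after_mad`, `dropped` per stage).
#' @export
filterSites <- function(meth, sites, expression = NULL, ipInputCounts = NULL,
                        exprMin = 8, countMin = 50, maxNA = 15L,
                        maxDist = 100L, rhoMin = 0.8, madMin = 0.4) {
  n0 <- nrow(meth)
  if (!is.null(expression) && !is.null(ipInputCounts))
    meth <- maskLowEvidence(meth, expression, ipInputCounts, exprMin, countMin)
  n1 <- nrow(meth)
  meth <- dropHighNA(meth, maxNA)
  dropNA <- attr(meth, "dropped")
  meth <- collapseNeighbors(meth, sites, maxDist, rhoMin)
  dropNb <- attr(meth, "dropped")
  meth <- madFilter(meth, madMin)
  dropMad <- attr(meth, "dropped")
  meth <- quantileNormalize(meth)
  report <- list(n_input_sites = n0,
                 n_after_masking = n1,
                 n_after_na_drop = n1 - length(dropNA),
                 n_after_neighbor_collapse = n1 - length(dropNA) - length(dropNb),
                 n_after_mad = nrow(meth),
                 dropped = list(na_drop = dropNA, neighbor_collapse = dropNb,
                                mad = dropMad))
  stopifnot(with(report, n_after_masking >= n_after_na_drop,
                 n_after_na_drop >= n_after_neighbor_collapse,
                 n_after_neighbor_collapse >= n_after_mad))
  list(meth = meth, report = report)
}

#' Write a filter report as JSON
#' @param report the `report` component of [filterSites()].
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
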