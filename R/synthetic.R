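#' Simulate a site-by-condition methylation matrix with planted modules
#'
#' Co-methylation is emulated with a single latent factor per module: every
#' condition draws one factor value per module, and each member site's
#' level is `loading * factor + N(0, noiseSd)`; background sites are pure
#' noise. The expected within-module correlation is therefore controlled
#' by the loading/noise ratio. Optional features of real data: a linear GC
#' trend (`level + gcSlope * gc_fraction`) and a missing-at-random mask.
#' Site coordinates are spaced widely (1 kb) so the neighbour-collapse
#' filter is inert unless duplicates are planted on purpose; each site gets
#' its own host gene, so planted modules are also planted gene
#' neighbourhoods.
#'
#' @param nSites total sites, default 300.
#' @param nConditions conditions, default 32 (the compendium size the
#'   pipeline targets).
#' @param nModules planted modules, default 4.
#' @param moduleSize sites per module, default 25.
#' @param loading factor loading of module sites, default 0.9.
#' @param noiseSd residual standard deviation, default 0.3.
#' @param naFraction missing-at-random fraction, default 0.
#' @param gcSlope slope of the planted GC trend, default 0 (none).
#' @param seed integer seed; same seed and parameters, same output.
#' @return list with `meth` ([MethylationSet-class]), `sites` (site table
#'   data.frame), and `truth` (list: `module_labels` named vector (0 =
#'   background), `latent_factors` modules x conditions, `gc_fraction`,
#'   generator parameters).
#' @export
simulateMethylation <- function(nSites = 300L, nConditions = 32L,
                                nModules = 4L, moduleSize = 25L,
                                loading = 0.9, noiseSd = 0.3,
                                naFraction = 0, gcSlope = 0, seed = 1L) {
  if (nConditions < 8) stopf("at least 8 conditions are required")
  if (moduleSize < 2) stopf("'moduleSize' must be at least 2")
  if (nModules * moduleSize > nSites)
    stopf("planted modules exceed the number of sites")
  withSeed(seed, {
    labels <- c(rep(seq_len(nModules), each = moduleSize),
                rep(0L, nSites - nModules * moduleSize))
    fac <- matrix(rnorm(nModules * nConditions), nModules, nConditions)
    x <- matrix(rnorm(nSites * nConditions, sd = noiseSd),
                nSites, nConditions)
    inMod <- labels > 0
    x[inMod, ] <- x[inMod, ] + loading * fac[labels[inMod], , drop = FALSE]
    gc <- runif(nSites, 0.3, 0.7)
    if (gcSlope != 0) x <- x + gcSlope * gc
    if (naFraction > 0) {
      mask <- matrix(runif(nSites * nConditions) < naFraction,
                     nSites, nConditions)
      x[mask] <- NA_real_
    }
    siteIds <- sprintf("site_%03d", seq_len(nSites))
    dimnames(x) <- list(siteIds, sprintf("cond_%02d", seq_len(nConditions)))
    names(labels) <- siteIds
    sites <- data.frame(site_id = siteIds,
                        chrom = "chr1",
                        position = 1000L * seq_len(nSites),
                        strand = "+",
                        gene_entrez = seq_len(nSites),
                        gene_symbol = sprintf("GENE%03d", seq_len(nSites)),
                        stringsAsFactors = FALSE)
    siteData <- S4Vectors::DataFrame(gc_fraction = gc,
                                     gene_entrez = sites$gene_entrez,
                                     gene_symbol = sites$gene_symbol,
                                     row.names = siteIds)
    list(meth = MethylationSet(x, siteData),
         sites = sites,
         truth = list(module_labels = labels,
                      latent_factors = fac,
                      gc_fraction = setNames(gc, siteIds),
                      params = list(nSites = nSites,
                                    nConditions = nConditions,
                                    nModules = nModules,
                                    moduleSize = moduleSize,
                                    loading = loading, noiseSd = noiseSd,
                                    naFraction = naFraction,
                                    gcSlope = gcSlope, seed = seed)))
  })
}

#' Simulate a toy GO-BP ontology, slim set and gene annotation
#'
#' Builds a three-level is_a DAG rooted at GO:0008150: one slim term per
#' planted module plus `nNoiseSlim` unlinked slim terms, each slim term
#' the parent of `termsPerModule` leaf terms. Genes of module `m` are
#' directly annotated with module `m`'s leaf terms with probability
#' `linkage` per leaf (function linkage; 0 decouples annotation from the
#' planted structure), and every gene additionally picks `noiseTermsPerGene`
#' random leaves. By construction each planted leaf has a unique minimal
#' slim ancestor, so slim mapping is exactly known.
#'
#' @param moduleLabels named vector from [simulateMethylation()]'s truth
#'   (site -> module id; genes inherit their site's module).
#' @param genes character/integer vector of gene ids parallel to
#'   `moduleLabels`.
#' @param termsPerModule leaf terms per module slim, default 3.
#' @param nNoiseSlim additional slim terms with leaves not tied to any
#'   module, default 30. The slim vocabulary must be large relative to the
#'   GN evaluation cutoffs, as the generic GO slim is (~150 terms), or a
#'   random predictor covers much of it by chance.
#' @param linkage probability a module gene carries each planted leaf,
#'   default 1.
#' @param noiseTermsPerGene random extra leaf annotations per gene,
#'   default 1.
#' @param seed integer seed.
#' @return list with `dag` ([OntologyDAG-class]), `annotation`
#'   ([GeneAnnotation-class]) and `truth` (list: `module_slim`,
#'   `module_leaves`).
#' @export
simulateOntology <- function(moduleLabels, genes, termsPerModule = 3L,
                             nNoiseSlim = 30L, linkage = 1,
                             noiseTermsPerGene = 1L, seed = 1L) {
  nModules <- max(c(0L, moduleLabels))
  genes <- as.character(genes)
  withSeed(seed, {
    rootId <- "GO:0008150"
    slimAll <- sprintf("GO:1%06d", seq_len(nModules + nNoiseSlim))
    leafOf <- lapply(seq_along(slimAll), function(i) {
      sprintf("GO:2%04d%02d", i, seq_len(termsPerModule))
    })
    leaves <- unlist(leafOf)
    ids <- c(rootId, slimAll, leaves)
    terms <- data.frame(id = ids,
                        name = c("biological_process",
                                 sprintf("slim process %d", seq_along(slimAll)),
                                 sprintf("leaf process %s", leaves)),
                        namespace = "biological_process",
                        stringsAsFactors = FALSE)
    parents <- c(setNames(list(character(0)), rootId),
                 setNames(rep(list(rootId), length(slimAll)), slimAll),
                 setNames(rep(slimAll, each = termsPerModule), leaves) |>
                   lapply(identity))
    dag <- makeOntology(terms, parents, slim = slimAll, rootId = rootId)
    gvec <- character(0); tvec <- character(0)
    for (i in seq_along(genes)) {
      m <- moduleLabels[i]
      ts <- character(0)
      if (m > 0 && linkage > 0) {
        planted <- leafOf[[m]]
        ts <- planted[runif(length(planted)) < linkage]
      }
      if (noiseTermsPerGene > 0)
        ts <- union(ts, sample(leaves, noiseTermsPerGene))
      if (length(ts)) {
        gvec <- c(gvec, rep(genes[i], length(ts)))
        tvec <- c(tvec, ts)
      }
    }
    annotation <- geneAnnotation(gvec, tvec, dag)
    list(dag = dag, annotation = annotation,
         truth = list(module_slim = setNames(slimAll[seq_len(nModules)],
                                             seq_len(nModules)),
                      module_leaves = leafOf[seq_len(nModules)]))
  })
}

#' Simulate IP/Input counts that invert the quantification model
#'
#' Per condition, one IP and one Input sample are drawn:
#' `Input ~ Poisson(depth * expr)` and
#' `IP ~ Poisson(depth * expr * 2^level)`, so
#' [quantifyMethylation()] recovers the planted levels with bias vanishing
#' as depth grows.
#'
#' @param level planted methylation-level matrix (sites x conditions), e.g.
#'   `methLevels()` of a simulated set.
#' @param meanDepth mean per-sample depth multiplier, default 100 (>= 10).
#' @param exprRange range of per-site expression intensities (uniform),
#'   default `c(5, 50)`.
#' @param seed integer seed.
#' @return a [MeripCountSet-class] with one IP and one Input sample per
#'   condition.
#' @export
simulateCounts <- function(level, meanDepth = 100, exprRange = c(5, 50),
                           seed = 1L) {
  if (meanDepth < 10) stopf("'meanDepth' must be at least 10")
  level[is.na(level)] <- 0
  withSeed(seed, {
    nS <- nrow(level); nC <- ncol(level)
    expr <- runif(nS, exprRange[1], exprRange[2])
    depth <- meanDepth * runif(2L * nC, 0.8, 1.25)
    counts <- matrix(0L, nS, 2L * nC)
    sampleIds <- character(2L * nC)
    cond <- assay <- character(2L * nC)
    for (j in seq_len(nC)) {
      ipCol <- 2L * j - 1L; inCol <- 2L * j
      counts[, ipCol] <- rpois(nS, depth[ipCol] * expr * 2 ^ level[, j])
      counts[, inCol] <- rpois(nS, depth[inCol] * expr)
      sampleIds[c(ipCol, inCol)] <- paste0(colnames(level)[j], c("_IP", "_Input"))
      cond[c(ipCol, inCol)] <- colnames(level)[j]
      assay[c(ipCol, inCol)] <- c("IP", "Input")
    }
    dimnames(counts) <- list(rownames(level), sampleIds)
    MeripCountSet(counts,
                  data.frame(condition = cond, assay = assay,
                             seq_type = "single", replicate_group = cond,
                             stringsAsFactors = FALSE))
  })
}

#' Assemble a complete synthetic study
#'
#' Bundles [simulateMethylation()] and [simulateOntology()] into the two
#' study presets used throughout the tests: `"function-linked"` (module
#' genes share planted GO leaves, linkage 1) and `"null"` (annotation
#' independent of the planted structure, linkage 0 with more random
#' annotation per gene so term frequencies stay comparable).
#'
#' @param preset `"function-linked"` or `"null"`.
#' @param seed integer seed.
#' @param ... overrides passed to [simulateMethylation()].
#' @return list with `meth`, `sites`, `dag`, `annotation`, `truth`.
#' @export
syntheticPreset <- function(preset = c("function-linked", "null"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  seeds <- childSeeds(seed, 2)
  sim <- simulateMethylation(seed = seeds[1], ...)
  linkage <- if (preset == "function-linked") 1 else 0
  noisePer <- if (preset == "function-linked") 1L else 3L
  ont <- simulateOntology(sim$truth$module_labels,
                          genes = sim$sites$gene_entrez,
                          linkage = linkage,
                          noiseTermsPerGene = noisePer,
                          seed = seeds[2])
  list(meth = sim$meth, sites = sim$sites, dag = ont$dag,
       annotation = ont$annotation,
       truth = c(sim$truth, ont$truth, list(preset = preset)))
}

#' Write a synthetic study to disk
#'
#' Emits the site table, methylation matrix (TSV, `NA` for missing), an
#' OBO serialisation of the toy ontology, the slim id list, the direct
#' gene annotation TSV and a truth JSON.
#'
#' @param study result of [syntheticPreset()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
writeSyntheticStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSiteTable(study$sites, file.path(dir, "sites.tsv"))
  x <- methLevels(study$meth)
  write.table(data.frame(site_id = rownames(x), x, check.names = FALSE),
              file.path(dir, "methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeObo(study$dag, file.path(dir, "ontology.obo"))
  writeLines(slimIds(study$dag), file.path(dir, "slim.txt"))
  ann <- study$annotation@direct
  df <- data.frame(gene_entrez = rep(names(ann), lengths(ann)),
                   term_id = unlist(ann, use.names = FALSE))
  write.table(df, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(module_labels = as.list(study$truth$module_labels),
         preset = study$truth$preset,
         params = study$truth$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Serialise an OntologyDAG to OBO
#' @param dag an [OntologyDAG-class].
#' @param path output path.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag@terms$name[i]),
                 paste0("namespace: ", dag@terms$namespace[i]),
                 paste0("is_a: ", dag@parents[[id]])), con)
  }
  invisible(path)
}

#' Read a methylation matrix written by [writeSyntheticStudy()]
#' @param path TSV with a `site_id` column followed by condition columns.
#' @return a [MethylationSet-class].
#' @export
readMethylationMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  MethylationSet(x)
}
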