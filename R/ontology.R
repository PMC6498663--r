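#' Read a GO ontology from OBO format
#'
#' Minimal OBO parser honouring `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `is_obsolete` tags (the carrier subset needed
#' for biological-process slim mapping). Obsolete terms are skipped;
#' `is_a` edges pointing outside the parsed term set are dropped;
#' acyclicity is certified at construction.
#'
#' @param path OBO file.
#' @param slim character vector of slim term ids, or a path to a one-id-per
#'   line file; may be empty.
#' @param rootId the namespace root excluded from all annotation output;
#'   default `"GO:0008150"` (biological_process).
#' @return an [OntologyDAG-class].
#' @export
readObo <- function(path, slim = character(0), rootId = "GO:0008150") {
  lines <- readLines(path)
  if (length(slim) == 1 && file.exists(slim)) {
    slim <- readLines(slim)
    slim <- trimws(slim[nzchar(trimws(slim))])
  }
  starts <- grep("^\\[", lines)
  termStarts <- which(lines == "[Term]")
  recs <- lapply(termStarts, function(s) {
    nxt <- starts[starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[seq(s + 1L, e)]
    tag <- function(t) sub(paste0("^", t, ":\\s*"), "",
                           grep(paste0("^", t, ":"), block, value = TRUE))
    isa <- tag("is_a")
    isa <- trimws(sub("!.*$", "", isa))
    list(id = tag("id")[1], name = tag("name")[1],
         namespace = if (length(tag("namespace"))) tag("namespace")[1]
                     else NA_character_,
         is_a = isa,
         obsolete = any(grepl("^is_obsolete:\\s*true", block)))
  })
  recs <- Filter(function(r) !r$obsolete && !is.na(r$id), recs)
  ids <- vapply(recs, `[[`, "", "id")
  terms <- data.frame(id = ids,
                      name = vapply(recs, `[[`, "", "name"),
                      namespace = vapply(recs, `[[`, "", "namespace"),
                      stringsAsFactors = FALSE)
  parents <- lapply(recs, function(r) intersect(r$is_a, ids))
  names(parents) <- ids
  makeOntology(terms, parents, slim, rootId)
}

#' Construct an OntologyDAG from term and parent tables
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list, term id -> character vector of direct is_a
#'   parents.
#' @param slim slim term ids.
#' @param rootId namespace root id.
#' @return an [OntologyDAG-class].
#' @export
makeOntology <- function(terms, parents, slim = character(0),
                         rootId = "GO:0008150") {
  anc <- transitiveAncestors(terms$id, parents)
  if (!rootId %in% terms$id)
    stopf("root term %s is not in the ontology", rootId)
  dag <- new("OntologyDAG", terms = terms, parents = parents,
             ancestors = anc, slimIds = intersect(slim, terms$id),
             rootId = rootId)
  validObject(dag)
  dag
}

# Transitive is_a closure by memoised DFS; a cycle manifests as a term on
# its own path and is reported as a format error.
transitiveAncestors <- function(ids, parents) {
  anc <- new.env(hash = TRUE, parent = emptyenv())
  onPath <- new.env(hash = TRUE, parent = emptyenv())
  visit <- function(id) {
    got <- get0(id, envir = anc, inherits = FALSE)
    if (!is.null(got)) return(got)
    if (!is.null(get0(id, envir = onPath, inherits = FALSE)))
      stopf("ontology contains an is_a cycle through term %s", id)
    assign(id, TRUE, onPath)
    ps <- parents[[id]]
    out <- unique(c(ps, unlist(lapply(ps, visit))))
    rm(list = id, envir = onPath)
    assign(id, out %||% character(0), anc)
    out %||% character(0)
  }
  res <- lapply(ids, visit)
  names(res) <- ids
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All is_a ancestors of a term
#'
#' @param dag an [OntologyDAG-class].
#' @param termId term id.
#' @return character vector of ancestors (the term itself excluded).
#' @export
termAncestors <- function(dag, termId) {
  stopifnot(is(dag, "OntologyDAG"))
  out <- dag@ancestors[[termId]]
  if (is.null(out)) stopf("unknown term: %s", termId)
  out
}

#' Reduce GO terms to their minimal slim ancestors
#'
#' Each input term maps to the slim terms that are the term itself or its
#' ancestors, minus any slim ancestor that is itself an ancestor of another
#' retained slim term (keeping the most specific slim representatives);
#' results are unioned across inputs. The namespace root (GO:0008150,
#' biological_process) is always excluded: it would otherwise appear in
#' virtually every reduction.
#'
#' @param dag an [OntologyDAG-class] with a non-empty slim set.
#' @param termIds character vector of term ids.
#' @return character vector of slim term ids (sorted).
#' @export
mapToSlim <- function(dag, termIds) {
  stopifnot(is(dag, "OntologyDAG"))
  out <- character(0)
  slim <- setdiff(dag@slimIds, dag@rootId)
  for (t in unique(termIds)) {
    cand <- intersect(c(t, termAncestors(dag, t)), slim)
    if (!length(cand)) next
    # drop slim ancestors of other candidates (keep minimal elements)
    keep <- vapply(cand, function(s) {
      !any(vapply(setdiff(cand, s),
                  function(o) s %in% dag@ancestors[[o]], logical(1)))
    }, logical(1))
    out <- union(out, cand[keep])
  }
  sort(setdiff(out, dag@rootId))
}

#' Build a GeneAnnotation from a gene-to-term table
#'
#' Direct assignments are closed under is_a ancestors ("propagation"), the
#' form required for enrichment so that annotating a gene with a term also
#' counts it for every more general term.
#'
#' @param genes,terms parallel character vectors (one row per direct
#'   assignment), or `genes` may be a two-column data.frame
#'   (gene, term).
#' @param dag an [OntologyDAG-class]; assignments to unknown terms are
#'   dropped with a warning.
#' @return a [GeneAnnotation-class].
#' @export
geneAnnotation <- function(genes, terms = NULL, dag) {
  if (is.data.frame(genes)) {
    terms <- as.character(genes[[2]])
    genes <- as.character(genes[[1]])
  }
  genes <- as.character(genes)
  known <- terms %in% termIds(dag)
  if (any(!known)) {
    warnf("%d assignment(s) to unknown terms dropped", sum(!known))
    genes <- genes[known]; terms <- terms[known]
  }
  direct <- split(terms, genes)
  direct <- lapply(direct, function(ts) sort(unique(ts)))
  propagated <- lapply(direct, function(ts) {
    sort(unique(c(ts, unlist(dag@ancestors[ts]))))
  })
  ga <- new("GeneAnnotation", direct = direct, propagated = propagated)
  validObject(ga)
  ga
}

#' Read a gene-to-GO annotation table
#'
#' Accepts a two-column TSV (`gene_entrez`, `term_id`) or a GAF 2.x file
#' (gene from column 2, term from column 5; comment lines starting with
#' `!` skipped).
#'
#' @param path annotation file.
#' @param dag an [OntologyDAG-class].
#' @param gaf logical; force GAF parsing (default: autodetect from leading
#'   `!` comments or a `.gaf` extension).
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path, dag, gaf = NA) {
  first <- readLines(path, n = 1)
  if (is.na(gaf)) gaf <- grepl("^!", first) || grepl("\\.gaf$", path)
  if (gaf) {
    df <- read.delim(path, header = FALSE, comment.char = "!",
                     stringsAsFactors = FALSE)
    geneAnnotation(df[[2]], df[[5]], dag)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    geneAnnotation(df[[1]], df[[2]], dag)
  }
}

#' Hypergeometric GO enrichment
#'
#' One-sided hypergeometric test (Fisher exact upper tail) per term: with
#' `N` background genes of which `K` carry the term (after propagation) and
#' a study set of `n` genes of which `k` carry it, the enrichment p-value
#' is `P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Genes without annotation
#' count in `N` but in no `K`. Terms are restricted to the `namespace`
#' (biological_process by default) and require `k >= minK`.
#'
#' @param studyGenes character vector, a subset of `backgroundGenes`.
#' @param backgroundGenes character vector (the gene universe).
#' @param annotation a [GeneAnnotation-class] (propagated).
#' @param dag an [OntologyDAG-class].
#' @param minK minimum study count per term, default 1.
#' @param namespace term namespace filter; `NULL` disables.
#' @return data.frame with columns `term_id`, `name`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_adj` (BH across the tested terms), sorted by `p_raw`.
#' @export
hypergeomEnrich <- function(studyGenes, backgroundGenes, annotation, dag,
                            minK = 1L, namespace = "biological_process") {
  studyGenes <- unique(as.character(studyGenes))
  backgroundGenes <- unique(as.character(backgroundGenes))
  if (!all(studyGenes %in% backgroundGenes))
    stopf("study genes must be a subset of the background")
  stopifnot(is(annotation, "GeneAnnotation"))
  prop <- annotation@propagated
  termsOk <- termIds(dag)
  if (!is.null(namespace))
    termsOk <- termsOk[dag@terms$namespace %in% namespace]
  geneTermPairs <- function(gs) {
    ts <- prop[intersect(gs, names(prop))]
    tt <- unlist(ts, use.names = FALSE)
    tt[tt %in% termsOk]
  }
  Ktab <- table(geneTermPairs(backgroundGenes))
  ktab <- table(geneTermPairs(studyGenes))
  ktab <- ktab[ktab >= minK]
  if (!length(ktab)) {
    return(data.frame(term_id = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  N <- length(backgroundGenes)
  n <- length(studyGenes)
  term <- names(ktab)
  k <- as.integer(ktab)
  K <- as.integer(Ktab[term])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = term,
                    name = dag@terms$name[match(term, dag@terms$id)],
                    k = k, n = n, K = K, N = N,
                    p_raw = p, p_adj = bhAdjust(p),
                    stringsAsFactors = FALSE)
  res[order(res$p_raw, res$term_id), , drop = FALSE]
}
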