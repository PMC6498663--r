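# Shared fixtures and independent oracles, built in code at test time.

# --- small site tables -----------------------------------------------------

makeSiteTable <- function(n = 4, chrom = "chr1", spacing = 1000L,
                          genes = seq_len(n)) {
  data.frame(site_id = sprintf("s%02d", seq_len(n)),
             chrom = chrom,
             position = spacing * seq_len(n),
             strand = "+",
             gene_entrez = genes,
             gene_symbol = sprintf("G%02d", genes),
             stringsAsFactors = FALSE)
}

# --- toy ontology: root -> slim s1, s2; s2 -> s2a; leaves under each -------

makeToyOntology <- function() {
  terms <- data.frame(
    id = c("GO:0008150", "S1", "S2", "S2A", "L1", "L2", "L3"),
    name = c("biological_process", "slim one", "slim two", "slim two a",
             "leaf one", "leaf two", "leaf three"),
    namespace = "biological_process", stringsAsFactors = FALSE)
  parents <- list(
    "GO:0008150" = character(0),
    S1 = "GO:0008150", S2 = "GO:0008150", S2A = "S2",
    L1 = "S1", L2 = "S2A", L3 = "S2")
  makeOntology(terms, parents, slim = c("S1", "S2", "S2A"),
               rootId = "GO:0008150")
}

# --- independent Spearman oracle: rank both vectors, then Pearson ----------

spearmanOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  cor(rank(x[ok]), rank(y[ok]))
}

# --- naive dense MCL oracle (no pruning), independent iteration code -------

mclOracle <- function(g, inflation = 1.4, expansion = 2, selfLoop = 1,
                      maxIter = 200, tol = 1e-8) {
  w <- igraph::edge_attr(g, "weight")
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (is.null(w)) NULL else "weight"))
  diag(A) <- selfLoop
  norm <- function(M) {
    s <- colSums(M); s[s == 0] <- 1
    t(t(M) / s)
  }
  M <- norm(A)
  for (it in seq_len(maxIter)) {
    Mx <- M
    for (e in seq_len(expansion - 1)) Mx <- Mx %*% M
    Mn <- norm(Mx ^ inflation)
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(M)))
  eps <- 1e-12
  owner <- rep(NA_integer_, nrow(M))
  for (a in which(diag(M) > eps)) {
    for (j in which(M[a, ] > eps)) {
      if (is.na(owner[j]) || a < owner[j]) owner[j] <- a
    }
  }
  for (j in seq_along(owner)) {
    a <- if (is.na(owner[j])) j else owner[j]
    while (!is.na(owner[a]) && owner[a] != a) a <- owner[a]
    owner[j] <- a
  }
  split(nodes, owner)
}

# canonical form of a partition for comparison across implementations
canonicalPartition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(unname(x)))
  unname(cl[order(vapply(cl, `[`, "", 1))])
}

# --- exhaustive double-edge-swap reachability with parity ------------------

edgeKey <- function(e) paste(sort(e), collapse = "-")

graphKey <- function(el) {
  paste(sort(apply(el, 1, edgeKey)), collapse = ";")
}

swapNeighbors <- function(el) {
  m <- nrow(el)
  ek <- apply(el, 1, edgeKey)
  out <- list()
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) for (flip in 0:1) {
    a <- el[i, 1]; b <- el[i, 2]; c <- el[j, 1]; d <- el[j, 2]
    if (flip == 1) { t <- c; c <- d; d <- t }
    if (a == d || c == b) next
    k1 <- edgeKey(c(a, d)); k2 <- edgeKey(c(c, b))
    if (k1 %in% ek || k2 %in% ek || k1 == k2) next
    el2 <- el; el2[i, ] <- c(a, d); el2[j, ] <- c(c, b)
    out[[length(out) + 1]] <- el2
  }
  out
}

# returns list(keys, parity): all reachable simple graphs and the parity
# (number of swaps mod 2) at which each is first reachable; a graph
# reachable at both parities gets parity NA
swapReachable <- function(el) {
  start <- graphKey(el)
  seen <- new.env(parent = emptyenv())
  assign(start, 0L, seen)
  frontier <- list(list(el = el, p = 0L))
  both <- character(0)
  while (length(frontier)) {
    nf <- list()
    for (node in frontier) {
      for (nb in swapNeighbors(node$el)) {
        k <- graphKey(nb); p <- (node$p + 1L) %% 2L
        prev <- get0(k, envir = seen, inherits = FALSE)
        if (is.null(prev)) {
          assign(k, p, seen)
          nf[[length(nf) + 1]] <- list(el = nb, p = p)
        } else if (!is.na(prev) && prev != p) {
          assign(k, NA_integer_, seen)
          nf[[length(nf) + 1]] <- list(el = nb, p = p)
        }
      }
    }
    frontier <- nf
  }
  keys <- ls(seen)
  list(keys = keys,
       parity = vapply(keys, function(k) get(k, envir = seen), 0L))
}

igraphKey <- function(g) graphKey(igraph::as_edgelist(g, names = TRUE))

# --- misc ------------------------------------------------------------------

degreesOf <- function(net) {
  g <- if (is(net, "CoMethNetwork")) siteGraph(net) else net
  sort(igraph::degree(g))
}
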