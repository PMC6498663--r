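test_that("spearmanMatrix agrees with the rank-then-Pearson oracle", {
  expect_equal(spearmanOracle(1:4, 4:1), -1)
  set.seed(31)
  x <- matrix(rnorm(6 * 20), 6, 20,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:20)))
  x[1, 1:4] <- NA; x[2, 3:6] <- NA
  sm <- spearmanMatrix(x, minPairs = 5)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(sm$rho[i, j], spearmanOracle(x[i, ], x[j, ]),
                 tolerance = 1e-12)
    expect_equal(sm$nObs[i, j], sum(!is.na(x[i, ]) & !is.na(x[j, ])))
  }
  expect_true(all(is.na(diag(sm$rho))))
  # worked example, expected value from the rank-then-Pearson oracle:
  # ranks of b are (1,3,2,5,4), sum d^2 = 4, rho = 1 - 24/120 = 0.8
  y <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4))
  expect_equal(spearmanOracle(y["a", ], y["b", ]), 0.8)
  expect_equal(spearmanMatrix(y, minPairs = 4)$rho["a", "b"], 0.8)
  # pairs under minPairs are undefined
  sm2 <- spearmanMatrix(x, minPairs = 15)
  expect_true(is.na(sm2$rho[1, 2]))
})

test_that("fisherPvalue matches the closed form and is monotone", {
  # closed form: z = atanh(rho); p = 2 * pnorm(-|z| * sqrt(n - 3))
  oracle <- function(rho, n) 2 * pnorm(-abs(0.5 * log((1 + rho) / (1 - rho))) * sqrt(n - 3))
  for (rho in c(-0.9, -0.5, 0, 0.3, 0.6, 0.95)) {
    expect_equal(fisherPvalue(rho, 32), oracle(rho, 32), tolerance = 1e-12)
  }
  expect_equal(fisherPvalue(0, 32), 1)
  expect_equal(fisherPvalue(0.6, 32),
               2 * pnorm(-0.5 * log(4) * sqrt(29)), tolerance = 1e-15)
  expect_lt(fisherPvalue(0.7, 32), fisherPvalue(0.5, 32))
  p1 <- fisherPvalue(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(isTRUE(attr(p1, "underflow")))
  expect_error(fisherPvalue(0.5, 3), "at least 4")
})

test_that("fisherPvalue agrees with a permutation p-value within Monte Carlo error", {
  set.seed(32)
  n <- 32; B <- 10000
  x <- rnorm(n)
  for (targetRho in c(0.2, 0.4, 0.6)) {
    y <- targetRho * x + sqrt(1 - targetRho^2) * rnorm(n)
    rho <- cor(x, y, method = "spearman")
    perm <- matrix(y[sapply(seq_len(B), function(i) sample.int(n))], n, B)
    rhoNull <- as.numeric(cor(x, perm, method = "spearman"))
    pPerm <- (1 + sum(abs(rhoNull) >= abs(rho))) / (B + 1)
    pFish <- fisherPvalue(rho, n)
    se <- sqrt(pPerm * (1 - pPerm) / B)
    expect_lt(abs(pFish - pPerm), max(3 * se, 5e-4))
  }
})

test_that("multiple-testing adjustments match hand-computed vectors", {
  expect_equal(bonferroniAdjust(0.01, 10), 0.1)
  expect_equal(bonferroniAdjust(0.2, 10), 1)
  expect_equal(bonferroniAdjust(c(0.01, 0.2), 10),
               c(bonferroniAdjust(0.01, 10), bonferroniAdjust(0.2, 10)))
  # BH step-up oracle by hand: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.03), 0.03)
  p <- c(0.002, 0.04, 0.9, 0.013)
  shuffled <- bhAdjust(p[c(3, 1, 4, 2)])
  expect_equal(shuffled[c(2, 4, 1, 3)], bhAdjust(p))
  expect_true(all(bhAdjust(p) >= p))
  expect_true(all(bonferroniAdjust(p, length(p)) >= bhAdjust(p)))
})

test_that("buildNetwork recovers planted modules and obeys the edge rule", {
  sim <- simulateMethylation(seed = 101)
  net <- buildNetwork(sim$meth, sim$sites)
  g <- siteGraph(net)
  expect_equal(igraph::vcount(g), 300)
  el <- igraph::as_edgelist(g)
  lab <- sim$truth$module_labels
  within <- lab[el[, 1]] > 0 & lab[el[, 1]] == lab[el[, 2]]
  expect_gt(mean(within), 0.9)
  # every edge satisfies the rank AND alpha rule
  expect_true(all(igraph::E(g)$p_adj < 0.05))
  expect_true(all(igraph::E(g)$scc >= net@params$rho_hi |
                    igraph::E(g)$scc <= net@params$rho_lo))
  expect_identical(igraph::E(g)$sign, ifelse(igraph::E(g)$scc >= 0, "+", "-"))
  # simple graph, isolated annotated sites retained
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))

  # invariant to site ordering
  perm <- sample(nrow(sim$sites))
  x2 <- methLevels(sim$meth)[perm, ]
  net2 <- buildNetwork(x2, sim$sites)
  key <- function(n) {
    e <- igraph::as_edgelist(siteGraph(n))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(key(net2), key(net))

  # adding an all-missing condition changes nothing (pairwise-complete)
  x3 <- cbind(methLevels(sim$meth), extra = NA_real_)
  net3 <- buildNetwork(x3, sim$sites)
  expect_identical(key(net3), key(net))
})

test_that("duplicated rows form an edge and alpha = 0 removes all edges", {
  set.seed(33)
  x <- matrix(rnorm(100 * 32), 100, 32,
              dimnames = list(sprintf("s%03d", 1:100), paste0("c", 1:32)))
  x[2, ] <- x[1, ]  # rho exactly 1
  sites <- makeSiteTable(100)
  sites$site_id <- rownames(x)
  net <- buildNetwork(x, sites)
  g <- siteGraph(net)
  expect_true(igraph::are_adjacent(g, "s001", "s002"))
  e <- igraph::E(g)[igraph::get_edge_ids(g, c("s001", "s002"))]
  expect_equal(e$scc, 1)
  expect_equal(e$p_adj, 0)

  net0 <- buildNetwork(x, sites, alpha = 0)
  expect_equal(igraph::ecount(siteGraph(net0)), 0)
})

test_that("sites without gene annotation are excluded before ranking", {
  set.seed(34)
  x <- matrix(rnorm(20 * 32), 20, 32,
              dimnames = list(sprintf("s%02d", 1:20), paste0("c", 1:32)))
  sites <- makeSiteTable(20)
  sites$site_id <- rownames(x)
  sites$gene_entrez[1:3] <- NA
  expect_message(net <- buildNetwork(x, sites), "3 site")
  expect_equal(igraph::vcount(siteGraph(net)), 17)
  expect_false(any(rownames(x)[1:3] %in% igraph::V(siteGraph(net))$name))
})

test_that("degreeFit recovers a power-law exponent on a scale-free graph", {
  g <- withr::with_seed(35, igraph::sample_pa(5000, m = 2, directed = FALSE))
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  fit <- degreeFit(g)
  expect_gte(fit$exponent, 2)
  expect_lte(fit$exponent, 4)
  # degenerate graphs: too few distinct degrees
  ring <- igraph::make_ring(10)
  expect_error(degreeFit(ring), "3 distinct")
  star <- igraph::make_star(50, mode = "undirected")
  expect_error(degreeFit(star), "3 distinct")
})

test_that("gene-level projection drops self-loops and merges site pairs", {
  x <- matrix(rnorm(6 * 32), 6, 32,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:32)))
  x[2, ] <- x[1, ] + rnorm(32, sd = 1e-3)  # same-gene pair, strong edge
  x[4, ] <- x[3, ] + rnorm(32, sd = 1e-3)  # cross-gene pair, strong edge
  sites <- makeSiteTable(6, genes = c(1, 1, 2, 3, 4, 5))
  sites$site_id <- rownames(x)
  net <- buildNetwork(x, sites, topFrac = 0.2)
  gg <- siteToGeneNetwork(net)
  expect_false(any(igraph::which_loop(gg)))
  expect_true(igraph::are_adjacent(gg, "2", "3"))
  expect_false(igraph::are_adjacent(gg, "1", "1"))

  empty <- buildNetwork(x, sites, alpha = 0)
  expect_equal(igraph::ecount(siteToGeneNetwork(empty)), 0)
})

test_that("compareNetworks matches the closed form on binary vectors", {
  g1 <- igraph::make_ring(5); igraph::V(g1)$name <- letters[1:5]
  expect_equal(compareNetworks(g1, g1), 1)
  # complement network: closed form for correlation of x and 1-x is -1
  gc <- igraph::complementer(g1)
  expect_equal(compareNetworks(g1, gc), -1)
  # partial overlap, hand-computed on the 10 pairs of K5
  g2 <- igraph::make_graph(~ a - b, b - c, c - d, d - e, a - c)
  va <- rep(0, 10); vb <- rep(0, 10)
  pairs <- t(combn(sort(letters[1:5]), 2))
  inG <- function(g, p) igraph::are_adjacent(g, p[1], p[2])
  for (i in 1:10) {
    va[i] <- inG(g1, pairs[i, ]); vb[i] <- inG(g2, pairs[i, ])
  }
  expect_equal(compareNetworks(g1, g2), cor(va, vb))
  # independent sparse random graphs are near-orthogonal
  set.seed(36)
  r1 <- igraph::sample_gnp(500, 0.01); r2 <- igraph::sample_gnp(500, 0.01)
  igraph::V(r1)$name <- igraph::V(r2)$name <- paste0("n", 1:500)
  expect_lt(abs(compareNetworks(r1, r2)), 0.02)
  # degenerate: edgeless network
  e0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(e0)$name <- letters[1:5]
  cmp <- compareNetworks(g1, e0)
  expect_equal(as.numeric(cmp), 0)
  expect_true(isTRUE(attr(cmp, "degenerate")))
  expect_error(compareNetworks(g1, igraph::make_ring(4)), "node set")
})

test_that("leave-one-out influence flags nothing on a stable matrix", {
  sim <- simulateMethylation(nSites = 80, nConditions = 12, nModules = 2,
                             moduleSize = 15, seed = 37)
  x <- methLevels(sim$meth)
  # duplicate one condition; removing the duplicate barely changes the network
  x[, 12] <- x[, 11] + rnorm(80, sd = 0.01)
  ors <- leaveOneOutInfluence(x, sites = sim$sites, minPairs = 5)
  expect_equal(length(ors), 12)
  expect_true(all(ors > 1))  # all leave-one-out nets share most edges
  bulk <- ors[seq_len(10)]
  expect_lt(ors[["cond_12"]], max(bulk) * 10)
  expect_gt(ors[["cond_12"]], min(bulk) / 10)
})

test_that("network export formats round-trip", {
  sim <- simulateMethylation(nSites = 40, nConditions = 10, nModules = 2,
                             moduleSize = 8, seed = 38)
  net <- buildNetwork(sim$meth, sim$sites, minPairs = 5)
  et <- edgeTable(net)
  expect_gt(nrow(et), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(et))
  expect_equal(back$scc, et$scc, tolerance = 1e-12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), nrow(et))
  expect_equal(igraph::vcount(g2), igraph::vcount(siteGraph(net)))

  sif <- withr::local_tempfile(fileext = ".sif")
  writeSif(net, sif)
  sifTab <- read.delim(sif, header = FALSE)
  expect_equal(nrow(sifTab), nrow(et))
  expect_true(all(sifTab$V2 %in% c("pos", "neg")))
})
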