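# constructed network: hub h with 4 neighbours whose genes share slim term
# S1's leaf; plus background nodes/genes to give enrichment contrast
makeHubFixture <- function() {
  dag <- makeToyOntology()
  nodes <- c("h", paste0("nb", 1:4), paste0("bg", 1:15))
  genes <- setNames(c(100L, 1:4, 11:25), nodes)
  edges <- rbind(cbind("h", paste0("nb", 1:4)),
                 cbind("bg1", "bg2"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  miss <- setdiff(nodes, igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(miss), name = miss)
  igraph::V(g)$gene_entrez <- genes[igraph::V(g)$name]
  igraph::V(g)$gene_symbol <- paste0("G", genes[igraph::V(g)$name])
  igraph::E(g)$scc <- 0.9; igraph::E(g)$p_raw <- 1e-8
  igraph::E(g)$p_adj <- 1e-5; igraph::E(g)$sign <- "+"
  net <- new("CoMethNetwork", graph = g, nConditions = 32L, params = list())
  # neighbour genes 1..4 and the hub's gene all carry leaf L1 (slim S1);
  # background genes carry L3 (slim S2)
  ann <- geneAnnotation(c(as.character(1:4), "100", as.character(11:25)),
                        c(rep("L1", 5), rep("L3", 15)), dag)
  list(net = net, dag = dag, ann = ann)
}

test_that("findHubs applies the more-than-three-neighbours rule", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("ctr", paste0("leaf", 1:5))
  expect_identical(findHubs(star), "ctr")
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- letters[1:4]
  expect_length(findHubs(ring), 0)
  g4 <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g4)$name <- c("ctr", paste0("leaf", 1:4))
  expect_identical(findHubs(g4), "ctr")  # degree exactly 4 is a hub
})

test_that("hubPredict recovers a planted shared function as a hit term", {
  fx <- makeHubFixture()
  has <- hubPredict(fx$net, fx$ann, fx$dag)
  expect_named(has, "h")
  ha <- has[["h"]]
  expect_equal(ha$degree, 4)
  expect_setequal(ha$neighbor_gene_ids, as.character(1:4))
  expect_true("S1" %in% ha$predicted$term)
  expect_true("S1" %in% ha$known_slim_terms)
  expect_true("S1" %in% ha$hit_terms)
  expect_false("GO:0008150" %in% c(ha$known_slim_terms, ha$predicted$term))
  # enrichment p of the planted term verified by the combinatorial oracle:
  # study 4 genes, all carry L1; background 20 genes, K = 5
  expect_equal(ha$enriched_terms$p_raw[ha$enriched_terms$term_id == "L1"],
               choose(5, 4) * choose(15, 0) / choose(20, 4) +
                 0,  # k can only reach 4 in a study of 4
               tolerance = 1e-12)
})

test_that("hubs with unannotated neighbours or genes degrade gracefully", {
  fx <- makeHubFixture()
  # annotation that knows nothing about the neighbour genes
  dag <- fx$dag
  annEmpty <- geneAnnotation(as.character(11:25), rep("L3", 15), dag)
  has <- hubPredict(fx$net, annEmpty, dag)
  ha <- has[["h"]]
  expect_equal(nrow(ha$predicted), 0)
  expect_length(ha$known_slim_terms, 0)
  expect_false(ha$known_annotated)
  expect_length(ha$hit_terms, 0)
  # empty slim set yields empty predictions, never an error
  dagNoSlim <- makeOntology(fx$dag@terms, fx$dag@parents, slim = character(0))
  has2 <- hubPredict(fx$net, fx$ann, dagNoSlim)
  expect_equal(nrow(has2[["h"]]$predicted), 0)
})

test_that("evaluate reproduces the worked two-hub recall/precision example", {
  mkHub <- function(id, known, predTerms, p = rep(1e-4, length(predTerms))) {
    structure(list(hub_site_id = id, degree = 4,
                   neighbor_site_ids = character(0),
                   neighbor_gene_ids = character(0),
                   known_slim_terms = known,
                   predicted = data.frame(term = predTerms, p = p,
                                          stringsAsFactors = FALSE),
                   enriched_terms = data.frame(term_id = character(0),
                                               p_raw = numeric(0)),
                   hit_terms = intersect(known, predTerms),
                   known_annotated = length(known) > 0),
              class = "hubAnnotation")
  }
  # hub A known {t1,t2} predicted {t2,t3}; hub B known {t1} predicted {t1}
  hubs <- list(mkHub("A", c("t1", "t2"), c("t2", "t3")),
               mkHub("B", "t1", "t1"))
  perf <- evaluatePerformance(hubs, pvCutoff = 0.05, gnCutoff = 16)
  expect_equal(perf$recall, 2 / 3)
  expect_equal(perf$precision, 2 / 3)

  # perfect prediction
  perfect <- list(mkHub("A", c("t1", "t2"), c("t1", "t2")))
  pp <- evaluatePerformance(perfect, 0.05, 16)
  expect_equal(pp$recall, 1); expect_equal(pp$precision, 1)

  # disjoint known and predicted
  disj <- list(mkHub("A", "t1", "t2"))
  pd <- evaluatePerformance(disj, 0.05, 16)
  expect_equal(pd$recall, 0); expect_equal(pd$precision, 0)

  # 0/0 flagged
  none <- list(mkHub("A", character(0), character(0)))
  pn <- evaluatePerformance(none, 0.05, 16)
  expect_equal(pn$recall, 0)
  expect_true(isTRUE(attr(pn, "undefined")))

  # invariance to hub ordering
  expect_equal(evaluatePerformance(rev(hubs), 0.05, 16)$recall, perf$recall)

  # GN truncation keeps the smallest-p terms
  h3 <- mkHub("C", "t1", c("t1", "t2", "t3"), p = c(0.04, 0.001, 0.002))
  p3 <- evaluatePerformance(list(h3), 0.05, 2)
  expect_equal(p3$sum_predicted, 2)
  expect_equal(p3$sum_hits, 0)  # t1 has the largest p and is truncated away
})

test_that("recall is non-decreasing in GN and predicted counts monotone in PV", {
  set.seed(71)
  fuzzHubs <- function() {
    lapply(1:15, function(i) {
      terms <- paste0("t", 1:12)
      predN <- sample(0:8, 1)
      pred <- sample(terms, predN)
      structure(list(hub_site_id = paste0("h", i), degree = 5,
                     neighbor_site_ids = character(0),
                     neighbor_gene_ids = character(0),
                     known_slim_terms = sample(terms, sample(0:5, 1)),
                     predicted = data.frame(term = pred,
                                            p = runif(predN, 0, 0.2),
                                            stringsAsFactors = FALSE),
                     enriched_terms = data.frame(term_id = character(0),
                                                 p_raw = numeric(0)),
                     hit_terms = character(0), known_annotated = TRUE),
                class = "hubAnnotation")
    })
  }
  for (rep in 1:5) {
    hubs <- fuzzHubs()
    sweep <- pvGnSweep(hubs, pvGrid = c(0.2, 0.05, 0.01),
                       gnGrid = c(1, 4, 8, 16))
    expect_true(all(sweep$recall >= 0 & sweep$recall <= 1))
    expect_true(all(sweep$precision >= 0 & sweep$precision <= 1))
    for (pv in unique(sweep$pv_cutoff)) {
      sub <- sweep[sweep$pv_cutoff == pv, ]
      sub <- sub[order(sub$gn_cutoff), ]
      expect_true(all(diff(sub$recall) >= -1e-12))
    }
    for (gn in unique(sweep$gn_cutoff)) {
      sub <- sweep[sweep$gn_cutoff == gn, ]
      sub <- sub[order(-sub$pv_cutoff), ]  # tightening PV
      expect_true(all(diff(sub$sum_predicted) <= 0))
    }
  }
})

test_that("module annotation flags planted functions and inherits to sites", {
  fx <- makeHubFixture()
  modules <- list(c("h", paste0("nb", 1:4), paste0("bg", 1:5)))
  res <- moduleAnnotate(modules, fx$net, fx$ann, fx$dag)
  expect_length(res, 1)
  m <- res[[1]]
  expect_setequal(m$member_gene_ids,
                  as.character(c(1:4, 100, 11:15)))
  expect_true("L1" %in% m$enrichment$term_id)
  expect_true(m$significant)  # planted term survives BH
  l1 <- m$enrichment[m$enrichment$term_id == "L1", ]
  expect_lt(l1$p_adj, 0.05)
  # module of unannotated genes only -> empty, flagged
  dag <- fx$dag
  annBg <- geneAnnotation("999", "L3", dag)
  res2 <- moduleAnnotate(list(paste0("nb", 1:4)), fx$net, annBg, dag,
                         background = c(as.character(1:4), "999"))
  expect_false(res2[[1]]$annotated)
  expect_false(res2[[1]]$significant)
})

test_that("random-module enrichment is controlled at the BH level", {
  dag <- makeToyOntology()
  set.seed(72)
  genes <- paste0("g", 1:60)
  falseFlags <- 0
  for (rep in 1:20) {
    ann <- geneAnnotation(sample(genes, 40, replace = TRUE),
                          sample(c("L1", "L2", "L3"), 40, replace = TRUE),
                          dag)
    study <- sample(genes, 12)
    res <- hypergeomEnrich(study, genes, ann, dag)
    res <- res[res$term_id != dag@rootId, , drop = FALSE]
    if (nrow(res) && any(bhAdjust(res$p_raw) < 0.05))
      falseFlags <- falseFlags + 1
  }
  expect_lte(falseFlags, 3)  # expect ~1 of 20 at alpha 0.05
})

test_that("overlapTerms counts cross-method term agreement per site", {
  fx <- makeHubFixture()
  has <- hubPredict(fx$net, fx$ann, fx$dag)
  modules <- list(c("h", paste0("nb", 1:4), paste0("bg", 1:5)))
  mods <- moduleAnnotate(modules, fx$net, fx$ann, fx$dag)
  ovl <- overlapTerms(has, mods)
  expect_true("h" %in% names(ovl$per_site))
  hubTerms <- has[["h"]]$enriched_terms$term_id
  modTerms <- mods[[1]]$enrichment$term_id[mods[[1]]$enrichment$p_raw < 0.05]
  expect_equal(ovl$per_site[["h"]],
               length(intersect(hubTerms, modTerms)))
  expect_equal(ovl$mean_overlap, mean(ovl$per_site))
  # identical sets of size 5 -> overlap 5; disjoint sets -> 0
  mk <- function(id, terms) structure(
    list(hub_site_id = id, degree = 4, neighbor_site_ids = character(0),
         neighbor_gene_ids = character(0), known_slim_terms = character(0),
         predicted = data.frame(term = character(0), p = numeric(0)),
         enriched_terms = data.frame(term_id = terms,
                                     p_raw = rep(1e-4, length(terms))),
         hit_terms = character(0), known_annotated = TRUE),
    class = "hubAnnotation")
  mod <- list(list(module_id = 1, member_site_ids = c("x", "y"),
                   member_gene_ids = character(0),
                   enrichment = data.frame(term_id = paste0("t", 1:5),
                                           p_raw = rep(1e-4, 5)),
                   annotated = TRUE, significant = TRUE))
  o2 <- overlapTerms(list(mk("x", paste0("t", 1:5)),
                          mk("y", paste0("u", 1:5))), mod)
  expect_equal(o2$per_site[["x"]], 5)
  expect_equal(o2$per_site[["y"]], 0)
})

test_that("annotationTable mirrors the per-site results-table columns", {
  fx <- makeHubFixture()
  has <- hubPredict(fx$net, fx$ann, fx$dag)
  sites <- data.frame(site_id = igraph::V(siteGraph(fx$net))$name,
                      chrom = "chr1",
                      position = seq_len(igraph::vcount(siteGraph(fx$net))) * 100L,
                      strand = "+",
                      gene_entrez = igraph::V(siteGraph(fx$net))$gene_entrez,
                      gene_symbol = igraph::V(siteGraph(fx$net))$gene_symbol)
  mods <- moduleAnnotate(list(c("h", paste0("nb", 1:4))), fx$net, fx$ann, fx$dag)
  tab <- annotationTable(has, sites, mods)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_neighbor_sites, 4)
  expect_equal(tab$n_neighbor_genes, 4)
  expect_gte(tab$n_hit, 1)
  expect_false(is.na(tab$n_module_terms))
})
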