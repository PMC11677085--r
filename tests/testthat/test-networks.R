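## small deterministic network builders -----------------------------------
edge_df <- function(from, to, r, from_domain = "bacteria", to_domain = "fungi") {
  data.frame(from = from, to = to, from_domain = from_domain,
             to_domain = to_domain, r = r, p = rep(0.001, length(from)),
             stringsAsFactors = FALSE)
}

test_that("pairwise spearman recovers monotone pairs and skips constants", {
  set.seed(12)
  n <- 24
  base <- matrix(rexp(n * 5), n, 5,
                 dimnames = list(paste0("s", 1:n), paste0("OTU", 1:5)))
  a <- tiny_table(base, domain = "bacteria")
  ## correlations act on relative abundances, so plant the ranks there:
  ## the two fungal OTUs sum to 1 per sample and track OTU1's share
  ra1 <- base[, 1] / rowSums(base)
  bmat <- cbind(ra1, 1 - ra1)
  colnames(bmat) <- paste0("FOTU", 1:2)
  rownames(bmat) <- rownames(base)
  b <- otu_table(bmat, "fungi", rep("W", n))
  cand <- pairwise_spearman(a, b, prevalence_min = 0)
  r11 <- cand$r[cand$from == "OTU1" & cand$to == "FOTU1"]
  r12 <- cand$r[cand$from == "OTU1" & cand$to == "FOTU2"]
  expect_equal(r11, 1)
  expect_equal(r12, -1)
  expect_true(all(cand$p >= 0 & cand$p <= 1))
  expect_error(pairwise_spearman(a, tiny_table(base[1:3, ], domain = "fungi")),
               "same samples")
})

test_that("network construction filters on both thresholds and keeps signs", {
  cand <- edge_df(c("b1", "b2", "b3"), c("f1", "f2", "f3"), c(0.7, 0.7, -0.65))
  cand$p <- c(0.01, 0.2, 0.01)
  net <- build_network(cand)
  expect_identical(sort(net$edges$from), c("b1", "b3"))
  expect_identical(net$edges$sign[net$edges$from == "b3"], "-")
  ## bipartite mode never emits a within-domain edge
  cand2 <- rbind(cand, edge_df("b9", "b10", 0.9, "bacteria", "bacteria"))
  net2 <- build_network(cand2, mode = "bipartite")
  expect_false(any(net2$edges$from_domain == net2$edges$to_domain))
  expect_warning(build_network(edge_df("a", "b", 0.1)), "no edges")
})

test_that("P/N ratio counts edges and flags the no-negative case", {
  pos <- edge_df(paste0("b", 1:10), paste0("f", 1:10), rep(0.8, 10))
  neg <- edge_df(paste0("b", 11:14), paste0("f", 11:14), rep(-0.8, 4))
  expect_equal(pn_ratio(build_network(rbind(pos, neg))), 2.5)
  expect_identical(pn_ratio(build_network(pos)), Inf)
  expect_equal(suppressWarnings(pn_ratio(build_network(neg))), 0)
  expect_error(pn_ratio(suppressWarnings(build_network(edge_df("a", "b", 0.1)))),
               "no edges")
  ## disjoint union: ratio of summed counts
  all_net <- build_network(rbind(pos, neg))
  expect_equal(pn_ratio(all_net),
               (10 + 0) / (4 + 0))
})

test_that("robustness matches closed-form and enumeration cases", {
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  expect_equal(net_robustness(k6, 0.5, n_rep = 20, seed = 1), 1)

  empty6 <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::V(empty6)$name <- paste0("v", 1:6)
  expect_equal(net_robustness(empty6, 0.5, n_rep = 20, seed = 1), 1/3)

  ## star S5: exhaustive over all C(6,3) survivor sets vs Monte-Carlo
  s5 <- igraph::make_star(6, mode = "undirected")
  igraph::V(s5)$name <- paste0("v", 1:6)
  combs <- combn(6, 3)
  exact <- mean(apply(combs, 2, function(keep) {
    sub <- igraph::induced_subgraph(s5, keep)
    max(igraph::components(sub)$csize) / 3
  }))
  mc <- net_robustness(s5, 0.5, n_rep = 400, seed = 7)
  se <- sd(apply(combs, 2, function(keep) {
    sub <- igraph::induced_subgraph(s5, keep)
    max(igraph::components(sub)$csize) / 3
  })) / sqrt(400)
  expect_lt(abs(mc - exact), 3 * se)
  expect_error(net_robustness(s5, 1.5), "removal_fraction")
})

test_that("centralities and core species identify hubs", {
  path3 <- igraph::make_graph(~ A - B - C)
  cent <- node_centralities(path3)
  expect_equal(cent$betweenness[cent$id == "B"], 1)
  expect_equal(cent$betweenness[cent$id != "B"], c(0, 0))

  star4 <- igraph::make_star(5, mode = "undirected")
  igraph::V(star4)$name <- c("hub", paste0("l", 1:4))
  cent2 <- node_centralities(star4)
  expect_equal(cent2$betweenness[cent2$id == "hub"], choose(4, 2))

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  expect_true(all(node_centralities(k5)$betweenness == 0))

  expect_identical(suppressWarnings(core_species(star4)), "hub")

  ## two planted hubs, each wired to its own leaves plus a bridge
  ed <- edge_df(c(rep("H1", 6), rep("H2", 6), "H1"),
                c(paste0("f", 1:6), paste0("g", 1:6), "H2"),
                rep(0.9, 13), from_domain = "bacteria", to_domain = "bacteria")
  net <- build_network(ed, mode = "unipartite")
  expect_setequal(core_species(net), c("H1", "H2"))
})
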