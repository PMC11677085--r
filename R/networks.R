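#' Pairwise Spearman correlations between two domains' OTUs
#'
#' Edge candidates for the interdomain co-occurrence network: Spearman r
#' and a two-sided p-value (t approximation on n - 2 df) for every
#' cross-domain OTU pair, computed on relative abundances after a
#' prevalence filter. When `a` and `b` are the same table, within-domain
#' pairs are returned instead (unipartite candidates).
#'
#' @param a,b [otu_table()]s over identical samples.
#' @param prevalence_min minimum fraction of samples in which an OTU must
#'   be present to enter the screen (default 1/3).
#' @param method correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @return Data frame: `from`, `to`, `from_domain`, `to_domain`, `r`, `p`.
#'   OTUs constant after filtering yield no rows (skipped pairs carry
#'   `NA` r and are removed with a message attribute).
#' @export
pairwise_spearman <- function(a, b, prevalence_min = 1/3,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(sample_ids(a), sample_ids(b)))
    stop("tables must share the same samples in the same order")
  n <- nrow(a$counts)
  if (n < 4) stop("need at least 4 samples")
  keep_a <- colMeans(a$counts > 0) >= prevalence_min
  keep_b <- colMeans(b$counts > 0) >= prevalence_min
  ra <- relative_abundance(a)$counts[, keep_a, drop = FALSE]
  rb <- relative_abundance(b)$counts[, keep_b, drop = FALSE]
  unipartite <- identical(a, b)
  const_a <- apply(ra, 2, function(v) stats::sd(v) == 0)
  const_b <- apply(rb, 2, function(v) stats::sd(v) == 0)
  ra <- ra[, !const_a, drop = FALSE]
  rb <- rb[, !const_b, drop = FALSE]
  if (!ncol(ra) || !ncol(rb)) return(data.frame())
  r <- stats::cor(ra, rb, method = method)
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  idx <- which(if (unipartite) upper.tri(r) else !is.na(r), arr.ind = TRUE)
  data.frame(from = rownames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
             from_domain = a$domain, to_domain = b$domain,
             r = r[idx], p = p[idx], stringsAsFactors = FALSE)
}

#' Build a co-occurrence network from edge candidates
#'
#' Retains candidates with `|r| > r_min` and `p < p_max`, drops isolated
#' nodes, and records edge signs. Bipartite mode keeps only cross-domain
#' edges.
#'
#' @param candidates data frame from [pairwise_spearman()] (several
#'   domain pairs may be row-bound together).
#' @param r_min correlation magnitude threshold (default 0.6).
#' @param p_max p-value threshold (default 0.05).
#' @param mode `"bipartite"` (cross-domain edges only) or `"unipartite"`.
#' @return Object of class `cooccurrence_network`: `edges` (from, to, r,
#'   p, sign), `nodes` (id, domain), an [igraph] graph, and the
#'   thresholds. Zero-edge networks are valid and carry a warning.
#' @export
build_network <- function(candidates, r_min = 0.6, p_max = 0.05,
                          mode = c("bipartite", "unipartite")) {
  mode <- match.arg(mode)
  ed <- candidates[!is.na(candidates$r) & abs(candidates$r) > r_min &
                     candidates$p < p_max, , drop = FALSE]
  if (mode == "bipartite")
    ed <- ed[ed$from_domain != ed$to_domain, , drop = FALSE]
  ed$sign <- ifelse(ed$r > 0, "+", "-")
  if (!nrow(ed)) warning("no edges pass the thresholds; empty network")
  nodes <- rbind(data.frame(id = ed$from, domain = ed$from_domain,
                            stringsAsFactors = FALSE),
                 data.frame(id = ed$to, domain = ed$to_domain,
                            stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[, c("from", "to", "r", "p", "sign")],
                                     directed = FALSE, vertices = nodes)
  structure(list(edges = ed, nodes = nodes, graph = g,
                 r_min = r_min, p_max = p_max, mode = mode),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  pn <- pn_ratio(x, .allow_empty = TRUE)
  cat(sprintf("%s co-occurrence network: %d nodes, %d edges (|r| > %g, p < %g)\n",
              x$mode, nrow(x$nodes), nrow(x$edges), x$r_min, x$p_max))
  if (nrow(x$edges))
    cat(sprintf("  P/N = %s (%d positive, %d negative)\n",
                if (is.infinite(pn)) "Inf (no negative edges)" else sprintf("%.3f", pn),
                sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Positive-to-negative edge ratio
#'
#' The P/N ratio summarizing cooperative vs competitive biotic
#' interaction in a co-occurrence network. A network with positive edges
#' but no negative edges returns `Inf` (flagged infinite).
#'
#' @param net a `cooccurrence_network`.
#' @param .allow_empty internal; return `NA` instead of erroring on a
#'   zero-edge network.
#' @return Non-negative number, or `Inf` when there are no negative edges.
#' @export
pn_ratio <- function(net, .allow_empty = FALSE) {
  n_edge <- nrow(net$edges)
  if (!n_edge) {
    if (.allow_empty) return(NA_real_)
    stop("network has no edges")
  }
  pos <- sum(net$edges$sign == "+")
  neg <- n_edge - pos
  if (neg == 0) Inf else pos / neg
}

#' Network robustness under random node removal
#'
#' Stability proxy: remove a fraction of nodes uniformly at random and
#' measure the share of surviving nodes left in the largest connected
#' component; the mean over replicates is the robustness index in [0, 1].
#'
#' @param net a `cooccurrence_network` (or igraph graph) with >= 3 nodes.
#' @param removal_fraction fraction of nodes removed per trial, in (0, 1).
#' @param n_rep number of removal replicates (default 100).
#' @param seed optional seed.
#' @return Mean proportion of survivors in the giant component.
#' @export
net_robustness <- function(net, removal_fraction = 0.5, n_rep = 100, seed = NULL) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes")
  if (removal_fraction <= 0 || removal_fraction >= 1)
    stop("removal_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_remove <- ceiling(removal_fraction * n)
  vals <- vapply(seq_len(n_rep), function(i) {
    keep <- sample.int(n, n - n_remove)
    sub <- igraph::induced_subgraph(g, keep)
    max(igraph::components(sub)$csize) / length(keep)
  }, numeric(1))
  mean(vals)
}

#' Degree and betweenness centrality per node
#'
#' Unnormalized shortest-path betweenness on the unweighted graph, and
#' edge-count degree.
#'
#' @param net a `cooccurrence_network` or igraph graph.
#' @return Data frame: id, degree, betweenness.
#' @export
node_centralities <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes")
  data.frame(id = igraph::V(g)$name,
             degree = as.numeric(igraph::degree(g)),
             betweenness = as.numeric(igraph::betweenness(g, weights = NA,
                                                          normalized = FALSE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core species of a network
#'
#' Nodes in the top quantile of BOTH degree and betweenness centrality
#' (ties at the quantile are kept).
#'
#' @param net a `cooccurrence_network` or igraph graph.
#' @param degree_quantile,betweenness_quantile quantile cutoffs (default
#'   0.9).
#' @return Character vector of node ids (possibly empty, with a warning
#'   on very small networks).
#' @export
core_species <- function(net, degree_quantile = 0.9, betweenness_quantile = 0.9) {
  cent <- node_centralities(net)
  if (nrow(cent) < 10)
    warning("fewer than 10 nodes; quantile-based core set may be unstable")
  dq <- stats::quantile(cent$degree, degree_quantile, type = 7)
  bq <- stats::quantile(cent$betweenness, betweenness_quantile, type = 7)
  cent$id[cent$degree >= dq & cent$betweenness >= bq]
}

#' Export a network edge and node table
#'
#' Writes `<prefix>_edges.tsv` (from, to, r, p, sign) and
#' `<prefix>_nodes.tsv` (id, domain, degree, betweenness), plus GraphML
#' for external visualization.
#'
#' @param net a `cooccurrence_network`.
#' @param prefix output path prefix.
#' @return The paths written, invisibly.
#' @export
write_network <- function(net, prefix) {
  e_path <- paste0(prefix, "_edges.tsv")
  n_path <- paste0(prefix, "_nodes.tsv")
  g_path <- paste0(prefix, ".graphml")
  write_results(net$edges[, c("from", "to", "r", "p", "sign")], e_path)
  nodes <- merge(net$nodes, node_centralities(net), by = "id", sort = FALSE)
  write_results(nodes, n_path)
  igraph::write_graph(net$graph, g_path, format = "graphml")
  invisible(c(e_path, n_path, g_path))
}
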