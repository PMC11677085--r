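#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over non-zero proportions, via [vegan::diversity()].
#'
#' @param counts non-negative abundance vector (or matrix, samples in rows).
#' @return Shannon entropy in nats (vector for matrix input).
#' @export
shannon_index <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  if (any(m < 0) || anyNA(m)) stop("abundances must be non-negative")
  if (any(rowSums(m) <= 0)) stop("sample(s) with zero total abundance")
  h <- vegan::diversity(m, index = "shannon")
  if (is.matrix(counts)) h else as.numeric(h)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning a sample's taxa
#' and their most recent common ancestor (root edge excluded; the MRCA
#' convention, under which a single-taxon sample has PD 0). Computed via
#' [picante::pd()].
#'
#' @param comm presence or abundance matrix (samples x taxa, taxa named) or
#'   a character vector of taxon ids for a single sample.
#' @param tree a rooted [ape::phylo]; all sampled taxa must be tips.
#' @return Numeric PD per sample.
#' @export
faith_pd <- function(comm, tree) {
  if (is.character(comm)) {
    m <- matrix(1, 1, length(comm), dimnames = list("s", comm))
  } else {
    m <- comm
  }
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  rich <- rowSums(m > 0)
  out <- numeric(nrow(m))
  multi <- rich >= 2
  if (any(multi)) {
    res <- picante::pd(m[multi, , drop = FALSE], tree, include.root = FALSE)
    out[multi] <- res$PD
  }
  names(out) <- rownames(m)
  out
}

#' Per-sample diversity profile
#'
#' Observed richness (Sobs), Shannon H (nats) and Faith PD for every sample
#' of an OTU table.
#'
#' @param t an [otu_table()].
#' @param tree optional tree for PD; when `NULL`, PD is `NA`.
#' @return data frame with columns sample, layer, sobs, shannon, pd.
#' @export
diversity_profile <- function(t, tree = NULL) {
  m <- t$counts
  data.frame(sample = sample_ids(t), layer = t$layer,
             sobs = rowSums(m > 0),
             shannon = shannon_index(m),
             pd = if (is.null(tree)) NA_real_ else faith_pd(m, tree),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, via [vegan::vegdist()].
#'
#' @param t an [otu_table()] (or plain samples x taxa matrix) with positive
#'   sample totals.
#' @return A symmetric matrix in [0, 1] with zero diagonal.
#' @export
bray_curtis <- function(t) {
  m <- if (inherits(t, "otu_table")) t$counts else t
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) <= 0)) stop("sample(s) with zero total abundance")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Kruskal stress-1 NMDS of a dissimilarity matrix via [vegan::metaMDS()]
#' (monotone regression engine, multiple random starts plus a metric-MDS
#' start), returning the lowest-stress configuration found.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param k number of dimensions (default 2).
#' @param n_starts random starts (default 20).
#' @param max_iter maximum iterations per start.
#' @param seed optional integer seed.
#' @return List of class `nmds_ordination`: `points` (centered samples x k
#'   coordinates), `stress` (stress-1 in [0, 1]), `k`, `converged`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, max_iter = 300, seed = NULL) {
  dm <- stats::as.dist(d)
  n <- attr(dm, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(dm, k = k, trymax = n_starts, maxit = max_iter,
                        autotransform = FALSE, trace = 0, wascores = FALSE)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  structure(list(points = pts, stress = fit$stress,
                 k = k, converged = fit$converged > 0),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS (k=%d): stress-1 = %.4f%s\n", x$k, x$stress,
              if (!x$converged) " [no convergent solution reached]" else ""))
  invisible(x)
}

.test_result <- function(name, stat, p, n_perm) {
  structure(list(statistic = name, value = unname(stat), p_value = unname(p),
                 n_perm = n_perm), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$value, x$p_value, x$n_perm))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- vs within-group dissimilarities,
#' `R = (mean between-rank - mean within-rank) / (M/2)`, with a
#' permutation p-value, via [vegan::anosim()].
#'
#' @param d dissimilarity matrix or `dist`.
#' @param groups per-sample group labels (named or in order).
#' @param n_perm permutations (default 999).
#' @param seed optional seed.
#' @return A `perm_test` with the R statistic and p-value.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- stats::as.dist(d)
  ids <- attr(dm, "Labels")
  g <- if (!is.null(names(groups)) && !is.null(ids)) groups[ids] else groups
  tab <- table(g)
  if (length(tab) < 2 || all(tab < 2))
    stop("need at least 2 groups with at least 2 members each")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(dm, grouping = factor(g), permutations = n_perm)
  .test_result("ANOSIM R", fit$statistic, fit$signif, n_perm)
}

#' Mantel test between two distance matrices
#'
#' Correlation of the vectorized upper triangles with a permutation
#' p-value, via [vegan::mantel()]. Ids must match (order is aligned by
#' name when both matrices are named).
#'
#' @param d1,d2 distance matrices with matching ids.
#' @param n_perm permutations (default 999).
#' @param method `"pearson"` or `"spearman"`.
#' @param seed optional seed.
#' @return A `perm_test` with Mantel r.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, method = c("pearson", "spearman"),
                        seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) stop("distance matrix ids differ")
    m2 <- m2[rownames(m1), rownames(m1)]
  } else if (!all(dim(m1) == dim(m2))) stop("distance matrix dimensions differ")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       method = method, permutations = n_perm)
  .test_result("Mantel r", fit$statistic, fit$signif, n_perm)
}

#' Partial Mantel test
#'
#' First-order partial correlation of `d1` and `d2` controlling for `d3`,
#' permutation p-value, via [vegan::mantel.partial()].
#'
#' @inheritParams mantel_test
#' @param d3 controlling distance matrix.
#' @return A `perm_test` with partial Mantel r.
#' @export
partial_mantel_test <- function(d1, d2, d3, n_perm = 999,
                                method = c("pearson", "spearman"), seed = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2); m3 <- as.matrix(d3)
  if (!is.null(rownames(m1))) {
    if (!setequal(rownames(m1), rownames(m2)) || !setequal(rownames(m1), rownames(m3)))
      stop("distance matrix ids differ")
    m2 <- m2[rownames(m1), rownames(m1)]
    m3 <- m3[rownames(m1), rownames(m1)]
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel.partial(stats::as.dist(m1), stats::as.dist(m2),
                               stats::as.dist(m3), method = method,
                               permutations = n_perm)
  stat <- fit$statistic
  if (!is.finite(stat)) {
    ## d2 ~ d3: the conditioning matrix explains d2 entirely, so nothing is
    ## left to correlate (0/0); report the fully-controlled value 0
    v1 <- m1[lower.tri(m1)]; v2 <- m2[lower.tri(m2)]; v3 <- m3[lower.tri(m3)]
    r12 <- stats::cor(v1, v2, method = method)
    r13 <- stats::cor(v1, v3, method = method)
    r23 <- stats::cor(v2, v3, method = method)
    if (abs(r12 - r13 * r23) < 1e-8) stat <- 0
  }
  .test_result("partial Mantel r", stat, fit$signif, n_perm)
}

## Spearman/Pearson correlation with a two-sided p-value. For spearman at
## n < 10 without ties an exact permutation p is computed; otherwise the
## t approximation on n - 2 degrees of freedom is used. Constant inputs
## are flagged (r = NA, flag = "constant").
.cor_with_p <- function(x, y, method = "spearman") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "constant"))
  r <- stats::cor(x, y, method = method)
  if (method == "spearman" && n < 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    perms <- .permutations(n)
    rx <- rank(x)
    rs <- apply(perms, 1, function(p) stats::cor(rx, rank(y)[p]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    rr <- min(max(r, -1 + 1e-15), 1 - 1e-15)
    tt <- rr * sqrt((n - 2) / (1 - rr^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, p = p, n = n, flag = "")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

#' Correlation screen of diversity responses against predictors
#'
#' For each combination of response column and predictor column, within
#' each layer separately, computes the correlation and a two-sided
#' p-value. Constant variables are flagged rather than propagated as NaN.
#'
#' @param responses data frame of response variables (e.g. bacterial
#'   diversity metrics), one row per sample, with row names.
#' @param predictors data frame of predictors (eukaryote composition
#'   variables, physicochemical parameters), same samples.
#' @param layers named per-sample layer labels; `NULL` pools all samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Long data frame: layer, response, predictor, r, p, n, flag.
#' @export
correlation_screen <- function(responses, predictors, layers = NULL,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ids <- rownames(responses)
  stopifnot(identical(ids, rownames(predictors)))
  lay <- if (is.null(layers)) rep("all", length(ids)) else as.character(layers[ids])
  out <- list()
  for (lv in unique(lay)) {
    idx <- which(lay == lv)
    if (length(idx) < 4) {
      warning("layer '", lv, "' has <4 samples; skipped")
      next
    }
    for (rs in colnames(responses)) for (pr in colnames(predictors)) {
      cw <- .cor_with_p(responses[idx, rs], predictors[idx, pr], method)
      out[[length(out) + 1]] <- data.frame(layer = lv, response = rs,
                                           predictor = pr, r = cw$r, p = cw$p,
                                           n = cw$n, flag = cw$flag,
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Greedy forward-selected multiple regression
#'
#' Starts from the intercept-only model and adds, at each step, the
#' candidate predictor that most improves the criterion (AIC by default),
#' stopping when no addition improves it. Predictors that become collinear
#' with the selected set are dropped with a warning.
#'
#' @param y numeric response.
#' @param X data frame or matrix of candidate predictors.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return List of class `forward_selection`: `selected` (names, possibly
#'   empty), `coefficients`, `adj_r_squared`, `criterion_path`, `model`.
#' @export
forward_select_regression <- function(y, X, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  crit_fun <- if (criterion == "AIC") stats::AIC else stats::BIC
  dat <- data.frame(.y = y, X, check.names = FALSE)
  selected <- character(0)
  remaining <- colnames(X)
  fit <- stats::lm(.y ~ 1, data = dat)
  best_crit <- crit_fun(fit)
  path <- best_crit
  repeat {
    if (!length(remaining) || length(selected) + 3 > n) break
    cand_crit <- rep(Inf, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      form <- stats::reformulate(sprintf("`%s`", c(selected, remaining[i])),
                                 response = ".y")
      f <- stats::lm(form, data = dat)
      if (anyNA(stats::coef(f))) next   # collinear with current set
      fits[[i]] <- f
      cand_crit[i] <- crit_fun(f)
    }
    if (all(!is.finite(cand_crit))) {
      if (length(remaining)) warning("remaining predictor(s) collinear with selected set: ",
                                     paste(remaining, collapse = ", "))
      break
    }
    j <- which.min(cand_crit)
    if (cand_crit[j] >= best_crit - 1e-9) break
    selected <- c(selected, remaining[j])
    remaining <- setdiff(remaining, remaining[j])
    fit <- fits[[j]]
    best_crit <- cand_crit[j]
    path <- c(path, best_crit)
  }
  structure(list(selected = selected, coefficients = stats::coef(fit),
                 adj_r_squared = summary(fit)$adj.r.squared,
                 criterion = criterion, criterion_path = path, model = fit),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("forward selection (", x$criterion, "): ",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "<intercept only>",
      "\n  adjusted R^2 = ", round(x$adj_r_squared, 4), "\n", sep = "")
  invisible(x)
}
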