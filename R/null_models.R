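#' Configuration for the assembly null models
#'
#' @param n_null number of null randomizations for both the tip-shuffle
#'   betaNTI null and the Raup-Crick assembly null.
#' @param bnti_threshold selection threshold on |betaNTI|; pairs beyond it
#'   are attributed to deterministic selection.
#' @param rc_threshold dispersal threshold on |RC-bray| applied to pairs
#'   with |betaNTI| within the selection threshold.
#' @param abundance_weighted logical; weight betaMNTD by relative abundance
#'   (the default) or equally across present taxa.
#' @param seed optional integer seed; when set, every stochastic step is
#'   bitwise reproducible.
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_null = 999, bnti_threshold = 2, rc_threshold = 0.95,
                        abundance_weighted = TRUE, seed = NULL) {
  stopifnot(n_null >= 1, bnti_threshold > 0, rc_threshold > 0)
  structure(list(n_null = as.integer(n_null),
                 bnti_threshold = bnti_threshold,
                 rc_threshold = rc_threshold,
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = seed),
            class = "null_config")
}

## Align table taxa with tree tips; returns list(D, W, taxa) with W taxa x
## samples. The taxon universe is the WHOLE tree: tips never observed in the
## table get zero weight but stay in the patristic matrix, because the
## tip-shuffle null randomizes across the full regional pool the tree
## represents. Pass a tree pruned to the table's taxa to restrict the null
## to observed taxa instead.
.bmntd_inputs <- function(t, tree, abundance_weighted) {
  taxa <- tree$tip.label
  missing <- setdiff(otu_ids(t), taxa)
  if (length(missing))
    stop("OTU(s) absent from tree: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  D <- ape::cophenetic.phylo(tree)[taxa, taxa, drop = FALSE]
  rel <- relative_abundance(t)$counts            # samples x observed taxa
  if (!abundance_weighted) {
    pres <- rel > 0
    rel <- pres / rowSums(pres)
  }
  W <- matrix(0, length(taxa), nrow(rel), dimnames = list(taxa, rownames(rel)))
  W[colnames(rel), ] <- t(rel)
  list(D = D, W = W, taxa = taxa)
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' The observed statistic underlying betaNTI: for each pair of samples, the
#' abundance-weighted mean patristic distance from every taxon in one
#' sample to its closest relative in the other (a taxon shared by both
#' samples contributes distance zero), averaged over both directions.
#'
#' @param t an [otu_table()] whose OTUs are all tips of `tree`.
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param abundance_weighted logical; see [null_config()].
#' @return A symmetric samples x samples numeric matrix with zero diagonal.
#' @export
beta_mntd <- function(t, tree, abundance_weighted = TRUE) {
  inp <- .bmntd_inputs(t, tree, abundance_weighted)
  b <- .bmntd_kernel(inp$D, inp$W)
  dimnames(b) <- list(sample_ids(t), sample_ids(t))
  b
}

#' Beta nearest taxon index (betaNTI) under a tip-shuffling null
#'
#' Standardized effect size of betaMNTD: for each sample pair,
#' `(obs - mean(null)) / sd(null)` where the null shuffles tip labels
#' across the whole tree (equivalently, permutes rows and columns of the
#' patristic matrix) and recomputes betaMNTD, `n_null` times. Pairs whose
#' null distribution is degenerate (sd ~ 0, e.g. on an equal-branch star
#' tree) are masked as `NA` with a warning rather than divided by zero.
#'
#' @inheritParams beta_mntd
#' @param cfg a [null_config()].
#' @return A [pairwise_statistic()] named `"bNTI"`, carrying the observed
#'   betaMNTD matrix and the null mean/sd matrices as `observed`,
#'   `null_mean` and `null_sd`.
#' @export
bnti <- function(t, tree, cfg = null_config()) {
  if (nrow(t$counts) < 2) stop("need at least 2 samples")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  inp <- .bmntd_inputs(t, tree, cfg$abundance_weighted)
  n_taxa <- length(inp$taxa)
  obs <- .bmntd_kernel(inp$D, inp$W)
  s1 <- matrix(0, nrow(obs), ncol(obs))
  s2 <- matrix(0, nrow(obs), ncol(obs))
  for (b in seq_len(cfg$n_null)) {
    nb <- .bmntd_kernel(inp$D, inp$W, sample.int(n_taxa))
    s1 <- s1 + nb
    s2 <- s2 + nb * nb
  }
  mu <- s1 / cfg$n_null
  va <- (s2 - cfg$n_null * mu * mu) / (cfg$n_null - 1)
  va[va < 0] <- 0
  sdv <- sqrt(va)
  z <- (obs - mu) / sdv
  degen <- sdv < 1e-10
  diag(degen) <- FALSE
  if (any(degen[upper.tri(degen)])) {
    warning(sum(degen[upper.tri(degen)]),
            " pair(s) masked: degenerate tip-shuffle null (sd ~ 0)")
    z[degen] <- NA_real_
  }
  dimnames(z) <- list(sample_ids(t), sample_ids(t))
  dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <- dimnames(z)
  out <- pairwise_statistic(z, "bNTI")
  out$n_null <- cfg$n_null
  out$observed <- obs
  out$null_mean <- mu
  out$null_sd <- sdv
  out
}

## One set of null assemblies for a single sample: n_null x n_taxa counts.
## Null communities keep the sample's observed richness S and total
## abundance N; taxa are drawn without replacement with probability
## proportional to metacommunity occupancy, each receives one individual,
## and the remaining N - S individuals are assigned multinomially with
## probability proportional to metacommunity relative abundance.
.rc_null_sample <- function(S, N, occ, abund, n_null) {
  n_taxa <- length(occ)
  out <- matrix(0, n_null, n_taxa)
  for (b in seq_len(n_null)) {
    sel <- sample.int(n_taxa, S, prob = occ)
    x <- numeric(n_taxa)
    x[sel] <- 1
    if (N > S) {
      w <- abund[sel]
      if (sum(w) <= 0) w <- rep(1, length(sel))
      x[sel] <- x[sel] + stats::rmultinom(1, N - S, prob = w)[, 1]
    }
    out[b, ] <- x
  }
  out
}

#' Abundance-based Raup-Crick metric on Bray-Curtis dissimilarity (RC-bray)
#'
#' Locates each pair's observed Bray-Curtis dissimilarity within a null
#' distribution of dissimilarities between probabilistically assembled
#' communities, rescaled to [-1, 1]:
#' `RC = 2 * (P(BC_null < BC_obs) + 0.5 * P(BC_null = BC_obs)) - 1`.
#' Values near -1 mean the pair is far more similar than expected by
#' chance (homogenizing dispersal); near +1, far more dissimilar
#' (dispersal limitation). The null preserves each sample's richness and
#' total abundance; presence is occupancy-weighted, abundance filling is
#' metacommunity-abundance weighted.
#'
#' @param t an [otu_table()] of integer counts (values are rounded).
#' @param cfg a [null_config()].
#' @return A [pairwise_statistic()] named `"RCbray"`.
#' @export
raup_crick_bray <- function(t, cfg = null_config()) {
  if (nrow(t$counts) < 2) stop("need at least 2 samples")
  counts <- round(t$counts)
  if (any(rowSums(counts) <= 0)) stop("sample(s) with zero total after rounding")
  occ <- colSums(counts > 0)
  if (sum(occ > 0) < 2) stop("null model undefined for a single-taxon metacommunity")
  abund <- colSums(counts)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- nrow(counts)
  nulls <- vector("list", n)
  for (s in seq_len(n)) {
    nulls[[s]] <- .rc_null_sample(sum(counts[s, ] > 0), sum(counts[s, ]),
                                  occ, abund, cfg$n_null)
  }
  eps <- 1e-10
  rc <- matrix(NA_real_, n, n, dimnames = list(rownames(counts), rownames(counts)))
  diag(rc) <- 0
  for (k in seq_len(n - 1)) {
    for (m in seq((k + 1), n)) {
      xo <- counts[k, ]; yo <- counts[m, ]
      obs <- sum(abs(xo - yo)) / sum(xo + yo)
      dn <- abs(nulls[[k]] - nulls[[m]])
      sm <- nulls[[k]] + nulls[[m]]
      bc_null <- rowSums(dn) / rowSums(sm)
      p_lt <- mean(bc_null < obs - eps)
      p_eq <- mean(abs(bc_null - obs) <= eps)
      rc[k, m] <- rc[m, k] <- 2 * (p_lt + 0.5 * p_eq) - 1
    }
  }
  out <- pairwise_statistic(rc, "RCbray")
  out$n_null <- cfg$n_null
  out
}

.process_levels <- c("heterogeneous selection", "homogeneous selection",
                     "dispersal limitation", "homogenizing dispersal",
                     "undominated")

#' Classify pairwise assembly processes from betaNTI and RC-bray
#'
#' The five-way attribution: betaNTI beyond +/- the selection threshold
#' assigns heterogeneous/homogeneous selection; otherwise RC-bray beyond
#' +/- the dispersal threshold assigns dispersal limitation/homogenizing
#' dispersal; remaining pairs are undominated. Pairs with masked betaNTI
#' are labelled `NA` and excluded from fractions.
#'
#' @param bnti a [pairwise_statistic()] of betaNTI values.
#' @param rc a [pairwise_statistic()] of RC-bray values over the same ids.
#' @param cfg a [null_config()] supplying the thresholds.
#' @return An object of class `assembly_result`: list with `bnti`, `rc`,
#'   `process` (character matrix), `fractions` (named proportions over all
#'   unmasked pairs) and the thresholds used.
#' @export
classify_assembly <- function(bnti, rc, cfg = null_config()) {
  if (!identical(bnti$ids, rc$ids)) stop("betaNTI and RC-bray ids differ")
  T_ <- cfg$bnti_threshold; R_ <- cfg$rc_threshold
  b <- bnti$values; r <- rc$values
  lab <- matrix(NA_character_, nrow(b), ncol(b), dimnames = dimnames(b))
  ok <- !is.na(b) & !is.na(r)
  lab[ok & b > T_] <- "heterogeneous selection"
  lab[ok & b < -T_] <- "homogeneous selection"
  mid <- ok & abs(b) <= T_
  lab[mid & r > R_] <- "dispersal limitation"
  lab[mid & r < -R_] <- "homogenizing dispersal"
  lab[mid & abs(r) <= R_] <- "undominated"
  diag(lab) <- NA_character_
  v <- lab[upper.tri(lab)]
  fr <- table(factor(v[!is.na(v)], levels = .process_levels))
  fractions <- if (sum(fr) > 0) as.numeric(fr) / sum(fr) else rep(NA_real_, 5)
  names(fractions) <- .process_levels
  structure(list(bnti = bnti, rc = rc, process = lab, fractions = fractions,
                 bnti_threshold = T_, rc_threshold = R_),
            class = "assembly_result")
}

#' Process fractions per sample group
#'
#' Restricts the classification to pairs whose two samples share a group
#' label (e.g. habitat layer) and tabulates process fractions per group.
#' Groups with fewer than two samples are omitted with a warning.
#'
#' @param res an `assembly_result` from [classify_assembly()].
#' @param groups named character vector mapping sample id to group.
#' @return A data frame: group, process, fraction, n_pairs.
#' @export
assembly_by_group <- function(res, groups) {
  ids <- res$bnti$ids
  g <- groups[ids]
  if (anyNA(g)) stop("group label missing for sample(s): ",
                     paste(ids[is.na(g)], collapse = ", "))
  out <- list()
  for (lev in unique(g)) {
    members <- which(g == lev)
    if (length(members) < 2) {
      warning("group '", lev, "' has <2 samples; omitted")
      next
    }
    sub <- res$process[members, members, drop = FALSE]
    v <- sub[upper.tri(sub)]
    v <- v[!is.na(v)]
    fr <- table(factor(v, levels = .process_levels))
    frac <- if (length(v)) as.numeric(fr) / length(v) else rep(NA_real_, 5)
    out[[lev]] <- data.frame(group = lev, process = .process_levels,
                             fraction = frac, n_pairs = length(v))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fit the community assembly null models
#'
#' The package's central fitting function: computes betaNTI and RC-bray
#' for every sample pair, classifies each pair into one of five assembly
#' processes, and tabulates process fractions within each habitat layer.
#'
#' @param t an [otu_table()] of counts whose OTUs are tips of `tree`.
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param cfg a [null_config()].
#' @param groups per-sample group labels; defaults to the table's layers.
#' @return An object of class `assembly_fit` (extending `assembly_result`)
#'   with `fractions_by_group`, printable and plottable.
#' @seealso [bnti()], [raup_crick_bray()], [classify_assembly()]
#' @export
fit_assembly <- function(t, tree, cfg = null_config(), groups = t$layer) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_nested <- cfg
  cfg_nested$seed <- NULL            # one stream for the whole fit
  b <- bnti(t, tree, cfg_nested)
  r <- raup_crick_bray(t, cfg_nested)
  res <- classify_assembly(b, r, cfg)
  res$fractions_by_group <- assembly_by_group(res, groups)
  res$groups <- groups[res$bnti$ids]
  res$config <- cfg
  class(res) <- c("assembly_fit", "assembly_result")
  res
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly process attribution (", length(x$bnti$ids), " samples, ",
      "thresholds |bNTI| > ", x$bnti_threshold, ", |RC| > ", x$rc_threshold,
      ")\n", sep = "")
  cat("overall fractions:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' @export
summary.assembly_fit <- function(object, ...) {
  v <- object$bnti$values[upper.tri(object$bnti$values)]
  cat("betaNTI: mean", round(mean(v, na.rm = TRUE), 3),
      "| range", paste(round(range(v, na.rm = TRUE), 3), collapse = " .. "), "\n")
  print(object$fractions_by_group)
  invisible(object$fractions_by_group)
}

#' @export
plot.assembly_fit <- function(x, ...) {
  ids <- x$bnti$ids
  g <- x$groups
  ut <- which(upper.tri(x$bnti$values), arr.ind = TRUE)
  same <- g[ut[, 1]] == g[ut[, 2]]
  vals <- x$bnti$values[upper.tri(x$bnti$values)][same]
  grp <- g[ut[same, 1]]
  graphics::boxplot(vals ~ grp, xlab = "layer", ylab = "betaNTI",
                    main = "within-layer betaNTI", ...)
  graphics::abline(h = c(-x$bnti_threshold, x$bnti_threshold), lty = 2)
  invisible(x)
}

#' Extract within-group pair values from a pairwise statistic
#'
#' Utility used by the perturbation experiment and the path-model
#' observation table: returns the upper-triangle values restricted to pairs
#' sharing a group label.
#'
#' @param ps a [pairwise_statistic()].
#' @param groups named group labels per id; `NULL` keeps all pairs.
#' @return A data frame with columns `id1`, `id2`, `group`, `value`.
#' @export
pair_values <- function(ps, groups = NULL) {
  v <- ps$values
  ut <- which(upper.tri(v), arr.ind = TRUE)
  df <- data.frame(id1 = ps$ids[ut[, 1]], id2 = ps$ids[ut[, 2]],
                   value = v[upper.tri(v)], stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    g1 <- groups[df$id1]; g2 <- groups[df$id2]
    df$group <- ifelse(g1 == g2, g1, NA_character_)
  }
  df
}
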