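#' Default ordinal encoding of habitat layers as depth
#'
#' Overlying water and successively deeper sediment layers. The
#' `"midpoint_cm"` encoding uses the midpoint depth of each horizon
#' instead (water column treated as 5 cm above the interface).
#'
#' @param layer character vector of layer labels (`W`, `S1`, `S2`, `S3`).
#' @param encoding `"ordinal"` (0, 1, 2, 3) or `"midpoint_cm"`.
#' @return Numeric depth per sample.
#' @export
layer_depth <- function(layer, encoding = c("ordinal", "midpoint_cm")) {
  encoding <- match.arg(encoding)
  map <- if (encoding == "ordinal") c(W = 0, S1 = 1, S2 = 2, S3 = 3)
         else c(W = -5, S1 = 2.5, S2 = 7.5, S3 = 15)
  unknown <- setdiff(unique(layer), names(map))
  if (length(unknown)) stop("unknown layer label(s): ", paste(unknown, collapse = ", "))
  out <- map[layer]
  names(out) <- names(layer)
  out
}

#' Random-forest importance ranking of OTUs against depth
#'
#' Regresses sample depth on OTU relative abundances with a random forest
#' and ranks OTUs by permutation importance (%IncMSE: the percentage
#' increase in out-of-bag mean-squared error when an OTU's abundances are
#' permuted). Ties are broken by OTU id.
#'
#' @param t an [otu_table()] (converted to relative abundances).
#' @param depth numeric response per sample (e.g. [layer_depth()]);
#'   defaults to the ordinal encoding of the table's layers.
#' @param n_trees trees in the forest (default 1000).
#' @param seed optional seed.
#' @return Object of class `importance_ranking`: data frame `ranking`
#'   (otu, importance) in descending order, plus the fitted forest.
#' @export
rf_importance <- function(t, depth = layer_depth(t$layer), n_trees = 1000,
                          seed = NULL) {
  if (ncol(t$counts) < 2) stop("need at least 2 OTUs")
  y <- as.numeric(depth)
  if (length(unique(y)) < 2) stop("depth response is constant")
  x <- as.data.frame(relative_abundance(t)$counts)
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  ord <- order(-imp, names(imp))
  structure(list(ranking = data.frame(otu = names(imp)[ord],
                                      importance = unname(imp[ord]),
                                      stringsAsFactors = FALSE),
                 forest = rf),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat("random-forest importance ranking (", nrow(x$ranking), " OTUs, %IncMSE)\n",
      sep = "")
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' Cross-validated feature-count refinement (rfcv)
#'
#' Recursive feature elimination via [randomForest::rfcv()]: repeatedly
#' keep the top fraction `step` of OTUs by importance and record the
#' k-fold cross-validated MSE; the selected feature count minimizes CV
#' error (smallest count on ties).
#'
#' @inheritParams rf_importance
#' @param folds cross-validation folds (default 10).
#' @param step fraction of features kept per elimination step (default
#'   0.5).
#' @return List of class `rfcv_curve`: `cv_curve` (n_features, cv_error),
#'   `selected_n`.
#' @export
rfcv_refine <- function(t, depth = layer_depth(t$layer), folds = 10, step = 0.5,
                        seed = NULL) {
  y <- as.numeric(depth)
  n <- nrow(t$counts)
  if (folds > n) stop("more folds than samples")
  x <- as.data.frame(relative_abundance(t)$counts)
  if (!is.null(seed)) set.seed(seed)
  cv <- randomForest::rfcv(trainx = x, trainy = y, cv.fold = folds, step = step)
  curve <- data.frame(n_features = cv$n.var, cv_error = cv$error.cv,
                      row.names = NULL)
  curve <- curve[order(curve$n_features), ]
  best <- min(curve$n_features[curve$cv_error <= min(curve$cv_error) + 1e-12])
  structure(list(cv_curve = curve, selected_n = best), class = "rfcv_curve")
}

#' @export
print.rfcv_curve <- function(x, ...) {
  cat("rfcv feature refinement: selected", x$selected_n, "features\n")
  print(x$cv_curve, row.names = FALSE)
  invisible(x)
}

#' Taxa-removal perturbation of the assembly null models
#'
#' Re-runs the full null-model classification after deleting a set of
#' taxa (e.g. the random-forest-important OTUs) from the community, with
#' the tree pruned to the surviving tips and the null redrawn over them,
#' and summarizes how betaNTI and the process fractions shift.
#'
#' @param t an [otu_table()] of counts.
#' @param tree rooted [ape::phylo] covering the table's OTUs.
#' @param taxa OTU ids to remove (empty set = exact no-op).
#' @param cfg a [null_config()]; the same seed is used before and after
#'   so an empty removal reproduces the unperturbed fit bit-exactly.
#' @param groups per-sample group labels (default: table layers).
#' @return Object of class `perturbation_experiment`: `before`, `after`
#'   ([fit_assembly()] objects), `delta_bnti` (per shared pair),
#'   `mean_shift` (mean within-group betaNTI after minus before).
#' @export
perturbation_experiment <- function(t, tree, taxa, cfg = null_config(),
                                    groups = t$layer) {
  before <- fit_assembly(t, tree, cfg, groups)
  if (length(taxa)) {
    t2 <- remove_taxa(t, taxa)
    if (ncol(t2$counts) < 3) stop("removal leaves fewer than 3 taxa")
    tree2 <- ape::keep.tip(tree, intersect(tree$tip.label, otu_ids(t2)))
    after <- fit_assembly(t2, tree2, cfg, groups[sample_ids(t2)])
  } else {
    after <- before
  }
  shared <- intersect(before$bnti$ids, after$bnti$ids)
  db <- after$bnti$values[shared, shared] - before$bnti$values[shared, shared]
  g <- groups[shared]
  ut <- which(upper.tri(db), arr.ind = TRUE)
  within <- g[ut[, 1]] == g[ut[, 2]]
  delta <- db[upper.tri(db)]
  structure(list(before = before, after = after,
                 delta_bnti = pairwise_statistic(db, "delta bNTI"),
                 mean_shift = mean(delta[within], na.rm = TRUE),
                 removed = as.character(taxa)),
            class = "perturbation_experiment")
}

#' @export
print.perturbation_experiment <- function(x, ...) {
  cat("taxa-removal perturbation:", length(x$removed), "OTU(s) removed\n")
  cat(sprintf("  mean within-group betaNTI shift: %+.3f\n", x$mean_shift))
  bf <- x$before$fractions; af <- x$after$fractions
  cat("  dominant process before:", names(which.max(bf)),
      "-> after:", names(which.max(af)), "\n")
  invisible(x)
}
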