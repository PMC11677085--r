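#' Specify a PLS path model
#'
#' Latent-variable blocks of manifest variables plus a directed acyclic
#' inner model. All blocks are reflective (mode A).
#'
#' @param blocks named list: latent variable name -> character vector of
#'   manifest (column) names; every manifest belongs to exactly one block.
#' @param inner named list: endogenous latent -> character vector of its
#'   predecessor latents. Latents absent from `names(inner)` are
#'   exogenous.
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"`
#'   or `"factor"`.
#' @return Object of class `plspm_spec`.
#' @export
plspm_spec <- function(blocks, inner, scheme = c("path", "centroid", "factor")) {
  scheme <- match.arg(scheme)
  lvs <- names(blocks)
  if (is.null(lvs) || anyDuplicated(lvs)) stop("blocks must be uniquely named")
  mans <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(mans))
    stop("manifest(s) in more than one block: ",
         paste(unique(mans[duplicated(mans)]), collapse = ", "))
  bad <- setdiff(unique(c(names(inner), unlist(inner))), lvs)
  if (length(bad)) stop("inner model names unknown latent(s): ",
                        paste(bad, collapse = ", "))
  ## acyclicity by topological elimination
  deps <- inner
  remaining <- lvs
  repeat {
    free <- remaining[vapply(remaining, function(l)
      !length(intersect(deps[[l]], remaining)), logical(1))]
    if (!length(free)) {
      if (length(remaining)) stop("inner model contains a cycle")
      break
    }
    remaining <- setdiff(remaining, free)
    if (!length(remaining)) break
  }
  structure(list(blocks = blocks, inner = inner, scheme = scheme),
            class = "plspm_spec")
}

## adjacency helpers ------------------------------------------------------
.plspm_neighbors <- function(spec) {
  lvs <- names(spec$blocks)
  adj <- matrix(FALSE, length(lvs), length(lvs), dimnames = list(lvs, lvs))
  for (to in names(spec$inner)) for (from in spec$inner[[to]]) {
    adj[from, to] <- TRUE
  }
  adj
}

#' Fit a PLS path model (Lohmoeller algorithm)
#'
#' Standardizes the manifest variables, then alternates outer
#' approximation (mode A: weights proportional to the correlation of each
#' manifest with its block's inner proxy) and inner approximation (path,
#' centroid or factor scheme) until the largest outer-weight change falls
#' below `tol`. Path coefficients are OLS regressions of each endogenous
#' latent score on its predecessors; GoF is the geometric mean of average
#' communality and average R-squared. Latent sign indeterminacy is
#' resolved by forcing each block's dominant manifest loading positive.
#'
#' @param data data frame / matrix containing every manifest variable as a
#'   numeric column; no constant columns.
#' @param spec a [plspm_spec()].
#' @param tol convergence tolerance on outer weights (default 1e-7).
#' @param max_iter maximum iterations (default 300).
#' @return Object of class `plspm_fit`: `loadings`, `weights`, `scores`
#'   (unit-variance latent scores), `paths` (data frame from, to,
#'   coefficient), `r_squared`, `gof`, `iterations`, plus the spec and
#'   data for refits.
#' @export
fit_plspm <- function(data, spec, tol = 1e-7, max_iter = 300) {
  stopifnot(inherits(spec, "plspm_spec"))
  mans <- unlist(spec$blocks, use.names = FALSE)
  missing <- setdiff(mans, colnames(data))
  if (length(missing)) stop("manifest(s) absent from data: ",
                            paste(missing, collapse = ", "))
  X <- as.matrix(data[, mans, drop = FALSE])
  if (anyNA(X)) stop("manifest variables contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant manifest variable(s): ",
                          paste(mans[sds == 0], collapse = ", "))
  n <- nrow(X)
  lvs <- names(spec$blocks)
  if (n <= length(lvs)) stop("need more observations than latent variables")
  Xs <- scale(X)
  adj <- .plspm_neighbors(spec)
  link <- adj | t(adj)

  w <- lapply(spec$blocks, function(b) rep(1, length(b)))
  norm_w <- function(wj, Xj) {
    y <- Xj %*% wj
    wj / stats::sd(y)
  }
  for (j in lvs) w[[j]] <- norm_w(w[[j]], Xs[, spec$blocks[[j]], drop = FALSE])

  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    Y <- sapply(lvs, function(j) Xs[, spec$blocks[[j]], drop = FALSE] %*% w[[j]])
    colnames(Y) <- lvs
    R <- stats::cor(Y)
    ## inner proxies
    Z <- matrix(0, n, length(lvs), dimnames = list(NULL, lvs))
    for (j in lvs) {
      nb <- lvs[link[j, ]]
      if (!length(nb)) { Z[, j] <- Y[, j]; next }
      e <- numeric(length(nb)); names(e) <- nb
      if (spec$scheme == "centroid") {
        e[] <- sign(R[j, nb])
      } else if (spec$scheme == "factor") {
        e[] <- R[j, nb]
      } else {                       # path scheme
        pred <- lvs[adj[, j]]        # predecessors of j
        succ <- setdiff(nb, pred)
        if (length(pred))
          e[pred] <- solve(R[pred, pred, drop = FALSE], R[pred, j])
        if (length(succ)) e[succ] <- R[j, succ]
      }
      Z[, j] <- Y[, nb, drop = FALSE] %*% e
    }
    ## outer update, mode A
    w_new <- w
    for (j in lvs) {
      Xj <- Xs[, spec$blocks[[j]], drop = FALSE]
      wj <- as.numeric(stats::cor(Xj, Z[, j]))
      if (all(wj == 0)) wj <- w[[j]]
      ## stabilize sign: dominant manifest weight positive
      if (wj[which.max(abs(wj))] < 0) wj <- -wj
      w_new[[j]] <- norm_w(wj, Xj)
    }
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter)
      stop("PLS-PM did not converge in ", max_iter,
           " iterations (last weight change ", signif(delta, 3), ")")
  }

  Y <- sapply(lvs, function(j) Xs[, spec$blocks[[j]], drop = FALSE] %*% w[[j]])
  colnames(Y) <- lvs
  ## sign fix on loadings
  loadings <- numeric(0)
  for (j in lvs) {
    Xj <- Xs[, spec$blocks[[j]], drop = FALSE]
    lj <- as.numeric(stats::cor(Xj, Y[, j]))
    if (lj[which.max(abs(lj))] < 0) {
      Y[, j] <- -Y[, j]
      w[[j]] <- -w[[j]]
      lj <- -lj
    }
    names(lj) <- spec$blocks[[j]]
    loadings <- c(loadings, lj)
  }
  Y <- apply(Y, 2, function(v) v / stats::sd(v))
  colnames(Y) <- lvs

  paths <- list(); r2 <- numeric(0)
  for (j in names(spec$inner)) {
    pred <- spec$inner[[j]]
    fit <- stats::lm.fit(cbind(1, Y[, pred, drop = FALSE]), Y[, j])
    beta <- fit$coefficients[-1]
    names(beta) <- pred
    r2[j] <- 1 - sum(fit$residuals^2) / sum((Y[, j] - mean(Y[, j]))^2)
    paths[[j]] <- data.frame(from = pred, to = j, coefficient = unname(beta),
                             stringsAsFactors = FALSE)
  }
  paths <- do.call(rbind, c(paths, list(make.row.names = FALSE)))
  communality <- loadings^2
  gof <- sqrt(mean(communality) * mean(r2))
  structure(list(loadings = loadings, weights = w, scores = Y, paths = paths,
                 r_squared = r2, gof = gof, communality = communality,
                 iterations = iter, converged = converged,
                 spec = spec, data = data),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model (%s scheme): GoF = %.4f, %d iterations\n",
              x$spec$scheme, x$gof, x$iterations))
  cat("paths:\n")
  df <- x$paths
  if (!is.null(x$boot)) df <- merge(df, x$boot, by = c("from", "to"), sort = FALSE)
  print(df, row.names = FALSE, digits = 4)
  cat("R^2:", paste(sprintf("%s = %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.plspm_fit <- function(object, ...) {
  cat("outer loadings:\n")
  print(round(object$loadings, 4))
  print(object)
  invisible(object)
}

#' Drop weak manifest variables and refit
#'
#' Iteratively removes manifests with |loading| below the threshold and
#' refits, until the spec is stable. A block that would lose all its
#' manifests keeps its single best one, with a warning.
#'
#' @param model a [fit_plspm()] result.
#' @param threshold loading magnitude below which a manifest is dropped
#'   (default 0.7).
#' @return A refit `plspm_fit` on the pruned spec.
#' @export
prune_low_loadings <- function(model, threshold = 0.7) {
  spec <- model$spec
  repeat {
    lo <- model$loadings
    blocks <- spec$blocks
    changed <- FALSE
    for (j in names(blocks)) {
      lj <- lo[blocks[[j]]]
      keep <- names(lj)[abs(lj) >= threshold]
      if (!length(keep)) {
        keep <- names(lj)[which.max(abs(lj))]
        if (length(lj) > 1)
          warning("block '", j, "': all loadings below ", threshold,
                  "; keeping its best manifest '", keep, "'")
      }
      if (!identical(keep, blocks[[j]])) changed <- TRUE
      blocks[[j]] <- keep
    }
    if (!changed) return(model)
    spec <- plspm_spec(blocks, spec$inner, spec$scheme)
    model <- fit_plspm(model$data, spec)
  }
}

#' Bootstrap significance of path coefficients
#'
#' Nonparametric bootstrap over observations; percentile confidence
#' intervals, and a two-sided p-value from the bootstrap distribution's
#' sign-crossing frequency.
#'
#' @param model a [fit_plspm()] result.
#' @param B bootstrap resamples (default 500).
#' @param seed optional seed.
#' @return The model with a `boot` data frame attached (from, to,
#'   ci_lower, ci_upper, p_value); also returned as the `boot` element.
#' @export
bootstrap_paths <- function(model, B = 500, seed = NULL) {
  if (nrow(model$data) < 10) stop("need at least 10 observations to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(model$data)
  key <- paste(model$paths$from, model$paths$to)
  draws <- matrix(NA_real_, B, length(key), dimnames = list(NULL, key))
  failures <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(fit_plspm(model$data[idx, , drop = FALSE], model$spec),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1; next }
    draws[b, paste(fit$paths$from, fit$paths$to)] <- fit$paths$coefficient
  }
  if (failures > 0.1 * B)
    stop("bootstrap refit failure rate above 10% (", failures, "/", B, ")")
  boot <- data.frame(from = model$paths$from, to = model$paths$to,
                     ci_lower = apply(draws, 2, stats::quantile, 0.025, na.rm = TRUE),
                     ci_upper = apply(draws, 2, stats::quantile, 0.975, na.rm = TRUE),
                     p_value = apply(draws, 2, function(v) {
                       v <- v[!is.na(v)]
                       min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
                     }),
                     row.names = NULL, stringsAsFactors = FALSE)
  model$boot <- boot
  model
}

#' Pairwise observation table for the assembly path model
#'
#' One observation per within-layer sample pair: environmental
#' heterogeneity (Euclidean distance between standardized physicochemical
#' vectors), the layer's interdomain P/N ratios broadcast to its pairs,
#' and the pair's betaNTI as the response.
#'
#' @param env data frame of numeric physicochemical variables, sample ids
#'   as row names. Pairs involving samples with missing values are
#'   dropped, with the count reported via a message.
#' @param pn_by_layer data frame with row names = layer and one column per
#'   P/N variable (e.g. `PN_BF`, `PN_BP`, `PN_BA`).
#' @param bnti a [pairwise_statistic()] of betaNTI values.
#' @param layers named per-sample layer labels.
#' @return Data frame: id1, id2, layer, Env, the P/N columns, bNTI.
#' @export
build_observation_table <- function(env, pn_by_layer, bnti, layers) {
  ids <- bnti$ids
  stopifnot(all(ids %in% rownames(env)))
  ez <- scale(as.matrix(env[ids, , drop = FALSE]))
  pv <- pair_values(bnti, groups = layers)
  pv <- pv[!is.na(pv$group), , drop = FALSE]
  drop_na <- !stats::complete.cases(ez[pv$id1, , drop = FALSE]) |
             !stats::complete.cases(ez[pv$id2, , drop = FALSE])
  if (any(drop_na))
    message(sum(drop_na), " pair(s) dropped for missing environmental values")
  pv <- pv[!drop_na, , drop = FALSE]
  pv$Env <- sqrt(rowSums((ez[pv$id1, , drop = FALSE] - ez[pv$id2, , drop = FALSE])^2))
  for (col in colnames(pn_by_layer))
    pv[[col]] <- pn_by_layer[pv$group, col]
  out <- data.frame(id1 = pv$id1, id2 = pv$id2, layer = pv$group, Env = pv$Env,
                    pv[, colnames(pn_by_layer), drop = FALSE],
                    bNTI = pv$value, stringsAsFactors = FALSE, row.names = NULL)
  out
}
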