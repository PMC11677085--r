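#' Run the full assembly analysis pipeline
#'
#' Executes the stages in the order of a typical community-assembly study:
#' diversity and ordination, null-model process attribution, interdomain
#' networks, the PLS path model, and random-forest important-taxa
#' identification with the taxa-removal perturbation. Each stage's outputs
#' are written before the next starts; a JSON manifest records inputs,
#' stage seeds and output hashes. Re-running with the same configuration
#' reproduces every stochastic output bit-exactly.
#'
#' @param config a list, or the path to a YAML file, with elements:
#'   \describe{
#'     \item{simulate}{list passed to [scenario_config()] (synthetic
#'       input), or}
#'     \item{input}{list of paths `table`, `tree`, `metadata`, and
#'       optionally `fungi`, `protozoa`, `algae` (file input),}
#'     \item{null}{overrides for [null_config()],}
#'     \item{network}{`r_min`, `p_max`, `prevalence_min`,
#'       `robust_fraction`, `robust_reps`,}
#'     \item{rf}{`n_trees`, `folds`, `top_n`,}
#'     \item{out_dir}{output directory,}
#'     \item{seed}{global seed, expanded into per-stage substreams.}
#'   }
#' @param out_dir overrides `config$out_dir`.
#' @return The manifest list, invisibly; all results are on disk.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory configured")
  seed <- config$seed
  ## validate before any computation
  if (is.null(config$simulate)) {
    inp <- config$input %||% stop("config needs either 'simulate' or 'input'")
    for (f in c("table", "tree", "metadata")) {
      if (is.null(inp[[f]])) stop("config$input$", f, " is required")
      if (!file.exists(inp[[f]])) stop("input file does not exist: ", inp[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list())
  manifest_path <- file.path(out_dir, "manifest.json")
  files <- character(0)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", out_dir, ")", call. = FALSE))
    manifest$stages[[name]] <<- list(seed = substream_seed(seed, name),
                                     outputs = res)
    files <<- c(files, res)
    write_results(manifest, manifest_path)
    res
  }
  out <- function(...) file.path(out_dir, paste0(...))

  ## ---- stage 0: data -------------------------------------------------
  dat <- NULL
  stage("data", function() {
    if (!is.null(config$simulate)) {
      cfg <- do.call(scenario_config,
                     c(config$simulate, list(seed = substream_seed(seed, "data"))))
      dat <<- simulate_dataset(cfg)
      write_otu_table(dat$table, out("bacteria.tsv"))
      ape::write.tree(dat$tree, out("tree.nwk"))
      write_results(data.frame(sample = rownames(dat$metadata), dat$metadata),
                    out("metadata.tsv"))
      write_results(list(scenario = dat$truth$scenario,
                         important_taxa = dat$truth$important_taxa,
                         planted_pn = dat$coupling_truth$planted_pn),
                    out("truth.json"))
      for (dom in c("fungi", "protozoa", "algae"))
        write_otu_table(dat[[dom]], out(dom, ".tsv"))
      c(out("bacteria.tsv"), out("tree.nwk"), out("metadata.tsv"), out("truth.json"))
    } else {
      inp <- config$input
      meta <- read_metadata(inp$metadata)
      layer_map <- stats::setNames(meta$layer, rownames(meta))
      d <- list(table = read_otu_table(inp$table, "bacteria", layer_map),
                tree = read_tree(inp$tree), metadata = meta)
      for (dom in c("fungi", "protozoa", "algae"))
        if (!is.null(inp[[dom]]))
          d[[dom]] <- read_otu_table(inp[[dom]], dom, layer_map)
      dat <<- d
      character(0)
    }
  })

  ## ---- stage 1: diversity -------------------------------------------
  stage("diversity", function() {
    prof <- diversity_profile(dat$table, dat$tree)
    write_results(prof, out("diversity.tsv"))
    bc <- bray_curtis(dat$table)
    ord <- nmds_ordination(bc, k = 2, seed = substream_seed(seed, "diversity"))
    write_results(data.frame(sample = rownames(ord$points), ord$points,
                             stress = ord$stress), out("nmds.tsv"))
    an <- anosim_test(bc, dat$table$layer, seed = substream_seed(seed, "diversity"))
    write_results(list(anosim_R = an$value, p = an$p_value, stress = ord$stress),
                  out("ordination_tests.json"))
    c(out("diversity.tsv"), out("nmds.tsv"), out("ordination_tests.json"))
  })

  ## ---- stage 2: assembly null models --------------------------------
  ncfg <- do.call(null_config,
                  c(config$null, list(seed = substream_seed(seed, "assembly"))))
  fit <- NULL
  stage("assembly", function() {
    fit <<- fit_assembly(dat$table, dat$tree, ncfg)
    write_results(fit$bnti, out("bnti.tsv"))
    write_results(fit$rc, out("rcbray.tsv"))
    pv <- pair_values(fit$bnti, dat$table$layer)
    pv$process <- fit$process[upper.tri(fit$process)]
    write_results(pv, out("processes.tsv"))
    write_results(fit$fractions_by_group, out("fractions.tsv"))
    c(out("bnti.tsv"), out("rcbray.tsv"), out("processes.tsv"), out("fractions.tsv"))
  })

  ## ---- stage 3: interdomain networks --------------------------------
  nw <- config$network %||% list()
  r_min <- nw$r_min %||% 0.6
  p_max <- nw$p_max %||% 0.05
  prev <- nw$prevalence_min %||% (1/3)
  doms <- intersect(c("fungi", "protozoa", "algae"), names(dat))
  pn_layer <- NULL
  stage("networks", function() {
    outs <- character(0)
    summ <- list()
    for (dom in doms) {
      cand <- pairwise_spearman(dat$table, dat[[dom]], prevalence_min = prev)
      net <- suppressWarnings(build_network(cand, r_min, p_max))
      write_network(net, out("network_bacteria_", dom))
      rob <- if (nrow(net$nodes) >= 3)
        net_robustness(net, nw$robust_fraction %||% 0.5, nw$robust_reps %||% 100,
                       seed = substream_seed(seed, paste0("networks_", dom)))
        else NA_real_
      summ[[dom]] <- data.frame(domain = dom, n_nodes = nrow(net$nodes),
                                n_edges = nrow(net$edges),
                                pn = pn_ratio(net, .allow_empty = TRUE),
                                robustness = rob)
      outs <- c(outs, out("network_bacteria_", dom, "_edges.tsv"))
    }
    ## per-layer P/N (Haldane-corrected so a no-negative-edge layer stays finite)
    pn_l <- list()
    for (l in unique(dat$table$layer)) {
      keep <- dat$table$layer == l
      row <- list(layer = l)
      if (sum(keep) < 4) {
        for (dom in doms)
          row[[paste0("PN_", toupper(substr(dom, 1, 1)))]] <- NA_real_
        pn_l[[l]] <- as.data.frame(row)
        next
      }
      for (dom in doms) {
        a <- otu_table(dat$table$counts[keep, , drop = FALSE], "bacteria",
                       dat$table$layer[keep])
        b <- otu_table(dat[[dom]]$counts[keep, , drop = FALSE], dat[[dom]]$domain,
                       dat[[dom]]$layer[keep])
        cand <- pairwise_spearman(a, b, prevalence_min = prev)
        net <- suppressWarnings(build_network(cand, r_min, p_max))
        pos <- sum(net$edges$sign == "+"); neg <- sum(net$edges$sign == "-")
        row[[paste0("PN_", toupper(substr(dom, 1, 1)))]] <-
          (pos + 0.5) / (neg + 0.5)
      }
      pn_l[[l]] <- as.data.frame(row)
    }
    pn_layer <<- do.call(rbind, pn_l)
    rownames(pn_layer) <<- pn_layer$layer
    write_results(do.call(rbind, c(summ, list(make.row.names = FALSE))),
                  out("network_summary.tsv"))
    write_results(pn_layer, out("pn_by_layer.tsv"))
    c(outs, out("network_summary.tsv"), out("pn_by_layer.tsv"))
  })

  ## ---- stage 4: PLS path model --------------------------------------
  stage("plspm", function() {
    if (!length(doms) || is.null(pn_layer) || anyNA(pn_layer)) return(character(0))
    env_cols <- setdiff(colnames(dat$metadata), "layer")
    pn_cols <- setdiff(colnames(pn_layer), "layer")
    obs <- build_observation_table(dat$metadata[, env_cols, drop = FALSE],
                                   pn_layer[, pn_cols, drop = FALSE],
                                   fit$bnti, dat$table$layer)
    varying <- pn_cols[vapply(pn_cols, function(cn) stats::sd(obs[[cn]]) > 0,
                              logical(1))]
    if (!length(varying)) return(character(0))
    ## the P/N covariates take one value per layer; with fewer layers than
    ## P/N variables separate latents would be collinear, so they collapse
    ## into a single biotic-interaction block
    n_lay <- length(unique(obs$layer))
    if (n_lay > length(varying)) {
      blocks <- c(list(Env = "Env"),
                  stats::setNames(as.list(varying), varying),
                  list(bNTI = "bNTI"))
      inner <- list(bNTI = c("Env", varying))
    } else {
      blocks <- list(Env = "Env", PN = varying, bNTI = "bNTI")
      inner <- list(bNTI = c("Env", "PN"))
    }
    spec <- plspm_spec(blocks, inner = inner, scheme = "path")
    mod <- fit_plspm(obs, spec)
    mod <- prune_low_loadings(mod)
    mod <- bootstrap_paths(mod, B = config$plspm_boot %||% 500,
                           seed = substream_seed(seed, "plspm"))
    write_results(list(loadings = as.list(mod$loadings),
                       paths = mod$paths, boot = mod$boot,
                       r_squared = as.list(mod$r_squared), gof = mod$gof,
                       note = paste("observations are within-layer sample",
                                    "pairs and are not independent")),
                  out("plspm.json"))
    out("plspm.json")
  })

  ## ---- stage 5: important taxa + perturbation -----------------------
  stage("important_taxa", function() {
    rf_cfg <- config$rf %||% list()
    s <- substream_seed(seed, "important_taxa")
    imp <- rf_importance(dat$table, n_trees = rf_cfg$n_trees %||% 1000, seed = s)
    write_results(imp$ranking, out("ranking.tsv"))
    folds <- min(rf_cfg$folds %||% 10, nrow(dat$table$counts))
    cv <- rfcv_refine(dat$table, folds = folds, seed = s)
    write_results(cv$cv_curve, out("cv_curve.tsv"))
    top_n <- rf_cfg$top_n %||% cv$selected_n
    taxa <- utils::head(imp$ranking$otu, top_n)
    pert <- perturbation_experiment(dat$table, dat$tree, taxa, ncfg)
    write_results(pert$before$fractions_by_group, out("fractions_before.tsv"))
    write_results(pert$after$fractions_by_group, out("fractions_after.tsv"))
    write_results(pert$delta_bnti, out("delta_bnti.tsv"))
    write_results(list(n_removed = length(taxa),
                       mean_within_group_shift = pert$mean_shift),
                  out("perturbation.json"))
    c(out("ranking.tsv"), out("cv_curve.tsv"), out("fractions_before.tsv"),
      out("fractions_after.tsv"), out("delta_bnti.tsv"), out("perturbation.json"))
  })

  manifest$files <- as.list(tools::md5sum(files[file.exists(files)]))
  write_results(manifest, manifest_path)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
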