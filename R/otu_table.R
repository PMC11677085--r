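#' Construct an OTU abundance table
#'
#' The unit of analysis throughout the package: a samples x OTUs matrix of
#' non-negative abundances for one microbial domain, with a habitat-layer
#' label per sample. In-memory orientation is always samples in rows and
#' OTUs in columns; on disk the canonical orientation is the transpose
#' (OTU rows), matching common amplicon-pipeline outputs.
#'
#' @param counts numeric matrix, samples x OTUs, with unique row and column
#'   names. Values must be non-negative; they need not be integers (relative
#'   abundances are stored in the same container).
#' @param domain character scalar, one of `"bacteria"`, `"fungi"`,
#'   `"protozoa"`, `"algae"`.
#' @param layer character vector of per-sample habitat labels (e.g. `"W"`,
#'   `"S1"`, `"S2"`, `"S3"`), either named by sample id or in row order.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `domain` and `layer` (named by sample).
#' @export
otu_table <- function(counts, domain = c("bacteria", "fungi", "protozoa", "algae"),
                      layer = NULL) {
  domain <- match.arg(domain)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("'counts' must be non-negative and non-missing")
  if (is.null(layer)) stop("every sample needs a layer label")
  if (is.null(names(layer))) {
    if (length(layer) != nrow(counts))
      stop("'layer' must have one label per sample")
    names(layer) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(layer))
  if (length(missing))
    stop("samples without a layer label: ", paste(missing, collapse = ", "))
  layer <- as.character(layer[rownames(counts)])
  names(layer) <- rownames(counts)
  structure(list(counts = counts, domain = domain, layer = layer),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table (%s): %d samples x %d OTUs, total abundance %.6g\n",
              x$domain, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  tab <- table(x$layer)
  cat("layers:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Sample and OTU identifiers of a table
#'
#' @param t an [otu_table()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(t) rownames(t$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(t) colnames(t$counts)

#' Read an OTU table from a tab-separated file
#'
#' The on-disk convention is OTU ids in the first column and sample ids in
#' the header (OTUs x samples); set `otu_rows = FALSE` if the file stores
#' samples in rows instead. Ids are case-sensitive; only leading/trailing
#' whitespace is stripped by the reader.
#'
#' @param path file path to a TSV file.
#' @param domain domain label, see [otu_table()].
#' @param layer_map named character vector mapping sample id to habitat
#'   layer. Entries for unknown samples are ignored; samples present in the
#'   file but absent from `layer_map` are an error.
#' @param otu_rows logical; `TRUE` (default) when rows are OTUs.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, domain, layer_map, otu_rows = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("malformed TSV: non-numeric abundance values in ", path)
  if (otu_rows) m <- t(m)
  otu_table(m, domain = domain, layer = layer_map[rownames(m)])
}

#' Write an OTU table as TSV (OTU rows x sample columns)
#'
#' @param t an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path) {
  m <- t(t$counts)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's abundances by its total so that rows sum to one.
#' Idempotent; errors on samples with zero total rather than producing NaN.
#'
#' @param t an [otu_table()].
#' @return An [otu_table()] whose rows sum to 1.
#' @export
relative_abundance <- function(t) {
  tot <- rowSums(t$counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(sample_ids(t)[tot <= 0], collapse = ", "))
  t$counts <- t$counts / tot
  t
}

#' Remove a set of OTUs from a table
#'
#' Drops the named columns. Samples whose total abundance becomes zero are
#' dropped with a warning naming them; sample order is otherwise preserved.
#'
#' @param t an [otu_table()].
#' @param taxa character vector of OTU ids to remove (must all exist).
#' @return An [otu_table()] without the given OTUs.
#' @export
remove_taxa <- function(t, taxa) {
  taxa <- as.character(taxa)
  unknown <- setdiff(taxa, otu_ids(t))
  if (length(unknown))
    stop("unknown OTU id(s): ", paste(unknown, collapse = ", "))
  if (!length(taxa)) return(t)
  keep <- setdiff(otu_ids(t), taxa)
  m <- t$counts[, keep, drop = FALSE]
  empty <- rowSums(m) <= 0
  if (any(empty)) {
    warning("dropping sample(s) emptied by taxa removal: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  otu_table(m, domain = t$domain, layer = t$layer[rownames(m)])
}

#' Read and validate a rooted Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validity checks the null models rely
#' on: unique tip labels and non-negative branch lengths.
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unreadable Newick file: ", conditionMessage(e)))
  if (is.null(tr)) stop("unreadable Newick file: ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylogenetic tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length(s) in tree")
  tr
}

#' Construct a symmetric pairwise statistic matrix
#'
#' Container for signed pairwise statistics such as betaNTI and RC-bray,
#' where the diagonal is undefined and masked as `NA`.
#'
#' @param values square numeric matrix with matching dimnames; must be
#'   symmetric up to `NA` masking.
#' @param statistic name of the statistic.
#' @return An object of class `pairwise_statistic`.
#' @export
pairwise_statistic <- function(values, statistic) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("'values' must be a square matrix")
  if (is.null(rownames(values))) stop("'values' must have ids as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids must match")
  v <- values
  diag(v) <- NA_real_
  if (!isTRUE(all.equal(v, t(v))) && !all(is.na(v) == is.na(t(v)) & (is.na(v) | abs(v - t(v)) < 1e-8)))
    stop("'values' must be symmetric")
  structure(list(ids = rownames(values), values = v, statistic = statistic),
            class = "pairwise_statistic")
}

#' @export
print.pairwise_statistic <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("pairwise statistic '%s' over %d ids (%d pairs, %d masked)\n",
              x$statistic, length(x$ids), length(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Write analysis results to disk
#'
#' TSV for matrix-like objects (round-trips at 15 significant digits), JSON
#' for list-like results.
#'
#' @param obj a `pairwise_statistic`, `otu_table`, data frame or list.
#' @param path output path; extension does not alter the format chosen by
#'   the object's class.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) UseMethod("write_results")

#' @export
write_results.pairwise_statistic <- function(obj, path) {
  m <- format(obj$values, digits = 15, trim = TRUE, scientific = NA)
  df <- data.frame(id = obj$ids, m, check.names = FALSE)
  colnames(df) <- c("id", obj$ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.otu_table <- function(obj, path) write_otu_table(obj, path)

#' @export
write_results.data.frame <- function(obj, path) {
  utils::write.table(format(obj, digits = 15, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.list <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a pairwise statistic written by [write_results()]
#'
#' @param path TSV path produced by `write_results()` on a
#'   `pairwise_statistic`.
#' @param statistic statistic name to attach.
#' @return A [pairwise_statistic()].
#' @export
read_pairwise_statistic <- function(path, statistic) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  pairwise_statistic(m, statistic)
}

#' Read a sample metadata table
#'
#' One row per sample (first column sample id), a `layer` column, and
#' numeric physicochemical columns (e.g. pH, NH4, NO3, TC, TOC, IC). Empty
#' cells become `NA` and are propagated as missing, never as zero.
#'
#' @param path TSV path.
#' @return A data frame with sample ids as row names.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (anyDuplicated(rownames(df))) stop("duplicate sample ids in metadata")
  df
}
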