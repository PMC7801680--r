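# Probe collapse and gene filtering so that all cohorts share one gene
# universe before network mining.

#' Collapse probe-level rows to one row per gene
#'
#' Probes without a gene annotation are dropped. When several probes map to
#' one gene, the probe with the highest mean expression across samples is
#' retained and the others are discarded.
#'
#' @param values probe x sample numeric matrix (rownames = probe ids)
#' @param probe_to_gene named character vector mapping probe id -> gene id;
#'   may cover only a subset of probes.
#' @return gene x sample matrix
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (!length(probe_to_gene)) stop("probe_to_gene mapping is empty")
  probes <- intersect(rownames(values), names(probe_to_gene))
  if (!length(probes)) stop("no probes overlap the mapping")
  v <- values[probes, , drop = FALSE]
  genes <- probe_to_gene[probes]
  means <- rowMeans(v)
  # stable within-gene selection: highest mean wins, first probe on ties
  ord <- order(genes, -means)
  keep <- ord[!duplicated(genes[ord])]
  out <- v[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter low-information genes
#'
#' Rules applied in order, each gene removed by the first rule that fires:
#' \enumerate{
#'   \item counts platform only: remove genes with more than
#'     \code{zero_frac} zeros within either condition group;
#'   \item remove genes with variance in the bottom \code{var_pct}
#'     percentile across all samples (bottom-inclusive);
#'   \item remove genes with mean expression in the bottom \code{mean_pct}
#'     percentile.
#' }
#' Percentiles use the inclusive linear-interpolation definition
#' (\code{quantile} type 7), so with distinct values the variance rule
#' removes exactly \code{ceiling(var_pct/100 * G)} genes.
#'
#' @param dataset an \code{ExpressionDataset}
#' @param zero_frac zero-fraction threshold (default 0.5)
#' @param var_pct variance percentile (default 20)
#' @param mean_pct mean percentile (default 10)
#' @return list with elements \code{dataset} (filtered) and \code{report}
#'   (a \code{FilterReport}: per-rule removal counts and survivors)
#' @export
filter_genes <- function(dataset, zero_frac = 0.5, var_pct = 20, mean_pct = 10) {
  v <- dataset$values
  G <- nrow(v)
  removed_zero <- character(0)

  if (dataset$platform == "counts" && !isTRUE(attr(dataset, "transformed"))) {
    cond <- dataset$condition
    frac_d <- rowMeans(v[, cond == "disease", drop = FALSE] == 0)
    frac_c <- rowMeans(v[, cond == "control", drop = FALSE] == 0)
    removed_zero <- rownames(v)[frac_d > zero_frac | frac_c > zero_frac]
    v <- v[setdiff(rownames(v), removed_zero), , drop = FALSE]
  }
  if (!nrow(v)) stop("zero-fraction filter removed all genes")

  removed_var <- character(0)
  if (var_pct > 0) {
    vars <- apply(v, 1L, stats::var)
    var_cut <- stats::quantile(vars, var_pct / 100, names = FALSE)
    removed_var <- rownames(v)[vars <= var_cut]
    v <- v[setdiff(rownames(v), removed_var), , drop = FALSE]
    if (!nrow(v)) stop("variance filter removed all genes")
  }

  removed_mean <- character(0)
  if (mean_pct > 0) {
    means <- rowMeans(v)
    mean_cut <- stats::quantile(means, mean_pct / 100, names = FALSE)
    removed_mean <- rownames(v)[means <= mean_cut]
    v <- v[setdiff(rownames(v), removed_mean), , drop = FALSE]
    if (!nrow(v)) stop("mean filter removed all genes")
  }

  out <- dataset
  out$values <- v
  report <- structure(list(
    dataset = dataset$name,
    input_genes = G,
    removed_zero_fraction = length(removed_zero),
    removed_variance = length(removed_var),
    removed_mean = length(removed_mean),
    survived = nrow(v)
  ), class = "FilterReport")
  stopifnot(report$survived + length(removed_zero) + length(removed_var) +
              length(removed_mean) == G)
  list(dataset = out, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport '%s': %d genes -> %d (zero %d, variance %d, mean %d)\n",
              x$dataset, x$input_genes, x$survived, x$removed_zero_fraction,
              x$removed_variance, x$removed_mean))
  invisible(x)
}

#' Serialize a filter report (or list of reports) to JSON
#' @param reports a \code{FilterReport} or list of them
#' @param path output path
#' @export
write_filter_report <- function(reports, path) {
  if (inherits(reports, "FilterReport")) reports <- list(reports)
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE)
  invisible(reports)
}

#' Transform raw counts to log2(CPM + 1)
#'
#' Applied after filtering; all downstream continuous math (correlations,
#' t scores, eigengenes) operates on the transformed values. The platform
#' label stays \code{"counts"} so that Spearman correlation is still used.
#'
#' @param dataset a counts-platform \code{ExpressionDataset}
#' @return the dataset with transformed values (attribute
#'   \code{transformed = TRUE}); continuous datasets pass through unchanged.
#' @export
normalize_counts <- function(dataset) {
  if (dataset$platform != "counts" || isTRUE(attr(dataset, "transformed")))
    return(dataset)
  lib <- colSums(dataset$values)
  if (any(lib == 0)) stop("sample(s) with zero library size")
  dataset$values <- log2(sweep(dataset$values, 2L, lib / 1e6, "/") + 1)
  attr(dataset, "transformed") <- TRUE
  dataset
}

#' Restrict datasets to their common gene universe
#'
#' @param datasets list of \code{ExpressionDataset} (>= 2)
#' @return list of datasets restricted to the sorted gene intersection, in
#'   identical gene order.
#' @export
intersect_genes <- function(datasets) {
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  common <- Reduce(intersect, lapply(datasets, gene_ids))
  if (!length(common)) stop("gene universes have an empty intersection")
  common <- sort(common)
  lapply(datasets, function(d) {
    d$values <- d$values[common, , drop = FALSE]
    d
  })
}

#' Run the full preprocessing stage on a list of datasets
#'
#' Filters each dataset, transforms counts to log2(CPM + 1), and intersects
#' the surviving gene universes.
#'
#' @param datasets list of \code{ExpressionDataset}
#' @inheritParams filter_genes
#' @return list with \code{datasets} and \code{reports}
#' @export
preprocess_datasets <- function(datasets, zero_frac = 0.5, var_pct = 20,
                                mean_pct = 10) {
  filtered <- lapply(datasets, filter_genes, zero_frac = zero_frac,
                     var_pct = var_pct, mean_pct = mean_pct)
  dss <- lapply(filtered, function(f) normalize_counts(f$dataset))
  reports <- lapply(filtered, `[[`, "report")
  list(datasets = intersect_genes(dss), reports = reports)
}
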