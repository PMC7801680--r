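# Marker-based estimation of relative cell-type abundances (surrogate
# proportion variables) and condition tests on them.

CELL_TYPES <- c("neu", "mic", "ast", "oli", "end")

#' Construct a cell-type marker set
#'
#' @param collection a \code{GeneSetCollection} whose set names are the five
#'   brain cell types \code{neu}, \code{mic}, \code{ast}, \code{oli},
#'   \code{end} (neurons, microglia, astrocytes, oligodendrocytes,
#'   endothelia); member order is the marker ranking.
#' @return object of class \code{CellTypeMarkers} (named list of ranked
#'   marker id vectors)
#' @export
cell_type_markers <- function(collection) {
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets
          else collection
  missing <- setdiff(CELL_TYPES, names(sets))
  if (length(missing))
    stop("marker sets missing for cell type(s): ",
         paste(missing, collapse = ", "))
  sets <- sets[CELL_TYPES]
  all_members <- unlist(sets, use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup))
    stop("gene(s) marking more than one cell type: ",
         paste(utils::head(dup, 5), collapse = ", "))
  structure(sets, class = "CellTypeMarkers")
}

#' Surrogate cell-type proportions from marker genes
#'
#' For each cell type, the top \code{n_markers} markers present in the
#' dataset are z-scored per gene and summarized by the first principal
#' component of the marker x sample submatrix; the PC sign is oriented so
#' that it correlates positively with the majority of member markers, and
#' the column is z-scaled. Surrogates are relative indices, not
#' compositional: columns have mean 0 and SD 1 and need not sum to 1.
#'
#' @param dataset an \code{ExpressionDataset} (continuous values; counts
#'   should be log-CPM transformed first)
#' @param markers a \code{CellTypeMarkers}
#' @param n_markers markers used per type (default 50)
#' @return \code{ProportionMatrix}: samples x 5 numeric matrix
#' @export
surrogate_proportions <- function(dataset, markers, n_markers = 50L) {
  stopifnot(inherits(markers, "CellTypeMarkers"))
  out <- sapply(CELL_TYPES, function(ct) {
    present <- intersect(markers[[ct]], gene_ids(dataset))
    if (length(present) < 3L)
      stop("fewer than 3 usable markers for cell type ", ct)
    present <- utils::head(present, n_markers)
    x <- dataset$values[present, , drop = FALSE]
    xz <- t(scale(t(x)))
    keep <- stats::complete.cases(xz)
    if (sum(keep) < 3L)
      stop("fewer than 3 usable markers for cell type ", ct)
    xz <- xz[keep, , drop = FALSE]
    sv <- svd(xz, nu = 0, nv = 1)
    score <- sv$v[, 1L]
    # orient toward the majority of markers
    cors <- as.numeric(stats::cor(score, t(xz)))
    s <- sum(sign(cors))
    if (s < 0 || (s == 0 && cors[1L] < 0)) score <- -score
    as.numeric(scale(score))
  })
  rownames(out) <- sample_ids(dataset)
  class(out) <- c("ProportionMatrix", class(out))
  out
}

#' Test per-type proportion differences between conditions
#'
#' Two-sided Wilcoxon rank-sum test per cell type with Benjamini-Hochberg
#' adjustment across the five types; direction is the sign of the median
#' shift (disease - control); stars: * adjusted p < 0.05, ** < 0.01.
#'
#' @param props a \code{ProportionMatrix} (samples x types)
#' @param condition per-sample labels (normalized as in
#'   \code{\link{expression_dataset}})
#' @return data.frame: cell_type, statistic, p, adj_p, direction, stars,
#'   low_power flag
#' @export
compare_proportions <- function(props, condition) {
  condition <- normalize_condition(condition)
  stopifnot(nrow(props) == length(condition))
  rows <- lapply(colnames(props), function(ct) {
    x <- props[condition == "disease", ct]
    y <- props[condition == "control", ct]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(cell_type = ct,
               statistic = unname(wt$statistic),
               p = wt$p.value,
               direction = ifelse(stats::median(x) >= stats::median(y),
                                  "up", "down"),
               low_power = min(length(x), length(y)) < 4L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$stars <- ifelse(out$adj_p < 0.01, "**",
               ifelse(out$adj_p < 0.05, "*", ""))
  out[, c("cell_type", "statistic", "p", "adj_p", "direction", "stars",
          "low_power")]
}
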