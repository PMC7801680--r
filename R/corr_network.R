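# Per-dataset top-correlation edge lists and their aggregation into the
# frequency-weighted network mined by lmQCM.

# Linear index helpers for the upper triangle (column-major, i < j) of a
# G x G matrix, avoiding materializing 2 * choose(G, 2) index vectors until
# a subset has been selected.
ut_index_to_pair <- function(idx, G) {
  j <- ((idx - 1) %/% G) + 1L
  i <- ((idx - 1) %% G) + 1L
  cbind(i = i, j = j)
}

#' All-pairs correlation within one condition group
#'
#' Pearson for continuous-platform datasets, Spearman for counts. Two-sided
#' p values use the t approximation with n - 2 degrees of freedom. Pairs
#' involving a zero-variance gene get an undefined (NA) coefficient and are
#' excluded from downstream edge selection.
#'
#' @param dataset an \code{ExpressionDataset}
#' @param group \code{"disease"} or \code{"control"}
#' @return object of class \code{corr_table}: genes, group size \code{n},
#'   method, and upper-triangular vectors \code{r}, \code{p} in column-major
#'   pair order.
#' @export
pairwise_correlation <- function(dataset, group = c("disease", "control")) {
  group <- match.arg(group)
  x <- dataset$values[, dataset$condition == group, drop = FALSE]
  n <- ncol(x)
  if (n < 4L) stop("condition group must have at least 4 samples")
  method <- if (dataset$platform == "counts") "spearman" else "pearson"
  if (method == "spearman")
    x <- t(apply(x, 1L, rank))
  sds <- apply(x, 1L, stats::sd)
  C <- suppressWarnings(stats::cor(t(x)))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  G <- nrow(x)
  r <- C[upper.tri(C)]
  # t approximation; clamp so that |r| = 1 maps to p = 0
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  structure(list(genes = rownames(x), n = n, method = method,
                 group = group, r = r, p = p),
            class = "corr_table")
}

#' @export
print.corr_table <- function(x, ...) {
  cat(sprintf("corr_table: %d genes, %d samples (%s, %s group), %d pairs (%d undefined)\n",
              length(x$genes), x$n, x$method, x$group, length(x$r),
              sum(is.na(x$r))))
  invisible(x)
}

#' Select the top-percentile correlated gene pairs
#'
#' Keeps pairs whose |coefficient| lies in the top \code{top_pct} percentile
#' of all defined pairs AND whose p value is below \code{p_max}. Pairs tied
#' at the percentile threshold are all included.
#'
#' @param table a \code{corr_table}
#' @param top_pct upper percentile of |r| retained (default 5)
#' @param p_max p-value cutoff (default 0.05)
#' @return an \code{EdgeList}: data.frame(gene_a, gene_b, r, p) with
#'   gene_a < gene_b lexicographically; attribute \code{dataset} if known.
#' @export
select_top_edges <- function(table, top_pct = 5, p_max = 0.05) {
  ok <- !is.na(table$r)
  if (!any(ok)) {
    log_msg("select_top_edges: no defined pairs")
    return(empty_edge_list())
  }
  absr <- abs(table$r[ok])
  thr <- stats::quantile(absr, 1 - top_pct / 100, names = FALSE)
  pass <- ok
  pass[ok] <- absr >= thr & table$p[ok] < p_max
  if (!any(pass)) {
    log_msg("select_top_edges: no pair passes (threshold %.3f)", thr)
    return(empty_edge_list())
  }
  G <- length(table$genes)
  sel <- which(pass)
  pairs <- ut_pos_to_ij(sel, G)
  a <- table$genes[pairs[, 1L]]
  b <- table$genes[pairs[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b,
                    r = table$r[sel], p = table$p[sel],
                    stringsAsFactors = FALSE)
  class(out) <- c("EdgeList", "data.frame")
  out
}

empty_edge_list <- function() {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    r = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("EdgeList", "data.frame")
  out
}

# Map positions within the packed upper-tri vector (column-major, as
# produced by M[upper.tri(M)]) back to (row, col) indices.
ut_pos_to_ij <- function(pos, G) {
  # column j holds pairs with cumulative count choose(j, 2)
  cum <- cumsum(seq_len(G) - 1L)          # pairs up to and including column j
  j <- findInterval(pos - 1L, cum) + 1L   # first j with cum[j] >= pos
  i <- pos - c(0L, cum)[j]
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Aggregate per-dataset edge lists into a frequency network
#'
#' Every pair occurring in at least one list becomes an edge whose weight is
#' its occurrence count divided by \code{K}, the number of lists.
#'
#' @param edge_lists list of \code{EdgeList} (one per dataset)
#' @param K number of lists (defaults to \code{length(edge_lists)}; must be
#'   >= 2)
#' @return object of class \code{FrequencyNetwork}: data.frame
#'   \code{edges(gene_a, gene_b, weight)}, node vector, and \code{K}.
#' @export
frequency_network <- function(edge_lists, K = length(edge_lists)) {
  if (K < 2L) stop("frequency network requires K >= 2 edge lists")
  gene_a <- unlist(lapply(edge_lists, `[[`, "gene_a"), use.names = FALSE)
  gene_b <- unlist(lapply(edge_lists, `[[`, "gene_b"), use.names = FALSE)
  if (!length(gene_a)) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(edges = edges, nodes = character(0), K = K),
                     class = "FrequencyNetwork"))
  }
  dt <- data.table::data.table(gene_a = gene_a, gene_b = gene_b)
  agg <- dt[, list(count = .N), by = c("gene_a", "gene_b")]
  data.table::setorder(agg, gene_a, gene_b)
  edges <- data.frame(gene_a = agg$gene_a, gene_b = agg$gene_b,
                      weight = agg$count / K, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes, K = K),
            class = "FrequencyNetwork")
}

#' @export
print.FrequencyNetwork <- function(x, ...) {
  cat(sprintf("FrequencyNetwork: %d nodes, %d edges, K = %d\n",
              length(x$nodes), nrow(x$edges), x$K))
  invisible(x)
}

#' Build a frequency network directly from a small weighted edge table
#'
#' Convenience constructor for tests and examples: takes a ready-made
#' weighted edge data.frame rather than per-dataset lists.
#'
#' @param edges data.frame(gene_a, gene_b, weight)
#' @param K nominal number of source lists
#' @return a \code{FrequencyNetwork}
#' @export
as_frequency_network <- function(edges, K) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  if (any(a == b)) stop("self-loops are not allowed")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ed <- data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(ed$gene_a, ed$gene_b, sep = "\r")))
    stop("duplicate edges")
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = ed, nodes = sort(unique(c(a, b))), K = K),
            class = "FrequencyNetwork")
}

#' Weighted degree (node strength) of every node in a network
#' @param net a \code{FrequencyNetwork}
#' @param nodes optional node universe (nodes absent from the network get 0)
#' @return named numeric vector
#' @export
weighted_degree <- function(net, nodes = net$nodes) {
  deg <- stats::setNames(numeric(length(nodes)), nodes)
  a <- net$edges$gene_a; b <- net$edges$gene_b; w <- net$edges$weight
  keep <- a %in% nodes & b %in% nodes
  da <- tapply(w[keep], a[keep], sum)
  db <- tapply(w[keep], b[keep], sum)
  deg[names(da)] <- deg[names(da)] + da
  deg[names(db)] <- deg[names(db)] + db
  deg
}
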