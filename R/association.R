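# Attribution of module expression changes to composition vs. regulation:
# eigengenes, covariate associations, marker/DE enrichment, module overlap,
# hub turnover, connectivity splits, and cross-region concordance.

#' Module eigengene
#'
#' First principal component of the gene-standardized member submatrix
#' (samples pooled across conditions). The score is oriented so that it
#' correlates positively with the module's mean standardized expression
#' profile; on an exact tie the lexicographically first member gene is made
#' positive.
#'
#' @param module a \code{GeneModule} or character vector (>= 2 genes present)
#' @param dataset an \code{ExpressionDataset} with >= 3 samples
#' @return object of class \code{Eigengene}: per-sample \code{score},
#'   \code{explained} variance fraction, unit-norm \code{loadings}
#' @export
module_eigengene <- function(module, dataset) {
  genes <- intersect(module_members(module), gene_ids(dataset))
  if (length(genes) < 2L) stop("need at least 2 member genes in the dataset")
  if (ncol(dataset$values) < 3L) stop("need at least 3 samples")
  x <- dataset$values[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s): ", paste(genes[sds == 0], collapse = ", "))
  xz <- t(scale(t(x)))
  sv <- svd(xz, nu = 1, nv = 1)
  score <- sv$v[, 1L] * sv$d[1L]
  mean_profile <- colMeans(xz)
  orient <- stats::cor(score, mean_profile)
  if (is.na(orient) || abs(orient) < 1e-12) {
    first <- sort(genes)[1L]
    orient <- stats::cor(score, xz[first, ])
  }
  if (orient < 0) {
    score <- -score
    sv$u <- -sv$u
  }
  structure(list(module_id = if (inherits(module, "GeneModule")) module$id
                             else NA_character_,
                 score = stats::setNames(score, sample_ids(dataset)),
                 explained = sv$d[1L]^2 / sum(sv$d^2),
                 loadings = stats::setNames(sv$u[, 1L], genes)),
            class = "Eigengene")
}

#' Associate eigengenes (or surrogate proportions) with covariates
#'
#' Coefficient and p value per (row, covariate) pair; the Bonferroni cutoff
#' is 0.05 / (rows x covariates); rows are ranked by mean |coefficient|.
#'
#' @param scores samples x rows numeric matrix (eigengene scores or
#'   proportion surrogates); column names label the rows of the result.
#' @param covariates samples x covariates numeric data.frame/matrix with
#'   matching row order (>= 3 shared samples).
#' @param method \code{"pearson"} (proportions) or \code{"spearman"} (traits)
#' @return \code{AssociationTable} data.frame: row, covariate, coef, p,
#'   bonferroni_significant, rank; attribute \code{bonferroni_cutoff}
#' @export
covariate_association <- function(scores, covariates,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  covariates <- as.matrix(covariates)
  if (nrow(scores) != nrow(covariates))
    stop("scores and covariates must cover the same samples")
  if (nrow(scores) < 3L) stop("need at least 3 shared samples")
  rows <- colnames(scores); covs <- colnames(covariates)
  cutoff <- 0.05 / (length(rows) * length(covs))
  out <- do.call(rbind, lapply(rows, function(rw) {
    do.call(rbind, lapply(covs, function(cv) {
      ct <- suppressWarnings(
        stats::cor.test(scores[, rw], covariates[, cv], method = method,
                        exact = FALSE))
      data.frame(row = rw, covariate = cv, coef = unname(ct$estimate),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }))
  }))
  out$bonferroni_significant <- out$p < cutoff
  mean_abs <- tapply(abs(out$coef), out$row, mean)
  rk <- rank(-mean_abs, ties.method = "first")
  out$rank <- rk[out$row]
  attr(out, "bonferroni_cutoff") <- cutoff
  class(out) <- c("AssociationTable", "data.frame")
  out
}

#' Marker enrichment of a module (hypergeometric upper tail)
#'
#' One-sided Fisher's exact / hypergeometric test per cell type: with
#' overlap k, module size m, K markers present in the background and
#' universe size G, p = P(X >= k). BH adjustment across the five types; the
#' module's assigned cell type is the most significant type passing
#' adjusted p < 0.05.
#'
#' @param module a \code{GeneModule} or character vector (subset of
#'   \code{background})
#' @param markers a \code{CellTypeMarkers}
#' @param background character vector, the gene universe
#' @return data.frame: cell_type, overlap, markers_in_background, p, adj_p;
#'   attribute \code{assigned_type} (NA if none passes)
#' @export
marker_enrichment <- function(module, markers, background) {
  genes <- module_members(module)
  if (!all(genes %in% background))
    stop("module must be a subset of the background universe")
  G <- length(background)
  m <- length(genes)
  rows <- lapply(names(markers), function(ct) {
    K <- length(intersect(markers[[ct]], background))
    k <- length(intersect(markers[[ct]], genes))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, G - K, m, lower.tail = FALSE)
    data.frame(cell_type = ct, overlap = k, markers_in_background = K,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  pass <- which(out$adj_p < 0.05)
  attr(out, "assigned_type") <-
    if (length(pass)) out$cell_type[pass[which.min(out$p[pass])]] else NA_character_
  out
}

#' Jaccard overlap between two module collections
#'
#' @param collection_A,collection_B \code{GeneModuleCollection}s (or lists
#'   of gene vectors)
#' @param flag_threshold pairs with J above this are flagged as shared
#'   (default 0.3)
#' @return matrix of Jaccard indices (rows = A, cols = B); attribute
#'   \code{shared}: data.frame of flagged pairs
#' @export
module_overlap <- function(collection_A, collection_B, flag_threshold = 0.3) {
  get_sets <- function(x) {
    if (inherits(x, "GeneModuleCollection")) {
      sets <- lapply(x$modules, `[[`, "members")
      names(sets) <- vapply(x$modules, `[[`, "", "id")
      sets
    } else x
  }
  A <- get_sets(collection_A); B <- get_sets(collection_B)
  J <- matrix(0, length(A), length(B), dimnames = list(names(A), names(B)))
  for (i in seq_along(A)) for (j in seq_along(B)) {
    J[i, j] <- length(intersect(A[[i]], B[[j]])) /
      length(union(A[[i]], B[[j]]))
  }
  idx <- which(J > flag_threshold, arr.ind = TRUE)
  attr(J, "shared") <- data.frame(
    module_a = rownames(J)[idx[, 1L]],
    module_b = colnames(J)[idx[, 2L]],
    jaccard = J[idx], stringsAsFactors = FALSE)
  J
}

#' Hub-gene gain and loss between condition networks
#'
#' Hubs are nodes whose weighted degree is at or above the
#' \code{100 - pct} percentile within a network (ties included), computed on
#' the shared node universe (missing nodes have degree 0). Gained hubs are
#' present only in the disease network's hub set; lost hubs only in the
#' control network's.
#'
#' @param net_disease,net_control \code{FrequencyNetwork}s
#' @param pct top percentile defining hubs (default 5)
#' @return \code{HubReport}: hub sets per condition, \code{gained},
#'   \code{lost}, and the degree tables
#' @export
hub_turnover <- function(net_disease, net_control, pct = 5) {
  universe <- sort(union(net_disease$nodes, net_control$nodes))
  deg_d <- weighted_degree(net_disease, universe)
  deg_c <- weighted_degree(net_control, universe)
  hubs <- function(deg) {
    thr <- stats::quantile(deg, 1 - pct / 100, names = FALSE)
    sort(names(deg)[deg >= thr])
  }
  h_d <- hubs(deg_d); h_c <- hubs(deg_c)
  structure(list(hubs_disease = h_d, hubs_control = h_c,
                 gained = setdiff(h_d, h_c), lost = setdiff(h_c, h_d),
                 degree_disease = deg_d, degree_control = deg_c),
            class = "HubReport")
}

#' @export
print.HubReport <- function(x, ...) {
  cat(sprintf("HubReport: %d disease hubs, %d control hubs, %d gained, %d lost\n",
              length(x$hubs_disease), length(x$hubs_control),
              length(x$gained), length(x$lost)))
  invisible(x)
}

#' Hub connectivity vs. cell-type proportion split
#'
#' Samples are split at the median surrogate proportion for
#' \code{cell_type}; within each half, each hub gene's connectivity is its
#' sum of |correlation| to the other hub genes; the per-gene signs of
#' (connectivity_high - connectivity_low) feed a two-sided exact sign test.
#'
#' @param dataset an \code{ExpressionDataset}
#' @param hub_genes character vector of hub gene ids present in the dataset
#' @param proportions \code{ProportionMatrix} for the dataset's samples
#' @param cell_type one of the proportion columns (e.g. \code{"neu"})
#' @return list: per-gene connectivity table, \code{n_higher} /
#'   \code{n_lower}, sign-test \code{p}
#' @export
connectivity_vs_proportion <- function(dataset, hub_genes, proportions,
                                       cell_type) {
  stopifnot(cell_type %in% colnames(proportions))
  miss <- setdiff(hub_genes, gene_ids(dataset))
  if (length(miss)) stop("hub gene(s) absent: ", paste(miss, collapse = ", "))
  p <- proportions[sample_ids(dataset), cell_type]
  high <- p > stats::median(p)
  if (sum(high) < 4L || sum(!high) < 4L)
    stop("need at least 4 samples in each half")
  conn <- function(cols) {
    x <- dataset$values[hub_genes, cols, drop = FALSE]
    if (dataset$platform == "counts") x <- t(apply(x, 1L, rank))
    C <- abs(suppressWarnings(stats::cor(t(x))))
    diag(C) <- 0
    rowSums(C, na.rm = TRUE)
  }
  c_high <- conn(high)
  c_low <- conn(!high)
  diff <- c_high - c_low
  nz <- diff[diff != 0]
  n_higher <- sum(nz > 0); n <- length(nz)
  p_val <- if (n == 0) 1 else
    stats::binom.test(n_higher, n, 0.5)$p.value
  list(connectivity = data.frame(gene = hub_genes, high = c_high,
                                 low = c_low, diff = diff,
                                 stringsAsFactors = FALSE, row.names = NULL),
       n_higher = n_higher, n_lower = n - n_higher, p = p_val)
}

#' Cross-region concordance of cell-type proportions
#'
#' The CCI (leading-eigenvalue statistic of \code{\link{module_cci}}) of the
#' region x subject matrix of one cell type's proportions: 1 when the
#' regional proportion profiles move together across subjects, ~0 when they
#' are independent.
#'
#' @param proportions_by_region named list (one element per region) of
#'   subject-named numeric vectors, or a region x subject matrix
#' @param cell_type informational label
#' @return scalar CCI in [0, 1]
#' @export
cross_region_concordance <- function(proportions_by_region,
                                     cell_type = NULL) {
  if (is.list(proportions_by_region)) {
    subj <- lapply(proportions_by_region, names)
    common <- Reduce(intersect, subj)
    unmatched <- setdiff(unique(unlist(subj)), common)
    if (length(unmatched))
      stop("subject(s) not matched across all regions: ",
           paste(utils::head(unmatched, 10), collapse = ", "))
    m <- do.call(rbind, lapply(proportions_by_region, `[`, common))
  } else {
    m <- as.matrix(proportions_by_region)
  }
  if (nrow(m) < 2L) stop("need at least 2 regions")
  module_cci(m)
}
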