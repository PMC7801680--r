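# Module-level differential expression (DE), differential co-expression (DC)
# and concordance (CCI) scores; median aggregation and quadrant
# classification; cross-dataset per-gene DE calls.

#' Welch t score for one gene
#'
#' \eqn{t = |\bar x_D - \bar x_N| / \sqrt{s_D^2/n_D + s_N^2/n_N}} with sample
#' (n - 1) standard deviations. Both groups constant with equal means gives
#' t = 0; a zero denominator with unequal means is undefined and flagged.
#'
#' @param expr_D,expr_N numeric vectors of log2 expression in the disease and
#'   control groups (each of length >= 2)
#' @return list of class \code{GeneTScore}: group means, SDs, sizes, \code{t}
#'   and a \code{defined} flag
#' @export
gene_t_score <- function(expr_D, expr_N) {
  if (length(expr_D) < 2L || length(expr_N) < 2L)
    stop("each group needs at least 2 samples")
  m_D <- mean(expr_D); m_N <- mean(expr_N)
  s_D <- stats::sd(expr_D); s_N <- stats::sd(expr_N)
  den <- sqrt(s_D^2 / length(expr_D) + s_N^2 / length(expr_N))
  if (den == 0) {
    t <- if (m_D == m_N) 0 else NA_real_
  } else {
    t <- abs(m_D - m_N) / den
  }
  structure(list(mean_D = m_D, mean_N = m_N, sd_D = s_D, sd_N = s_N,
                 n_D = length(expr_D), n_N = length(expr_N),
                 t = t, defined = !is.na(t)),
            class = "GeneTScore")
}

# Vectorized per-gene Welch statistics for a gene x sample matrix.
# Returns list(t = abs t, diff = mean_D - mean_N, p = two-sided Welch p).
welch_stats <- function(values, condition) {
  d <- values[, condition == "disease", drop = FALSE]
  n <- values[, condition == "control", drop = FALSE]
  nd <- ncol(d); nn <- ncol(n)
  md <- rowMeans(d); mn <- rowMeans(n)
  vd <- rowSums((d - md)^2) / (nd - 1)
  vn <- rowSums((n - mn)^2) / (nn - 1)
  se2 <- vd / nd + vn / nn
  tt <- abs(md - mn) / sqrt(se2)
  tt[se2 == 0 & md == mn] <- 0
  tt[se2 == 0 & md != mn] <- NA_real_
  df <- se2^2 / ((vd / nd)^2 / (nd - 1) + (vn / nn)^2 / (nn - 1))
  p <- 2 * stats::pt(tt, df = df, lower.tail = FALSE)
  list(t = tt, diff = md - mn, p = p, var_D = vd, var_N = vn,
       n_D = nd, n_N = nn)
}

#' Module DE score
#'
#' Mean absolute Welch t over the module's member genes (sum of t values
#' divided by the module size); genes with an undefined t are excluded from
#' both the sum and the denominator.
#'
#' @param module a \code{GeneModule} or character vector of gene ids
#' @param dataset an \code{ExpressionDataset} containing those genes
#' @return non-negative scalar
#' @export
module_de_score <- function(module, dataset) {
  genes <- module_members(module)
  miss <- setdiff(genes, gene_ids(dataset))
  if (length(miss))
    stop("module gene(s) absent from dataset: ", paste(miss, collapse = ", "))
  st <- welch_stats(dataset$values[genes, , drop = FALSE], dataset$condition)
  tt <- st$t[!is.na(st$t)]
  if (!length(tt)) stop("all module genes have undefined t scores")
  if (length(tt) < length(genes))
    log_msg("module_de_score: %d undefined gene(s) excluded",
            length(genes) - length(tt))
  mean(tt)
}

module_members <- function(module) {
  if (inherits(module, "GeneModule")) module$members else as.character(module)
}

#' Pairwise differential co-expression statistic
#'
#' \eqn{Z = |z^N - z^D| / \sqrt{1/(n_N - 3) + 1/(n_D - 3)}} where
#' \eqn{z = \frac12 \ln|(1 + r)/(1 - r)|} is the Fisher transform;
#' correlations are clamped to \eqn{|r| \le 1 - 10^{-7}} before transforming.
#' Vectorized over \code{r_N}, \code{r_D}.
#'
#' @param r_N,r_D correlation coefficients in the control and disease groups
#' @param n_N,n_D group sizes (> 3)
#' @return list of class \code{PairDC}: \code{z_N}, \code{z_D}, \code{Z}
#' @export
pair_dc <- function(r_N, r_D, n_N, n_D) {
  if (n_N <= 3L || n_D <= 3L) stop("Fisher-z DC requires n > 3 in both groups")
  if (any(abs(c(r_N, r_D)) > 1, na.rm = TRUE)) stop("|r| must be <= 1")
  clamp <- function(r) pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z_N <- 0.5 * log(abs((1 + clamp(r_N)) / (1 - clamp(r_N))))
  z_D <- 0.5 * log(abs((1 + clamp(r_D)) / (1 - clamp(r_D))))
  Z <- abs(z_N - z_D) / sqrt(1 / (n_N - 3) + 1 / (n_D - 3))
  structure(list(r_N = r_N, r_D = r_D, z_N = z_N, z_D = z_D, Z = Z,
                 n_N = n_N, n_D = n_D),
            class = "PairDC")
}

# correlation matrix of a module submatrix within one condition, using the
# platform-selected measure (Pearson continuous / Spearman counts)
module_cor <- function(module, dataset, group) {
  genes <- module_members(module)
  x <- dataset$values[genes, dataset$condition == group, drop = FALSE]
  if (dataset$platform == "counts") x <- t(apply(x, 1L, rank))
  suppressWarnings(stats::cor(t(x)))
}

#' Module DC score
#'
#' Computes the Fisher-z statistic Z for every member gene pair and returns
#' the root-mean-square \eqn{\sqrt{\sum Z^2 / P}} over the P defined pairs
#' (the size-normalized L2 norm of the Z vector). Set
#' \code{aggregate = "mean"} for the mean-|Z| alternative.
#'
#' @param module a \code{GeneModule} or character vector (>= 2 genes)
#' @param dataset an \code{ExpressionDataset}; both condition groups must
#'   have >= 4 samples
#' @param aggregate \code{"rms"} (default) or \code{"mean"}
#' @return non-negative scalar
#' @export
module_dc_score <- function(module, dataset, aggregate = c("rms", "mean")) {
  aggregate <- match.arg(aggregate)
  genes <- module_members(module)
  if (length(genes) < 2L) stop("module must have at least 2 genes")
  n_D <- sum(dataset$condition == "disease")
  n_N <- sum(dataset$condition == "control")
  if (n_D < 4L || n_N < 4L) stop("both condition groups need >= 4 samples")
  C_D <- module_cor(module, dataset, "disease")
  C_N <- module_cor(module, dataset, "control")
  ut <- upper.tri(C_D)
  r_D <- C_D[ut]; r_N <- C_N[ut]
  ok <- !is.na(r_D) & !is.na(r_N)
  if (!any(ok)) stop("no defined gene pairs in module")
  Z <- pair_dc(r_N[ok], r_D[ok], n_N, n_D)$Z
  if (aggregate == "rms") sqrt(mean(Z^2)) else mean(Z)
}

#' Concordance correlation index (CCI) of a gene set
#'
#' \eqn{CCI = (\lambda_1 - 1)/(m - 1)} where \eqn{\lambda_1} is the largest
#' eigenvalue of the m x m gene-gene correlation matrix, clipped to [0, 1].
#' 1 means all genes carry one common signal; 0 means mutual independence.
#'
#' @param values gene x sample numeric matrix (>= 2 genes, >= 3 samples),
#'   e.g. a module's expression restricted to one condition group
#' @param method correlation measure (default Pearson)
#' @return scalar in [0, 1]
#' @export
module_cci <- function(values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(values) < 2L) stop("CCI needs at least 2 genes")
  if (ncol(values) < 3L) stop("CCI needs at least 3 samples")
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s): ",
         paste(rownames(values)[sds == 0], collapse = ", "))
  if (method == "spearman") values <- t(apply(values, 1L, rank))
  C <- stats::cor(t(values))
  lambda1 <- eigen(C, symmetric = TRUE, only.values = TRUE)$values[1L]
  m <- nrow(values)
  min(max((lambda1 - 1) / (m - 1), 0), 1)
}

#' Per-condition CCI of a module within a dataset
#'
#' @param module a \code{GeneModule} or character vector
#' @param dataset an \code{ExpressionDataset}
#' @return named vector c(cci_disease, cci_control)
#' @export
module_cci_by_condition <- function(module, dataset) {
  genes <- module_members(module)
  method <- if (dataset$platform == "counts") "spearman" else "pearson"
  vapply(c(cci_disease = "disease", cci_control = "control"), function(g) {
    module_cci(dataset$values[genes, dataset$condition == g, drop = FALSE],
               method = method)
  }, 1.0)
}

#' Score all modules in all datasets
#'
#' @param collections a \code{GeneModuleCollection} or list of them (e.g.
#'   disease- and control-mined)
#' @param datasets list of \code{ExpressionDataset} sharing the module genes
#' @return long data.frame: module_id, dataset, n_genes, de_score, dc_score,
#'   cci_disease, cci_control
#' @export
score_modules <- function(collections, datasets) {
  if (inherits(collections, "GeneModuleCollection"))
    collections <- list(collections)
  modules <- unlist(lapply(collections, `[[`, "modules"), recursive = FALSE)
  if (!length(modules)) stop("no modules to score")
  rows <- lapply(modules, function(m) {
    do.call(rbind, lapply(datasets, function(d) {
      cci <- module_cci_by_condition(m, d)
      data.frame(module_id = m$id, dataset = d$name,
                 n_genes = length(m$members),
                 de_score = module_de_score(m, d),
                 dc_score = module_dc_score(m, d),
                 cci_disease = cci[["cci_disease"]],
                 cci_control = cci[["cci_control"]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-dataset scores and classify modules into DE/DC quadrants
#'
#' Takes the median across datasets per module for DE and DC; a module is
#' high-DE (HDE) iff its median DE strictly exceeds the across-module median
#' of median DE scores, likewise HDC; quadrants are HDE_HDC, HDE_LDC,
#' LDE_HDC, LDE_LDC.
#'
#' @param per_dataset_scores long table from \code{\link{score_modules}}
#' @return \code{ModuleScoreTable} data.frame: module_id, median_de,
#'   median_dc, median_cci_disease, median_cci_control, quadrant; attributes
#'   \code{de_split}, \code{dc_split}
#' @export
aggregate_and_classify <- function(per_dataset_scores) {
  s <- per_dataset_scores
  ids <- unique(s$module_id)
  med <- function(col) vapply(ids, function(m)
    stats::median(s[[col]][s$module_id == m]), 1.0)
  median_de <- med("de_score")
  median_dc <- med("dc_score")
  de_split <- stats::median(median_de)
  dc_split <- stats::median(median_dc)
  hde <- median_de > de_split
  hdc <- median_dc > dc_split
  quadrant <- paste0(ifelse(hde, "HDE", "LDE"), "_", ifelse(hdc, "HDC", "LDC"))
  out <- data.frame(module_id = ids,
                    median_de = median_de,
                    median_dc = median_dc,
                    median_cci_disease = med("cci_disease"),
                    median_cci_control = med("cci_control"),
                    quadrant = quadrant,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "de_split") <- de_split
  attr(out, "dc_split") <- dc_split
  class(out) <- c("ModuleScoreTable", "data.frame")
  out
}

#' Paired test of CCI differences across datasets
#'
#' For each module, a paired two-sided t test over datasets of
#' (CCI_disease - CCI_control).
#'
#' @param per_dataset_scores long table from \code{\link{score_modules}}
#' @return data.frame: module_id, mean_diff, p
#' @export
cci_condition_test <- function(per_dataset_scores) {
  s <- per_dataset_scores
  ids <- unique(s$module_id)
  rows <- lapply(ids, function(m) {
    d <- s$cci_disease[s$module_id == m] - s$cci_control[s$module_id == m]
    p <- if (length(d) >= 2 && stats::sd(d) > 0)
      stats::t.test(d)$p.value else NA_real_
    data.frame(module_id = m, mean_diff = mean(d), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call differentially expressed genes across datasets
#'
#' Per dataset: Welch test on log2 values, Benjamini-Hochberg adjustment
#' across genes; a gene passes iff |mean difference| >= log2(fc) and adjusted
#' p < fdr. A gene is globally UP (DOWN) iff it passes with that sign in at
#' least \code{min_datasets} datasets; passes with conflicting signs are
#' recorded but do not count toward either direction.
#'
#' With \code{moderated = TRUE}, gene variances are shrunk toward a common
#' prior fitted by moments (a light empirical-Bayes alternative for small
#' cohorts).
#'
#' @param datasets list of \code{ExpressionDataset} on a shared gene universe
#' @param fc fold-change threshold on the natural scale (default 1.2)
#' @param fdr adjusted p-value threshold (default 0.05)
#' @param min_datasets minimum datasets a gene must pass in (default 2)
#' @param moderated use variance shrinkage (default FALSE)
#' @return data.frame per gene: n_up, n_down, direction in
#'   \{"up", "down", "none"\}
#' @export
call_de_genes <- function(datasets, fc = 1.2, fdr = 0.05, min_datasets = 2L,
                          moderated = FALSE) {
  if (length(datasets) < min_datasets)
    stop("need at least min_datasets datasets")
  genes <- gene_ids(datasets[[1]])
  for (d in datasets) stopifnot(identical(gene_ids(d), genes))
  lfc <- log2(fc)
  up <- down <- matrix(FALSE, length(genes), length(datasets),
                       dimnames = list(genes, NULL))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    st <- welch_stats(d$values, d$condition)
    p <- if (moderated) moderated_p(d$values, d$condition) else st$p
    adj <- stats::p.adjust(p, method = "BH")
    pass <- !is.na(adj) & adj < fdr & abs(st$diff) >= lfc
    up[, k] <- pass & st$diff > 0
    down[, k] <- pass & st$diff < 0
  }
  n_up <- rowSums(up); n_down <- rowSums(down)
  direction <- ifelse(n_up >= min_datasets & n_down < min_datasets, "up",
               ifelse(n_down >= min_datasets & n_up < min_datasets, "down",
                      "none"))
  data.frame(gene_id = genes, n_up = n_up, n_down = n_down,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Welch test with variances shrunk toward the pooled mean variance via a
# moment-matched inverse-gamma prior (d0, s0^2).
moderated_p <- function(values, condition) {
  st <- welch_stats(values, condition)
  shrink <- function(v, df) {
    m <- mean(v); vv <- stats::var(v)
    # moments of scaled inv-chisq sampling around the prior
    d0 <- if (vv > 0) max(2 * m^2 / max(vv - 2 * m^2 / df, 1e-8), 1) else 1e6
    (d0 * m + df * v) / (d0 + df)
  }
  vd <- shrink(st$var_D, st$n_D - 1)
  vn <- shrink(st$var_N, st$n_N - 1)
  se2 <- vd / st$n_D + vn / st$n_N
  tt <- abs(st$diff) / sqrt(se2)
  df <- se2^2 / ((vd / st$n_D)^2 / (st$n_D - 1) + (vn / st$n_N)^2 / (st$n_N - 1))
  2 * stats::pt(tt, df = df, lower.tail = FALSE)
}

#' Fraction of module members called DE up/down
#'
#' @param module a \code{GeneModule} or character vector
#' @param de_table output of \code{\link{call_de_genes}}
#' @return named vector c(frac_up, frac_down)
#' @export
module_de_fractions <- function(module, de_table) {
  genes <- module_members(module)
  sub <- de_table[de_table$gene_id %in% genes, , drop = FALSE]
  c(frac_up = mean(sub$direction == "up"),
    frac_down = mean(sub$direction == "down"))
}
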