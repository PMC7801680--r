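# On-disk formats and core containers shared by every stage of the pipeline.

#' Construct an expression dataset
#'
#' The central container of the pipeline: a gene x sample expression matrix
#' with per-sample condition labels and optional region/trait annotations.
#' The \code{platform} selects the correlation measure used downstream
#' (\code{"continuous"} -> Pearson, \code{"counts"} -> Spearman).
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids and colnames sample ids. Log2-intensity units for
#'   \code{platform = "continuous"}, non-negative integer counts for
#'   \code{platform = "counts"}.
#' @param condition character/factor of per-sample labels; normalized
#'   case-insensitively, accepting the aliases "AD" -> disease and
#'   "CTL"/"ND" -> control.
#' @param platform one of \code{"continuous"}, \code{"counts"}.
#' @param region optional per-sample region labels.
#' @param traits optional data.frame of per-sample numeric covariates
#'   (e.g. \code{cdr}, \code{bb_score}, \code{plaque_mean}).
#' @param name dataset identifier.
#' @return an object of class \code{ExpressionDataset}.
#' @export
expression_dataset <- function(values, condition,
                               platform = c("continuous", "counts"),
                               region = NULL, traits = NULL,
                               name = "dataset") {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  condition <- normalize_condition(condition)
  ds <- structure(list(
    name = name,
    values = values,
    condition = condition,
    region = region,
    traits = traits,
    platform = platform
  ), class = "ExpressionDataset")
  validate_dataset(ds)
  ds
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%s; %d disease / %d control)\n",
              x$name, nrow(x$values), ncol(x$values), x$platform,
              sum(x$condition == "disease"), sum(x$condition == "control")))
  invisible(x)
}

#' Gene ids of a dataset
#' @param dataset an \code{ExpressionDataset}
#' @return character vector
#' @export
gene_ids <- function(dataset) rownames(dataset$values)

#' Sample ids of a dataset
#' @param dataset an \code{ExpressionDataset}
#' @return character vector
#' @export
sample_ids <- function(dataset) colnames(dataset$values)

# Map free-text condition labels to the canonical {disease, control} pair.
normalize_condition <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  out <- ifelse(lab %in% c("disease", "ad", "case"), "disease",
         ifelse(lab %in% c("control", "ctl", "nd", "normal"), "control", NA))
  if (anyNA(out)) {
    bad <- unique(lab[is.na(out)])
    stop("unrecognized condition label(s): ", paste(bad, collapse = ", "))
  }
  factor(out, levels = c("disease", "control"))
}

#' Validate an ExpressionDataset against its invariants
#'
#' Checks finiteness (and integer non-negativity for counts), duplicate gene
#' or sample ids, missing conditions and non-empty condition groups.
#'
#' @param dataset an \code{ExpressionDataset}
#' @return the dataset, invisibly; errors on violation.
#' @export
validate_dataset <- function(dataset) {
  v <- dataset$values
  if (!all(is.finite(v))) stop("expression values must be finite")
  if (dataset$platform == "counts" && !isTRUE(attr(dataset, "transformed"))) {
    if (any(v < 0) || any(v != round(v)))
      stop("counts platform requires non-negative integer values")
  }
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v))) stop("duplicate sample ids")
  if (length(dataset$condition) != ncol(v))
    stop("condition must have one label per sample")
  tab <- table(dataset$condition)
  if (any(tab == 0)) stop("both condition groups must be non-empty")
  if (!is.null(dataset$region) && length(dataset$region) != ncol(v))
    stop("region must have one label per sample")
  if (!is.null(dataset$traits) && nrow(dataset$traits) != ncol(v))
    stop("traits must have one row per sample")
  invisible(dataset)
}

#' Read an expression matrix and its phenotype table
#'
#' The matrix is a UTF-8 TSV with header \code{gene_id} followed by sample
#' ids and genes in rows (the usual series-matrix orientation; a transposed
#' file is rejected, not silently fixed). The phenotype TSV must contain
#' \code{sample_id} and \code{condition} columns and may contain
#' \code{region}, \code{cdr}, \code{bb_score}, \code{plaque_mean}.
#'
#' @param matrix_path path to the expression TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @param platform \code{"continuous"} or \code{"counts"}.
#' @param name dataset name; defaults to the matrix file stem.
#' @return an \code{ExpressionDataset}; sample order follows the matrix header.
#' @export
read_expression <- function(matrix_path, phenotype_path,
                            platform = c("continuous", "counts"),
                            name = NULL) {
  platform <- match.arg(platform)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(matrix_path))
  header <- strsplit(readLines(matrix_path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("expression matrix must have a gene_id column plus sample columns")
  tab <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = c("character", rep("numeric", length(header) - 1L)))
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at gene row %d, sample column %d",
                 idx[1], idx[2]))
  }
  rownames(m) <- genes

  ph <- utils::read.table(phenotype_path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(ph)))
    stop("phenotype table requires sample_id and condition columns")
  missing <- setdiff(colnames(m), ph$sample_id)
  if (length(missing))
    stop("sample(s) in matrix missing from phenotype: ",
         paste(missing, collapse = ", "))
  ph <- ph[match(colnames(m), ph$sample_id), , drop = FALSE]

  trait_cols <- intersect(c("cdr", "bb_score", "plaque_mean"), names(ph))
  traits <- if (length(trait_cols)) ph[, trait_cols, drop = FALSE] else NULL
  region <- if ("region" %in% names(ph)) ph$region else NULL
  expression_dataset(m, ph$condition, platform = platform,
                     region = region, traits = traits, name = name)
}

#' Write an expression dataset to TSV (matrix + phenotype)
#'
#' @param dataset an \code{ExpressionDataset}
#' @param matrix_path,phenotype_path output paths
#' @return invisibly, the dataset
#' @export
write_expression <- function(dataset, matrix_path, phenotype_path) {
  df <- data.frame(gene_id = gene_ids(dataset), dataset$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(sample_id = sample_ids(dataset),
                   condition = as.character(dataset$condition))
  if (!is.null(dataset$region)) ph$region <- dataset$region
  if (!is.null(dataset$traits)) ph <- cbind(ph, dataset$traits)
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (member gene ids).
#' @param descriptions optional character vector parallel to \code{sets}.
#' @return an object of class \code{GeneSetCollection}
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets))
    stop("sets must be a named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(sets) && any(lengths(sets) == 0)) stop("sets must be non-empty")
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]]))
      stop("duplicate members within set ", nm)
  }
  structure(list(sets = sets, descriptions = stats::setNames(descriptions, names(sets))),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              paste(utils::head(lengths(x$sets), 10), collapse = ", ")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line is \code{name TAB description TAB gene TAB gene ...}. Duplicate
#' members within a line are dropped with a warning; member order is
#' otherwise preserved.
#'
#' @param path path to the GMT file
#' @return a \code{GeneSetCollection}
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members dropped in set ", nms[i])
      members <- members[!duplicated(members)]
    }
    members
  })
  names(sets) <- nms
  gene_set_collection(sets, desc)
}

#' Write a gene set collection as GMT
#'
#' Round-trips exactly through \code{\link{read_gmt}} (names, descriptions,
#' member order).
#'
#' @param collection a \code{GeneSetCollection}
#' @param path output path
#' @return invisibly, the collection
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}

#' Write an edge list as TSV
#'
#' Columns \code{gene_a}, \code{gene_b}, \code{weight} with
#' \code{gene_a < gene_b} lexicographically. For a frequency network a
#' header comment line records K.
#'
#' @param edges data.frame with gene_a, gene_b and a numeric column
#' @param path output path
#' @param K optional number of source lists, recorded as a comment header
#' @return invisibly, the edges
#' @export
write_edge_list <- function(edges, path, K = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(K)) writeLines(sprintf("# K=%d", K), con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read an edge list TSV written by \code{\link{write_edge_list}}
#' @param path input path
#' @return data.frame; attribute \code{K} set if a header comment is present
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  K <- NULL
  skip <- 0L
  if (startsWith(first, "# K=")) {
    K <- as.integer(sub("# K=", "", first, fixed = TRUE))
    skip <- 1L
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          stringsAsFactors = FALSE)
  if (!is.null(K)) attr(df, "K") <- K
  df
}

# Timestamped logging to stderr; verbosity set via options(fgcna.verbose=...).
log_msg <- function(...) {
  if (isTRUE(getOption("fgcna.quiet", FALSE))) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}
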