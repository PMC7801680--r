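# End-to-end orchestration: preprocess -> per-condition networks -> lmQCM
# mining -> module scores -> deconvolution -> association.

#' Run the full analysis pipeline
#'
#' Stages: (1) gene filtering, counts transformation and gene-universe
#' intersection; (2) per-dataset, per-condition top-percentile correlation
#' edge lists aggregated into disease and control frequency networks;
#' (3) lmQCM module mining on each network (prefixes "AD" / "N");
#' (4) module DE/DC/CCI scoring, median aggregation and quadrant
#' classification; (5) cross-dataset per-gene DE calls; (6) marker-based
#' surrogate proportions and condition tests; (7) module eigengenes and
#' their associations with proportions (Pearson) and traits (Spearman);
#' (8) hub turnover between the two networks. Fully deterministic: re-running
#' on identical inputs reproduces identical numeric outputs.
#'
#' @param datasets list of >= 2 \code{ExpressionDataset}
#' @param markers optional \code{CellTypeMarkers} (or GMT-loaded
#'   \code{GeneSetCollection}) enabling the deconvolution and association
#'   stages
#' @param lmqcm an \code{LmqcmParams}
#' @param top_pct,p_max edge-selection parameters (defaults 5, 0.05)
#' @param fc,fdr,min_datasets DE-call thresholds (defaults 1.2, 0.05, 2)
#' @param n_markers markers per type for deconvolution (default 50)
#' @param zero_frac,var_pct,mean_pct gene-filter parameters
#' @param preprocess set FALSE if the datasets are already filtered,
#'   transformed and intersected
#' @param outdir optional directory; if given, key outputs and the resolved
#'   configuration are written there
#' @return a \code{RunBundle} list: datasets, filter reports, edge lists,
#'   networks, module collections, scores, classification, CCI tests, DE
#'   calls, proportions, proportion tests, eigengenes, associations, hub
#'   report, and the resolved config
#' @export
run_pipeline <- function(datasets, markers = NULL,
                         lmqcm = lmqcm_params(),
                         top_pct = 5, p_max = 0.05,
                         fc = 1.2, fdr = 0.05, min_datasets = 2L,
                         n_markers = 50L,
                         zero_frac = 0.5, var_pct = 20, mean_pct = 10,
                         preprocess = TRUE, outdir = NULL) {
  if (length(datasets) < 2L)
    stop(">= 2 datasets required (frequency weights undefined otherwise)")
  if (!is.null(markers) && !inherits(markers, "CellTypeMarkers"))
    markers <- cell_type_markers(markers)
  config <- list(lmqcm = unclass(lmqcm), top_pct = top_pct, p_max = p_max,
                 fc = fc, fdr = fdr, min_datasets = min_datasets,
                 n_markers = n_markers, zero_frac = zero_frac,
                 var_pct = var_pct, mean_pct = mean_pct)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  reports <- NULL
  if (preprocess) {
    pre <- stage("preprocess", preprocess_datasets(
      datasets, zero_frac = zero_frac, var_pct = var_pct,
      mean_pct = mean_pct))
    datasets <- pre$datasets
    reports <- pre$reports
  } else {
    datasets <- lapply(datasets, normalize_counts)
  }
  log_msg("pipeline: %d datasets, %d shared genes", length(datasets),
          nrow(datasets[[1]]$values))

  K <- length(datasets)
  edge_lists <- stage("corr_network", lapply(
    stats::setNames(c("disease", "control"), c("disease", "control")),
    function(grp) lapply(datasets, function(d)
      select_top_edges(pairwise_correlation(d, grp), top_pct, p_max))))
  networks <- stage("corr_network", lapply(edge_lists, frequency_network,
                                           K = K))
  log_msg("pipeline: networks built (%d / %d edges)",
          nrow(networks$disease$edges), nrow(networks$control$edges))

  mods_d <- stage("lmqcm", mine_modules(networks$disease, lmqcm, "AD"))
  mods_c <- stage("lmqcm", mine_modules(networks$control, lmqcm, "N"))
  log_msg("pipeline: mined %d AD and %d N modules",
          length(mods_d$modules), length(mods_c$modules))
  if (!length(mods_d$modules) && !length(mods_c$modules))
    stop("pipeline stage 'lmqcm' failed: no modules mined in either network")

  scores <- stage("module_scores",
                  score_modules(list(mods_d, mods_c), datasets))
  classification <- aggregate_and_classify(scores)
  cci_tests <- cci_condition_test(scores)
  de_calls <- stage("module_scores",
                    call_de_genes(datasets, fc, fdr, min_datasets))

  proportions <- prop_tests <- NULL
  if (!is.null(markers)) {
    proportions <- stage("deconv", lapply(datasets, surrogate_proportions,
                                          markers = markers,
                                          n_markers = n_markers))
    prop_tests <- lapply(seq_along(datasets), function(k)
      compare_proportions(proportions[[k]], datasets[[k]]$condition))
    names(prop_tests) <- names(proportions)
  }

  all_modules <- c(mods_d$modules, mods_c$modules)
  eigengenes <- stage("association", lapply(datasets, function(d) {
    eg <- vapply(all_modules, function(m) module_eigengene(m, d)$score,
                 numeric(ncol(d$values)))
    colnames(eg) <- vapply(all_modules, `[[`, "", "id")
    rownames(eg) <- sample_ids(d)
    eg
  }))

  prop_assoc <- trait_assoc <- NULL
  if (!is.null(proportions)) {
    prop_assoc <- lapply(seq_along(datasets), function(k)
      covariate_association(eigengenes[[k]], proportions[[k]], "pearson"))
    names(prop_assoc) <- names(proportions)
  }
  has_traits <- vapply(datasets, function(d) !is.null(d$traits), TRUE)
  if (any(has_traits)) {
    trait_assoc <- lapply(which(has_traits), function(k)
      covariate_association(eigengenes[[k]],
                            data.matrix(datasets[[k]]$traits), "spearman"))
    names(trait_assoc) <- names(datasets)[has_traits]
  }

  hub_report <- stage("association",
                      hub_turnover(networks$disease, networks$control))

  bundle <- structure(list(
    datasets = datasets, filter_reports = reports,
    edge_lists = edge_lists, networks = networks,
    modules_disease = mods_d, modules_control = mods_c,
    scores = scores, classification = classification,
    cci_tests = cci_tests, de_calls = de_calls,
    proportions = proportions, proportion_tests = prop_tests,
    eigengenes = eigengenes, proportion_associations = prop_assoc,
    trait_associations = trait_assoc, hub_report = hub_report,
    config = config
  ), class = "RunBundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' @export
print.RunBundle <- function(x, ...) {
  cat(sprintf(paste0("RunBundle: %d datasets, %d AD + %d N modules, ",
                     "%d scored rows\n"),
              length(x$datasets), length(x$modules_disease$modules),
              length(x$modules_control$modules), nrow(x$scores)))
  invisible(x)
}

#' Write the main outputs of a pipeline run
#'
#' @param bundle a \code{RunBundle}
#' @param outdir output directory (created if needed)
#' @return invisibly, the bundle
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(bundle$scores, "module_scores.tsv")
  tsv(bundle$classification, "module_classification.tsv")
  tsv(bundle$de_calls, "de_calls.tsv")
  for (grp in names(bundle$networks))
    write_edge_list(bundle$networks[[grp]]$edges,
                    file.path(outdir, paste0("network_", grp, ".tsv")),
                    K = bundle$networks[[grp]]$K)
  write_gmt(modules_as_gene_sets(bundle$modules_disease),
            file.path(outdir, "modules_AD.gmt"))
  write_gmt(modules_as_gene_sets(bundle$modules_control),
            file.path(outdir, "modules_N.gmt"))
  if (!is.null(bundle$proportions)) {
    for (nm in names(bundle$proportions)) {
      pr <- bundle$proportions[[nm]]
      tsv(data.frame(sample_id = rownames(pr), pr, check.names = FALSE),
          paste0("proportions_", nm, ".tsv"))
    }
  }
  if (!is.null(bundle$filter_reports))
    write_filter_report(bundle$filter_reports,
                        file.path(outdir, "filter_reports.json"))
  jsonlite::write_json(bundle$config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE)
  invisible(bundle)
}
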