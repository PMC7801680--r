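# Multi-cohort bulk-expression simulator with known cell-type mixtures and
# planted modules, so every pipeline stage is testable without restricted
# cohort data.
#
# Stated world: five cohorts (2 microarray-like continuous, 3 RNA-seq-like
# counts), 60 disease + 60 control samples each, 2000 genes. Per-sample
# cell-type proportions are Dirichlet draws whose concentrations differ by
# condition (neurons down; microglia, astrocytes, endothelia up;
# oligodendrocytes unchanged). Marker genes are affine in their type's
# proportion; one "neuron-like" module is regulation-perturbed (block
# correlation 0.4 control -> 0.7 disease plus a mean drop); one
# housekeeping block is condition-invariant.

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic world; see the methods
#' vignette for the rationale behind each constant.
#'
#' @param n_datasets number of cohorts (default 5)
#' @param platforms platform per cohort (default 2 continuous + 3 counts)
#' @param n_per_group samples per condition per cohort (default 60)
#' @param n_genes total genes (default 2000)
#' @param markers_per_type planted markers per cell type (default 50)
#' @param alpha_control,alpha_disease Dirichlet concentrations over
#'   (neu, mic, ast, oli, end)
#' @param marker_base mean log2 baseline of all genes (default 8)
#' @param marker_snr per-type marker signal-to-noise ratio, scalar or named
#'   vector over (neu, mic, ast, oli, end). Every type's slope is
#'   \code{noise_sd / sd(proportion)} in controls (one fixed absolute signal
#'   spread), and the per-gene additive noise SD is
#'   \code{noise_sd / marker_snr}. The default sharpens endothelial markers
#'   (vascular markers are highly cell-type specific, and vascular content
#'   varies strongly between bulk dissections).
#' @param noise_sd additive log2 noise SD for marker genes (default 0.5)
#' @param reg_size regulation-perturbed module size (default 40)
#' @param reg_r_control,reg_r_disease block correlation per condition
#'   (defaults 0.4 / 0.7)
#' @param reg_shift disease mean decrease in log2 units (default 0.5)
#' @param reg_neuron_coef slope of the neuron-proportion component tracked
#'   by the perturbed module (default 3)
#' @param reg_sd marginal SD of the perturbed block (default 1)
#' @param hk_size housekeeping module size (default 30)
#' @param hk_r condition-invariant housekeeping block correlation
#'   (default 0.5; kept moderate so the block's pair correlations do not
#'   fluctuate coherently, which would inflate its null DC spread)
#' @param hk_sd housekeeping marginal SD (default 0.7)
#' @param hk_offset baseline log2 boost of housekeeping genes (default 1.5;
#'   housekeeping transcripts are among the most abundant)
#' @param bg_sd_range background per-gene SD range (default 0.2..0.8)
#' @param lib_size counts-platform library size (default 1e6)
#' @param trait_noise SD of the noise added to the latent pathology index
#'   before discretizing traits (default 0.5)
#' @param seed integer seed; recorded in the truth object
#' @return object of class \code{SimulationConfig}
#' @export
simulation_config <- function(n_datasets = 5L,
                              platforms = c("continuous", "continuous",
                                            "counts", "counts", "counts"),
                              n_per_group = 60L,
                              n_genes = 2000L,
                              markers_per_type = 50L,
                              alpha_control = c(neu = 12, mic = 2, ast = 3,
                                                oli = 4, end = 1.5),
                              alpha_disease = c(neu = 8, mic = 4, ast = 5,
                                                oli = 4, end = 2.5),
                              marker_base = 8,
                              marker_snr = c(neu = 1, mic = 1, ast = 1,
                                             oli = 1, end = 2.5),
                              noise_sd = 0.5,
                              reg_size = 40L,
                              reg_r_control = 0.4,
                              reg_r_disease = 0.7,
                              reg_shift = 0.5,
                              reg_neuron_coef = 3,
                              reg_sd = 1.0,
                              hk_size = 30L,
                              hk_r = 0.5,
                              hk_sd = 0.7,
                              hk_offset = 1.5,
                              bg_sd_range = c(0.2, 0.8),
                              lib_size = 1e6,
                              trait_noise = 0.5,
                              seed = 1L) {
  stopifnot(length(platforms) == n_datasets,
            all(platforms %in% c("continuous", "counts")),
            all(alpha_control > 0), all(alpha_disease > 0),
            length(alpha_control) == 5L, length(alpha_disease) == 5L,
            n_per_group >= 8L, noise_sd > 0,
            reg_r_control >= 0, reg_r_control < 1,
            reg_r_disease >= 0, reg_r_disease < 1,
            hk_r >= 0, hk_r < 1)
  names(alpha_control) <- names(alpha_disease) <- CELL_TYPES
  if (length(marker_snr) == 1L) marker_snr <- rep(marker_snr, 5L)
  stopifnot(length(marker_snr) == 5L, all(marker_snr > 0))
  names(marker_snr) <- CELL_TYPES
  total_planted <- 5L * markers_per_type + reg_size + hk_size
  if (n_genes <= total_planted)
    stop("n_genes must exceed the planted gene count (", total_planted, ")")
  structure(as.list(environment()), class = "SimulationConfig")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# planted gene ids, fixed by the configuration
planted_layout <- function(config) {
  marker_ids <- lapply(CELL_TYPES, function(ct)
    sprintf("%s%03d", toupper(ct), seq_len(config$markers_per_type)))
  names(marker_ids) <- CELL_TYPES
  reg <- sprintf("REG%03d", seq_len(config$reg_size))
  hk <- sprintf("HKP%03d", seq_len(config$hk_size))
  n_bg <- config$n_genes - 5L * config$markers_per_type -
    config$reg_size - config$hk_size
  bg <- sprintf("BG%04d", seq_len(n_bg))
  list(markers = marker_ids, reg = reg, hk = hk, bg = bg,
       all = c(unlist(marker_ids, use.names = FALSE), reg, hk, bg))
}

#' Simulate the multi-cohort benchmark
#'
#' Deterministic given the config (including its seed). Returns the cohorts
#' plus a \code{SyntheticTruth} carrying true proportions, planted module
#' memberships and classes, traits, markers and the generative parameters.
#'
#' @param config a \code{SimulationConfig}
#' @return list with \code{datasets} (list of \code{ExpressionDataset}) and
#'   \code{truth} (\code{SyntheticTruth})
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  lay <- planted_layout(config)
  G <- config$n_genes
  n <- config$n_per_group

  baseline <- stats::setNames(stats::rnorm(G, config$marker_base, 1), lay$all)
  baseline[lay$hk] <- baseline[lay$hk] + config$hk_offset
  bg_sd <- stats::runif(length(lay$bg), config$bg_sd_range[1],
                        config$bg_sd_range[2])

  # per-type slopes: unit SNR against control-condition proportion spread
  a0 <- sum(config$alpha_control)
  p_bar <- config$alpha_control / a0
  sd_p <- sqrt(p_bar * (1 - p_bar) / (a0 + 1))
  slope <- config$noise_sd / sd_p
  marker_noise <- config$noise_sd / config$marker_snr

  datasets <- vector("list", config$n_datasets)
  proportions <- vector("list", config$n_datasets)
  traits <- vector("list", config$n_datasets)

  for (k in seq_len(config$n_datasets)) {
    cond <- factor(rep(c("disease", "control"), each = n),
                   levels = c("disease", "control"))
    props <- rbind(rdirichlet(n, config$alpha_disease),
                   rdirichlet(n, config$alpha_control))
    ns <- 2L * n
    sample_names <- sprintf("D%d_S%03d", k, seq_len(ns))
    rownames(props) <- sample_names

    x <- matrix(0, G, ns, dimnames = list(lay$all, sample_names))
    # proportion-driven marker blocks
    for (ct in CELL_TYPES) {
      ids <- lay$markers[[ct]]
      m <- length(ids)
      x[ids, ] <- baseline[ids] +
        matrix(slope[ct] * props[, ct], m, ns, byrow = TRUE) +
        matrix(stats::rnorm(m * ns, 0, marker_noise[ct]), m, ns)
    }
    # regulation-perturbed block: equicorrelated via a shared factor whose
    # loading depends on condition; mean tracks neuron proportion and drops
    # in disease
    r_s <- ifelse(cond == "disease", config$reg_r_disease,
                  config$reg_r_control)
    f <- stats::rnorm(ns)
    mreg <- length(lay$reg)
    common <- sqrt(r_s) * f
    eps <- matrix(stats::rnorm(mreg * ns), mreg, ns)
    noise <- sweep(eps, 2L, sqrt(1 - r_s), "*")
    x[lay$reg, ] <- baseline[lay$reg] + config$reg_sd *
      (matrix(common, mreg, ns, byrow = TRUE) + noise) +
      matrix(config$reg_neuron_coef * props[, "neu"] -
               config$reg_shift * (cond == "disease"), mreg, ns, byrow = TRUE)
    # housekeeping block: same correlation in both conditions, no mean effect
    fh <- stats::rnorm(ns)
    mh <- length(lay$hk)
    x[lay$hk, ] <- baseline[lay$hk] + config$hk_sd *
      (sqrt(config$hk_r) * matrix(fh, mh, ns, byrow = TRUE) +
         sqrt(1 - config$hk_r) * matrix(stats::rnorm(mh * ns), mh, ns))
    # independent background
    mb <- length(lay$bg)
    x[lay$bg, ] <- baseline[lay$bg] +
      matrix(stats::rnorm(mb * ns), mb, ns) * bg_sd

    platform <- config$platforms[k]
    if (platform == "counts") {
      lin <- 2^x
      lam <- sweep(lin, 2L, colSums(lin) / config$lib_size, "/")
      x <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
                  dimnames = dimnames(x))
    }
    tr <- simulate_traits_from_props(props, config$trait_noise)
    datasets[[k]] <- expression_dataset(
      x, cond, platform = platform, traits = tr,
      name = sprintf("cohort%d_%s", k, substr(platform, 1, 4)))
    proportions[[k]] <- props
    traits[[k]] <- tr
  }
  names(datasets) <- vapply(datasets, `[[`, "", "name")
  names(proportions) <- names(traits) <- names(datasets)

  modules <- c(
    stats::setNames(lapply(CELL_TYPES, function(ct)
      list(members = lay$markers[[ct]], class = "proportion_driven",
           cell_type = ct)),
      paste0("prop_", CELL_TYPES)),
    list(reg_neuronlike = list(members = lay$reg,
                               class = "regulation_perturbed",
                               cell_type = "neu"),
         housekeeping = list(members = lay$hk, class = "housekeeping",
                             cell_type = NA_character_)))

  truth <- structure(list(
    proportions = proportions,
    modules = modules,
    markers = cell_type_markers(lay$markers),
    traits = traits,
    slopes = slope,
    config = config
  ), class = "SyntheticTruth")
  list(datasets = datasets, truth = truth)
}

# latent pathology index -> noisy monotone traits
simulate_traits_from_props <- function(props, trait_noise) {
  idx <- scale(props[, "mic"] + props[, "ast"])[, 1] - scale(props[, "neu"])[, 1]
  idx <- idx / stats::sd(idx)
  noisy <- function() idx + stats::rnorm(length(idx), 0, trait_noise)
  z_cdr <- noisy(); z_bb <- noisy(); z_pl <- noisy()
  cdr_levels <- c(0, 0.5, 1, 2, 3)
  out <- data.frame(
    cdr = cdr_levels[pmin(1L + floor(5 * stats::pnorm(z_cdr)), 5L)],
    bb_score = pmin(floor(7 * stats::pnorm(z_bb)), 6L),
    plaque_mean = pmax(10 + 6 * z_pl, 0),
    row.names = rownames(props))
  attr(out, "index") <- idx
  attr(out, "latents") <- cbind(cdr = z_cdr, bb = z_bb, plaque = z_pl)
  out
}

#' Simulate clinicopathological traits from true proportions
#'
#' Traits increase in the glial (mic + ast) proportion and decrease in the
#' neuron proportion: a latent standardized pathology index plus noise is
#' discretized to CDR in \{0, 0.5, 1, 2, 3\} and Braak stage 0..6;
#' plaque_mean stays continuous and non-negative. The latent index is
#' attached as attribute \code{"index"}.
#'
#' @param truth a \code{SyntheticTruth} (or a samples x 5 proportion matrix)
#' @param trait_noise noise SD on the latent index (default from the truth's
#'   config, else 0.5)
#' @return data.frame per sample (or list of them, one per dataset)
#' @export
simulate_traits <- function(truth, trait_noise = NULL) {
  if (inherits(truth, "SyntheticTruth")) {
    tn <- if (is.null(trait_noise)) truth$config$trait_noise else trait_noise
    lapply(truth$proportions, simulate_traits_from_props, trait_noise = tn)
  } else {
    simulate_traits_from_props(truth,
                               if (is.null(trait_noise)) 0.5 else trait_noise)
  }
}

#' Simulate subject-matched per-region proportion vectors
#'
#' Small helper for cross-region concordance tests: one cell type's relative
#' proportion measured in several brain regions of the same subjects, with a
#' controllable common-factor correlation across regions.
#'
#' @param n_subjects number of matched subjects
#' @param n_regions number of regions (default 4)
#' @param rho cross-region correlation (default 0.8)
#' @param seed integer seed
#' @return named list (region -> subject-named numeric vector)
#' @export
simulate_matched_regions <- function(n_subjects, n_regions = 4L, rho = 0.8,
                                     seed = 1L) {
  set.seed(seed)
  subj <- sprintf("subj%03d", seq_len(n_subjects))
  f <- stats::rnorm(n_subjects)
  out <- lapply(seq_len(n_regions), function(r)
    stats::setNames(sqrt(rho) * f +
                      sqrt(1 - rho) * stats::rnorm(n_subjects), subj))
  names(out) <- sprintf("region%d", seq_len(n_regions))
  out
}

#' Write a simulated benchmark to disk in the pipeline's input formats
#'
#' Expression + phenotype TSVs per cohort, the marker GMT, and a truth JSON,
#' so the command-line pipeline runs on the output unchanged.
#'
#' @param sim output of \code{\link{simulate_cohorts}}
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest of written files
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (d in sim$datasets) {
    mp <- file.path(dir, paste0(d$name, "_expression.tsv"))
    pp <- file.path(dir, paste0(d$name, "_phenotype.tsv"))
    write_expression(d, mp, pp)
    files[[d$name]] <- list(matrix = mp, phenotype = pp,
                            platform = d$platform)
  }
  gmt <- file.path(dir, "markers.gmt")
  write_gmt(gene_set_collection(unclass(sim$truth$markers)), gmt)
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    proportions = lapply(sim$truth$proportions, function(p)
      as.data.frame(p)),
    modules = sim$truth$modules,
    seed = sim$truth$config$seed
  ), truth_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(datasets = files, markers = gmt, truth = truth_json)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Evaluate pipeline output against the planted truth
#'
#' For every planted module: best-Jaccard match among the mined modules, its
#' assigned quadrant, and the median across datasets of the correlation
#' between the matched module's eigengene and the planted cell type's true
#' proportion. For every cell type: the median across datasets of the
#' correlation between surrogate and true proportion. Pass flags encode the
#' benchmark's attribution expectations (proportion-driven microglia module
#' HDE_LDC with eigengene r >= 0.9; regulation-perturbed module HDE_HDC with
#' CCI_disease > CCI_control in a majority of cohorts; housekeeping
#' LDE_LDC).
#'
#' @param bundle a \code{RunBundle} from \code{\link{run_pipeline}}
#' @param truth the matching \code{SyntheticTruth}
#' @return list: \code{modules} data.frame, \code{deconvolution} data.frame,
#'   \code{checks} named logical vector
#' @export
truth_evaluation <- function(bundle, truth) {
  mined <- c(bundle$modules_disease$modules, bundle$modules_control$modules)
  mined_sets <- lapply(mined, `[[`, "members")
  names(mined_sets) <- vapply(mined, `[[`, "", "id")
  agg <- bundle$classification

  module_rows <- lapply(names(truth$modules), function(nm) {
    pm <- truth$modules[[nm]]
    if (length(mined_sets)) {
      jac <- vapply(mined_sets, function(s)
        length(intersect(s, pm$members)) / length(union(s, pm$members)), 1.0)
      best <- which.max(jac)
      match_id <- names(mined_sets)[best]
      quadrant <- agg$quadrant[agg$module_id == match_id]
      eg_cor <- if (!is.na(pm$cell_type)) {
        stats::median(vapply(seq_along(bundle$datasets), function(k) {
          eg <- bundle$eigengenes[[k]][, match_id]
          stats::cor(eg, truth$proportions[[k]][, pm$cell_type])
        }, 1.0))
      } else NA_real_
      data.frame(planted = nm, class = pm$class, match = match_id,
                 jaccard = unname(jac[best]), quadrant = quadrant,
                 eigengene_prop_cor = eg_cor, stringsAsFactors = FALSE)
    } else {
      data.frame(planted = nm, class = pm$class, match = NA_character_,
                 jaccard = 0, quadrant = NA_character_,
                 eigengene_prop_cor = NA_real_, stringsAsFactors = FALSE)
    }
  })
  modules <- do.call(rbind, module_rows)

  deconv <- do.call(rbind, lapply(CELL_TYPES, function(ct) {
    cors <- vapply(seq_along(bundle$datasets), function(k) {
      pr <- bundle$proportions[[k]]
      stats::cor(pr[, ct], truth$proportions[[k]][, ct])
    }, 1.0)
    data.frame(cell_type = ct, median_cor = stats::median(cors),
               min_cor = min(cors), stringsAsFactors = FALSE)
  }))

  row_of <- function(nm) modules[modules$planted == nm, ]
  mic <- row_of("prop_mic"); reg <- row_of("reg_neuronlike")
  hk <- row_of("housekeeping")
  reg_cci_wins <- if (!is.na(reg$match)) {
    s <- bundle$scores[bundle$scores$module_id == reg$match, ]
    sum(s$cci_disease > s$cci_control)
  } else 0L
  checks <- c(
    mic_hde_ldc = identical(mic$quadrant, "HDE_LDC"),
    mic_eigengene = isTRUE(mic$eigengene_prop_cor >= 0.9),
    reg_hde_hdc = identical(reg$quadrant, "HDE_HDC"),
    reg_cci_majority = reg_cci_wins >= ceiling(length(bundle$datasets) * 0.8),
    hk_lde_ldc = identical(hk$quadrant, "LDE_LDC"),
    deconv_all_types = all(deconv$median_cor >= 0.9)
  )
  list(modules = modules, deconvolution = deconv,
       reg_cci_wins = reg_cci_wins, checks = checks)
}
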