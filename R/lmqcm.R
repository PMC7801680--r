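# Local-maximum Quasi-Clique Merger (lmQCM) mining of the frequency network.
#
# Seeds are locally maximal edges with weight >= gamma; each seed is grown
# greedily while the module density stays above the adaptive threshold
# gamma * alpha(n), alpha(n) = 1 - 1/(2 * lambda * (n + t)); overlapping raw
# modules are merged at overlap ratio >= beta. Mining is fully deterministic.

#' lmQCM mining parameters
#'
#' @param t density-offset parameter (default 1.0)
#' @param lam density-decay parameter lambda (default 1.0)
#' @param gamma seed-weight / density threshold (default 0.81: on a 5-cohort
#'   frequency network this requires the seeding pair in all five lists;
#'   0.80 would admit 4-of-5 pairs)
#' @param beta merge-overlap threshold (default 0.3)
#' @param min_size minimum module size (default 10)
#' @return object of class \code{LmqcmParams}
#' @export
lmqcm_params <- function(t = 1.0, lam = 1.0, gamma = 0.81, beta = 0.3,
                         min_size = 10L) {
  stopifnot(gamma > 0, gamma <= 1, beta > 0, beta <= 1,
            min_size >= 2, lam > 0, t >= 0)
  structure(list(t = t, lam = lam, gamma = gamma, beta = beta,
                 min_size = as.integer(min_size)),
            class = "LmqcmParams")
}

# Sparse symmetric adjacency of a FrequencyNetwork plus the node index map.
net_adjacency <- function(net) {
  nodes <- net$nodes
  i <- match(net$edges$gene_a, nodes)
  j <- match(net$edges$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(net$edges$weight, 2L),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  A
}

#' Find lmQCM seed edges
#'
#' Edges with weight >= gamma that are local maxima (no adjacent edge has a
#' strictly larger weight), sorted by weight descending then lexicographic
#' pair order.
#'
#' @param net a \code{FrequencyNetwork}
#' @param gamma seed threshold
#' @return data.frame(gene_a, gene_b, weight); possibly empty
#' @export
find_seed_edges <- function(net, gamma = 0.81) {
  ed <- net$edges
  if (!nrow(ed)) return(ed[0, , drop = FALSE])
  node_max <- pmax(
    stats::setNames(numeric(length(net$nodes)), net$nodes),
    weighted_node_max(net))
  cand <- ed$weight >= gamma &
    ed$weight >= node_max[ed$gene_a] &
    ed$weight >= node_max[ed$gene_b]
  out <- ed[cand, , drop = FALSE]
  out <- out[order(-out$weight, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximum incident edge weight per node
weighted_node_max <- function(net) {
  a <- net$edges$gene_a; b <- net$edges$gene_b; w <- net$edges$weight
  m <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  ma <- tapply(w, a, max)
  mb <- tapply(w, b, max)
  m[names(ma)] <- pmax(m[names(ma)], ma)
  m[names(mb)] <- pmax(m[names(mb)], mb)
  m
}

#' Grow a module from a seed edge
#'
#' Greedy quasi-clique expansion: repeatedly add the outside vertex with the
#' largest total weight to the current set (ties broken lexicographically by
#' gene id) as long as the resulting density
#' \eqn{d = 2 W / (n (n - 1))} stays at or above
#' \eqn{\gamma \, \alpha(n)} with \eqn{\alpha(n) = 1 - 1/(2\lambda(n + t))}
#' evaluated at the pre-addition size; growth stops at the first rejection.
#'
#' @param net a \code{FrequencyNetwork} (or a precomputed adjacency from it)
#' @param seed character vector of the two seed gene ids
#' @param params an \code{LmqcmParams}
#' @param adjacency optional sparse adjacency (for repeated calls)
#' @return character vector of member gene ids (sorted)
#' @export
expand_module <- function(net, seed, params = lmqcm_params(),
                          adjacency = NULL) {
  A <- if (is.null(adjacency)) net_adjacency(net) else adjacency
  nodes <- rownames(A)
  u <- match(seed, nodes)
  if (anyNA(u) || length(u) != 2L) stop("seed must be a valid edge of the network")
  in_set <- logical(length(nodes))
  in_set[u] <- TRUE
  gain <- as.numeric(A[, u[1]] + A[, u[2]])
  W <- A[u[1], u[2]]
  n <- 2L
  repeat {
    gain_out <- gain
    gain_out[in_set] <- -Inf
    g <- max(gain_out)
    if (g <= 0) break
    # lexicographic tie-break on gene id among max-gain candidates
    cand <- which(gain_out == g)
    v <- cand[order(nodes[cand])][1L]
    new_density <- 2 * (W + g) / ((n + 1) * n)
    alpha <- 1 - 1 / (2 * params$lam * (n + params$t))
    if (new_density < params$gamma * alpha) break
    in_set[v] <- TRUE
    W <- W + g
    n <- n + 1L
    gain <- gain + as.numeric(A[, v])
  }
  sort(nodes[in_set])
}

#' Merge overlapping raw modules
#'
#' Iteratively merges the pair with the largest overlap ratio
#' \eqn{|A \cap B| / \min(|A|, |B|)} while any ratio is >= beta, then drops
#' modules smaller than \code{min_size} and assigns sequential ids by
#' descending final size (ties by lexicographically first member).
#'
#' @param raw list of character vectors (gene sets), in mining order
#' @param beta overlap-ratio threshold
#' @param min_size minimum retained module size
#' @param prefix id prefix ("AD" for disease-mined, "N" for control-mined)
#' @param seeds optional list of seed pairs parallel to \code{raw}
#' @param params optional \code{LmqcmParams} recorded as provenance
#' @return a \code{GeneModuleCollection}
#' @export
merge_modules <- function(raw, beta = 0.3, min_size = 10L, prefix = "M",
                          seeds = NULL, params = NULL) {
  sets <- lapply(raw, unique)
  seed_of <- if (is.null(seeds)) vector("list", length(sets)) else seeds
  repeat {
    k <- length(sets)
    if (k < 2L) break
    best <- 0; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      ov <- length(intersect(sets[[i]], sets[[j]])) /
        min(length(sets[[i]]), length(sets[[j]]))
      if (ov > best + 1e-12) { best <- ov; bi <- i; bj <- j }
    }
    if (best < beta) break
    sets[[bi]] <- sort(union(sets[[bi]], sets[[bj]]))
    sets[[bj]] <- NULL
    seed_of[[bj]] <- NULL
  }
  keep <- lengths(sets) >= min_size
  sets <- sets[keep]
  seed_of <- seed_of[keep]
  if (length(sets)) {
    first <- vapply(sets, function(s) sort(s)[1L], "")
    ord <- order(-lengths(sets), first)
    sets <- sets[ord]
    seed_of <- seed_of[ord]
  }
  modules <- lapply(seq_along(sets), function(i) {
    structure(list(id = paste0(prefix, i),
                   members = sort(sets[[i]]),
                   seed = seed_of[[i]],
                   prefix = prefix,
                   params = params),
              class = "GeneModule")
  })
  structure(list(modules = modules, prefix = prefix, params = params),
            class = "GeneModuleCollection")
}

#' @export
print.GeneModuleCollection <- function(x, ...) {
  cat(sprintf("GeneModuleCollection '%s': %d modules (sizes %s)\n",
              x$prefix, length(x$modules),
              paste(vapply(x$modules, function(m) length(m$members), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.GeneModule <- function(x, ...) {
  cat(sprintf("GeneModule %s: %d genes\n", x$id, length(x$members)))
  invisible(x)
}

#' Mine co-expression modules from a frequency network
#'
#' Orchestrates \code{\link{find_seed_edges}} -> \code{\link{expand_module}}
#' per seed (skipping seeds already absorbed into a previously grown module)
#' -> \code{\link{merge_modules}}. Deterministic given its input.
#'
#' @param net a \code{FrequencyNetwork}
#' @param params an \code{LmqcmParams}
#' @param prefix module id prefix: "AD" for disease-mined, "N" for
#'   control-mined
#' @return a \code{GeneModuleCollection}
#' @export
mine_modules <- function(net, params = lmqcm_params(), prefix = "AD") {
  seeds <- find_seed_edges(net, params$gamma)
  if (!nrow(seeds))
    return(merge_modules(list(), params$beta, params$min_size, prefix,
                         params = params))
  A <- net_adjacency(net)
  raw <- list()
  used <- list()
  kept_seeds <- list()
  for (k in seq_len(nrow(seeds))) {
    s <- c(seeds$gene_a[k], seeds$gene_b[k])
    absorbed <- any(vapply(raw, function(m) all(s %in% m), TRUE))
    if (absorbed) next
    mod <- expand_module(net, s, params, adjacency = A)
    raw[[length(raw) + 1L]] <- mod
    kept_seeds[[length(kept_seeds) + 1L]] <- s
  }
  merge_modules(raw, params$beta, params$min_size, prefix,
                seeds = kept_seeds, params = params)
}

#' Export a module collection as a GMT gene-set collection
#'
#' The description field records provenance:
#' \code{prefix=..;seed=a,b;gamma=..;beta=..}.
#'
#' @param collection a \code{GeneModuleCollection}
#' @return a \code{GeneSetCollection} suitable for \code{\link{write_gmt}}
#' @export
modules_as_gene_sets <- function(collection) {
  sets <- lapply(collection$modules, `[[`, "members")
  names(sets) <- vapply(collection$modules, `[[`, "", "id")
  desc <- vapply(collection$modules, function(m) {
    seed <- if (is.null(m$seed)) "" else paste(m$seed, collapse = ",")
    p <- collection$params
    pstr <- if (is.null(p)) "" else
      sprintf(";t=%g;lam=%g;gamma=%g;beta=%g;min_size=%d",
              p$t, p$lam, p$gamma, p$beta, p$min_size)
    sprintf("prefix=%s;seed=%s%s", collection$prefix, seed, pstr)
  }, "")
  gene_set_collection(sets, desc)
}
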