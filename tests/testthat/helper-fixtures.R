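# Fixture builders shared across the suite; everything is generated in code.

# small dataset with explicit values
make_dataset <- function(values, condition, platform = "continuous",
                         name = "toy", ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, condition, platform = platform, name = name, ...)
}

# random continuous dataset: G genes x (n_d + n_n) samples
random_dataset <- function(G = 20, n_d = 10, n_n = 10, seed = 1,
                           platform = "continuous", name = "rand") {
  set.seed(seed)
  v <- matrix(rnorm(G * (n_d + n_n), 8, 1), G,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              sprintf("s%03d", seq_len(n_d + n_n))))
  if (platform == "counts") v <- matrix(rpois(length(v), 2^v / 50), nrow(v),
                                        dimnames = dimnames(v))
  make_dataset(v, rep(c("disease", "control"), c(n_d, n_n)),
               platform = platform, name = name)
}

# weighted network from an explicit edge data.frame
toy_network <- function(edges, K = 5) as_frequency_network(edges, K = K)

# network of planted cliques over a node universe, plus sparse background
planted_clique_network <- function(block_sizes, n_background = 35,
                                   within_weights = 1.0,
                                   bg_prob = 0.01, bg_weight = 0.2,
                                   seed = 1, K = 5) {
  set.seed(seed)
  n_block <- sum(block_sizes)
  nodes <- sprintf("n%03d", seq_len(n_block + n_background))
  blocks <- split(nodes[seq_len(n_block)],
                  rep(seq_along(block_sizes), block_sizes))
  edges <- list()
  for (b in blocks) {
    pr <- t(combn(b, 2))
    w <- sample(within_weights, nrow(pr), replace = TRUE)
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = pr[, 1], gene_b = pr[, 2], weight = w)
  }
  all_pairs <- t(combn(nodes, 2))
  in_block <- vapply(seq_len(nrow(all_pairs)), function(i)
    any(vapply(blocks, function(b)
      all(all_pairs[i, ] %in% b), TRUE)), TRUE)
  bg_pairs <- all_pairs[!in_block, , drop = FALSE]
  keep <- runif(nrow(bg_pairs)) < bg_prob
  if (any(keep))
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = bg_pairs[keep, 1], gene_b = bg_pairs[keep, 2],
                 weight = bg_weight)
  list(net = as_frequency_network(do.call(rbind, edges), K = K),
       blocks = blocks)
}

# reduced-size simulation config for fast tests
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_datasets = 3,
                    platforms = c("continuous", "continuous", "counts"),
                    n_per_group = 20, n_genes = 400, markers_per_type = 20,
                    reg_size = 15, hk_size = 12, seed = seed, ...)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
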