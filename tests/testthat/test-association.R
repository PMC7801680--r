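test_that("eigengene closed forms: rank-1 modules and orientation", {
  set.seed(10)
  base <- rnorm(40)
  v <- rbind(a = base, b = base, c = base)
  colnames(v) <- sprintf("s%02d", 1:40)
  d <- make_dataset(v + 8, rep(c("disease", "control"), each = 20))
  eg <- module_eigengene(c("a", "b", "c"), d)
  expect_equal(eg$explained, 1, tolerance = 1e-12)
  expect_gte(cor(eg$score, base), 1 - 1e-9)   # oriented with the profile

  # two perfectly anticorrelated genes: explained 1, tie -> first gene +
  v2 <- rbind(a = base, b = -base)
  colnames(v2) <- colnames(v)
  d2 <- make_dataset(v2 + 8, rep(c("disease", "control"), each = 20))
  eg2 <- module_eigengene(c("a", "b"), d2)
  expect_equal(eg2$explained, 1, tolerance = 1e-12)
  expect_gt(cor(eg2$score, v2["a", ]), 0)

  # invariance to gene order and per-gene affine rescaling
  set.seed(11)
  d3 <- random_dataset(G = 8, n_d = 15, n_n = 15, seed = 11)
  g <- gene_ids(d3)[1:5]
  e1 <- module_eigengene(g, d3)$score
  d4 <- d3
  d4$values <- d3$values * rep(runif(8, 0.5, 2), 30) +
    rep(rnorm(8), 30)
  e2 <- module_eigengene(rev(g), d4)$score
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("random independent module explains ~1/m variance", {
  set.seed(12)
  v <- matrix(rnorm(10 * 200), 10,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("s%03d", 1:200)))
  d <- make_dataset(v, rep(c("disease", "control"), each = 100))
  eg <- module_eigengene(gene_ids(d), d)
  expect_lt(abs(eg$explained - 0.1), 0.05)
})

test_that("covariate_association: coefficients, Bonferroni family, ranking", {
  set.seed(13)
  n <- 30
  trait <- rnorm(n)
  scores <- cbind(m1 = exp(trait),        # monotone transform -> rho = 1
                  m2 = -trait,            # rho = -1
                  m3 = rnorm(n))
  covs <- cbind(cdr = trait)
  at <- covariate_association(scores, covs, method = "spearman")
  expect_equal(at$coef[at$row == "m1"], 1, tolerance = 1e-12)
  expect_equal(at$coef[at$row == "m2"], -1, tolerance = 1e-12)
  expect_equal(attr(at, "bonferroni_cutoff"), 0.05 / 3)
  # ranking by mean |coefficient|
  expect_true(at$rank[at$row == "m3"] == 3)

  # the 29 x 3 family reproduces the 5.7e-4 cutoff
  sc29 <- matrix(rnorm(10 * 29), 10, dimnames = list(NULL, paste0("m", 1:29)))
  cv3 <- matrix(rnorm(30), 10, dimnames = list(NULL, c("cdr", "bb", "pl")))
  at29 <- covariate_association(sc29, cv3, "spearman")
  expect_equal(attr(at29, "bonferroni_cutoff"), 0.05 / 87)
  expect_equal(attr(at29, "bonferroni_cutoff"), 5.7e-4, tolerance = 0.01)
  expect_error(covariate_association(sc29[1:2, ], cv3[1:2, ], "pearson"),
               "3 shared")
})

test_that("marker enrichment equals the exact combinatorial tail sum", {
  markers <- cell_type_markers(list(
    neu = sprintf("N%02d", 1:20), mic = sprintf("M%02d", 1:15),
    ast = sprintf("A%02d", 1:10), oli = sprintf("O%02d", 1:10),
    end = sprintf("E%02d", 1:5)))
  bg <- c(unlist(unclass(markers), use.names = FALSE),
          sprintf("B%03d", 1:140))  # universe 200
  exact_tail <- function(k, K, G, m)
    sum(vapply(k:min(K, m), function(x)
      choose(K, x) * choose(G - K, m - x), 1.0)) / choose(G, m)
  # sweep overlap configurations against the oracle
  for (k in c(0, 1, 3, 5, 8)) {
    mod <- c(sprintf("N%02d", seq_len(k)),
             sprintf("B%03d", seq_len(10 - k)))
    res <- marker_enrichment(mod, markers, bg)
    expect_equal(res$p[res$cell_type == "neu"],
                 exact_tail(k, 20, 200, 10), tolerance = 1e-12)
  }
  # module = exactly one marker set -> single-term tail
  res2 <- marker_enrichment(sprintf("E%02d", 1:5), markers, bg)
  expect_equal(res2$p[res2$cell_type == "end"],
               1 / choose(200, 5) * choose(195, 0) * choose(5, 5),
               tolerance = 1e-12)
  expect_identical(attr(res2, "assigned_type"), "end")
  # no overlap anywhere -> nothing assigned
  res3 <- marker_enrichment(sprintf("B%03d", 1:10), markers, bg)
  expect_true(is.na(attr(res3, "assigned_type")))
  expect_error(marker_enrichment(c("ZZZ"), markers, bg), "subset")
})

test_that("module_overlap computes Jaccard with shared flags", {
  A <- list(x = c("A", "B", "C"), y = c("P", "Q"))
  B <- list(u = c("B", "C", "D"), v = c("P", "Q"), w = c("Z"))
  J <- module_overlap(A, B)
  expect_equal(J["x", "u"], 0.5)
  expect_equal(J["y", "v"], 1)
  expect_equal(J["x", "w"], 0)
  shared <- attr(J, "shared")
  expect_setequal(shared$module_a, c("x", "y"))
})

test_that("hub_turnover is exact on hand-constructed networks", {
  # 100-node network with distinct degrees -> exactly 5 hubs
  set.seed(14)
  nodes <- sprintf("n%03d", 1:100)
  ed <- data.frame(gene_a = nodes[1:99], gene_b = nodes[2:100],
                   weight = seq(0.01, 0.99, length.out = 99))
  net <- as_frequency_network(ed, K = 5)
  hr_same <- hub_turnover(net, net)
  expect_length(hr_same$hubs_disease, 5)
  expect_length(hr_same$gained, 0)
  expect_length(hr_same$lost, 0)

  # toy pair: node X hub only in disease -> gained = {X}
  mk <- function(w_x, w_ab, w_cd) as_frequency_network(data.frame(
    gene_a = c("X", "X", "a", "c"),
    gene_b = c("a", "b", "b", "d"),
    weight = c(w_x, w_x, w_ab, w_cd)), K = 5)
  hr <- hub_turnover(mk(1.0, 0.5, 0.3), mk(0.1, 1.0, 1.0), pct = 40)
  expect_setequal(hr$hubs_disease, c("X", "a", "b"))
  expect_setequal(hr$hubs_control, c("a", "b"))
  expect_identical(hr$gained, "X")
  expect_length(hr$lost, 0)
  expect_length(intersect(hr$gained, hr$lost), 0)
})

test_that("connectivity split sign test has the closed-form extremes", {
  set.seed(15)
  d <- random_dataset(G = 10, n_d = 20, n_n = 20, seed = 15)
  props <- matrix(rnorm(40 * 5), 40,
                  dimnames = list(sample_ids(d), c("neu", "mic", "ast",
                                                   "oli", "end")))
  hubs <- gene_ids(d)[1:6]
  res <- connectivity_vs_proportion(d, hubs, props, "neu")
  expect_true(res$p > 0.001)  # null-ish construction rarely extreme
  expect_equal(res$n_higher + res$n_lower, nrow(res$connectivity) -
                 sum(res$connectivity$diff == 0))

  # constructed: low half perfectly correlated, high half independent
  n <- 20
  neu <- c(rep(-1, n), rep(1, n)) + rnorm(2 * n, 0, 0.01)
  base <- rnorm(n)
  vals <- rbind(
    do.call(rbind, lapply(1:6, function(i)
      c(base * 3 + rnorm(n, 0, 0.01), rnorm(n)))))
  rownames(vals) <- sprintf("h%02d", 1:6)
  colnames(vals) <- sprintf("s%03d", 1:(2 * n))
  dd <- make_dataset(vals, rep(c("disease", "control"), 2 * n / 2))
  pr <- matrix(0, 2 * n, 5,
               dimnames = list(colnames(vals),
                               c("neu", "mic", "ast", "oli", "end")))
  pr[, "neu"] <- neu
  res2 <- connectivity_vs_proportion(dd, rownames(vals), pr, "neu")
  expect_equal(res2$n_higher, 0)
  expect_equal(res2$p, 2 * 0.5^6, tolerance = 1e-12)
})

test_that("cross-region concordance closed forms", {
  # identical vectors across 4 regions -> 1
  v <- setNames(rnorm(30), sprintf("subj%03d", 1:30))
  expect_equal(cross_region_concordance(list(r1 = v, r2 = v, r3 = v,
                                             r4 = v)), 1, tolerance = 1e-12)
  # 2 regions with correlation r -> |r|
  set.seed(16)
  a <- setNames(rnorm(200), sprintf("subj%03d", 1:200))
  b <- setNames(0.6 * a + rnorm(200), names(a))
  expect_equal(cross_region_concordance(list(r1 = a, r2 = b)),
               abs(cor(a, b)), tolerance = 1e-12)
  # independent vectors, many subjects -> ~0
  sim <- simulate_matched_regions(5000, n_regions = 4, rho = 0, seed = 17)
  expect_lt(cross_region_concordance(sim), 0.05)
  # strongly concordant generator -> high CCI
  sim2 <- simulate_matched_regions(100, n_regions = 4, rho = 0.8, seed = 18)
  expect_gt(cross_region_concordance(sim2), 0.6)
  # unmatched subjects error by name
  bad <- list(r1 = a, r2 = b[-(1:3)])
  expect_error(cross_region_concordance(bad), "subj001")
})
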