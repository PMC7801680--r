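test_that("gene_t_score matches the Welch formula and flags degeneracy", {
  # identical groups -> 0
  expect_equal(gene_t_score(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # hand evaluation: D = (1,2,3), N = (4,5,6) -> 3 / sqrt(2/3)
  ts <- gene_t_score(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ts$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ts$t, 3.674235, tolerance = 1e-6)
  # both groups constant with unequal means -> undefined, flagged
  bad <- gene_t_score(c(5, 5, 5), c(7, 7, 7))
  expect_true(is.na(bad$t))
  expect_false(bad$defined)
  # equal constants -> t = 0
  expect_equal(gene_t_score(c(5, 5), c(5, 5))$t, 0)
  expect_error(gene_t_score(1, c(1, 2)), "at least 2")
})

test_that("module_de_score is the mean |t| over defined member genes", {
  v <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(2, 2, 2, 2, 2, 2))
  colnames(v) <- paste0("s", 1:6)
  d <- make_dataset(v, rep(c("disease", "control"), each = 3))
  t1 <- gene_t_score(c(1, 2, 3), c(4, 5, 6))$t
  expect_equal(module_de_score(c("g1", "g2"), d), t1 / 2, tolerance = 1e-12)
  expect_equal(module_de_score("g1", d), t1, tolerance = 1e-12)
  # identical group distributions -> 0
  v2 <- rbind(g1 = rep(c(1, 2, 3), 2), g2 = rep(c(9, 7, 8), 2))
  colnames(v2) <- paste0("s", 1:6)
  d2 <- make_dataset(v2, rep(c("disease", "control"), each = 3))
  expect_equal(module_de_score(c("g1", "g2"), d2), 0, tolerance = 1e-12)
  expect_error(module_de_score(c("g1", "nope"), d), "nope")
})

test_that("pair_dc evaluates the printed Fisher-z statistic", {
  # equal correlations -> 0
  expect_equal(pair_dc(0.5, 0.5, 10, 10)$Z, 0)
  # hand evaluation at r_N = 0.9, r_D = 0, n = 53/53
  pd <- pair_dc(0.9, 0, 53, 53)
  expect_equal(pd$z_N, 0.5 * log(19), tolerance = 1e-6)
  expect_equal(pd$Z, 0.5 * log(19) / 0.2, tolerance = 1e-5)
  expect_equal(pd$Z, 7.361126, tolerance = 1e-5)
  # sign symmetry: z(-0.9) = -z(0.9)
  pd2 <- pair_dc(-0.9, 0.9, 53, 53)
  expect_equal(pd2$Z, 2 * 0.5 * log(19) / 0.2, tolerance = 1e-5)
  expect_error(pair_dc(0.5, 0.5, 3, 10), "n > 3")
  expect_error(pair_dc(1.5, 0, 10, 10), "<= 1")
  # clamping keeps |r| = 1 finite
  expect_true(is.finite(pair_dc(1, -1, 10, 10)$Z))
})

test_that("module_dc_score is the RMS of pairwise Z (brute force agreement)", {
  set.seed(21)
  G <- 12; nd <- 9; nn <- 8
  v <- matrix(rnorm(G * (nd + nn)), G,
              dimnames = list(sprintf("g%02d", 1:G),
                              sprintf("s%02d", 1:(nd + nn))))
  d <- make_dataset(v, rep(c("disease", "control"), c(nd, nn)))
  genes <- sprintf("g%02d", 1:8)
  # independent brute-force oracle: explicit double loop over pairs
  zs <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    rd <- cor(v[genes[i], 1:nd], v[genes[j], 1:nd])
    rn <- cor(v[genes[i], nd + 1:nn], v[genes[j], nd + 1:nn])
    zn <- 0.5 * log(abs((1 + rn) / (1 - rn)))
    zd <- 0.5 * log(abs((1 + rd) / (1 - rd)))
    zs <- c(zs, abs(zn - zd) / sqrt(1 / (nn - 3) + 1 / (nd - 3)))
  }
  expect_equal(module_dc_score(genes, d), sqrt(mean(zs^2)),
               tolerance = 1e-12)
  expect_equal(module_dc_score(genes, d, aggregate = "mean"), mean(zs),
               tolerance = 1e-12)
  # RMS of {3, 4} = sqrt(25/2); single pair = |Z|
  expect_equal(sqrt(mean(c(3, 4)^2)), 3.535534, tolerance = 1e-6)
})

test_that("module_cci follows the leading-eigenvalue closed forms", {
  # all genes identical profiles -> 1
  base <- rnorm(30)
  v <- rbind(a = base, b = base, c = base)
  colnames(v) <- sprintf("s%02d", 1:30)
  expect_equal(module_cci(v), 1, tolerance = 1e-12)
  # 2-gene module -> |r|
  set.seed(5)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50)
  v2 <- rbind(a = x, b = y)
  colnames(v2) <- sprintf("s%02d", 1:50)
  expect_equal(module_cci(v2), abs(cor(x, y)), tolerance = 1e-12)
  v3 <- rbind(a = x, b = -y)
  colnames(v3) <- colnames(v2)
  expect_equal(module_cci(v3), abs(cor(x, y)), tolerance = 1e-12)
  # constant gene errors by name
  v4 <- rbind(a = x, flatgene = rep(1, 50))
  colnames(v4) <- colnames(v2)
  expect_error(module_cci(v4), "flatgene")
})

test_that("aggregate_and_classify uses strict median splits", {
  mk_scores <- function(de, dc) {
    do.call(rbind, lapply(seq_along(de), function(i)
      data.frame(module_id = paste0("M", i), dataset = "d1", n_genes = 10,
                 de_score = de[i], dc_score = dc[i],
                 cci_disease = 0.5, cci_control = 0.5)))
  }
  # medians: DE split 2.5, DC split 2.5
  tab <- aggregate_and_classify(mk_scores(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  expect_identical(tab$quadrant,
                   c("LDE_HDC", "LDE_HDC", "HDE_LDC", "HDE_LDC"))
  # all identical -> strict > classifies everything low
  tab2 <- aggregate_and_classify(mk_scores(rep(2, 3), rep(2, 3)))
  expect_identical(unique(tab2$quadrant), "LDE_LDC")
  # median across datasets: (1,2,9,2,2) -> 2
  s <- do.call(rbind, lapply(1:5, function(k)
    data.frame(module_id = "M1", dataset = paste0("d", k), n_genes = 10,
               de_score = c(1, 2, 9, 2, 2)[k], dc_score = 1,
               cci_disease = 0.5, cci_control = 0.4)))
  expect_equal(aggregate_and_classify(s)$median_de, 2)
})

test_that("DE and DC scores are invariant to label swap and permutations", {
  set.seed(31)
  d <- random_dataset(G = 15, n_d = 12, n_n = 10, seed = 31)
  genes <- gene_ids(d)[1:6]
  de <- module_de_score(genes, d)
  dc <- module_dc_score(genes, d)
  # swap condition labels
  swapped <- d
  swapped$condition <- factor(
    ifelse(d$condition == "disease", "control", "disease"),
    levels = c("disease", "control"))
  expect_equal(module_de_score(genes, swapped), de, tolerance = 1e-12)
  expect_equal(module_dc_score(genes, swapped), dc, tolerance = 1e-12)
  # permute genes within the module and samples within the dataset
  perm <- d
  sp <- sample(ncol(d$values))
  perm$values <- d$values[, sp]
  perm$condition <- d$condition[sp]
  expect_equal(module_de_score(rev(genes), perm), de, tolerance = 1e-12)
  expect_equal(module_dc_score(sample(genes), perm), dc, tolerance = 1e-12)
})

test_that("null DC calibration and decorrelation response", {
  # under the null the per-pair Z is |N(0,1)|, so the RMS module score ~ 1
  set.seed(77)
  n <- 50; m <- 10
  scores <- replicate(200, {
    v <- matrix(rnorm(m * 2 * n), m,
                dimnames = list(sprintf("g%02d", 1:m),
                                sprintf("s%03d", 1:(2 * n))))
    d <- make_dataset(v, rep(c("disease", "control"), each = n))
    module_dc_score(gene_ids(d), d)
  })
  expect_equal(mean(scores), 1, tolerance = 0.1)
  # planting decorrelation (control r = 0.7 -> disease r = 0) raises DC >= 3x
  set.seed(78)
  dc_pert <- replicate(20, {
    f <- rnorm(n)
    ctl <- sqrt(0.7) * matrix(f, m, n, byrow = TRUE) +
      sqrt(0.3) * matrix(rnorm(m * n), m, n)
    dis <- matrix(rnorm(m * n), m, n)
    v <- cbind(dis, ctl)
    dimnames(v) <- list(sprintf("g%02d", 1:m), sprintf("s%03d", 1:(2 * n)))
    d <- make_dataset(v, rep(c("disease", "control"), each = n))
    module_dc_score(gene_ids(d), d)
  })
  expect_gte(mean(dc_pert), 3 * mean(scores))
})

test_that("call_de_genes applies FC + FDR gates and the 2-dataset rule", {
  set.seed(55)
  G <- 40; n <- 20
  mk <- function(shift_genes, shift, name) {
    v <- matrix(rnorm(G * 2 * n, 8, 0.3), G,
                dimnames = list(sprintf("g%02d", 1:G),
                                sprintf("s%03d", 1:(2 * n))))
    v[shift_genes, 1:n] <- v[shift_genes, 1:n] + shift
    make_dataset(v, rep(c("disease", "control"), each = n), name = name)
  }
  # g01 strongly up in 3 datasets; g02 tiny shift everywhere; g03 up in 1
  d1 <- mk(c("g01", "g03"), 1.0, "d1")
  d2 <- mk("g01", 1.0, "d2")
  d3 <- mk("g01", 1.0, "d3")
  for (nm in c("d1", "d2", "d3")) NULL
  d1$values["g02", ] <- rnorm(2 * n, 8, 0.05) +
    rep(c(0.1, 0), each = n)  # below log2(1.2) ~ 0.263
  de <- call_de_genes(list(d1, d2, d3), fc = 1.2, fdr = 0.05,
                      min_datasets = 2)
  expect_identical(de$direction[de$gene_id == "g01"], "up")
  expect_identical(de$direction[de$gene_id == "g02"], "none")
  expect_identical(de$direction[de$gene_id == "g03"], "none")
  expect_equal(de$n_up[de$gene_id == "g01"], 3)
  # down direction symmetric
  d4 <- mk("g05", -1.0, "d4"); d5 <- mk("g05", -1.0, "d5")
  de2 <- call_de_genes(list(d4, d5), min_datasets = 2)
  expect_identical(de2$direction[de2$gene_id == "g05"], "down")
  # moderated variant returns the same obvious calls
  dem <- call_de_genes(list(d1, d2, d3), moderated = TRUE)
  expect_identical(dem$direction[dem$gene_id == "g01"], "up")
})

test_that("cci_condition_test is a paired t-test over datasets", {
  s <- do.call(rbind, lapply(1:5, function(k)
    data.frame(module_id = "M1", dataset = paste0("d", k), n_genes = 10,
               de_score = 1, dc_score = 1,
               cci_disease = c(0.7, 0.72, 0.69, 0.71, 0.7)[k],
               cci_control = c(0.4, 0.41, 0.39, 0.42, 0.4)[k])))
  res <- cci_condition_test(s)
  expect_equal(res$p,
               t.test(c(0.7, 0.72, 0.69, 0.71, 0.7) -
                        c(0.4, 0.41, 0.39, 0.42, 0.4))$p.value,
               tolerance = 1e-12)
  expect_gt(res$mean_diff, 0.25)
})
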