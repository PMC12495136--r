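test_that("genotype PCA matches an explicit eigendecomposition", {
  g <- toy_genotypes()
  pca <- genotype_pca(g, n_components = 3)
  M <- g$calls
  Mc <- sweep(M, 2, colMeans(M, na.rm = TRUE))
  Mc[is.na(Mc)] <- 0
  ev <- eigen(Mc %*% t(Mc), symmetric = TRUE)
  scores_o <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  expect_equal_up_to_sign(pca$scores, scores_o, tol = 1e-8)
  expect_true(all(diff(pca$var_explained) <= 1e-12))

  # duplicated individual -> identical scores
  g2 <- new_genotype_matrix(
    rbind(g$calls, g$calls[1, , drop = FALSE]),
    g$snp_meta,
    rbind(g$ind_meta, data.frame(id = "dup", population = "A")))
  p2 <- genotype_pca(g2, 2)
  expect_equal(unname(p2$scores[13, ]), unname(p2$scores[1, ]),
               tolerance = 1e-10)

  expect_warning(genotype_pca(g, n_components = 50), "rank")
})

test_that("k-means gene pools recover simulated discrete clusters", {
  land <- simulate_landscape(landscape_config(
    n_pops = 10, n_ind_per_pop = 12, n_snps = 200, frac_adaptive = 0,
    drift_fst = 0.35, admixture_gradient = FALSE, missing_rate = 0,
    seed = 31))
  pca <- genotype_pca(land$geno, 4)
  lab <- assign_gene_pools(pca$scores, K = 2, seed = 1)
  truth <- land$truth$gene_pool_labels[land$geno$ind_meta$population]
  agreement <- max(mean((lab == 1) == (truth == "west")),
                   mean((lab == 2) == (truth == "west")))
  expect_gte(agreement, 0.95)

  # PC1 separates the pools: silhouette-style check on PC1
  pc1 <- pca$scores[, 1]
  a <- pc1[truth == "west"]; b <- pc1[truth == "east"]
  gap <- abs(mean(a) - mean(b))
  expect_gt(gap / (sd(a) + sd(b)), 2)

  expect_identical(lab, assign_gene_pools(pca$scores, K = 2, seed = 1))
  expect_equal(assign_gene_pools(pca$scores, K = 1), rep(1L, 120))
  expect_error(assign_gene_pools(pca$scores[1:3, ], K = 5), "exceeds")
})

test_that("population-specific FST behaves at the null and extremes", {
  # one panmictic pool: |FST| small
  set.seed(55)
  p <- runif(2000, 0.1, 0.9)
  calls <- t(replicate(60, rbinom(2000, 2, p)))
  storage.mode(calls) <- "integer"
  g <- new_genotype_matrix(
    calls,
    data.frame(id = sprintf("s%d", 1:2000), contig = "c",
               position = 1:2000),
    data.frame(id = sprintf("i%d", 1:60),
               population = rep(c("A", "B", "C"), each = 20)))
  fst <- pop_specific_fst(g)
  expect_true(all(abs(fst) < 0.02))

  # a population fixed for private alleles is near-maximally differentiated
  calls2 <- rbind(matrix(0L, 10, 50), matrix(0L, 10, 50), matrix(2L, 10, 50))
  calls2[1:20, 1:25] <- 1L   # keep the shared pool polymorphic
  g2 <- new_genotype_matrix(
    calls2,
    data.frame(id = sprintf("s%d", 1:50), contig = "c", position = 1:50),
    data.frame(id = sprintf("i%d", 1:30),
               population = rep(c("A", "B", "C"), each = 10)))
  fst2 <- pop_specific_fst(g2)
  expect_gt(fst2[["C"]], 0.9)
})

test_that("FST matching proportions agree with hand arithmetic", {
  # 2 pops x 2 loci, counts small enough to work by hand
  calls <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 1L))
  g <- new_genotype_matrix(
    calls,
    data.frame(id = c("l1", "l2"), contig = "c", position = c(1L, 2L)),
    data.frame(id = sprintf("i%d", 1:4),
               population = c("A", "A", "B", "B")))
  got <- pop_specific_fst(g)
  oracle <- oracle_beta_fst(
    alt = rbind(A = c(1, 2), B = c(4, 3)),
    n2 = matrix(4, 2, 2))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
})

test_that("Jost's D spans its range and matches the corrected formula", {
  # identical allele frequencies everywhere -> no differentiation: the
  # per-locus estimates are non-positive (small-sample correction), the
  # multi-locus global is 0
  hwe <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))   # p = 0.5, 20 individuals
  g0 <- new_genotype_matrix(
    matrix(c(hwe, hwe), ncol = 1),
    data.frame(id = "l1", contig = "c", position = 1L),
    data.frame(id = sprintf("i%d", 1:40),
               population = rep(c("A", "B"), each = 20)))
  d0 <- josts_d(g0)
  expect_lte(unname(d0$per_locus), 0)
  expect_gt(unname(d0$per_locus), -0.05)
  expect_equal(unname(d0$per_locus),
               oracle_jost_locus(c(20, 20), c(20, 20), c(10, 10)),
               tolerance = 1e-12)
  expect_equal(d0$global, 0)

  # two populations fixed for different alleles -> pairwise D = 1
  calls1 <- rbind(matrix(0L, 6, 4), matrix(2L, 6, 4))
  g1 <- new_genotype_matrix(
    calls1,
    data.frame(id = sprintf("l%d", 1:4), contig = "c", position = 1:4),
    data.frame(id = sprintf("i%d", 1:12),
               population = rep(c("A", "B"), each = 6)))
  d1 <- josts_d(g1)
  expect_equal(unname(d1$pairwise["A", "B"]), 1, tolerance = 1e-12)

  # hand-checkable arithmetic case: p = 0.2 vs 0.8, n = 20 per population
  set.seed(7)
  mk <- function(p, n) {
    # exact genotype counts at HWE-rounded proportions
    nhom_alt <- round(n * p^2); nhet <- round(n * 2 * p * (1 - p))
    c(rep(2L, nhom_alt), rep(1L, nhet), rep(0L, n - nhom_alt - nhet))
  }
  ga <- mk(0.2, 20); gb <- mk(0.8, 20)
  g2 <- new_genotype_matrix(
    matrix(c(ga, gb), ncol = 1),
    data.frame(id = "l1", contig = "c", position = 1L),
    data.frame(id = sprintf("i%d", 1:40),
               population = rep(c("A", "B"), each = 20)))
  got <- josts_d(g2)
  want <- oracle_jost_locus(nind = c(20, 20),
                            alt = c(sum(ga), sum(gb)),
                            het = c(sum(ga == 1), sum(gb == 1)))
  expect_equal(unname(got$per_locus), want, tolerance = 1e-12)
  expect_gt(want, 0.5)
})

test_that("both differentiation indices track the drift parameter together", {
  fst_means <- c(); jost_means <- c()
  for (fst_gen in c(0.05, 0.15, 0.3)) {
    land <- simulate_landscape(landscape_config(
      n_pops = 8, n_ind_per_pop = 10, n_snps = 300, frac_adaptive = 0,
      drift_fst = fst_gen, missing_rate = 0, seed = 77))
    fst_means <- c(fst_means, mean(pop_specific_fst(land$geno)))
    jost_means <- c(jost_means,
                    mean(josts_d(land$geno, pairwise = FALSE)$per_locus))
  }
  expect_true(all(diff(fst_means) > 0))
  expect_true(all(diff(jost_means) > 0))
})

test_that("per-population FST and Jost's D rank populations alike", {
  rhos <- vapply(1:5, function(s) {
    land <- simulate_landscape(landscape_config(
      n_pops = 14, n_ind_per_pop = 10, n_snps = 600, frac_adaptive = 0,
      drift_fst = 0.15, missing_rate = 0, seed = 500 + s))
    fst <- pop_specific_fst(land$geno)
    jd <- josts_d(land$geno, stat = "mean")
    cor(fst, rowMeans(jd$pairwise)[names(fst)], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.8)
})
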