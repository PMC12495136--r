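toy_rda_inputs <- function(seed = 2, n = 6, m = 10, k = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, c("c1", "c2")[1:k]))
  Y <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("p%d", 1:n), sprintf("s%d", 1:m)))
  list(Y = Y, X = X)
}

test_that("rda_fit matches the brute-force ordination oracle", {
  d <- toy_rda_inputs()
  m <- rda_fit(d$Y, d$X)
  o <- oracle_rda(d$Y, d$X)
  expect_equal(m$total_R2, o$R2, tolerance = 1e-10)
  expect_equal(unname(m$eig), o$eig, tolerance = 1e-8)
  expect_equal_up_to_sign(m$site_scores, o$site_scores, tol = 1e-8)

  # partial model against the oracle with conditioning
  set.seed(5)
  Z <- matrix(rnorm(6), 6, 1)
  mp <- rda_fit(d$Y, d$X, condition = Z)
  op <- oracle_rda(d$Y, d$X, condition = Z)
  expect_equal(mp$total_R2, op$R2, tolerance = 1e-10)
  expect_equal(unname(mp$eig), op$eig, tolerance = 1e-8)
})

test_that("rda_fit agrees with vegan's constrained ordination", {
  d <- toy_rda_inputs(seed = 7, n = 12, m = 20)
  m <- rda_fit(d$Y, d$X)
  v <- vegan::rda(d$Y ~ d$X)
  expect_equal(m$total_R2,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-10)
  expect_equal(unname(m$eig), unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(m$adjusted_R2,
               vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-10)
})

test_that("rda_fit edge cases behave as defined", {
  d <- toy_rda_inputs(seed = 3, n = 8, m = 5)
  lin <- d$X %*% matrix(rnorm(2 * 5), 2, 5)
  colnames(lin) <- sprintf("s%d", 1:5)
  expect_equal(rda_fit(lin, d$X)$total_R2, 1, tolerance = 1e-10)

  # response orthogonal to the predictors by construction
  q <- qr.resid(qr(cbind(1, d$X)), matrix(rnorm(8 * 5), 8, 5))
  expect_lt(rda_fit(q, d$X)$total_R2, 1e-20)

  Xs <- cbind(d$X, dup = d$X[, 1])
  expect_error(rda_fit(d$Y, Xs), "collinear")
  expect_error(rda_fit(d$Y[1:3, ], d$X[1:3, ]), "more populations")
})

test_that("variance partition satisfies its algebraic identity", {
  set.seed(10)
  Y <- matrix(rnorm(15 * 25), 15, 25)
  cl <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("a", "b")))
  st <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("p1", "p2")))
  ge <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("m1", "m2")))
  vp <- variance_partition(Y, cl, st, ge, n_perm = 49, seed = 1)
  expect_equal(vp$R2_full, sum(vp$pure) + vp$confounded, tolerance = 1e-10)
  expect_equal(vp$unexplained, 1 - vp$R2_full, tolerance = 1e-12)
  expect_equal(sum(vp$relative), 1, tolerance = 1e-10)

  # with a single block the pure fraction is the full fraction
  vp1 <- variance_partition(Y, cl, NULL, NULL, n_perm = 49, seed = 1)
  expect_equal(vp1$R2_full, unname(vp1$pure["climate"]), tolerance = 1e-12)
  expect_equal(vp1$confounded, 0, tolerance = 1e-12)

  expect_error(variance_partition(Y[1:4, ], cl[1:4, ], st[1:4, ],
                                  ge[1:4, ], n_perm = 9),
               "below n_pops")
})

test_that("Mahalanobis outlier scan calibrates and flags displaced SNPs", {
  land <- small_landscape()
  af <- small_freqs()
  m <- rda_fit(af, land$clim_ref)
  out <- rda_outliers(m, K = 2, fdr = 0.1)
  expect_true(all(out$stats$q >= out$stats$p - 1e-12))
  expect_gt(out$gif, 0.3)
  expect_lt(out$gif, 3)

  # a grossly displaced loading is always flagged
  m2 <- m
  m2$snp_loadings[5, 1:2] <- colMeans(m$snp_loadings[, 1:2]) +
    10 * apply(m$snp_loadings[, 1:2], 2, sd)
  out2 <- rda_outliers(m2, K = 2, fdr = 0.1)
  expect_true(rownames(m2$snp_loadings)[5] %in% out2$candidates)

  # GIF of exact chi-squared distances is about 1
  set.seed(33)
  fake <- m
  # small correlations: the Fisher transform is near-identity there, so
  # the distances are essentially exact chi-squared draws
  fake$snp_loadings <- matrix(rnorm(4000, 0, 0.05), 2000, 2)
  rownames(fake$snp_loadings) <- sprintf("x%d", 1:2000)
  expect_equal(rda_outliers(fake, K = 2, fdr = 0.1)$gif, 1,
               tolerance = 0.12)

  expect_error(rda_outliers(m, K = 0), "K must be")
})

test_that("the latent-factor scan reduces to OLS and matches ridge algebra", {
  d <- toy_rda_inputs(seed = 12, n = 14, m = 12)
  # K_latent = 0, ridge = 0: per-SNP OLS t statistics
  fit <- lfmm_ridge(d$Y, d$X, K_latent = 0, ridge = 0)
  for (j in c(1, 5, 12)) {
    ols <- summary(lm(d$Y[, j] ~ d$X))$coefficients
    expect_equal(unname(fit$z[, j]),
                 unname(ols[2:3, "t value"]), tolerance = 1e-8)
  }

  # ridge solution equals the longhand normal equations
  fit2 <- lfmm_ridge(d$Y, d$X, K_latent = 2, ridge = 0.7)
  W <- cbind(scale(d$X), fit2$latent)
  Bo <- oracle_ridge(d$Y, W, 0.7)
  expect_equal(unname(fit2$effects), unname(Bo[1:2, ]), tolerance = 1e-8)

  expect_error(lfmm_ridge(d$Y, d$X, K_latent = 14), "K_latent")
})

test_that("forest importance ranks deterministic signals first", {
  set.seed(3)
  n <- 24
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- cbind(sig = plogis(2 * X[, "a"]),
             matrix(rnorm(n * 19, 0.5, 0.05), n, 19))
  colnames(Y) <- c("sig", sprintf("n%d", 1:19))
  gf <- gf_importance(Y, X, n_trees = 100, n_runs = 1, top_frac = 0.05,
                      seed = 4)
  expect_equal(names(which.max(gf$importance)), "sig")
  # n_runs = 1: candidates are exactly the positive top-5% set
  n_top <- ceiling(0.05 * ncol(Y))
  ord <- names(sort(gf$importance, decreasing = TRUE))[1:n_top]
  expect_setequal(gf$candidates, ord)

  # constant SNP: zero importance, never a candidate
  Y2 <- cbind(Y, flat = rep(0.3, n))
  gf2 <- gf_importance(Y2, X, n_trees = 50, n_runs = 2, seed = 5)
  expect_equal(unname(gf2$importance["flat"]), 0)
  expect_false("flat" %in% gf2$candidates)
})

test_that("pure-noise SNPs have near-zero mean forest importance", {
  set.seed(14)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  imp <- c()
  for (s in 1:10) {
    set.seed(s)
    Y <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, sprintf("s%d", 1:5)))
    imp <- c(imp, gf_importance(Y, X, n_trees = 60, n_runs = 1,
                                seed = s)$importance)
  }
  expect_lt(mean(imp), 0.08)
})

test_that("consensus counting matches brute force", {
  expect_equal(consensus_candidates(list(c("A", "B"), c("B", "C"), "D"), 2),
               "B")
  sets <- list(c("A", "B"), c("B", "C"), "D")
  expect_setequal(consensus_candidates(sets, 1), c("A", "B", "C", "D"))

  set.seed(9)
  ids <- sprintf("s%04d", 1:1000)
  five <- lapply(1:5, function(i) sample(ids, 150))
  got <- consensus_candidates(five, 2)
  counts <- table(unlist(five))
  expect_setequal(got, names(counts)[counts >= 2])
})

test_that("matched random sets reproduce the target MAF distribution", {
  set.seed(21)
  maf <- setNames(runif(800, 0.02, 0.5), sprintf("s%d", 1:800))
  target <- sample(names(maf), 60)
  exclude <- union(target, sample(setdiff(names(maf), target), 100))
  rs <- matched_random_set(maf, exclude, target, n_bins = 10, seed = 3)
  expect_length(rs, 60)
  expect_length(intersect(rs, exclude), 0)
  breaks <- seq(min(maf) - 1e-9, max(maf) + 1e-9, length.out = 11)
  expect_equal(as.vector(table(cut(maf[rs], breaks))),
               as.vector(table(cut(maf[target], breaks))))
  # two-sample KS distance bounded by the bin width scale
  ks <- suppressWarnings(stats::ks.test(maf[rs], maf[target])$statistic)
  expect_lt(unname(ks), 0.15)

  expect_identical(matched_random_set(maf, exclude, character(0)),
                   character(0))
})
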