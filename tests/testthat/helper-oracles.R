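# Brute-force reference implementations, kept independent of the package
# internals: different primitives (explicit normal equations, eigen instead
# of svd, scalar loops) computing the same defined quantities.

# constrained ordination by explicit normal equations + eigendecomposition
oracle_rda <- function(Y, X, condition = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Xs <- apply(X, 2, function(c) (c - mean(c)) / sd(c))
  Yc <- apply(Y, 2, function(c) c - mean(c))
  tot <- sum(Yc^2)
  if (!is.null(condition)) {
    Z <- apply(as.matrix(condition), 2, function(c) c - mean(c))
    P <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
    Yc_r <- Yc - P %*% Yc
    Xs <- Xs - P %*% Xs
  } else Yc_r <- Yc
  B <- solve(t(Xs) %*% Xs) %*% t(Xs) %*% Yc_r
  Yhat <- Xs %*% B
  ec <- eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-9
  list(R2 = sum(Yhat^2) / tot,
       eig = ec$values[keep],
       site_scores = Yhat %*% ec$vectors[, keep, drop = FALSE],
       axes = ec$vectors[, keep, drop = FALSE],
       B = B, Yc = Yc_r)
}

# weighted score-distance offset computed from first principles
oracle_rda_offset <- function(Y, X, clim_ref, clim_fut, K) {
  o <- oracle_rda(Y, X)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  stdz <- function(C) sweep(sweep(as.matrix(C), 2, ctr), 2, scl, "/")
  proj <- function(C) stdz(C) %*% o$B %*% o$axes[, 1:K, drop = FALSE]
  w <- o$eig[1:K] / sum(o$eig[1:K])
  d <- (proj(clim_ref) - proj(clim_fut)) %*% diag(w, K)
  sqrt(rowSums(d^2))
}

oracle_gdi <- function(Y, X, K) {
  o <- oracle_rda(Y, X)
  obs <- o$Yc %*% o$axes[, 1:K, drop = FALSE]
  pred <- o$site_scores[, 1:K, drop = FALSE]
  w <- o$eig[1:K] / sum(o$eig[1:K])
  sqrt(rowSums(((obs - pred) %*% diag(w, K))^2))
}

# ridge normal equations written out longhand
oracle_ridge <- function(Y, W, lambda) {
  solve(t(W) %*% W + diag(lambda, ncol(W))) %*% t(W) %*%
    apply(Y, 2, function(c) c - mean(c))
}

# Nei-Chesser-corrected Jost's D for one locus from raw per-pop counts
# (n individuals, alt-allele count, het count), scalar arithmetic
oracle_jost_locus <- function(nind, alt, het) {
  k <- length(nind)
  p <- alt / (2 * nind)
  ho <- het / nind
  nh <- k / sum(1 / nind)
  hs_raw <- mean(1 - p^2 - (1 - p)^2)
  hs <- nh / (nh - 1) * (hs_raw - mean(ho) / (2 * nh))
  pbar <- mean(p)
  ht <- (1 - pbar^2 - (1 - pbar)^2) + hs / (nh * k) - mean(ho) / (2 * nh * k)
  (ht - hs) / (1 - hs) * k / (k - 1)
}

# Weir-Goudet beta for 2 populations x L loci from allele counts
oracle_beta_fst <- function(alt, n2) {
  p <- alt / n2
  Mw <- (alt * (alt - 1) + (n2 - alt) * (n2 - alt - 1)) / (n2 * (n2 - 1))
  Mb <- p[1, ] * p[2, ] + (1 - p[1, ]) * (1 - p[2, ])
  apply(Mw, 1, function(mwi) sum(mwi - Mb) / sum(1 - Mb))
}

# greedy within-contig pruning by exhaustive pair checks
oracle_ld_prune <- function(calls, meta, r2_max) {
  kept <- character(0)
  for (ctg in unique(meta$contig)) {
    ids <- meta$id[meta$contig == ctg][order(meta$position[meta$contig == ctg])]
    for (id in ids) {
      ok <- TRUE
      for (kid in intersect(kept, ids)) {
        both <- !is.na(calls[, id]) & !is.na(calls[, kid])
        if (sum(both) >= 3 &&
            !is.na(cor(calls[both, id], calls[both, kid])) &&
            cor(calls[both, id], calls[both, kid])^2 >= r2_max) {
          ok <- FALSE; break
        }
      }
      if (ok) kept <- c(kept, id)
    }
  }
  kept
}

expect_equal_up_to_sign <- function(A, B, tol = 1e-8) {
  A <- as.matrix(A); B <- as.matrix(B)
  expect_equal(dim(A), dim(B))
  for (k in seq_len(ncol(A))) {
    s <- sign(sum(A[, k] * B[, k]))
    if (s == 0) s <- 1
    expect_equal(unname(A[, k]), unname(s * B[, k]), tolerance = tol)
  }
}
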