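#' Fit a (partial) redundancy analysis of allele frequencies on predictors
#'
#' Constrained ordination by explicit least squares: the column-centered
#' response is regressed on the (internally standardized) predictors, and
#' the constrained axes are the singular vectors of the fitted values. With
#' `condition`, both response and predictors are first residualized on the
#' conditioning covariates (partial RDA); the reported R-squared is then the
#' semipartial fraction of the *total* variance of the original response,
#' so that variance-partition components are comparable across models.
#'
#' @param Y Populations x SNPs allele-frequency matrix (or an
#'   `allele_freq_matrix`).
#' @param X Populations x predictors matrix/data.frame.
#' @param condition Optional populations x covariates matrix partialled out.
#' @return An object of class `rda_model`: coefficients `B` (predictors x
#'   SNPs), `site_scores` (populations x K), `snp_loadings` (SNPs x K,
#'   correlations of the centered SNP columns with the axis scores),
#'   `axis_coef`
#'   (predictors x K, for climate-only score prediction), eigenvalues
#'   `eig` (descending), `K_retained`, `total_R2`, `adjusted_R2`, and the
#'   training centering/scaling needed to project new climates.
#' @export
rda_fit <- function(Y, X, condition = NULL) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y)
  n_cond <- if (is.null(condition)) 0 else ncol(as.matrix(condition))
  if (n <= ncol(X) + n_cond + 1)
    stop("need more populations than predictors + conditioning variables + 1")
  xs <- std_fit(X)
  Xs <- std_apply(X, xs)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  tot_ss <- sum(Yc^2)
  Yr <- Yc; Xr <- Xs
  if (!is.null(condition)) {
    Z <- scale(as.matrix(condition), scale = FALSE)
    qz <- qr(Z)
    Yr <- qr.resid(qz, Yc)
    Xr <- qr.resid(qz, Xs)
  }
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr))
    stop("predictors are collinear (singular cross-product); ",
         "prune them first, e.g. with prune_vif()")
  B <- qr.coef(qx, Yr)
  Yhat <- Xr %*% B
  sv <- svd(Yhat)
  r <- sum(sv$d > max(sv$d) * 1e-9)
  r <- max(r, 1L)
  d <- sv$d[seq_len(r)]
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  eig <- d^2 / (n - 1)
  R2 <- sum(d^2) / tot_ss
  k <- ncol(Xs)
  # loadings as correlations of the (residualized) SNP columns with the
  # axis scores: per-SNP scale is divided out, which homogenizes the null
  # loading cloud across allele-frequency spectra (monomorphic SNPs get 0)
  loadings <- suppressWarnings(cor(Yr, U))
  loadings[!is.finite(loadings)] <- 0
  out <- list(B = B, V = V,
              axis_coef = B %*% V,
              site_scores = U %*% diag(d, r),
              snp_loadings = loadings,
              eig = eig, K_retained = r,
              total_R2 = R2,
              adjusted_R2 = adj_r2(R2, n, k + n_cond),
              x_std = xs, y_center = y_center,
              predictors = colnames(Xs), n = n,
              conditioned = !is.null(condition))
  rownames(out$site_scores) <- rownames(Y)
  colnames(out$site_scores) <- colnames(out$axis_coef) <-
    colnames(out$snp_loadings) <- sprintf("RDA%d", seq_len(r))
  class(out) <- "rda_model"
  out
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: %d populations, %d SNPs, %d predictors%s\n",
              x$n, nrow(x$snp_loadings), length(x$predictors),
              if (x$conditioned) " (partial)" else ""))
  cat(sprintf("  R2 = %.4f (adjusted %.4f), %d constrained axes\n",
              x$total_R2, x$adjusted_R2, x$K_retained))
  invisible(x)
}

# predicted axis scores from climate alone, in the model's standardization
predict_scores <- function(model, clim, K) {
  clim <- as.matrix(clim)
  miss <- setdiff(model$predictors, colnames(clim))
  if (length(miss) > 0)
    stop("climate table lacks model variable(s): ",
         paste(miss, collapse = ", "))
  Cs <- std_apply(clim[, model$predictors, drop = FALSE], model$x_std)
  Cs %*% model$axis_coef[, seq_len(K), drop = FALSE]
}

# permutation p-value for the (semipartial) contribution of block X given Z
perm_block_p <- function(Yc, X, Z, tot_ss, n_perm, n) {
  Xr <- if (is.null(Z)) scale(X, scale = FALSE) else
    qr.resid(qr(scale(Z, scale = FALSE)), scale(X, scale = FALSE))
  Yr <- if (is.null(Z)) Yc else qr.resid(qr(scale(Z, scale = FALSE)), Yc)
  r2_of <- function(Xb) {
    f <- qr.fitted(qr(Xb), Yr)
    sum(f^2) / tot_ss
  }
  obs <- r2_of(Xr)
  perm <- vapply(seq_len(n_perm), function(b)
    r2_of(Xr[sample(n), , drop = FALSE]), numeric(1))
  list(r2 = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Partition genetic variance among climate, structure and geography
#'
#' Fits the full redundancy model on all three predictor blocks and the
#' three partial models in which one block is conditioned on the other two,
#' yielding the pure (semipartial) fractions; the confounded fraction is the
#' remainder of the full R-squared. Permutation p-values permute the rows of
#' the tested block after residualization on the conditioning blocks.
#'
#' @param Y Populations x SNPs allele-frequency matrix.
#' @param climate,structure_pcs,geography_dbmems Predictor blocks (matrix or
#'   NULL for an absent block).
#' @param n_perm Permutations for the p-values (default 999).
#' @param seed Integer seed.
#' @return Object of class `variance_partition`: a `table` data.frame in
#'   the usual partition layout (component, R2, relative fraction, p) plus
#'   the individual fractions.
#' @export
variance_partition <- function(Y, climate, structure_pcs = NULL,
                               geography_dbmems = NULL, n_perm = 999,
                               seed = 1) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y)
  n <- nrow(Y)
  blocks <- Filter(Negate(is.null),
                   list(climate = climate, structure = structure_pcs,
                        geography = geography_dbmems))
  blocks <- lapply(blocks, as.matrix)
  k_tot <- sum(vapply(blocks, ncol, integer(1)))
  if (k_tot >= n - 1)
    stop("combined predictor count must be below n_pops - 1")
  Yc <- scale(Y, scale = FALSE)
  tot_ss <- sum(Yc^2)
  set.seed(seed)
  Xall <- do.call(cbind, blocks)
  full <- perm_block_p(Yc, Xall, NULL, tot_ss, n_perm, n)
  pure <- lapply(names(blocks), function(b) {
    others <- do.call(cbind, blocks[setdiff(names(blocks), b)])
    perm_block_p(Yc, blocks[[b]], others, tot_ss, n_perm, n)
  })
  names(pure) <- names(blocks)
  pure_r2 <- vapply(pure, `[[`, numeric(1), "r2")
  confounded <- full$r2 - sum(pure_r2)
  unexplained <- 1 - full$r2
  rel <- c(pure_r2, confounded = confounded) / full$r2
  tab <- data.frame(
    component = c("full", paste0("pure_", names(blocks)), "confounded",
                  "unexplained"),
    R2 = c(full$r2, pure_r2, confounded, unexplained),
    relative = c(1, rel, NA),
    p = c(full$p, vapply(pure, `[[`, numeric(1), "p"), NA, NA),
    row.names = NULL)
  structure(list(table = tab, R2_full = full$r2,
                 pure = pure_r2, confounded = confounded,
                 unexplained = unexplained, relative = rel),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}

#' Mahalanobis outlier detection on RDA loadings
#'
#' Computes the Mahalanobis distance of every SNP's K-axis loading vector
#' from the center and covariance of the loading cloud, recalibrates the
#' distances by the genomic inflation factor (median distance over the
#' chi-squared median with K degrees of freedom), converts to upper-tail
#' chi-squared p-values and Benjamini-Hochberg q-values, and flags SNPs at
#' the requested false discovery rate. The correlation loadings are
#' variance-stabilized (Fisher z) first: this homogenizes the null cloud
#' across the allele-frequency spectrum while keeping strongly clinal
#' loci unbounded, which is what keeps the scan calibrated under drift
#' and powerful under selection.
#'
#' @param model An `rda_model`.
#' @param K Number of leading axes (default 2).
#' @param fdr q-value threshold (default 0.10).
#' @return List: `stats` (data.frame snp, D2, p, q), `gif`, `candidates`.
#' @export
rda_outliers <- function(model, K = 2, fdr = 0.10) {
  stopifnot(inherits(model, "rda_model"), fdr > 0, fdr < 1)
  if (K < 1) stop("K must be >= 1")
  K <- min(K, model$K_retained)
  L <- model$snp_loadings[, seq_len(K), drop = FALSE]
  L <- atanh(pmin(pmax(L, -0.9999), 0.9999))
  D2 <- mahalanobis(L, colMeans(L), cov(L))
  gif <- median(D2) / qchisq(0.5, K)
  p <- pchisq(D2 / gif, df = K, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  snp <- rownames(L) %||% sprintf("snp%d", seq_along(D2))
  list(stats = data.frame(snp = snp, D2 = D2, p = p, q = q,
                          row.names = NULL),
       gif = gif, candidates = snp[q <= fdr])
}

#' Latent-factor ridge association scan
#'
#' Per-SNP linear association between allele frequencies and climate with
#' unobserved structure absorbed by latent factors: the factors are the
#' leading left singular vectors of the residual of the response on climate,
#' then climate effects are re-estimated jointly with the factors by (ridge)
#' least squares. Per-variable t-ratios are recalibrated by the genomic
#' inflation factor, converted to F(1, df) p-values, and adjusted by
#' Benjamini-Hochberg jointly over the whole SNP-by-variable test family
#' (so the FDR level applies to the candidate list as a whole, not per
#' variable); a SNP is a candidate when any climate variable reaches
#' `q <= fdr`. With `K_latent = 0` and `ridge = 0` the statistics reduce
#' to ordinary per-SNP least-squares t-tests.
#'
#' @param Y Populations x SNPs allele-frequency matrix.
#' @param X Populations x variables climate matrix.
#' @param K_latent Number of latent factors (default 2).
#' @param ridge Ridge penalty added to the normal equations (default 0).
#' @param fdr q-value threshold (default 0.10).
#' @return List: `effects` (climate x SNPs), `z`, `p`, `q` (same shape),
#'   `gif` per variable, `latent` (factor scores), `candidates`.
#' @export
lfmm_ridge <- function(Y, X, K_latent = 2, ridge = 0, fdr = 0.10) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (K_latent >= min(dim(Y)))
    stop("K_latent must be below min(n_pops, n_snps)")
  Xs <- scale(X)
  Yc <- scale(Y, scale = FALSE)
  U <- NULL
  if (K_latent > 0) {
    R <- qr.resid(qr(Xs), Yc)
    U <- svd(R)$u[, seq_len(K_latent), drop = FALSE]
    colnames(U) <- sprintf("LF%d", seq_len(K_latent))
  }
  W <- cbind(Xs, U)
  A <- crossprod(W) + diag(ridge, ncol(W))
  Ainv <- solve(A)
  B <- Ainv %*% crossprod(W, Yc)
  resid <- Yc - W %*% B
  df <- n - ncol(W) - 1
  if (df < 1) stop("not enough populations for the requested model")
  sigma2 <- colSums(resid^2) / df
  Vb <- Ainv %*% crossprod(W) %*% Ainv     # = Ainv when ridge = 0
  se2_unit <- diag(Vb)[seq_len(ncol(Xs))]
  b_clim <- B[seq_len(ncol(Xs)), , drop = FALSE]
  z <- b_clim / sqrt(outer(se2_unit, sigma2))
  # a monomorphic (constant-frequency) SNP carries no evidence
  z[, sigma2 < .Machine$double.eps] <- 0
  gif <- apply(z, 1, function(zr) median(zr^2) / qchisq(0.5, 1))
  z2_cal <- sweep(z^2, 1, gif, "/")
  # the statistics are t-ratios on df residual degrees of freedom, so the
  # squared statistics are compared to F(1, df) rather than chi-squared
  p <- pf(z2_cal, 1, df, lower.tail = FALSE)
  q <- matrix(p.adjust(p, method = "BH"), nrow(p), ncol(p))
  snp <- colnames(Y) %||% sprintf("snp%d", seq_len(ncol(Y)))
  dimnames(z) <- dimnames(p) <- dimnames(q) <-
    list(colnames(Xs), snp)
  list(effects = b_clim, z = z, p = p, q = q, gif = gif, latent = U,
       candidates = snp[apply(q <= fdr, 2, any)])
}

#' Remove latent-factor structure from an allele-frequency matrix
#'
#' Residualizes the centered response on the latent factors estimated as in
#' [lfmm_ridge()]; used to build the structure-corrected input of the
#' forest-based scan.
#'
#' @inheritParams lfmm_ridge
#' @return Corrected matrix of the same shape as `Y`.
#' @export
lfmm_correct <- function(Y, X, K_latent = 2) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y)
  fit <- lfmm_ridge(Y, X, K_latent = K_latent)
  if (is.null(fit$latent)) return(scale(Y, scale = FALSE))
  out <- qr.resid(qr(fit$latent), scale(Y, scale = FALSE))
  dimnames(out) <- dimnames(Y)
  out
}

#' Per-SNP random-forest importance scan
#'
#' Fits one regression forest of allele frequency on climate per SNP;
#' importance is the out-of-bag R-squared (non-positive values truncated to
#' zero). Candidates are the SNPs in the top `top_frac` importance set of
#' every one of `n_runs` independently seeded runs. With `correct = TRUE`
#' the response matrix is first residualized on latent factors
#' ([lfmm_correct()]).
#'
#' @param Y Populations x SNPs allele-frequency matrix.
#' @param X Populations x variables climate matrix.
#' @param n_trees Trees per forest (default 100; the row dimension is the
#'   number of populations, so small forests stabilize quickly).
#' @param n_runs Independent runs intersected for candidates (default 5).
#' @param top_frac Fraction of top-importance SNPs per run (default 0.05).
#' @param correct Residualize on latent factors first (default FALSE).
#' @param K_latent Latent factors used when `correct = TRUE`.
#' @param seed Integer seed; run r uses `seed + r`.
#' @return List: `importance` (mean OOB R-squared per SNP),
#'   `var_importance` (SNPs x variables, impurity importance rescaled to the
#'   SNP's R-squared), `candidates`, `runs` (per-run top sets).
#' @export
gf_importance <- function(Y, X, n_trees = 100, n_runs = 5, top_frac = 0.05,
                          correct = FALSE, K_latent = 2, seed = 1) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y); X <- as.data.frame(as.matrix(X))
  stopifnot(n_runs >= 1, top_frac > 0, top_frac <= 1)
  if (correct) Y <- lfmm_correct(Y, X, K_latent = K_latent)
  snp <- colnames(Y) %||% sprintf("snp%d", seq_len(ncol(Y)))
  imp_runs <- matrix(0, ncol(Y), n_runs, dimnames = list(snp, NULL))
  var_imp <- matrix(0, ncol(Y), ncol(X),
                    dimnames = list(snp, colnames(X)))
  top_sets <- vector("list", n_runs)
  n_top <- ceiling(top_frac * ncol(Y))
  for (r in seq_len(n_runs)) {
    for (j in seq_len(ncol(Y))) {
      y <- Y[, j]
      vy <- var(y)
      if (vy < .Machine$double.eps) next   # constant SNP: importance 0
      fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                            importance = "impurity",
                            seed = seed + r * 1000L + j,
                            num.threads = 1)
      r2 <- max(0, 1 - fit$prediction.error / vy)
      imp_runs[j, r] <- r2
      vi <- fit$variable.importance
      if (r2 > 0 && sum(vi) > 0)
        var_imp[j, ] <- var_imp[j, ] + r2 * vi / sum(vi) / n_runs
    }
    ord <- order(imp_runs[, r], decreasing = TRUE)
    top_sets[[r]] <- snp[ord[seq_len(n_top)]][imp_runs[ord[seq_len(n_top)], r] > 0]
  }
  list(importance = rowMeans(imp_runs),
       var_importance = var_imp,
       candidates = Reduce(intersect, top_sets),
       runs = top_sets)
}

#' Consensus candidate set across association methods
#'
#' @param per_method_sets Named list of candidate id vectors.
#' @param min_methods Minimum number of methods (default 2).
#' @return Character vector of ids found by at least `min_methods` methods.
#' @export
consensus_candidates <- function(per_method_sets, min_methods = 2) {
  stopifnot(length(per_method_sets) >= 2)
  counts <- table(unlist(lapply(per_method_sets, unique)))
  sort(names(counts)[counts >= min_methods])
}

#' Frequency-matched random SNP set
#'
#' Draws, without replacement, a control set of non-candidate SNPs whose
#' minor-allele-frequency distribution matches the target (outlier) set:
#' target SNPs are binned into `n_bins` equal-width MAF bins and the same
#' count per bin is sampled from the eligible SNPs. A bin without enough
#' eligible SNPs is widened by merging with its neighbours (with a message)
#' before sampling.
#'
#' @param maf Named per-SNP mean minor-allele frequency.
#' @param exclude Ids never eligible (typically the union of all methods'
#'   candidates).
#' @param target Ids of the set whose MAF distribution is matched.
#' @param n_bins Number of equal-width bins (default 10).
#' @param seed Integer seed.
#' @return Character vector of sampled ids, of length `length(target)`.
#' @export
matched_random_set <- function(maf, exclude, target, n_bins = 10, seed = 1) {
  if (length(target) == 0) return(character(0))
  stopifnot(!is.null(names(maf)), all(target %in% names(maf)))
  eligible <- setdiff(names(maf), union(exclude, target))
  if (length(eligible) < length(target))
    stop("not enough non-candidate SNPs to match the target set")
  set.seed(seed)
  rng <- range(maf)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  tbin <- cut(maf[target], breaks)
  ebin <- cut(maf[eligible], breaks)
  out <- character(0)
  need <- table(tbin)
  for (b in names(need)) {
    if (need[[b]] == 0) next
    pool <- eligible[ebin == b & !eligible %in% out]
    width <- 1L
    while (length(pool) < need[[b]] && width < n_bins) {
      # widen: include neighbouring bins
      bi <- match(b, levels(tbin))
      nb <- levels(tbin)[max(1, bi - width):min(n_bins, bi + width)]
      pool <- eligible[ebin %in% nb & !eligible %in% out]
      width <- width + 1L
      message("matched_random_set: widening MAF bin ", b)
    }
    if (length(pool) < need[[b]])
      stop("cannot match MAF distribution: bin ", b, " exhausted")
    out <- c(out, sample(pool, need[[b]]))
  }
  sort(out)
}
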