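# multivariate R^2 of a centered response matrix on predictors
# (the RDA constrained proportion): R^2 = tr(Yhat'Yhat) / tr(Yc'Yc)
multiv_r2 <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  qr_x <- qr(Xc)
  Yhat <- qr.fitted(qr_x, Yc)
  sum(Yhat^2) / sum(Yc^2)
}

adj_r2 <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)

#' Permutation-based forward selection of climate predictors
#'
#' Iteratively adds the variable that maximizes the adjusted R-squared of
#' the multivariate regression (RDA) of the allele-frequency matrix on the
#' kept set. A candidate is admitted only if the permutation p-value of its
#' marginal contribution (partial pseudo-F, candidate rows permuted) is at
#' most `alpha`. Selection stops when no candidate passes, or when the
#' adjusted R-squared of the kept set exceeds that of the full model on all
#' candidates (the global stopping rule of forward selection in constrained
#' ordination). Variables are standardized internally, so selection is
#' invariant to affine rescaling.
#'
#' @param Y Populations x SNPs allele-frequency matrix (or
#'   `allele_freq_matrix`).
#' @param X Populations x variables climate matrix/data.frame.
#' @param alpha Admission p-value threshold (default 0.05).
#' @param n_perm Number of permutations (default 1000, minimum 99).
#' @param seed Integer seed for the permutations.
#' @return A list of class `selection_report`: `kept` (ordered), `dropped`
#'   (variable, rule, statistic), `pvalues` per admitted step, `adj_r2`
#'   path.
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_perm = 1000, seed = 1) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  stopifnot(n_perm >= 99, nrow(Y) == nrow(X))
  X <- scale(as.matrix(X))
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  vars <- colnames(X)
  set.seed(seed)
  full_adj <- adj_r2(multiv_r2(Yc, X), n, ncol(X))
  kept <- character(0); pvals <- numeric(0); path <- numeric(0)
  dropped <- data.frame(variable = character(), rule = character(),
                        statistic = numeric())
  repeat {
    cand <- setdiff(vars, kept)
    if (length(cand) == 0) break
    if (n < length(kept) + 3) {
      warning("fewer populations than kept variables + 2; stopping")
      break
    }
    r2_kept <- if (length(kept)) multiv_r2(Yc, X[, kept, drop = FALSE]) else 0
    r2_cand <- vapply(cand, function(v)
      multiv_r2(Yc, X[, c(kept, v), drop = FALSE]), numeric(1))
    best <- cand[which.max(adj_r2(r2_cand, n, length(kept) + 1))]
    k_full <- length(kept) + 1
    pseudo_f <- function(r2_full, r2_red)
      (r2_full - r2_red) / ((1 - r2_full) / (n - k_full - 1))
    f_obs <- pseudo_f(r2_cand[best], r2_kept)
    f_perm <- vapply(seq_len(n_perm), function(b) {
      Xp <- X[, c(kept, best), drop = FALSE]
      Xp[, best] <- Xp[sample(n), best]
      pseudo_f(multiv_r2(Yc, Xp), r2_kept)
    }, numeric(1))
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
    adj_new <- adj_r2(r2_cand[best], n, k_full)
    if (p > alpha) {
      dropped <- rbind(dropped, data.frame(
        variable = best, rule = sprintf("permutation p > %g", alpha),
        statistic = p))
      break
    }
    # global stopping rule: never exceed the full model's adjusted R^2
    # (bypassed at alpha = 1, where the caller wants the full ordering)
    if (adj_new > full_adj && alpha < 1) break
    kept <- c(kept, best)
    pvals <- c(pvals, p); path <- c(path, adj_new)
  }
  structure(list(kept = kept, dropped = dropped, pvalues = pvals,
                 adj_r2 = path, full_adj_r2 = full_adj),
            class = "selection_report")
}

#' Prune pairwise-correlated climate variables
#'
#' While any pair of variables has absolute Pearson correlation strictly
#' greater than `r_max`, drops from the worst-offending pair the variable
#' ranked lower in `priority` (e.g. forward-selection order); variables
#' absent from `priority` rank below all listed ones, later columns below
#' earlier ones.
#'
#' @param X Populations x variables matrix/data.frame.
#' @param r_max Absolute-correlation threshold (default 0.75; a pair at
#'   exactly `r_max` is kept).
#' @param priority Ordered character vector of preferred variables.
#' @return A `selection_report` with `kept` and `dropped`.
#' @export
prune_correlated <- function(X, r_max = 0.75, priority = character(0)) {
  stopifnot(r_max > 0, r_max < 1)
  X <- as.matrix(X)
  vars <- colnames(X)
  rank_of <- function(v) {
    i <- match(v, priority)
    ifelse(is.na(i), length(priority) + match(v, vars), i)
  }
  kept <- vars
  dropped <- data.frame(variable = character(), rule = character(),
                        statistic = numeric())
  repeat {
    cm <- abs(cor(X[, kept, drop = FALSE]))
    diag(cm) <- 0
    if (all(cm <= r_max)) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- kept[ij]
    loser <- pair[which.max(rank_of(pair))]
    dropped <- rbind(dropped, data.frame(
      variable = loser, rule = sprintf("|r| > %g with %s", r_max,
                                       setdiff(pair, loser)),
      statistic = max(cm)))
    kept <- setdiff(kept, loser)
  }
  structure(list(kept = kept, dropped = dropped),
            class = "selection_report")
}

# VIF of each column regressed on the others; +Inf under perfect collinearity
vif_values <- function(X) {
  X <- scale(as.matrix(X))
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- multiv_r2(X[, j, drop = FALSE], X[, -j, drop = FALSE])
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Prune climate variables by variance inflation factor
#'
#' Iteratively removes the variable with the largest VIF
#' (1 / (1 - R-squared of that variable on the others)) until all VIFs are
#' below `vif_max`. Perfectly collinear variables have infinite VIF and are
#' removed first.
#'
#' @param X Populations x variables matrix/data.frame (>= 2 columns).
#' @param vif_max Threshold (default 10).
#' @return A `selection_report` with `kept`, `dropped` and final `vifs`.
#' @export
prune_vif <- function(X, vif_max = 10) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  kept <- colnames(X)
  dropped <- data.frame(variable = character(), rule = character(),
                        statistic = numeric())
  repeat {
    if (length(kept) < 2) break
    v <- vif_values(X[, kept, drop = FALSE])
    if (all(v < vif_max)) break
    j <- which.max(v)
    dropped <- rbind(dropped, data.frame(
      variable = kept[j], rule = sprintf("VIF >= %g", vif_max),
      statistic = v[j]))
    kept <- kept[-j]
  }
  vfin <- if (length(kept) >= 2) setNames(vif_values(X[, kept, drop = FALSE]),
                                          kept) else setNames(1, kept)
  structure(list(kept = kept, dropped = dropped, vifs = vfin),
            class = "selection_report")
}

#' Distance-based Moran's eigenvector maps
#'
#' Spatial eigenvector covariates from population coordinates: great-circle
#' (haversine) distances, truncation at the longest edge of the minimum
#' spanning tree, distances above the truncation replaced by four times the
#' truncation, principal-coordinate (double-centered) eigendecomposition,
#' and retention of the eigenvectors showing positive spatial
#' autocorrelation (Moran's I above its null expectation -1/(n-1), computed
#' with the within-truncation connectivity).
#'
#' @param coords data.frame with columns `lon`, `lat` (and optionally
#'   `population` used for row names).
#' @return Matrix (populations x eigenvectors) of retained eigenvectors,
#'   ordered by decreasing eigenvalue; eigenvalues in attribute `values`,
#'   truncation distance in attribute `truncation`.
#' @export
dbmem <- function(coords) {
  stopifnot(all(c("lon", "lat") %in% names(coords)))
  xy <- as.matrix(coords[, c("lon", "lat")])
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 locations")
  D <- geosphere::distm(xy, fun = geosphere::distHaversine) / 1000  # km
  if (max(D) == 0) stop("all coordinates identical")
  mst <- vegan::spantree(as.dist(D))
  trunc <- max(mst$dist)
  Dt <- D
  Dt[Dt > trunc] <- 4 * trunc
  A <- -0.5 * Dt^2
  H <- diag(n) - matrix(1 / n, n, n)
  G <- H %*% A %*% H
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- ev$values > sqrt(.Machine$double.eps) * max(abs(ev$values))
  V <- ev$vectors[, pos, drop = FALSE]
  lam <- ev$values[pos]
  # Moran's I per eigenvector with binary within-truncation connectivity
  W <- (D <= trunc) & (D > 0)
  morans <- apply(V, 2, function(v) {
    z <- v - mean(v)
    n / sum(W) * sum(W * outer(z, z)) / sum(z^2)
  })
  keep <- morans > -1 / (n - 1)
  V <- V[, keep, drop = FALSE]
  if (ncol(V) == 0) stop("no eigenvector with positive spatial autocorrelation")
  colnames(V) <- sprintf("MEM%d", seq_len(ncol(V)))
  rownames(V) <- coords$population %||% rownames(coords)
  attr(V, "values") <- lam[keep]
  attr(V, "truncation") <- trunc
  V
}

#' Full climate-predictor selection pipeline
#'
#' Convenience wrapper: forward selection, then correlation pruning with the
#' forward-selection order as priority, then VIF pruning.
#'
#' @inheritParams forward_select
#' @param r_max,vif_max Pruning thresholds (defaults 0.75 and 10).
#' @return A `selection_report` with the final `kept` set and the
#'   sub-reports of each step.
#' @export
select_climate <- function(Y, X, alpha = 0.05, n_perm = 1000, r_max = 0.75,
                           vif_max = 10, seed = 1) {
  fwd <- forward_select(Y, X, alpha = alpha, n_perm = n_perm, seed = seed)
  kept <- if (length(fwd$kept) >= 1) fwd$kept else colnames(X)
  pc <- prune_correlated(as.matrix(X)[, kept, drop = FALSE], r_max = r_max,
                         priority = fwd$kept)
  pv <- if (length(pc$kept) >= 2)
    prune_vif(as.matrix(X)[, pc$kept, drop = FALSE], vif_max = vif_max)
  else list(kept = pc$kept)
  structure(list(kept = pv$kept, forward = fwd, correlation = pc,
                 vif = pv), class = "selection_report")
}
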