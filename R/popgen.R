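#' Principal component analysis of a genotype matrix
#'
#' Columns (SNPs) are centered on their mean over non-missing calls;
#' missing calls contribute zero after centering (the standard
#' mean-imputed PCA of genotype data). Optionally columns are scaled by
#' the binomial standard deviation sqrt(p(1-p)).
#'
#' @param g A `genotype_matrix`.
#' @param n_components Number of components to return (default 10,
#'   truncated to the matrix rank with a warning).
#' @param scale Scale columns by sqrt(p(1-p)) (default FALSE: ordination on
#'   centered allele counts).
#' @return List: `scores` (individuals x components), `var_explained`
#'   (fraction per component, non-increasing).
#' @export
genotype_pca <- function(g, n_components = 10, scale = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  M <- g$calls
  ctr <- colMeans(M, na.rm = TRUE)
  Mc <- sweep(M, 2, ctr)
  Mc[is.na(Mc)] <- 0
  if (scale) {
    p <- ctr / 2
    s <- sqrt(pmax(p * (1 - p), 1e-8))
    Mc <- sweep(Mc, 2, s, "/")
  }
  sv <- svd(Mc)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  if (n_components > rank) {
    warning("n_components exceeds matrix rank; truncated to ", rank)
    n_components <- rank
  }
  idx <- seq_len(n_components)
  scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components)
  dimnames(scores) <- list(rownames(M), sprintf("PC%d", idx))
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[idx])
}

#' Assign individuals to gene pools by k-means on PC scores
#'
#' Clusters individuals on the first `max(2, K)` principal components with
#' multiple restarts; deterministic given the seed. The labels feed
#' [impute_modal_by_pool()].
#'
#' @param pc_scores Individuals x components score matrix from
#'   [genotype_pca()].
#' @param K Number of gene pools (default 2).
#' @param seed Integer seed.
#' @return Integer vector of per-individual labels in `1..K`.
#' @export
assign_gene_pools <- function(pc_scores, K = 2, seed = 1) {
  stopifnot(K >= 1)
  if (K > nrow(pc_scores)) stop("K exceeds the number of individuals")
  if (K == 1) return(rep(1L, nrow(pc_scores)))
  set.seed(seed)
  use <- pc_scores[, seq_len(min(max(2, K), ncol(pc_scores))), drop = FALSE]
  kmeans(use, centers = K, nstart = 25)$cluster
}

# per-locus, per-population allele counts (alt count x, total alleles n2)
pop_allele_counts <- function(g) {
  pops <- unique(g$ind_meta$population)
  alt <- n2 <- matrix(0, length(pops), ncol(g$calls),
                      dimnames = list(pops, colnames(g$calls)))
  het <- nind <- alt
  for (p in pops) {
    sub <- g$calls[g$ind_meta$population == p, , drop = FALSE]
    alt[p, ] <- colSums(sub, na.rm = TRUE)
    nind[p, ] <- colSums(!is.na(sub))
    n2[p, ] <- 2 * nind[p, ]
    het[p, ] <- colSums(sub == 1L, na.rm = TRUE)
  }
  list(alt = alt, n2 = n2, het = het, nind = nind, pops = pops)
}

#' Population-specific FST by allele-matching proportions
#'
#' Moment (beta) estimator of the differentiation of each population from
#' the common gene pool: the within-population allele-matching proportion
#' (distinct pairs without replacement) is contrasted with the mean
#' between-population matching over all population pairs,
#' beta_i = sum_l (M_ii,l - M_B,l) / sum_l (1 - M_B,l).
#' Values can be slightly negative under panmixia.
#'
#' @param g A `genotype_matrix`.
#' @return Named per-population numeric vector; populations with fewer than
#'   two individuals are excluded with a warning.
#' @export
pop_specific_fst <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  cnt <- pop_allele_counts(g)
  small <- rowSums(cnt$nind >= 2) == 0 |
    table(g$ind_meta$population)[cnt$pops] < 2
  if (any(small)) {
    warning("population(s) with < 2 individuals excluded: ",
            paste(cnt$pops[small], collapse = ", "))
    keep <- cnt$pops[!small]
    cnt <- lapply(cnt[c("alt", "n2", "het", "nind")],
                  function(m) m[keep, , drop = FALSE])
    cnt$pops <- keep
  }
  if (length(cnt$pops) < 2) stop("need at least 2 populations")
  x <- cnt$alt; n2 <- cnt$n2
  p <- ifelse(n2 > 0, x / n2, NA_real_)
  # within matching over distinct allele pairs
  Mw <- ifelse(n2 >= 2,
               (x * (x - 1) + (n2 - x) * (n2 - x - 1)) / (n2 * (n2 - 1)),
               NA_real_)
  np <- nrow(p)
  # mean between-population matching per locus over all pairs
  Mb_l <- vapply(seq_len(ncol(p)), function(l) {
    pl <- p[, l]
    ok <- !is.na(pl)
    if (sum(ok) < 2) return(NA_real_)
    pl <- pl[ok]; ql <- 1 - pl
    m <- outer(pl, pl) + outer(ql, ql)
    mean(m[upper.tri(m)])
  }, numeric(1))
  beta <- vapply(seq_len(np), function(i) {
    ok <- !is.na(Mw[i, ]) & !is.na(Mb_l)
    sum(Mw[i, ok] - Mb_l[ok]) / sum(1 - Mb_l[ok])
  }, numeric(1))
  setNames(beta, cnt$pops)
}

# per-locus Jost's D with Nei-Chesser sample-size correction, vectorized
# over loci; p, nind, ho are pops x loci
josts_d_loci <- function(p, nind, ho) {
  ok <- !is.na(p) & nind > 0
  p[!ok] <- NA; ho[!ok] <- NA
  nind_na <- nind; nind_na[!ok] <- NA
  k <- colSums(ok)
  nh <- k / colSums(1 / nind_na, na.rm = TRUE)
  hs_raw <- colMeans(1 - p^2 - (1 - p)^2, na.rm = TRUE)
  hom <- colMeans(ho, na.rm = TRUE)
  hs <- nh / (nh - 1) * (hs_raw - hom / (2 * nh))
  pbar <- colMeans(p, na.rm = TRUE)
  ht_raw <- 1 - pbar^2 - (1 - pbar)^2
  ht <- ht_raw + hs / (nh * k) - hom / (2 * nh * k)
  d <- (ht - hs) / (1 - hs) * k / (k - 1)
  d[k < 2 | nh <= 1 | (1 - hs) <= 0] <- NA_real_
  d[hs_raw == 0 & ht_raw == 0] <- 0    # monomorphic across populations
  d
}

#' Jost's D differentiation (pairwise and global)
#'
#' Per-locus D = (H_T - H_S) / (1 - H_S) * k/(k-1) with sample-size
#' corrected heterozygosities (Nei-Chesser estimators using the harmonic
#' mean sample size and observed heterozygosity). The multi-locus global
#' value is the harmonic mean across loci (restricted to loci with positive
#' D, the usual convention since non-positive per-locus values have no
#' effective-number interpretation); monomorphic loci contribute D = 0.
#'
#' @param g A `genotype_matrix`.
#' @param pairwise Also compute the pairwise population matrix (default
#'   TRUE; quadratic in populations).
#' @param stat Multi-locus aggregation: `"harmonic"` (harmonic mean over
#'   loci with positive D, the conventional global estimator) or `"mean"`
#'   (arithmetic mean over loci, more informative for ranking pairs when
#'   most loci are weakly differentiated).
#' @return List: `global` (scalar), `per_locus` (vector), `pairwise`
#'   (symmetric population matrix of two-population global D, or NULL).
#' @export
josts_d <- function(g, pairwise = TRUE, stat = c("harmonic", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(g, "genotype_matrix"))
  cnt <- pop_allele_counts(g)
  if (length(cnt$pops) < 2) stop("need at least 2 populations")
  p <- ifelse(cnt$n2 > 0, cnt$alt / cnt$n2, NA_real_)
  ho <- ifelse(cnt$nind > 0, cnt$het / cnt$nind, NA_real_)
  d_multi <- function(rows) {
    dl <- josts_d_loci(p[rows, , drop = FALSE],
                       cnt$nind[rows, , drop = FALSE],
                       ho[rows, , drop = FALSE])
    dl[is.na(dl)] <- 0
    pos <- dl[dl > 0]
    global <- if (stat == "mean") mean(dl)
    else if (length(pos) == 0) 0 else harmonic_mean(pos)
    list(global = global, per_locus = dl)
  }
  all_d <- d_multi(seq_along(cnt$pops))
  np <- length(cnt$pops)
  pw <- NULL
  if (pairwise) {
    pw <- matrix(0, np, np, dimnames = list(cnt$pops, cnt$pops))
    for (i in seq_len(np - 1))
      for (j in (i + 1):np)
        pw[i, j] <- pw[j, i] <- d_multi(c(i, j))$global
  }
  list(global = all_d$global, per_locus = all_d$per_locus, pairwise = pw)
}
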