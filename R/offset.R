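#' Cumulative-importance turnover functions from per-SNP forests
#'
#' Builds, for each climate variable, a monotone non-decreasing step
#' function of cumulative split importance along the variable's gradient:
#' one regression forest is fitted per SNP, each forest's out-of-bag
#' R-squared is distributed over the variables in proportion to impurity
#' importance, and within a variable over that forest's split points. The
#' pooled, value-sorted cumulative sum (averaged over SNPs) is the turnover
#' function used by [gf_offset()].
#'
#' @param Y Populations x SNPs allele-frequency matrix.
#' @param X Populations x variables climate matrix.
#' @param n_trees Trees per forest (default 50).
#' @param seed Integer seed.
#' @return Object of class `gf_turnover`: per-variable `breaks` and `cum`
#'   step coordinates, training `range`, and total importance.
#' @export
gf_turnover <- function(Y, X, n_trees = 50, seed = 1) {
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Y <- as.matrix(Y); X <- as.data.frame(as.matrix(X))
  splits <- setNames(vector("list", ncol(X)), colnames(X))
  n_snps <- ncol(Y)
  for (j in seq_len(n_snps)) {
    y <- Y[, j]
    vy <- var(y)
    if (vy < .Machine$double.eps) next
    fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                          importance = "impurity",
                          seed = seed + j, num.threads = 1)
    r2 <- max(0, 1 - fit$prediction.error / vy)
    if (r2 == 0) next
    vi <- fit$variable.importance
    if (sum(vi) == 0) next
    vi <- r2 * vi / sum(vi)
    info <- do.call(rbind, lapply(seq_len(n_trees), function(tr)
      ranger::treeInfo(fit, tr)[, c("splitvarName", "splitval")]))
    info <- info[!is.na(info$splitvarName), , drop = FALSE]
    for (v in unique(info$splitvarName)) {
      sv <- info$splitval[info$splitvarName == v]
      # variable importance spread evenly over that forest's splits on v
      splits[[v]] <- rbind(splits[[v]],
                           data.frame(val = sv, w = vi[[v]] / length(sv)))
    }
  }
  fns <- lapply(colnames(X), function(v) {
    s <- splits[[v]]
    if (is.null(s)) return(list(breaks = numeric(0), cum = numeric(0)))
    agg <- tapply(s$w, s$val, sum)
    breaks <- as.numeric(names(agg))
    ord <- order(breaks)
    list(breaks = breaks[ord], cum = cumsum(agg[ord]) / n_snps)
  })
  names(fns) <- colnames(X)
  structure(list(functions = fns,
                 range = apply(X, 2, range),
                 importance = vapply(fns, function(f)
                   if (length(f$cum)) max(f$cum) else 0, numeric(1))),
            class = "gf_turnover")
}

# evaluate a turnover step function, clamped outside the training range
eval_turnover <- function(fn, x) {
  if (length(fn$breaks) == 0) return(rep(0, length(x)))
  c(0, fn$cum)[findInterval(x, fn$breaks) + 1L]
}

#' Redundancy-analysis genomic offset
#'
#' Projects reference and future climates into the constrained ordination
#' space through the model's climate coefficients and returns, per
#' population, the Euclidean distance between the two projections over the
#' first K axes, each axis weighted by its share of the constrained
#' eigenvalues (w_k = lambda_k / sum lambda_1..K).
#'
#' @param model An `rda_model` fitted on the same climate variables.
#' @param clim_ref,clim_fut Populations x variables climate matrices on the
#'   raw scale of the training climate (standardization is re-applied from
#'   the model).
#' @param K Number of axes (default 2).
#' @param weight Axis weighting: `"eigfrac"` (default), `"sqrt"` (square
#'   root of the eigenvalue fraction) or `"none"`.
#' @return Named per-population vector of raw offsets (>= 0).
#' @export
rda_offset <- function(model, clim_ref, clim_fut, K = 2,
                       weight = c("eigfrac", "sqrt", "none")) {
  weight <- match.arg(weight)
  stopifnot(inherits(model, "rda_model"))
  K <- min(K, model$K_retained)
  s_ref <- predict_scores(model, clim_ref, K)
  s_fut <- predict_scores(model, clim_fut, K)
  w <- axis_weights(model$eig[seq_len(K)], weight)
  diff <- sweep(s_ref - s_fut, 2, w, "*")
  out <- sqrt(rowSums(diff^2))
  names(out) <- rownames(clim_ref)
  out
}

axis_weights <- function(eig, weight) {
  switch(weight,
         eigfrac = eig / sum(eig),
         sqrt = sqrt(eig / sum(eig)),
         none = rep(1, length(eig)))
}

#' Gradient-forest genomic offset
#'
#' Transforms every climate variable through its cumulative-importance
#' turnover function (clamped outside the training range) and returns the
#' per-population Euclidean distance between the transformed reference and
#' future climate vectors.
#'
#' @param turnover A [gf_turnover()] object.
#' @param clim_ref,clim_fut Populations x variables climate matrices.
#' @return Named per-population vector of raw offsets (>= 0).
#' @export
gf_offset <- function(turnover, clim_ref, clim_fut) {
  stopifnot(inherits(turnover, "gf_turnover"))
  clim_ref <- as.matrix(clim_ref); clim_fut <- as.matrix(clim_fut)
  miss <- setdiff(colnames(clim_ref), names(turnover$functions))
  if (length(miss) > 0)
    stop("variable(s) absent from turnover set: ",
         paste(miss, collapse = ", "))
  d2 <- rep(0, nrow(clim_ref))
  for (v in colnames(clim_ref)) {
    fn <- turnover$functions[[v]]
    d2 <- d2 + (eval_turnover(fn, clim_fut[, v]) -
                  eval_turnover(fn, clim_ref[, v]))^2
  }
  out <- sqrt(d2)
  names(out) <- rownames(clim_ref)
  out
}

#' Aggregate per-GCM offsets into a classified result
#'
#' Averages raw offsets across GCMs, min-max normalizes the means across
#' populations, and assigns five (by default) equal-occupancy classes
#' (class 1 = lowest offset; class sizes differ by at most one; ties broken
#' by population label order).
#'
#' @param raw Populations x GCMs matrix of raw offsets (a vector is treated
#'   as a single GCM).
#' @param method Label, e.g. `"rda"` or `"gf"`.
#' @param snp_set Label, e.g. `"all"`, `"outlier"`, `"random"`.
#' @param n_classes Number of classes (default 5).
#' @return Object of class `offset_result`: data.frame with population,
#'   mean_raw, normalized, class; raw matrix kept as attribute `raw`.
#' @export
aggregate_offsets <- function(raw, method = "rda", snp_set = "all",
                              n_classes = 5) {
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 1,
                                       dimnames = list(names(raw), "gcm1"))
  stopifnot(ncol(raw) >= 1)
  pops <- rownames(raw) %||% sprintf("pop%d", seq_len(nrow(raw)))
  mean_raw <- rowMeans(raw)
  if (diff(range(mean_raw)) == 0) {
    warning("all offsets equal; single class, normalized values set to 0")
    normalized <- rep(0, length(mean_raw))
    cls <- rep(1L, length(mean_raw))
  } else {
    normalized <- minmax(mean_raw, warn = FALSE)
    n <- length(mean_raw)
    bounds <- round(seq(0, n, length.out = n_classes + 1))
    ord <- order(mean_raw, pops)
    cls <- integer(n)
    for (k in seq_len(n_classes))
      cls[ord[(bounds[k] + 1):bounds[k + 1]]] <- k
  }
  out <- data.frame(population = pops, mean_raw = mean_raw,
                    normalized = normalized, class = cls,
                    method = method, snp_set = snp_set, row.names = NULL)
  attr(out, "raw") <- raw
  class(out) <- c("offset_result", "data.frame")
  out
}

#' Cross-model robustness of offset classifications
#'
#' Two classified offset results are congruent for a population when their
#' classes differ by less than two; larger differences flag the prediction
#' as non-robust.
#'
#' @param result_a,result_b `offset_result` objects on the same
#'   populations.
#' @return data.frame: population, class_a, class_b, robust (logical).
#' @export
robustness_flags <- function(result_a, result_b) {
  if (!setequal(result_a$population, result_b$population))
    stop("population sets differ between the two offset results")
  b <- result_b[match(result_a$population, result_b$population), ]
  data.frame(population = result_a$population,
             class_a = result_a$class, class_b = b$class,
             robust = abs(result_a$class - b$class) < 2)
}

#' Genomic discrepancy index in the constrained ordination space
#'
#' Contrasts, per population, the observed ordination scores (projection of
#' the centered allele-frequency vector on the leading constrained axes)
#' with the scores predicted from climate alone (the linear combination of
#' the climate variables). Both score sets are weighted by axis importance
#' (eigenvalue fraction over the first K axes) and their Euclidean distance
#' is min-max normalized across populations. Large values flag populations
#' deviating from the species-wide gene-climate relationship.
#'
#' @param model An (unconditioned) `rda_model`.
#' @param Y The allele-frequency matrix the model was fitted on.
#' @param clim_ref Reference-period climate matrix.
#' @param K Number of axes (default 2).
#' @param weight Axis weighting as in [rda_offset()].
#' @return Object of class `gdi_result`: `observed`, `predicted`
#'   (populations x K), `weights`, `raw` distances, normalized `gdi`.
#' @export
gdi_rda <- function(model, Y, clim_ref, K = 2,
                    weight = c("eigfrac", "sqrt", "none")) {
  weight <- match.arg(weight)
  stopifnot(inherits(model, "rda_model"))
  if (K > model$K_retained) stop("K exceeds the number of model axes")
  if (inherits(Y, "allele_freq_matrix")) Y <- Y$freqs
  Yc <- sweep(as.matrix(Y), 2, model$y_center)
  observed <- Yc %*% model$V[, seq_len(K), drop = FALSE]
  predicted <- predict_scores(model, clim_ref, K)
  w <- axis_weights(model$eig[seq_len(K)], weight)
  diff <- sweep(observed - predicted, 2, w, "*")
  raw <- sqrt(rowSums(diff^2))
  names(raw) <- rownames(Y)
  structure(list(observed = observed, predicted = predicted, weights = w,
                 raw = raw, gdi = minmax(raw, warn = FALSE)),
            class = "gdi_result")
}

#' Genomic offset to a common-garden climate
#'
#' Distance between the predicted genomic composition at each population's
#' reference climate of origin and at the garden site's climate over the
#' evaluation window; identical to [rda_offset()]/[gf_offset()] with the
#' future climate replaced by the garden climate replicated across
#' populations.
#'
#' @param model An `rda_model` or a `gf_turnover` object.
#' @param clim_origin_ref Populations x variables reference climate of the
#'   populations' origins.
#' @param clim_garden Named climate vector (or 1-row matrix) of the garden
#'   over the evaluation window.
#' @param K Number of axes (RDA only).
#' @return Named per-population vector of raw garden offsets.
#' @export
garden_offset <- function(model, clim_origin_ref, clim_garden, K = 2) {
  clim_origin_ref <- as.matrix(clim_origin_ref)
  garden <- matrix(rep(as.numeric(clim_garden), each = nrow(clim_origin_ref)),
                   nrow(clim_origin_ref),
                   dimnames = list(rownames(clim_origin_ref),
                                   names(clim_garden) %||%
                                     colnames(clim_garden)))
  if (inherits(model, "gf_turnover"))
    gf_offset(model, clim_origin_ref, garden)
  else
    rda_offset(model, clim_origin_ref, garden, K = K)
}
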