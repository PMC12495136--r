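#' Population BLUPs from common-garden trait observations
#'
#' Fits the Gaussian mixed model
#' `value = mu + covariates + pop_i + geno_j(i) + e_ijk`
#' with random population and genotype-within-population intercepts, and
#' returns the predicted population intercepts (BLUPs), their conditional
#' standard errors and the variance components. Estimation is by REML
#' (lme4) by default; `method = "gibbs"` runs a Gibbs sampler with weak
#' inverse-gamma priors on all variances and returns posterior means of the
#' population intercepts, mirroring a Bayesian animal-model fit at reduced
#' chain length (the posterior mean under weak priors closely tracks the
#' REML BLUP).
#'
#' @param obs Long-format data.frame with columns individual, genotype_id,
#'   population, trait, value, plus any covariate columns.
#' @param trait Trait to fit (required when `obs` has several traits).
#' @param covariates Names of fixed-effect covariate columns.
#' @param min_plants Minimum measured plants per population (default 3);
#'   populations below it are excluded.
#' @param include_genotype Keep the genotype random term (default TRUE).
#' @param method `"reml"` (default) or `"gibbs"`.
#' @param gibbs_iter,gibbs_burnin Chain length and burn-in for the Gibbs
#'   option.
#' @param seed Seed for the Gibbs option.
#' @return Object of class `trait_blups`: data.frame `blups` (population,
#'   blup, se, n_plants), `varcomp` (sigma2_pop, sigma2_geno, sigma2_res),
#'   `trait`.
#' @export
fit_trait_blups <- function(obs, trait = NULL, covariates = character(),
                            min_plants = 3, include_genotype = TRUE,
                            method = c("reml", "gibbs"),
                            gibbs_iter = 2000, gibbs_burnin = 500,
                            seed = 1) {
  method <- match.arg(method)
  stopifnot(all(c("individual", "genotype_id", "population", "trait",
                  "value") %in% names(obs)))
  traits <- unique(obs$trait)
  if (is.null(trait)) {
    if (length(traits) > 1)
      stop("obs contains several traits; pass `trait`")
    trait <- traits
  }
  d <- obs[obs$trait == trait & is.finite(obs$value), ]
  n_plants <- tapply(d$individual, d$population,
                     function(x) length(unique(x)))
  keep <- names(n_plants)[n_plants >= min_plants]
  d <- d[d$population %in% keep, ]
  if (length(keep) < 2)
    stop("fewer than 2 populations with >= ", min_plants, " plants")
  d$population <- factor(d$population)
  d$geno <- factor(paste(d$population, d$genotype_id, sep = ":"))
  if (method == "gibbs")
    return(gibbs_blups(d, trait, covariates, include_genotype,
                       gibbs_iter, gibbs_burnin, seed,
                       n_plants[levels(d$population)]))
  fixed <- paste(c("1", covariates), collapse = " + ")
  form <- sprintf("value ~ %s + (1 | population)%s", fixed,
                  if (include_genotype) " + (1 | geno)" else "")
  fit <- tryCatch(
    lme4::lmer(stats::as.formula(form), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) {
      if (!include_genotype) stop(e)
      warning("genotype term dropped after fit failure: ",
              conditionMessage(e))
      lme4::lmer(stats::as.formula(
        sprintf("value ~ %s + (1 | population)", fixed)), data = d)
    })
  re <- lme4::ranef(fit, condVar = TRUE)$population
  pv <- attr(re, "postVar")
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  blups <- data.frame(population = rownames(re), blup = re[, 1],
                      se = sqrt(pv[1, 1, ]),
                      n_plants = as.integer(n_plants[rownames(re)]),
                      row.names = NULL)
  structure(list(blups = blups,
                 varcomp = c(sigma2_pop = getvc("population"),
                             sigma2_geno = getvc("geno"),
                             sigma2_res = getvc("Residual")),
                 trait = trait, method = "reml"),
            class = "trait_blups")
}

# Gibbs sampler for the same model with IG(0.001, 0.001) variance priors
gibbs_blups <- function(d, trait, covariates, include_genotype,
                        n_iter, burnin, seed, n_plants) {
  set.seed(seed)
  y <- d$value
  X <- model.matrix(stats::as.formula(
    paste("~", paste(c("1", covariates), collapse = " + "))), d)
  Zp <- model.matrix(~ 0 + population, d)
  Zg <- if (include_genotype) model.matrix(~ 0 + geno, d) else NULL
  np <- ncol(Zp); n <- length(y)
  b <- qr.coef(qr(X), y); up <- rep(0, np)
  ug <- if (include_genotype) rep(0, ncol(Zg)) else NULL
  s2p <- s2g <- s2e <- var(y)
  a0 <- b0 <- 0.001
  keep_up <- matrix(0, n_iter - burnin, np)
  XtXi <- solve(crossprod(X))
  for (it in seq_len(n_iter)) {
    res_b <- y - Zp %*% up - (if (include_genotype) Zg %*% ug else 0)
    b <- XtXi %*% crossprod(X, res_b) +
      t(chol(s2e * XtXi)) %*% rnorm(ncol(X))
    res_p <- y - X %*% b - (if (include_genotype) Zg %*% ug else 0)
    prec <- colSums(Zp) / s2e + 1 / s2p
    mu <- (crossprod(Zp, res_p) / s2e) / prec
    up <- rnorm(np, mu, sqrt(1 / prec))
    if (include_genotype) {
      res_g <- y - X %*% b - Zp %*% up
      precg <- colSums(Zg) / s2e + 1 / s2g
      mug <- (crossprod(Zg, res_g) / s2e) / precg
      ug <- rnorm(ncol(Zg), mug, sqrt(1 / precg))
      s2g <- 1 / rgamma(1, a0 + ncol(Zg) / 2, b0 + sum(ug^2) / 2)
    }
    s2p <- 1 / rgamma(1, a0 + np / 2, b0 + sum(up^2) / 2)
    e <- y - X %*% b - Zp %*% up - (if (include_genotype) Zg %*% ug else 0)
    s2e <- 1 / rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    if (it > burnin) keep_up[it - burnin, ] <- up
  }
  pops <- sub("^population", "", colnames(Zp))
  blups <- data.frame(population = pops, blup = colMeans(keep_up),
                      se = apply(keep_up, 2, sd),
                      n_plants = as.integer(n_plants[pops]),
                      row.names = NULL)
  structure(list(blups = blups,
                 varcomp = c(sigma2_pop = s2p,
                             sigma2_geno = if (include_genotype) s2g else 0,
                             sigma2_res = s2e),
                 trait = trait, method = "gibbs"),
            class = "trait_blups")
}

#' Composite trait index across traits
#'
#' Min-max standardizes the population BLUPs of every trait to [0, 1]
#' across the populations common to all traits, then averages with equal
#' weights. A trait constant across populations contributes 0.5 for every
#' population (with a message). With a single trait the index equals the
#' standardized BLUPs.
#'
#' @param blups_by_trait Named list of `trait_blups` objects (or
#'   data.frames with columns population, blup).
#' @return data.frame of class `composite_index`: population, index.
#' @export
composite_trait_index <- function(blups_by_trait) {
  stopifnot(length(blups_by_trait) >= 1)
  tabs <- lapply(blups_by_trait, function(b)
    if (inherits(b, "trait_blups")) b$blups else b)
  pops <- Reduce(intersect, lapply(tabs, function(t) t$population))
  std <- vapply(seq_along(tabs), function(i) {
    t <- tabs[[i]]
    v <- t$blup[match(pops, t$population)]
    if (diff(range(v)) == 0) {
      message("trait ", names(blups_by_trait)[i] %||% i,
              " constant across populations; contributes 0.5")
      return(rep(0.5, length(pops)))
    }
    minmax(v, warn = FALSE)
  }, numeric(length(pops)))
  out <- data.frame(population = pops, index = rowMeans(std))
  class(out) <- c("composite_index", "data.frame")
  out
}

#' Validate genomic offsets against fitness proxies
#'
#' For every combination of offset (method x SNP set) and trait, computes
#' the Pearson correlation between the per-population offsets and the
#' fitness proxy (two-sided p) and the ordinary least-squares slope of the
#' proxy on the offset. Under the maladaptation hypothesis the expected
#' sign is negative: populations predicted to be further from their climate
#' optimum should have lower fitness proxies.
#'
#' @param offsets A single `offset_result` or a list of them.
#' @param fitness data.frame with columns population, trait, value
#'   (BLUPs and/or the composite index).
#' @param min_pops Minimum shared populations per cell (default 5; smaller
#'   cells are reported as NA).
#' @return data.frame: method, snp_set, trait, n, r, r_p, slope, slope_se,
#'   slope_p.
#' @export
validate_offsets <- function(offsets, fitness, min_pops = 5) {
  if (inherits(offsets, "offset_result")) offsets <- list(offsets)
  stopifnot(all(c("population", "trait", "value") %in% names(fitness)))
  rows <- list()
  for (off in offsets) {
    for (tr in unique(fitness$trait)) {
      f <- fitness[fitness$trait == tr, ]
      common <- intersect(off$population, f$population)
      x <- off$mean_raw[match(common, off$population)]
      y <- f$value[match(common, f$population)]
      if (length(common) < min_pops || sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = off$method[1], snp_set = off$snp_set[1], trait = tr,
          n = length(common), r = NA, r_p = NA, slope = NA,
          slope_se = NA, slope_p = NA,
          note = sprintf("fewer than %d usable populations", min_pops))
        next
      }
      ct <- stats::cor.test(x, y)
      sl <- suppressWarnings(summary(lm(y ~ x)))$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        method = off$method[1], snp_set = off$snp_set[1], trait = tr,
        n = length(common), r = unname(ct$estimate), r_p = ct$p.value,
        slope = sl["x", 1], slope_se = sl["x", 2], slope_p = sl["x", 4],
        note = "")
    }
  }
  do.call(rbind, rows)
}
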