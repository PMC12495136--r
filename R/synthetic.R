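#' Configuration for a synthetic landscape
#'
#' Bundles the parameters of the synthetic-landscape generator. The defaults
#' describe a range-wide sample of a long-lived conifer: 29 populations of
#' 16 trees genotyped at 2000 SNPs, two admixing gene pools arranged along
#' an east-west gradient, a minority of loci following logistic
#' allele-frequency clines on one climate variable, and drift-dominated
#' neutral loci with moderate differentiation.
#'
#' @param n_pops Number of populations.
#' @param n_ind_per_pop Diploid individuals sampled per population.
#' @param n_snps Number of biallelic SNPs.
#' @param frac_adaptive Fraction of SNPs under climate-driven selection.
#' @param n_climate_vars Number of climate variables (first is the driver).
#' @param cline_slope Logit-scale slope of adaptive clines per climate SD.
#' @param drift_fst Balding-Nichols differentiation parameter in (0, 1).
#' @param admixture_gradient Mix the two gene pools linearly along the
#'   east-west axis (mimics admixed central populations).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param contig_size SNPs per contig (controls within-contig linkage).
#' @param ld_prob Probability that a neutral SNP is a tightly linked copy of
#'   its left neighbour on the same contig.
#' @param future_shift Per-variable climate change, in SD units of the
#'   reference climate. Recycled to `n_climate_vars`.
#' @param n_gcms Number of future climate realizations (GCMs).
#' @param gcm_jitter GCM-to-GCM spread as a fraction of `future_shift`.
#' @param polygenic If `TRUE` all adaptive loci share small slopes
#'   (polygenic architecture); default is oligogenic (full-slope clines).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_pops = 29, n_ind_per_pop = 16, n_snps = 2000,
                             frac_adaptive = 0.05, n_climate_vars = 6,
                             cline_slope = 1.5, drift_fst = 0.15,
                             admixture_gradient = TRUE, missing_rate = 0.05,
                             contig_size = 10, ld_prob = 0.15,
                             future_shift = c(1.5, 0.3, 0.8, 1.5, -1.0, 0.5),
                             n_gcms = 5, gcm_jitter = 0.05,
                             polygenic = FALSE, seed = 17) {
  cfg <- list(n_pops = n_pops, n_ind_per_pop = n_ind_per_pop, n_snps = n_snps,
              frac_adaptive = frac_adaptive, n_climate_vars = n_climate_vars,
              cline_slope = cline_slope, drift_fst = drift_fst,
              admixture_gradient = admixture_gradient,
              missing_rate = missing_rate, contig_size = contig_size,
              ld_prob = ld_prob,
              future_shift = rep_len(future_shift, n_climate_vars),
              n_gcms = n_gcms, gcm_jitter = gcm_jitter,
              polygenic = polygenic, seed = as.integer(seed))
  stopifnot(n_pops >= 1, n_ind_per_pop >= 1, n_snps >= 1,
            n_climate_vars >= 1, contig_size >= 1, n_gcms >= 1,
            frac_adaptive >= 0, frac_adaptive <= 1,
            missing_rate >= 0, missing_rate <= 1,
            drift_fst > 0, drift_fst < 1)
  class(cfg) <- "landscape_config"
  cfg
}

#' Logistic allele-frequency cline
#'
#' Expected alternate-allele frequency of an adaptive locus as a logistic
#' function of a standardized climate value.
#'
#' @param env_value Standardized climate scalar (finite).
#' @param intercept Logit-scale intercept (ancestral log-odds).
#' @param slope Logit-scale slope per climate SD.
#' @return Allele frequency strictly in (0, 1), monotone in `env_value`
#'   when `slope != 0`.
#' @examples
#' adaptive_cline_freq(0, 0, 3)   # 0.5
#' adaptive_cline_freq(1, 0, 3)   # 1 / (1 + exp(-3))
#' @export
adaptive_cline_freq <- function(env_value, intercept, slope) {
  if (!all(is.finite(env_value), is.finite(intercept), is.finite(slope)))
    stop("adaptive_cline_freq: all inputs must be finite")
  logistic(intercept + slope * env_value)
}

# Balding-Nichols draw around an ancestral frequency p with differentiation F
bn_draw <- function(n, p, fst) {
  p <- pmin(pmax(p, 0.01), 0.99)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  pmin(pmax(rbeta(n, a, b), 1e-4), 1 - 1e-4)
}

#' Simulate a synthetic landscape with known adaptive architecture
#'
#' Generates genotypes, reference and future climate tables, coordinates and
#' the generating truth. Neutral loci are drawn per gene pool from a
#' Balding-Nichols distribution (differentiation `drift_fst`), mixed along an
#' east-west admixture gradient, with additional population-level drift at
#' half that differentiation. Adaptive loci follow [adaptive_cline_freq()] of
#' the designated driver climate variable (the first one). Genotypes are two
#' Bernoulli draws per individual (Hardy-Weinberg within populations);
#' within-contig linkage is emulated by making some neutral SNPs near-copies
#' of their left neighbour. Future climates are the reference plus
#' `future_shift` plus a small per-GCM jitter.
#'
#' @param config A [landscape_config()].
#' @return A list of class `yew_landscape` with elements `geno` (a
#'   `genotype_matrix`), `clim_ref` (populations x variables matrix),
#'   `clim_fut` (list of per-GCM matrices), `coords` (population lon/lat),
#'   `truth` (adaptive loci, cline parameters, gene-pool labels, generating
#'   population frequencies, fitness function) and `config`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  np <- config$n_pops; ni <- config$n_ind_per_pop; ns <- config$n_snps
  pops <- sprintf("pop%02d", seq_len(np))

  # geography: populations strung along an east-west axis with jitter
  lon <- seq(-9, 25, length.out = np) + rnorm(np, 0, 0.8)
  lat <- seq(55, 38, length.out = np) + rnorm(np, 0, 1.5)
  coords <- data.frame(population = pops, lon = lon, lat = lat)

  # admixture weight of the western pool, decreasing eastwards
  w <- if (config$admixture_gradient) {
    1 - (rank(lon) - 1) / (np - 1)
  } else rep(c(1, 0), length.out = np)
  pool_lab <- setNames(ifelse(w > 0.5, "west", "east"), pops)

  # climate: driver variable tracks the spatial axis, the rest are
  # AR(1)-correlated Gaussians (max correlation 0.5) partially spatial
  s <- as.numeric(scale(lon))
  nv <- config$n_climate_vars
  Sigma <- 0.5^abs(outer(seq_len(nv), seq_len(nv), "-"))
  E <- matrix(rnorm(np * nv), np, nv) %*% chol(Sigma)
  a <- c(0.6, rep(0.25, nv - 1))
  clim <- sweep(E, 2, sqrt(1 - a^2), "*") + outer(s, a)
  clim <- scale(clim)
  attr(clim, "scaled:center") <- attr(clim, "scaled:scale") <- NULL
  vars <- c("Annual_Tc", "Diurnal_range_Tc", "Tc_Seasonality",
            "Tc_Driest_quarter", "Annual_P", "P_Seasonality",
            if (nv > 6) sprintf("clim%d", 7:nv))[seq_len(nv)]
  dimnames(clim) <- list(pops, vars)

  # adaptive architecture
  n_adapt <- floor(config$frac_adaptive * ns)
  if (config$frac_adaptive > 0 && n_adapt < 1)
    warning("frac_adaptive * n_snps < 1: no adaptive loci generated")
  adaptive <- if (n_adapt >= 1) sort(sample(ns, n_adapt)) else integer(0)
  p0 <- runif(ns, 0.1, 0.9)
  slope_mag <- if (config$polygenic) config$cline_slope * 0.5 else
    config$cline_slope
  slopes <- sample(c(-1, 1), n_adapt, replace = TRUE) * slope_mag
  intercepts <- logit(p0[adaptive])
  driver <- clim[, 1]

  # per-locus population frequencies
  pw <- bn_draw(ns, p0, config$drift_fst)       # western pool
  pe <- bn_draw(ns, p0, config$drift_fst)       # eastern pool
  pfreq <- matrix(NA_real_, np, ns, dimnames = list(pops, NULL))
  for (i in seq_len(np)) {
    mix <- w[i] * pw + (1 - w[i]) * pe
    pfreq[i, ] <- bn_draw(ns, mix, config$drift_fst / 2)
  }
  if (n_adapt >= 1)
    for (k in seq_len(n_adapt))
      pfreq[, adaptive[k]] <-
        adaptive_cline_freq(driver, intercepts[k], slopes[k])

  # linkage plan: neutral SNPs may be near-copies of their left neighbour
  # on the same contig
  contig <- ceiling(seq_len(ns) / config$contig_size)
  linked <- runif(ns) < config$ld_prob
  first_on_contig <- c(TRUE, diff(contig) != 0)
  linked[first_on_contig | seq_len(ns) %in% c(adaptive, adaptive + 1)] <- FALSE
  # a linked copy shares its neighbour's generating frequencies, so the
  # marginal per-locus frequency stays correct while genotypes are in LD
  for (j in which(linked)) pfreq[, j] <- pfreq[, j - 1L]

  n_tot <- np * ni
  ind_pop <- rep(pops, each = ni)
  ids <- sprintf("%s_i%02d", ind_pop, rep(seq_len(ni), np))
  h1 <- h2 <- matrix(0L, n_tot, ns)
  for (j in seq_len(ns)) {
    pj <- pfreq[ind_pop, j]
    if (linked[j]) {
      flip1 <- runif(n_tot) < 0.05
      flip2 <- runif(n_tot) < 0.05
      h1[, j] <- ifelse(flip1, rbinom(n_tot, 1L, pj), h1[, j - 1L])
      h2[, j] <- ifelse(flip2, rbinom(n_tot, 1L, pj), h2[, j - 1L])
    } else {
      h1[, j] <- rbinom(n_tot, 1L, pj)
      h2[, j] <- rbinom(n_tot, 1L, pj)
    }
  }
  calls <- h1 + h2
  if (config$missing_rate > 0)
    calls[matrix(runif(n_tot * ns) < config$missing_rate, n_tot, ns)] <-
      NA_integer_

  snp_meta <- data.frame(
    id = sprintf("snp%05d", seq_len(ns)),
    contig = sprintf("ctg%04d", contig),
    position = ((seq_len(ns) - 1L) %% config$contig_size) * 137L + 101L)
  dimnames(calls) <- list(ids, snp_meta$id)
  geno <- new_genotype_matrix(calls, snp_meta,
                              data.frame(id = ids, population = ind_pop))

  # future climates: shift plus per-GCM jitter
  clim_fut <- lapply(seq_len(config$n_gcms), function(g) {
    jit <- matrix(rnorm(np * nv, 0,
                        config$gcm_jitter * (abs(config$future_shift) + 0.05)),
                  np, nv, byrow = TRUE)
    fut <- clim + matrix(config$future_shift, np, nv, byrow = TRUE) + jit
    dimnames(fut) <- dimnames(clim)
    fut
  })
  names(clim_fut) <- sprintf("gcm%d", seq_len(config$n_gcms))

  truth <- list(adaptive_loci = adaptive,
                cline_intercepts = intercepts, cline_slopes = slopes,
                ancestral_freqs = p0, gene_pool_labels = pool_lab,
                admixture_weight = w, driver_var = vars[1],
                pop_freqs = pfreq, pop_climate = clim,
                fitness_fn = function(d) exp(-0.5 * (d / 2)^2))
  structure(list(geno = geno, clim_ref = clim, clim_fut = clim_fut,
                 coords = coords, truth = truth, config = config),
            class = "yew_landscape")
}

#' Simulate common-garden phenotypes from landscape truth
#'
#' Generates long-format trait observations for clonally replicated genotypes
#' grown at one garden site. The expected population value of every trait is
#' an increasing function of the population's expected relative fitness at
#' the garden, which itself decreases with the distance between the
#' population's home driver-climate value and the garden's; genotype-level
#' and residual Gaussian noise are added on top, so traits are positively
#' correlated through the shared fitness signal.
#'
#' @param truth The `truth` element of a [simulate_landscape()] result.
#' @param climate_of_garden Named climate vector of the garden site (must
#'   include the driver variable), on the standardized landscape scale.
#' @param pops Character vector of populations to include.
#' @param n_clones Genotypes (clones) sampled per population; must be >= 1.
#' @param noise_sd Residual standard deviation; genotype-level standard
#'   deviation defaults to `0.6 * noise_sd`.
#' @param seed Integer seed.
#' @param traits Trait names to simulate.
#' @param n_ramets Ramets (measured plants) per genotype.
#' @param trait_scale Slope of trait expectation on expected fitness.
#' @param geno_sd Genotype-effect standard deviation (overrides the default).
#' @return A long-format data.frame: individual, genotype_id, population,
#'   trait, year, value.
#' @export
simulate_phenotypes <- function(truth, climate_of_garden, pops,
                                n_clones = 5, noise_sd = 0.5, seed = 1,
                                traits = c("growth", "shoot_elongation",
                                           "repro_phenology",
                                           "leaf_thickness"),
                                n_ramets = 3, trait_scale = 2,
                                geno_sd = NULL) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  stopifnot(all(pops %in% rownames(truth$pop_climate)))
  geno_sd <- geno_sd %||% (0.6 * noise_sd)
  set.seed(seed)
  gd <- climate_of_garden[[truth$driver_var]]
  d <- abs(truth$pop_climate[pops, truth$driver_var] - gd)
  fit <- truth$fitness_fn(d)
  out <- list()
  for (i in seq_along(pops)) {
    for (j in seq_len(n_clones)) {
      gid <- sprintf("%s_g%02d", pops[i], j)
      geff <- rnorm(1, 0, geno_sd)
      for (m in seq_along(traits)) {
        val <- m + trait_scale * fit[i] + geff +
          rnorm(n_ramets, 0, noise_sd)
        out[[length(out) + 1L]] <- data.frame(
          individual = sprintf("%s_r%d", gid, seq_len(n_ramets)),
          genotype_id = gid, population = pops[i], trait = traits[m],
          year = 2010L, value = val)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic landscape to disk as standard text formats
#'
#' Writes a VCF v4.2 (GT field only), a population map TSV, a long-format
#' climate CSV covering the reference period and every GCM, a coordinates
#' CSV, an optional phenotype CSV and a truth JSON.
#'
#' @param landscape A [simulate_landscape()] result.
#' @param dir Output directory (created if absent).
#' @param phenotypes Optional long-format phenotype data.frame.
#' @return Invisibly, a named list of file paths.
#' @export
write_fixtures <- function(landscape, dir, phenotypes = NULL) {
  stopifnot(inherits(landscape, "yew_landscape"))
  g <- landscape$geno
  if (nrow(g$ind_meta) == 0 || length(unique(g$ind_meta$population)) == 0)
    stop("landscape has an empty population set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                popmap = file.path(dir, "popmap.tsv"),
                climate = file.path(dir, "climate.csv"),
                coords = file.path(dir, "coords.csv"),
                truth = file.path(dir, "truth.json"))
  write_vcf(g, paths$vcf)
  write.table(g$ind_meta[, c("id", "population")], paths$popmap,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("individual", "population"))
  long <- climate_to_long(landscape$clim_ref, "reference", "")
  for (gcm in names(landscape$clim_fut))
    long <- rbind(long,
                  climate_to_long(landscape$clim_fut[[gcm]], "future", gcm))
  write.csv(long, paths$climate, row.names = FALSE)
  write.csv(landscape$coords, paths$coords, row.names = FALSE)
  tr <- landscape$truth
  jsonlite::write_json(
    list(adaptive_loci = tr$adaptive_loci,
         cline_intercepts = tr$cline_intercepts,
         cline_slopes = tr$cline_slopes,
         gene_pool_labels = tr$gene_pool_labels,
         driver_var = tr$driver_var),
    paths$truth, auto_unbox = FALSE, digits = NA)
  if (!is.null(phenotypes)) {
    paths$phenotypes <- file.path(dir, "phenotypes.csv")
    write.csv(phenotypes, paths$phenotypes, row.names = FALSE)
  }
  invisible(paths)
}

climate_to_long <- function(mat, period, gcm) {
  data.frame(population = rep(rownames(mat), ncol(mat)),
             variable = rep(colnames(mat), each = nrow(mat)),
             value = as.vector(mat), period = period, gcm = gcm)
}

# plain-text VCF v4.2 writer (GT only); read back with vcfR
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=yewoffset-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0("##contig=<ID=", unique(g$snp_meta$contig), ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$ind_meta$id), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$snp_meta))) {
    calls <- g$calls[, j]
    gt <- ifelse(is.na(calls), "./.", gt_code[calls + 1L])
    writeLines(paste(c(g$snp_meta$contig[j], g$snp_meta$position[j],
                       g$snp_meta$id[j], "A", "C", ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}
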