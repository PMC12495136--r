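#' Default pipeline configuration
#'
#' All thresholds default to the study design they implement: missing-data
#' filters at 30\% for SNPs and individuals, minor allele count 20,
#' correlation pruning at |r| > 0.75, VIF below 10, candidate FDR 10\%,
#' forest top fraction 5\% intersected over 5 runs, consensus over at least
#' 2 methods, within-contig linkage pruning at r-squared < 0.7, K = 2
#' ordination axes, five offset classes, and at least 3 plants per
#' population for trait BLUPs.
#'
#' @param landscape A [landscape_config()] used when no file inputs are
#'   given.
#' @param input Optional named list of file paths: `vcf`, `popmap`,
#'   `climate`, `coords`, optionally `phenotypes`.
#' @param seed Integer master seed.
#' @param n_perm Permutations for forward selection and variance partition
#'   (default 199 in the pipeline; the selection functions default to 1000
#'   when called directly).
#' @param run_gf Fit forest-based importance and offsets (default TRUE).
#' @param gf_sets SNP sets for forest offsets (default outlier + random).
#' @param pairwise_d Compute the pairwise Jost's D matrix (default FALSE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(), input = NULL,
                            seed = 17, n_perm = 199, run_gf = TRUE,
                            gf_sets = c("outlier", "random"),
                            pairwise_d = FALSE) {
  structure(list(
    landscape = landscape, input = input, seed = as.integer(seed),
    max_missing_snp = 0.30, max_missing_ind = 0.30, min_mac = 20,
    alpha = 0.05, n_perm = n_perm, r_max = 0.75, vif_max = 10,
    fdr = 0.10, top_frac = 0.05, n_runs = 5, min_methods = 2,
    r2_prune = 0.7, K = 2, n_classes = 5, min_plants = 3,
    K_latent = 2, n_pcs = 2, run_gf = run_gf, gf_sets = gf_sets,
    pairwise_d = pairwise_d), class = "pipeline_config")
}

#' Run the full genomic-offset analysis pipeline
#'
#' Orchestrates: data simulation or reading; missingness/MAC filtering;
#' genotype PCA and gene-pool assignment; modal imputation; population
#' allele frequencies; climate-predictor selection and spatial
#' eigenvectors; variance partitioning; the association scans (RDA, partial
#' RDA, latent-factor ridge, forest raw/corrected) with consensus,
#' LD-pruned outlier set and frequency-matched random sets; per-GCM RDA
#' (and optionally forest) offsets for every SNP set with five-class
#' aggregation and robustness flags; the genomic discrepancy index; and
#' population differentiation statistics. Stage outputs are written as CSV
#' under `out_dir` with a JSON manifest; reruns with the same configuration
#' and seed are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res <- list()
  if (is.null(config$input)) {
    land <- stage("simulate", simulate_landscape(config$landscape))
    g_raw <- land$geno
    clim_ref <- land$clim_ref
    clim_fut <- land$clim_fut
    coords <- land$coords
    res$truth <- land$truth
  } else {
    for (f in c("vcf", "popmap", "climate", "coords"))
      if (!file.exists(config$input[[f]] %||% ""))
        stop("missing input file for '", f, "': ", config$input[[f]])
    g_raw <- stage("read", read_inputs(config$input$vcf,
                                       config$input$popmap))
    cl <- stage("read", read_climate(config$input$climate))
    clim_ref <- cl$ref
    clim_fut <- cl$future
    coords <- read.csv(config$input$coords)
  }

  # structure preset: missingness filter only (keep low-frequency alleles)
  g_struct <- stage("filter", filter_genotypes(
    g_raw, config$max_missing_snp, config$max_missing_ind, min_mac = 0))
  pca <- stage("pca", genotype_pca(g_struct, n_components = 10))
  pools <- stage("pools", assign_gene_pools(pca$scores, K = 2,
                                            seed = config$seed))
  # analysis preset: full filter, then modal imputation by gene pool
  g <- stage("filter", filter_genotypes(
    g_raw, config$max_missing_snp, config$max_missing_ind,
    config$min_mac))
  pool_lab <- pools[match(g$ind_meta$id, g_struct$ind_meta$id)]
  pool_lab[is.na(pool_lab)] <- 1L
  g <- stage("impute", impute_modal_by_pool(g, pool_lab))
  af <- stage("freqs", population_allele_freqs(g))
  Y <- af$freqs
  res$geno <- g; res$freqs <- af

  # population-level structure covariates: mean individual PC scores
  pcs <- stage("structure", {
    m <- matrix(NA_real_, nrow(Y), config$n_pcs,
                dimnames = list(rownames(Y),
                                sprintf("PC%d", seq_len(config$n_pcs))))
    for (p in rownames(Y))
      m[p, ] <- colMeans(pca$scores[
        g_struct$ind_meta$population == p, seq_len(config$n_pcs),
        drop = FALSE])
    m
  })
  mems <- stage("dbmem", dbmem(coords))
  mems <- mems[rownames(Y), , drop = FALSE]

  sel <- stage("climsel", select_climate(
    Y, clim_ref, alpha = config$alpha, n_perm = config$n_perm,
    r_max = config$r_max, vif_max = config$vif_max, seed = config$seed))
  clim_sel <- clim_ref[, sel$kept, drop = FALSE]
  res$selection <- sel

  vp <- stage("varpart", variance_partition(
    Y, clim_sel, pcs, mems, n_perm = config$n_perm, seed = config$seed))
  res$varpart <- vp

  # association scans
  rda_m <- stage("gea", rda_fit(Y, clim_sel))
  prda_m <- stage("gea", rda_fit(Y, clim_sel, condition = pcs))
  rda_out <- rda_outliers(rda_m, K = config$K, fdr = config$fdr)
  prda_out <- rda_outliers(prda_m, K = config$K, fdr = config$fdr)
  lf <- stage("gea", lfmm_ridge(Y, clim_sel, K_latent = config$K_latent,
                                fdr = config$fdr))
  sets <- list(rda = rda_out$candidates, prda = prda_out$candidates,
               lfmm = lf$candidates)
  if (config$run_gf) {
    gf_raw <- stage("gea", gf_importance(
      Y, clim_sel, n_runs = config$n_runs, top_frac = config$top_frac,
      seed = config$seed))
    gf_cor <- stage("gea", gf_importance(
      Y, clim_sel, n_runs = config$n_runs, top_frac = config$top_frac,
      correct = TRUE, K_latent = config$K_latent, seed = config$seed + 1))
    sets$gf_raw <- gf_raw$candidates
    sets$gf_corrected <- gf_cor$candidates
    res$gf <- list(raw = gf_raw, corrected = gf_cor)
  }
  all_outlier <- sort(unique(unlist(sets)))
  consensus <- consensus_candidates(sets, config$min_methods)
  outlier_set <- ld_prune_within_contigs(g, consensus, config$r2_prune)
  maf <- pmin(colMeans(Y), 1 - colMeans(Y))
  random_set <- matched_random_set(maf, all_outlier, outlier_set,
                                   seed = config$seed)
  random_set_2 <- matched_random_set(maf, union(all_outlier, random_set),
                                     outlier_set, seed = config$seed + 1)
  res$candidates <- list(per_method = sets, all_outlier = all_outlier,
                         consensus = consensus, outlier_set = outlier_set,
                         random_set = random_set,
                         random_set_2 = random_set_2,
                         stats = list(rda = rda_out, prda = prda_out,
                                      lfmm = lf["gif"]))

  # offsets per SNP set
  snp_sets <- list(all = colnames(Y), outlier = outlier_set,
                   random = random_set, random_2 = random_set_2,
                   all_outlier = all_outlier)
  snp_sets <- Filter(function(s) length(s) >= 2, snp_sets)
  offsets <- list(); models <- list()
  for (nm in names(snp_sets)) {
    m <- rda_fit(Y[, snp_sets[[nm]], drop = FALSE], clim_sel)
    models[[nm]] <- m
    raw <- vapply(clim_fut, function(cf)
      rda_offset(m, clim_ref[, sel$kept, drop = FALSE],
                 cf[, sel$kept, drop = FALSE], K = config$K),
      numeric(nrow(Y)))
    offsets[[paste0("rda_", nm)]] <-
      aggregate_offsets(raw, method = "rda", snp_set = nm,
                        n_classes = config$n_classes)
  }
  if (config$run_gf) {
    for (nm in intersect(config$gf_sets, names(snp_sets))) {
      tv <- gf_turnover(Y[, snp_sets[[nm]], drop = FALSE], clim_sel,
                        seed = config$seed)
      models[[paste0("gf_", nm)]] <- tv
      raw <- vapply(clim_fut, function(cf)
        gf_offset(tv, clim_ref[, sel$kept, drop = FALSE],
                  cf[, sel$kept, drop = FALSE]), numeric(nrow(Y)))
      offsets[[paste0("gf_", nm)]] <-
        aggregate_offsets(raw, method = "gf", snp_set = nm,
                          n_classes = config$n_classes)
    }
    a <- offsets[[paste0("rda_", config$gf_sets[1])]]
    b <- offsets[[paste0("gf_", config$gf_sets[1])]]
    if (!is.null(a) && !is.null(b))
      res$robustness <- robustness_flags(a, b)
  }
  res$offsets <- offsets; res$models <- models

  gdi_set <- if ("random" %in% names(models)) "random" else "all"
  res$gdi <- stage("gdi", gdi_rda(
    models[[gdi_set]], Y[, snp_sets[[gdi_set]], drop = FALSE],
    clim_ref[, sel$kept, drop = FALSE], K = config$K))

  res$popgen <- stage("popgen", list(
    fst = pop_specific_fst(g),
    jost = josts_d(g, pairwise = config$pairwise_d),
    pca_var = pca$var_explained, gene_pools = pools))

  write_pipeline_outputs(res, config, out_dir)
  res$out_dir <- out_dir
  invisible(res)
}

write_pipeline_outputs <- function(res, config, out_dir) {
  p <- function(f) file.path(out_dir, f)
  write.csv(res$varpart$table, p("variance_partition.csv"),
            row.names = FALSE)
  off <- do.call(rbind, lapply(res$offsets, function(o)
    o[, c("population", "method", "snp_set", "mean_raw", "normalized",
          "class")]))
  write.csv(off, p("offsets.csv"), row.names = FALSE)
  write.csv(data.frame(population = names(res$gdi$raw),
                       raw = res$gdi$raw, gdi = res$gdi$gdi),
            p("gdi.csv"), row.names = FALSE)
  cand <- res$candidates
  cand_df <- data.frame(snp = colnames(res$freqs$freqs))
  for (m in names(cand$per_method))
    cand_df[[m]] <- cand_df$snp %in% cand$per_method[[m]]
  cand_df$outlier_set <- cand_df$snp %in% cand$outlier_set
  cand_df$random_set <- cand_df$snp %in% cand$random_set
  write.csv(cand_df, p("candidates.csv"), row.names = FALSE)
  write.csv(data.frame(population = names(res$popgen$fst),
                       fst = res$popgen$fst),
            p("popgen_fst.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("yewoffset")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    settings = config[!vapply(config, is.list, logical(1)) &
                        names(config) != "input"],
    files = as.list(tools::md5sum(list.files(out_dir, "\\.csv$",
                                             full.names = TRUE))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `run_dir` and tabulates the variance
#' partition, candidate counts per method (with the union count), offsets
#' and discrepancy index per population, and, when present, the validation
#' table.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of data.frames with a `complete` flag.
#' @export
report <- function(run_dir) {
  p <- function(f) file.path(run_dir, f)
  need <- c("variance_partition.csv", "offsets.csv", "gdi.csv",
            "candidates.csv", "manifest.json")
  present <- file.exists(vapply(need, p, character(1)))
  out <- list(complete = all(present))
  if (!out$complete)
    warning("incomplete run; missing: ",
            paste(need[!present], collapse = ", "))
  if (present[1]) out$variance_partition <- read.csv(p(need[1]))
  if (present[2]) out$offsets <- read.csv(p(need[2]))
  if (present[3]) out$gdi <- read.csv(p(need[3]))
  if (present[4]) {
    cand <- read.csv(p(need[4]))
    methods <- setdiff(names(cand),
                       c("snp", "outlier_set", "random_set"))
    counts <- data.frame(
      method = methods,
      n_candidates = vapply(methods, function(m) sum(cand[[m]]),
                            integer(1)))
    counts <- rbind(counts, data.frame(
      method = "union",
      n_candidates = sum(rowSums(cand[methods]) > 0)))
    out$candidate_counts <- counts
  }
  if (present[5]) out$manifest <- jsonlite::read_json(p(need[5]))
  if (file.exists(p("validation.csv")))
    out$validation <- read.csv(p("validation.csv"))
  out
}
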