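#' Construct a genotype matrix container
#'
#' Container for diploid biallelic genotypes coded as the count of the
#' alternate allele (0/1/2, `NA` for missing) together with SNP metadata
#' (contig, 1-based position) and individual-to-population assignment.
#'
#' @param calls Integer matrix, individuals x SNPs, values in
#'   `{0, 1, 2, NA}`.
#' @param snp_meta data.frame with columns `id`, `contig`, `position`.
#' @param ind_meta data.frame with columns `id`, `population`.
#' @return An object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(calls, snp_meta, ind_meta) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(ind_meta), ncol(calls) == nrow(snp_meta),
            all(calls %in% c(0L, 1L, 2L, NA_integer_)),
            !anyDuplicated(snp_meta$id),
            all(c("id", "contig", "position") %in% names(snp_meta)),
            all(c("id", "population") %in% names(ind_meta)))
  dimnames(calls) <- list(ind_meta$id, snp_meta$id)
  structure(list(calls = calls,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 ind_meta = as.data.frame(ind_meta,
                                          stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %d populations, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$ind_meta$population)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read a VCF and population map into a genotype matrix
#'
#' Keeps biallelic SNPs only; multiallelic records are dropped and counted.
#' Genotypes are coded as the number of alternate alleles, regardless of the
#' phasing separator; any allele missing in a call makes the call missing.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param popmap_path Path to a TSV with columns individual, population
#'   (header optional).
#' @return A `genotype_matrix`; the number of dropped multiallelic records
#'   is attached as attribute `n_multiallelic_dropped`.
#' @export
read_inputs <- function(vcf_path, popmap_path) {
  stopifnot(file.exists(vcf_path), file.exists(popmap_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_drop <- sum(!bi)
  if (n_drop > 0) message(n_drop, " multiallelic record(s) dropped")
  vcf <- vcf[bi, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # alternate-allele count, phase-agnostic
  code <- function(x) {
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, integer(1))
  }
  calls <- t(apply(gt, 1, code))
  if (ncol(vcf@gt) == 2L) calls <- matrix(calls, ncol = 1L,
                                          dimnames = dimnames(gt))
  calls <- t(calls)  # individuals x SNPs
  popmap <- read.table(popmap_path, sep = "\t", header = FALSE,
                       stringsAsFactors = FALSE)
  if (identical(tolower(popmap[1, 1]), "individual"))
    popmap <- popmap[-1, , drop = FALSE]
  names(popmap)[1:2] <- c("id", "population")
  missing_samples <- setdiff(rownames(calls), popmap$id)
  if (length(missing_samples) > 0)
    stop("VCF sample(s) absent from popmap: ",
         paste(missing_samples, collapse = ", "))
  popmap <- popmap[match(rownames(calls), popmap$id), ]
  fix <- vcfR::getFIX(vcf)
  snp_meta <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    contig = fix[, "CHROM"], position = as.integer(fix[, "POS"]),
    stringsAsFactors = FALSE)
  g <- new_genotype_matrix(calls, snp_meta, popmap[, c("id", "population")])
  attr(g, "n_multiallelic_dropped") <- n_drop
  g
}

report_rows <- function(items, type, rule)
  data.frame(item = items, type = rep(type, length(items)),
             rule = rep(rule, length(items)))

#' Filter genotypes by missingness and minor allele count
#'
#' Applies, in this order: (1) drop SNPs with missing-data fraction above
#' `max_missing_snp`; (2) drop individuals with missing-data fraction above
#' `max_missing_ind` (over the retained SNPs); (3) drop SNPs whose minor
#' allele count over the retained individuals, counted on non-missing calls,
#' is below `min_mac`. The order is fixed because the allele count depends
#' on the retained individual set. With 475 diploid individuals, the default
#' `min_mac = 20` corresponds to a minor allele frequency of
#' 20 / (2 * 475) = 2.11\%.
#'
#' @param g A `genotype_matrix`.
#' @param max_missing_snp,max_missing_ind Maximum tolerated missing fraction
#'   (default 0.30 for both).
#' @param min_mac Minimum minor allele count (default 20).
#' @return A filtered `genotype_matrix`; a data.frame of dropped items and
#'   rules is attached as attribute `filter_report`.
#' @export
filter_genotypes <- function(g, max_missing_snp = 0.30,
                             max_missing_ind = 0.30, min_mac = 20) {
  stopifnot(inherits(g, "genotype_matrix"),
            max_missing_snp >= 0, max_missing_snp <= 1,
            max_missing_ind >= 0, max_missing_ind <= 1, min_mac >= 0)
  report <- data.frame(item = character(), type = character(),
                       rule = character())
  snp_miss <- colMeans(is.na(g$calls))
  keep_snp <- snp_miss <= max_missing_snp
  report <- rbind(report, report_rows(
    g$snp_meta$id[!keep_snp], "snp",
    sprintf("missingness > %g", max_missing_snp)))
  calls <- g$calls[, keep_snp, drop = FALSE]

  ind_miss <- rowMeans(is.na(calls))
  keep_ind <- ind_miss <= max_missing_ind
  report <- rbind(report, report_rows(
    g$ind_meta$id[!keep_ind], "individual",
    sprintf("missingness > %g", max_missing_ind)))
  calls <- calls[keep_ind, , drop = FALSE]

  alt <- colSums(calls, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(calls))
  mac <- pmin(alt, tot - alt)
  keep_mac <- mac >= min_mac
  report <- rbind(report, report_rows(
    colnames(calls)[!keep_mac], "snp",
    sprintf("minor allele count < %d", min_mac)))
  calls <- calls[, keep_mac, drop = FALSE]
  if (ncol(calls) == 0) stop("all SNPs removed by filtering")

  out <- new_genotype_matrix(
    calls,
    g$snp_meta[match(colnames(calls), g$snp_meta$id), ],
    g$ind_meta[match(rownames(calls), g$ind_meta$id), ])
  attr(out, "filter_report") <- report
  out
}

#' Impute missing genotypes with the modal genotype of the gene pool
#'
#' Each missing call is replaced by the most common genotype code among the
#' non-missing calls of the same gene pool at that SNP; ties break toward
#' the lowest code. A pool with no data at a SNP falls back to the global
#' mode across all individuals.
#'
#' @param g A `genotype_matrix`.
#' @param pool_labels Per-individual gene-pool labels (e.g. from
#'   [assign_gene_pools()]), in the order of `g$ind_meta`.
#' @return A `genotype_matrix` with no missing calls.
#' @export
impute_modal_by_pool <- function(g, pool_labels) {
  stopifnot(inherits(g, "genotype_matrix"),
            length(pool_labels) == nrow(g$calls), !anyNA(pool_labels))
  calls <- g$calls
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_integer_)
    tab <- tabulate(x + 1L, nbins = 3L)
    which.max(tab) - 1L  # which.max takes the first (lowest) on ties
  }
  global_mode <- apply(calls, 2, modal)
  if (anyNA(global_mode))
    stop("SNP(s) missing in all individuals: ",
         paste(colnames(calls)[is.na(global_mode)], collapse = ", "))
  for (pool in unique(pool_labels)) {
    rows <- pool_labels == pool
    sub <- calls[rows, , drop = FALSE]
    nmiss <- colSums(is.na(sub))
    for (j in which(nmiss > 0)) {
      m <- modal(sub[, j])
      if (is.na(m)) m <- global_mode[j]
      sub[is.na(sub[, j]), j] <- m
    }
    calls[rows, ] <- sub
  }
  new_genotype_matrix(calls, g$snp_meta, g$ind_meta)
}

#' Population alternate-allele frequencies
#'
#' Frequency per population and SNP over non-missing calls:
#' sum of genotype codes / (2 x number of genotyped individuals).
#'
#' @param g A `genotype_matrix`.
#' @return A list of class `allele_freq_matrix` with `freqs`
#'   (populations x SNPs) and `n_obs` (non-missing allele counts).
#' @export
population_allele_freqs <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$ind_meta$population)
  if (any(table(g$ind_meta$population) == 0)) stop("empty population")
  freqs <- matrix(NA_real_, length(pops), ncol(g$calls),
                  dimnames = list(pops, colnames(g$calls)))
  n_obs <- matrix(0L, length(pops), ncol(g$calls),
                  dimnames = dimnames(freqs))
  for (p in pops) {
    sub <- g$calls[g$ind_meta$population == p, , drop = FALSE]
    n <- 2L * colSums(!is.na(sub))
    n_obs[p, ] <- n
    freqs[p, ] <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / n, NA_real_)
  }
  structure(list(freqs = freqs, n_obs = n_obs),
            class = "allele_freq_matrix")
}

#' Prune linked SNPs within contigs
#'
#' Greedy left-to-right scan over the requested SNPs, ordered by position
#' within each contig: a SNP is dropped when its squared Pearson correlation
#' (r-squared of 0/1/2 genotype codes, over individuals with both calls
#' present) with an already-kept SNP of the same contig reaches `r2_max`.
#' SNPs on different contigs are never compared.
#'
#' @param g A `genotype_matrix`.
#' @param snp_subset Character vector of SNP ids to prune (default: all).
#' @param r2_max Linkage threshold; kept pairs satisfy r-squared < `r2_max`
#'   (default 0.7).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune_within_contigs <- function(g, snp_subset = NULL, r2_max = 0.7) {
  stopifnot(inherits(g, "genotype_matrix"), r2_max > 0, r2_max <= 1)
  snp_subset <- snp_subset %||% g$snp_meta$id
  bad <- setdiff(snp_subset, g$snp_meta$id)
  if (length(bad) > 0)
    stop("SNP id(s) not in matrix: ", paste(bad, collapse = ", "))
  meta <- g$snp_meta[g$snp_meta$id %in% snp_subset, ]
  kept <- character(0)
  for (ctg in unique(meta$contig)) {
    sub <- meta[meta$contig == ctg, ]
    sub <- sub[order(sub$position), ]
    kept_ctg <- character(0)
    for (id in sub$id) {
      x <- g$calls[, id]
      ok <- TRUE
      for (kid in kept_ctg) {
        y <- g$calls[, kid]
        both <- !is.na(x) & !is.na(y)
        if (sum(both) < 3) next
        r <- suppressWarnings(cor(x[both], y[both]))
        if (!is.na(r) && r^2 >= r2_max) { ok <- FALSE; break }
      }
      if (ok) kept_ctg <- c(kept_ctg, id)
    }
    kept <- c(kept, kept_ctg)
  }
  kept[order(match(kept, g$snp_meta$id))]
}

#' Read a long-format climate CSV into per-period matrices
#'
#' Expects columns population, variable, value, period, gcm (as written by
#' [write_fixtures()]). Returns the reference matrix and one matrix per GCM.
#'
#' @param path CSV path.
#' @return List with `ref` (populations x variables matrix) and `future`
#'   (named list of per-GCM matrices).
#' @export
read_climate <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "variable", "value", "period", "gcm") %in%
                  names(long)))
  tomat <- function(d) {
    pops <- unique(d$population); vars <- unique(d$variable)
    m <- matrix(NA_real_, length(pops), length(vars),
                dimnames = list(pops, vars))
    m[cbind(match(d$population, pops), match(d$variable, vars))] <- d$value
    m
  }
  ref <- tomat(long[long$period == "reference", ])
  fut <- lapply(split(long[long$period != "reference", ],
                      long$gcm[long$period != "reference"]), tomat)
  list(ref = ref, future = fut)
}
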