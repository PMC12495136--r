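write_lines_vcf <- function(body, dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  writeLines(body, path)
  path
}

toy_vcf_header <- function(samples)
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

test_that("VCF reading codes alt-allele counts and drops multiallelics", {
  dir <- withr::local_tempdir()
  vcf <- write_lines_vcf(c(
    toy_vcf_header(c("s1", "s2", "s3")),
    "c1\t10\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "c1\t20\tv2\tG\tC,T\t.\tPASS\t.\tGT\t0/0\t1/2\t0/0",
    "c1\t30\tv3\tG\tT\t.\tPASS\t.\tGT\t./.\t1|0\t0/1"), dir)
  popmap <- file.path(dir, "popmap.tsv")
  writeLines(c("s1\tP1", "s2\tP1", "s3\tP2"), popmap)
  expect_message(g <- read_inputs(vcf, popmap), "multiallelic")
  expect_equal(dim(g$calls), c(3L, 2L))
  expect_equal(attr(g, "n_multiallelic_dropped"), 1L)
  # phase separator is irrelevant; missing alleles give NA
  expect_equal(unname(g$calls[, "v1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "v3"]), c(NA_integer_, 1L, 1L))

  writeLines(c("s1\tP1", "s2\tP1"), popmap)
  expect_error(read_inputs(vcf, popmap), "s3")
})

test_that("missingness and allele-count filters apply in the stated order", {
  g <- toy_genotypes()
  # identity when nothing can fail
  same <- filter_genotypes(g, 1, 1, min_mac = 0)
  expect_identical(same$calls, g$calls)

  # a singleton SNP is removed at min_mac = 2
  calls <- cbind(rep(0L, 10), c(1L, rep(0L, 9)))
  g1 <- new_genotype_matrix(
    calls + 0L,
    data.frame(id = c("a", "b"), contig = "c", position = c(1L, 2L)),
    data.frame(id = sprintf("i%d", 1:10), population = "P"))
  g1$calls[, 1] <- c(rep(1L, 5), rep(0L, 5))  # keep one SNP polymorphic
  f <- filter_genotypes(g1, 1, 1, min_mac = 2)
  expect_equal(colnames(f$calls), "a")
  expect_true("b" %in% attr(f, "filter_report")$item)

  # the MAC count uses individuals retained after the missingness steps:
  # the dropped individual carries the only copies of SNP b's minor allele
  calls2 <- cbind(c(2L, rep(0L, 3)), c(1L, 0L, 1L, 0L),
                  rbind(rep(NA_integer_, 2), matrix(0L, 3, 2)))
  calls2[1, 3:4] <- NA_integer_
  g2 <- new_genotype_matrix(
    calls2,
    data.frame(id = letters[1:4], contig = "c", position = 1:4 * 10L),
    data.frame(id = sprintf("i%d", 1:4), population = "P"))
  f2 <- filter_genotypes(g2, max_missing_snp = 0.6, max_missing_ind = 0.4,
                         min_mac = 1)
  expect_false("i1" %in% rownames(f2$calls))   # 50% missing individual
  expect_false("a" %in% colnames(f2$calls))    # minor allele left with i1
  expect_true("b" %in% colnames(f2$calls))
})

test_that("modal imputation respects pools, ties and fallbacks", {
  calls <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(NA, 1L),
                 c(2L, NA), c(2L, NA), c(1L, NA), c(NA, NA))
  g <- new_genotype_matrix(
    calls,
    data.frame(id = c("x", "y"), contig = "c", position = c(1L, 2L)),
    data.frame(id = sprintf("i%d", 1:8), population = "P"))
  pools <- rep(c("w", "e"), each = 4)
  gi <- impute_modal_by_pool(g, pools)
  expect_false(anyNA(gi$calls))
  # pool w at snp x: {0,0,1} -> mode 0
  expect_equal(unname(gi$calls[4, "x"]), 0L)
  # pool e at snp x: {2,2,1} -> mode 2
  expect_equal(unname(gi$calls[8, "x"]), 2L)
  # pool e at snp y entirely missing -> global mode over {0,0,1,1} -> tie -> 0
  expect_equal(unname(gi$calls[5:8, "y"]), rep(0L, 4))

  # no missing -> identity
  expect_identical(impute_modal_by_pool(gi, pools)$calls, gi$calls)

  all_na <- g
  all_na$calls[, "x"] <- NA_integer_
  expect_error(impute_modal_by_pool(all_na, pools), "missing in all")
})

test_that("population frequencies are counts over non-missing alleles", {
  calls <- rbind(c(0L, 0L), c(1L, NA), c(2L, 2L))
  g <- new_genotype_matrix(
    calls,
    data.frame(id = c("x", "y"), contig = "c", position = c(1L, 2L)),
    data.frame(id = c("i1", "i2", "i3"), population = "P"))
  af <- population_allele_freqs(g)
  expect_equal(unname(af$freqs["P", ]), c(3 / 6, 2 / 4))
  expect_equal(unname(af$n_obs["P", ]), c(6L, 4L))

  mono <- new_genotype_matrix(
    matrix(0L, 3, 1), data.frame(id = "m", contig = "c", position = 1L),
    data.frame(id = c("i1", "i2", "i3"), population = "P"))
  expect_equal(unname(population_allele_freqs(mono)$freqs[1, 1]), 0)
})

test_that("linkage pruning is greedy within contigs and matches brute force", {
  set.seed(42)
  n <- 40
  base <- rbinom(n, 2, 0.4)
  calls <- cbind(base, base,                                   # duplicates
                 rbinom(n, 2, 0.5), base, rbinom(n, 2, 0.3),
                 base)                                          # c2 copy
  storage.mode(calls) <- "integer"
  meta <- data.frame(id = paste0("s", 1:6),
                     contig = c(rep("c1", 5), "c2"),
                     position = c(10L, 20L, 30L, 40L, 50L, 10L))
  g <- new_genotype_matrix(calls, meta,
                           data.frame(id = sprintf("i%d", 1:n),
                                      population = "P"))
  kept <- ld_prune_within_contigs(g, r2_max = 0.7)
  # duplicate of s1 on c1 dropped; same genotypes on c2 kept
  expect_false("s2" %in% kept)
  expect_false("s4" %in% kept)
  expect_true(all(c("s1", "s6") %in% kept))
  expect_equal(sort(kept),
               sort(oracle_ld_prune(g$calls, meta, 0.7)))

  # self-consistency: no kept pair within a contig at or above the threshold
  land <- small_landscape()
  kept2 <- ld_prune_within_contigs(land$geno, r2_max = 0.5)
  meta2 <- land$geno$snp_meta[land$geno$snp_meta$id %in% kept2, ]
  for (ctg in unique(meta2$contig)) {
    ids <- meta2$id[meta2$contig == ctg]
    if (length(ids) < 2) next
    cc <- suppressWarnings(
      cor(land$geno$calls[, ids], use = "pairwise.complete.obs"))
    diag(cc) <- 0
    expect_true(all(cc^2 < 0.5, na.rm = TRUE))
  }

  expect_error(ld_prune_within_contigs(g, "nope"), "not in matrix")
})
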