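# shared small fixtures, built once per test run

the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, the_cache)) assign(key, expr, the_cache)
  get(key, the_cache)
}

small_landscape <- function() cached("land_small", {
  simulate_landscape(landscape_config(
    n_pops = 20, n_ind_per_pop = 10, n_snps = 300, frac_adaptive = 0.1,
    seed = 11))
})

small_freqs <- function() cached("freqs_small", {
  land <- small_landscape()
  g <- impute_modal_by_pool(
    land$geno, ifelse(land$truth$gene_pool_labels[
      land$geno$ind_meta$population] == "west", 1L, 2L))
  population_allele_freqs(g)
})

# hand-built genotype matrix: 3 pops x 4 individuals, 6 SNPs on 2 contigs
toy_genotypes <- function() {
  calls <- rbind(
    c(0L, 1L, 0L, 2L, 0L, 0L),
    c(0L, 1L, 1L, 2L, 0L, 1L),
    c(1L, 0L, 0L, 1L, NA, 0L),
    c(0L, 0L, 0L, 2L, 0L, 0L),
    c(2L, 2L, 1L, 0L, 1L, 2L),
    c(1L, 2L, 2L, 0L, 1L, 1L),
    c(2L, 1L, 1L, 1L, 2L, 2L),
    c(2L, 2L, 1L, 0L, NA, 2L),
    c(1L, 1L, 2L, 1L, 1L, 1L),
    c(1L, 2L, 1L, 1L, 2L, 1L),
    c(0L, 1L, 1L, 2L, 1L, 0L),
    c(1L, 1L, 2L, 1L, 1L, 1L))
  new_genotype_matrix(
    calls,
    snp_meta = data.frame(id = paste0("s", 1:6),
                          contig = rep(c("c1", "c2"), each = 3),
                          position = rep(c(100L, 250L, 400L), 2)),
    ind_meta = data.frame(id = sprintf("i%02d", 1:12),
                          population = rep(c("A", "B", "C"), each = 4)))
}
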