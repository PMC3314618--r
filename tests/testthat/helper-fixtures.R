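# Shared fixtures: reads are built in code, never stored.

make_reads <- function(bases, q = 40, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%02d", seq_along(bases))
  quals <- lapply(nchar(bases), function(n) rep(as.integer(q), n))
  read_set(ids, bases, quals)
}

# a tiny but realistic simulation: 1 species, few individuals/loci
tiny_config <- function(seed, ...) {
  args <- list(n_populations = 1, n_individuals = 4, n_loci = 2,
               n_species = 1, heterozygosity = 0.5, mean_coverage = 25,
               intron_len_range = c(200, 260), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

noise_free <- list(substitution_rate = 0, hp_base_rate = 0,
                   chimera_rate = 0, short_frac = 0)

run_tiny_pipeline <- function(cfg) {
  truth <- simulate_genotypes(cfg)
  sim <- simulate_reads(truth, cfg)
  dm <- suppressWarnings(demultiplex(sim$reads, sim$samples, sim$loci))
  list(sim = sim, dm = dm)
}

# fraction of bins whose called allele pair equals the truth pair exactly
recovery_fraction <- function(genotypes, truth_genotypes) {
  m <- match(paste(genotypes$individual, genotypes$locus),
             paste(truth_genotypes$individual, truth_genotypes$locus))
  ok <- mapply(function(a1, a2, t1, t2) {
    !is.na(a1) && setequal(c(a1, a2), c(t1, t2))
  }, genotypes$allele1, genotypes$allele2,
     truth_genotypes$allele1_seq[m], truth_genotypes$allele2_seq[m])
  mean(ok)
}
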