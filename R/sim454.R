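# sim454: ground-truthed simulator of multiplexed 454-style amplicon
# libraries. Reads follow the fusion layout
#   adaptorA + MID + fwd_primer + insert + rc(rev_primer) + rc(MID) + rc(adaptorB)
# with per-base substitution errors driven by a two-level quality mixture,
# homopolymer run-length errors, single-crossover chimeras at heterozygous
# templates, truncated-read contamination, and random read orientation.

#' Simulation configuration
#'
#' Defaults are the study conditions the pipeline is validated under: one
#' gasketed plate region (population) of 20 individuals for each of 2
#' species at 5 loci (200 bins), introns of 400--600 bp, negative-binomial
#' coverage with mean 70.7, 1% substitution error, 12.5% chimeric reads at
#' heterozygous templates, and a 13:9 allelic sampling skew. Heterozygosity
#' defaults contrast a diverse species (0.6) with a depauperate one (0.1).
#'
#' @param n_populations,n_individuals,n_loci,n_species Design counts.
#' @param intron_len_range Intron length bounds (bp).
#' @param pool_size Alleles per locus pool.
#' @param divergence Per-base substitution divergence of pool alleles from
#'   the ancestral intron (every pair of pool alleles is kept >= 2
#'   substitutions apart so phasing and chimera detection are defined).
#' @param heterozygosity Per-species heterozygosity (recycled to
#'   `n_species`).
#' @param mean_coverage,dispersion Negative-binomial coverage per bin
#'   (`dispersion` is the NB size parameter).
#' @param substitution_rate Expected per-base substitution error.
#' @param hp_base_rate,hp_max_rate Per-run homopolymer error probability
#'   `min(hp_base_rate * (L - 1), hp_max_rate)` for runs of length L >= 3.
#' @param chimera_rate Fraction of reads at heterozygous bins replaced by
#'   single-crossover recombinants of the two true alleles.
#' @param allelic_skew Probability a non-chimeric read at a het bin copies
#'   allele 1 (default 13/22, the 13:9 ratio).
#' @param short_frac Truncated-read contamination fraction.
#' @param trunc_len_range Length range of truncated reads (below the 150
#'   bp filter).
#' @param mid_length MID barcode length.
#' @param primer_length Template-specific primer length.
#' @param q_high,q_low Quality mixture levels; the low-quality fraction is
#'   set so the expected error equals `substitution_rate`.
#' @param q_hp_err Quality written across a run that received a
#'   homopolymer error.
#' @param adapter_a,adapter_b Fusion adaptor sequences.
#' @param seed Mandatory RNG seed; every simulator draw derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 1, n_individuals = 20, n_loci = 5,
                       n_species = 2, intron_len_range = c(400, 600),
                       pool_size = 8, divergence = 0.01,
                       heterozygosity = c(0.6, 0.1),
                       mean_coverage = 70.7, dispersion = 8,
                       substitution_rate = 0.01,
                       hp_base_rate = 0.01, hp_max_rate = 0.10,
                       chimera_rate = 0.125, allelic_skew = 13 / 22,
                       short_frac = 0.05, trunc_len_range = c(50, 149),
                       mid_length = 10, primer_length = 20,
                       q_high = 40, q_low = 10, q_hp_err = 15,
                       adapter_a = ADAPTER_A, adapter_b = ADAPTER_B,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  cfg <- list(
    n_populations = as.integer(n_populations),
    n_individuals = as.integer(n_individuals),
    n_loci = as.integer(n_loci), n_species = as.integer(n_species),
    intron_len_range = as.integer(intron_len_range),
    pool_size = as.integer(pool_size), divergence = divergence,
    heterozygosity = rep_len(heterozygosity, n_species),
    mean_coverage = mean_coverage, dispersion = dispersion,
    substitution_rate = substitution_rate, hp_base_rate = hp_base_rate,
    hp_max_rate = hp_max_rate, chimera_rate = chimera_rate,
    allelic_skew = allelic_skew, short_frac = short_frac,
    trunc_len_range = as.integer(trunc_len_range),
    mid_length = as.integer(mid_length),
    primer_length = as.integer(primer_length),
    q_high = as.integer(q_high), q_low = as.integer(q_low),
    q_hp_err = as.integer(q_hp_err),
    adapter_a = adapter_a, adapter_b = adapter_b, seed = as.integer(seed)
  )
  rates <- c(cfg$divergence, cfg$substitution_rate, cfg$hp_base_rate,
             cfg$hp_max_rate, cfg$chimera_rate, cfg$allelic_skew,
             cfg$short_frac, cfg$heterozygosity)
  stopifnot(all(rates >= 0 & rates <= 1), cfg$mean_coverage > 0,
            cfg$dispersion > 0, cfg$pool_size >= 1, cfg$mid_length >= 6,
            cfg$intron_len_range[1] <= cfg$intron_len_range[2])
  class(cfg) <- "sim_config"
  cfg
}

# Allele frequency vector with sum(p^2) = 1 - H: one major allele at
# frequency x, the rest uniform. H is capped at the pool's maximum
# 1 - 1/pool_size.
.pool_frequencies <- function(pool_size, heterozygosity) {
  if (pool_size == 1L) return(1)
  s <- max(1 - heterozygosity, 1 / pool_size)
  f <- function(x) x^2 + (1 - x)^2 / (pool_size - 1) - s
  x <- uniroot(f, c(1 / pool_size, 1), tol = 1e-12)$root
  c(x, rep((1 - x) / (pool_size - 1), pool_size - 1L))
}

.mutate_seq <- function(seq, n_mut) {
  ch <- strsplit1(seq)
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

.hamming <- function(a, b) sum(strsplit1(a) != strsplit1(b))

#' Simulate true diploid genotypes
#'
#' Per species and locus, an allele pool is generated by mutating a random
#' ancestral intron (all differences are substitutions; every allele pair
#' is at least 2 apart). Individuals draw two alleles i.i.d. from pool
#' frequencies tuned so expected heterozygosity matches the configured
#' value. Also generates the MID sample sheet and the locus/primer table.
#'
#' @param config A [sim_config()].
#' @return List: `genotypes` (per individual x locus truth), `samples`
#'   (sample sheet), `loci` (locus table with a `species` column),
#'   `pools` (allele pools), `config`.
#' @export
simulate_genotypes <- function(config) {
  withr::with_seed(config$seed, {
    n_sp <- config$n_species
    species <- sprintf("SP%d", seq_len(n_sp))
    pops <- sprintf("P%02d", seq_len(config$n_populations))

    # primers: unique random k-mers per species x locus x direction
    n_prim <- 2L * n_sp * config$n_loci
    repeat {
      prim <- random_dna(n_prim, config$primer_length)
      if (!anyDuplicated(prim)) break
    }
    loci <- expand.grid(l = seq_len(config$n_loci), species = species,
                        stringsAsFactors = FALSE)
    loci <- data.frame(
      locus = sprintf("%s_L%d", loci$species, loci$l),
      fwd_primer = prim[seq_len(nrow(loci))],
      rev_primer = prim[nrow(loci) + seq_len(nrow(loci))],
      min_len = config$intron_len_range[1], max_len = config$intron_len_range[2],
      species = loci$species, stringsAsFactors = FALSE
    )

    # allele pools
    pools <- list()
    for (i in seq_len(nrow(loci))) {
      len <- sample(config$intron_len_range[1]:config$intron_len_range[2], 1)
      anc <- random_dna(1, len)
      pool <- anc
      tries <- 0L
      while (length(pool) < config$pool_size && tries < 1000L) {
        n_mut <- max(2L, rbinom(1, len, config$divergence))
        cand <- .mutate_seq(anc, n_mut)
        if (all(vapply(pool, .hamming, numeric(1), b = cand) >= 2)) {
          pool <- c(pool, cand)
        }
        tries <- tries + 1L
      }
      pools[[loci$locus[i]]] <- unname(pool)
    }

    # MIDs: globally unique so pooled libraries stay unambiguous
    n_mid <- config$n_populations * n_sp * config$n_individuals
    repeat {
      mids <- random_dna(n_mid, config$mid_length)
      if (!anyDuplicated(mids)) break
    }
    samples <- expand.grid(i = seq_len(config$n_individuals),
                           species = species, population = pops,
                           stringsAsFactors = FALSE)
    samples <- data.frame(
      mid = mids[seq_len(nrow(samples))],
      individual = sprintf("%s_%s_I%02d", samples$species, samples$population,
                           samples$i),
      population = samples$population, species = samples$species,
      stringsAsFactors = FALSE
    )

    gt <- list()
    for (si in seq_len(nrow(samples))) {
      sp_idx <- match(samples$species[si], species)
      sp_loci <- loci[loci$species == samples$species[si], , drop = FALSE]
      freqs <- .pool_frequencies(config$pool_size,
                                 config$heterozygosity[sp_idx])
      for (li in seq_len(nrow(sp_loci))) {
        pool <- pools[[sp_loci$locus[li]]]
        pick <- sample.int(length(pool), 2L, replace = TRUE,
                           prob = freqs[seq_along(pool)] / sum(freqs[seq_along(pool)]))
        gt[[length(gt) + 1L]] <- data.frame(
          individual = samples$individual[si],
          population = samples$population[si],
          species = samples$species[si], locus = sp_loci$locus[li],
          allele1_idx = pick[1], allele2_idx = pick[2],
          allele1_seq = pool[pick[1]], allele2_seq = pool[pick[2]],
          stringsAsFactors = FALSE
        )
      }
    }
    genotypes <- do.call(rbind, gt)
    rownames(genotypes) <- NULL
    list(genotypes = genotypes, samples = samples, loci = loci,
         pools = pools, config = config)
  })
}

# Apply the quality-mixture substitution process; returns chars, quals and
# the error count.
.inject_substitutions <- function(ch, config) {
  L <- length(ch)
  if (config$substitution_rate <= 0) {
    return(list(ch = ch, q = rep(config$q_high, L), n_err = 0L))
  }
  p_high <- 10^(-config$q_high / 10)
  p_low <- 10^(-config$q_low / 10)
  f <- (config$substitution_rate - p_high) / (p_low - p_high)
  f <- min(max(f, 0), 1)
  q <- ifelse(runif(L) < f, config$q_low, config$q_high)
  flip <- runif(L) < 10^(-q / 10)
  if (any(flip)) {
    for (i in which(flip)) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  }
  list(ch = ch, q = as.integer(q), n_err = sum(flip))
}

# Per-run homopolymer length errors (+/- 1 base) on runs of length >= 3.
.inject_hp_errors <- function(ch, q, config) {
  if (config$hp_base_rate <= 0) return(list(ch = ch, q = q, n_err = 0L))
  r <- rle(ch)
  n_runs <- length(r$lengths)
  qs <- split(q, factor(rep(seq_len(n_runs), r$lengths),
                        levels = seq_len(n_runs)))
  n_err <- 0L
  for (i in seq_len(n_runs)) {
    L <- r$lengths[i]
    if (L < 3L) next
    rate <- min(config$hp_base_rate * (L - 1), config$hp_max_rate)
    if (runif(1) < rate) {
      d <- if (L > 1L && runif(1) < 0.5) -1L else 1L
      r$lengths[i] <- L + d
      qs[[i]] <- rep(config$q_hp_err, L + d)
      n_err <- n_err + 1L
    }
  }
  list(ch = rep(r$values, r$lengths), q = as.integer(unlist(qs)),
       n_err = n_err)
}

#' Simulate a multiplexed amplicon library with full ground truth
#'
#' Coverage per bin is negative-binomial; each read copies one of the
#' individual's two alleles (binomially skewed), or a single-crossover
#' chimera of both at heterozygous bins; substitution and homopolymer
#' errors are injected with qualities consistent with the error process;
#' a configured fraction of reads is truncated below the length filter;
#' orientation is random.
#'
#' @param truth A [simulate_genotypes()] result.
#' @param config A [sim_config()] (defaults to `truth$config`).
#' @return List: `reads` (a [read_set()]), `truth_reads` (one row per
#'   emitted read: source bin, allele, `is_chimera`, `truncated`, error
#'   counts, orientation), plus `genotypes`, `samples`, `loci` passed
#'   through.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  withr::with_seed(config$seed + 1L, {
    gt <- truth$genotypes
    loci <- truth$loci
    samples <- truth$samples
    mid_of <- setNames(samples$mid, samples$individual)
    covs <- rnbinom(nrow(gt), size = config$dispersion,
                    mu = config$mean_coverage)
    n_reads <- sum(covs)
    reads_b <- character(n_reads)
    reads_q <- vector("list", n_reads)
    t_bin <- rep(seq_len(nrow(gt)), covs)
    t_allele <- integer(n_reads)
    t_chim <- logical(n_reads)
    t_trunc <- logical(n_reads)
    t_nsub <- integer(n_reads)
    t_nhp <- integer(n_reads)
    t_rev <- logical(n_reads)
    counter <- 0L

    for (bi in seq_len(nrow(gt))) {
      if (covs[bi] == 0L) next
      ldef <- loci[loci$locus == gt$locus[bi], , drop = FALSE]
      mid <- mid_of[[gt$individual[bi]]]
      a1 <- gt$allele1_seq[bi]
      a2 <- gt$allele2_seq[bi]
      is_het <- a1 != a2
      diffs <- if (is_het) which(strsplit1(a1) != strsplit1(a2)) else integer(0)
      flank5 <- paste0(config$adapter_a, mid, ldef$fwd_primer)
      flank3 <- paste0(revcomp(ldef$rev_primer), revcomp(mid),
                       revcomp(config$adapter_b))
      for (ri in seq_len(covs[bi])) {
        counter <- counter + 1L
        is_chim <- is_het && length(diffs) >= 2L &&
          runif(1) < config$chimera_rate
        if (is_chim) {
          x <- if (diffs[1] <= diffs[length(diffs)] - 1L) {
            sample(seq(diffs[1], diffs[length(diffs)] - 1L), 1)
          } else diffs[1]
          swap <- runif(1) < 0.5
          lhs <- if (swap) a2 else a1
          rhs <- if (swap) a1 else a2
          insert <- paste0(substring(lhs, 1, x), substring(rhs, x + 1))
          allele <- NA_integer_
        } else {
          allele <- if (!is_het) 1L else if (runif(1) < config$allelic_skew) 1L else 2L
          insert <- if (allele == 1L) a1 else a2
        }
        ch <- strsplit1(paste0(flank5, insert, flank3))
        sub <- .inject_substitutions(ch, config)
        hp <- .inject_hp_errors(sub$ch, sub$q, config)
        b <- paste(hp$ch, collapse = "")
        q <- hp$q
        truncated <- runif(1) < config$short_frac
        if (truncated) {
          tl <- sample(config$trunc_len_range[1]:config$trunc_len_range[2], 1)
          tl <- min(tl, nchar(b))
          b <- substring(b, 1, tl)
          q <- pmin(q[seq_len(tl)], config$q_hp_err)
        }
        rev <- runif(1) < 0.5
        if (rev) {
          b <- revcomp(b)
          q <- rev(q)
        }
        reads_b[counter] <- b
        reads_q[[counter]] <- as.integer(q)
        t_allele[counter] <- allele
        t_chim[counter] <- is_chim
        t_trunc[counter] <- truncated
        t_nsub[counter] <- sub$n_err
        t_nhp[counter] <- hp$n_err
        t_rev[counter] <- rev
      }
    }
    reads_id <- sprintf("sim%06d", seq_len(n_reads))
    truth_reads <- data.frame(
      read_id = reads_id, individual = gt$individual[t_bin],
      population = gt$population[t_bin], species = gt$species[t_bin],
      locus = gt$locus[t_bin], allele = t_allele, is_chimera = t_chim,
      truncated = t_trunc, n_sub_errors = t_nsub, n_hp_errors = t_nhp,
      orientation = ifelse(t_rev, "reverse", "forward"),
      stringsAsFactors = FALSE
    )
    list(reads = read_set(reads_id, reads_b, reads_q),
         truth_reads = truth_reads, genotypes = gt, samples = samples,
         loci = loci, config = config)
  })
}

#' Degrade a library with truncated low-quality reads
#'
#' Replaces a fraction of reads with short (below the 150 bp filter),
#' low-quality truncations of themselves, emulating a contaminated
#' library in which more reads are discarded than used.
#'
#' @param reads A [read_set()].
#' @param short_frac Fraction of reads to degrade.
#' @param seed RNG seed.
#' @param trunc_len_range Length range of the truncations.
#' @return The degraded [read_set()].
#' @export
degrade_library <- function(reads, short_frac, seed = 1L,
                            trunc_len_range = c(50L, 149L)) {
  stopifnot(short_frac >= 0, short_frac <= 1)
  if (short_frac == 0 || nrow(reads) == 0L) return(reads)
  withr::with_seed(seed, {
    n <- nrow(reads)
    idx <- sample.int(n, ceiling(short_frac * n))
    for (i in idx) {
      tl <- sample(trunc_len_range[1]:trunc_len_range[2], 1)
      tl <- min(tl, nchar(reads$bases[i]))
      reads$bases[i] <- substring(reads$bases[i], 1, tl)
      reads$quals[[i]] <- pmin(reads$quals[[i]][seq_len(tl)], 10L)
    }
    reads
  })
}

#' Write a simulated library to disk
#'
#' Emits one FASTQ per population (the gasketed-region layout: regions
#' arrive as separate files) plus `samples.tsv`, `loci.tsv`,
#' `truth_genotypes.tsv` and `truth_reads.tsv`.
#'
#' @param sim A [simulate_reads()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
write_simulated_library <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (p in unique(sim$samples$population)) {
    ids <- sim$truth_reads$read_id[sim$truth_reads$population == p]
    sub <- sim$reads[sim$reads$read_id %in% ids, , drop = FALSE]
    f <- file.path(out_dir, sprintf("reads_%s.fastq", p))
    write_fastq(sub, f)
    paths[[paste0("reads_", p)]] <- f
  }
  tsv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  paths$samples <- tsv(sim$samples, "samples.tsv")
  paths$loci <- tsv(sim$loci, "loci.tsv")
  paths$truth_genotypes <- tsv(sim$genotypes, "truth_genotypes.tsv")
  paths$truth_reads <- tsv(sim$truth_reads, "truth_reads.tsv")
  invisible(paths)
}
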