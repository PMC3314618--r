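test_that("star pileups stack identical and near-identical reads correctly", {
  pu <- build_pileup(make_reads(rep("ACGTACGTACGT", 5)))
  expect_equal(ncol(pu$chars), 12)
  pc <- pileup_counts(pu)
  expect_true(all(pc$depth == 5))
  expect_true(all(apply(pc$counts, 2, max) == 5)) # zero-mismatch columns

  # one substitution -> exactly one mixed column
  pu2 <- build_pileup(make_reads(c("ACGTACGTACGT", "ACGTACCTACGT")))
  pc2 <- pileup_counts(pu2)
  mixed <- colSums(pc2$counts > 0) > 1
  expect_equal(sum(mixed), 1)
})

test_that("staggered reads give a depth profile equal to per-column overlap", {
  # hand-constructed 3-read toy: seed spans 1-12 (highest quality),
  # one read covers 1-8, one read covers 5-12 (non-repetitive sequence so
  # the alignments are unambiguous)
  seed <- "AACGGTTCATGC"
  rs <- read_set(c("s", "l", "r"),
                 c(seed, substr(seed, 1, 8), substr(seed, 5, 12)),
                 list(rep(40L, 12), rep(30L, 8), rep(30L, 8)))
  pu <- build_pileup(rs)
  pc <- pileup_counts(pu)
  expect_equal(unname(pc$depth), c(2, 2, 2, 2, 3, 3, 3, 3, 2, 2, 2, 2))
  expect_equal(pu$seed_id, "s")
})

test_that("pileups are order-independent and reproducible", {
  cfg <- tiny_config(seed = 91, n_individuals = 2, n_loci = 1)
  sim <- simulate_reads(simulate_genotypes(cfg), cfg)
  dm <- suppressWarnings(demultiplex(sim$reads, sim$samples, sim$loci))
  kept <- dm$assignments[dm$assignments$status == "kept", ]
  key <- paste(kept$individual, kept$locus)
  bin <- kept[key == names(sort(table(key), decreasing = TRUE))[1], ]
  rs <- read_set(bin$read_id, bin$bases, bin$quals)
  pu1 <- build_pileup(rs)
  perm <- withr::with_seed(2, sample(nrow(rs)))
  pu2 <- build_pileup(rs[perm, ])
  expect_identical(pu1$chars, pu2$chars)
  expect_identical(pu1$col_pos, pu2$col_pos)
})

test_that("the 75% consensus boundary is strict", {
  expect_equal(call_column(c(A = 76, C = 24))$type, "hom")
  expect_equal(call_column(c(A = 76, C = 24))$major, "A")
  cc <- call_column(c(A = 74, C = 26))
  expect_equal(cc$type, "het")
  expect_equal(c(cc$major, cc$minor), c("A", "C"))
  # exactly 75% is NOT below 75%
  expect_equal(call_column(c(A = 75, C = 25))$type, "hom")
  # gaps count as a symbol and in depth; N counts in neither
  expect_equal(call_column(c(A = 70, `-` = 30))$type, "het")
  expect_equal(call_column(c(A = 9, N = 91))$type, "hom")
})

test_that("het calling matches a brute-force check on random columns", {
  brute <- function(counts, thr = 0.75) {
    depth <- sum(counts) - counts["N"]
    syms <- setdiff(names(counts), "N")
    mx <- max(counts[syms])
    if (depth >= 1 && mx / depth < thr) "het" else "hom"
  }
  withr::with_seed(99, {
    for (i in 1:500) {
      counts <- setNames(rmultinom(1, sample(1:200, 1),
                                   prob = runif(6))[, 1],
                         c("A", "C", "G", "T", "N", "-"))
      if (sum(counts) - counts["N"] < 1) next
      expect_equal(call_column(counts)$type, unname(brute(counts)),
                   info = paste(counts, collapse = ","))
    }
  })
})

test_that("homopolymer arbitration follows majority, quality, then shorter", {
  # build a pileup with an A-run of length 7 vs 8 around flanking context
  run_reads <- function(n7, n8, q7 = 30, q8 = 35) {
    bases <- c(rep(paste0("CCG", strrep("A", 7), "GCC"), n7),
               rep(paste0("CCG", strrep("A", 8), "GCC"), n8))
    quals <- c(lapply(seq_len(n7), function(i) rep(as.integer(q7), 13)),
               lapply(seq_len(n8), function(i) rep(as.integer(q8), 14)))
    build_pileup(read_set(sprintf("r%03d", seq_along(bases)), bases, quals))
  }

  # depth 50, lengths {7:46, 8:4} -> majority picks 7
  pu <- run_reads(46, 4)
  site <- find_het_sites(pu)
  hp <- resolve_homopolymer(pu, if (nrow(site)) site$column_index[1] else 5, "A")
  expect_equal(hp$chosen_length, 7)
  expect_equal(hp$decision_basis, "majority")
  expect_setequal(hp$candidate_lengths, c(7, 8))

  # depth 8 (below 10x): quality decides alone even with equal counts
  pu2 <- run_reads(4, 4, q7 = 32, q8 = 25)
  hp2 <- resolve_homopolymer(pu2, 5, "A")
  expect_equal(hp2$chosen_length, 7)
  expect_equal(hp2$decision_basis, "quality")

  # depth 20, equal counts and equal quality: tie breaks to the shorter run
  pu3 <- run_reads(10, 10, q7 = 30, q8 = 30)
  hp3 <- resolve_homopolymer(pu3, 5, "A")
  expect_equal(hp3$chosen_length, 7)
  expect_equal(hp3$decision_basis, "quality")

  # when majority and quality agree the basis says so
  pu4 <- run_reads(46, 4, q7 = 38, q8 = 25)
  hp4 <- resolve_homopolymer(pu4, 5, "A")
  expect_equal(hp4$chosen_length, 7)
  expect_equal(hp4$decision_basis, "both")
})

test_that("below 10x coverage the decision basis is always quality", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(2:9, 1)
      lens <- sample(3:6, n, replace = TRUE)
      bases <- paste0("GGC", strrep("T", lens), "CGG")
      quals <- lapply(nchar(bases), function(k) {
        as.integer(sample(15:40, k, replace = TRUE))
      })
      pu <- build_pileup(read_set(sprintf("r%02d", 1:n), bases, quals))
      hp <- tryCatch(resolve_homopolymer(pu, 4, "T"), error = function(e) NULL)
      if (is.null(hp)) next
      expect_equal(hp$decision_basis, "quality")
      expect_true(hp$chosen_length %in% lens)
    }
  })
})

# Enumeration oracle: count symbol-vector keys over het sites by brute
# force; the two most frequent (count desc, then lexicographic) are the
# expected alleles.
oracle_phase <- function(keymat) {
  complete <- rowSums(is.na(keymat)) == 0
  keys <- apply(keymat[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  list(k1 = names(tab)[ord[1]], k2 = names(tab)[ord[2]],
       n1 = as.integer(tab)[ord[1]], n2 = as.integer(tab)[ord[2]])
}

test_that("phasing agrees with exhaustive key enumeration on small bins", {
  # the worked two-site example: A-C x40, G-T x35, A-T x5
  template <- "CCAATTGGCCAATTGG"
  mk <- function(s1, s2, n) {
    b <- template
    substr(b, 4, 4) <- s1
    substr(b, 12, 12) <- s2
    rep(b, n)
  }
  rs <- make_reads(c(mk("A", "C", 40), mk("G", "T", 35), mk("A", "T", 5)))
  pu <- build_pileup(rs)
  sites <- find_het_sites(pu)
  expect_equal(nrow(sites), 2)
  ph <- phase_reads(pu, sites)
  expect_false(ph$fallback)
  expect_equal(ph$support1, 40)
  expect_equal(ph$support2, 35)
  expect_equal(paste(ph$key1, collapse = ""), "AC")
  expect_equal(paste(ph$key2, collapse = ""), "GT")

  # one het site, 12 vs 9
  rs2 <- make_reads(c(mk("A", "T", 12), mk("G", "T", 9)))
  pu2 <- build_pileup(rs2)
  s2 <- find_het_sites(pu2)
  expect_equal(nrow(s2), 1)
  ph2 <- phase_reads(pu2, s2)
  expect_equal(c(ph2$support1, ph2$support2), c(12, 9))

  # tie 10 vs 10 -> allele1 is the lexicographically smaller sequence
  rs3 <- make_reads(c(mk("C", "T", 10), mk("A", "T", 10)))
  g3 <- genotype_bin(rs3)
  expect_equal(c(g3$support1, g3$support2), c(10L, 10L))
  expect_true(g3$allele1 < g3$allele2)
})

test_that("phasing matches the oracle over randomized small bins", {
  withr::with_seed(123, {
    for (rep in 1:120) {
      n_reads <- sample(4:12, 1)
      n_sites <- sample(1:3, 1)
      # build reads over a 20 bp template with engineered variable sites
      template <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                        collapse = "")
      site_pos <- sort(sample(3:18, n_sites))
      hap1 <- template
      hap2 <- template
      for (p in site_pos) {
        subs <- sample(c("A", "C", "G", "T"), 2)
        substr(hap1, p, p) <- subs[1]
        substr(hap2, p, p) <- subs[2]
      }
      from1 <- rbinom(1, n_reads - 2, 0.5) + 1 # both haplotypes present
      bases <- c(rep(hap1, from1), rep(hap2, n_reads - from1))
      pu <- build_pileup(make_reads(bases))
      sites <- find_het_sites(pu)
      if (nrow(sites) == 0) next # below-threshold imbalance: not phaseable
      ph <- phase_reads(pu, sites)
      expect_false(ph$fallback)
      om <- oracle_phase(pu$chars[, sites$column_index, drop = FALSE])
      expect_equal(paste(ph$key1, collapse = ""), om$k1)
      expect_equal(paste(ph$key2, collapse = ""), om$k2)
      expect_equal(ph$support1, om$n1)
      expect_equal(ph$support2, om$n2)
    }
  })
})

test_that("chimeric reads are recognised, removed, and removal is idempotent", {
  template <- "CCAATTGGCCAATTGG"
  mk <- function(s1, s2, n) {
    b <- template
    substr(b, 4, 4) <- s1
    substr(b, 12, 12) <- s2
    rep(b, n)
  }
  rs <- make_reads(c(mk("A", "C", 10), mk("G", "T", 8), mk("A", "T", 3)))
  pu <- build_pileup(rs)
  sites <- find_het_sites(pu)
  ph <- phase_reads(pu, sites)
  cl <- remove_chimeras(pu, sites, ph)
  expect_length(cl$chimeric, 3) # the A-T recombinants
  expect_equal(c(cl$support1, cl$support2), c(10L, 8L))
  # idempotent: removing again changes nothing
  cl2 <- remove_chimeras(pu, sites, cl)
  expect_identical(cl2$chimeric, cl$chimeric)
  expect_identical(cl2$class1, cl$class1)
  # a key equal to allele1 is retained
  expect_true(all(!(cl$class1 %in% cl$chimeric)))

  # genotype-level: chimeras never touch homozygous bins
  hom <- genotype_bin(make_reads(rep(template, 12)))
  expect_equal(hom$n_chimeras_removed, 0L)
  expect_equal(hom$allele1, hom$allele2)
})

test_that("genotype_bin handles empty, homozygous and heterozygous bins", {
  empty <- genotype_bin(make_reads(character(0)), "L", "I")
  expect_equal(empty$status, "failed_no_reads")

  hom <- genotype_bin(make_reads(rep("ACGTACGTACGTACGT", 30)), "L", "I")
  expect_equal(hom$status, "called")
  expect_equal(hom$coverage, 30)
  expect_equal(hom$allele1, "ACGTACGTACGTACGT")
  expect_equal(hom$allele2, hom$allele1)

  # paper-scale heterozygote: 107 reads at 13:9 with ~12.5% chimeras
  a1 <- "GGCCAATTGGCCAATTGGCC"
  a2 <- a1
  substr(a2, 5, 5) <- "G"
  substr(a2, 15, 15) <- "C"
  chim <- a1
  substr(chim, 15, 15) <- "C" # allele1 left half, allele2 right half
  n1 <- 55; n2 <- 39; nc <- 13 # 107 reads, ratio ~13:9, 12.1% chimeric
  g <- genotype_bin(make_reads(c(rep(a1, n1), rep(a2, n2), rep(chim, nc))),
                    "L", "I")
  expect_equal(g$status, "called")
  expect_equal(g$coverage, 107)
  expect_setequal(c(g$allele1, g$allele2), c(a1, a2))
  expect_equal(g$n_chimeras_removed, 13L)
  expect_equal(c(g$support1, g$support2), c(55L, 39L))
})
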