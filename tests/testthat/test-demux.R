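# Fixture: one individual, one locus, reads built base by base so every
# rule boundary is exercised exactly.

MID <- "ACGAGTGCGT"
FWD <- "TTTGCACCAGTGACCTTTTG"  # an ATPSa-style exon-anchored primer
REV <- "GCCCTTTGAGCTACAGTTCG"

demo_sheet <- function() {
  data.frame(mid = MID, individual = "A01", population = "P01",
             species = "SP1", stringsAsFactors = FALSE)
}
demo_loci <- function() {
  suppressWarnings(validate_locus_table(data.frame(
    locus = "ATPSa", fwd_primer = FWD, rev_primer = REV,
    min_len = 150, max_len = 600, stringsAsFactors = FALSE
  )))
}
# a full forward-layout read: MID+FWD+insert+rc(REV)+rc(MID), no adaptors
layout_read <- function(insert) {
  paste0(MID, FWD, insert, revcomp(REV), revcomp(MID))
}
long_insert <- function(n = 200) strrep("ACGT", ceiling(n / 4))

test_that("length and mean-quality filters use strict below-threshold rules", {
  expect_false(length_filter(strrep("A", 149)))
  expect_true(length_filter(strrep("A", 150)))
  expect_true(length_filter(strrep("A", 400)))

  expect_true(mean_quality_filter(list(rep(30L, 200))))
  expect_false(mean_quality_filter(list(rep(29L, 200))))
  expect_true(mean_quality_filter(list(rep(c(20L, 40L), 100)))) # mean exactly 30
})

test_that("MID must match and agree at both read ends", {
  sheet <- demo_sheet()
  ok <- layout_read(long_insert())
  m <- match_mid(ok, sheet)
  expect_equal(m$individual, "A01")

  # 5' only
  one_end <- paste0(MID, FWD, long_insert(), revcomp(REV))
  expect_true(is.na(match_mid(one_end, sheet)$individual))

  # two different individuals' MIDs at the two ends
  sheet2 <- rbind(sheet, data.frame(mid = "TGTGTGCGCG", individual = "A02",
                                    population = "P01", species = "SP1"))
  cross <- paste0(MID, FWD, long_insert(), revcomp(REV), revcomp("TGTGTGCGCG"))
  expect_true(is.na(match_mid(cross, sheet2)$individual))

  # adaptor-flanked layout is tolerated
  flanked <- paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG", ok,
                    revcomp("CCTATCCCCTGTGTGCCTTGGCAGTCTCAG"))
  expect_equal(match_mid(flanked, sheet)$individual, "A01")

  # one substitution in the MID: rejected under the strict rule, accepted
  # under the optional 1-edit mode when only one MID is that close
  damaged <- ok
  substr(damaged, 2, 2) <- "T" # ACGAGTGCGT -> ATGAGTGCGT at the 5' end
  expect_true(is.na(match_mid(damaged, sheet)$individual))
  expect_equal(match_mid(damaged, sheet, max_edits = 1)$individual, "A01")
  # two MIDs within one substitution of the prefix: stays unassigned
  # (ATGAGT... is one substitution from both ACGAGT... and AGGAGT...)
  twin <- rbind(sheet, data.frame(mid = "AGGAGTGCGT", individual = "A03",
                                  population = "P01", species = "SP1"))
  expect_true(is.na(match_mid(damaged, twin, max_edits = 1)$individual))
})

test_that("primer identification is IUPAC-aware exact matching", {
  loci <- demo_loci()
  core <- paste0(FWD, long_insert(), revcomp(REV))
  pm <- match_primer(core, loci)
  expect_equal(pm$locus, "ATPSa")
  expect_equal(pm$orientation, "forward")

  # reverse-orientation core starts with the reverse primer
  rc_core <- revcomp(core)
  pm2 <- match_primer(rc_core, loci)
  expect_equal(pm2$locus, "ATPSa")
  expect_equal(pm2$orientation, "reverse")

  # one substitution anywhere in the primer -> whole primer not present
  broken <- core
  substr(broken, 3, 3) <- "A" # TTTGCA... -> TTAGCA...
  expect_equal(match_primer(broken, loci)$reason, "primer_absent")

  # degenerate code expansion: R matches A and G but not C
  dloci <- suppressWarnings(validate_locus_table(data.frame(
    locus = "GPI", fwd_primer = "GTGGCCCTGTCAACCRACG", rev_primer = REV,
    min_len = 150, max_len = 600, stringsAsFactors = FALSE
  )))
  for (b in c("A", "G")) {
    c2 <- paste0(sub("R", b, dloci$fwd_primer), long_insert(), revcomp(REV))
    expect_equal(match_primer(c2, dloci)$locus, "GPI")
  }
  c3 <- paste0(sub("R", "C", dloci$fwd_primer), long_insert(), revcomp(REV))
  expect_equal(match_primer(c3, dloci)$reason, "primer_absent")

  # degenerate overlap hitting two loci -> ambiguous
  two <- suppressWarnings(validate_locus_table(data.frame(
    locus = c("L1", "L2"), fwd_primer = c("ACGTACGTACGTACGTACGT",
                                          "ACGTACGTACGTACGTACGN"),
    rev_primer = c(REV, "GCCCTTTGAGCTACAGAACG"),
    min_len = 150, max_len = 600, stringsAsFactors = FALSE
  )))
  c4 <- paste0("ACGTACGTACGTACGTACGT", long_insert(), revcomp(REV))
  expect_equal(match_primer(c4, two)$reason, "ambiguous")
})

test_that("modified-Mott trimming keeps the maximal-scoring segment", {
  # all high quality -> identity
  tr <- quality_trim(strrep("A", 20), rep(40L, 20))
  expect_equal(nchar(tr$bases), 20)

  # hand-computed 10-base toy at cutoff 0.05:
  # quals  2,2,40,40,40,40,40,40,2,2
  # scores -0.581.. x2, +0.0499 x6, -0.581.. x2; best segment = 3..8
  toy <- quality_trim("ACGTAACGTA",
                      c(2L, 2L, 40L, 40L, 40L, 40L, 40L, 40L, 2L, 2L))
  expect_equal(toy$range, c(3L, 8L))
  expect_equal(toy$bases, "GTAACG")
  expect_equal(toy$quals, rep(40L, 6))

  # all low quality -> empty
  gone <- quality_trim(strrep("A", 30), rep(2L, 30))
  expect_equal(gone$bases, "")
  expect_length(gone$quals, 0)

  # a Q2 tail is removed, the head kept
  tail20 <- quality_trim(strrep("ACGT", 10), c(rep(40L, 20), rep(2L, 20)))
  expect_equal(tail20$range, c(1L, 20L))
})

test_that("demultiplex applies rules in order and partitions every read", {
  sheet <- demo_sheet()
  loci <- demo_loci()
  ins <- long_insert(200)
  reads <- make_reads(c(
    layout_read(ins),                        # kept, forward
    revcomp(layout_read(ins)),               # kept, reverse
    strrep("A", 100),                        # too short
    paste0(MID, FWD, ins, revcomp(REV)),     # MID missing at 3' end
    layout_read(long_insert(100))            # insert below 150 after trimming
  ))
  low_q <- make_reads(layout_read(ins), q = 20, ids = "lowq")
  reads <- rbind(reads, low_q)
  out <- demultiplex(reads, sheet, loci)
  led <- out$assignments
  expect_equal(nrow(led), 6)
  expect_equal(out$report$kept_reads + sum(out$report$discarded_by_reason), 6)
  expect_equal(sort(led$status), sort(c("kept", "kept", rep("discarded", 4))))
  kept <- led[led$status == "kept", ]
  expect_equal(unique(kept$individual), "A01")
  expect_equal(unique(kept$locus), "ATPSa")
  expect_setequal(kept$orientation, c("forward", "reverse"))
  # reverse read reoriented: identical trimmed insert
  expect_equal(kept$bases[1], kept$bases[2])
  expect_equal(nchar(kept$bases[1]), nchar(ins))

  reasons <- led$discard_reason[led$status == "discarded"]
  expect_setequal(reasons, c("too_short", "mid_mismatch", "too_short",
                             "low_mean_quality"))

  # empty input
  empty <- demultiplex(make_reads(character(0)), sheet, loci)
  expect_equal(nrow(empty$assignments), 0)
  expect_equal(empty$report$total_reads, 0)
})

test_that("the ledger is identical whatever the input read order", {
  cfg <- tiny_config(seed = 31)
  sim <- simulate_reads(simulate_genotypes(cfg), cfg)
  out1 <- demultiplex(sim$reads, sim$samples, sim$loci)
  perm <- withr::with_seed(1, sample(nrow(sim$reads)))
  out2 <- demultiplex(sim$reads[perm, ], sim$samples, sim$loci)
  expect_identical(out1$assignments$read_id, out2$assignments$read_id)
  expect_identical(out1$assignments$status, out2$assignments$status)
  expect_identical(out1$assignments$bases, out2$assignments$bases)
  expect_identical(out1$report$discarded_by_reason,
                   out2$report$discarded_by_reason)
})

test_that("error-free simulated libraries demultiplex perfectly", {
  cfg <- do.call(tiny_config, c(list(seed = 5, n_individuals = 6,
                                     mean_coverage = 18), noise_free))
  sim <- simulate_reads(simulate_genotypes(cfg), cfg)
  out <- demultiplex(sim$reads, sim$samples, sim$loci)
  led <- out$assignments
  expect_equal(out$report$kept_reads, nrow(sim$reads))
  m <- match(led$read_id, sim$truth_reads$read_id)
  expect_true(all(led$individual == sim$truth_reads$individual[m]))
  expect_true(all(led$locus == sim$truth_reads$locus[m]))
  ori <- sim$truth_reads$orientation[m]
  expect_true(all(led$orientation == ori))
})
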