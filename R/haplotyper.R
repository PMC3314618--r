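# haplotyper: per-bin diploid genotype calling. Heterozygous sites are
# pileup columns whose majority symbol falls strictly below 75% of depth;
# homopolymer length variants are arbitrated (majority consensus when
# depth allows, else quality); reads are phased into the two most common
# haplotypes across the remaining het sites; recombinant (chimeric) reads
# are removed and the alleles re-derived.

#' Call one pileup column homozygous or heterozygous
#'
#' A column is heterozygous iff the most frequent symbol accounts for
#' strictly less than `het_threshold` of the depth ("below 75% consensus";
#' a column at exactly 75% is homozygous). Gaps count as a symbol and in
#' the depth; N bases count in neither.
#'
#' @param counts Named counts over A, C, G, T, N, `-` (missing names = 0).
#' @param het_threshold Consensus fraction (default 0.75).
#' @param qual_sums Optional named quality sums, used only to break count
#'   ties deterministically.
#' @return List with `type` ("hom" or "het"), `major`, `major_count`,
#'   `depth`, and for het columns `minor`, `minor_count`.
#' @export
call_column <- function(counts, het_threshold = 0.75, qual_sums = NULL) {
  full <- setNames(numeric(6), PILEUP_SYMBOLS)
  full[names(counts)] <- counts
  qs <- setNames(numeric(6), PILEUP_SYMBOLS)
  if (!is.null(qual_sums)) qs[names(qual_sums)] <- qual_sums
  depth <- sum(full) - full[["N"]]
  if (depth < 1) stop("call_column requires depth >= 1")
  syms <- c("A", "C", "G", "T", "-")
  o <- order(-full[syms], -qs[syms], seq_along(syms))
  major <- syms[o[1]]
  minor <- syms[o[2]]
  if (full[[major]] / depth < het_threshold && full[[minor]] >= 1) {
    list(type = "het", major = major, minor = minor,
         major_count = unname(full[[major]]), minor_count = unname(full[[minor]]),
         depth = unname(depth))
  } else {
    list(type = "hom", major = major, major_count = unname(full[[major]]),
         depth = unname(depth))
  }
}

#' Locate heterozygous sites in a pileup
#'
#' Columns covered by only a sliver of the bin (read ends hanging past the
#' seed, which carry no gap evidence from the reads that stop short of
#' them) are not eligible: a site needs coverage from at least
#' `min_cover_frac` of the bin's reads (and never fewer than 2).
#'
#' @param pileup A [build_pileup()] result.
#' @param het_threshold Consensus fraction (default 0.75).
#' @param min_cover_frac Minimum covering fraction for a column to be
#'   callable (default 0.25).
#' @return Data frame, one row per het column: `column_index`, `major`,
#'   `minor`, `major_count`, `minor_count`, `is_indel` (one of the two
#'   symbols is a gap), `is_homopolymer` (indel whose base extends an
#'   adjacent consensus run).
#' @export
find_het_sites <- function(pileup, het_threshold = 0.75,
                           min_cover_frac = 0.25) {
  pc <- pileup_counts(pileup)
  cons <- .consensus_symbols(pileup)
  n_reads <- nrow(pileup$chars)
  min_depth <- max(2, min_cover_frac * n_reads)
  rows <- list()
  for (j in seq_len(ncol(pc$counts))) {
    if (pc$depth[j] < min_depth) next
    cc <- call_column(pc$counts[, j], het_threshold, pc$qual_sums[, j])
    if (cc$type != "het") next
    is_indel <- cc$major == "-" || cc$minor == "-"
    is_hp <- FALSE
    if (is_indel) {
      b <- setdiff(c(cc$major, cc$minor), "-")[1]
      left <- j - 1L
      while (left >= 1L && !is.na(cons[left]) && cons[left] == "-") left <- left - 1L
      right <- j + 1L
      nmax <- length(cons)
      while (right <= nmax && !is.na(cons[right]) && cons[right] == "-") right <- right + 1L
      is_hp <- (left >= 1L && identical(cons[left], b)) ||
        (right <= nmax && identical(cons[right], b))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      column_index = j, major = cc$major, minor = cc$minor,
      major_count = cc$major_count, minor_count = cc$minor_count,
      is_indel = is_indel, is_homopolymer = is_hp, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(column_index = integer(0), major = character(0),
                      minor = character(0), major_count = numeric(0),
                      minor_count = numeric(0), is_indel = logical(0),
                      is_homopolymer = logical(0)))
  }
  do.call(rbind, rows)
}

# Maximal run of columns around `j` belonging to a homopolymer of `base`:
# columns whose plurality non-gap symbol is `base`.
.hp_region <- function(pileup, j, base) {
  pc <- pileup_counts(pileup)
  ok <- function(col) {
    cnt <- pc$counts[c("A", "C", "G", "T"), col]
    sum(cnt) > 0 && names(which.max(cnt)) == base
  }
  lo <- j
  while (lo > 1L && ok(lo - 1L)) lo <- lo - 1L
  hi <- j
  while (hi < ncol(pc$counts) && ok(hi + 1L)) hi <- hi + 1L
  if (!ok(j)) stop("column ", j, " is not part of a homopolymer of ", base)
  lo:hi
}

#' Arbitrate a homopolymer length variant
#'
#' Three criteria, in order: (1) a run-length class supported by at least
#' `het_threshold` of the spanning reads wins by majority consensus;
#' (2) otherwise the class whose reads have the higher mean quality across
#' the run wins; (3) quality ties break toward the shorter run. Below 10x
#' coverage the majority criterion is skipped and quality decides alone.
#' Only anchored reads testify: a read must cover the nearest non-gap
#' consensus column on each side of the run and agree with the consensus
#' there, which excludes reads that start inside the run and reads the
#' ends-free aligner shifted out of register against a seed-side run
#' error.
#'
#' @param pileup A [build_pileup()] result.
#' @param column_index A column inside the homopolymer region.
#' @param base The repeated base; derived from the column when NULL.
#' @param het_threshold Majority fraction (default 0.75).
#' @param min_majority_cov Coverage below which quality decides alone
#'   (default 10).
#' @param rows Optional read subset (row indices) the call is based on;
#'   used to re-resolve a run within one phased allele class, whose reads
#'   alone carry that allele's true run length.
#' @return A `homopolymer_call` list: `flank_position` (first column of the
#'   run), `base`, `candidate_lengths`, `counts_per_length`,
#'   `mean_quality_per_length`, `chosen_length`, `decision_basis`
#'   ("majority", "quality", or "both" when both criteria agree), plus the
#'   region `columns` and spanning-read `depth`.
#' @export
resolve_homopolymer <- function(pileup, column_index, base = NULL,
                                het_threshold = 0.75, min_majority_cov = 10,
                                rows = NULL) {
  if (is.null(base)) {
    pc <- pileup_counts(pileup)
    cnt <- pc$counts[c("A", "C", "G", "T"), column_index]
    if (sum(cnt) == 0) stop("no base evidence at column ", column_index)
    base <- names(which.max(cnt))
  }
  region <- .hp_region(pileup, column_index, base)
  if (is.null(rows)) rows <- seq_len(nrow(pileup$chars))
  ch <- pileup$chars[rows, region, drop = FALSE]
  qu <- pileup$quals[rows, region, drop = FALSE]
  # A read testifies to the run length only if it is anchored: it must
  # cover the nearest non-gap consensus column on each side of the run
  # AND agree with the consensus there. A read that starts inside the run,
  # or that the ends-free aligner shifted out of register against a
  # seed-side run error (a mismatch being cheaper than a gap), would
  # otherwise contribute a confidently wrong run length.
  cons <- .consensus_symbols(pileup)
  nc <- ncol(pileup$chars)
  left <- region[1] - 1L
  while (left >= 1L && (is.na(cons[left]) || cons[left] == "-")) {
    left <- left - 1L
  }
  right <- max(region) + 1L
  while (right <= nc && (is.na(cons[right]) || cons[right] == "-")) {
    right <- right + 1L
  }
  anchored <- rep(TRUE, length(rows))
  for (a in c(if (left >= 1L) left, if (right <= nc) right)) {
    anchored <- anchored & !is.na(pileup$chars[rows, a]) &
      pileup$chars[rows, a] == cons[a]
  }
  spans <- which(rowSums(is.na(ch)) == 0L & anchored)
  if (!length(spans)) stop("no anchored read spans the homopolymer region")
  isb <- ch[spans, , drop = FALSE] == base
  runlen <- rowSums(isb)
  readq <- rowSums(qu[spans, , drop = FALSE] * isb) / pmax(runlen, 1)
  readq[runlen == 0] <- NA_real_
  counts <- table(runlen)
  lens <- as.integer(names(counts))
  mean_q <- vapply(lens, function(l) {
    v <- readq[runlen == l]
    if (all(is.na(v))) -Inf else mean(v, na.rm = TRUE)
  }, numeric(1))
  depth <- length(spans)

  maj_choice <- NA_integer_
  if (depth >= min_majority_cov) {
    top <- which.max(counts)
    if (counts[top] / depth >= het_threshold) maj_choice <- lens[top]
  }
  best_q <- which(mean_q == max(mean_q))
  qual_choice <- min(lens[best_q]) # quality tie -> shorter run
  if (!is.na(maj_choice)) {
    chosen <- maj_choice
    basis <- if (qual_choice == maj_choice) "both" else "majority"
  } else {
    chosen <- qual_choice
    basis <- "quality"
  }
  structure(list(flank_position = region[1], base = base,
                 candidate_lengths = lens,
                 counts_per_length = as.integer(counts),
                 mean_quality_per_length = mean_q,
                 chosen_length = chosen, decision_basis = basis,
                 columns = region, depth = depth),
            class = "homopolymer_call")
}

# Haplotype key of every read over the given het columns: a character
# vector per read, NA where the read does not cover the column.
.read_keys <- function(pileup, cols) {
  pileup$chars[, cols, drop = FALSE]
}

#' Phase reads into the two most common haplotypes
#'
#' Each read is keyed by its symbol vector across the heterozygous sites.
#' The two most frequent complete keys (ties: lexicographically smaller
#' key first) become the two allelic states. Reads not spanning every het
#' site are assigned to the unique allele consistent with the sites they
#' do span, or left unassigned.
#'
#' @param pileup A [build_pileup()] result.
#' @param het_sites Data frame from [find_het_sites()] (homopolymer sites
#'   are normally excluded by the caller; see [genotype_bin()]).
#' @return List: `fallback` (TRUE when fewer than two distinct complete
#'   keys exist, i.e. the bin should be re-called homozygous), `key1`,
#'   `key2` (character vectors over the sites), `class1`, `class2`
#'   (read-row indices), `unassigned`, `support1`, `support2`.
#' @export
phase_reads <- function(pileup, het_sites) {
  cols <- het_sites$column_index
  if (!length(cols)) stop("phase_reads needs at least one het site")
  km <- .read_keys(pileup, cols)
  complete <- rowSums(is.na(km)) == 0L
  if (sum(complete) < 2L) return(list(fallback = TRUE))
  keystr <- apply(km[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(keystr), decreasing = TRUE)
  if (length(tab) < 2L) return(list(fallback = TRUE))
  cnt <- as.integer(tab)
  keys <- names(tab)
  ord <- order(-cnt, keys)
  k1 <- strsplit1(keys[ord[1]])
  k2 <- strsplit1(keys[ord[2]])

  n <- nrow(km)
  assign_class <- integer(n) # 0 = unassigned
  for (r in seq_len(n)) {
    sp <- which(!is.na(km[r, ]))
    if (!length(sp)) next
    m1 <- all(km[r, sp] == k1[sp])
    m2 <- all(km[r, sp] == k2[sp])
    if (m1 && !m2) assign_class[r] <- 1L
    if (m2 && !m1) assign_class[r] <- 2L
    if (m1 && m2) assign_class[r] <- 1L # spans only agreement sites; count with major
  }
  list(fallback = FALSE, sites = cols, key1 = k1, key2 = k2,
       class1 = which(assign_class == 1L), class2 = which(assign_class == 2L),
       unassigned = which(assign_class == 0L),
       support1 = sum(assign_class == 1L), support2 = sum(assign_class == 2L))
}

#' Detect and remove PCR-chimeric (recombinant) reads
#'
#' A read is chimeric iff, over the sites where the two alleles differ, its
#' key matches allele 1 at one or more sites AND allele 2 at one or more
#' sites. Homozygous calls are never modified. Removal is idempotent and
#' never alters the haplotype keys of non-chimeric reads.
#'
#' @param pileup A [build_pileup()] result.
#' @param het_sites The sites used for phasing.
#' @param phase A [phase_reads()] result (with `fallback = FALSE`).
#' @return `phase` updated: chimeric rows dropped from the classes and
#'   `unassigned`, plus `chimeric` (row indices) and `removed_read_ids`.
#' @export
remove_chimeras <- function(pileup, het_sites, phase) {
  if (isTRUE(phase$fallback)) stop("remove_chimeras applies to heterozygous calls only")
  km <- .read_keys(pileup, phase$sites)
  diff_sites <- which(phase$key1 != phase$key2)
  chim <- logical(nrow(km))
  if (length(diff_sites) >= 2L) {
    for (r in seq_len(nrow(km))) {
      sp <- diff_sites[!is.na(km[r, diff_sites])]
      if (length(sp) < 2L) next
      hits1 <- any(km[r, sp] == phase$key1[sp])
      hits2 <- any(km[r, sp] == phase$key2[sp])
      chim[r] <- hits1 && hits2
    }
  }
  idx <- which(chim)
  phase$class1 <- setdiff(phase$class1, idx)
  phase$class2 <- setdiff(phase$class2, idx)
  phase$unassigned <- setdiff(phase$unassigned, idx)
  phase$support1 <- length(phase$class1)
  phase$support2 <- length(phase$class2)
  phase$chimeric <- idx
  phase$removed_read_ids <- pileup$read_ids[idx]
  phase
}

# Assemble an allele sequence from a pileup restricted to a read class.
# Columns with no class coverage fall back to the overall consensus;
# homopolymer-arbitrated regions are rewritten to the chosen run length.
# Flank columns carry no gap evidence (a read that starts later or ends
# earlier is silent there, not a deletion), so low-coverage columns are
# trimmed inward from both ends until at least a quarter of the bin's
# reads (and no fewer than 2) cover one: a quality-trimmed seed end is
# covered by most reads, a single read's own end artifact by almost none.
.allele_seq <- function(pileup, rows, hp_calls, overall_cons = NULL,
                        key_cols = NULL, key_syms = NULL) {
  cons <- .consensus_symbols(pileup, rows)
  if (is.null(overall_cons)) overall_cons <- .consensus_symbols(pileup)
  cons[is.na(cons)] <- overall_cons[is.na(cons)]
  # at the phased het sites the allele is its haplotype key by definition
  if (length(key_cols)) cons[key_cols] <- key_syms
  n_total <- length(pileup$read_ids)
  cover <- colSums(!is.na(pileup$chars))
  low <- cover < pmax(2, 0.25 * n_total)
  nc <- length(cons)
  j <- 1L
  while (j <= nc && low[j]) { cons[j] <- "-"; j <- j + 1L }
  j <- nc
  while (j >= 1L && low[j]) { cons[j] <- "-"; j <- j - 1L }
  mask <- rep(FALSE, length(cons))
  for (hp in hp_calls) mask[hp$columns] <- TRUE
  out <- character(0)
  j <- 1L
  nmax <- length(cons)
  while (j <= nmax) {
    if (!mask[j]) {
      if (!is.na(cons[j]) && cons[j] != "-") out <- c(out, cons[j])
      j <- j + 1L
    } else {
      hp <- NULL
      for (h in hp_calls) if (j %in% h$columns) { hp <- h; break }
      out <- c(out, rep(hp$base, hp$chosen_length))
      j <- max(hp$columns) + 1L
    }
  }
  paste(out, collapse = "")
}

#' Genotype one demultiplexed read bin
#'
#' Runs the full per-bin pipeline: star-alignment pileup, column calls at
#' the consensus threshold, homopolymer arbitration, phasing of the
#' remaining het sites into the two most common haplotypes, chimera
#' removal, and re-derivation of the two allele sequences. Exactly two
#' alleles are emitted (equal for homozygotes); `allele1` is the
#' better-supported one (ties: lexicographically smaller sequence).
#'
#' @param reads A [read_set()] for one individual x locus bin (forward
#'   orientation, already trimmed).
#' @param locus_id,individual_id Identifiers for the call.
#' @param het_threshold Consensus fraction (default 0.75).
#' @param min_coverage Bins below this read count fail with
#'   `failed_low_coverage` (default 1).
#' @param min_majority_cov Homopolymer majority-criterion floor (default 10).
#' @param scores Alignment scores, see `default_align_scores()`.
#' @return One-row data frame: `individual`, `locus`, `status` (`called`,
#'   `failed_low_coverage`, `failed_no_reads`), `coverage`, `allele1`,
#'   `allele2`, `support1`, `support2`, `n_het_sites`,
#'   `n_chimeras_removed`.
#' @export
genotype_bin <- function(reads, locus_id = NA_character_,
                         individual_id = NA_character_, het_threshold = 0.75,
                         min_coverage = 1, min_majority_cov = 10,
                         scores = default_align_scores()) {
  empty_call <- function(status, coverage = 0L) {
    data.frame(individual = individual_id, locus = locus_id, status = status,
               coverage = coverage, allele1 = NA_character_,
               allele2 = NA_character_, support1 = NA_integer_,
               support2 = NA_integer_, n_het_sites = NA_integer_,
               n_chimeras_removed = NA_integer_, stringsAsFactors = FALSE)
  }
  if (is.null(reads) || nrow(reads) == 0L) return(empty_call("failed_no_reads"))
  reads <- reads[nchar(reads$bases) > 0L, , drop = FALSE]
  if (nrow(reads) == 0L) return(empty_call("failed_no_reads"))
  coverage <- nrow(reads)
  if (coverage < min_coverage) return(empty_call("failed_low_coverage", coverage))

  pu <- build_pileup(reads, locus_id, individual_id, scores)
  sites <- find_het_sites(pu, het_threshold)

  # arbitrate homopolymer length variants (one call per run region)
  hp_calls <- list()
  done_cols <- integer(0)
  hp_idx <- which(sites$is_homopolymer)
  for (i in hp_idx) {
    j <- sites$column_index[i]
    if (j %in% done_cols) next
    b <- setdiff(c(sites$major[i], sites$minor[i]), "-")[1]
    hp <- tryCatch(
      resolve_homopolymer(pu, j, b, het_threshold, min_majority_cov),
      error = function(e) NULL
    )
    if (is.null(hp)) next
    hp_calls[[length(hp_calls) + 1L]] <- hp
    done_cols <- c(done_cols, hp$columns)
  }
  phase_sites <- sites[!sites$is_homopolymer &
                         !(sites$column_index %in% done_cols), , drop = FALSE]

  overall_cons <- .consensus_symbols(pu)
  mk_call <- function(a1, a2, s1, s2, nhet, nchim) {
    if (s2 > s1 || (s1 == s2 && a2 < a1)) {
      tmp <- a1; a1 <- a2; a2 <- tmp
      tmp <- s1; s1 <- s2; s2 <- tmp
    }
    data.frame(individual = individual_id, locus = locus_id,
               status = "called", coverage = coverage, allele1 = a1,
               allele2 = a2, support1 = as.integer(s1),
               support2 = as.integer(s2), n_het_sites = as.integer(nhet),
               n_chimeras_removed = as.integer(nchim),
               stringsAsFactors = FALSE)
  }

  if (nrow(phase_sites) == 0L) {
    a <- .allele_seq(pu, NULL, hp_calls, overall_cons)
    return(mk_call(a, a, coverage, coverage, 0L, 0L))
  }
  ph <- phase_reads(pu, phase_sites)
  if (isTRUE(ph$fallback)) {
    warning("bin ", individual_id, "/", locus_id,
            ": het sites without two consistent haplotypes; calling homozygous")
    a <- .allele_seq(pu, NULL, hp_calls, overall_cons)
    return(mk_call(a, a, coverage, coverage, 0L, 0L))
  }
  ph <- remove_chimeras(pu, phase_sites, ph)
  if (ph$support1 == 0L || ph$support2 == 0L) {
    if (ph$support1 + ph$support2 == 0L) {
      return(empty_call("failed_low_coverage", coverage))
    }
    a <- .allele_seq(pu, c(ph$class1, ph$class2), hp_calls, overall_cons)
    return(mk_call(a, a, coverage, coverage, 0L, length(ph$chimeric)))
  }
  # a run's true length can differ between the two alleles (a substitution
  # at a run edge shortens one allele's run), so each class re-resolves
  # every arbitrated run from its own reads
  class_hp <- function(rows) {
    lapply(hp_calls, function(hp) {
      tryCatch(
        resolve_homopolymer(pu, hp$columns[1], hp$base, het_threshold,
                            min_majority_cov, rows = rows),
        error = function(e) hp
      )
    })
  }
  a1 <- .allele_seq(pu, ph$class1, class_hp(ph$class1), overall_cons,
                    key_cols = ph$sites, key_syms = ph$key1)
  a2 <- .allele_seq(pu, ph$class2, class_hp(ph$class2), overall_cons,
                    key_cols = ph$sites, key_syms = ph$key2)
  mk_call(a1, a2, ph$support1, ph$support2, nrow(phase_sites),
          length(ph$chimeric))
}

#' Genotype every individual x locus bin of a demultiplexed run
#'
#' Bins are the kept assignments grouped by (individual, locus); when a
#' sample sheet and locus table are supplied, every expected combination is
#' reported, with empty bins recorded as `failed_no_reads` (they count as
#' 0x coverage in downstream summaries). When both tables carry a
#' `species` column, loci are crossed with individuals of their own
#' species only.
#'
#' @param assignments Ledger from [demultiplex()] (or several, row-bound).
#' @param sample_sheet,loci Optional validated sheets defining the
#'   expected bins.
#' @param ... Passed to [genotype_bin()].
#' @return Data frame of genotype calls, one row per bin.
#' @export
genotype_all <- function(assignments, sample_sheet = NULL, loci = NULL, ...) {
  kept <- assignments[assignments$status == "kept", , drop = FALSE]
  expected <- unique(kept[c("individual", "locus")])
  if (!is.null(sample_sheet) && !is.null(loci)) {
    if (!is.null(sample_sheet$species) && !is.null(loci$species)) {
      expected <- merge(sample_sheet[c("individual", "species")],
                        loci[c("locus", "species")], by = "species")
      expected <- unique(expected[c("individual", "locus")])
    } else {
      expected <- expand.grid(individual = unique(sample_sheet$individual),
                              locus = loci$locus, stringsAsFactors = FALSE)
    }
  }
  expected <- expected[order(expected$individual, expected$locus), , drop = FALSE]
  key <- paste(kept$individual, kept$locus, sep = "\r")
  calls <- vector("list", nrow(expected))
  for (i in seq_len(nrow(expected))) {
    sel <- key == paste(expected$individual[i], expected$locus[i], sep = "\r")
    bin <- kept[sel, , drop = FALSE]
    rs <- read_set(bin$read_id, bin$bases, bin$quals)
    calls[[i]] <- genotype_bin(rs, expected$locus[i], expected$individual[i], ...)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
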