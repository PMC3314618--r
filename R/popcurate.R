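# popcurate: population-level allele curation and the run summary
# statistics (coverage, diversity, heterozygosity, allelic ratios).

#' Tabulate alleles within populations
#'
#' Stacks both alleles of every successfully called diploid genotype into
#' per-(locus, population) counts. The total count per group is twice the
#' number of called individuals at that locus.
#'
#' @param genotypes Calls from [genotype_all()].
#' @param sample_sheet Validated sample sheet (maps individual to
#'   population).
#' @return Data frame: `locus`, `population`, `allele_seq`, `count`.
#' @export
population_allele_table <- function(genotypes, sample_sheet) {
  called <- genotypes[genotypes$status == "called", , drop = FALSE]
  pop <- sample_sheet$population[match(called$individual, sample_sheet$individual)]
  long <- data.frame(
    locus = rep(called$locus, 2L),
    population = rep(pop, 2L),
    allele_seq = c(called$allele1, called$allele2),
    stringsAsFactors = FALSE
  )
  if (nrow(long) == 0L) {
    return(data.frame(locus = character(0), population = character(0),
                      allele_seq = character(0), count = integer(0)))
  }
  agg <- aggregate(list(count = rep(1L, nrow(long))),
                   long[c("locus", "population", "allele_seq")], sum)
  agg <- agg[order(agg$locus, agg$population, -agg$count, agg$allele_seq), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Do two aligned alleles differ by exactly one length-1 INDEL inside a
# homopolymer run (run length >= 2 in the longer sequence)?
.single_hp_indel <- function(a, b, scores = default_align_scores()) {
  if (a == b) return(FALSE)
  pal <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .sub_matrix(scores),
    gapOpening = scores$gap_open, gapExtension = scores$gap_ext
  )
  pa <- strsplit1(as.character(Biostrings::alignedPattern(pal)))
  pb <- strsplit1(as.character(Biostrings::alignedSubject(pal)))
  diff <- which(pa != pb)
  if (length(diff) != 1L) return(FALSE)
  i <- diff[1]
  if (pa[i] != "-" && pb[i] != "-") return(FALSE) # substitution, not an INDEL
  longer <- if (pa[i] == "-") pb else pa # the sequence carrying the extra base
  base <- longer[i]
  (i > 1L && longer[i - 1L] == base) ||
    (i < length(longer) && longer[i + 1L] == base)
}

#' Correct singleton alleles that differ by one homopolymer INDEL
#'
#' Within each (locus, population) group, an allele observed exactly once
#' whose alignment to some allele observed at least twice shows exactly
#' one difference -- a single-base INDEL inside a homopolymer run of
#' length >= 2 in the longer sequence -- is treated as a pyrosequencing
#' artifact and rewritten to the matched allele. Several candidate
#' matches: the highest pre-correction count wins, then the
#' lexicographically smaller sequence. Eligibility and ranking use the
#' pre-correction counts throughout, so the operation is order-independent
#' and idempotent, never touches alleles with count >= 2, and conserves
#' the total allele count.
#'
#' @param table A [population_allele_table()].
#' @param scores Alignment scores used for the pairwise scan.
#' @return List with `table` (corrected) and `edits` (log of rewrites:
#'   `locus`, `population`, `from`, `to`).
#' @export
singleton_correction <- function(table, scores = default_align_scores()) {
  edits <- list()
  groups <- unique(table[c("locus", "population")])
  out <- table
  for (g in seq_len(nrow(groups))) {
    sel <- which(out$locus == groups$locus[g] &
                   out$population == groups$population[g])
    grp <- out[sel, , drop = FALSE]
    singles <- grp$allele_seq[grp$count == 1L]
    cand <- grp[grp$count >= 2L, , drop = FALSE]
    if (!length(singles) || !nrow(cand)) next
    cand <- cand[order(-cand$count, cand$allele_seq), , drop = FALSE]
    for (s in sort(singles)) {
      for (ci in seq_len(nrow(cand))) {
        if (.single_hp_indel(s, cand$allele_seq[ci], scores)) {
          edits[[length(edits) + 1L]] <- data.frame(
            locus = groups$locus[g], population = groups$population[g],
            from = s, to = cand$allele_seq[ci], stringsAsFactors = FALSE
          )
          i_from <- sel[grp$allele_seq == s]
          i_to <- sel[grp$allele_seq == cand$allele_seq[ci]]
          out$count[i_to] <- out$count[i_to] + 1L
          out$count[i_from] <- 0L
          break
        }
      }
    }
  }
  out <- out[out$count > 0L, , drop = FALSE]
  out <- out[order(out$locus, out$population, -out$count, out$allele_seq), ,
             drop = FALSE]
  rownames(out) <- NULL
  edits <- if (length(edits)) do.call(rbind, edits) else
    data.frame(locus = character(0), population = character(0),
               from = character(0), to = character(0))
  list(table = out, edits = edits)
}

#' Coverage, diversity and heterozygosity summary
#'
#' Unique alleles are counted after curation when a curated table is
#' supplied; a heterozygote is a called genotype whose two alleles differ;
#' coverage fractions are computed over all attempted individual-loci,
#' with failed bins counting as 0x.
#'
#' @param genotypes Calls from [genotype_all()] (including failed bins).
#' @param allele_table Optional (curated) [population_allele_table()].
#' @return List with `per_locus` (data frame: `locus`, `n_individuals`,
#'   `unique_alleles`, `heterozygotes`, `mean_coverage`, `frac_cov_ge1`,
#'   `frac_cov_ge5`) and `overall` (mean coverage, coverage fractions,
#'   heterozygote count, mean het allelic ratio).
#' @export
diversity_summary <- function(genotypes, allele_table = NULL) {
  if (nrow(genotypes) == 0L) stop("diversity_summary needs at least one genotype row")
  cov <- ifelse(genotypes$status == "called", genotypes$coverage, 0)
  is_het <- genotypes$status == "called" & genotypes$allele1 != genotypes$allele2
  uniq <- function(locus) {
    if (!is.null(allele_table)) {
      length(unique(allele_table$allele_seq[allele_table$locus == locus]))
    } else {
      sel <- genotypes$status == "called" & genotypes$locus == locus
      length(unique(c(genotypes$allele1[sel], genotypes$allele2[sel])))
    }
  }
  loci <- sort(unique(genotypes$locus))
  per_locus <- do.call(rbind, lapply(loci, function(l) {
    sel <- genotypes$locus == l
    data.frame(locus = l, n_individuals = sum(sel),
               unique_alleles = uniq(l), heterozygotes = sum(is_het[sel]),
               mean_coverage = mean(cov[sel]),
               frac_cov_ge1 = mean(cov[sel] >= 1),
               frac_cov_ge5 = mean(cov[sel] >= 5),
               stringsAsFactors = FALSE)
  }))
  ratios <- allelic_ratio_stats(genotypes)
  overall <- list(
    n_bins = nrow(genotypes),
    mean_coverage = mean(cov),
    frac_cov_ge1 = mean(cov >= 1),
    frac_cov_ge5 = mean(cov >= 5),
    heterozygotes = sum(is_het),
    heterozygote_fraction = sum(is_het) / max(sum(genotypes$status == "called"), 1L),
    mean_allelic_ratio = ratios$mean
  )
  list(per_locus = per_locus, overall = overall)
}

#' Allelic support ratio at heterozygous loci
#'
#' The major:minor read-support ratio (support1 / support2) per
#' heterozygous call; the paper-scale statistic behind the "13:9 average
#' allelic ratio" observation.
#'
#' @param genotypes Calls from [genotype_all()].
#' @return List with `ratios` (one per het call), `mean`, and `n`. Empty
#'   (mean NA) when there are no heterozygous calls.
#' @export
allelic_ratio_stats <- function(genotypes) {
  het <- genotypes$status == "called" & genotypes$allele1 != genotypes$allele2
  r <- genotypes$support1[het] / genotypes$support2[het]
  list(ratios = r, mean = if (length(r)) mean(r) else NA_real_, n = length(r))
}

#' Proportion of total coverage carried by allele 1
#'
#' @param allele1_cov Reads supporting allele 1.
#' @param total_cov Total reads at the locus; must be positive and at
#'   least `allele1_cov`.
#' @return `allele1_cov / total_cov`.
#' @export
allele_proportion <- function(allele1_cov, total_cov) {
  if (any(total_cov <= 0)) stop("total coverage must be positive")
  if (any(allele1_cov <= 0) || any(allele1_cov > total_cov)) {
    stop("allele 1 coverage must be in (0, total]")
  }
  allele1_cov / total_cov
}
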