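# demux: route reads to (individual, locus, orientation) by dual-end MID
# and locus-specific primer, applying the library's discard rules in fixed
# order: length -> mean quality -> MID -> primer -> quality trim -> length.

# Roche 454 Titanium Lib-L adaptors (configurable; reads may also begin
# directly at the MID).
ADAPTER_A <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
ADAPTER_B <- "CCTATCCCCTGTGTGCCTTGGCAGTCTCAG"

DISCARD_REASONS <- c("too_short", "low_mean_quality", "mid_mismatch",
                     "primer_absent", "ambiguous")

#' Read length filter
#'
#' Reads strictly below `min_len` bases are discarded ("below 150 bp" is a
#' strict inequality: a 150 bp read is kept).
#'
#' @param bases Character vector of read sequences.
#' @param min_len Minimum length kept (default 150).
#' @return Logical vector: TRUE = keep.
#' @export
length_filter <- function(bases, min_len = 150) nchar(bases) >= min_len

#' Mean quality filter
#'
#' Discards reads whose arithmetic mean Phred score is strictly below
#' `min_q`, computed on the raw (untrimmed) read.
#'
#' @param quals List of integer Phred vectors.
#' @param min_q Minimum mean quality kept (default 30).
#' @return Logical vector: TRUE = keep.
#' @export
mean_quality_filter <- function(quals, min_q = 30) {
  vapply(quals, function(q) length(q) > 0L && mean(q) >= min_q, logical(1))
}

# Locate a MID at the 5' end of each read, allowing the configured adaptor
# to be present (intact or substitution-damaged, i.e. same length) or
# absent. With max_edits = 1, a prefix within one substitution of exactly
# one MID is accepted after the exact pass. Returns individual id (or NA)
# and the offset past adaptor + MID.
.match_mid_end <- function(seqs, mids, individuals, offsets, max_edits = 0L) {
  lens <- sort(unique(nchar(mids)), decreasing = TRUE)
  ind <- rep(NA_character_, length(seqs))
  cut <- rep(NA_integer_, length(seqs))
  for (off in offsets) {
    for (L in lens) {
      sel <- nchar(mids) == L
      map <- setNames(individuals[sel], mids[sel])
      todo <- which(is.na(ind))
      if (!length(todo)) break
      pref <- substring(seqs[todo], off + 1L, off + L)
      hit <- pref %in% names(map)
      ind[todo[hit]] <- unname(map[pref[hit]])
      cut[todo[hit]] <- off + L
    }
  }
  if (max_edits >= 1L) {
    for (off in offsets) {
      for (L in lens) {
        sel <- which(nchar(mids) == L)
        todo <- which(is.na(ind))
        if (!length(todo)) break
        pref <- substring(seqs[todo], off + 1L, off + L)
        nmm <- matrix(0L, length(todo), length(sel))
        for (i in seq_len(L)) {
          pc <- substring(pref, i, i)
          for (j in seq_along(sel)) {
            nmm[, j] <- nmm[, j] + (pc != substring(mids[sel[j]], i, i))
          }
        }
        near <- nmm <= max_edits
        one <- rowSums(near) == 1L & nchar(pref) == L
        for (r in which(one)) {
          j <- sel[which(near[r, ])]
          ind[todo[r]] <- individuals[j]
          cut[todo[r]] <- off + L
        }
      }
    }
  }
  list(individual = ind, cut = cut)
}

#' Match the MID barcode at both read ends
#'
#' The MID found at the 5' end (immediately after the sequencing adaptor,
#' if any) and the reverse-complemented MID at the 3' end must identify the
#' same individual; anything else is a `mid_mismatch`. Matching is exact
#' (Roche MIDs are designed to be error tolerant, and the discard rule is
#' strict).
#'
#' @param bases Character vector of read sequences.
#' @param sample_sheet Validated sample sheet (see [read_sample_sheet()]).
#' @param adapter_a,adapter_b Adaptor sequences to tolerate at the ends.
#' @param max_edits MID substitution tolerance; 0 (the default, the
#'   published strict rule) or 1, in which case a prefix within one
#'   substitution of exactly one MID is accepted.
#' @return A list with `individual` (id or NA), and the 5'/3' cut
#'   positions `cut5`, `cut3` delimiting the inner core of each read.
#' @export
match_mid <- function(bases, sample_sheet,
                      adapter_a = ADAPTER_A, adapter_b = ADAPTER_B,
                      max_edits = 0L) {
  offs <- unique(c(0L, nchar(adapter_a), nchar(adapter_b)))
  m5 <- .match_mid_end(bases, sample_sheet$mid, sample_sheet$individual,
                       offs, max_edits)
  m3 <- .match_mid_end(revcomp(bases), sample_sheet$mid,
                       sample_sheet$individual, offs, max_edits)
  same <- !is.na(m5$individual) & !is.na(m3$individual) &
    m5$individual == m3$individual
  list(
    individual = ifelse(same, m5$individual, NA_character_),
    cut5 = ifelse(same, m5$cut, NA_integer_),
    cut3 = ifelse(same, nchar(bases) - m3$cut, NA_integer_)
  )
}

#' Identify the locus and orientation from the template-specific primer
#'
#' The complete forward or reverse primer must match (IUPAC-aware, zero
#' mismatches) at the very start of the MID-trimmed core. Reads matching
#' primers of two or more loci are discarded as `ambiguous`; reads matching
#' none as `primer_absent`. The reverse-complemented partner primer at the
#' 3' end of the core is trimmed positionally: its location is fixed once
#' both MIDs have matched, so a sequencing error inside it does not
#' discard the read (the core must still be long enough to hold both
#' primer copies).
#'
#' @param cores Character vector of MID-trimmed read cores.
#' @param loci Validated locus table (see [read_locus_table()]).
#' @return A list of vectors `locus`, `orientation` (`"forward"` /
#'   `"reverse"` or NA), `reason` (NA, `"primer_absent"` or `"ambiguous"`),
#'   and `ins_start`, `ins_end` bounding the insert within the core.
#' @export
match_primer <- function(cores, loci) {
  n <- length(cores)
  nhit <- integer(n)
  locus <- rep(NA_character_, n)
  orient <- rep(NA_character_, n)
  p5len <- integer(n)
  p3 <- rep(NA_character_, n)
  for (i in seq_len(nrow(loci))) {
    fw <- iupac_match_at(loci$fwd_primer[i], cores)
    rv <- iupac_match_at(loci$rev_primer[i], cores)
    both <- fw & rv
    if (any(both)) { # degenerate overlap of the pair itself: treat as two hits
      nhit[both] <- nhit[both] + 2L
      fw <- fw & !both
      rv <- rv & !both
    }
    nhit[fw] <- nhit[fw] + 1L
    nhit[rv] <- nhit[rv] + 1L
    locus[fw] <- loci$locus[i]
    orient[fw] <- "forward"
    p5len[fw] <- nchar(loci$fwd_primer[i])
    p3[fw] <- revcomp(loci$rev_primer[i])
    locus[rv] <- loci$locus[i]
    orient[rv] <- "reverse"
    p5len[rv] <- nchar(loci$rev_primer[i])
    p3[rv] <- revcomp(loci$fwd_primer[i])
  }
  reason <- rep(NA_character_, n)
  reason[nhit == 0L] <- "primer_absent"
  reason[nhit >= 2L] <- "ambiguous"
  one <- which(nhit == 1L)
  ins_end <- rep(NA_integer_, n)
  if (length(one)) {
    # The partner primer's reverse complement sits right before the 3' MID;
    # with both MIDs matched exactly, its position is fully determined, so
    # it is trimmed positionally (a sequencing error inside it is not
    # grounds for discarding the read). The core must still be long enough
    # to contain both primer copies.
    p3len <- nchar(p3[one])
    long_enough <- nchar(cores[one]) >= p5len[one] + p3len
    reason[one[!long_enough]] <- "primer_absent"
    ins_end[one[long_enough]] <- (nchar(cores[one]) - p3len)[long_enough]
  }
  keep <- is.na(reason)
  locus[!keep] <- NA_character_
  orient[!keep] <- NA_character_
  list(locus = locus, orientation = orient, reason = reason,
       ins_start = ifelse(keep, p5len + 1L, NA_integer_), ins_end = ins_end)
}

#' Quality-trim a read by the modified-Mott algorithm
#'
#' Each base scores `cutoff - P_error`; the retained segment is the first
#' maximal-sum contiguous subsequence (the classic phred/Mott end trim).
#' Never lengthens a read; an all-low-quality read trims to empty.
#'
#' @param bases A single read sequence.
#' @param quals Its integer Phred scores.
#' @param cutoff Error-probability cutoff (default 0.05).
#' @return List with trimmed `bases`, `quals`, and the retained `range`
#'   (c(start, end), 0-length range c(0, -1) for an empty result).
#' @export
quality_trim <- function(bases, quals, cutoff = 0.05) {
  s <- cutoff - 10^(-quals / 10)
  best <- 0
  best_range <- c(0L, -1L)
  cur <- 0
  cur_start <- 1L
  for (i in seq_along(s)) {
    cur <- cur + s[i]
    if (cur <= 0) {
      cur <- 0
      cur_start <- i + 1L
    } else if (cur > best + 1e-12) {
      best <- cur
      best_range <- c(cur_start, i)
    }
  }
  if (best_range[2] < best_range[1]) {
    list(bases = "", quals = integer(0), range = best_range)
  } else {
    list(bases = substring(bases, best_range[1], best_range[2]),
         quals = quals[best_range[1]:best_range[2]], range = best_range)
  }
}

#' Demultiplex a library
#'
#' Applies the discard rules in order (length, mean quality, dual-end MID,
#' primer, quality trim, post-trim length), trims adaptor + MID + primers,
#' and reorients reverse reads onto the forward strand. Every input read
#' appears exactly once in the returned ledger; the ledger is sorted by
#' read id so the output is independent of input order.
#'
#' @param reads A [read_set()].
#' @param sample_sheet Validated sample sheet.
#' @param loci Validated locus table.
#' @param min_len Minimum read length (applied before and after trimming).
#' @param min_mean_q Minimum raw-read mean Phred score.
#' @param trim_cutoff Mott error-probability cutoff.
#' @param mid_max_edits MID substitution tolerance (0 = the published
#'   strict both-ends rule; see [match_mid()]).
#' @param adapter_a,adapter_b Adaptor sequences tolerated at the ends.
#' @return List with `assignments` (the per-read ledger: `read_id`,
#'   `individual`, `locus`, `orientation`, `status`, `discard_reason`, and
#'   trimmed `bases`/`quals` for kept reads) and `report` (a
#'   `library_quality_report`: totals, per-reason discard counts, raw
#'   read-length histogram).
#' @export
demultiplex <- function(reads, sample_sheet, loci,
                        min_len = 150, min_mean_q = 30, trim_cutoff = 0.05,
                        mid_max_edits = 0L,
                        adapter_a = ADAPTER_A, adapter_b = ADAPTER_B) {
  sample_sheet <- validate_sample_sheet(sample_sheet)
  loci <- validate_locus_table(loci)
  n <- nrow(reads)
  status <- rep("kept", n)
  reason <- rep(NA_character_, n)
  individual <- rep(NA_character_, n)
  locus <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  out_bases <- rep(NA_character_, n)
  out_quals <- vector("list", n)
  n_short_raw <- 0L
  n_short_trim <- 0L

  live <- rep(TRUE, n)
  fail <- function(idx, why) {
    status[idx] <<- "discarded"
    reason[idx] <<- why
    live[idx] <<- FALSE
  }

  # 1. raw length
  bad <- which(live & !length_filter(reads$bases, min_len))
  n_short_raw <- length(bad)
  fail(bad, "too_short")
  # 2. raw mean quality
  bad <- which(live)[!mean_quality_filter(reads$quals[live], min_mean_q)]
  fail(bad, "low_mean_quality")
  # 3. MID at both ends
  idx <- which(live)
  if (length(idx)) {
    mm <- match_mid(reads$bases[idx], sample_sheet, adapter_a, adapter_b,
                    max_edits = mid_max_edits)
    hit <- !is.na(mm$individual)
    fail(idx[!hit], "mid_mismatch")
    idx <- idx[hit]
    individual[idx] <- mm$individual[hit]
    cores <- substring(reads$bases[idx], mm$cut5[hit] + 1L, mm$cut3[hit])
    core_off <- mm$cut5[hit]
    # 4. locus-specific primer
    pm <- match_primer(cores, loci)
    bad <- !is.na(pm$reason)
    fail(idx[bad], pm$reason[bad])
    keep <- which(!bad)
    locus[idx[keep]] <- pm$locus[keep]
    orientation[idx[keep]] <- pm$orientation[keep]
    for (j in keep) {
      i <- idx[j]
      a <- core_off[j] + pm$ins_start[j]
      b <- core_off[j] + pm$ins_end[j]
      if (b < a) { # zero-length insert
        fail(i, "too_short")
        n_short_trim <- n_short_trim + 1L
        next
      }
      ins <- substring(reads$bases[i], a, b)
      q <- reads$quals[[i]][a:b]
      if (pm$orientation[j] == "reverse") {
        ins <- revcomp(ins)
        q <- rev(q)
      }
      # 5. quality trim, 6. post-trim length
      tr <- quality_trim(ins, q, trim_cutoff)
      if (nchar(tr$bases) < min_len) {
        fail(i, "too_short")
        n_short_trim <- n_short_trim + 1L
      } else {
        out_bases[i] <- tr$bases
        out_quals[[i]] <- tr$quals
      }
    }
  }

  ord <- order(reads$read_id)
  assignments <- data.frame(
    read_id = reads$read_id, individual = individual, locus = locus,
    orientation = orientation, status = status, discard_reason = reason,
    bases = out_bases, stringsAsFactors = FALSE
  )
  assignments$quals <- out_quals
  assignments <- assignments[ord, , drop = FALSE]
  rownames(assignments) <- NULL

  tab <- table(factor(reason[status == "discarded"], levels = DISCARD_REASONS))
  breaks <- seq(0L, max(c(nchar(reads$bases), 0L)) + 50L, by = 50L)
  hist_counts <- if (n) table(cut(nchar(reads$bases), breaks, right = FALSE)) else NULL
  report <- structure(list(
    total_reads = n,
    kept_reads = sum(status == "kept"),
    discarded_by_reason = as.integer(tab),
    reason_levels = DISCARD_REASONS,
    n_too_short_raw = n_short_raw,
    n_too_short_after_trim = n_short_trim,
    length_hist_breaks = breaks,
    length_hist_counts = as.integer(hist_counts)
  ), class = "library_quality_report")
  names(report$discarded_by_reason) <- DISCARD_REASONS
  stopifnot(report$kept_reads + sum(report$discarded_by_reason) == n)
  list(assignments = assignments, report = report)
}

#' @export
print.library_quality_report <- function(x, ...) {
  cat("Library quality report\n")
  cat("  total reads:", x$total_reads, "\n")
  cat("  kept reads: ", x$kept_reads, "\n")
  for (r in names(x$discarded_by_reason)) {
    cat(sprintf("  discarded %-18s %d\n", paste0(r, ":"), x$discarded_by_reason[[r]]))
  }
  cat("  (too_short raw:", x$n_too_short_raw,
      "/ after trim:", x$n_too_short_after_trim, ")\n")
  invisible(x)
}
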