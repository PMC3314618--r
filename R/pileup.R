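# Star-alignment pileup: one individual x locus read bin, aligned column
# by column. The seed (highest mean-quality read) defines the coordinate
# frame; every other read is pairwise-aligned to it (ends-free) and merged.
# Columns are keyed (p, k): seed position p with k = 0, or the k-th
# inserted column after p. Read bases extending past the seed ends are kept
# as end-insertion columns keyed by their distance from the seed end, so a
# quality-trimmed seed never truncates the called alleles.

PILEUP_SYMBOLS <- c("A", "C", "G", "T", "N", "-")

default_align_scores <- function() {
  list(match = 1, mismatch = -2, gap_open = 4, gap_ext = 1)
}

.sub_matrix <- function(scores) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scores$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scores$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Parse one pairwise alignment into pileup cells.
# Returns data.frame(p, k, char, qual) in alignment order.
.aln_cells <- function(pat_str, sub_str, p_start, p_end, s_start, s_end,
                       read_bases, read_quals, seed_len) {
  pc <- strsplit1(pat_str)
  sc <- strsplit1(sub_str)
  is_sgap <- sc == "-"
  p <- s_start - 1L + cumsum(!is_sgap)
  k <- integer(length(sc))
  if (any(is_sgap)) {
    r <- rle(is_sgap)
    k[is_sgap] <- sequence(r$lengths[r$values])
  }
  is_pgap <- pc == "-"
  ppos <- p_start - 1L + cumsum(!is_pgap)
  qual <- rep(0, length(pc))
  qual[!is_pgap] <- read_quals[ppos[!is_pgap]]
  cells <- data.frame(p = p, k = k, char = pc, qual = qual,
                      stringsAsFactors = FALSE)
  # Unaligned read overhangs past the seed ends are kept as end-insertion
  # columns keyed by distance from the seed end (k < 0 before the seed,
  # k > 0 after it), so a short seed does not truncate the pileup. An
  # overhang clipped against the seed interior (alignment chose not to use
  # it) is dropped.
  if (p_start > 1L && s_start == 1L) {
    idx <- seq_len(p_start - 1L)
    pre <- data.frame(p = 0L, k = -(p_start - idx),
                      char = strsplit1(substring(read_bases, 1L, p_start - 1L)),
                      qual = read_quals[idx], stringsAsFactors = FALSE)
    cells <- rbind(pre, cells)
  }
  nb <- nchar(read_bases)
  if (p_end < nb && s_end == seed_len) {
    idx <- (p_end + 1L):nb
    k0 <- max(c(k[p == seed_len], 0L)) # past any internal insertions at the end
    post <- data.frame(p = seed_len, k = k0 + seq_along(idx),
                       char = strsplit1(substring(read_bases, p_end + 1L, nb)),
                       qual = read_quals[idx], stringsAsFactors = FALSE)
    cells <- rbind(cells, post)
  }
  cells
}

#' Build a read pileup by star alignment
#'
#' The read with the highest mean quality (ties: smallest read id) seeds
#' the alignment; every other read is aligned to it with Needleman-Wunsch
#' ends-free alignment (match +1, mismatch -2, gap open -4, gap extend -1
#' by default) and the alignments are merged column-wise. Deterministic for
#' a given read multiset, irrespective of input order.
#'
#' @param reads A [read_set()] (or the kept rows of a demultiplex ledger)
#'   for one individual x locus bin, all in forward orientation.
#' @param locus_id,individual_id Identifiers recorded on the pileup.
#' @param scores Alignment scores, see `default_align_scores()`.
#' @return A `pileup` object: character matrix `chars` (reads x columns;
#'   NA = read does not cover the column, "-" = gap), numeric matrix
#'   `quals`, `col_pos` data frame (`p`, `k`), `read_ids`, and the seed id.
#' @export
build_pileup <- function(reads, locus_id = NA_character_,
                         individual_id = NA_character_,
                         scores = default_align_scores()) {
  reads <- reads[nchar(reads$bases) > 0L, , drop = FALSE]
  if (nrow(reads) == 0L) stop("cannot build a pileup from zero reads")
  meanq <- vapply(reads$quals, mean, numeric(1))
  ord <- order(-meanq, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  seed <- reads$bases[1]
  L <- nchar(seed)

  cells <- vector("list", nrow(reads))
  cells[[1]] <- data.frame(p = seq_len(L), k = 0L, char = strsplit1(seed),
                           qual = reads$quals[[1]], stringsAsFactors = FALSE)
  if (nrow(reads) > 1L) {
    pal <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads$bases[-1]),
      Biostrings::DNAString(seed),
      type = "overlap", substitutionMatrix = .sub_matrix(scores),
      gapOpening = scores$gap_open, gapExtension = scores$gap_ext
    )
    pat <- Biostrings::pattern(pal)
    sub <- Biostrings::subject(pal)
    pat_str <- as.character(pat)
    sub_str <- as.character(sub)
    p_start <- Biostrings::start(pat)
    p_end <- Biostrings::end(pat)
    s_start <- Biostrings::start(sub)
    s_end <- Biostrings::end(sub)
    for (i in seq_len(nrow(reads) - 1L)) {
      cells[[i + 1L]] <- .aln_cells(pat_str[i], sub_str[i], p_start[i],
                                    p_end[i], s_start[i], s_end[i],
                                    reads$bases[i + 1L], reads$quals[[i + 1L]],
                                    L)
    }
  }

  all_keys <- unique(do.call(rbind, lapply(cells, function(d) d[c("p", "k")])))
  all_keys <- all_keys[order(all_keys$p, all_keys$k), , drop = FALSE]
  key_id <- paste(all_keys$p, all_keys$k)
  nc <- nrow(all_keys)
  nr <- nrow(reads)
  chars <- matrix(NA_character_, nr, nc)
  quals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    d <- cells[[r]]
    ci <- match(paste(d$p, d$k), key_id)
    chars[r, ci] <- d$char
    quals[r, ci] <- d$qual
    span <- range(ci)
    inside <- seq(span[1], span[2])
    gap <- inside[is.na(chars[r, inside])]
    chars[r, gap] <- "-"
    quals[r, gap] <- 0
  }
  structure(list(chars = chars, quals = quals,
                 col_pos = data.frame(p = all_keys$p, k = all_keys$k),
                 read_ids = reads$read_id, seed_id = reads$read_id[1],
                 locus_id = locus_id, individual_id = individual_id),
            class = "pileup")
}

#' Per-column symbol counts, quality sums and depth of a pileup
#'
#' @param pileup A [build_pileup()] result.
#' @param rows Optional integer subset of reads (default all).
#' @return List with `counts` (6 x n columns matrix over A,C,G,T,N,-),
#'   `qual_sums` (same shape), and `depth` (covering reads excluding N).
#' @export
pileup_counts <- function(pileup, rows = NULL) {
  ch <- pileup$chars
  qu <- pileup$quals
  if (!is.null(rows)) {
    ch <- ch[rows, , drop = FALSE]
    qu <- qu[rows, , drop = FALSE]
  }
  counts <- vapply(PILEUP_SYMBOLS, function(s) {
    colSums(ch == s, na.rm = TRUE)
  }, numeric(ncol(ch)))
  qual_sums <- vapply(PILEUP_SYMBOLS, function(s) {
    colSums(qu * (!is.na(ch) & ch == s), na.rm = TRUE)
  }, numeric(ncol(ch)))
  if (ncol(ch) == 1L) { # vapply drops to vector
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(NULL, PILEUP_SYMBOLS))
    qual_sums <- matrix(qual_sums, nrow = 1,
                        dimnames = list(NULL, PILEUP_SYMBOLS))
  }
  counts <- t(counts)
  qual_sums <- t(qual_sums)
  depth <- colSums(counts) - counts["N", ]
  list(counts = counts, qual_sums = qual_sums, depth = depth)
}

# Per-column consensus symbol for a read subset. Plurality, ties broken by
# summed quality then by fixed symbol order (A, C, G, T, then gap) -- except
# at insertion-type columns (k != 0), where a count tie resolves to the
# gap: a gap cell there means "read has no inserted base" and carries
# quality 0 by construction, so quality must not arbitrate, and an
# insertion into the consensus needs strictly positive evidence. N wins
# only when nothing else covers the column; NA when the subset has no
# coverage at all.
.consensus_symbols <- function(pileup, rows = NULL) {
  pc <- pileup_counts(pileup, rows)
  syms <- c("A", "C", "G", "T", "-")
  ins_type <- pileup$col_pos$k != 0L
  out <- rep(NA_character_, ncol(pc$counts))
  cnt <- pc$counts[syms, , drop = FALSE]
  qs <- pc$qual_sums[syms, , drop = FALSE]
  gap_first <- syms != "-"
  for (j in seq_len(ncol(cnt))) {
    if (sum(cnt[, j]) == 0L) {
      if (pc$counts["N", j] > 0L) out[j] <- "N"
      next
    }
    o <- if (ins_type[j]) {
      order(-cnt[, j], gap_first, -qs[, j], seq_along(syms))[1]
    } else {
      order(-cnt[, j], -qs[, j], seq_along(syms))[1]
    }
    out[j] <- syms[o]
  }
  out
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup:", length(x$read_ids), "reads x", ncol(x$chars), "columns",
      sprintf("(%s / %s, seed %s)\n",
              x$individual_id, x$locus_id, x$seed_id))
  invisible(x)
}
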