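# Sequence-level helpers shared across modules. Sequences are plain
# uppercase character strings over ACGTN (IUPAC codes allowed in primers);
# qualities are integer Phred scores carried as list columns.

PHRED_OFFSET <- 33L

#' Decode a Sanger (Phred+33) quality string to integer scores
#'
#' @param qual_string A single quality string.
#' @return Integer vector of Phred scores, one per character.
#' @export
phred_decode <- function(qual_string) {
  if (nchar(qual_string) == 0L) return(integer(0))
  as.integer(charToRaw(qual_string)) - PHRED_OFFSET
}

#' Encode integer Phred scores as a Sanger (Phred+33) quality string
#'
#' @param quals Integer vector of Phred scores (0--60).
#' @return A single quality string.
#' @export
phred_encode <- function(quals) {
  if (length(quals) == 0L) return("")
  q <- as.integer(quals)
  if (any(q < 0L | q > 93L)) stop("Phred scores must be in [0, 93]")
  rawToChar(as.raw(q + PHRED_OFFSET))
}

#' Reverse complement DNA strings
#'
#' Vectorised; IUPAC ambiguity codes are complemented correctly.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

is_dna <- function(x) grepl("^[ACGTN]*$", x)
is_iupac <- function(x) grepl("^[ACGTMRWSYKVHDBN]+$", x)

iupac_sets <- function() {
  if (is.null(.pkg_cache$iupac)) {
    map <- Biostrings::IUPAC_CODE_MAP
    s <- strsplit(unname(map), "")
    names(s) <- names(map)
    .pkg_cache$iupac <- s
  }
  .pkg_cache$iupac
}

#' IUPAC-aware exact match of a primer at a fixed position
#'
#' Tests whether `pattern` (which may contain IUPAC degeneracy codes)
#' matches each of `subjects` (plain ACGTN) with zero mismatches, starting
#' at position `at`. An N in the subject only matches an N (or code
#' containing all bases is still a set test: N in the subject is the
#' literal character and matches only when it is in the expansion, i.e.
#' never for A/C/G/T codes).
#'
#' @param pattern IUPAC DNA string.
#' @param subjects Character vector of DNA strings.
#' @param at Start position (1-based); scalar or one per subject.
#' @return Logical vector, one per subject.
#' @export
iupac_match_at <- function(pattern, subjects, at = 1L) {
  stopifnot(length(pattern) == 1L, is_iupac(pattern))
  sets <- iupac_sets()
  pc <- strsplit(pattern, "")[[1]]
  at <- rep_len(as.integer(at), length(subjects))
  ok <- at >= 1L & nchar(subjects) >= at + length(pc) - 1L
  for (i in seq_along(pc)) {
    idx <- which(ok)
    if (!length(idx)) break
    allowed <- sets[[pc[i]]]
    pos <- at[idx] + i - 1L
    ok[idx] <- substring(subjects[idx], pos, pos) %in% allowed
  }
  ok
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

strsplit1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
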