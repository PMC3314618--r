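# io_formats: readers/writers for the formats the pipeline touches and
# validation of the bespoke tab-delimited sheets.

#' Construct a read set
#'
#' A read set is a data frame with one row per sequencing read: `read_id`
#' (opaque string), `bases` (uppercase DNA over ACGTN) and `quals` (list
#' column of integer Phred scores, one per base).
#'
#' @param read_id Character vector of identifiers.
#' @param bases Character vector of DNA strings.
#' @param quals List of integer vectors, one per read.
#' @return A `data.frame` of class `read_set`.
#' @export
read_set <- function(read_id = character(0), bases = character(0),
                     quals = list()) {
  stopifnot(length(read_id) == length(bases), length(bases) == length(quals))
  bases <- toupper(bases)
  bad <- which(!is_dna(bases))
  if (length(bad)) {
    stop("read '", read_id[bad[1]], "': bases contain characters outside ACGTN")
  }
  mism <- which(nchar(bases) != lengths(quals))
  if (length(mism)) {
    stop("read '", read_id[mism[1]], "': ", nchar(bases[mism[1]]),
         " bases but ", lengths(quals)[mism[1]], " quality scores")
  }
  out <- data.frame(read_id = as.character(read_id), bases = bases,
                    stringsAsFactors = FALSE)
  out$quals <- lapply(quals, as.integer)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Read a Sanger (Phred+33) FASTQ file
#'
#' Strict four-line-record parser. Malformed records (base/quality length
#' mismatch, bad quality characters, missing markers) are fatal errors that
#' name the offending record. Quality characters implying scores above 60
#' are rejected loudly as a likely Phred+64 file; this package fixes the
#' encoding to Phred+33.
#'
#' @param path Path to a FASTQ file.
#' @return A [read_set()] data frame. N bases are preserved.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) return(read_set())
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq.int(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq.int(2L, by = 4L, length.out = n)])
  plus <- lines[seq.int(3L, by = 4L, length.out = n)]
  qstr <- lines[seq.int(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("record ", bad[1], ": separator line does not start with '+'")
  ids <- sub("\\s.*$", "", substring(hdr, 2L))

  bad <- which(!is_dna(seqs))
  if (length(bad)) stop("read '", ids[bad[1]], "': non-ACGTN base characters")
  bad <- which(nchar(seqs) != nchar(qstr))
  if (length(bad)) {
    stop("read '", ids[bad[1]], "': ", nchar(seqs[bad[1]]), " bases but ",
         nchar(qstr[bad[1]]), " quality characters")
  }
  quals <- lapply(qstr, phred_decode)
  lo <- vapply(quals, function(q) if (length(q)) min(q) else 0L, integer(1))
  hi <- vapply(quals, function(q) if (length(q)) max(q) else 0L, integer(1))
  bad <- which(lo < 0L)
  if (length(bad)) stop("read '", ids[bad[1]], "': quality character below '!' (not Phred+33)")
  bad <- which(hi > 60L)
  if (length(bad)) {
    stop("read '", ids[bad[1]], "': quality score above 60; ",
         "this looks like Phred+64 input, which is not supported")
  }
  read_set(ids, seqs, quals)
}

#' Write a read set as Sanger (Phred+33) FASTQ
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qstr <- vapply(reads$quals, phred_encode, character(1))
  out <- character(4L * nrow(reads))
  out[seq.int(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  out[seq.int(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
  out[seq.int(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq.int(4L, by = 4L, length.out = nrow(reads))] <- qstr
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA + QUAL file pair
#'
#' The legacy 454 export format: bases in FASTA, whitespace-separated
#' integer Phred scores under matching headers in a .qual file.
#'
#' @param fasta_path Path to the FASTA file.
#' @param qual_path Path to the QUAL file.
#' @return A [read_set()].
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(qual_path)
  hdr_at <- which(startsWith(lines, ">"))
  if (length(hdr_at) != length(seqs)) {
    stop("FASTA has ", length(seqs), " records but QUAL has ", length(hdr_at))
  }
  qids <- sub("\\s.*$", "", substring(lines[hdr_at], 2L))
  if (!identical(qids, ids)) stop("FASTA and QUAL record names differ or are reordered")
  ends <- c(hdr_at[-1] - 1L, length(lines))
  quals <- lapply(seq_along(hdr_at), function(i) {
    if (ends[i] < hdr_at[i] + 1L) return(integer(0))
    as.integer(scan(text = paste(lines[(hdr_at[i] + 1L):ends[i]], collapse = " "),
                    what = integer(), quiet = TRUE))
  })
  read_set(ids, toupper(as.character(seqs)), quals)
}

#' Read and validate a sample sheet
#'
#' Tab-delimited with header; required columns `mid`, `individual`,
#' `population`, `species`. MIDs must be plain ACGT of length >= 6 and
#' unique within each (population, species) pool.
#'
#' @param path Path to the sheet.
#' @return Data frame with the four required columns (extras preserved).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate in place of a file.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("mid", "individual", "population", "species")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("sample sheet is missing column(s): ",
                         paste(miss, collapse = ", "))
  sheet$mid <- toupper(sheet$mid)
  bad <- which(!grepl("^[ACGT]{6,}$", sheet$mid))
  if (length(bad)) {
    stop("sample sheet row ", bad[1], ": MID '", sheet$mid[bad[1]],
         "' is not plain ACGT of length >= 6")
  }
  pool <- paste(sheet$population, sheet$species, sep = "\r")
  dup <- which(duplicated(paste(pool, sheet$mid, sep = "\r")))
  if (length(dup)) {
    stop("duplicate MID '", sheet$mid[dup[1]], "' within pool (population '",
         sheet$population[dup[1]], "', species '", sheet$species[dup[1]], "')")
  }
  # one MID must map to one individual within any pooled library
  amb <- tapply(sheet$individual, paste(sheet$population, sheet$mid),
                function(x) length(unique(x)))
  if (any(amb > 1L)) {
    stop("a MID maps to more than one individual within one population pool; ",
         "demultiplexing would be ambiguous")
  }
  sheet
}

#' Read and validate a locus table
#'
#' Tab-delimited with header; required columns `locus`, `fwd_primer`,
#' `rev_primer`, `min_len`, `max_len`. Primers may carry IUPAC degeneracy
#' codes. Amplicons designed outside the 400--600 bp target range trigger a
#' warning but are accepted.
#'
#' @param path Path to the table.
#' @return Data frame (extra columns such as `species` are preserved).
#' @export
read_locus_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_locus_table(df)
}

#' @rdname read_locus_table
#' @param loci A data frame to validate in place of a file.
#' @export
validate_locus_table <- function(loci) {
  req <- c("locus", "fwd_primer", "rev_primer", "min_len", "max_len")
  miss <- setdiff(req, names(loci))
  if (length(miss)) stop("locus table is missing column(s): ",
                         paste(miss, collapse = ", "))
  loci$locus <- as.character(loci$locus)
  loci$fwd_primer <- toupper(as.character(loci$fwd_primer))
  loci$rev_primer <- toupper(as.character(loci$rev_primer))
  loci$min_len <- as.numeric(loci$min_len)
  loci$max_len <- as.numeric(loci$max_len)
  if (any(duplicated(loci$locus))) stop("duplicate locus id in locus table")
  for (col in c("fwd_primer", "rev_primer")) {
    bad <- which(nchar(loci[[col]]) == 0L | !is_iupac(loci[[col]]))
    if (length(bad)) {
      stop("locus '", loci$locus[bad[1]], "': ", col,
           " is empty or contains non-IUPAC characters")
    }
  }
  bad <- which(loci$min_len > loci$max_len)
  if (length(bad)) stop("locus '", loci$locus[bad[1]], "': min_len > max_len")
  off <- which(loci$min_len < 400 | loci$max_len > 600)
  if (length(off)) {
    warning("locus/loci outside the 400-600 bp amplicon design range: ",
            paste(loci$locus[off], collapse = ", "))
  }
  loci
}

#' Write allele records as FASTA
#'
#' Headers encode `locus|population|individual|allele_index|support` so the
#' file round-trips through [read_alleles()].
#'
#' @param records Data frame with columns `locus`, `population`,
#'   `individual`, `allele_index`, `support`, `seq`.
#' @param path Output path.
#' @param allow_empty Write an empty file when `records` has zero rows
#'   (otherwise an error).
#' @return Invisibly, `path`.
#' @export
write_alleles <- function(records, path, allow_empty = FALSE) {
  req <- c("locus", "population", "individual", "allele_index", "support", "seq")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("allele records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) {
    if (!allow_empty) stop("no allele records to write (set allow_empty = TRUE)")
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(records$support < 1)) stop("supporting_reads must be >= 1")
  fields <- c("locus", "population", "individual", "allele_index", "support")
  for (f in fields) {
    if (any(grepl("|", as.character(records[[f]]), fixed = TRUE))) {
      stop("field '", f, "' contains the reserved '|' separator")
    }
  }
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- paste(records$locus, records$population, records$individual,
                    records$allele_index, records$support, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read allele records written by [write_alleles()]
#'
#' @param path Path to the FASTA file.
#' @return Data frame with columns `locus`, `population`, `individual`,
#'   `allele_index`, `support`, `seq`.
#' @export
read_alleles <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) {
    return(data.frame(locus = character(0), population = character(0),
                      individual = character(0), allele_index = integer(0),
                      support = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad)) stop("record ", bad[1], ": header is not locus|population|individual|allele_index|support")
  m <- do.call(rbind, parts)
  data.frame(locus = m[, 1], population = m[, 2], individual = m[, 3],
             allele_index = as.integer(m[, 4]), support = as.integer(m[, 5]),
             seq = as.character(x), stringsAsFactors = FALSE, row.names = NULL)
}
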