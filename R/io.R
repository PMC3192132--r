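## File-format plumbing. Genomes are carried internally as named character
## vectors (one element per sequence); Biostrings handles FASTA/FASTQ and
## rtracklayer handles BED. All TSV interfaces are 1-based inclusive for
## positions; BED stays 0-based half-open on disk.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector, one element per sequence, uppercased.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome (named character vector) to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with fixed high quality scores
#'
#' Base qualities play no role in any of the audited criteria, so reads are
#' written with a constant Sanger quality of "I" (Q40).
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(unlist(reads))
  names(seqs) <- names(reads)
  quals <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a candidate-RDD site table
#'
#' Expected columns: `site_id`, `chrom`, `pos` (1-based), `strand` (+/-),
#' `genomic_base` (the nucleotide A reported in the genome) and `rdd_base`
#' (the nucleotide B reported in the RNA). A and B are given on the
#' transcript strand.
#'
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_site_table(df)
}

#' @rdname read_site_table
#' @param sites site table data.frame.
#' @export
write_site_table <- function(sites, path) {
  write_tsv(sites, path)
}

validate_site_table <- function(df) {
  need <- c("site_id", "chrom", "pos", "strand", "genomic_base", "rdd_base")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("site table strand must be '+' or '-'", call. = FALSE)
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id in site table", call. = FALSE)
  df$pos <- as.integer(df$pos)
  df$genomic_base <- toupper(df$genomic_base)
  df$rdd_base <- toupper(df$rdd_base)
  if (any(df$genomic_base == df$rdd_base))
    stop("genomic_base and rdd_base must differ at every site", call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path BED file (0-based, half-open on disk).
#' @return a `GRanges` (1-based, closed) with interval names when present.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals to BED
#'
#' @param gr a `GRanges` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

intervals_df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
}

#' Write alignments as minimal SAM
#'
#' Minimal dialect: `@HD`/`@SQ` header, flag 0/16, full-length match CIGAR,
#' `NM` tag. `SEQ` is stored in target-forward orientation as SAM requires.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param targets named character vector of target sequences (for `@SQ`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alignments, targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    seq <- ifelse(alignments$strand == "-",
                  revcomp(alignments$read_seq), alignments$read_seq)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alignments$read_id, flag, alignments$target,
                       alignments$target_start + 1L, nchar(seq), seq,
                       alignments$n_mismatches), con)
  }
  invisible(path)
}

#' Read externally produced alignments from SAM
#'
#' Reads a (possibly real-mapper-produced) SAM file against the flank or
#' transcript database and reconstitutes the alignment records used
#' downstream. Mismatch counts and positions are recomputed from `SEQ`
#' against the supplied target sequences, so `MD` tags are not required;
#' unmapped records and records without a stored sequence are skipped (the
#' number skipped is attached as attribute `n_skipped`).
#'
#' @param path SAM file.
#' @param targets named character vector of target sequences.
#' @return alignment data.frame with the same columns as [map_reads()].
#' @export
read_external_alignments <- function(path, targets) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) { skipped <- skipped + 1L; next }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped: not an alignment
    if (f[10] == "*" || !(f[3] %in% names(targets))) {
      skipped <- skipped + 1L
      next
    }
    seq <- toupper(f[10])
    tgt <- targets[[f[3]]]
    start <- as.integer(f[4]) - 1L
    L <- nchar(seq)
    if (start < 0L || start + L > nchar(tgt)) { skipped <- skipped + 1L; next }
    tsub <- substr(tgt, start + 1L, start + L)
    a <- charToRaw(seq)
    b <- charToRaw(tsub)
    mm <- which(a != b | a == charToRaw("N") | b == charToRaw("N")) - 1L
    minus <- bitwAnd(flag, 16L) != 0L
    rows[[i]] <- data.frame(
      read_id = f[1], target = f[3], target_start = start,
      strand = if (minus) "-" else "+",
      n_mismatches = length(mm),
      mismatch_positions = paste(start + mm, collapse = ","),
      read_seq = if (minus) revcomp(seq) else seq,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- empty_alignments()
  attr(out, "n_skipped") <- skipped
  out
}

empty_alignments <- function() {
  data.frame(read_id = character(), target = character(),
             target_start = integer(), strand = character(),
             n_mismatches = integer(), mismatch_positions = character(),
             read_seq = character(), stringsAsFactors = FALSE)
}
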