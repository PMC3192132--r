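## Flank database construction, ungapped read mapping and per-site pileups.
## The matcher is a desk-scale stand-in for a short-read mapper: exhaustive
## ungapped (Hamming) placement search accelerated by exact k-mer seeding,
## guaranteed equivalent to a full scan because the seed length is capped at
## read_length / (max_mismatches + 1).

#' Build the flank database for a set of candidate RDD sites
#'
#' Extracts `flank` bases on each side of every site from the reference
#' genome (99 bp entries at the default flank of 49). Minus-strand sites are
#' reverse-complemented so that the stored entry and its RDD offset are on
#' the transcript strand, carrying the genomic nucleotide A at the offset.
#' Sites where the reference already shows the RDD nucleotide B are diverted
#' to the `reference_mismatch` table (their claim is void); sites where the
#' reference shows neither A nor B are excluded as inconsistent.
#' Sites closer than `flank` to a sequence end get truncated entries with the
#' RDD offset adjusted.
#'
#' @param sites site table (see [read_site_table()]).
#' @param genome named character vector of reference sequences.
#' @param flank flank length in bases on each side (default 49).
#' @return an object of class `FlankDatabase`: list with `entries` (data.frame
#'   with `site_id`, `seq`, `rdd_offset` 0-based, `strand`, `chrom`,
#'   `src_start`/`src_end` 0-based half-open, `genomic_base`, `rdd_base`),
#'   `flank`, `reference_mismatch` and `inconsistent` data.frames.
#' @export
build_flank_db <- function(sites, genome, flank = 49L) {
  sites <- validate_site_table(sites)
  flank <- stopifnot_count(flank, "flank")
  if (!all(sites$chrom %in% names(genome)))
    stop("site table refers to sequences absent from the genome", call. = FALSE)
  slen <- nchar(genome)[sites$chrom]
  if (any(sites$pos < 1L | sites$pos > slen))
    stop("site position outside genome sequence", call. = FALSE)

  lo <- pmax(1L, sites$pos - flank)
  hi <- pmin(slen, sites$pos + flank)
  raw <- substr(genome[sites$chrom], lo, hi)
  off_plus <- sites$pos - lo                       # 0-based offset in raw
  seq <- ifelse(sites$strand == "-", revcomp(raw), raw)
  off <- ifelse(sites$strand == "-", nchar(raw) - 1L - off_plus, off_plus)
  base_at <- substr(seq, off + 1L, off + 1L)       # transcript-strand base

  entries <- data.frame(
    site_id = sites$site_id, seq = seq, rdd_offset = as.integer(off),
    strand = sites$strand, chrom = sites$chrom,
    src_start = lo - 1L, src_end = as.integer(hi),
    genomic_base = sites$genomic_base, rdd_base = sites$rdd_base,
    stringsAsFactors = FALSE)

  is_ref_mm <- base_at == sites$rdd_base
  is_ok <- base_at == sites$genomic_base
  inconsistent <- cbind(sites[!is_ref_mm & !is_ok, , drop = FALSE],
                        reference_base = base_at[!is_ref_mm & !is_ok])
  if (nrow(inconsistent))
    message(nrow(inconsistent),
            " site(s) excluded: reference base matches neither A nor B")
  db <- list(
    entries = entries[is_ok, , drop = FALSE],
    flank = flank,
    reference_mismatch = cbind(sites[is_ref_mm, , drop = FALSE],
                               reference_base = base_at[is_ref_mm]),
    inconsistent = inconsistent)
  class(db) <- "FlankDatabase"
  db
}

#' @export
print.FlankDatabase <- function(x, ...) {
  cat("FlankDatabase:", nrow(x$entries), "entries (flank", x$flank, "bp);",
      nrow(x$reference_mismatch), "reference-mismatch site(s);",
      nrow(x$inconsistent), "inconsistent site(s)\n")
  invisible(x)
}

flank_db_targets <- function(db) {
  setNames(db$entries$seq, db$entries$site_id)
}

#' Site lookup map for pileups
#'
#' Describes where each site's RDD column lies inside each mapping target:
#' for a flank database the target is the site itself; for a transcript
#' database the offsets are computed from the transcript coordinates.
#'
#' @param db a `FlankDatabase`.
#' @return data.frame with `target`, `site_id`, `rdd_offset` (0-based),
#'   `genomic_base`, `rdd_base`.
#' @export
site_map_from_flank_db <- function(db) {
  data.frame(target = db$entries$site_id, site_id = db$entries$site_id,
             rdd_offset = db$entries$rdd_offset,
             genomic_base = db$entries$genomic_base,
             rdd_base = db$entries$rdd_base, stringsAsFactors = FALSE)
}

#' Site lookup map for a transcript database
#'
#' Transcripts are single-exon here, so a genomic site inside a transcript
#' maps to offset `pos - start` (plus strand) or `end - pos` (minus strand),
#' 0-based on the transcript strand.
#'
#' @param sites site table.
#' @param transcripts data.frame with `transcript_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`.
#' @return data.frame as in [site_map_from_flank_db()]; sites not contained
#'   in any transcript are dropped.
#' @export
site_map_from_transcripts <- function(sites, transcripts) {
  sites <- validate_site_table(sites)
  hit <- merge(sites, transcripts, by = "chrom", suffixes = c("", ".tx"))
  hit <- hit[hit$pos >= hit$start & hit$pos <= hit$end &
               hit$strand == hit$strand.tx, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(target = character(), site_id = character(),
                      rdd_offset = integer(), genomic_base = character(),
                      rdd_base = character(), stringsAsFactors = FALSE))
  off <- ifelse(hit$strand == "+", hit$pos - hit$start, hit$end - hit$pos)
  data.frame(target = hit$transcript_id, site_id = hit$site_id,
             rdd_offset = as.integer(off), genomic_base = hit$genomic_base,
             rdd_base = hit$rdd_base, stringsAsFactors = FALSE)
}

#' Map reads against a target database (ungapped)
#'
#' Searches each read and its reverse complement against every fully
#' contained offset of every target and reports the minimum-Hamming-distance
#' placement when the distance is at most `max_mismatches`. A minimum
#' achieved in more than one distinct target makes the read ambiguous and it
#' is discarded; ties within one target resolve to the leftmost placement,
#' then to the forward orientation. N bases count as mismatches.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param targets named character vector of target sequences, or a
#'   `FlankDatabase`.
#' @param max_mismatches maximum Hamming distance (2 for the RNA criteria,
#'   5 for the genomic-read screen).
#' @param seed_k requested seed k-mer length (default 16); internally capped
#'   at `read length / (max_mismatches + 1)` so the seeded search stays
#'   exactly equivalent to the exhaustive scan.
#' @return data.frame with `read_id`, `target`, `target_start` (0-based),
#'   `strand`, `n_mismatches`, `mismatch_positions` (comma-joined 0-based
#'   target offsets), `read_seq` (original orientation).
#' @export
map_reads <- function(reads, targets, max_mismatches, seed_k = 16L) {
  if (inherits(targets, "FlankDatabase")) targets <- flank_db_targets(targets)
  if (length(targets) == 0) stop("empty target database", call. = FALSE)
  if (length(reads) == 0) return(empty_alignments())
  if (max(nchar(reads)) > max(nchar(targets)))
    stop("reads longer than every target", call. = FALSE)
  hits <- cpp_map_reads(toupper(as.character(reads)),
                        toupper(as.character(targets)),
                        as.integer(max_mismatches), as.integer(seed_k))
  ids <- names(reads) %||% as.character(seq_along(reads))
  data.frame(read_id = ids[hits$read],
             target = names(targets)[hits$target],
             target_start = hits$start, strand = hits$strand,
             n_mismatches = hits$n_mismatches,
             mismatch_positions = hits$mismatch_positions,
             read_seq = toupper(as.character(reads))[hits$read],
             stringsAsFactors = FALSE)
}

#' Filter genomic alignments by non-RDD mismatch count
#'
#' Against the flank database, a genomic read is kept only if it has at most
#' one mismatch other than a mismatch falling exactly at the RDD column of
#' its target (a read showing the RDD nucleotide B mismatches the entry, which
#' stores the genomic nucleotide A, at that column -- that mismatch is free).
#'
#' @param alignments alignment data.frame from [map_reads()] against a
#'   `FlankDatabase`.
#' @param db the `FlankDatabase` the alignments were produced against.
#' @return the retained subset of `alignments`.
#' @export
filter_genomic_alignments <- function(alignments, db) {
  if (!nrow(alignments)) return(alignments)
  off <- setNames(db$entries$rdd_offset, db$entries$site_id)
  rdd_off <- off[alignments$target]
  mm <- strsplit(alignments$mismatch_positions, ",", fixed = TRUE)
  at_rdd <- mapply(function(m, o) !is.na(o) && any(m != "" & as.integer(m) == o),
                   mm, rdd_off)
  keep <- (alignments$n_mismatches - as.integer(at_rdd)) <= 1L
  alignments[keep, , drop = FALSE]
}

#' Build per-site, per-individual nucleotide pileups
#'
#' Counts, at each site's RDD column, the read base of every alignment that
#' covers the column. RNA-side mapping caps alignments at `max_mismatches`
#' (2 in the published criteria); the genomic side is instead pre-filtered
#' with [filter_genomic_alignments()], so the cap defaults to `Inf`.
#'
#' @param alignments alignment data.frame.
#' @param site_map data.frame from [site_map_from_flank_db()] or
#'   [site_map_from_transcripts()].
#' @param individuals character vector, one per alignment row, labelling the
#'   individual each read came from; a single value is recycled.
#' @param source `"RNA"` or `"DNA"` (recorded in the output).
#' @param max_mismatches drop alignments exceeding this mismatch count.
#' @return data.frame with one row per (site, individual) observed: counts
#'   per nucleotide (`count_A` ... `count_N`), derived `n_A` (genomic
#'   nucleotide), `n_B` (RDD nucleotide), `n_other` and `total`.
#' @export
pileup <- function(alignments, site_map, individuals, source = "RNA",
                   max_mismatches = Inf) {
  stopifnot(source %in% c("RNA", "DNA"))
  if (length(individuals) == 1L)
    individuals <- rep(individuals, nrow(alignments))
  stopifnot(length(individuals) == nrow(alignments))
  keep <- alignments$n_mismatches <= max_mismatches
  aln <- alignments[keep, , drop = FALSE]
  ind <- individuals[keep]
  if (!nrow(aln) || !nrow(site_map)) return(empty_pileup())
  aln$individual <- ind
  x <- merge(aln, site_map, by = "target")
  L <- nchar(x$read_seq)
  covers <- x$target_start <= x$rdd_offset &
    x$rdd_offset < x$target_start + L
  x <- x[covers, , drop = FALSE]
  if (!nrow(x)) return(empty_pileup())
  q0 <- x$rdd_offset - x$target_start
  base <- ifelse(x$strand == "+",
                 substr(x$read_seq, q0 + 1L, q0 + 1L),
                 comp_base(substr(x$read_seq, nchar(x$read_seq) - q0,
                                  nchar(x$read_seq) - q0)))
  base[!base %in% DNA_BASES] <- "N"
  key <- paste(x$site_id, x$individual, sep = "\r")
  tab <- table(key, factor(base, levels = c(DNA_BASES, "N")))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(site_id = parts[, 1], individual = parts[, 2],
                    source = source,
                    count_A = as.integer(tab[, "A"]),
                    count_C = as.integer(tab[, "C"]),
                    count_G = as.integer(tab[, "G"]),
                    count_T = as.integer(tab[, "T"]),
                    count_N = as.integer(tab[, "N"]),
                    stringsAsFactors = FALSE)
  ab <- site_map[match(out$site_id, site_map$site_id), ]
  finish_pileup(out, ab$genomic_base, ab$rdd_base)
}

finish_pileup <- function(out, genomic_base, rdd_base) {
  counts <- as.matrix(out[, paste0("count_", c(DNA_BASES, "N"))])
  pick <- function(b) {
    i <- match(b, c(DNA_BASES, "N"))
    counts[cbind(seq_len(nrow(counts)), i)]
  }
  out$n_A <- as.integer(pick(genomic_base))
  out$n_B <- as.integer(pick(rdd_base))
  out$total <- as.integer(rowSums(counts))
  out$n_other <- out$total - out$n_A - out$n_B
  out
}

empty_pileup <- function() {
  data.frame(site_id = character(), individual = character(),
             source = character(), count_A = integer(), count_C = integer(),
             count_G = integer(), count_T = integer(), count_N = integer(),
             n_A = integer(), n_B = integer(), total = integer(),
             n_other = integer(), stringsAsFactors = FALSE)
}

#' Write / read pileup tables
#'
#' @param pileups pileup data.frame.
#' @param path TSV path.
#' @return invisibly `path`, or the data.frame for the reader.
#' @export
write_pileup <- function(pileups, path) write_tsv(pileups, path)

#' @rdname write_pileup
#' @export
read_pileup <- function(path) read_tsv(path)
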