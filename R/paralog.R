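## Reference-genome paralog screen: search every site's flank entry against
## the genome (both strands, ungapped), keep hits longer than the RNA read
## length with identity strictly above 90%, and ask whether the aligned base
## at the RDD column is the RDD nucleotide B.

#' Search flank entries against the reference genome
#'
#' Desk-scale stand-in for a BLAT search: every full-length ungapped window
#' of each flank query is scored on both strands of the genome (seeded k-mer
#' search, exactly equivalent to an exhaustive Hamming scan). A window is a
#' hit when its identity is strictly greater than `min_identity` and the
#' query is at least `min_length` long; the window identical in coordinates
#' to the query's own locus is excluded.
#'
#' @param db a `FlankDatabase`.
#' @param genome named character vector of reference sequences.
#' @param min_identity identity threshold, strict (default 0.9).
#' @param min_length minimum hit length in bases (default 50, the RNA read
#'   length whose mismapping the screen models).
#' @param seed_k requested seed length (capped internally for exactness).
#' @return data.frame of paralog hits: `site_id`, `chrom`, `start`/`end`
#'   (0-based half-open), `strand`, `aligned_length`, `identity`,
#'   `covers_rdd_column`, `base_at_rdd_column` (query orientation),
#'   `rdd_col_pos` (1-based plus-strand genomic position of the aligned RDD
#'   column), `classification` (`matching_B` / `non_matching`).
#' @export
search_flanks <- function(db, genome, min_identity = 0.9, min_length = 50L,
                          seed_k = 16L) {
  ent <- db$entries
  keep <- nchar(ent$seq) >= min_length
  ent <- ent[keep, , drop = FALSE]
  if (!nrow(ent)) return(empty_paralog_hits())
  L <- nchar(ent$seq)
  max_mm <- max_mm_for_identity(max(L), min_identity)
  hits <- cpp_hamming_all(ent$seq, unname(genome), as.integer(max_mm),
                          as.integer(seed_k))
  if (!nrow(hits)) return(empty_paralog_hits())
  qi <- hits$query
  hl <- L[qi]
  ok_id <- (hl - hits$n_mismatches) * 1e6 > round(min_identity * 1e6) * hl
  hits <- hits[ok_id, , drop = FALSE]
  qi <- hits$query
  if (!nrow(hits)) return(empty_paralog_hits())

  chrom <- names(genome)[hits$target]
  self <- chrom == ent$chrom[qi] & hits$start == ent$src_start[qi] &
    hits$strand == ent$strand[qi]
  hits <- hits[!self, , drop = FALSE]
  qi <- hits$query
  if (!nrow(hits)) return(empty_paralog_hits())

  chrom <- names(genome)[hits$target]
  hl <- L[qi]
  off <- ent$rdd_offset[qi]
  col_pos <- ifelse(hits$strand == "+",
                    hits$start + off + 1L,
                    hits$start + (hl - 1L - off) + 1L)
  raw_base <- substr(genome[chrom], col_pos, col_pos)
  base <- ifelse(hits$strand == "+", raw_base, comp_base(raw_base))
  data.frame(
    site_id = ent$site_id[qi], chrom = chrom, start = hits$start,
    end = hits$start + hl, strand = hits$strand,
    aligned_length = hl,
    identity = (hl - hits$n_mismatches) / hl,
    covers_rdd_column = TRUE,
    base_at_rdd_column = base,
    rdd_col_pos = as.integer(col_pos),
    classification = ifelse(base == ent$rdd_base[qi], "matching_B",
                            "non_matching"),
    stringsAsFactors = FALSE)
}

# Largest mismatch count whose identity stays strictly above the threshold.
max_mm_for_identity <- function(L, min_identity) {
  mm <- 0L
  while ((L - mm - 1) * 1e6 > round(min_identity * 1e6) * L) mm <- mm + 1L
  mm
}

empty_paralog_hits <- function() {
  data.frame(site_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), aligned_length = integer(),
             identity = numeric(), covers_rdd_column = logical(),
             base_at_rdd_column = character(), rdd_col_pos = integer(),
             classification = character(), stringsAsFactors = FALSE)
}

#' Classify sites by paralog status
#'
#' Precedence: a site on the reference-mismatch list is `reference_mismatch`
#' regardless of hits; otherwise one hit carrying the RDD nucleotide makes it
#' `has_matching_paralog`; otherwise any RDD-column-spanning hit makes it
#' `has_nonmatching_paralog_only`; otherwise `no_paralog`. Hits that do not
#' span the RDD column (possible with imported BLAT/BLAST alignments)
#' contribute to no category.
#'
#' @param site_ids character vector of site ids to classify.
#' @param hits paralog hit data.frame from [search_flanks()] or a reader.
#' @param reference_mismatch_ids site ids whose reference base already shows
#'   the RDD nucleotide.
#' @return data.frame `site_id`, `paralog_status`.
#' @export
classify_sites <- function(site_ids, hits, reference_mismatch_ids = character()) {
  spanning <- hits[hits$covers_rdd_column, , drop = FALSE]
  matching <- unique(spanning$site_id[spanning$classification == "matching_B"])
  nonmatch <- unique(spanning$site_id[spanning$classification == "non_matching"])
  status <- rep("no_paralog", length(site_ids))
  status[site_ids %in% nonmatch] <- "has_nonmatching_paralog_only"
  status[site_ids %in% matching] <- "has_matching_paralog"
  status[site_ids %in% reference_mismatch_ids] <- "reference_mismatch"
  data.frame(site_id = site_ids, paralog_status = status,
             stringsAsFactors = FALSE)
}

#' Annotate paralog hits against gene / transcribed-region intervals
#'
#' A hit lies in a gene (or transcribed region) when the genomic position of
#' its aligned RDD column falls inside any interval.
#'
#' @param hits paralog hit data.frame.
#' @param genes `GRanges` of annotated genes (e.g. from [read_bed()]).
#' @param transcribed `GRanges` of transcribed regions.
#' @return list with `hits` (input plus logical `in_gene`, `in_transcribed`)
#'   and `summary` (per classification: count and fractions in genes and
#'   transcribed regions).
#' @export
annotate_hits <- function(hits, genes, transcribed) {
  pos <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$rdd_col_pos,
                                                 hits$rdd_col_pos))
  hits$in_gene <- GenomicRanges::countOverlaps(pos, genes) > 0
  hits$in_transcribed <- GenomicRanges::countOverlaps(pos, transcribed) > 0
  grp <- split(hits, hits$classification)
  summary <- do.call(rbind, lapply(names(grp), function(g) {
    h <- grp[[g]]
    data.frame(classification = g, n = nrow(h),
               n_in_gene = sum(h$in_gene),
               frac_in_gene = if (nrow(h)) mean(h$in_gene) else 0,
               n_in_transcribed = sum(h$in_transcribed),
               frac_in_transcribed = if (nrow(h)) mean(h$in_transcribed) else 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(classification = character(), n = integer(),
                          n_in_gene = integer(), frac_in_gene = numeric(),
                          n_in_transcribed = integer(),
                          frac_in_transcribed = numeric(),
                          stringsAsFactors = FALSE)
  list(hits = hits, summary = summary)
}

#' Import BLAT PSL hits as paralog hits
#'
#' Minimal PSL dialect: tab-separated 21-column rows (header lines are
#' skipped), single-block ungapped hits only (multi-block rows are dropped
#' with a message). For minus-strand rows the query offsets are taken in
#' query-forward coordinates with the target interval forward, the
#' convention produced by [search_flanks()] round-trips.
#'
#' @param path PSL file.
#' @param db the `FlankDatabase` whose entries were the queries.
#' @param genome named character vector of reference sequences.
#' @return paralog hit data.frame (see [search_flanks()]).
#' @export
read_psl <- function(path, db, genome) {
  lines <- readLines(path)
  lines <- lines[grepl("^[0-9]", lines)]
  if (!length(lines)) return(empty_paralog_hits())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  n_blocks <- as.integer(f[, 18])
  if (any(n_blocks != 1L))
    message(sum(n_blocks != 1L), " multi-block PSL row(s) dropped")
  f <- f[n_blocks == 1L, , drop = FALSE]
  if (!nrow(f)) return(empty_paralog_hits())
  hit_from_coords(
    site_id = f[, 10], chrom = f[, 14],
    t_start = as.integer(f[, 16]), t_end = as.integer(f[, 17]),
    strand = f[, 9],
    q_start = as.integer(f[, 12]), q_end = as.integer(f[, 13]),
    n_match = as.integer(f[, 1]) + as.integer(f[, 3]),
    aligned = as.integer(f[, 1]) + as.integer(f[, 2]) +
      as.integer(f[, 3]) + as.integer(f[, 4]),
    db = db, genome = genome)
}

#' Import BLAST tabular (outfmt 6) hits as paralog hits
#'
#' Standard 12 columns; gapped rows (`gapopen > 0`) are dropped with a
#' message since the screen's semantics are ungapped.
#'
#' @inheritParams read_psl
#' @return paralog hit data.frame.
#' @export
read_blast6 <- function(path, db, genome) {
  f <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(f)) return(empty_paralog_hits())
  gapped <- f[[6]] > 0
  if (any(gapped)) message(sum(gapped), " gapped BLAST row(s) dropped")
  f <- f[!gapped, , drop = FALSE]
  if (!nrow(f)) return(empty_paralog_hits())
  minus <- f[[10]] < f[[9]]
  hit_from_coords(
    site_id = as.character(f[[1]]), chrom = as.character(f[[2]]),
    t_start = ifelse(minus, f[[10]], f[[9]]) - 1L,
    t_end = ifelse(minus, f[[9]], f[[10]]),
    strand = ifelse(minus, "-", "+"),
    q_start = f[[7]] - 1L, q_end = f[[8]],
    n_match = as.integer(round(f[[3]] / 100 * f[[4]])),
    aligned = as.integer(f[[4]]),
    db = db, genome = genome)
}

# Shared back half of the external-alignment readers: q_start/q_end are
# 0-based half-open in query-forward coordinates; t interval is forward.
hit_from_coords <- function(site_id, chrom, t_start, t_end, strand,
                            q_start, q_end, n_match, aligned, db, genome) {
  ent <- db$entries[match(site_id, db$entries$site_id), , drop = FALSE]
  off <- ent$rdd_offset
  covers <- !is.na(off) & q_start <= off & off < q_end
  col_pos <- rep(NA_integer_, length(site_id))
  p <- ifelse(strand == "+",
              t_start + (off - q_start) + 1L,
              t_start + (q_end - 1L - off) + 1L)
  col_pos[covers] <- as.integer(p[covers])
  raw_base <- rep(NA_character_, length(site_id))
  valid <- covers & chrom %in% names(genome)
  raw_base[valid] <- substr(genome[chrom[valid]], col_pos[valid],
                            col_pos[valid])
  base <- ifelse(strand == "+", raw_base, comp_base(raw_base))
  data.frame(
    site_id = site_id, chrom = chrom, start = t_start, end = t_end,
    strand = strand, aligned_length = aligned,
    identity = n_match / aligned,
    covers_rdd_column = covers,
    base_at_rdd_column = base,
    rdd_col_pos = col_pos,
    classification = ifelse(covers & !is.na(base) & base == ent$rdd_base,
                            "matching_B", "non_matching"),
    stringsAsFactors = FALSE)
}
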