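## Synthetic cohort generator. Plants, with known ground truth, the three
## sources of spurious RDD calls -- reference-genome paralogs diverging at
## one "trap" position, reference paralogs whose trap difference segregates
## as a SNP in the cohort, and segregating duplications absent from the
## reference -- plus genuine editing events, and simulates RNA and DNA short
## reads per diploid individual.

#' Simulation configuration
#'
#' Returns a validated configuration list. Every planted confounder forces a
#' single-nucleotide difference between the expressed paralog/variant and
#' the annotated gene at exactly one transcript position (the "trap"), so
#' the truth table is unambiguous; background divergence is added elsewhere
#' at `paralog_divergence` per site.
#'
#' @param genome_length reference length in bases (one sequence).
#' @param n_genes number of annotated single-exon genes.
#' @param gene_length transcript length in bases.
#' @param paralog_fraction fraction of genes given a reference-genome
#'   paralog.
#' @param paralog_divergence per-site substitution probability between the
#'   two copies (away from the trap).
#' @param paralog_pad bases of flanking sequence on each side of a gene
#'   that belong to the duplicated block (default 60, comfortably more
#'   than the 49-bp screen flank: segmental duplications copy flanking
#'   sequence along with the gene, which is what lets a full flank window
#'   align to the paralog).
#' @param polymorphic_fraction fraction of the paralog-bearing genes whose
#'   trap difference is not fixed in the reference but segregates as a SNP
#'   (the reference paralog then shows the genomic nucleotide; only SNP
#'   carriers harbor the RDD nucleotide).
#' @param snp_allele_freq allele frequency of that segregating trap SNP.
#' @param n_individuals cohort size (the audited study sampled 27).
#' @param cnv_fraction fraction of genes carrying a segregating duplication
#'   absent from the reference.
#' @param cnv_allele_freq allele frequency of the duplication; a diploid
#'   individual carries it with probability `1 - (1 - f)^2`.
#' @param snp_rate per-site heterozygosity of background private SNPs per
#'   individual (human-scale default 1e-3).
#' @param n_true_edits number of genuine editing sites.
#' @param edit_fraction fraction of transcripts edited at a true site.
#' @param edit_type `"A>G"` (ADAR-like, default) or `"random"`.
#' @param paralog_transcribed are paralogs (and duplication copies)
#'   transcribed? Transcription of the confounder is what creates the
#'   spurious RNA signal.
#' @param rna_read_length,dna_read_length read lengths in bases.
#' @param rna_depth,dna_depth mean fold-coverage of the transcriptome /
#'   genome per individual.
#' @param error_rate per-base sequencing error probability.
#' @param seed master random seed.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(genome_length = 1e6, n_genes = 250L,
                       gene_length = 300L, paralog_fraction = 0.4,
                       paralog_divergence = 0.02, paralog_pad = 60L,
                       polymorphic_fraction = 0.25, snp_allele_freq = 0.3,
                       n_individuals = 27L, cnv_fraction = 0.1,
                       cnv_allele_freq = 0.3, snp_rate = 0.001,
                       n_true_edits = 50L, edit_fraction = 0.3,
                       edit_type = c("A>G", "random"),
                       paralog_transcribed = TRUE,
                       rna_read_length = 50L, dna_read_length = 50L,
                       rna_depth = 30, dna_depth = 20,
                       error_rate = 0.005, seed = 1L) {
  edit_type <- match.arg(edit_type)
  cfg <- list(
    genome_length = stopifnot_count(genome_length, "genome_length"),
    n_genes = stopifnot_count(n_genes, "n_genes"),
    gene_length = stopifnot_count(gene_length, "gene_length"),
    paralog_fraction = stopifnot_fraction(paralog_fraction,
                                          "paralog_fraction"),
    paralog_divergence = stopifnot_fraction(paralog_divergence,
                                            "paralog_divergence"),
    paralog_pad = stopifnot_count(paralog_pad, "paralog_pad",
                                  positive = FALSE),
    polymorphic_fraction = stopifnot_fraction(polymorphic_fraction,
                                              "polymorphic_fraction"),
    snp_allele_freq = stopifnot_fraction(snp_allele_freq, "snp_allele_freq"),
    n_individuals = stopifnot_count(n_individuals, "n_individuals"),
    cnv_fraction = stopifnot_fraction(cnv_fraction, "cnv_fraction"),
    cnv_allele_freq = stopifnot_fraction(cnv_allele_freq, "cnv_allele_freq"),
    snp_rate = stopifnot_fraction(snp_rate, "snp_rate"),
    n_true_edits = stopifnot_count(n_true_edits, "n_true_edits",
                                   positive = FALSE),
    edit_fraction = stopifnot_fraction(edit_fraction, "edit_fraction"),
    edit_type = edit_type,
    paralog_transcribed = isTRUE(paralog_transcribed),
    rna_read_length = stopifnot_count(rna_read_length, "rna_read_length"),
    dna_read_length = stopifnot_count(dna_read_length, "dna_read_length"),
    rna_depth = rna_depth, dna_depth = dna_depth,
    error_rate = stopifnot_fraction(error_rate, "error_rate"),
    seed = stopifnot_count(seed, "seed", positive = FALSE))
  if (cfg$rna_read_length > cfg$gene_length)
    stop("rna_read_length must not exceed the transcript length",
         call. = FALSE)
  cfg$n_paralog <- as.integer(round(cfg$paralog_fraction * cfg$n_genes))
  cfg$n_cnv <- as.integer(round(cfg$cnv_fraction * cfg$n_genes))
  if (cfg$n_paralog + cfg$n_cnv + cfg$n_true_edits > cfg$n_genes)
    stop("not enough genes for the requested paralog, CNV and edit counts",
         call. = FALSE)
  if ((cfg$n_genes + cfg$n_paralog) *
      (cfg$gene_length + 2 * cfg$paralog_pad) > 0.9 * cfg$genome_length)
    stop("genome too small to place the requested genes without overlap",
         call. = FALSE)
  class(cfg) <- c("SimConfig", "list")
  cfg
}

extract_tx <- function(seqstr, start, end, strand) {
  s <- substr(seqstr, start, end)
  if (strand == "-") revcomp(s) else s
}

# Substitute bases at 1-based positions of one sequence string.
apply_variants <- function(seqstr, pos, alt) {
  if (!length(pos)) return(seqstr)
  r <- charToRaw(seqstr)
  r[pos] <- charToRaw(paste(alt, collapse = ""))
  rawToChar(r)
}

# Per-site substitutions at `rate`, sparing `exclude` (1-based positions);
# returns the mutated sequence.
mutate_seq <- function(seqstr, rate, exclude = integer()) {
  n <- nchar(seqstr)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, exclude)
  if (!length(hit)) return(seqstr)
  cur <- substring(seqstr, hit, hit)
  alt <- other_base(cur)
  apply_variants(seqstr, hit, alt)
}

# A uniformly chosen base different from each element of `cur`.
other_base <- function(cur) {
  i <- match(cur, DNA_BASES)
  shift <- sample.int(3L, length(cur), replace = TRUE)
  DNA_BASES[((i - 1L + shift) %% 4L) + 1L]
}

#' Simulate a cohort with planted confounders and ground truth
#'
#' @param config a `SimConfig` from [sim_config()].
#' @return a list of class `SimCohort` with elements `config`, `genome`
#'   (named character), `genes` (data.frame: `gene_id`, `chrom`, `start`,
#'   `end` 1-based, `strand`, `role`), `transcripts` (annotated mapping
#'   database: data.frame plus `seq`), `paralogs` (data.frame of
#'   reference-paralog loci), `sites` (candidate-RDD site table), `truth`
#'   (data.frame `site_id`, `cause`, `donor_locus`, `carriers`),
#'   `annotation` (list of interval data.frames `genes`, `transcribed`,
#'   `duplications`), `individuals` (per-individual genotype list) and
#'   `cnv_copies` (duplication copy sequences).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  chrom <- "chrS"
  genome <- random_dna(cfg$genome_length)
  gl <- cfg$gene_length
  pad <- cfg$paralog_pad
  slot_len <- gl + 2L * pad
  n_units <- cfg$n_genes + cfg$n_paralog

  # uniform non-overlapping placement of equal slots: sort n starts in the
  # shrunk genome, then re-inflate by one slot length per preceding slot.
  # Genes sit in the middle of their slot so that `pad` bases of flanking
  # sequence on each side belong to the locus (and are copied along when
  # the locus is duplicated, as in real segmental duplications).
  raw_starts <- sort(sample.int(cfg$genome_length - n_units * slot_len,
                                n_units))
  starts <- raw_starts + (seq_len(n_units) - 1L) * slot_len
  strands <- sample(c("+", "-"), n_units, replace = TRUE)

  unit_order <- sample.int(n_units)
  gene_units <- unit_order[seq_len(cfg$n_genes)]
  par_units <- unit_order[cfg$n_genes + seq_len(cfg$n_paralog)]

  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  genes <- data.frame(
    gene_id = ids, chrom = chrom,
    start = starts[gene_units] + pad,
    end = starts[gene_units] + pad + gl - 1L,
    strand = strands[gene_units], role = "plain",
    stringsAsFactors = FALSE)

  # roles: paralog-bearing genes first (split fixed / polymorphic), then
  # CNV genes, then true-edit genes
  ord <- sample.int(cfg$n_genes)
  i_par <- ord[seq_len(cfg$n_paralog)]
  n_poly <- round(cfg$polymorphic_fraction * cfg$n_paralog)
  i_poly <- if (n_poly > 0) i_par[seq_len(n_poly)] else integer()
  i_fixed <- setdiff(i_par, i_poly)
  i_cnv <- ord[cfg$n_paralog + seq_len(cfg$n_cnv)]
  i_edit <- ord[cfg$n_paralog + cfg$n_cnv + seq_len(cfg$n_true_edits)]
  genes$role[i_fixed] <- "ref_paralog"
  genes$role[i_poly] <- "polymorphic_paralog"
  genes$role[i_cnv] <- "cnv_paralog"
  genes$role[i_edit] <- "true_edit"

  # trap / edit offsets, interior so reads can cover them
  margin <- min(25L, max(1L, gl %/% 4L))
  trap <- sample(seq.int(margin, gl - margin + 1L), cfg$n_genes,
                 replace = TRUE)

  # force the edited base to A for A>G editing (transcript strand)
  if (cfg$edit_type == "A>G" && length(i_edit)) {
    for (i in i_edit) {
      pos_g <- tx_to_genomic(genes$start[i], genes$end[i], genes$strand[i],
                             trap[i])
      base <- if (genes$strand[i] == "+") "A" else "T"
      genome <- apply_variants(genome, pos_g, base)
    }
  }

  gene_seq <- vapply(seq_len(cfg$n_genes), function(i)
    extract_tx(genome, genes$start[i], genes$end[i], genes$strand[i]),
    character(1))

  # build paralog copies and write them into the reference
  paralogs <- data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
  par_seq <- list()
  site_rows <- list()
  truth_rows <- list()
  ind_ids <- sprintf("ind%02d", seq_len(cfg$n_individuals))
  individuals <- lapply(ind_ids, function(i)
    list(id = i, snps = NULL, paralog_snps = NULL, cnv = NULL))
  names(individuals) <- ind_ids
  poly_snp_rows <- list()
  cnv_rows <- list()
  cnv_copies <- list()

  par_slot <- 0L
  for (i in sort(c(i_fixed, i_poly))) {
    par_slot <- par_slot + 1L
    u <- par_units[par_slot]
    t <- trap[i]
    A <- substring(gene_seq[i], t, t)
    B <- other_base(A)
    # the duplicated block is the gene plus `pad` bases of flanking
    # sequence on each side, in transcript orientation; background
    # divergence applies to the whole block, sparing the trap
    block <- extract_tx(genome, genes$start[i] - pad, genes$end[i] + pad,
                        genes$strand[i])
    bseq <- mutate_seq(block, cfg$paralog_divergence, exclude = pad + t)
    fixed <- i %in% i_fixed
    # fixed paralog: reference copy carries B at the trap; polymorphic:
    # reference copy keeps A, the B allele segregates in the cohort
    bseq <- apply_variants(bseq, pad + t, if (fixed) B else A)
    ps_slot <- starts[u]
    pstrand <- strands[u]
    genome <- apply_variants(
      genome, ps_slot:(ps_slot + slot_len - 1L),
      strsplit(if (pstrand == "-") revcomp(bseq) else bseq, "")[[1]])
    ps <- ps_slot + pad; pe <- ps + gl - 1L   # transcribed portion
    paralogs <- rbind(paralogs, data.frame(
      gene_id = ids[i], chrom = chrom, start = ps, end = pe,
      strand = pstrand, stringsAsFactors = FALSE))
    par_seq[[ids[i]]] <- substr(bseq, pad + 1L, pad + gl)
    donor_pos <- tx_to_genomic(ps, pe, pstrand, t)
    site_pos <- tx_to_genomic(genes$start[i], genes$end[i], genes$strand[i],
                              t)
    sid <- sprintf("site_%s", ids[i])
    site_rows[[sid]] <- data.frame(
      site_id = sid, chrom = chrom, pos = site_pos,
      strand = genes$strand[i], genomic_base = A, rdd_base = B,
      gene_id = ids[i], stringsAsFactors = FALSE)
    if (fixed) {
      truth_rows[[sid]] <- data.frame(
        site_id = sid, cause = "ref_paralog",
        donor_locus = sprintf("%s:%d", chrom, donor_pos),
        carriers = paste(ind_ids, collapse = ","), stringsAsFactors = FALSE)
    } else {
      g <- rbinom(cfg$n_individuals, 2L, cfg$snp_allele_freq)
      if (all(g == 0)) g[sample.int(cfg$n_individuals, 1L)] <- 1L
      carriers <- ind_ids[g > 0]
      alt_plus <- if (pstrand == "-") comp_base(B) else B
      poly_snp_rows[[sid]] <- data.frame(
        gene_id = ids[i], site_id = sid, pos = donor_pos,
        alt_plus = alt_plus,
        n_alleles = g, individual = ind_ids, stringsAsFactors = FALSE)
      truth_rows[[sid]] <- data.frame(
        site_id = sid, cause = "polymorphic_paralog",
        donor_locus = sprintf("%s:%d", chrom, donor_pos),
        carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  # segregating duplications absent from the reference
  for (i in i_cnv) {
    t <- trap[i]
    A <- substring(gene_seq[i], t, t)
    B <- other_base(A)
    cseq <- mutate_seq(gene_seq[i], cfg$paralog_divergence, exclude = t)
    cseq <- apply_variants(cseq, t, B)
    cnv_copies[[ids[i]]] <- cseq
    g <- rbinom(cfg$n_individuals, 2L, cfg$cnv_allele_freq)
    if (all(g == 0)) g[sample.int(cfg$n_individuals, 1L)] <- 1L
    carriers <- ind_ids[g > 0]
    site_pos <- tx_to_genomic(genes$start[i], genes$end[i], genes$strand[i],
                              t)
    sid <- sprintf("site_%s", ids[i])
    site_rows[[sid]] <- data.frame(
      site_id = sid, chrom = chrom, pos = site_pos,
      strand = genes$strand[i], genomic_base = A, rdd_base = B,
      gene_id = ids[i], stringsAsFactors = FALSE)
    cnv_rows[[sid]] <- data.frame(
      gene_id = ids[i], n_alleles = g, individual = ind_ids,
      stringsAsFactors = FALSE)
    truth_rows[[sid]] <- data.frame(
      site_id = sid, cause = "cnv_paralog",
      donor_locus = sprintf("dupcopy:%s:%d", ids[i], t),
      carriers = paste(carriers, collapse = ","), stringsAsFactors = FALSE)
  }

  # genuine editing events
  edits <- data.frame(gene_id = character(), offset = integer(),
                      edit_base = character(), stringsAsFactors = FALSE)
  for (i in i_edit) {
    t <- trap[i]
    A <- substring(gene_seq[i], t, t)
    B <- if (cfg$edit_type == "A>G") "G" else other_base(A)
    site_pos <- tx_to_genomic(genes$start[i], genes$end[i], genes$strand[i],
                              t)
    sid <- sprintf("site_%s", ids[i])
    site_rows[[sid]] <- data.frame(
      site_id = sid, chrom = chrom, pos = site_pos,
      strand = genes$strand[i], genomic_base = A, rdd_base = B,
      gene_id = ids[i], stringsAsFactors = FALSE)
    truth_rows[[sid]] <- data.frame(
      site_id = sid, cause = "true_edit", donor_locus = NA_character_,
      carriers = paste(ind_ids, collapse = ","), stringsAsFactors = FALSE)
    edits <- rbind(edits, data.frame(gene_id = ids[i], offset = t,
                                     edit_base = B, stringsAsFactors = FALSE))
  }

  # background private SNPs, heterozygous, one haplotype each
  for (ind in ind_ids) {
    n_snp <- rbinom(1L, cfg$genome_length, cfg$snp_rate)
    if (n_snp > 0) {
      pos <- sort(sample.int(cfg$genome_length, n_snp))
      cur <- substring(genome, pos, pos)
      individuals[[ind]]$snps <- data.frame(
        pos = pos, alt_plus = other_base(cur),
        hap = sample(c(1L, 2L), n_snp, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      individuals[[ind]]$snps <- data.frame(pos = integer(),
                                            alt_plus = character(),
                                            hap = integer(),
                                            stringsAsFactors = FALSE)
    }
  }
  poly_snps <- do.call(rbind, poly_snp_rows)
  cnv_geno <- do.call(rbind, cnv_rows)
  for (ind in ind_ids) {
    individuals[[ind]]$paralog_snps <-
      if (!is.null(poly_snps))
        poly_snps[poly_snps$individual == ind & poly_snps$n_alleles > 0, ,
                  drop = FALSE]
      else NULL
    individuals[[ind]]$cnv <-
      if (!is.null(cnv_geno))
        cnv_geno[cnv_geno$individual == ind & cnv_geno$n_alleles > 0, ,
                 drop = FALSE]
      else NULL
  }

  sites <- do.call(rbind, site_rows) %||%
    data.frame(site_id = character(), chrom = character(), pos = integer(),
               strand = character(), genomic_base = character(),
               rdd_base = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_rows) %||%
    data.frame(site_id = character(), cause = character(),
               donor_locus = character(), carriers = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- rownames(truth) <- NULL

  # re-extract gene transcripts from the final reference (paralog insertion
  # never touches gene slots, but keep one source of truth)
  tx_seq <- vapply(seq_len(cfg$n_genes), function(i)
    extract_tx(genome, genes$start[i], genes$end[i], genes$strand[i]),
    character(1))
  transcripts <- data.frame(
    transcript_id = paste0("tx_", ids), gene_id = ids, chrom = chrom,
    start = genes$start, end = genes$end, strand = genes$strand,
    stringsAsFactors = FALSE)
  transcripts$seq <- tx_seq

  annotation <- list(
    genes = data.frame(chrom = chrom, start = genes$start, end = genes$end,
                       name = ids, stringsAsFactors = FALSE),
    transcribed = data.frame(
      chrom = chrom,
      start = c(genes$start, if (cfg$paralog_transcribed) paralogs$start),
      end = c(genes$end, if (cfg$paralog_transcribed) paralogs$end),
      name = c(ids, if (cfg$paralog_transcribed)
        sprintf("%s_par", paralogs$gene_id)),
      stringsAsFactors = FALSE),
    duplications = data.frame(
      chrom = rep(chrom, length(i_cnv)),
      start = genes$start[i_cnv], end = genes$end[i_cnv],
      name = sprintf("%s_dup", ids[i_cnv]), stringsAsFactors = FALSE))

  cohort <- list(config = cfg, genome = setNames(genome, chrom),
                 genes = genes, transcripts = transcripts,
                 paralogs = paralogs, paralog_seq = par_seq,
                 sites = sites, truth = truth, edits = edits,
                 annotation = annotation, individuals = individuals,
                 cnv_copies = cnv_copies)
  class(cohort) <- "SimCohort"
  cohort
}

# 1-based transcript offset -> 1-based genomic (plus-strand) position.
tx_to_genomic <- function(start, end, strand, offset) {
  if (strand == "+") start + offset - 1L else end - offset + 1L
}

#' @export
print.SimCohort <- function(x, ...) {
  cat("SimCohort:", nchar(x$genome), "bp genome,", nrow(x$genes), "genes,",
      nrow(x$sites), "planted sites (",
      paste(names(table(x$truth$cause)), table(x$truth$cause),
            collapse = ", "), "),",
      length(x$individuals), "individuals\n")
  invisible(x)
}

#' Diploid haplotype genomes of one individual
#'
#' Applies the individual's background SNPs (each on its assigned
#' haplotype) and any segregating paralog-trap SNP alleles (first allele on
#' haplotype 1, second on haplotype 2) to the reference.
#'
#' @param cohort a `SimCohort`.
#' @param individual individual id.
#' @return character vector of length 2 (haplotype genome sequences).
#' @export
individual_haplotypes <- function(cohort, individual) {
  ind <- cohort$individuals[[individual]]
  if (is.null(ind)) stop("unknown individual: ", individual, call. = FALSE)
  ref <- unname(cohort$genome[1])
  haps <- c(ref, ref)
  for (h in 1:2) {
    snps <- ind$snps[ind$snps$hap == h, , drop = FALSE]
    pos <- snps$pos
    alt <- snps$alt_plus
    ps <- ind$paralog_snps
    if (!is.null(ps) && nrow(ps)) {
      extra <- ps[ps$n_alleles >= h, , drop = FALSE]
      pos <- c(pos, extra$pos)
      alt <- c(alt, extra$alt_plus)
    }
    haps[h] <- apply_variants(haps[h], pos, alt)
  }
  haps
}

#' Simulate single-end reads from a set of source sequences
#'
#' Reads are drawn uniformly along the sources (sources weighted by their
#' number of valid start positions), optionally edited at a designated
#' per-source offset with a per-read editing probability, hit by uniform
#' per-base substitution errors, and reverse-complemented with probability
#' 1/2. Read names record provenance as
#' `<prefix>:<source>:<start>:<serial>`.
#'
#' @param sources data.frame with columns `name`, `seq`, and optionally
#'   `edit_offset` (1-based, `NA` for none), `edit_base`, `edit_fraction`;
#'   or a named character vector of sequences.
#' @param depth target mean fold-coverage over the source pool.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed (`NULL`: use current RNG stream).
#' @param ploidy copies over which `depth` is spread: with `ploidy = 2` a
#'   locus present on both haplotypes ends up at `depth` total coverage.
#' @param prefix read-name prefix (e.g. the individual id).
#' @return named character vector of reads.
#' @export
simulate_reads <- function(sources, depth, read_length, error_rate = 0,
                           seed = NULL, ploidy = 1L, prefix = "sim") {
  if (!is.data.frame(sources))
    sources <- data.frame(name = names(sources) %||%
                            as.character(seq_along(sources)),
                          seq = as.character(sources),
                          stringsAsFactors = FALSE)
  if (is.null(sources$edit_offset)) sources$edit_offset <- NA_integer_
  if (is.null(sources$edit_base)) sources$edit_base <- NA_character_
  if (is.null(sources$edit_fraction)) sources$edit_fraction <- 0
  stopifnot(depth > 0, read_length >= 1)
  valid <- nchar(sources$seq) - read_length + 1L
  if (any(valid < 1L))
    stop("read_length exceeds the length of a source sequence",
         call. = FALSE)
  S <- sum(as.numeric(valid))
  n <- as.integer(round(depth * S / (ploidy * read_length)))
  if (n < 1L) return(setNames(character(0), character(0)))
  with_seed(seed, {
    src <- sample.int(nrow(sources), n, replace = TRUE,
                      prob = valid / S)
    start <- floor(runif(n) * valid[src]) + 1L
    reads <- substring(sources$seq[src], start, start + read_length - 1L)

    # per-read editing at the designated transcript offset
    off <- sources$edit_offset[src]
    hit <- which(!is.na(off) & start <= off & off <= start + read_length - 1L)
    if (length(hit)) {
      sel <- hit[runif(length(hit)) < sources$edit_fraction[src[hit]]]
      if (length(sel))
        reads <- cpp_apply_substitutions(
          reads, sel, off[sel] - start[sel] + 1L,
          sources$edit_base[src[sel]])
    }

    # sequencing errors: per-read binomial count, positions then bases
    if (error_rate > 0) {
      n_err <- rbinom(n, read_length, error_rate)
      w <- which(n_err > 0)
      if (length(w)) {
        idx <- rep(w, n_err[w])
        pos <- sample.int(read_length, length(idx), replace = TRUE)
        dup <- duplicated(paste(idx, pos))
        idx <- idx[!dup]; pos <- pos[!dup]
        cur <- substring(reads[idx], pos, pos)
        reads <- cpp_apply_substitutions(reads, idx, pos, other_base(cur))
      }
    }
    flip <- runif(n) < 0.5
    reads <- cpp_revcomp(reads, flip)
    names(reads) <- sprintf("%s:%s:%d:%d", prefix, sources$name[src], start,
                            seq_len(n))
    reads
  })
}

#' Simulate an individual's genomic (DNA) reads
#'
#' Sources are the two haplotype genomes plus one extra copy of each
#' duplication allele the individual carries; coverage lands at
#' `config$dna_depth` for a normal diploid locus and proportionally higher
#' inside carried duplications.
#'
#' @param cohort a `SimCohort`.
#' @param individual individual id.
#' @param seed integer seed.
#' @param depth,read_length,error_rate overrides of the config values.
#' @return named character vector of reads.
#' @export
simulate_dna_reads <- function(cohort, individual, seed = NULL,
                               depth = cohort$config$dna_depth,
                               read_length = cohort$config$dna_read_length,
                               error_rate = cohort$config$error_rate) {
  haps <- individual_haplotypes(cohort, individual)
  src <- data.frame(name = c("hap1", "hap2"), seq = haps,
                    stringsAsFactors = FALSE)
  cnv <- cohort$individuals[[individual]]$cnv
  if (!is.null(cnv) && nrow(cnv)) {
    for (j in seq_len(nrow(cnv))) {
      reps <- cnv$n_alleles[j]
      src <- rbind(src, data.frame(
        name = paste0("dup_", cnv$gene_id[j], "_", seq_len(reps)),
        seq = rep(cohort$cnv_copies[[cnv$gene_id[j]]], reps),
        stringsAsFactors = FALSE))
    }
  }
  simulate_reads(src, depth, read_length, error_rate, seed = seed,
                 ploidy = 2L, prefix = paste0(individual, ":D"))
}

#' Simulate an individual's RNA-seq reads
#'
#' Expressed sources per haplotype: every annotated gene transcript (with
#' the individual's variants), plus -- when `paralog_transcribed` -- the
#' transcripts of reference paralogs and of carried duplication copies.
#' True-edit genes carry their per-read editing fraction. Note the mapping
#' database downstream contains only the annotated transcripts: the
#' confounding transcripts are expressed but unannotated, which is exactly
#' what makes their reads mis-map onto the genes.
#'
#' @inheritParams simulate_dna_reads
#' @return named character vector of reads.
#' @export
simulate_rna_reads <- function(cohort, individual, seed = NULL,
                               depth = cohort$config$rna_depth,
                               read_length = cohort$config$rna_read_length,
                               error_rate = cohort$config$error_rate) {
  cfg <- cohort$config
  haps <- individual_haplotypes(cohort, individual)
  genes <- cohort$genes
  edits <- cohort$edits
  rows <- list()
  for (h in 1:2) {
    tx <- vapply(seq_len(nrow(genes)), function(i)
      extract_tx(haps[h], genes$start[i], genes$end[i], genes$strand[i]),
      character(1))
    e <- match(genes$gene_id, edits$gene_id)
    rows[[h]] <- data.frame(
      name = paste0("tx_", genes$gene_id, "_h", h), seq = tx,
      edit_offset = edits$offset[e], edit_base = edits$edit_base[e],
      edit_fraction = ifelse(is.na(e), 0, cfg$edit_fraction),
      stringsAsFactors = FALSE)
    if (cfg$paralog_transcribed && nrow(cohort$paralogs)) {
      p <- cohort$paralogs
      ptx <- vapply(seq_len(nrow(p)), function(i)
        extract_tx(haps[h], p$start[i], p$end[i], p$strand[i]),
        character(1))
      rows[[h]] <- rbind(rows[[h]], data.frame(
        name = paste0("par_", p$gene_id, "_h", h), seq = ptx,
        edit_offset = NA_integer_, edit_base = NA_character_,
        edit_fraction = 0, stringsAsFactors = FALSE))
    }
  }
  src <- do.call(rbind, rows)
  cnv <- cohort$individuals[[individual]]$cnv
  if (cfg$paralog_transcribed && !is.null(cnv) && nrow(cnv)) {
    for (j in seq_len(nrow(cnv))) {
      reps <- cnv$n_alleles[j]
      src <- rbind(src, data.frame(
        name = paste0("duptx_", cnv$gene_id[j], "_", seq_len(reps)),
        seq = rep(cohort$cnv_copies[[cnv$gene_id[j]]], reps),
        edit_offset = NA_integer_, edit_base = NA_character_,
        edit_fraction = 0, stringsAsFactors = FALSE))
    }
  }
  simulate_reads(src, depth, read_length, error_rate, seed = seed,
                 ploidy = 2L, prefix = paste0(individual, ":R"))
}

#' Write a simulated cohort to a directory
#'
#' Emits the reference FASTA, the candidate-site and truth TSVs, the
#' annotated-transcript FASTA and TSV, BED interval files (genes,
#' transcribed regions, duplication polymorphisms) and per-individual
#' variant TSVs. Reads are written separately (see [simulate_dna_reads()]).
#'
#' @param cohort a `SimCohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(cohort$genome, file.path(dir, "reference.fa"))
  write_site_table(cohort$sites, file.path(dir, "sites.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  tx <- cohort$transcripts
  write_genome_fasta(setNames(tx$seq, tx$transcript_id),
                     file.path(dir, "transcripts.fa"))
  write_tsv(tx[, c("transcript_id", "gene_id", "chrom", "start", "end",
                   "strand")], file.path(dir, "transcripts.tsv"))
  for (nm in names(cohort$annotation)) {
    df <- cohort$annotation[[nm]]
    if (nrow(df)) {
      gr <- intervals_df_to_granges(df)
      names(gr) <- df$name
      write_bed(gr, file.path(dir, paste0(nm, ".bed")))
    } else {
      file.create(file.path(dir, paste0(nm, ".bed")))
    }
  }
  vars <- do.call(rbind, lapply(cohort$individuals, function(ind) {
    if (nrow(ind$snps))
      data.frame(individual = ind$id, pos = ind$snps$pos,
                 alt = ind$snps$alt_plus, hap = ind$snps$hap,
                 stringsAsFactors = FALSE)
    else NULL
  }))
  write_tsv(vars %||% data.frame(individual = character(), pos = integer(),
                                 alt = character(), hap = integer()),
            file.path(dir, "snps.tsv"))
  invisible(dir)
}
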