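# Build a genome carrying one gene copy and a planted paralog with chosen
# substitutions, plus the site table describing the trap.
plant_world <- function(n_sub = 3, trap_to_B = TRUE, seed = 1,
                        site_strand = "+", par_revcomp = FALSE) {
  set.seed(seed)
  left <- random_genome(600)
  gene <- random_genome(99)
  mid <- random_genome(400)
  copy <- gene
  subs <- if (n_sub > 0) sample(99, n_sub) else integer(0)
  if (trap_to_B && !(50 %in% subs)) subs[1] <- 50
  for (p in setdiff(subs, 50)) copy <- mutate_positions(copy, p)
  A_plus <- substr(gene, 50, 50)
  B_plus <- sample(setdiff(c("A", "C", "G", "T"), A_plus), 1)
  if (trap_to_B && 50 %in% subs) substr(copy, 50, 50) <- B_plus
  genome <- c(chr1 = paste0(left, gene, mid,
                            if (par_revcomp) oracle_revcomp(copy) else copy,
                            random_genome(300)))
  pos <- 600 + 50
  sites <- data.frame(
    site_id = "s1", chrom = "chr1", pos = pos, strand = site_strand,
    genomic_base = if (site_strand == "+") A_plus else
      oracle_revcomp(A_plus),
    rdd_base = if (site_strand == "+") B_plus else oracle_revcomp(B_plus),
    stringsAsFactors = FALSE)
  list(genome = genome, sites = sites, copy_start = 600 + 99 + 400,
       n_sub = length(unique(c(subs, if (trap_to_B) 50))))
}

test_that("an exact extra copy yields one full-identity hit", {
  w <- plant_world(n_sub = 0, trap_to_B = FALSE)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  hits <- search_flanks(db, w$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$aligned_length, 99L)
  expect_equal(hits$start, w$copy_start)
  expect_equal(hits$classification, "non_matching")  # copy shows A, not B
})

test_that("a trap-carrying paralog is found and classified matching_B", {
  w <- plant_world(n_sub = 3, trap_to_B = TRUE, seed = 2)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  hits <- search_flanks(db, w$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, (99 - w$n_sub) / 99)
  expect_equal(hits$classification, "matching_B")
  expect_equal(hits$base_at_rdd_column, w$sites$rdd_base)
})

test_that("identity strictly above 90% is required", {
  # 10 substitutions in 99 bp: 89/99 < 90% -> no hit
  w <- plant_world(n_sub = 10, trap_to_B = TRUE, seed = 3)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  expect_equal(nrow(search_flanks(db, w$genome)), 0L)
  # 9 substitutions: 90/99 ~ 90.9% > 90% -> hit
  w <- plant_world(n_sub = 9, trap_to_B = TRUE, seed = 4)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  expect_equal(nrow(search_flanks(db, w$genome)), 1L)
})

test_that("minus-strand sites and reverse-complemented copies are handled", {
  w <- plant_world(n_sub = 3, trap_to_B = TRUE, seed = 5,
                   site_strand = "-", par_revcomp = TRUE)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  hits <- search_flanks(db, w$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$classification, "matching_B")
  expect_equal(hits$base_at_rdd_column, w$sites$rdd_base)
})

test_that("a genome without paralogs yields zero hits (self-hit excluded)", {
  set.seed(6)
  genome <- c(chr1 = random_genome(5000))
  sites <- data.frame(site_id = paste0("s", 1:3), chrom = "chr1",
                      pos = c(500L, 2500L, 4500L), strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  sites$genomic_base <- ifelse(
    sites$strand == "+", substring(genome, sites$pos, sites$pos),
    oracle_revcomp(substring(genome, sites$pos, sites$pos)))
  sites$rdd_base <- vapply(sites$genomic_base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  db <- build_flank_db(sites, genome, flank = 49L)
  expect_equal(nrow(db$entries), 3L)
  expect_equal(nrow(search_flanks(db, genome)), 0L)
})

test_that("search_flanks equals the windowed Hamming oracle", {
  for (seed in 1:6) {
    w <- plant_world(n_sub = sample(0:8, 1), trap_to_B = TRUE, seed = seed + 10)
    db <- build_flank_db(w$sites, w$genome, flank = 49L)
    hits <- search_flanks(db, w$genome)
    q <- db$entries$seq
    oracle <- oracle_scan(q, as.list(w$genome), max_mm = 9)
    oracle$identity <- (99 - oracle$n_mm) / 99
    oracle <- oracle[oracle$identity > 0.9, ]
    self <- oracle$start == db$entries$src_start &
      oracle$strand == db$entries$strand
    oracle <- oracle[!self, ]
    expect_equal(nrow(hits), nrow(oracle))
    o <- order(oracle$start, oracle$strand)
    h <- order(hits$start, hits$strand)
    expect_equal(hits$start[h], oracle$start[o])
    expect_equal(hits$strand[h], oracle$strand[o])
    expect_equal(hits$identity[h], oracle$identity[o])
  }
})

test_that("classify_sites applies the documented precedence", {
  hits <- data.frame(
    site_id = c("s1", "s1", "s2", "s3"),
    covers_rdd_column = c(TRUE, TRUE, TRUE, FALSE),
    classification = c("matching_B", "non_matching", "non_matching",
                       "non_matching"),
    stringsAsFactors = FALSE)
  st <- classify_sites(c("s1", "s2", "s3", "s4", "s5"), hits,
                       reference_mismatch_ids = "s5")
  expect_equal(st$paralog_status,
               c("has_matching_paralog", "has_nonmatching_paralog_only",
                 "no_paralog",   # non-spanning hits contribute nothing
                 "no_paralog", "reference_mismatch"))
  # reference mismatch wins even with matching hits
  st2 <- classify_sites("s1", hits, reference_mismatch_ids = "s1")
  expect_equal(st2$paralog_status, "reference_mismatch")
})

test_that("annotation fractions equal the quadratic oracle", {
  set.seed(8)
  hits <- data.frame(
    site_id = paste0("s", 1:30), chrom = "chr1",
    start = 0L, end = 99L, strand = "+", aligned_length = 99L,
    identity = 1, covers_rdd_column = TRUE, base_at_rdd_column = "G",
    rdd_col_pos = sample(10000, 30),
    classification = sample(c("matching_B", "non_matching"), 30, TRUE),
    stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = c(100, 4000, 8000),
                      end = c(1500, 5000, 9000))
  txr <- data.frame(chrom = "chr1", start = c(50, 6000), end = c(2000, 9500))
  gg <- rddaudit:::intervals_df_to_granges(genes)
  tt <- rddaudit:::intervals_df_to_granges(txr)
  ann <- annotate_hits(hits, gg, tt)
  in_gene <- vapply(hits$rdd_col_pos, function(p)
    any(p >= genes$start & p <= genes$end), logical(1))
  in_txr <- vapply(hits$rdd_col_pos, function(p)
    any(p >= txr$start & p <= txr$end), logical(1))
  expect_equal(ann$hits$in_gene, in_gene)
  expect_equal(ann$hits$in_transcribed, in_txr)
  for (cl in unique(hits$classification)) {
    i <- hits$classification == cl
    row <- ann$summary[ann$summary$classification == cl, ]
    expect_equal(row$frac_in_gene, mean(in_gene[i]))
    expect_equal(row$frac_in_transcribed, mean(in_txr[i]))
  }
  # empty interval set: all fractions zero
  empty <- rddaudit:::intervals_df_to_granges(genes[0, ])
  ann0 <- annotate_hits(hits, empty, empty)
  expect_true(all(ann0$summary$frac_in_gene == 0))
})

test_that("PSL and BLAST readers reproduce search_flanks hits", {
  w <- plant_world(n_sub = 3, trap_to_B = TRUE, seed = 30)
  db <- build_flank_db(w$sites, w$genome, flank = 49L)
  hits <- search_flanks(db, w$genome)
  expect_equal(nrow(hits), 1L)
  n_match <- round(hits$identity * 99)
  # PSL row for the same alignment
  psl <- sprintf(paste0("%d\t%d\t0\t0\t0\t0\t0\t0\t%s\t%s\t99\t0\t99\t%s\t",
                        "%d\t%d\t%d\t1\t99,\t0,\t%d,"),
                 n_match, 99 - n_match, hits$strand, hits$site_id,
                 hits$chrom, nchar(w$genome), hits$start, hits$end,
                 hits$start)
  f <- tempfile(fileext = ".psl")
  writeLines(psl, f)
  got <- read_psl(f, db, w$genome)
  expect_equal(got$classification, hits$classification)
  expect_equal(got$rdd_col_pos, hits$rdd_col_pos)
  expect_equal(got$identity, hits$identity)
  # BLAST outfmt-6 row for the same alignment
  sstart <- if (hits$strand == "+") hits$start + 1L else hits$end
  send <- if (hits$strand == "+") hits$end else hits$start + 1L
  b6 <- sprintf("%s\t%s\t%.3f\t99\t%d\t0\t1\t99\t%d\t%d\t1e-30\t180",
                hits$site_id, hits$chrom, hits$identity * 100,
                99 - n_match, sstart, send)
  f6 <- tempfile(fileext = ".tsv")
  writeLines(b6, f6)
  got6 <- read_blast6(f6, db, w$genome)
  expect_equal(got6$classification, hits$classification)
  expect_equal(got6$rdd_col_pos, hits$rdd_col_pos)
  # gapped rows are dropped
  writeLines(sub("\t0\t1\t99", "\t2\t1\t99", b6), f6)
  expect_message(got_g <- read_blast6(f6, db, w$genome), "gapped")
  expect_equal(nrow(got_g), 0L)
})
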