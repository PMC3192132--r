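test_that("build_flank_db extracts entries, routes reference mismatches", {
  genome <- c(chr1 = "AACGTAA")
  sites <- data.frame(
    site_id = c("plus", "minus", "refmm", "bad"),
    chrom = "chr1", pos = 4L,
    strand = c("+", "-", "+", "+"),
    genomic_base = c("G", "C", "A", "T"),
    rdd_base = c("A", "T", "G", "C"),
    stringsAsFactors = FALSE)
  expect_message(db <- build_flank_db(sites, genome, flank = 2L),
                 "matches neither")
  # plus strand: direct extraction
  e <- db$entries[db$entries$site_id == "plus", ]
  expect_equal(e$seq, "ACGTA")
  expect_equal(e$rdd_offset, 2L)
  # minus strand: reverse complement, offset mirrored
  e <- db$entries[db$entries$site_id == "minus", ]
  expect_equal(e$seq, oracle_revcomp("ACGTA"))
  expect_equal(e$seq, "TACGT")
  expect_equal(substr(e$seq, e$rdd_offset + 1, e$rdd_offset + 1), "C")
  # reference base equals B: diverted, never in the database
  expect_equal(db$reference_mismatch$site_id, "refmm")
  expect_false("refmm" %in% db$entries$site_id)
  # reference base equals neither A nor B: excluded and logged
  expect_equal(db$inconsistent$site_id, "bad")
})

test_that("build_flank_db truncates flanks at sequence ends", {
  genome <- c(chr1 = "ACGTACGTACGT")
  sites <- data.frame(site_id = "edge", chrom = "chr1", pos = 2L,
                      strand = "+", genomic_base = "C", rdd_base = "T",
                      stringsAsFactors = FALSE)
  db <- build_flank_db(sites, genome, flank = 5L)
  e <- db$entries
  expect_equal(e$seq, substr(genome[[1]], 1, 7))  # truncated on the left
  expect_equal(e$rdd_offset, 1L)              # offset adjusted
  expect_error(build_flank_db(transform(sites, pos = 99L), genome, 5),
               "outside")
})

test_that("map_reads handles exact, threshold and ambiguous cases", {
  set.seed(11)
  t1 <- random_genome(300)
  targets <- c(a = t1, b = random_genome(250))
  r_exact <- substr(t1, 101, 150)
  aln <- map_reads(c(r1 = r_exact), targets, max_mismatches = 2)
  expect_equal(aln$target, "a")
  expect_equal(aln$target_start, 100L)
  expect_equal(aln$n_mismatches, 0L)
  expect_equal(aln$strand, "+")
  # distance max_mm + 1 everywhere: nothing emitted
  r_far <- mutate_positions(r_exact, c(3, 10, 20))
  expect_equal(nrow(map_reads(c(rf = r_far), targets, max_mismatches = 2)),
               0L)
  expect_equal(map_reads(c(rf = r_far), targets, 3)$n_mismatches, 3L)
  # identical best placement in two distinct targets: discarded
  targets2 <- c(a = t1, b = paste0(random_genome(40), substr(t1, 101, 150),
                                   random_genome(40)))
  expect_equal(nrow(map_reads(c(r1 = r_exact), targets2, 2)), 0L)
  expect_error(map_reads(c(r1 = r_exact), character(0), 2), "empty")
})

test_that("map_reads equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:12) {
    targets <- setNames(
      vapply(1:3, function(i) random_genome(sample(80:400, 1)), ""),
      paste0("t", 1:3))
    max_mm <- sample(c(2L, 5L), 1)
    reads <- character(10)
    for (i in 1:10) {
      src <- sample(3, 1)
      L <- min(50, nchar(targets[src]) - 5)
      s <- sample(nchar(targets[src]) - L + 1, 1)
      r <- substr(targets[src], s, s + L - 1)
      nmut <- sample(0:(max_mm + 1), 1)
      if (nmut > 0) r <- mutate_positions(r, sample(L, nmut))
      if (runif(1) < 0.5) r <- oracle_revcomp(r)
      reads[i] <- r
    }
    names(reads) <- paste0("r", 1:10)
    aln <- map_reads(reads, targets, max_mm)
    for (i in 1:10) {
      want <- oracle_map_read(reads[i], targets, max_mm)
      got <- aln[aln$read_id == names(reads)[i], ]
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$target, want$target)
        expect_equal(got$target_start, want$start)
        expect_equal(got$strand, want$strand)
        expect_equal(got$n_mismatches, want$n_mm)
        expect_equal(got$mismatch_positions, want$mm)
      }
    }
  }
})

test_that("strand involution: reverse-complemented reads mirror placements", {
  set.seed(5)
  targets <- c(a = random_genome(400))
  reads <- setNames(vapply(1:8, function(i) {
    s <- sample(370, 1)
    mutate_positions(substr(targets[1], s, s + 29), sample(30, 1))
  }, ""), paste0("r", 1:8))
  fwd <- map_reads(reads, targets, 2)
  rev <- map_reads(setNames(oracle_revcomp(reads), names(reads)), targets, 2)
  expect_equal(nrow(fwd), nrow(rev))
  m <- match(fwd$read_id, rev$read_id)
  expect_equal(fwd$target_start, rev$target_start[m])
  expect_equal(fwd$n_mismatches, rev$n_mismatches[m])
  expect_true(all(fwd$strand != rev$strand[m]))
})

test_that("N bases count as mismatches", {
  targets <- c(a = "ACGTACGTACGTACGTACGT")
  aln <- map_reads(c(r = "ACGTNCGTAC"), targets, 1)
  expect_equal(aln$n_mismatches, 1L)
  expect_equal(aln$mismatch_positions, "4")
  expect_equal(nrow(map_reads(c(r = "NCGTNCGTNC"), targets, 2)), 0L)
})

make_db <- function() {
  genome <- c(chr1 = random_genome(400))
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 200L,
                      strand = "+",
                      genomic_base = substr(genome, 200, 200),
                      rdd_base = setdiff(c("A", "C", "G", "T"),
                                         substr(genome, 200, 200))[1],
                      stringsAsFactors = FALSE)
  list(db = build_flank_db(sites, genome, flank = 49L), genome = genome)
}

test_that("filter_genomic_alignments allows one free mismatch at the RDD column", {
  set.seed(21)
  x <- make_db()
  db <- x$db
  off <- db$entries$rdd_offset  # 49
  base_aln <- function(mm) {
    data.frame(read_id = "r", target = "s1", target_start = 20L,
               strand = "+", n_mismatches = length(mm),
               mismatch_positions = paste(mm, collapse = ","),
               read_seq = strrep("A", 50), stringsAsFactors = FALSE)
  }
  # mismatch at RDD offset plus one other: retained
  expect_equal(nrow(filter_genomic_alignments(base_aln(c(off, 25L)), db)), 1L)
  # three non-RDD mismatches: eliminated
  expect_equal(nrow(filter_genomic_alignments(base_aln(c(21L, 25L, 30L)),
                                              db)), 0L)
  # single mismatch at the RDD offset only: retained
  expect_equal(nrow(filter_genomic_alignments(base_aln(off), db)), 1L)
  # two non-RDD mismatches: eliminated
  expect_equal(nrow(filter_genomic_alignments(base_aln(c(21L, 25L)), db)),
               0L)
  # idempotent and never increasing
  a <- do.call(rbind, lapply(list(c(off, 25L), c(21L, 25L, 30L), off, 25L),
                             base_aln))
  f1 <- filter_genomic_alignments(a, db)
  expect_lte(nrow(f1), nrow(a))
  expect_identical(filter_genomic_alignments(f1, db), f1)
})

test_that("pileup counts covering reads at the RDD column", {
  set.seed(31)
  x <- make_db()
  db <- x$db
  entry <- db$entries$seq
  off <- db$entries$rdd_offset
  A <- db$entries$genomic_base
  B <- db$entries$rdd_base
  # 7 reads showing A, 3 showing B at the column
  mk_read <- function(base) {
    r <- substr(entry, off - 19, off + 30)  # covers column at offset 20
    substr(r, 21, 21) <- base
    r
  }
  reads <- c(setNames(rep(mk_read(A), 7), paste0("a", 1:7)),
             setNames(rep(mk_read(B), 3), paste0("b", 1:3)))
  aln <- map_reads(reads, db, 2)
  p <- pileup(aln, site_map_from_flank_db(db), "ind1", source = "DNA")
  expect_equal(p$n_A, 7L)
  expect_equal(p$n_B, 3L)
  expect_equal(p$n_other, 0L)
  expect_equal(p$total, 10L)
  # non-covering reads leave no pileup row
  far <- setNames(substr(entry, 1, 30), "far")
  p2 <- pileup(map_reads(far, db, 2), site_map_from_flank_db(db), "ind1",
               source = "DNA")
  expect_equal(nrow(p2), 0L)
})

test_that("pileup totals match an independent per-column tally", {
  set.seed(41)
  x <- make_db()
  db <- x$db
  entry <- db$entries$seq
  off <- db$entries$rdd_offset
  reads <- setNames(vapply(1:40, function(i) {
    s <- sample(50, 1)
    r <- substr(entry, s, s + 49)
    r <- mutate_positions(r, sample(50, sample(0:2, 1)))
    if (runif(1) < 0.5) r <- oracle_revcomp(r)
    r
  }, ""), paste0("r", 1:40))
  aln <- map_reads(reads, db, 2)
  p <- pileup(aln, site_map_from_flank_db(db), "ind1", source = "DNA")
  # oracle: reconstruct each aligned read in target orientation and read
  # off the column base directly
  tally <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (i in seq_len(nrow(aln))) {
    s <- aln$target_start[i]
    if (s <= off && off < s + 50) {
      oriented <- if (aln$strand[i] == "-")
        oracle_revcomp(aln$read_seq[i]) else aln$read_seq[i]
      b <- substr(oriented, off - s + 1, off - s + 1)
      tally[b] <- tally[b] + 1
    }
  }
  if (nrow(p)) {
    expect_equal(p$total, sum(tally))
    expect_equal(unname(p$count_A), unname(tally["A"]))
    expect_equal(unname(p$count_G), unname(tally["G"]))
  }
})

test_that("SAM round trip preserves pileups; unmapped records are skipped", {
  set.seed(51)
  x <- make_db()
  db <- x$db
  targets <- setNames(db$entries$seq, db$entries$site_id)
  entry <- db$entries$seq
  reads <- setNames(vapply(1:15, function(i) {
    s <- sample(50, 1)
    r <- mutate_positions(substr(entry, s, s + 49), sample(50, 1))
    if (runif(1) < 0.5) r <- oracle_revcomp(r) else r
  }, ""), paste0("r", 1:15))
  aln <- map_reads(reads, db, 2)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, targets, sam)
  back <- read_external_alignments(sam, targets)
  expect_equal(attr(back, "n_skipped"), 0L)
  sm <- site_map_from_flank_db(db)
  p1 <- pileup(aln, sm, "i1", source = "DNA")
  p2 <- pileup(back[order(match(back$read_id, aln$read_id)), ], sm, "i1",
               source = "DNA")
  rownames(p2) <- NULL
  expect_equal(p1, p2)
  # hand-written records: NM:i:0 inside an entry; flag-4 record dropped
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)),
             sprintf("q1\t0\t%s\t5\t255\t20M\t*\t0\t0\t%s\t*\tNM:i:0",
                     names(targets)[1], substr(entry, 5, 24)),
             "q2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*")
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  got <- read_external_alignments(f, targets)
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_mismatches, 0L)
  expect_equal(got$target_start, 4L)
})
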