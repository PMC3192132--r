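base_cfg <- function(...) {
  sim_config(genome_length = 60000, n_genes = 12L, gene_length = 150L,
             n_individuals = 3L, seed = 99L, ...)
}

test_that("nothing planted means an empty truth table", {
  co <- simulate_cohort(base_cfg(paralog_fraction = 0, cnv_fraction = 0,
                                 snp_rate = 0, n_true_edits = 0L))
  expect_equal(nrow(co$truth), 0L)
  expect_equal(nrow(co$sites), 0L)
})

test_that("true edits alone give exactly n truth rows, all true_edit", {
  co <- simulate_cohort(base_cfg(paralog_fraction = 0, cnv_fraction = 0,
                                 snp_rate = 0, n_true_edits = 5L))
  expect_equal(nrow(co$truth), 5L)
  expect_true(all(co$truth$cause == "true_edit"))
  expect_true(all(is.na(co$truth$donor_locus)))
  # A>G editing: every site is A -> G on the transcript strand
  expect_true(all(co$sites$genomic_base == "A"))
  expect_true(all(co$sites$rdd_base == "G"))
})

test_that("same seed reproduces the cohort byte for byte", {
  cfg <- base_cfg(n_true_edits = 3L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("truth invariants hold: carriers non-empty, donor iff spurious", {
  co <- simulate_cohort(base_cfg(paralog_fraction = 0.5,
                                 polymorphic_fraction = 0.5,
                                 cnv_fraction = 0.2, n_true_edits = 2L))
  expect_true(all(nzchar(co$truth$carriers)))
  expect_true(all(is.na(co$truth$donor_locus) ==
                    (co$truth$cause == "true_edit")))
  # site table and truth align one to one
  expect_setequal(co$truth$site_id, co$sites$site_id)
})

test_that("planted paralogs diverge at the stated background rate", {
  co <- simulate_cohort(sim_config(
    genome_length = 3e5, n_genes = 60L, gene_length = 300L,
    paralog_fraction = 1, polymorphic_fraction = 0, cnv_fraction = 0,
    snp_rate = 0, n_true_edits = 0L, paralog_divergence = 0.03,
    n_individuals = 2L, seed = 12L))
  mism <- 0L; tot <- 0L
  for (g in names(co$paralog_seq)) {
    i <- match(g, co$genes$gene_id)
    gene_seq <- substring(co$genome, co$genes$start[i], co$genes$end[i])
    if (co$genes$strand[i] == "-") gene_seq <- oracle_revcomp(gene_seq)
    a <- strsplit(gene_seq, "")[[1]]
    b <- strsplit(co$paralog_seq[[g]], "")[[1]]
    trap <- co$sites$pos[co$sites$gene_id == g]
    # trap offset in transcript coordinates
    toff <- if (co$genes$strand[i] == "+") trap - co$genes$start[i] + 1L
            else co$genes$end[i] - trap + 1L
    keep <- setdiff(seq_along(a), toff)
    mism <- mism + sum(a[keep] != b[keep])
    tot <- tot + length(keep)
    # the trap itself always differs (fixed reference paralogs)
    expect_true(a[toff] != b[toff])
  }
  p <- 0.03
  expect_lt(abs(mism / tot - p), 3 * sqrt(p * (1 - p) / tot))
})

test_that("simulate_reads: exact substrings when error free, provenance names", {
  src <- c(geneA = random_genome(2000))
  reads <- simulate_reads(src, depth = 10, read_length = 40,
                          error_rate = 0, seed = 3L, prefix = "x")
  expect_true(all(grepl("^x:geneA:\\d+:\\d+$", names(reads))))
  starts <- as.integer(vapply(strsplit(names(reads), ":"), `[`, "", 3))
  for (i in seq_along(reads)) {
    truth <- substr(src, starts[i], starts[i] + 39)
    expect_true(reads[i] == truth || reads[i] == oracle_revcomp(truth))
  }
})

test_that("simulate_reads hits the target coverage and error rate", {
  src <- c(g = random_genome(10000))
  # mean coverage at an interior position across seeds ~ depth
  cov <- vapply(1:40, function(s) {
    reads <- simulate_reads(src, depth = 30, read_length = 50,
                            error_rate = 0, seed = s)
    starts <- as.integer(vapply(strsplit(names(reads), ":"), `[`, "", 3))
    sum(starts <= 5000 & 5000 <= starts + 49)
  }, numeric(1))
  expect_lt(abs(mean(cov) - 30), 3)
  # per-base mismatch fraction vs source within 3 SE of the error rate
  e <- 0.01
  reads <- simulate_reads(src, depth = 30, read_length = 50, error_rate = e,
                          seed = 77L)
  starts <- as.integer(vapply(strsplit(names(reads), ":"), `[`, "", 3))
  nmm <- vapply(seq_along(reads), function(i) {
    truth <- substr(src, starts[i], starts[i] + 49)
    d1 <- sum(charToRaw(reads[i]) != charToRaw(truth))
    d2 <- sum(charToRaw(reads[i]) != charToRaw(oracle_revcomp(truth)))
    min(d1, d2)
  }, numeric(1))
  N <- 50 * length(reads)
  expect_lt(abs(sum(nmm) / N - e), 3 * sqrt(e * (1 - e) / N))
  # different seeds give different read sets
  r2 <- simulate_reads(src, depth = 30, read_length = 50, error_rate = e,
                       seed = 78L)
  expect_false(identical(unname(reads), unname(r2)))
})

test_that("diploid carrier frequencies follow 1 - (1 - f)^2", {
  co <- simulate_cohort(sim_config(
    genome_length = 4e5, n_genes = 80L, gene_length = 150L,
    paralog_fraction = 0, cnv_fraction = 1, cnv_allele_freq = 0.3,
    snp_rate = 0, n_true_edits = 0L, n_individuals = 20L, seed = 5L))
  carriers <- vapply(strsplit(co$truth$carriers, ","), length, integer(1))
  expected <- (1 - (1 - 0.3)^2) * 20
  # mean carrier count across 80 duplications, allowing for the
  # at-least-one-carrier floor
  expect_lt(abs(mean(carriers) - expected) / expected, 0.15)
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(genome_length = 5000, n_genes = 20L,
                          gene_length = 300L, n_true_edits = 0L,
                          paralog_fraction = 0, cnv_fraction = 0),
               "too small")
  expect_error(sim_config(paralog_fraction = 1.5), "must be")
  expect_error(sim_config(n_genes = 10L, n_true_edits = 20L,
                          genome_length = 1e5), "not enough genes")
  expect_error(sim_config(rna_read_length = 400L, gene_length = 300L),
               "read_length")
})
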