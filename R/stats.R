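## Statistical comparisons: exact 2x2 tests and the random-position
## permutation test for duplication-polymorphism enrichment.

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric computation. Two-sided p sums the probabilities of
#' all tables (with the observed margins) whose probability does not exceed
#' the observed table's (probability-ordering rule, the convention of the
#' standard implementations). A degenerate margin gives p = 1.
#'
#' @param a,b,c,d the four cell counts, rows = group, columns = outcome.
#' @param alternative `"two.sided"` (default), `"greater"` (association
#'   enriching cell `a`) or `"less"`.
#' @return the p-value.
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  m1 <- a + b          # row 1 total
  m2 <- c + d          # row 2 total
  n1 <- a + c          # column 1 total
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) return(1)
  k <- max(0, n1 - m2):min(m1, n1)
  probs <- dhyper(k, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[k >= a]),
    less = sum(probs[k <= a]))
  min(1, p)
}

#' A-to-G composition shift after removing explained sites
#'
#' If genuine editing is dominated by ADAR-style A-to-G changes and the
#' explained sites are spurious, removing the explained sites should raise
#' the A-to-G fraction among those retained. Builds the 2x2 table
#' (explained / retained) x (A>G / other) and tests it exactly.
#'
#' @param substitution character vector of substitution types per site
#'   (e.g. `"A>G"`, `"C>T"`), on the transcript strand.
#' @param explained logical vector per site.
#' @return list with `fraction_before` (A>G fraction over all sites),
#'   `fraction_after` (over retained sites), `table` (2x2 matrix) and
#'   `p_value`.
#' @export
ag_shift_test <- function(substitution, explained) {
  stopifnot(length(substitution) == length(explained))
  is_ag <- substitution == "A>G"
  if (!any(is_ag))
    return(list(fraction_before = 0, fraction_after = 0,
                table = matrix(0, 2, 2), p_value = 1))
  tab <- matrix(c(sum(explained & is_ag), sum(explained & !is_ag),
                  sum(!explained & is_ag), sum(!explained & !is_ag)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("explained", "retained"),
                                c("A>G", "other")))
  list(fraction_before = mean(is_ag),
       fraction_after = if (any(!explained)) mean(is_ag[!explained]) else 0,
       table = tab,
       p_value = fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

#' Permutation test for duplication-polymorphism overlap
#'
#' The observed statistic counts sites whose own position, or any of their
#' paralogs' positions, falls inside a duplication-polymorphism interval
#' (each site counts once). Each replicate replaces every examined position
#' with a uniform random genomic position (sequences weighted by length) and
#' recounts. The empirical p-value uses the add-one convention
#' `(1 + #\{null >= observed\}) / (1 + replicates)` so it is never zero.
#'
#' @param positions data.frame with `site_id`, `chrom`, `pos` (1-based):
#'   one row per examined position (the site itself and each paralog
#'   column position).
#' @param intervals `GRanges` of duplication polymorphisms exhibiting gain
#'   alleles, or a data.frame with `chrom`, `start`, `end` (1-based closed).
#' @param genome_sizes named integer vector of sequence lengths.
#' @param replicates number of replicates (published test: 1,000).
#' @param seed integer seed; caller's RNG stream untouched.
#' @return object of class `PermutationResult`: list with `observed`,
#'   `null_counts`, `fold` (observed / mean null, `NA` if the mean is 0),
#'   `p_value`, `replicates`, `seed`, `n_sites`.
#' @export
cnv_permutation <- function(positions, intervals, genome_sizes,
                            replicates = 1000L, seed = NULL) {
  replicates <- stopifnot_count(replicates, "replicates")
  if (is.data.frame(intervals)) intervals <- intervals_df_to_granges(intervals)
  n_pos <- nrow(positions)
  n_sites <- length(unique(positions$site_id))
  count_sites <- function(chrom, pos, site_id) {
    if (!length(pos)) return(0L)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hit <- GenomicRanges::countOverlaps(gr, intervals) > 0
    length(unique(site_id[hit]))
  }
  observed <- count_sites(positions$chrom, positions$pos, positions$site_id)
  if (length(intervals) == 0) {
    res <- list(observed = observed, null_counts = rep(0L, replicates),
                fold = NA_real_, p_value = 1, replicates = replicates,
                seed = seed, n_sites = n_sites)
    class(res) <- "PermutationResult"
    return(res)
  }
  weights <- as.numeric(genome_sizes) / sum(as.numeric(genome_sizes))
  null_counts <- with_seed(seed, {
    # draw all replicates at once, then overlap once
    total <- n_pos * replicates
    chr_i <- sample.int(length(genome_sizes), total, replace = TRUE,
                        prob = weights)
    pos <- floor(runif(total) * genome_sizes[chr_i]) + 1L
    gr <- GenomicRanges::GRanges(names(genome_sizes)[chr_i],
                                 IRanges::IRanges(pos, pos))
    hit <- GenomicRanges::countOverlaps(gr, intervals) > 0
    rep_id <- rep(seq_len(replicates), each = n_pos)
    site <- rep(positions$site_id, times = replicates)
    key <- paste(rep_id[hit], site[hit], sep = "\r")
    tabulate(rep_id[hit][!duplicated(key)], nbins = replicates)
  })
  mean_null <- mean(null_counts)
  res <- list(observed = observed, null_counts = as.integer(null_counts),
              fold = if (mean_null > 0) observed / mean_null else NA_real_,
              p_value = (1 + sum(null_counts >= observed)) / (1 + replicates),
              replicates = replicates, seed = seed, n_sites = n_sites)
  class(res) <- "PermutationResult"
  res
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("Permutation test:", x$observed, "of", x$n_sites,
      "sites overlap;", x$replicates, "replicates; fold =",
      format(x$fold, digits = 3), "; p =", format(x$p_value, digits = 3),
      "\n")
  invisible(x)
}
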