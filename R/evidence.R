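## Per-individual genomic-read evidence: does an individual's own DNA carry
## the RDD nucleotide? Lenient = at least one read showing B; stringent =
## the 90%/10% purity/minor-fraction rule with the coverage-10 requirement
## deliberately omitted (genomic coverage is far lower than RNA coverage).

#' Evaluate genomic-read evidence for each (site, individual)
#'
#' @param pileups DNA pileup data.frame (alignments pre-filtered with
#'   [filter_genomic_alignments()]).
#' @param min_ab_fraction stringent purity threshold (default 0.9).
#' @param min_b_fraction stringent minor-fraction threshold (default 0.1).
#' @return data.frame `site_id`, `individual`, `n_A`, `n_B`, `n_other`,
#'   `total`, `lenient_pass`, `stringent_pass`. Zero-coverage pileups fail
#'   both criteria; a single B read passes both.
#' @export
evaluate_evidence <- function(pileups, min_ab_fraction = 0.9,
                              min_b_fraction = 0.1) {
  stopifnot(all(pileups$source == "DNA" | !nrow(pileups)))
  ab <- pileups$n_A + pileups$n_B
  lenient <- pileups$n_B >= 1L
  stringent <- frac_ge(ab, pileups$total, min_ab_fraction) &
    frac_ge(pileups$n_B, ab, min_b_fraction)
  data.frame(site_id = pileups$site_id, individual = pileups$individual,
             n_A = pileups$n_A, n_B = pileups$n_B, n_other = pileups$n_other,
             total = pileups$total,
             lenient_pass = lenient, stringent_pass = stringent,
             stringsAsFactors = FALSE)
}

#' Aggregate evidence to "matched by any individual" per site
#'
#' @param verdicts data.frame from [evaluate_evidence()].
#' @param site_ids all site ids (defaults to those observed).
#' @param reference_explained_ids site ids already explained by the
#'   reference genome alone (reference-mismatch sites plus sites with a
#'   matching paralog); used for the union flag.
#' @return data.frame `site_id`, `lenient_any`, `stringent_any`,
#'   `explained_union` (stringent-any OR reference explanation).
#' @export
aggregate_any_individual <- function(verdicts, site_ids = NULL,
                                     reference_explained_ids = character()) {
  site_ids <- site_ids %||% unique(verdicts$site_id)
  len_ids <- unique(verdicts$site_id[verdicts$lenient_pass])
  str_ids <- unique(verdicts$site_id[verdicts$stringent_pass])
  data.frame(
    site_id = site_ids,
    lenient_any = site_ids %in% len_ids,
    stringent_any = site_ids %in% str_ids,
    explained_union = site_ids %in% str_ids |
      site_ids %in% reference_explained_ids,
    stringsAsFactors = FALSE)
}

#' Nucleotide-swap specificity control
#'
#' Replaces, per iteration and per site, the RDD nucleotide B by one of the
#' two nucleotides that are neither A nor B (uniformly at random), re-tallies
#' the stringent criterion against the swapped target, and reports the
#' number of sites passing in any individual, averaged over iterations. With
#' error-free reads and no confounders no site can ever pass.
#'
#' @param pileups DNA pileup data.frame.
#' @param sites site table (provides A and B per site).
#' @param iterations number of swap iterations (published control: 10,000;
#'   tests use fewer).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param min_ab_fraction,min_b_fraction stringent thresholds.
#' @return list with `mean`, `sd`, `per_iteration` (integer vector of
#'   passing-site counts), `iterations`, `seed`.
#' @export
swap_control <- function(pileups, sites, iterations = 10000L, seed = NULL,
                         min_ab_fraction = 0.9, min_b_fraction = 0.1) {
  iterations <- stopifnot_count(iterations, "iterations")
  sites <- validate_site_table(sites)
  p <- merge(pileups, sites[, c("site_id", "genomic_base", "rdd_base")],
             by = "site_id")
  counts <- as.matrix(p[, paste0("count_", DNA_BASES)])
  base_idx <- function(b) match(b, DNA_BASES)
  a_i <- base_idx(p$genomic_base)
  b_i <- base_idx(p$rdd_base)
  # the two alternative target nucleotides, fixed per site; one draw per
  # site per iteration is shared by all of that site's individuals
  usite <- unique(p$site_id)
  srow <- match(usite, p$site_id)
  alt <- t(vapply(srow, function(i)
    setdiff(seq_len(4L), c(a_i[i], b_i[i])), integer(2)))
  site_of_row <- match(p$site_id, usite)
  n_A <- counts[cbind(seq_len(nrow(p)), a_i)]
  total <- p$total
  per_iter <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      draw <- sample(c(1L, 2L), length(usite), replace = TRUE)
      pick <- alt[cbind(site_of_row, draw[site_of_row])]
      n_B2 <- counts[cbind(seq_len(nrow(p)), pick)]
      ab <- n_A + n_B2
      pass <- frac_ge(ab, total, min_ab_fraction) &
        frac_ge(n_B2, ab, min_b_fraction)
      length(unique(p$site_id[pass]))
    }, numeric(1))
  })
  list(mean = mean(per_iter), sd = if (iterations > 1) sd(per_iter) else NA_real_,
       per_iteration = as.integer(per_iter), iterations = iterations,
       seed = seed)
}

#' Per-individual match rate of called RDD events
#'
#' For each individual: among its called RDD events, the fraction matched by
#' at least one genomic read from that same individual showing B (lenient).
#' The specificity control is the same fraction computed against the two
#' nucleotides that are neither A nor B, averaged over the two choices
#' (the expectation of a uniform random swap).
#'
#' @param calls calls data.frame from [call_cohort()]`$calls`.
#' @param pileups DNA pileup data.frame.
#' @param sites site table.
#' @return list with `per_individual` (data.frame `individual`, `n_called`,
#'   `n_matched`, `rate`, `control_rate`), `mean_rate`, `mean_control_rate`.
#'   Individuals with zero called events are excluded from the means.
#' @export
per_individual_match_rate <- function(calls, pileups, sites) {
  sites <- validate_site_table(sites)
  called <- calls[calls$called, c("site_id", "individual"), drop = FALSE]
  p <- merge(pileups, sites[, c("site_id", "genomic_base", "rdd_base")],
             by = "site_id")
  counts <- as.matrix(p[, paste0("count_", DNA_BASES)])
  b_i <- match(p$rdd_base, DNA_BASES)
  a_i <- match(p$genomic_base, DNA_BASES)
  n_B <- counts[cbind(seq_len(nrow(p)), b_i)]
  other <- vapply(seq_len(nrow(p)), function(i) {
    alt <- setdiff(seq_len(4L), c(a_i[i], b_i[i]))
    mean(counts[i, alt] >= 1L)  # expected indicator under a uniform swap
  }, numeric(1))
  key <- function(s, i) paste(s, i, sep = "\r")
  m <- match(key(called$site_id, called$individual),
             key(p$site_id, p$individual))
  called$matched <- !is.na(m) & n_B[m] >= 1L
  called$control <- ifelse(is.na(m), 0, other[m])
  inds <- unique(calls$individual)
  per <- do.call(rbind, lapply(inds, function(ind) {
    sub <- called[called$individual == ind, , drop = FALSE]
    data.frame(individual = ind, n_called = nrow(sub),
               n_matched = sum(sub$matched),
               rate = if (nrow(sub)) mean(sub$matched) else NA_real_,
               control_rate = if (nrow(sub)) mean(sub$control) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  has <- per$n_called > 0
  list(per_individual = per,
       mean_rate = if (any(has)) mean(per$rate[has]) else NA_real_,
       mean_control_rate = if (any(has)) mean(per$control_rate[has])
       else NA_real_)
}
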