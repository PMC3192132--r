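## The three published calling criteria, evaluated with integer
## cross-multiplication so that boundary cases (10% of 10 reads) are exact.

#' Call an RDD event from RNA pileups
#'
#' An individual exhibits an RDD site when, among RNA reads covering the
#' site: (1) at least 10 reads map to it, (2) at least 90% of those reads
#' show either the genomic nucleotide A or the RDD nucleotide B, and (3) of
#' the reads showing A or B, at least 10% show B. All three thresholds are
#' inclusive; fractions are compared by integer cross-multiplication.
#'
#' @param pileups RNA pileup data.frame (see [pileup()]); one row per
#'   (site, individual).
#' @param min_total criterion-1 threshold (default 10).
#' @param min_ab_fraction criterion-2 threshold (default 0.9).
#' @param min_b_fraction criterion-3 threshold (default 0.1).
#' @return data.frame with `site_id`, `individual`, `total`, `n_A`, `n_B`
#'   and logical `called`.
#' @export
call_rdd <- function(pileups, min_total = 10L, min_ab_fraction = 0.9,
                     min_b_fraction = 0.1) {
  stopifnot(all(pileups$source == "RNA" | !nrow(pileups)))
  total <- as.numeric(pileups$total)
  ab <- as.numeric(pileups$n_A + pileups$n_B)
  b <- as.numeric(pileups$n_B)
  called <- total >= min_total &
    frac_ge(ab, total, min_ab_fraction) &
    frac_ge(b, ab, min_b_fraction) &
    ab > 0
  data.frame(site_id = pileups$site_id, individual = pileups$individual,
             total = pileups$total, n_A = pileups$n_A, n_B = pileups$n_B,
             called = called, stringsAsFactors = FALSE)
}

#' Call RDD events across a cohort
#'
#' Completes the (site x individual) grid (missing pileups are
#' zero-coverage, hence uncalled), applies [call_rdd()], and summarizes as
#' the per-individual event-count histogram plus per-site carrier sets.
#'
#' @param pileups RNA pileup data.frame for the whole cohort.
#' @param site_ids all candidate site ids (defaults to those observed).
#' @param individuals all individual ids (defaults to those observed).
#' @param ... thresholds passed to [call_rdd()].
#' @return list with `calls` (full grid), `per_individual` (data.frame
#'   `individual`, `n_called`), `carriers` (named list site_id -> character
#'   vector of individuals exhibiting the site).
#' @export
call_cohort <- function(pileups, site_ids = NULL, individuals = NULL, ...) {
  site_ids <- site_ids %||% unique(pileups$site_id)
  individuals <- individuals %||% unique(pileups$individual)
  calls <- call_rdd(pileups, ...)
  grid <- expand.grid(site_id = site_ids, individual = individuals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calls <- merge(grid, calls, by = c("site_id", "individual"), all.x = TRUE)
  for (col in c("total", "n_A", "n_B"))
    calls[[col]][is.na(calls[[col]])] <- 0L
  calls$called[is.na(calls$called)] <- FALSE
  per_ind <- aggregate(called ~ individual, data = calls, FUN = sum)
  names(per_ind)[2] <- "n_called"
  per_ind <- per_ind[match(individuals, per_ind$individual), , drop = FALSE]
  rownames(per_ind) <- NULL
  carriers <- lapply(split(calls[calls$called, "individual"],
                           calls[calls$called, "site_id"]), sort)
  list(calls = calls, per_individual = per_ind, carriers = carriers)
}
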