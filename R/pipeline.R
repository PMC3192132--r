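## End-to-end orchestration on a synthetic cohort: simulate reads, map,
## call, screen, collect genomic evidence, run the statistics and the
## rarefaction, and emit one consolidated per-site verdict table.

#' Pipeline settings
#'
#' All thresholds default to the published values: 49-bp flanks, >90%
#' identity and >=50-bp hits for the paralog screen, <=2 RNA mismatches,
#' <=5 genomic mismatches with <=1 non-RDD mismatch retained, the 10-read /
#' 90% / 10% calling rule, and the coverage-free stringent evidence rule.
#'
#' @param flank flank length for the site database.
#' @param min_identity,min_hit_length paralog screen thresholds.
#' @param rna_max_mismatches,dna_max_mismatches mapper mismatch caps.
#' @param min_total,min_ab_fraction,min_b_fraction calling thresholds.
#' @param swap_iterations nucleotide-swap control iterations (published:
#'   10,000; the default here is desk-scale).
#' @param cnv_replicates random-position permutation replicates.
#' @param rarefaction_replicates random orderings for the curve.
#' @param rarefaction_criterion `"stringent"` or `"lenient"` elimination.
#' @param saturation_form `"michaelis"` or `"exponential"`.
#' @param target_fraction extrapolation target (published headline: 0.9).
#' @param do_screen,do_evidence,do_stats,do_rarefy stage toggles.
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @return list of class `RunSettings`.
#' @export
run_settings <- function(flank = 49L, min_identity = 0.9,
                         min_hit_length = 50L, rna_max_mismatches = 2L,
                         dna_max_mismatches = 5L, min_total = 10L,
                         min_ab_fraction = 0.9, min_b_fraction = 0.1,
                         swap_iterations = 200L, cnv_replicates = 1000L,
                         rarefaction_replicates = 1000L,
                         rarefaction_criterion = c("stringent", "lenient"),
                         saturation_form = c("michaelis", "exponential"),
                         target_fraction = 0.9, do_screen = TRUE,
                         do_evidence = TRUE, do_stats = TRUE,
                         do_rarefy = TRUE, seed = 1L) {
  s <- list(flank = flank, min_identity = min_identity,
            min_hit_length = min_hit_length,
            rna_max_mismatches = rna_max_mismatches,
            dna_max_mismatches = dna_max_mismatches,
            min_total = min_total, min_ab_fraction = min_ab_fraction,
            min_b_fraction = min_b_fraction,
            swap_iterations = swap_iterations,
            cnv_replicates = cnv_replicates,
            rarefaction_replicates = rarefaction_replicates,
            rarefaction_criterion = match.arg(rarefaction_criterion),
            saturation_form = match.arg(saturation_form),
            target_fraction = target_fraction,
            do_screen = isTRUE(do_screen), do_evidence = isTRUE(do_evidence),
            do_stats = isTRUE(do_stats), do_rarefy = isTRUE(do_rarefy),
            seed = stopifnot_count(seed, "seed", positive = FALSE))
  class(s) <- c("RunSettings", "list")
  s
}

#' Run the full audit pipeline on a synthetic cohort
#'
#' @param cohort a `SimCohort` from [simulate_cohort()].
#' @param settings a `RunSettings` from [run_settings()].
#' @param out_dir optional directory; when given, stage tables and a
#'   manifest JSON are written there.
#' @return list of class `RddRun` with elements `calls` (cohort calling),
#'   `screen` (hits, site status, annotation), `evidence` (pileups,
#'   verdicts, per-site aggregation, swap control, match rates), `stats`
#'   (A>G shift, CNV permutation), `rarefaction` (curve, fit,
#'   extrapolation), `verdicts` (consolidated per-site table) and
#'   `manifest`. Reruns with identical inputs are deterministic.
#' @export
run_pipeline <- function(cohort, settings = run_settings(), out_dir = NULL) {
  stopifnot(inherits(cohort, "SimCohort"))
  seeds <- derive_seeds(settings$seed, 6L + 2L * length(cohort$individuals))
  sites <- cohort$sites
  inds <- names(cohort$individuals)
  db <- build_flank_db(sites, cohort$genome, settings$flank)
  ref_mm_ids <- db$reference_mismatch$site_id
  kept_ids <- setdiff(sites$site_id, db$inconsistent$site_id)

  tx_targets <- setNames(cohort$transcripts$seq,
                         cohort$transcripts$transcript_id)
  tx_map <- site_map_from_transcripts(sites, cohort$transcripts)
  flank_map <- site_map_from_flank_db(db)

  rna_piles <- list()
  dna_piles <- list()
  for (i in seq_along(inds)) {
    ind <- inds[i]
    rna <- simulate_rna_reads(cohort, ind, seed = seeds[6L + 2L * i - 1L])
    aln <- map_reads(rna, tx_targets, settings$rna_max_mismatches)
    rna_piles[[ind]] <- pileup(aln, tx_map, ind, source = "RNA",
                               max_mismatches = settings$rna_max_mismatches)
    if (settings$do_evidence || settings$do_rarefy) {
      dna <- simulate_dna_reads(cohort, ind, seed = seeds[6L + 2L * i])
      daln <- map_reads(dna, db, settings$dna_max_mismatches)
      daln <- filter_genomic_alignments(daln, db)
      dna_piles[[ind]] <- pileup(daln, flank_map, ind, source = "DNA")
    }
  }
  rna_pile <- do.call(rbind, rna_piles) %||% empty_pileup()
  dna_pile <- do.call(rbind, dna_piles) %||% empty_pileup()
  rownames(rna_pile) <- rownames(dna_pile) <- NULL

  calls <- call_cohort(rna_pile, site_ids = kept_ids, individuals = inds,
                       min_total = settings$min_total,
                       min_ab_fraction = settings$min_ab_fraction,
                       min_b_fraction = settings$min_b_fraction)

  screen <- NULL
  status <- data.frame(site_id = kept_ids,
                       paralog_status = NA_character_,
                       stringsAsFactors = FALSE)
  hits <- empty_paralog_hits()
  if (settings$do_screen) {
    hits <- search_flanks(db, cohort$genome, settings$min_identity,
                          settings$min_hit_length)
    status <- classify_sites(kept_ids, hits, ref_mm_ids)
    ann <- annotate_hits(hits,
                         intervals_df_to_granges(cohort$annotation$genes),
                         intervals_df_to_granges(
                           cohort$annotation$transcribed))
    hits <- ann$hits
    screen <- list(hits = hits, status = status,
                   annotation_summary = ann$summary)
  }
  matching_ids <- status$site_id[
    !is.na(status$paralog_status) &
      status$paralog_status == "has_matching_paralog"]
  reference_explained <- union(ref_mm_ids, matching_ids)

  evidence <- NULL
  any_ind <- data.frame(site_id = kept_ids, lenient_any = FALSE,
                        stringent_any = FALSE,
                        explained_union = kept_ids %in% reference_explained,
                        stringsAsFactors = FALSE)
  if (settings$do_evidence) {
    verdicts <- evaluate_evidence(dna_pile, settings$min_ab_fraction,
                                  settings$min_b_fraction)
    any_ind <- aggregate_any_individual(verdicts, kept_ids,
                                        reference_explained)
    swap <- swap_control(dna_pile, sites,
                         iterations = settings$swap_iterations,
                         seed = seeds[2])
    match_rate <- per_individual_match_rate(calls$calls, dna_pile, sites)
    evidence <- list(pileups = dna_pile, verdicts = verdicts,
                     any_individual = any_ind, swap_control = swap,
                     match_rate = match_rate)
  }

  stats <- NULL
  if (settings$do_stats && settings$do_screen) {
    sub <- substitution_type(sites$genomic_base, sites$rdd_base)
    names(sub) <- sites$site_id
    ag <- ag_shift_test(sub[any_ind$site_id], any_ind$explained_union)
    pos_df <- rbind(
      data.frame(site_id = sites$site_id, chrom = sites$chrom,
                 pos = sites$pos, stringsAsFactors = FALSE),
      if (nrow(hits))
        data.frame(site_id = hits$site_id, chrom = hits$chrom,
                   pos = hits$rdd_col_pos, stringsAsFactors = FALSE))
    pos_df <- pos_df[pos_df$site_id %in% kept_ids &
                       !is.na(pos_df$pos), , drop = FALSE]
    cnv <- cnv_permutation(pos_df, cohort$annotation$duplications,
                           setNames(nchar(cohort$genome),
                                    names(cohort$genome)),
                           replicates = settings$cnv_replicates,
                           seed = seeds[3])
    stats <- list(ag_shift = ag, cnv_enrichment = cnv)
  }

  rarefaction <- NULL
  if (settings$do_rarefy && settings$do_evidence) {
    crit <- if (settings$rarefaction_criterion == "stringent")
      "stringent_pass" else "lenient_pass"
    v <- evidence$verdicts
    elim <- lapply(setNames(inds, inds), function(ind)
      unique(v$site_id[v$individual == ind & v[[crit]]]))
    curve <- build_curve(elim, reference_explained,
                         replicates = settings$rarefaction_replicates,
                         seed = seeds[4])
    fit <- tryCatch(fit_saturation(curve, settings$saturation_form),
                    error = function(e) e)
    extrap <- if (inherits(fit, "SaturationFit"))
      individuals_to_fraction(fit, length(kept_ids),
                              settings$target_fraction)
    else NULL
    rarefaction <- list(curve = curve, fit = fit, extrapolation = extrap)
  }

  kept <- sites[match(kept_ids, sites$site_id), , drop = FALSE]
  verdict_table <- data.frame(
    site_id = kept$site_id, chrom = kept$chrom, pos = kept$pos,
    strand = kept$strand, genomic_base = kept$genomic_base,
    rdd_base = kept$rdd_base,
    substitution = substitution_type(kept$genomic_base, kept$rdd_base),
    paralog_status = status$paralog_status[match(kept$site_id,
                                                 status$site_id)],
    lenient_any = any_ind$lenient_any[match(kept$site_id,
                                            any_ind$site_id)],
    stringent_any = any_ind$stringent_any[match(kept$site_id,
                                                any_ind$site_id)],
    stringsAsFactors = FALSE)
  dup_gr <- if (nrow(cohort$annotation$duplications))
    intervals_df_to_granges(cohort$annotation$duplications) else NULL
  verdict_table$cnv_overlap <- site_cnv_overlap(verdict_table, hits, dup_gr)
  verdict_table$explained <- verdict_table$site_id %in% reference_explained |
    (verdict_table$stringent_any %in% TRUE)

  manifest <- list(
    settings = unclass(settings), seeds = seeds,
    n_sites_in = nrow(sites), n_sites_kept = length(kept_ids),
    inconsistent_sites = db$inconsistent$site_id,
    reference_mismatch_sites = ref_mm_ids,
    n_individuals = length(inds))

  run <- list(flank_db = db, rna_pileups = rna_pile, calls = calls,
              screen = screen, evidence = evidence, stats = stats,
              rarefaction = rarefaction, verdicts = verdict_table,
              manifest = manifest)
  class(run) <- "RddRun"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

site_cnv_overlap <- function(verdicts, hits, dup_gr) {
  if (is.null(dup_gr)) return(rep(FALSE, nrow(verdicts)))
  own <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(verdicts$chrom,
                           IRanges::IRanges(verdicts$pos, verdicts$pos)),
    dup_gr) > 0
  par_ids <- character()
  if (nrow(hits)) {
    h <- hits[!is.na(hits$rdd_col_pos), , drop = FALSE]
    if (nrow(h)) {
      in_dup <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(h$chrom,
                               IRanges::IRanges(h$rdd_col_pos,
                                                h$rdd_col_pos)),
        dup_gr) > 0
      par_ids <- unique(h$site_id[in_dup])
    }
  }
  own | verdicts$site_id %in% par_ids
}

#' @export
print.RddRun <- function(x, ...) {
  v <- x$verdicts
  cat("RddRun:", nrow(v), "sites;",
      sum(v$explained), "explained (",
      length(x$manifest$reference_mismatch_sites), "reference-mismatch,",
      sum(v$paralog_status %in% "has_matching_paralog"), "matching-paralog,",
      sum(v$stringent_any %in% TRUE), "stringent-evidence );",
      x$manifest$n_individuals, "individuals\n")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$verdicts, file.path(out_dir, "verdicts.tsv"))
  write_tsv(run$calls$calls, file.path(out_dir, "calls.tsv"))
  write_tsv(run$calls$per_individual,
            file.path(out_dir, "calls_per_individual.tsv"))
  write_pileup(run$rna_pileups, file.path(out_dir, "rna_pileups.tsv"))
  if (!is.null(run$evidence)) {
    write_pileup(run$evidence$pileups, file.path(out_dir, "dna_pileups.tsv"))
    write_tsv(run$evidence$verdicts, file.path(out_dir, "evidence.tsv"))
    write_tsv(data.frame(iteration = seq_along(
      run$evidence$swap_control$per_iteration),
      n_passing = run$evidence$swap_control$per_iteration),
      file.path(out_dir, "swap_control.tsv"))
  }
  if (!is.null(run$screen))
    write_tsv(run$screen$hits, file.path(out_dir, "paralog_hits.tsv"))
  if (!is.null(run$rarefaction)) {
    cu <- run$rarefaction$curve
    write_tsv(data.frame(k = cu$k, mean_eliminated = cu$mean_eliminated,
                         sd_eliminated = cu$sd_eliminated),
              file.path(out_dir, "rarefaction.tsv"))
  }
  manifest <- run$manifest
  if (!is.null(run$stats)) {
    manifest$ag_shift <- run$stats$ag_shift[
      c("fraction_before", "fraction_after", "p_value")]
    manifest$cnv_enrichment <- run$stats$cnv_enrichment[
      c("observed", "fold", "p_value", "replicates")]
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}

#' Score a verdict table against synthetic ground truth
#'
#' @param verdicts consolidated verdict table from [run_pipeline()].
#' @param truth truth table from [simulate_cohort()] (`cohort$truth`).
#' @return list with `confusion` (data.frame per cause: `n`, `n_explained`,
#'   `rate`), `sensitivity` (named vector per spurious cause: fraction of
#'   planted sites explained), `false_explanation_rate` (fraction of true
#'   edits wrongly explained) and `n_scored`. Site sets are scored on their
#'   intersection; a mismatch is reported via warning.
#' @export
score_against_truth <- function(verdicts, truth) {
  common <- intersect(verdicts$site_id, truth$site_id)
  if (!length(common)) {
    warning("no sites in common between verdicts and truth")
    return(list(confusion = data.frame(), sensitivity = numeric(),
                false_explanation_rate = NA_real_, n_scored = 0L))
  }
  if (length(common) < max(nrow(verdicts), nrow(truth)))
    warning("verdict/truth site sets differ; scoring the intersection")
  v <- verdicts[match(common, verdicts$site_id), ]
  t <- truth[match(common, truth$site_id), ]
  causes <- unique(t$cause)
  confusion <- do.call(rbind, lapply(causes, function(cs) {
    idx <- t$cause == cs
    data.frame(cause = cs, n = sum(idx),
               n_explained = sum(v$explained[idx]),
               rate = mean(v$explained[idx]), stringsAsFactors = FALSE)
  }))
  spurious <- setdiff(causes, "true_edit")
  sens <- setNames(confusion$rate[match(spurious, confusion$cause)],
                   spurious)
  fer <- if ("true_edit" %in% causes)
    confusion$rate[confusion$cause == "true_edit"] else NA_real_
  list(confusion = confusion, sensitivity = sens,
       false_explanation_rate = fer, n_scored = length(common))
}
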