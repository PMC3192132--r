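# Shared fixtures. The acceptance cohort is the stated desk-scale world:
# ~1 Mb genome, 200 reference-paralog traps with transcribed paralogs, 50
# A>G true edits, DNA depth 20, error rate 0.005; 4 individuals keep the
# run inside the time budget. Memoized so several criteria reuse one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

acceptance_config <- function() {
  sim_config(genome_length = 1e6, n_genes = 250L, gene_length = 300L,
             paralog_fraction = 0.8, paralog_divergence = 0.02,
             polymorphic_fraction = 0, cnv_fraction = 0, snp_rate = 0,
             n_individuals = 4L, n_true_edits = 50L, edit_fraction = 0.3,
             edit_type = "A>G", rna_depth = 30, dna_depth = 20,
             error_rate = 0.005, seed = 424242L)
}

acceptance_cohort <- function() {
  memo("cohort", simulate_cohort(acceptance_config()))
}

acceptance_run <- function() {
  memo("run", run_pipeline(
    acceptance_cohort(),
    run_settings(seed = 90210L, swap_iterations = 100L,
                 cnv_replicates = 200L, rarefaction_replicates = 200L)))
}

# A clean world: no confounders, no sequencing error; used for the
# zero-false-explanation and exact-zero swap-control assertions.
clean_cohort <- function() {
  memo("clean", simulate_cohort(sim_config(
    genome_length = 1e5, n_genes = 30L, gene_length = 200L,
    paralog_fraction = 0, cnv_fraction = 0, snp_rate = 0,
    polymorphic_fraction = 0, n_individuals = 3L, n_true_edits = 10L,
    edit_fraction = 0.3, edit_type = "A>G", rna_depth = 30, dna_depth = 20,
    error_rate = 0, seed = 777L)))
}

clean_run <- function() {
  memo("clean_run", run_pipeline(
    clean_cohort(),
    run_settings(seed = 1234L, swap_iterations = 50L,
                 cnv_replicates = 100L, rarefaction_replicates = 50L)))
}
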