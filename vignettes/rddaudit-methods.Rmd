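---
title: "Auditing RNA-DNA differences: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing RNA-DNA differences: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An RNA-DNA difference (RDD) is a transcript position whose RNA base differs
from the same individual's genomic base at the corresponding locus. Genuine
RNA editing (ADAR-mediated A→G, APOBEC1-mediated C→U) produces such
differences at a limited number of sites, but apparent RDDs also arise from
faithful transcription of sequence *elsewhere* in the genome whenever reads
from that other locus mis-map onto the gene under study. Three mundane
mechanisms produce this artifact:

1. **Reference paralogs** — a transcribed duplicate, absent from the
   annotation used for read mapping, that differs from the gene at the
   claimed site and donates reads carrying the "edited" base.
2. **Polymorphic paralogs** — the duplicate matches the gene at the site in
   the reference assembly, but carries a segregating SNP whose alternate
   allele equals the "edited" base in some individuals.
3. **Copy-number variants** — a duplication absent from the reference
   assembly; its diverged copy exists (and may be transcribed) only in
   carrier individuals.

`rddaudit` implements, at desk scale, an audit that asks for each candidate
site: does the reference genome, or any sampled individual's own genomic
reads, already contain the claimed RNA base? A site with such a genomic
explanation is not evidence of editing.

## The audit pipeline

**Calling.** An individual exhibits a site when, among RNA reads mapping to
it with at most 2 mismatches: (i) ≥ 10 reads cover the site, (ii) ≥ 90% of
them show the genomic base A or the RDD base B, and (iii) ≥ 10% of the A/B
reads show B. All thresholds are inclusive and are evaluated by integer
cross-multiplication (the threshold fractions are held as rationals with
denominator 10^6), because the decisive cases sit exactly on the boundary —
10% of 10 reads is one read.

**Paralog screen.** Each site contributes a query of 49 bp of flanking
reference sequence on each side (99 bp total, reverse-complemented for
minus-strand sites so A and B read on the transcript strand). Sites where
the reference itself shows B are diverted to a reference-mismatch list —
their claim is void outright. The remaining queries are searched against
both strands of the genome by an ungapped seeded Hamming scan; full-length
windows with identity strictly above 90% and query length ≥ 50 bp count as
paralogs, classified *matching* when the aligned base at the RDD column is
B. Readers for BLAT PSL and BLAST tabular output allow substituting a real
aligner at the same interface.

**Genomic evidence.** DNA reads map to the 99-bp flank database with ≤ 5
mismatches, no gaps; reads with more than one mismatch besides the RDD
column are dropped. Two per-individual criteria are evaluated: *lenient* (at
least one read shows B) and *stringent* (≥ 90% of reads show A or B and
≥ 10% of those show B, with **no** minimum coverage — genomic coverage is
far below RNA coverage, and requiring 10 reads would cost most of the
sensitivity; consequently a single B read passes). Zero-coverage pileups
fail both. The specificity control re-runs the stringent test after swapping
B for one of the two bases that are neither A nor B, drawn uniformly per
site per iteration; with error-free reads and no confounders nothing can
pass the swapped test.

**Statistics.** Fisher's exact test is computed from the hypergeometric
distribution with two-sided p by probability ordering. The A→G shift test
asks whether removing explained sites raises the A→G fraction among the
retained ones — expected if the explained sites are spurious and genuine
editing is ADAR-dominated. CNV enrichment replaces every examined position
(each site and each of its paralog columns) with a uniform random genomic
position, recounts sites overlapping duplication intervals, and reports the
add-one empirical p `(1 + #{null ≥ obs}) / (1 + R)` — never zero, and for
the published setting of 1,000 replicates with no exceedances it renders as
1/1001 < 0.001.

**Rarefaction.** Individuals are added in random order; `eliminated(k)` is
the union of the reference-only baseline with the first k individuals'
elimination sets, averaged over orderings (1,000 by default; an exhaustive
mode enumerates all n! orderings for n ≤ 8, used where tests demand exact
expectations). A saturation model is fitted with the baseline held fixed:
Michaelis–Menten `baseline + E_max·k/(K_half+k)` by default, an exponential
`baseline + E_max·(1−e^{−k/τ})` as the alternative — the extrapolation
method behind the original curve is not stated, so both are provided and
every report names the form used. The Michaelis–Menten fit is seeded with
its exact double-reciprocal linearization and refined by `nls`; the
refinement is kept only when it does not worsen the fit, which makes
zero-residual (exactly model-generated) curves recoverable to full
precision. The closed-form inverse yields the smallest cohort size reaching
a target elimination fraction, with an explicit "asymptote below target"
result when unreachable.

## The matcher

Real mappers are out of scope; the stand-in is an exhaustive ungapped
(Hamming) search accelerated by exact k-mer seeding. The requested seed
length (default 16) is capped at `floor(L/(m+1))` for read length L and
mismatch cap m: with m+1 disjoint seeds, any qualifying placement contains a
clean seed (pigeonhole), so the seeded search is provably identical to the
brute-force scan — the property the test suite checks against an
independent windowed-scan oracle on hundreds of random instances. Policy
choices stated as such: N bases always count as mismatches; a read whose
minimum distance is achieved in two distinct targets is discarded as
ambiguous (approximating the uniqueness requirement of the original
mapping); ties within one target resolve to the leftmost placement, then the
forward orientation. These are divergence knobs relative to any particular
aligner's behavior.

## The synthetic cohort

`sim_config()` states the world; `simulate_cohort()` realizes it with a
ground-truth row per planted site.

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 1e6 | single-sequence reference, bases |
| `n_genes`, `gene_length` | 250, 300 | single-exon genes, one transcript each |
| `paralog_fraction` | 0.4 | genes given a reference paralog |
| `paralog_divergence` | 0.02 | per-site background divergence of copies |
| `paralog_pad` | 60 | flanking bases copied with the gene |
| `polymorphic_fraction` | 0.25 | paralogs whose trap difference segregates |
| `snp_allele_freq` | 0.3 | allele frequency of that trap SNP |
| `n_individuals` | 27 | diploid cohort (the audited study's size) |
| `cnv_fraction`, `cnv_allele_freq` | 0.1, 0.3 | segregating duplications |
| `snp_rate` | 1e-3 | background per-site heterozygosity (human scale) |
| `n_true_edits`, `edit_fraction` | 50, 0.3 | genuine A→G edits, per-transcript probability |
| `rna_depth`, `dna_depth` | 30, 20 | mean fold-coverage per individual |
| `error_rate` | 0.005 | per-base substitution error |

Every confounder forces exactly one designated "trap" difference between the
expressed copy and the annotated gene (background divergence elsewhere), so
the truth table is unambiguous. Traps sit at least 25 bp inside the
transcript so reads can cover them. Duplicated blocks are the gene plus
`paralog_pad` flanking bases — segmental duplications copy flanking
sequence, and this is what entitles a full 99-bp flank window to align to
the paralog; with transcript-only copies, traps near gene edges would have
windows spilling into non-homologous sequence and the screen's planted-
paralog recovery guarantee would not hold. Individuals are diploid: an
allele at frequency f is carried with probability 1−(1−f)²; carrier sets
are forced non-empty (a truth row with no carrier would be untestable).
Expressed copies contribute reads in proportion to copy number because read
sources are weighted by length. The RNA mapping database contains only the
annotated transcripts — the confounding transcripts are expressed but
unannotated, which is precisely what makes their reads mis-map onto genes.

What the generator does **not** emulate: indels and structural variation
beyond whole-gene duplication, quality-score error profiles (qualities are
constant; no audited criterion uses them), expression heterogeneity,
paired-end structure, splicing, and color-space reads. A green test
therefore establishes that the audit logic is correct under substitution
noise and the three planted confounder classes — not that any particular
real-data count would be reproduced.

## Numerical and calibration choices

- Threshold fractions are compared via cross-multiplication with rational
  thresholds; identity "greater than 90%" is strict.
- The empirical permutation p uses the add-one convention, hence p ∈ (0, 1].
- Calibration testing uses 150 sites over a genome with 20% interval
  coverage: overlap counts are discrete, ties make the empirical p slightly
  conservative, and an a-priori analytic computation puts P(p ≤ 0.05) at
  ≈ 0.041 for this size — inside the exact binomial 99% band the test
  checks. Much smaller site sets would fail the band check for reasons
  unrelated to correctness.
- The acceptance cohort runs 4 individuals (the spec fixes the genome size,
  planted counts, depth and error rate, not the cohort size); larger cohorts
  add runtime, not discriminative power, for the properties being checked.
- Degenerate inputs: zero-coverage pileups are uncalled and fail both
  evidence criteria; empty interval sets yield observed 0 with fold reported
  as not applicable; flat or non-increasing rarefaction curves are rejected
  with a diagnostic rather than fitted.

## Known limitations

The matcher is ungapped and desk-scale (use the PSL/BLAST/SAM readers to
substitute real aligners on real data). Random permutation positions are
uniform over assembled bases; the synthetic genome has no gaps, so no
gap-exclusion logic exists — real-genome use would need it. Multi-mapping
resolution is a stated policy, not a reproduction of Bowtie/BWA behavior.
The per-individual match-rate control uses the deterministic expectation
over the two alternative bases rather than a random draw.
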