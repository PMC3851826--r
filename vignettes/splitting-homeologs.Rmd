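---
title: "Splitting merged homeologs by per-accession expression bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting merged homeologs by per-accession expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeosplitr)
```

## The model and its assumptions

An allo-tetraploid carries two sub-genomes whose gene copies
(homeologs) are typically a few percent divergent. When a de novo
transcriptome assembly collapses the two copies of a gene into one
contig, mapping reads from a panel of near-inbred accessions back onto
it produces apparent SNPs at every divergent site, heterozygous in
essentially every accession. `homeosplitr` reconstructs the two copies
from the per-accession, per-site nucleotide counts alone, under three
assumptions:

1. **Fixed divergence.** At a questionable site the two copies carry
   two different nucleotides, shared by all accessions (the panel is
   near-inbred, so within-copy polymorphism at the same site is rare).
2. **Constant within-accession expression ratio.** Accession `a`
   transcribes the first copy in proportion `p1[a]`, roughly constant
   along the contig. The proportion may differ freely between
   accessions — this is what the likelihood exploits, and what the
   pooled-majority baseline ignores.
3. **Binomial sampling.** Given coverage `n` at a site, the count of
   the nucleotide assigned to copy 1 is Binomial(`n`, `p1[a]`) and the
   count of copy 2's nucleotide Binomial(`n`, `1 - p1[a]`);
   keeping both terms penalises patterns that explain one rare
   nucleotide (e.g. a sequencing error) while leaving the bulk of the
   counts improbable. Sites are treated as independent, so the split
   log-likelihood is the sum of per-site, per-accession terms.

The search space is the set of patterns assigning one nucleotide to
each questionable site. The exhaustive search enumerates, per site, the
nucleotides with at least `min_allele_count` reads in at least one
accession and takes the cartesian product; it is refused (with an
explicit error) above `max_combinations` = 2^20 patterns, because the
product grows at least as 2^Nq. The heuristic instead scores each
accession's own majority sequence plus the pooled majority — at most
M + 1 candidates after deduplication. Mode `"auto"` uses the exhaustive
search whenever it is tractable. Both searches score candidates with
exactly the same vectorised likelihood, so their results are
comparable; the test suite checks that the exhaustive optimum never
falls below the heuristic's and that the two pick the same split in
well over 95% of unbalanced-expression simulations.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `min_allele_count` | 5 reads | evidence per nucleotide for heterozygosity and for entering a site's candidate alphabet; guards against sequencing error |
| `het_fraction` | 1/8 | fraction of genotyped accessions that must be heterozygous for a site to be questionable; suited to a near-inbred panel, where true heterozygotes are rare |
| `min_genotyped_coverage` | 10 reads | coverage at which an accession counts as genotyped in the 1/8 denominator |
| `min_mean_coverage` | 5X | contig-level floor (total reads across accessions / length) below which no split is attempted |
| `p1_min_cov` | 10 reads | per-accession site coverage required to enter the `p1` average |
| `max_combinations` | 2^20 | tractability cap of the exhaustive search |
| `homologous_threshold` | 0.6 | strict Fis bound above which a SNP is accepted as homologous |

All thresholds are arguments, not constants, because the right settings
depend on the panel's inbreeding and sequencing depth.

## Numerical and design choices

* **Denominator of the 1/8 rule.** "Genotyped" accessions are those
  with site coverage ≥ `min_genotyped_coverage`; counting uncovered
  accessions as non-heterozygous would make deeply uneven coverage hide
  questionable sites. A fixed-denominator mode
  (`denominator = "all"`) is available for comparison.
* **Inclusive comparisons, deterministic ties.** All "at least"
  thresholds are `>=`. Most/second-most frequent nucleotides break ties
  towards the smaller index (A < C < G < T), and exact likelihood ties
  in `best_split()` resolve towards the pooled-majority pattern, then
  the lexicographically smallest one, so output is reproducible. Exact
  ties do occur, e.g. a single accession with perfectly balanced counts.
* **Proportion clamping.** The `p1` estimator can return exactly 0 or 1
  (an accession expressing only one copy), for which the binomial
  log-mass is undefined; proportions are clamped to
  [1e-6, 1 − 1e-6] before scoring. The clamp preserves the ordering of
  candidate splits.
* **Accessions without a defined `p1`** (no questionable site at
  ≥ 10X) contribute nothing to the likelihood rather than being scored
  at an arbitrary default proportion.
* **Binomial coefficients are kept** in the likelihood: `k1` and `k2`
  depend on the candidate pattern, so the coefficients differ between
  candidates and affect the argmax.
* **Near-tie flag.** When the margin between the best and second-best
  candidate log-likelihood is below `near_tie_gap` (default 0.01), the
  report flags the contig: with balanced expression the model cannot
  orient the split, and the two labelings are almost equally likely.
* **Genotype caller.** The Fis machinery needs genotypes; the caller
  used here is a transparent count-threshold rule (coverage strictly
  > 10; alleles need ≥ 5 reads and ≥ 10% of the site's coverage;
  one passing allele = homozygote, two = heterozygote, otherwise
  missing). It is *not* a probabilistic genotyper and is intentionally
  simple so that its behaviour is fully auditable; plugging in
  model-based calls upstream of `fis_per_site()` is straightforward.
* **Fis classification bounds.** Only the 0.6 homologous bound is an
  empirically motivated acceptance threshold; the −0.5 bound merely
  bins the homeologous mode of the trimodal Fis distribution.
* **Coordinates.** Sites are 1-based everywhere (files and R objects
  alike); nucleotides are indexed A=1, C=2, G=3, T=4.
* **Benchmark alignment.** `diff_sym()` requires its five sequences
  pre-aligned on common coordinates. Producing that alignment (e.g.
  from a clustering of assembled contigs) is left to external tools on
  purpose: the benchmark quantity itself is alignment-agnostic.

## What the simulator emulates — and what it does not

`simulate_contig()` plants two homeolog sequences differing at
`n_divergent` sites (default 2.5% of the length, matching the typical
divergence of the two wheat progenitor genomes), draws per-accession
expression biases from Beta(6, 2) with a random orientation flip
(clearly unbalanced expression, favouring either copy), allocates
Poisson(λ = 30) coverage binomially between copies, and misreads each
read with probability 0.005 uniformly over the other three
nucleotides. Homologous SNPs — genuine within-copy polymorphism — are
planted as alleles fixed within an accession (a selfing panel), at a
default density of ~1 per kb; the SNP yields reported for inbred wheat
transcriptomes imply densities below one homologous SNP per kb, so this
default is at the generous end of realistic. The per-copy read
provenance is retained in the truth object.

Because a real mapper is out of scope, `remap_to_split()` emulates
re-mapping onto the split sequences: each copy's reads are routed to the
split sequence that matches that copy better at the divergent sites,
with a 50/50 random split on ties. A correct split therefore separates
the copies, while a chimeric split gains nothing — but the emulation is
deliberately idealised: it uses the simulator's truth where a real
mapper would rely on read-level similarity, and it cannot model mapping
ambiguity, soft-clipping or paired-end rescue.

The simulator also does not model: read-level linkage (each site is
sampled independently, so there is nothing for phasing methods to
exploit), indels and splice variation, position-dependent error
profiles or quality strings (the minimal SAM emitter used to test the
pileup converter writes uniform qualities), expression-level dominance
changing along a contig, or more than two gene copies. Passing tests on
these simulations therefore demonstrates correctness of the count-based
model under its own assumptions — not robustness to every artefact of
real RNA-seq mappings.

## Problem sizes used by the test suite

The statistical acceptance checks run at desk scale, chosen as the
smallest sizes at which the properties are statistically meaningful:
200 random small instances for the likelihood-oracle comparison
(counts ≤ 30, ≤ 3 questionable sites); 500 simulated contigs
(12 accessions, 60 bp, 2–6 divergent sites) for
exhaustive-vs-heuristic dominance and agreement; 100 mixed contigs
(30 accessions, 400 bp, 10 divergent sites, one homologous SNP each,
30X, 0.5% error) for parameter recovery and the before/after Fis
comparison; and 100 contigs (15 accessions, 200 bp) for the paired
diffSym comparison against the per-site random baseline.

## Known limitations

* Splits are binary: loci present in more than two copies (paralogous
  families, higher ploidy) violate the model and will at best be split
  into two mixtures.
* Balanced expression (`p1 ≈ 0.5` in all accessions) carries no signal
  for orienting the split; such contigs are split arbitrarily and
  flagged via the near-tie column rather than refused.
* The screen's heterozygosity rule needs ~10 reads per accession per
  site; shallow libraries push divergent sites below detection rather
  than into errors.
* ALR is a package-defined dialect (documented in `?read_alr`);
  count files produced by other tools may need reformatting.
* The statistical paralog-detection approaches used for outbred panels
  are out of scope; the screen here is the heterozygosity-excess rule,
  which relies on the panel being near-inbred.
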