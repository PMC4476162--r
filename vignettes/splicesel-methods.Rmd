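---
title: "Methods: quantifying selection on exonic splice-associated cis-motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selection on exonic splice-associated cis-motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicesel)
```

# The scientific problem

Exonic splice enhancers (ESEs) are short exonic motifs — modelled here as
hexamers — bound by SR proteins that reinforce recognition of nearby splice
sites. Because ESEs sit inside coding sequence, purifying selection on them
is visible as a *deficit of synonymous divergence* at exon ends relative to
exon cores. `splicesel` quantifies this signal within a genome and relates
cis-motif usage to intron architecture and effective population size across
species:

* **Within a genome** — mask 69-bp exon-end flanks with an ESE hexamer set,
  estimate the synonymous substitution rate (Ks) in ESE, non-ESE and core
  partitions over 20 equal-count intron-size bins, and summarise selection
  as the *flank ESE constraint* `(Ks_core − Ks_ESE) / Ks_core` and the
  per-exon *selection proportion* (ESE density × regression-interpolated
  constraint).
* **Across species** — measure cis-motif usage as the proportion of codons
  or amino acids whose proportional usage trends with distance from the
  exon–intron junction (the Y metric), splice-site usage (`AGgt`, `agGT`),
  genomic traits (mean CDS/gene-length ratio X, intron density N, mean
  intron size M), per-site N~e~·µ from polymorphism (π, Watterson S, η),
  and phylogenetically controlled trait correlations under bivariate
  Brownian motion.
* **Within genes** — the decoy-splice-site comparison of second versus
  last-but-one exon ESE density, with a loess control for proximal intron
  size.

Every stage is testable offline because a synthetic-data module generates
gene sets, ortholog alignments, polymorphism samples and correlated traits
with *known* planted parameters.

# Gene models and features

Annotations (GFF3) and genomes (FASTA) are read with `rtracklayer` and
`Biostrings`; coordinates are 1-based inclusive on disk and 0-based
half-open internally, converted once at the I/O boundary. One transcript
per gene is kept (the longest CDS), and genes are retained only if the
spliced CDS starts with ATG, ends with a stop codon, contains no internal
stop and no ambiguous base, has length divisible by three, and has at
least one intron; the loader logs the first failing rule per gene. Exon
structure is taken from the coding (CDS) segments.

Internal exons (first and last excluded) yield one feature row each:
flanking intron sizes, splice-site strings (`AGgt` style: exonic bases
upper case, intronic lower case), codon phase, and — for exons longer
than 138 bp — the two 69-nt flanks and a central 69-nt core placed at
offset `floor((length − 69) / 2)`, maximising distance from both
junctions.

# Ks and the constraint metric

The synonymous rate engine is Nei–Gojobori (1986) counting with
Jukes–Cantor correction: synonymous sites per codon are the fraction of
single-nucleotide changes preserving the amino acid (changes to stops
count as nonsynonymous), averaged over the two sequences; multi-hit
codons are resolved by averaging over minimal mutational pathways,
excluding pathways through stop codons; `Ks = −(3/4)·ln(1 − (4/3)·ps)`,
flagged saturated at `ps ≥ 3/4`. The engine is verified against an
independent brute-force pathway-enumeration oracle at 10^−10^ on a
thousand random codon pairs.

ESE masking marks every flank nucleotide covered by at least one exact
hexamer hit (overlaps unioned); *density* is the covered fraction of the
69 positions (the field's reported medians, e.g. 12/69 ≈ 0.174, are
consistent with this per-nucleotide definition). When projecting onto
codon columns of the ortholog alignment, a codon is ESE if at least two
of its three sites are covered (majority rule); only complete, gap-free
codon columns enter a partition, and matching is performed on the
reference flank only. Exon ends are binned by their own flanking intron
size into equal-count bins (ties broken by a stable sort on size, gene
and exon index; bins may differ by one when the count is not divisible
by the bin number).

Pseudo-ESE null sets contain the same number of unique hexamers with
positions drawn i.i.d. from the true set's pooled base composition
(duplicates redrawn, exact matches to true motifs *not* excluded): they
control for the possibility that apparent ESE slowdown reflects
nucleotide-composition-linked mutation bias rather than selection.

Negative constraints and negative density × constraint products are kept
unfloored; the downstream rank statistics are invariant to monotone
truncation anyway, and flooring would bias bin means.

The per-exon selection proportion uses an ordinary least-squares line of
unbinned per-end constraint on log10 intron size (ends with undefined Ks
excluded) and interpolates the constraint at each end's intron size; the
gene-level analysis concatenates all flank-ESE and core columns per gene,
requires both concatenations to exceed a cutoff (102/150/201 bp), and
correlates the gene constraint with mean intron size, intron density and
intron number by Spearman, partial Spearman and Goodman–Kruskal gamma.

# Junction usage trends and the Y metric

For each exon end, the proportional usage of each sense codon (61) or
amino acid (20) is computed among all internal exons contributing a
complete codon at distance d = 2..34 codons from the junction (the
boundary-adjacent codon, position 1, absorbs any partial codon and is
excluded). The trend statistic is a two-tailed Spearman correlation of
proportion versus distance: negative rho marks a k-mer preferred near
exon ends. Significance is Bonferroni-corrected within each family and
end (α/61 or α/20).

P-values for the trend correlation come from a Monte-Carlo permutation
null of rho: distances are permuted against the usage profile (a fixed,
internally seeded table of 100,000 permutations shared across k-mers, so
results are deterministic and the caller's RNG stream is untouched), and
the two-tailed p is `(k + 1)/(m + 1)` with k the permuted |rho| values
at least as large as the observed one. This choice matters at the
Bonferroni threshold: at n = 33 positions the t approximation's realised
per-test size is about 1.1 × 10^−3^ against a nominal 8.2 × 10^−4^ — a
35% inflation that propagates directly into the family-wise error of
the Y metric — and exact tie-free Spearman tables do not apply because
integer counts over a shared denominator tie frequently. The
permutation p is valid under any tie pattern and never smaller than
1/(m + 1) = 10^−5^, ample for decisions at α/61.

The species-level metric Y is the proportion of k-mers with a
significant trend; a k-mer counts if significant at *either* end (the
conjunction rule is available via `rule = "both"` — the field's phrase
"both 5′- and 3′-ends" is ambiguous, and the either-end reading is the
default). To compare species with different exon counts, Y is also
reported as the mean over 100 subsamples of 5,000 exons drawn with
replacement, seeded and fully reproducible.

# Population genetics and comparative layers

Per-site θ estimators follow their textbook definitions on gap-filtered
columns: π (mean pairwise differences per site), Watterson's S / (a~n~L),
and η / (a~n~L) with η the parsimony mutation count (distinct bases − 1
per site). In CDS mode only synonymous segregating sites are counted and
L is the NG86 synonymous site count. N~e~·µ = θ/4 by default (diploid
autosomal; the divisor is configurable because published usage rarely
states it).

Phylogenetic control uses Felsenstein independent contrasts (implemented
in-package; polytomies resolved deterministically with zero-length
branches; cross-checked against `ape::pic`). The primary evidence
statistic for correlated evolution of two traits is the likelihood-ratio
`−k·ln(1 − ρ̂²)` with ρ̂ the through-origin correlation of the k contrast
pairs — twice a log-likelihood difference, hence on the same scale as the
log Bayes factors conventional in Bayesian comparative software, and
classified with the usual thresholds (weak < 2, positive ≥ 2, strong
5–10, very strong > 10). A secondary MCMC mode estimates the same
quantity as twice the difference of log harmonic-mean likelihoods from
seeded Metropolis chains over the Brownian rates and correlation
(default 10^6^ steps, 10% burn-in); harmonic-mean estimators are
high-variance, which is why the deterministic LRT is primary. Exact
published log-BF values are not reproducible in any case, since the
original chains' priors and settings are unreported.

# The synthetic-data generators

The generators define the study conditions; their defaults are fixed
once:

* **Gene sets** — 3 + Poisson(4) exons per gene; internal exon lengths
  log-normal around 85 codons with a 69-codon floor so that flanks are
  always defined *and* the central core never overlaps a flank (with
  shorter exons the core shares codons with the flanks, as it does in
  real data, and the planted core/flank contrast becomes partially
  unidentifiable); intron sizes log-normal (median 500 bp, sdlog 1,
  minimum 60); phase-0 exon boundaries only, so flanks are codon-aligned;
  canonical `gt..ag` introns; donors forced to `AGgt` with probability
  0.3. ESE hexamers are planted codon-aligned in disjoint slots at an
  expected coverage `0.05 + 0.02·log10(intron size) + 0.005·(downstream
  introns)`; incidental background matches of the 84-motif set raise the
  realised flank density to ≈ 0.16, near the field's reported medians.
  The bundled hexamer set is synthetic (generated purine-rich motifs,
  labelled as such); real catalogues are supplied as plain-text inputs.
* **Orthologs** — synonymous substitutions at third codon positions with
  per-codon probability `ps·s_c`, multiplied by `1 − c` for flank codons
  inside ESE coverage (same majority rule as the analysis, so recovery
  of c is unbiased by construction); nonsynonymous positions frozen —
  the analysis consumes only Ks, and simulating amino-acid change would
  add noise without exercising more code. Alignments are gap-free.
* **Polymorphism** — a neutral Kingman coalescent genealogy, mutation
  count Poisson(θ·L·T~total~/2), infinite-sites placement at distinct
  positions. Using a genealogy (not fixed E[S]) keeps estimator
  variances realistic.
* **Traits** — bivariate Brownian increments along branches with
  correlation ρ (default 0.8) from a (0,0) root.

What passing tests on these fixtures shows — and does not show: the
pipeline recovers planted parameters under its own model (uniform codon
usage, phase-0 junctions, gap-free alignments, neutral coalescent). Real
genomes add alignment error, indels, non-equilibrium base composition,
isoform ambiguity and mutation-rate heterogeneity, none of which the
generator emulates; results on real data inherit those caveats.

# Statistical conventions and calibration checks

* Permutation p for gamma is one-sided, `(n + 1)/(m + 1)` with ties
  counted into n (conservative, never below 1/(m+1)).
* The second-vs-penultimate comparison uses the standard exact two-sided
  binomial test (double the smaller tail, capped at 1). Published counts
  of this kind have been reported with smaller p-values than this
  convention yields; the package reports the standard test and does not
  attempt to match any particular variant.
* The Mann–Whitney U wrapper uses exact enumeration for small tie-free
  samples and the tie-corrected normal approximation otherwise; loess
  defaults to span 0.75, degree 1, on log10 intron size (no span is
  canonical; 0.75 is the conventional default and it is configurable).
* Stochastic calibration assertions (Bonferroni family-wise error ≤
  0.05; permutation-test size ≤ α + 1/(m+1)) are tested with a
  pre-registered one-sided binomial test against the stated bound: the
  bound *equals* the expected rate under correct control, so a point
  assertion at a few hundred replicates would fail a correct
  implementation roughly half the time; the binomial formulation rejects
  only when the observed rate is significantly above the bound.

## Problem sizes used in the shipped tests

The test suite and acceptance script run at deliberately compact sizes
chosen to keep Monte-Carlo error small relative to the asserted
tolerances: ~2,000 internal exons for constraint recovery (bin-level
mean within ±0.08 of planted c ∈ {0, 0.3, 0.6}); 20,000 exons for exact
recovery of six planted codon gradients (Y = 6/61); 200 null replicates
of 5,000 exons for family-wise error; 200 coalescent replicates at
θ = 0.005, n = 10, L = 10^5^ for estimator unbiasedness (3-SE band); 500
trees of 30 tips for ρ = 0.8 recovery (mean within [0.75, 0.85]); 200–500
datasets for intragene power and null uniformity.

# Known limitations

* NG86 with Jukes–Cantor is deliberately simple; it ignores
  transition/transversion bias and codon-frequency effects that
  likelihood codon models capture. At primate-scale divergence
  (Ks ≈ 0.06) the practical difference is small, and the engine is exact
  against its own counting oracle.
* ESE "non-ESE" sequence is a strict complement of motif coverage; if a
  motif catalogue is incomplete, true enhancers contaminate the non-ESE
  partition and constraint estimates are conservative.
* The harmonic-mean evidence mode inherits the estimator's well-known
  instability and is provided for scale compatibility, not inference.
* Gene-level gamma permutation is O(n²·m) and is the slowest routine at
  large gene counts; the permutation count is configurable.
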