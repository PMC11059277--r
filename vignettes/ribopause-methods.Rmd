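---
title: "ribopause: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribopause: models, synthetic worlds and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

# Scope

ribopause implements five linked analyses on a shared coordinate backbone
of filtered, frame-consistent gene models: a translation-dependent decay
(TDD) index from inhibitor time courses, differential ribosome-pause peak
calling from paired Ribo-seq/RNA-seq coverage, codon/amino-acid
compositional statistics (matched-control randomization and zero-inflated
beta regression), empirical amino-acid enrichment of protein lists, and
transcriptional-mutation tallies from pileups. A synthetic-data generator
produces every input with planted, truth-tabled signal. This vignette is
the package's own account of the models, the choices that were genuinely
open, and what the green tests do and do not establish.

# Gene models

One mRNA is kept per gene: the concatenation of its CDS segments in
transcription order, which must start with ATG, end with a stop, be
divisible by three, contain no internal stop, and carry a self-consistent
reading frame. Two rules were open and are resolved as follows:

* **"Merged" genes** are operationalized as genes whose CDS overlaps
  another gene's CDS on the same strand; both members of a pair are
  dropped. This is the conservative reading; it is a filter, so the only
  cost of over-dropping is a smaller background.
* **Multiple transcripts**: the union of CDS across transcripts is used
  when it is frame-consistent; otherwise the longest frame-consistent
  transcript. Annotated `phase` values that contradict the cumulative
  segment length drop the gene as frame-ambiguous (`check_phase = FALSE`
  disables this).

Coordinates are 0-based half-open internally; GTF (1-based closed) is
converted at the boundary. Codons spanning a segment junction are flagged
`boundary` and excluded from window analyses.

# TDD index

With stable-gene-normalized abundances, the index of one observation is
$(R_{Tci+Tli,t} - R_{Tci,t})/R_0$. Key properties: it is invariant to
scaling all three abundances, may be negative, and on noiseless
exponential decay equals $e^{-k_b t} - e^{-(k_b+k_d)t}$ exactly, where
$k_b$ is the basal and $k_d$ the translation-dependent rate.

**Stable genes.** Under transcription shutoff CPM is compositional: total
mRNA shrinks, so the *relative* abundance of non-decaying genes rises.
The three criteria — CPM$_0$ > 0.2; CPM$_t \ge 1.1\cdot$CPM$_0$;
CPM$_0 > 0.1\cdot$CPM$_t$ — are applied in every condition × replicate, at
both inhibitor times by default. Two readings of criterion (ii) ship:
`literal` (the default, a ≥ 10% rise) and `ratio` (a symmetric ten-fold
window), because the source text is ambiguous; times `both`/`any` likewise.
A consequence worth knowing: the criteria separate near-zero-decay genes
from the background only when typical genes decay faster than 1.1× the
bulk mixture. In slow-decay regimes (e.g. $k_b = 0.1$/h) background genes
also gain ≥ 10% relative CPM and pass; the exactness tests therefore
normalize with the generator's truth table, and detection is validated in
a faster-decaying world ($k_b = 0.4$/h). When detection returns no gene,
`tdd_index_table()` falls back to all-gene median-of-ratios with a
warning rather than failing.

**Size factors** are median-of-ratios restricted to the stable set (each
sample against the geometric-mean pseudo-reference); with every gene
declared stable this is the standard estimator, and the test suite checks
agreement with DESeq2's implementation at 1e-10.

**Condition test.** Per gene, `index ~ condition + time + replicate`
(main effects, factors) by least squares; a two-sided *t*-test on the
condition coefficient; classification `increased`/`decreased` by the sign
of the unweighted mean difference when $p \le \alpha$ (default 0.05, raw —
a BH column is emitted for reference but, matching the source procedure,
not used for classification). Genes with a complete design share one model
matrix and are fitted jointly by matrix least squares; incomplete genes
fall back to `lm`. No interaction terms: none were stated, and the
calibration test shows the main-effects model holds its nominal type-I
level.

# Peak calling

The implementation follows the printed pipeline literally: `cNorm =
ribo/rna` with zero-RNA positions masked (masked in any replicate of
either condition ⇒ masked in `cMean`); population SD (divide by the number
of defined positions) for `StdMean`; strict `>` both for peak membership
and for the score filter. Open points and their resolutions:

* `(e − s)` is the peak length under half-open coordinates.
* The printed score uses `cMean` and cannot vary by replicate, so the
  two-replicate rule recomputes the score on each replicate's `cDiff`
  against the *shared* threshold (`score_rule = "mean-only"` restores a
  single-score rule).
* The two overlapping RNA-coverage filter sentences are treated as one
  rule: mean RNA coverage across all RNA replicates (both conditions)
  over the peak must be ≥ 3.
* A non-positive threshold (possible when the difference track is ≤ 0 on
  average and flat) makes the score undefined; such peaks are kept on the
  coverage rule alone and flagged.

A constant track yields `T = MeanCov` and, by strictness, no peak — the
degenerate null behaves correctly by construction. Equivalence with an
independent naive reimplementation (plain loops over the formulas) is
asserted exactly on random genes.

# Composition statistics

**Randomization test.** Control sets match the observed peaks in number
and per-peak codon length; each control peak picks a gene with probability
proportional to its number of eligible codon start positions, then a
uniform start. Controls may overlap each other and the observed peaks
(nothing in the procedure forbids it, and forbidding would bias long-peak
placements in small transcriptomes). Ties count in both `k` (controls ≥
observed) and `l` (≤), `p = \min(k,l)/n`, floored at `1/n`. The statistic
is the unweighted mean of per-peak frequencies, so within a length group
the per-set sum of frequencies equals the summed codon counts divided by
the length — the implementation aggregates counts per control set directly
and never materializes per-placement tables. Peak→codon mapping takes any
codon with ≥ 1 overlapped nucleotide; the `size` covariate of the
regression and control matching are in codons, not nucleotides.

Note a floor interaction: with `F` features tested, the smallest
achievable BH-adjusted p is `F/n_controls`. At the default 10 000 sets and
64 codons that is 0.0064; reduced set counts (as in quick tests) can make
even a maximally extreme feature non-significant after adjustment — choose
`n_controls` ≥ `F/0.05`.

**Zero-inflated beta regression.** Frequencies in [0, 1) with excess
zeros are modeled in two parts sharing no parameters: a logistic model of
the zero indicator on `set`, and a beta likelihood on the positive values
with `logit(μ) ~ set + size` and a common precision φ, fit by BFGS with a
numerical Hessian; exact ones are shrunk by `(y(n−1)+0.5)/n` before
fitting. Pairwise set contrasts are Wald tests on the positive part;
the zero part uses a likelihood-ratio test on the pair subset because Wald
degenerates under the quasi-separation of an all-zero set — exactly the
degenerate case the contract requires to be detected. Family-wise
adjustment across contrasts is Holm (the single-step multivariate-normal
adjustment would need a distribution package not available here), then BH
across features. Non-converged features are flagged and excluded from the
BH denominator.

**Window profiles** anchor at the center codon (`start + ⌈(end−start)/2⌉`
in codon units); offset 0 is the within-peak frequency and offsets ±k are
`window`-codon windows stepped by `step`, truncated at CDS ends, boundary
codons excluded. Cells report contributing-peak counts so sparse offsets
are visible.

**GRAVY** is the mean Kyte–Doolittle hydropathy over residues in the
20-amino-acid table; stops and unknowns are excluded from the mean.

# Protein-list enrichment

GO lists are assembled by walking `is_a`/`part_of` edges from the root
terms; associations qualified `NOT` are excluded and only the accepted
qualifiers (`involved_in`, `located_in`, `is_active_in`, `part_of`) are
kept. Controls are size-matched draws *without* replacement within a set,
independent across the 10 000 sets. The per-list statistic is the
unweighted mean over proteins of per-protein frequencies (count/length,
stop excluded). `P_emp = (\min(k,l)+1)/(n+1)` — note the pseudocount,
different from the peak test's floored ratio; both follow their printed
formulas. The display transform `T = 1 − P_{adj}·s` with `s = +1` iff
`k > l` (ties take −1) maps enriched amino acids above 1 and depleted ones
below — values above 1 are expected and emitted literally.

# Transcriptional mutations

Pileups are thinned binomially to the smallest library's total base count,
then filtered: `QUAL ≥ 10` (column consumed as given; `use_qual = FALSE`
skips it), depth ≥ 700 (the source text says both "at least" and "greater
than"; `≥` is the default, the comparator is configurable), and any
alternative allele fraction ≥ 5% excludes the site entirely as a genomic
variant. Proportions are per REF>ALT and per REF>\* (any SNP on that REF),
with an overall \*>\* row pooling all eligible sites. The condition
comparison is a logistic regression of the site-level SNP indicator on
condition, replicates pooled (no replicate terms were stated); it is fit
in aggregated binomial form, which has identical likelihood and Wald
inference and is much faster. Separated fits get reason codes instead of
meaningless Wald p-values.

# The synthetic worlds

The generator states one world per analysis and the defaults are fixed:

* **Transcriptome**: single-CDS genes of 100–300 codons on their own
  contigs (10 nt flanks), uniform codon usage over the 61 sense codons;
  biased genes enrich `{GAA, GAT, AAT, AAA}` exactly
  `bias_multiplier`-fold (the remaining codons are rescaled, so the
  planted fold is exact in expectation; infeasible folds error).
* **TDD counts**: $A(t) = A_0 e^{-(k_b + k_d \cdot \text{active})t}$,
  negative binomial (dispersion 0.05, the bulk RNA-seq convention) around
  a fixed library size shared across a sample — counts are therefore
  compositional and the counter-intuitive rise of stable-gene CPM under
  shutoff is reproduced. Defaults $k_b = 0.1$/h, $k_d = 0.2$/h
  (half-lives of a few hours, the scale on which a 3–5 h shutoff is
  informative); 10% zero-decay spikes.
* **Coverage**: flat Poisson RNA (50×), Ribo proportional except one
  planted pause per designated gene, the pause codon's 3 nt multiplied by
  `pause_intensity` (8) in the treated condition only. The footprint
  default is one codon; 26–32 nt footprints are a parameter away.
* **Pileups**: per-base mismatch probability 1e-4 (control) and 1.2e-4
  (treated). At 2000× depth this puts the per-alternative intensity near
  0.07 — the unsaturated regime where the site-proportion relative
  frequency tracks the underlying rate ratio. True transcriptional error
  rates are lower (~1e-5), but post-filter RNA-seq mismatch rates of this
  order are realistic, and the analysis operates on proportions either
  way. 1% genomic variants at 50% allele fraction; 98% of sites pass
  QUAL.

What the worlds do *not* emulate: footprint-length and digestion biases,
codon-level elongation heterogeneity outside planted pauses, 5′/3′ ramp
effects, UTRs and isoforms, overdispersed coverage, sequencing-error
structure (quality-correlated, strand-biased), and library-composition
artifacts beyond the single compositional factor. A green recovery test
therefore establishes the statistics' correctness and calibration on
their stated assumptions — not robustness to those real-data features.

# Numerical and degenerate-input choices

* Empirical p-values are bit-reproducible under a fixed seed; placements
  draw through R's Mersenne-Twister only.
* `R_0 \le 0` excludes a gene with a reason code rather than producing
  NaN; all-masked coverage skips the gene likewise.
* The score threshold is applied with strict `>`; note a score of exactly
  3 is not representable in binary floating point, so the strictness is
  exercised in tests at an exactly representable cutoff.
* Zero residual degrees of freedom (or a single condition) yield class
  `unchanged` with `p = NA` and a reason code.
* Per-stage seeds derive deterministically from the global seed and stay
  below $2^{31}$; reruns with the same config hash identically.

# Known limitations

* The beta positive part assumes a common precision across sets; strong
  heteroscedasticity between sets will miscalibrate the Wald contrasts.
* The stable-gene criteria are uninformative in slow-decay regimes (see
  above); users should inspect the stable-set size, and the fallback
  warning, before trusting absolute index values.
* The two-replicate score rule shares one threshold across replicates; a
  per-replicate threshold variant was considered and rejected because the
  printed score is defined against the gene-level threshold.
* GO parsing covers `is_a`/`part_of` only, which matches the stated
  qualifier set but ignores `regulates`-type edges.
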