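# ribopause

Tools for asking how translation shapes the fate of mRNAs under drug
treatment: does a transcript's decay require ongoing translation, where do
ribosomes pile up along its coding sequence, and are those pause regions —
or whole regulated gene sets — biased in their codon and amino-acid
composition? The package also tallies low-frequency nucleotide mismatches in
RNA-seq pileups as a readout of transcriptional mutagenesis. It is aimed at
computational biologists analyzing transcription/translation-inhibition
time courses and paired Ribo-seq/RNA-seq experiments (bulk, two conditions,
replicated), and ships a synthetic-data generator so every stage can be run
and validated without any external download.

## The statistics at the core

**TDD index.** For a gene *G* with stable-gene-normalized abundances
*R₀* (at *t* = 0), *R*<sub>Tci,t</sub> (after *t* h of transcription
inhibitor) and *R*<sub>Tci+Tli,t</sub> (transcription + translation
inhibitors),

    TDD index = (R_{Tci+Tli,t} − R_{Tci,t}) / R₀

Translation-dependent decay spares the doubly inhibited sample, so the
index is positive when decay requires translation. "Stable genes" — genes
whose CPM satisfies three criteria through the time course in every
replicate — anchor median-of-ratios size factors. Per mRNA, the index is
modeled as `index ~ condition + time + replicate` and the condition effect
is tested with a two-sided Student's *t*-test.

**Differential pause peaks.** Per replicate *i*, `cNorm = ribo / rna`
per nucleotide (zero-RNA positions masked), `cDiff_i = cNorm_test −
cNorm_ctrl`, `cMean` the replicate mean. With `MeanCov` and the population
SD `StdMean` of `cMean` over the gene, the threshold is
`T = MeanCov + 3·StdMean`; maximal runs with `cMean > T` are peaks, scored
`(Σ cMean / ((e−s)·T) − 1) × 100`, kept when mean RNA coverage ≥ 3 and the
per-replicate score exceeds 3 in ≥ 2 replicates. Everything is run in both
directions (TC = test > control, CC = reverse).

**Empirical composition tests.** Peak codon/amino-acid frequencies are
compared with 10 000 control peak sets matched in number and per-peak codon
length, placed uniformly in expressed CDS; `p_emp = min(k, l)/10000`
floored at 1/10 000, BH across features. Protein-list amino-acid enrichment
uses size-matched proteome samples and `P_emp = (min(k, l)+1)/10001`, with
the display transform `T = 1 − P_adj·s` (`s = +1` iff `k > l`). Gene-set
frequency contrasts use a zero-inflated beta regression
(`logit(μ) ~ set + size`).

**Transcriptional mutations.** After depth-matching, sites with
`QUAL ≥ 10`, depth ≥ 700 and all alternative allele fractions < 5% are
eligible; the proportion of REF sites carrying each SNP REF>ALT is compared
between conditions by logistic regression, with the relative frequency
`(prop_test − prop_ctrl)/prop_ctrl` reported as a percentage.

## Worked example

A full synthetic run — generate a 40-gene world with planted GAA pause
sites, call peaks, test composition, compare mutation rates and render a
report:

```r
library(ribopause)
cfg <- run_config(out_dir = "demo_run", seed = 42L,
                  sim = list(n_genes = 40L, gene_length_codons = c(80L, 160L),
                             pause_gene_fraction = 0.5, mean_coverage = 50),
                  composition = list(n_controls = 2000L),
                  n_pileup_sites = 1000L)
state <- run_pipeline(cfg)
writeLines(readLines(file.path(cfg$out_dir, "report.md")))
```

which prints (excerpt):

```
## Kept peaks per direction
- TC: 21
- CC: 3

## Top enriched codons in TC peaks
- GAA (p_adj = 0.032)
- TCT (p_adj = 0.806)
...
## Planted-pause recovery
- 16/16 planted sites overlapped by kept TC peaks (100.0%)
```

Reading it: pauses were planted only in the test condition, so kept peaks
are almost all TC; every planted site is recovered; the randomization test
singles out the planted pause codon GAA (`p_adj = 0.032` is the BH-adjusted
empirical floor at 2 000 control sets — at the default 10 000 sets it
reaches 0.0064), while other codons stay at background. The mutation
section shows the Refreq point estimates at 1 000 sites, too noisy
individually to reach significance — the acceptance suite demonstrates the
calibrated recovery at the stated 5 000-site depth.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/ribopause", package="ribopause"))') \
    all --config config.json
```

## Documentation

The methods vignette (`vignettes/ribopause-methods.Rmd`) describes the
models, the synthetic worlds and their limits, numerical choices, and known
limitations.
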