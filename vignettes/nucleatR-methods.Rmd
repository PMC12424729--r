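---
title: "Classifying PRC2 de novo nucleation sites from degron ChIP-seq dynamics"
author: "nucleatR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying PRC2 de novo nucleation sites from degron ChIP-seq dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental design this package models

Polycomb Repressive Complex 2 (PRC2) writes H3K27me3 over broad repressive
domains in mouse embryonic stem cells. At steady state, its occupancy map
cannot distinguish the positions where the complex is first recruited
(nucleation sites) from the surrounding regions it spreads into. An
auxin-inducible degron on Suz12 — the core subunit required to assemble the
complex — turns the system into a three-condition time course:

1. **steady state** — the unperturbed occupancy landscape;
2. **auxin** — Suz12 is degraded, its binding (and, later, H3K27me3) erased;
3. **reintroduction** — auxin washout; the earliest rebinding events mark
   *de novo* nucleation.

The package consumes per-condition peak calls (BED/narrowPeak) and a
peak-by-sample count matrix (or per-sample fragment intervals), and carries
the analysis from differential binding through classification to the
downstream characterisation of the nucleation set: CpG-island methylation
status, GC content, labelled-feature enrichment against a resampling null,
and loop architecture from HiChIP-style loops and binned contact matrices.
Read trimming, alignment and peak calling are upstream of this package;
peak calls and counts are its inputs.

## Coordinates

On disk every interval format follows the BED convention: 0-based,
half-open. In memory every interval is a `GRanges` (1-based, closed), the
Bioconductor currency. The conversion happens exactly once, in the readers
and writers of the io layer; no other function reinterprets coordinate
bases. Positions in the methylation table are taken as 0-based positions of
the CpG cytosine (the convention is fixed here and documented because
public tables are ambiguous on this point).

## The count model and the Wald test

Counts $k_{ij}$ over union peaks (built by merging the per-condition calls;
overlapping *and book-ended* intervals merge) are treated as negative
binomial with $\mathrm{Var} = \mu + \alpha\mu^2$.

* **Normalisation.** Median-of-ratios: $s_j = \mathrm{median}_i\,
  k_{ij}/(\prod_{j'} k_{ij'})^{1/m}$ over features with all-positive
  counts. The factors are not renormalised afterwards, and there is no
  pseudo-reference fallback: if no feature is positive everywhere the
  estimator stops, because silently switching reference would change the
  meaning of the fold changes. Median-of-ratios assumes a majority of
  unchanged features; see the generator notes below for how the synthetic
  bundle respects that assumption, and its limits on real degron data.
* **Dispersion.** A deliberately simple method-of-moments estimator:
  pooled residual variance after removing group means on normalised
  counts, $\hat\alpha_i = \max((V_i - \bar\mu_i)/\bar\mu_i^2,\,10^{-8})$,
  then shrunk half-way to the across-feature median
  ($\alpha_i = \tfrac12\hat\alpha_i + \tfrac12\,\mathrm{median}(\hat\alpha)$).
  The shrinkage weight 0.5 trades a little efficiency for stability at
  $n = 2$ replicates per condition; with hundreds of samples the raw MoM
  estimate dominates and is consistent (verified by simulation in the test
  suite).
* **Wald contrast.** Group means on normalised counts with pseudo-count
  $c_0 = 0.5$ give $\log_2\mathrm{FC} = \log_2\frac{\mu_B + c_0}{\mu_A + c_0}$,
  a delta-method standard error
  $se^2 = (1/\ln 2)^2 \sum_g \frac1{n_g}\left(\frac1{\mu_g + c_0} + \alpha_i\right)$,
  and a two-sided normal p-value. The pseudo-count bounds the fold change
  for peaks that vanish in one condition and keeps the SE finite at zero
  means. Features with no counts in any sample get $p = 1$ rather than
  being dropped, so the Benjamini–Hochberg family is the full union peak
  set in both contrasts — keeping $m$ constant makes the two adjusted
  p-value columns comparable row by row.

This is a bespoke, fully specified test — not a re-implementation of any
particular GLM package. Its operating characteristics are pinned by tests:
type-I control at the dual threshold on null data, ≥ 95% power at the
planted effect size, scale invariance, and antisymmetry under condition
swap.

## The classifier

With contrast 1 (auxin vs steady state) and contrast 2 (reintroduction vs
auxin) over the same union peaks and the per-condition presence flags
(≥ 1 bp overlap with a call):

* newly acquired peaks — absent from steady-state calls — are labelled
  `new_in_auxin` (present under auxin) or `new_in_reintro` (present only
  after reintroduction) and excluded from the nucleation bookkeeping;
* among steady-state-present peaks, **nucleation** requires
  $\log_2\mathrm{FC}_1 < -1.5$, $\mathrm{padj}_1 < 0.005$,
  $\log_2\mathrm{FC}_2 > +1.5$ and $\mathrm{padj}_2 < 0.005$ — all strict,
  so boundary values are excluded;
* non-nucleation steady-state peaks still called under auxin are
  **persistent**; the rest are **control-exclusive**, the background set
  for every enrichment analysis.

"Persistent" is decided by presence in the auxin calls rather than by a
non-significant contrast: persistence is about still being a peak, and a
presence criterion does not depend on power. The labels partition the
union; the partition and the monotonicity of the nucleation count in both
thresholds are tested properties.

Interpeak distance is the nearest-neighbour edge-to-edge gap on the same
chromosome (0 for overlapping peaks, undefined for a chromosome's sole
peak). Edge gaps rather than midpoint distances keep the statistic
comparable between a broad class and a narrow one. Genomic context uses
the priority promoter (TSS ± 2 kb; the window is a parameter —
annotation conventions vary and none is canonical) > exon > intron >
intergenic, testing the peak midpoint; nearest genes minimise
|midpoint − TSS| with lexicographic tie-breaking and a strand-aware signed
distance.

## Resampling enrichment and exact tests

The resampling null draws, `N = 1000` times, as many control-exclusive
peaks as there are nucleation sites (uniformly, without replacement within
a draw — a peak set cannot contain a peak twice) and evaluates the overlap
statistic on each draw. Reported are observed/expected, and the add-one
empirical p-value $(1 + \#\{T_{null} \ge T_{obs}\})/(N+1)$, which can never
be exactly zero. Calibration is a tested property: under the null the
empirical p-values are approximately uniform.

The Fisher test on the 2×2 overlap table uses the exact two-sided
probability-mass ordering (tables as or less probable than the observed
one), with the customary $1+10^{-7}$ relative guard against ties lost to
floating-point; the odds ratio is the sample odds ratio $(ad)/(bc)$ with
the Haldane–Anscombe +0.5 applied to all cells when any cell is zero —
chosen over the conditional MLE because the corrected sample OR is what the
field's interval tools report. An exact p-value of numerically zero in
published work is underflow; the implementation never returns 0.

## CpG methylation rules

Per published convention the two thresholds are asymmetric and are kept
exactly as printed: a *site* is methylated iff its level is **strictly**
greater than 0.5; an *island* is methylated iff **at least** 20% of its
covered CpGs are methylated. The island denominator is the CpGs with data
overlapping the island, not a theoretical CpG count; islands with no
covered CpGs are `no_data` and never enter enrichment feature sets.

## Loop architecture

Loops (BEDPE) are anchor-normalised so anchor 1 precedes anchor 2; spans
are midpoint distances, undefined for interchromosomal pairs. An anchor is
a nucleation anchor iff it overlaps ≥ 1 nucleation site by ≥ 1 bp (a
boolean per anchor, so an anchor covering two sites counts once). Span
differences between the 0/1/2-anchor classes use the classical one-way
ANOVA (F = between/within mean squares), which for two groups equals the
squared pooled t statistic — a tested identity.

Aggregate Peak Analysis averages the $(2w+1)\times(2w+1)$ contact window
(default $w = 5$) around each loop pixel, anchor 1 on rows; loops whose
window leaves the matrix or whose pixel lies within $2w$ bins of the
diagonal are excluded and counted. The score divides the centre pixel by
the mean of the 3×3 **lower-left** corner — the shorter-genomic-distance
background quadrant; the convention is stated because tools differ, and
absolute scores are therefore not comparable across conventions. By default
the observed matrix is used with corner normalisation only; an
observed/expected mode was considered and left out of the default because
corner normalisation already absorbs the mild distance decay at the scales
the package targets. The default 10 kb resolution matches the contact data
the design uses; any uniform resolution is accepted. Virtual 4C extracts
the viewpoint bin's matrix row, masks the viewpoint itself and normalises
the profile to sum one.

## The synthetic-data generator

`simConfig(seed)` defaults define the conditions every recovery test runs
under; they mirror the published scale of the mESC Suz12 degron system:

| parameter | default | note |
|---|---|---|
| peaks per class | 1109 / 3832 / 896 / 372 / 448 | nucleation / control-exclusive / persistent / new-in-auxin / new-in-reintro |
| replicates | 2 per condition | replicate count is not published; 2 is the minimal replicated design |
| planted effect | \|log2FC\| = 3 | nucleation: (−3, +3); new peaks: one +3 |
| peak widths | log-normal, median 1342 / 714 bp | nucleation vs all other classes |
| baseline mean | log-normal, median 400, sd(log) 0.6 | new peaks start near background (mean 8) |
| dispersion | uniform 0.01–0.1 | typical ChIP-seq peak-level range |
| size factors | log-normal, sd 0.15 | realistic depth variation |
| genome | 4 × 12 Mb | desk-scale stand-in for mm10 |
| CpG islands | 1600 × 1 kb, GC ≥ 0.65, CpG ≥ 0.06 | on a GC 0.42 background |
| island placement | 35% at nucleation, 50% at control-exclusive peaks | see below |
| unmethylated odds | 0.9 at nucleation vs 0.5 elsewhere | the planted methylation bias |
| loops | 3892 / 260 / 102 with 0/1/2 nucleation anchors | mean spans 0.18 / 0.33 / 0.86 Mb |
| contact matrix | 10 kb bins, decay $c/(1+|i-j|)$, 5× focal pixels | first chromosome |

Two modelling choices deserve emphasis.

*Planted dynamics are restricted to nucleation and newly acquired peaks.*
In the real system auxin erases most Suz12 peaks, control-exclusive ones
included. A count matrix over union peaks cannot identify such a global
loss: median-of-ratios (or any normalisation that assumes a stable
majority) absorbs it into the size factors. The synthetic bundle therefore
encodes control-exclusive status through the per-condition peak calls
(absent under auxin and reintroduction) while planting flat counts, which
keeps ~70% of features unchanged and the normalisation identifiable. This
is exactly what passing recovery tests do and do not show: they validate
the dual-contrast machinery under identifiable normalisation, not the
ability to detect a genome-wide occupancy loss — on real degron data that
global component is carried by depth normalisation and presence calls, and
users should treat size factors from strongly perturbed designs with
corresponding care.

*Island placement balances presence against status.* CpG islands are
planted at peaks of both classes at comparable per-peak rates (≈ 0.51 at
nucleation, ≈ 0.21 at control-exclusive), so that the planted contrast the
enrichment analysis must recover is the *methylation status* bias
(unmethylated with probability 0.9 at nucleation vs 0.5 elsewhere) —
giving O/E > 1 for unmethylated and O/E < 1 for methylated islands — with
a realistic, but not overwhelming, excess of island presence at nucleation
sites. Methylated islands are planted with ≥ 20% (and unmethylated with
< 20%) high-level CpGs by exact count, so the island caller recovers every
planted status deterministically; the recovery tests then probe the
enrichment machinery, not the caller's noise tolerance.

Fragment-level read simulation is omitted: counts are generated directly
at peak level from the NB model, and the fragment-counting operation is
exercised by small interval fixtures instead. Loops shorter than 3 bins
are rejected and resampled; two-anchor loops additionally reject pairs
whose realised (peak-snapped) span deviates more than 25% from the drawn
one so the configured span distribution is honoured. Every generator is a
pure function of (config, seed): sub-seeds are derived per stage, and the
written bundle is byte-identical across runs.

What the generator does *not* emulate: ChIP efficiency and
background-to-signal ratios, fragment-length effects, mappability,
replication timing, copy-number structure, and realistic interpeak
spacing (the desk-scale genome is ~50× denser in peaks than mm10).
Absolute interpeak-distance and loop-span summaries from the bundle are
therefore scale model quantities, not predictions of the real values.

## Numerical and degenerate-case conventions

* Strict vs inclusive thresholds follow the printed rules everywhere
  (classifier strict; site strict; island inclusive).
* Ties: nearest-gene ties break lexicographically; BH ties share an
  adjusted value; Fisher two-sided ties are included via the $1+10^{-7}$
  relative guard.
* Degenerate inputs error loudly rather than guess: no all-positive
  feature for normalisation, fewer than two peaks for interpeak distances,
  ANOVA with one loop per group, APA with every loop excluded, a virtual-4C
  viewpoint outside the matrix or with an all-zero row.
* Empty classes in summaries report `n = 0` with missing statistics.
* Problem sizes in the test suite are chosen so the full suite runs in a
  few minutes on one CPU: the study-scale bundle (~6.7k peaks, 6 samples,
  4254 loops, 1.4M-cell contact matrix) for recovery tests, and 200–600
  interval sets for calibration loops.

## Interfaces

`runPipeline(pipelineConfig(seed, outdir, ...))` executes simulate (optional)
→ diffbind → classify → enrich → cgi → loops, writing TSV/BED outputs that
each carry a header comment with the package version and a hash of the
analysis parameters, plus a manifest of per-stage row counts and seeds.
The package is a library: the exported functions and this pipeline runner
are its interface, and the same entry points back `scripts/acceptance.R`.

## Known limitations

* The NB engine fits no covariates (no batch terms, no GLM), applies no
  LFC shrinkage prior and no outlier handling; it is intentionally the
  smallest fully specified test that meets its tested operating
  characteristics.
* Enrichment backgrounds are user-supplied (control-exclusive peaks, per
  the design); there is no GC- or length-matched background construction.
* The contact-matrix dialect is dense text for one chromosome at a time —
  adequate at desk scale, not a substitute for sparse multi-resolution
  stores.
* APA scores follow this package's stated corner convention and are not
  numerically comparable to scores from tools with other conventions.
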