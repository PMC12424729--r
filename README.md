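# nucleatR

Identification and characterisation of **PRC2 *de novo* nucleation sites**
from auxin-degron ChIP-seq dynamics in mouse embryonic stem cells.

Polycomb Repressive Complex 2 (PRC2) deposits H3K27me3 across large
repressive domains, but the genomic positions where the complex first
(re-)engages chromatin — its nucleation sites — are hidden at steady state.
An auxin-inducible degron on the core subunit Suz12 makes them visible:
depleting Suz12 erases its binding genome-wide, and reintroducing it reveals
the earliest rebinding events. `nucleatR` implements the computational side
of that experiment for users with per-condition peak calls and a peak-level
count matrix: it classifies every union peak by its binding dynamics across
the three conditions (steady state → auxin → reintroduction) and
characterises the resulting nucleation set — CpG-island methylation,
GC content, cofactor/feature enrichment against a resampling null, and
chromatin-loop architecture from HiChIP-style input.

## The model

Counts `k_ij` over union peaks are modelled as negative binomial with
`Var = mu + alpha * mu^2`. Per-sample size factors are median-of-ratios,

    s_j = median_i  k_ij / ( prod_j' k_ij' )^(1/m)

over features with all-positive counts. Per-feature dispersion is a
method-of-moments estimate on normalised counts with group means removed,
floored at `1e-8` and shrunk half-way to the across-feature median. For a
contrast B over A with normalised group means `mu_A`, `mu_B` and
pseudo-count `c0 = 0.5`:

    log2FC = log2( (mu_B + c0) / (mu_A + c0) )
    se^2   = (1/ln 2)^2 * sum_g (1/n_g) * ( 1/(mu_g + c0) + alpha )
    z      = log2FC / se,   p = two-sided normal tail,  padj = BH

A union peak present in the steady-state calls is a **nucleation site** iff
it *loses* signal under auxin (`log2FC < -1.5`, `padj < 0.005` in auxin vs
steady state) *and regains* it upon reintroduction (`log2FC > +1.5`,
`padj < 0.005` in reintroduction vs auxin); both inequalities strict.
Remaining steady-state peaks are **persistent** (still called under auxin)
or **control-exclusive**; peaks absent from steady state are newly acquired
(`new_in_auxin` / `new_in_reintro`) and excluded from further analysis.

Enrichment of any labelled feature set at nucleation sites is measured
against `N = 1000` draws of equally many control-exclusive peaks
(observed/expected ratio, add-one empirical p), alongside a two-sided Fisher
exact test with a Haldane–Anscombe-corrected sample odds ratio. CpG sites
are methylated if their level is `> 0.5` (strict); islands with `>= 20%`
methylated CpGs are methylated (inclusive). Loops are classified by how many
anchors overlap nucleation sites (0/1/2); Aggregate Peak Analysis scores the
mean contact window around loop pixels by centre over the 3×3 lower-left
(short-distance) corner, and `virtual4C()` extracts viewpoint profiles.

A fully seeded synthetic-data generator (`simConfig()` / `simulateBundle()`)
plants ground truth for every stage — NB counts with planted |log2FC| = 3
dynamics, a genome with GC-rich CpG islands and a per-CpG methylation
landscape, and loops with 0/1/2 nucleation anchors plus a matching
focal-enriched contact matrix — so the whole pipeline is testable without
any sequencing data.

## Worked example

```r
library(nucleatR)
library(SummarizedExperiment)

cfg    <- simConfig(seed = 42)          # study-scale synthetic bundle
bundle <- simulateBundle(cfg)

pe <- estimateDispersions(estimateSizeFactors(bundle$counts))
c1 <- waldContrast(pe, "steady_state", "auxin")
c2 <- waldContrast(pe, "auxin", "reintroduction")
c1
#> ContrastResult: auxin vs steady_state (B over A)
#>   6657 features; 1728 with padj < 0.05

union      <- rowRanges(pe)
classified <- classifyPeaks(union, flagPresence(union, bundle$calls), c1, c2)
table(classified$label)
#>        nucleation control_exclusive        persistent      new_in_auxin
#>              1101              3840               896               372
#>    new_in_reintro          excluded
#>               448                 0
widthStats(classified)[1:2, ]
#>               class    n median  q1   q3
#> 1        nucleation 1101   1331 979 1792
#> 2 control_exclusive 3840    711 525  963
```

Of 1,109 planted nucleation peaks, 1,101 are recovered (no false calls),
and the planted width contrast — broad nucleation sites (median ≈ 1.3 kb)
versus narrow control-exclusive peaks (≈ 0.7 kb) — is reproduced.

```r
islands <- callIslandStatus(bundle$cgi, bundle$methylation)
nuc <- classified[classified$label == "nucleation"]
ctl <- classified[classified$label == "control_exclusive"]
cgiEnrichment(nuc, ctl, islands, N = 1000, seed = 42)$unmethylated
#> ResamplingResult (enrichment): observed = 506, expected = 119,
#>   O/E = 4.253, p = 0.000999 (N = 1000 draws, seed = 42)

loops <- classifyLoopAnchors(bundle$loops, nuc)
loops
#> LoopSet: 4254 loops (0 interchromosomal)
#>   nucleation anchors 0/1/2: 3895/261/98
apa(loops, bundle$matrix, w = 5)
#> APAResult: score = 2.265 over 845 loops (3409 excluded), w = 5
```

Unmethylated CpG islands are ~4-fold over-represented at nucleation sites
relative to random control-exclusive draws, and the planted focal contact
enrichment at loop pixels yields an APA score well above the distance-decay
background. `runPipeline(pipelineConfig(seed = 42, outdir = "out"))` runs
all stages end to end and writes TSV/BED outputs plus a manifest; rerunning
with the same seed reproduces every file byte for byte.

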