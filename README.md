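# barcodeFdr

Detection and demultiplexing of DNA-barcoded reads in noisy long-read
sequencing data, with the detection threshold chosen by controlling the
tail area-based false discovery rate (Fdr).

## The problem

In multiplexed single-molecule long-read experiments (PacBio continuous
long reads being the motivating platform), sequencing may start anywhere
in the molecule: many reads begin inside the genomic insert and carry no
barcode at all, while reads that do carry one carry it corrupted by an
indel-heavy per-base error rate on the order of 10–15%. At the same time,
short barcodes are coincidentally similar to windows of almost any
genome, so a naive edit-distance cutoff either throws away most true
barcodes or floods every sample with false assignments. This package is
for anyone demultiplexing such data — or designing barcode sets for it —
who wants an explicit, quantitative precision/sensitivity trade-off
instead of a guessed cutoff.

## The method

Every read is scored by its minimal **Sequence-Levenshtein distance**
δ to the reference set *BC* — the minimal number of insertions,
deletions and substitutions turning a reference into a *prefix* of the
read (or vice versa), i.e. the minimum over the last row and last column
of the Levenshtein DP matrix:

d_SL(A,B) = min( min_j D(|A|,j), min_i D(i,|B|) ),  δ(s) = min_{b∈BC} d_SL(b,s)

The observed histogram f(δ) over all reads (and their reverse
complements) is a two-component mixture of barcoded reads f̂₁(δ) and
orphaned reads f̂₀(δ). Both components are *simulated*: barcoded reads as
corrupted reference constructs under a per-read error-rate model
Normal(μ, σ) truncated to [0,1] with insertion/deletion/substitution
ratios R, orphans as barcode-free fragments. The free parameters
(π₁, μ, σ) are fitted to the empirical histogram by an evolutionary
search minimising the RMS count distance; R is estimated from the
single-edit (δ = 1) reads. The fitted, labeled simulation then gives, for
every candidate threshold δ_t,

Fdr(δ_t) = Σ_{δ≤δ_t} f̂₀ / Σ_{δ≤δ_t} (f̂₀+f̂₁),  precision = 1 − Fdr,

and the largest δ_t with precision above the requested floor (e.g. 0.95)
is used to demultiplex: a read is assigned when a single sample attains
the minimal distance at either end within δ_t, ties across the two ends
are left unassigned, and matched barcodes (with primer, if the
barcoded-primer references are used) are trimmed.

The package also designs the error-correcting barcode sets this scheme
assumes: `[l,d]` sets (pairwise d_SL ≥ d, with d ≥ 3 correcting any
single error in DNA context) built greedily from GC-, self-complement-
and homopolymer-filtered candidates.

See the methods vignette (`vignettes/barcode-fdr-methods.Rmd`) for the
full model, parameter meanings, and design decisions.

## Worked example

```r
library(barcodeFdr)
set.seed(42)

# design a [7,3] barcode set and keep 20 barcodes for 20 samples
bc <- generateBarcodeSet(length = 7, dmin = 3, nRestarts = 100)
bc20 <- BarcodeSet(as.character(bc)[1:20], minDistance = 3)

# 40 barcoded PCR primers: each barcode + forward / reverse primer
refs <- barcodedPrimerSet(bc20,
                          forward = "GGGAGCTGCTCTCTTCTCTT",
                          reverse = "TATAAACCTTGCCCGCTGTC")

# simulate a labeled 10,000-read mixture at the fitted error model
model  <- ErrorModel(muError = 0.122, sigmaError = 0.048,
                     ratios = c(0.55, 0.362, 0.088))
insert <- randomInsert(300)
reads  <- simulateMixture(10000, pi1 = 0.34, bc = refs,
                          insert = insert, model = model)

tab <- fdrTable(reads, refs)
tab[tab$threshold %in% 7:11, 1:5]
#> threshold n_detected detection_fdr detection_precision detection_sensitivity
#>         7       3361      0.000595               0.999                 0.988
#>         8       3404      0.004113               0.996                 0.997
#>         9       3477      0.022721               0.977                 0.999
#>        10       3764      0.096706               0.903                 1.000
#>        11       4629      0.265500               0.734                 1.000

chooseThreshold(tab, minPrecision = 0.95)
#> [1] 9

demultiplex(reads, refs, threshold = 9)
#> DemuxResult: 10000 read(s): 3244 assigned, 280 ambiguous, 6476 unassigned
```

Reading the numbers: with the 27-nt barcoded-primer references, threshold
9 is the largest with precision above 95% — it detects 99.9% of the truly
barcoded reads while keeping the false discovery rate among detections at
2.3%. The demultiplexer then assigns 3,244 of the 3,400 truly barcoded
reads to samples; reads whose two ends tie between different samples stay
unassigned rather than contaminating a sample. With the bare 7-nt
barcodes instead of the barcoded primers the same workflow caps out near
89% precision at 83% sensitivity (threshold 1) — the insert-adjacent
primer context is what buys the extra discrimination.

On real data, replace `simulateMixture()` with your FASTQ
(`readReadSet()`) and let `runPipeline()` estimate the error ratios, fit
(π₁, μ, σ), pick the threshold and write per-sample FASTQs plus TSV/JSON
reports. A thin command-line wrapper with `design`, `simulate`,
`profile`, `fit`, `fdr`, `demux` and `pipeline` subcommands is installed
at `system.file("scripts", "barcodefdr", package = "barcodeFdr")`.

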