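---
title: "Predicting base-wise chromatin signal from DNA sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting base-wise chromatin signal from DNA sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seq2cov)
```

## The problem

ATAC-seq measures chromatin accessibility and H3K4me3 ChIP-seq marks active
promoter regions; both are informative about where cis-regulatory elements
sit, and both are expensive to produce. seq2cov implements a
sequence-to-coverage framework: a neural network reads genomic DNA, one-hot
encoded in fixed-length windows, and regresses the per-base read coverage of
such assays. Everything around the network — data preparation, containers,
peak calling, evaluation — is part of the package, so the whole system runs
at desk scale on synthetic data with known ground truth.

## Data representation

**Encoding.** Nucleotides become four-dimensional vectors in the fixed
channel order C, A, T, G (`SEQ2COV_CHANNELS`). `N` is encoded as the uniform
vector 0.25·**1**, which keeps every real-base row summing to one while
remaining distinguishable from padding, which is the all-zero vector. Under
this channel order, complementing a base is a reversal of the channel axis,
so reverse-complementing an encoded matrix is a cheap double reversal — a
property the tests exploit. Soft-masked (lowercase) residues are uppercased
and kept: repeat masking is an annotation, not missing data.

**Chunking.** Genomes are tiled into non-overlapping windows of 21384 bp by
default. That length spans typical plant gene loci and is divisible by ten
of the integers 1–20, so repeated strided down- and upsampling inside the
network always lands on integer lengths. Only terminal chunks are padded
(with the zero vector); padded positions are recorded in a mask and excluded
from the loss and all metrics. A chunk whose real bases are all `N` ("gap
subsequence") carries no signal and is dropped before training. Both strands
are used — the assays are unstranded, so the same coverage serves the
forward window and its reverse complement, a built-in augmentation.

**Coverage.** ATAC-seq reads are shifted +4 bp on the plus and −5 bp on the
minus strand so read starts sit at the centre of the transposase binding
site; the whole interval moves, and the shift is truncated at the sequence
edges so read length is preserved. Coverage is the per-base count of
read-covering positions (the tracks are "reads per bp", not cut-site
counts — counting fragments instead of reads would be the natural variant
for paired-end data and is deliberately left out). Replicate samples are
averaged into one track per dataset kind; coverage is *not* rescaled by
sequencing depth, and the mean-subtraction-plus-ReLU normalisation that is
sometimes used for such data is intentionally not implemented — both choices
keep targets on the raw Poisson count scale the loss assumes.

**Container.** Encoded chunks, masks, per-chunk blacklist flags and coverage
targets are persisted in a plain HDF5 file with a documented schema and a
version attribute (see `?write_container`). The package carries its own
minimal C binding to libhdf5; containers are readable by any HDF5 tool. A
container without coverage groups is valid and serves prediction-only runs.

**Blacklists.** Unplaced scaffolds and organellar sequences attract
transposase noise; they are flagged by whole sequence ID, either from a
plain ID list or from NCBI-style sequence-report JSON-lines, and excluded
from training and evaluation.

## Architectures

Three families are built by `build_model()`:

* **unet** — a stack of strided convolutions halving (by default) the length
  at each level, mirrored by transposed convolutions that restore base
  resolution;
* **hybrid** — the same with a block of unidirectional LSTM layers at the
  bottleneck;
* **bihybrid** — bidirectional LSTMs at the bottleneck.

Every convolutional and transposed convolutional layer is followed by a ReLU
and, when enabled, a batch-normalisation layer; with dropout enabled, one
dropout layer follows each recurrent layer except the last. The output of
the last transposed convolution (after its activation/normalisation) is the
prediction in log space. Two placement questions were genuinely open and are
decided as follows:

* *Batch norm after the activation.* The count of six batch-norm layers for
  a three-level model implies one after every (transposed) convolution,
  including the output-producing one; we place it after the ReLU. A useful
  side effect is that the final affine restores the full real line to the
  log-rate output. With `batch_norm = FALSE` the log rates are consequently
  non-negative (rates ≥ 1) — acceptable for the plain variants, which exist
  mainly as architecture comparisons.
* *Stride doubles as pooling.* Downsampling uses strided convolutions with
  total padding `kernel − step`, which maps length `L` exactly to `L/step`
  and mirrors back exactly (`conv_geometry()`); odd kernels give symmetric
  padding. There is no separate pooling layer.

Exact kernel sizes, filter counts and recurrent widths are configuration,
not constants. The package defaults (`filters = c(16, 32, 64)`,
`kernel = 9`, `step = 2`, two BiLSTM layers of 32 units, dropout 0.3) are
our choices, exposed in `model_config()`. Two sizing lessons from the
synthetic experiments are recorded here because they generalise. First, the
convolutional receptive field must cover a good part of the coverage peak
width, otherwise most peak positions cannot be conditioned on the causal
sequence element at all and learning stalls; the desk-scale configuration
used in the tests therefore widens the kernel to 21 for 400 bp peaks.
Second, whether gradient descent discovers the motif at all within a short
training budget depends on the first convolutional layer winning an
initialisation lottery; widening that layer (more independent filters) makes
discovery reliable across seeds at essentially no extra cost, because the
first layer is the cheapest in the stack.

The implementation is vectorised base R: im2col convolutions, transposed
convolutions sharing the same index plan (which guarantees the length
round trip), BPTT for the recurrent layers, and Adam. Every layer's
backward pass is verified against finite differences in the test suite.
Evaluation mode is deterministic (dropout off, batch norm on running
statistics).

## Loss, training and model selection

The loss is the Poisson negative log-likelihood in log space,

$$\mathrm{loss} = \frac{1}{n}\sum_{i=1}^{n} e^{x_i} - y_i x_i,$$

with `x` the network output and `y` the coverage counts; the sum runs over
the `n` *unmasked* positions only (padding never contributes — the
definition of `n` under masking is ours, since the unmasked form leaves it
implicit). Predicting in log space keeps rates positive and matches the
Poisson assumption peak callers make about such data.

Training is plain minibatch Adam with seeded shuffling. After each epoch the
validation Pearson correlation between predicted rates and targets is
computed over all unmasked validation positions concatenated (not averaged
per chunk; with several output tracks, per-track correlations are averaged —
both choices are ours and documented here). The epoch with the highest
validation Pearson defines the returned model. Learning rate, batch size and
patience are configuration with defaults chosen for the desk-scale problem
(1e-2, 16, no patience); they are not taken from any published setting.

Splits assign whole sequence IDs: `intra_species_split()` shuffles IDs
(seeded) and moves a prefix to validation so the realised share of bases is
as close to the target fraction as whole-ID assignment allows.
`loocv_plan()` builds one fold per species for leave-one-out runs.

## Peak calling and post-processing

`call_peaks()` is a bedGraph-level threshold caller: maximal runs with value
≥ cutoff, merging of runs separated by at most `max_gap` below-cutoff bases,
then removal of merged regions shorter than `min_length`. Two conventions
are pinned by oracle tests because the reference tooling leaves them
ambiguous: ties at the cutoff are *included*, and a gap of exactly
`max_gap` *is* merged (anyone comparing against external callers should
check that caller's strictness). Merging precedes the length filter, so
short runs can survive by joining neighbours. The peak score is the maximum
track value inside the peak; summits are not computed because nothing
downstream uses them.

`rolling_mean()` smooths predictions with a centred window, truncated at the
track edges (no NA padding); window 1 is the identity. Typical windows are
50–250 bp for accessibility signal and 250–750 bp for the broader histone
mark. Smoothing is applied at evaluation/prediction time only and never
baked into stored tracks, keeping raw predictions auditable.

## Evaluation

* `pearson_r()` adds 1e-8 to the denominator, so constant inputs give 0
  rather than a division by zero.
* Peak agreement is base-wise: peaks become 0/1 masks, `base_confusion()`
  counts TP/FP/FN over valid positions (flagged sequences are excluded
  entirely), and `prf1()` applies the standard definitions with the
  convention that a zero denominator yields 0 — so F1 is 0, never NaN, when
  nothing is called.
* `pr_curve()` sweeps the peak-calling cutoff over a grid (the bundled grids
  are 1–25 step 1; 1 then 5–200 step 5; and 1 then 5–100 step 5), producing
  one precision/recall point per cutoff; AUPRC is the trapezoidal integral
  over recall-sorted points. The no-peak regime (cutoff above the track
  maximum) is recorded as precision = recall = 0 by convention. The baseline
  AUPRC is the fraction of positive bases — what an uninformative predictor
  would score.
* `meta_profile()` averages coverage over ±3 kbp windows around anchors
  (transcription start sites in real data, planted sites in synthetic data),
  reading minus-strand anchors right-to-left. The enrichment QC passes a
  dataset when the profile maximum is at least 2.5× the background;
  "background" is defined here as the median over the two outermost quarters
  of the window — a definition of ours (the criterion itself does not fix
  one), configurable via `flank_fraction`.

## The synthetic-data generator

`synthetic_spec()` describes the desk-scale study conditions: 64 sequences
of 8192 bp of i.i.d. uniform background, a fixed 12-bp motif planted at 2
random, well-separated sites per sequence on random strands, an
accessibility bump (width 400 bp) centred on each site, a broader histone
bump (width 1000 bp) shifted 400 bp downstream in the site's strand
direction — the canonical promoter geometry of an accessible region at the
transcription start flanked by H3K4me3 over the gene-body start — and
per-base Poisson sampling around `background_rate = 0.5` with
`peak_height = 8`. The bump is a Gaussian truncated at ±2σ with σ = width/4.
These defaults put the positive (peak-base) fraction in the mid-single-digit
percent range for the accessibility track, with the histone mark roughly
twice as abundant, echoing the class balance of real datasets. Truth peaks
are the full-width-at-half-maximum regions of the noiseless expectation.

Tests are chunked at 1024 bp (the 21384 bp default remains the production
setting); the end-to-end suite trains a small BiHybrid
(filters 32/24/32, kernel 21, step 2, two BiLSTM layers of 16 units,
dropout 0.3, batch 16, learning rate 1e-2, 8 epochs) on the accessibility
track of this dataset and requires validation Pearson ≥ 0.3 plus an AUPRC
above the positives-fraction baseline for a majority of three seeds. The
standalone acceptance run (`scripts/acceptance.R`), which regenerates the
dataset under a caller-supplied seed and therefore faces more variation,
uses a wider first layer (48 filters) and 12 epochs for extra headroom. For
calibration: the correlation between the true rates and their own Poisson
draws — the noise ceiling no model can beat — is about 0.85 under these
conditions.

What the generator does *not* emulate: GC bias, nucleosome positioning,
fragment-length structure, mappability artefacts, replicate variability,
motif degeneracy, or any dependence of signal on sequence context beyond the
planted motif. Passing the end-to-end test therefore demonstrates that the
pipeline is correct and that the architectures can learn a
motif-conditioned, spatially structured Poisson signal — it says nothing
about prediction quality on real genomes, which depends on data volume and
diversity far beyond desk scale.

## Numerical and degenerate-input choices

* Padded coverage positions carry the sentinel −1 in containers and are
  masked everywhere; perturbing masked values changes no result (tested at
  tolerance 0).
* An all-masked batch, a peak-less `prf1` denominator, an empty anchor set
  and a zero QC background all have defined behaviour (error, 0, error, and
  an infinite passing ratio, respectively) rather than NaN.
* Batch-norm uses ε = 1e-5 and momentum 0.1; Adam uses the standard
  β = (0.9, 0.999), ε = 1e-8. LSTM forget-gate biases initialise to 1;
  convolutions use He initialisation.
* Reads shifted past a sequence edge are moved back just enough to stay in
  bounds (length preserved) rather than being truncated or dropped.
* All randomness (genome generation, Poisson sampling, splits, shuffling,
  dropout, initialisation) flows from explicit seeds; training twice with
  the same seed yields bit-identical checkpoints in single-threaded BLAS.

## Known limitations

* The network runs on the CPU in base R; it is sized for method validation,
  not for training on whole plant genomes.
* Fragment (paired-end) counting, input-sample normalisation and external
  peak-caller integration are out of scope; experimental peak sets enter as
  BED input.
* The intra-species splitter warns and returns an empty validation set for
  single-sequence genomes rather than splitting within a sequence.
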