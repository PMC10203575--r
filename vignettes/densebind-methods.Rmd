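---
title: "Models and methods in densebind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in densebind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It complements the function reference: here we
describe the models and the judgement calls, not the call signatures.

## The classification problem

A TFBS dataset is a set of fixed-length DNA windows labelled by whether a
transcription factor binds them. Positives come from assay peaks: each
peak is re-centred on its summit (or midpoint when no summit is recorded)
and extended 250 bp each side, giving half-open windows `[c - 250, c + 250)`
of exactly 500 bp. We use the half-open convention because it keeps window
length even and matches BED coordinates; the alternative reading
("summit plus 250 each side inclusive", 501 bp) is available by setting
`flank` differently, but 500 bp is the package convention throughout.
Negatives are random genomic windows of the same length and number,
rejected if they overlap any exclusion interval by a single base or
contain more than 10% ambiguous bases. The N-content cap and the retry
budget (`max_tries = 50 n`) are guards against assembly gaps and
unbounded rejection loops; they are not biologically motivated thresholds.
Samples are pooled and split uniformly at random, 80% training / 20% test.

Strand handling: the classifier sees the given strand only; there is no
reverse-complement augmentation. Motif scanning (below) handles strand
explicitly instead.

## The DenseNet classifier

The model input is one-hot DNA (`A,C,G,T` channels; `N` is an all-zero
row). The architecture is the densely connected convolutional design, in
one dimension:

* a stem of two width-3 convolutions with 64 filters each, followed by one
  average pooling of stride 2;
* four dense blocks with 6, 12, 24 and 16 dense layers; each dense layer
  is a pre-activated bottleneck — batch normalization, ReLU, width-1
  convolution to `4 x growth_rate` channels, batch normalization, ReLU,
  width-3 convolution to `growth_rate` channels — whose output is
  concatenated onto every earlier output in its block, so channels grow
  linearly (`c_in + l * growth_rate` after layer `l`);
* transition layers between blocks: width-1 convolution compressing
  channels by 0.5, then average pooling of stride 2;
* a final batch normalization and ReLU, a flatten, and a single
  fully-connected sigmoid unit.

The block pattern 6/12/24/16 is the DenseNet-121 recipe; for the knobs the
pattern itself does not pin down (growth rate, bottleneck width,
compression, normalization placement, loss, optimizer) we take the
canonical DenseNet-121 values:
growth 32, bottleneck factor 4, compression 0.5, pre-activation ordering,
binary cross-entropy with Adam. Padding is "same" everywhere so only
pooling changes length; for a 500 bp input the length trace is
500 → 250 → 125 → 62 → 31. One open point we resolved explicitly: the two
stem convolutions share a single pooling after both (not one each), and no
dropout is used anywhere.

Training runs minibatches of 64 at learning rate 0.001 for at most 80
epochs, with a 10% validation split, early stopping on validation loss
(patience 5) and restoration of the best weights. The epoch cap alone does not prevent overfitting at desk scale, so early
stopping is on by default; the cap is still honoured.
All randomness (initialization, shuffling, splits) flows from one seed in
the spec, so a fixed seed reproduces a fit bit-for-bit.

The whole engine — im2col convolution on BLAS matrix products, batch
normalization with running inference statistics, dense-connectivity
bookkeeping, Adam, and backpropagation through to the input layer — is
implemented in R in this package. Correctness is pinned by tests that
compare every analytic gradient (parameters and inputs) against central
finite differences, and by the channel-accounting law asserted on the
built graph.

## Interpretation methods

All three methods interrogate a trained model `f` about one sequence `x`.

**Contribution scores.** We attribute `f(x) - mean_r f(r)` to individual
bases, where the references `r` are dinucleotide-preserving shuffles of
`x` (uniform Eulerian shuffles, so the full 16-entry dinucleotide count
table — and hence base composition and first/last base — is conserved
exactly). The attribution backend is integrated gradients along the
straight path from each reference to `x`, midpoint rule with 25 steps,
averaged over 10 references. Ten references is a pragmatic default; the contract the package commits
to is
*reference-based attribution with approximate completeness*:
`|sum(scores) - (f(x) - mean_r f(r))| <= 0.1 |f(x) - mean_r f(r)| + 0.01`,
asserted in the test suite. For an additive (linear) scorer the
decomposition is exact at any step count, which the suite also checks
against a closed-form oracle.

**Tiling deletion.** Windows of 10 bp at 1 bp steps are replaced by `N`
(all-zero input rows) and the drop `f(x) - f(x_masked)` is recorded per
window start; a high positive delta marks bases the prediction depends on.
Masking-by-N is the primary reading; a scramble mode (window content
dinucleotide-shuffled, averaged over 10 shuffles) is available where a
composition-preserving perturbation is preferred. Sign convention: deltas
are "wild type minus edited" so that important windows score positive.

**Saturation mutagenesis.** All `3L` single-base mutants are evaluated and
`delta[i, b] = f(mutant) - f(x)` recorded, reference cells fixed at zero.
For a motif the model has truly learned, |delta| concentrates inside the
motif instance — the planted-motif suite requires the inside/outside mean
ratio to exceed 5.

**Seqlets.** Candidate motif instances are maximal runs of the smoothed
absolute attribution track above its 85th percentile, extended by 5 bp
flanks and merged when overlapping. The smoothing window (15) and flank (5) follow the TF-MoDISco seqlet
settings; the percentile threshold reinterprets that tool's target
seqlet FDR of 0.15, whose proper null-model calibration belongs to the
full motif-discovery pipeline and is out of scope here. This simplification finds
high-attribution segments; it does not cluster or align them into motifs.

## Global importance analysis

GIA measures a motif's population-level effect: embed the literal motif at
the 70th, 170th, 270th, 370th and 470th bp (1-based starts; 0-based
offsets 69…469) of each of 1000 background sequences, and average

```
local(x) = mean_p f(embed(x, m, p)) - f(x),    GI(m) = mean_x local(x)
```

The sign convention makes a binding-promoting motif positive. Backgrounds
default to held-out negatives; synthetic backgrounds are accepted. The
single-nucleotide GIA map evaluates every single-base mutant `m'` of the
motif and reports `GI(m') - GI(m)` per position and base. For PWMs, the
embedded fragment is the top-affinity k-mer (per-column argmax, ties
broken A < C < G < T).

Bookkeeping invariants asserted in tests: GI equals the mean of the local
importances exactly; GI is invariant to the order of backgrounds and
positions; and for an additive position-weight scorer GIA equals the
closed-form score difference to float tolerance.

## PWM scanning and co-occurrence

PWMs parse from JASPAR and MEME-minimal files; a total pseudocount of 0.8,
split by the background, keeps every probability positive (0.8 is a
common scanning default). Windows are
scored by log2 odds against the background and called at a threshold
calibrated from the *exact* distribution of the score of a random
background-distributed w-mer: per-column scores are placed on a shared
integer lattice (1000 steps across the total score range) and convolved
column by column; for widths up to 8 the package enumerates all `4^w`
words instead, which is exact without discretization. The threshold is
the smallest lattice score whose tail probability is at most `p.cutoff`
(default 1e-05). When even the maximal score is more probable than the
cutoff — unavoidable for short motifs, since a single 8-mer already has
background probability `4^-8 ≈ 1.5e-5` — the maximal score is used and a
warning logged. The dynamic-programming tail is tested against brute-force
enumeration on the same lattice to 1e-12.

Both strands are scanned by default (the reverse-complement matrix runs
over the forward sequence, so minus-strand hits are reported in forward
coordinates); strand handling is recorded in the scan configuration so a
single-strand analysis is one flag away. A sample "contains" a motif when it has at least one hit; two
motifs' presence cross-tabulates each sample set into neither / only-A /
only-B / both, with fractions over all samples. Total instance counts
remain available separately from the binary presence calls. The six
aggregation schemes (M1-SUM, M1-MAX, SUM-SUM, MAX-SUM, SUM-MAX, MAX-MAX)
reduce unthresholded per-position score tracks of up to five PWMs to one
scalar per sequence; "sum of position scores" is the plain sum over all
offsets, with no pre-aggregation thresholding.

## Evaluation metrics

ROC-AUC uses the rank (Mann–Whitney) formulation with midranks for ties —
equivalently the probability that a random positive outscores a random
negative, ties counted half. Thresholded metrics (TPR/FPR/PPV/NPV/recall)
call a sample positive at score ≥ 0.5 by default (the sigmoid convention;
the threshold is an argument). Metrics with zero denominators are
reported as `NA`, never silently as 0. The suite pins the identities
`recall = TPR`, monotone invariance of AUC, and the complement identity
`AUC(s) + AUC(-s) = 1` for tie-free scores, and cross-checks the AUC
against an independent reference implementation.

## The synthetic benchmark: what it does and does not emulate

`make_benchmark()` plants a literal 8-mer (or PWM samples) at uniform
random offsets in i.i.d. background sequences with a symmetric GC split —
by default 2000 positives and 2000 negatives of 500 bp with
`GCACGTGC` planted in every positive, the study condition of the
integration suite. The generator records every plant, so tiling deletion,
mutagenesis, attribution and GIA can be scored against exact ground
truth.

What it deliberately does not model: dinucleotide and repeat structure of
real intergenic DNA, peak-strength gradients, partially degenerate sites,
flanking-sequence preferences, or cooperative multi-motif grammars. A
passing planted-motif suite therefore demonstrates that the machinery
recovers a known signal through the full pipeline — not that any
particular biological dataset will reach the same operating point.

## Desk-scale choices

The integration suite trains a deliberately small instance of the
architecture — blocks `[1, 1, 1, 1]`, growth 8, stem 16 filters, learning
rate 0.01, at most 14 epochs — on the 2000+2000 benchmark. Two of these
choices deserve a note. The stem width and epoch cap simply size the fit
to the problem. The learning rate is raised above the 0.001 default
because, at this model scale, 0.001 lets the positional head memorize the
training set before the convolutional filters discover the
translation-invariant motif feature; at 0.01 the filters win. The
package defaults remain the published full-scale values (stem 64, blocks
6/12/24/16, growth 32, learning rate 0.001, 80 epochs); nothing in the
package depends on the small instance beyond the tests.

## Known limitations

* Attribution is integrated gradients, not DeepLIFT's rescale rules; the
  contract (reference sequences, approximate completeness) is the same,
  and the backend is swappable behind `contribution_scores()`.
* Seqlet extraction stops at segment finding; no clustering, alignment, or
  database matching.
* The scanner's p-value calibration assumes an i.i.d. background; no
  higher-order null, and no q-value machinery.
* Training is CPU-bound and single-threaded R + BLAS; the full-scale
  default spec is provided and correct, but fitting it on large datasets
  is outside what this implementation is sized for.
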