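---
title: "Predicting disorder-mediated RNA-, DNA- and protein-binding residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disorder-mediated RNA-, DNA- and protein-binding residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbind)
```

## The problem

Intrinsically disordered regions (IDRs) lack a stable fold yet mediate many
interactions with RNA, DNA and other proteins. Predictors built on crystal
structures target *ordered* binding interfaces and miss these disorder-
mediated sites. `idrbind` predicts, from sequence alone, a per-residue
propensity in $[0,1]$ for each of three disorder-mediated functions —
RNA-binding, DNA-binding and protein-binding — and calls binding regions of
at least 4 consecutive residues, the conventional minimum length of an
annotated IDR.

## Model

The predictor is a four-stage pipeline.

**1. Profile channels.** A protein of length $n$ becomes a set of
real-valued channels of length $n$: one channel per amino-acid scale in the
working scale set (17 classical physicochemical scales are bundled —
hydropathy, hydrophilicity, charge, polarity, bulkiness, flexibility,
helix/sheet/turn propensity, disorder propensity, ...), all min–max
normalized to $[0,1]$; 20 windowed amino-acid composition channels; a
windowed Shannon-entropy complexity channel
$H_i = -\sum_a f_a \log_2 f_a / \log_2 20$; three putative-disorder channels;
and three secondary-structure channels. Disorder and secondary structure are
*providers*: externally computed scores can be injected from a TSV, and the
bundled defaults (smoothed disorder-propensity and Chou–Fasman profiles over
windows of 21/9/41 and 7 residues) keep the pipeline dependency-free. The
bundled providers are fast surrogates whose smoothing windows match the
long/short/globular semantics; they do not re-implement any published
disorder predictor.

**2. Contrast features.** Each function uses a sliding window of odd size
$ws$, by default the nearest-rank 20th centile of that function's training
region lengths (decremented to odd, clamped to $\ge 5$); without training
lengths the defaults are $ws = 55$ (RNA), $21$ (DNA) and $33$ (protein).
From each channel two features are derived per residue: the truncated window
mean, and the *near-vs-remote contrast* — the mean over the $(ws-1)/2$
central residues minus the mean over the $\lfloor (ws-1)/4 \rfloor$ residues
pooled from the two window ends. Since $(ws-1)/2$ is even for odd $ws$, the
near block is rounded up to the nearest odd count so it stays centered; the
remote means are pooled over both ends, and a terminus-truncated window uses
whatever remote residues survive (zero if none). Candidate features are
filtered in two stages: *relevance* keeps features with single-feature
$\max(\mathrm{AUC}, 1-\mathrm{AUC}) \ge 0.55$, and *redundancy* greedily
drops features with $|r| > 0.7$ to an already-kept feature, scanning by
descending relevance with ties broken by feature id. If nothing passes
relevance the trainer falls back to all candidates with a warning rather
than emitting an untrainable model.

**3. Ridge logistic regression.** One model per function maximizes the
L2-penalized log-likelihood (intercept unpenalized, $\lambda = 1$ by default
on features standardized to zero mean and unit variance; an internal 4-fold
grouped CV over a $\lambda$ grid is available). Training labels follow the
assessment convention: positives are residues annotated with the target
function, negatives are *all* other residues, other disordered and ordered
alike. Optimization is damped Newton from a zero start to gradient norm
$10^{-8}$; the problem is convex, so training is deterministic and the
objective trace is non-increasing. Residues marked `X` are excluded from
training but still receive predictions (their scale values are imputed with
the scale mean).

**4. Homology transfer.** The query is aligned against the annotated
training library (builtin local alignment with BLOSUM62 and affine gaps
11/1; a Karlin–Altschul-style E-value $E = Kmn\,e^{-\lambda S}$ with gapped
constants $\lambda = 0.267$, $K = 0.041$ over the total library length; or a
12-column tabular file from any standard tool). If the best hit has
$E < 0.1$, query positions aligned to binding-annotated subject positions
receive a binary transferred label, and the final propensity is
$(1 + p_i)/2$ at transferred residues and $p_i$ elsewhere — the transfer can
only raise a propensity. Setting the cut-off to 0 disables the layer
exactly, which is the ablation switch used in testing. An optional
calibration routine scans cut-off candidates by leave-one-out transfer,
maximizing the mean TP-rate/FP-rate ratio. Only the single best hit is used
by default (`use_all_hits` exposes the alternative). Tabular hits carry no
gap structure, so their position maps are the ungapped linear maps over the
aligned spans — a documented approximation; the builtin engine produces
exact maps.

## Region calls and evaluation

Propensities are binarized at 0.5 (ties positive — the convention is
$p \ge$ cut-off) and maximal positive runs of $\ge 4$ residues become
regions; a protein is a binder for a function iff it has at least one
region. Evaluation is per-residue: ROC curves sweep all distinct scores with
half-credit ties, so the trapezoidal area equals the Mann–Whitney statistic;
TP-rate at a fixed FP-rate (0.1 by default) is linearly interpolated between
ROC vertices (the nearest-operating-point alternative was rejected as
discontinuous). Significance of AUC differences uses subset resampling: 10
random halves of the proteins, both predictors' AUCs per half, then a
t-test iff both 10-vectors pass Anderson–Darling normality at 0.05 and a
Wilcoxon rank-sum test otherwise. False-positive rates on non-binding
regions are measured on control regions sampled to match the positive
regions' count and length multiset, drawn either from other-function
disordered regions or from non-disordered regions. The proteome-level
module reuses the same resampling comparison for overlap with reference
binder sets, localization enrichment (terms under 2% of the annotation
count are dropped first), promiscuity–region-count correlation (PCC between
the region count $k$ and the mean interaction degree at $k$, against a
baseline with permuted $k$), and linear-motif overlap (motifs in disorder
that intersect a predicted protein-binding region by $\ge 1$ residue).
Statistics with empty denominators are reported as `NA` with counts, never
silently as zero.

## The synthetic world

`simulate_corpus()` emulates a curated disorder corpus so that every stage
is testable offline. Defaults, chosen once: 200 proteins of 100–400
residues; disordered segments drawn to a 40% disorder content with a
composition enriching P/E/S/K/Q/G and depleting W/C/F/I/Y/V (the classic
disorder bias); binding regions log-uniform on $[4, 60/25/40]$ placed inside
disordered runs, covering 5%/10%/30% of disordered residues for
RNA/DNA/protein — mirroring the strong protein > DNA > RNA ordering of
curated annotations; 10% of proteins duplicated with 10% point mutations to
exercise the transfer layer. The binding signal is compositional: residues
inside binding regions are redrawn from an exponentially tilted disordered
composition whose mean on a designated scale (isoelectric point for RNA,
net charge for DNA, hydropathy for protein) is shifted by `effect_size`
standard deviations; the tilt parameter is solved by root finding, and an
unattainable shift errors rather than saturating. A fixed seed gives a
byte-identical corpus.

What a green end-to-end test establishes — and what it does not. With
`effect_size = 1`, held-out whole-set AUC exceeds 0.70 for each function:
the pipeline detects a planted 1-SD compositional signal. It does **not**
establish performance on real proteins, where the signal is weaker, the
annotation incomplete, and homology structure richer. Conversely, at
`effect_size = 0` the held-out AUC does *not* fall to 0.5: binding positives
are confined to composition-biased disordered segments by the generator's
own invariant, so any disorder-sensitive feature separates them from the
ordered majority (measured null AUCs ≈ 0.68–0.84), and even within
disordered residues, long regions placed uniformly inside runs sit
preferentially in run interiors, which window features detect. The
corresponding null-calibration acceptance check is therefore expected to
fail and is left failing deliberately; the meaningful null calibrations are
the label-independent-feature check (CV AUC ≈ 0.5) and the resampling-test
rejection rate (≈ 5% under the null), both green.

## Numerical choices and degenerate inputs

Min–max normalization maps a constant scale to all 0.5, the same value used
to impute `X`. Windows truncate at termini rather than pad. The window
denominator includes `X` positions, so composition rows sum to 1 only in
`X`-free windows; entropy excludes `X` from counts and an all-`X` window has
complexity 0. An empty remote pool yields contrast 0. Standardization of a
constant feature column uses SD 1 to avoid division by zero. Model files
store 17 significant digits so propensities round-trip bit-exactly.
Sequences shorter than 5 residues are predicted with fully truncated
windows and a warning. Ratios against a zero-median random baseline are
reported as 0 (when the observed statistic is also zero) or `NA`, never
fabricated. Sampling "half" of a set always rounds down and samples without
replacement.

## Known limitations

The bundled scale library is a documented default, not a claim about which
scales an optimal model would select; the selection machinery, not the
membership list, is the contract. Bundled disorder/secondary-structure
providers are smoothing surrogates — inject real predictor outputs through
the file provider for serious use. The builtin aligner's E-values use fixed
gapped Karlin–Altschul constants rather than sequence-specific estimation.
GO-hierarchy resolution, database downloads and webserver functionality are
out of scope: the proteome module consumes pre-resolved ID lists and tables.
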