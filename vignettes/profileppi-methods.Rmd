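---
title: "Predicting protein-protein interactions from evolutionary profiles: methods and design"
author: "ProfilePPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from evolutionary profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whether two proteins physically interact is expensive to establish
experimentally, so sequence-based classifiers are widely used to triage
candidate pairs. ProfilePPI implements one such pipeline built entirely on
*evolutionary* sequence information: each protein is represented by its
position-specific scoring matrix (PSSM), a learned low-dimensional
embedding of that profile is computed with a denoising autoencoder, and a
gradient-boosted tree classifier scores concatenated pair embeddings.
The package also contains everything needed to evaluate such a pipeline
honestly — stratified cross-validation with leakage-free feature
learning, the standard ACC/PE/SN/MCC/AUC panel, an ablation harness, and
a synthetic benchmark generator with a planted, tunable signal.

## From sequence to a fixed-size profile

A PSSM is an $L \times 20$ matrix $P$ of log-odds scores, one row per
residue and one column per standard amino acid (columns are kept in the
native PSI-BLAST order throughout; files with permuted headers are
re-mapped on read). Because $L$ varies per protein, $P$ is compressed to
a fixed $20 \times 20$ matrix by the Gram ("equal-size") transform

$$\hat P = P^\top P, \qquad
  \hat P_{jk} = \sum_{i=1}^{L} P_{ij} P_{ik}.$$

$\hat P$ is symmetric positive semi-definite, independent of row order,
and summarises the co-occurrence structure of the evolutionary scores.
The baseline alternative is zero-padding/truncation: keep the first 20
rows, padding with zero rows when $L < 20$. Truncation takes the
N-terminal rows; the choice of end is a convention, fixed here once so
results are reproducible.

The transform is applied to the raw log-odds scores; min-max scaling to
$[0,1]$ happens once, after the transform, because the autoencoder's
sigmoid decoder can only reconstruct values in that range. Scaling is
per matrix, so no training-set statistics are needed at featurisation
time. A constant matrix maps to all $0.5$ (the scaling is otherwise
undefined there). Note a subtlety: min-max scaling is affine and
preserves symmetry, but *not* positive semi-definiteness (subtracting
a positive constant from every entry can introduce a negative
eigenvalue), so the PSD guarantee is stated for unscaled Gram matrices
only.

Which block of the PSI-BLAST ASCII file feeds the transform is a real
choice: the file carries both integer log-odds and weighted observed
percentages. ProfilePPI uses the log-odds block, the conventional
evolutionary feature. The ASCII parser takes the first 20 numeric
columns; the bundled writer emits the same dialect so profile sets
round-trip bit-exactly (log-odds are integers, which makes exact
round-tripping meaningful).

## The denoising autoencoder

The extractor is a sigmoid feed-forward autoencoder trained to
reconstruct clean inputs from corrupted ones. With corruption
$\tilde x = x + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$,
encoder $y = s(W\tilde x + b)$, decoder $z = s(W'y + b')$, and
$s(t) = 1/(1+e^{-t})$, training minimises the mean squared
reconstruction error $\frac1n \sum_i \lVert x_i - z_i \rVert^2$ against
the *uncorrupted* inputs. At $\sigma = 0$ this degenerates exactly to a
plain autoencoder. Masking corruption (randomly zeroed entries) is
available behind a configuration switch.

Design choices that the mathematics does not fix, made once:

* **Depth.** Default encoder $400 \to 256 \to 128$ with a mirrored
  decoder, trained end-to-end (no layer-wise pretraining). The latent
  width 128 is a package default, not an externally given value.
* **Corruption schedule.** Fresh noise is drawn every epoch — the
  standard denoising regime.
* **Inference.** Feature extraction always encodes clean inputs.
* **Optimiser.** Adam at the configured learning rate (default $10^{-3}$),
  mini-batches of 64, 100 epochs. A single integer seed fixes weight
  initialisation, batch shuffling and noise draws, making training
  bit-reproducible on one machine.
* **Numerical stability.** The logistic function is evaluated in its
  two algebraically equivalent forms on the two half-lines, so it
  saturates cleanly (no overflow) for $|t|$ up to $10^3$ and beyond.

The HOG baseline treats the scaled matrix as a 20x20 grayscale image:
central-difference gradients with edge replication, 5-pixel cells, 2x2
cell blocks with stride one, nine unsigned orientation bins, block-level
L2 normalisation. Orientation votes use hard bin assignment rather than
bilinear interpolation: on a 20x20 input the refinement is noise-level,
and hard bins make the 90-degree-rotation behaviour of the descriptor
exact, which is what the tests pin down.

## Pair encoding and classification

Two protein embeddings $f_a, f_b$ are combined by concatenation
$[f_a \,\|\, f_b]$. Concatenation is order-sensitive while interaction
is symmetric, so the harness trains on both orders of every training
pair and averages the two orders at prediction time; scores are then
exactly symmetric under swapping the pair.

The main classifier is gradient-boosted decision trees (500 iterations,
depth 6, learning rate 0.05, seeded). The ordered target statistic that
ordered boosting uses to encode categorical features without target
leakage,

$$\hat x_i = \frac{\sum_{j<p,\; c_j = c_i} y_j + \alpha p_0}
                   {\left|\{j<p : c_j = c_i\}\right| + \alpha},$$

(visiting the data in a random permutation, so each item sees only
*earlier* labels; the first occurrence of a category receives the pure
prior $p_0$) is implemented and tested as a standalone encoder. The
pipeline's pair features are continuous, so the boosted-tree library is
used directly for fitting; the encoder is exposed for categorical
inputs and validated against a brute-force prefix-counting oracle.
Comparison classifiers — naive Bayes, LDA, RBF-kernel SVM with
probability outputs, a decision tree, and KNN with $k=5$ — run at
library defaults behind the same probability interface. LDA and naive
Bayes cannot digest features that are constant within a class
(structural zeros from zero-padding or empty HOG blocks), so those
columns are screened out at fit time and the kept set is replayed at
prediction time.

Hard labels use a fixed 0.5 threshold. Metrics follow the standard
confusion-count formulas; MCC is algebraically the phi (Pearson)
coefficient of the label/prediction vectors, which the tests verify on
random tables. A metric with a zero denominator is returned as `NaN` —
flagged undefined, never an exception — and fold aggregation skips such
values explicitly. The ROC curve steps once per distinct score and AUC
is its trapezoidal integral, which equals the probability that a random
positive outscores a random negative with ties counted one half; the
tests check this equivalence exhaustively on small inputs.

## Cross-validation protocol

`crossValidate()` uses stratified folds (pair labels balanced to within
one pair per fold). Within each fold the autoencoder is trained **only
on proteins that occur in the training pairs**, then applied to all
proteins; the classifier sees only training pairs. Retraining the
extractor per fold is the defensible protocol: extracting features once
on the full data would leak information from test proteins into the
representation. Per-fold seeds are derived from the harness seed, so a
whole report is reproducible from one integer.

## The synthetic benchmark and what it can show

Real curated PPI datasets require external databases and a PSI-BLAST
run per protein, so the package ships a generator that emulates their
*design*: proteins belong to clusters (a stand-in for subcellular
localisation), each carries a latent compatibility vector centred on
its cluster, positives are sampled from same-cluster pairs with high
latent affinity (above the same-cluster median dot product), and
negatives strictly span clusters — mirroring the differing-localisation
heuristic used to build real negative sets. The signal enters the data
through amino-acid composition: residue sampling probabilities are
$\mathrm{softmax}(\text{separation} \cdot M u)$ for a fixed random
projection $M$, so pseudo-PSSM row statistics — and hence $P^\top P$ —
genuinely carry the latent structure, which makes the autoencoder arm
meaningfully testable rather than only the classifier. At separation 0
the composition is uninformative and downstream AUC sits at chance.

One pitfall surfaced during design and is worth recording: if negatives
are sampled uniformly from cross-cluster pairs, the affinity filter
makes high-affinity proteins appear predominantly in positive pairs.
Protein embeddings are individually recognisable (each protein's
empirical composition and profile noise are stable fingerprints), so a
classifier can score well above chance purely by memorising per-protein
label bias — even at separation 0. The generator therefore samples
negatives with *degree balancing*: cross-cluster pairs are drawn with
probability tilted toward proteins whose positive degree is not yet
matched, so protein identity carries (almost) no label information and
the only learnable signal is the planted one. Remaining transductive
effects (proteins recur across folds, as they do in real benchmarks)
are quantified by the label-permutation null, which the acceptance
checks require to land in the chance band. One residual artifact is
worth knowing about: because balancing fixes each protein's *overall*
label mix, splitting pairs into folds induces a mild negative
correlation between a protein's training-fold and test-fold label bias
(a without-replacement, hypergeometric effect), so zero-separation runs
can dip slightly *below* 0.5 AUC — the classifier memorises a bias that
anti-predicts the held-out pairs. The effect shrinks with pair count
and sequence length and never manufactures spurious positive skill.

Generator defaults: 4 latent dimensions, 3 clusters, within-cluster
latent spread 0.35, projection scale $1/\sqrt{d}$, uniform background
composition, sequence lengths uniform on 50–300 residues (mirroring the
short-protein filter of curated sets), pseudo-PSSM integer noise with
unit standard deviation. These were fixed once, after a single pilot of
the full pipeline at separation 2, and are not tuned per experiment.
A ground-truth sidecar (clusters, latents) is always written for test
assertions; the pipeline never reads it.

What passing these tests does **not** show: the generator plants the
signal in global composition, while real PSSMs carry positional
homology structure, alignment-depth artefacts and sequence-identity
redundancy that are absent here. Synthetic results validate the
machinery and its relative orderings (Gram transform over zero-padding,
learned features over HOG), not absolute real-data performance.

## Problem sizes used by the tests

The headline check runs the study-sized benchmark — 120 proteins,
400+400 pairs, separation 2 — through five-fold cross-validation at
full defaults. Auxiliary checks use configurations chosen for what they
measure: the label-permutation null and the ablation grid use a lighter
autoencoder (64–32 or 128–64 units, 30–40 epochs) and 100–150 boosting
rounds, since chance-level calibration and directional comparisons do
not depend on the heavy defaults; and the separation-response sweep
(150 proteins, 200+200 pairs, three replicate seeds per level) uses
short sequences (50–80 residues) so composition estimates stay noisy
and the AUC response curve is observed away from its ceiling, where a
monotonicity check is informative.

## Known limitations

* Running PSI-BLAST itself is out of scope; the package parses and
  writes its ASCII PSSM format and documents the conventional profile
  settings (three iterations, e-value 0.001) in the README.
* The ordered target statistic is an encoder, not a re-implementation
  of ordered boosting's internals; the boosted-tree library provides
  the fitting.
* Degenerate inputs are handled by convention where a convention is
  required (constant matrix scales to 0.5; undefined metrics are NaN;
  ambiguity residues map to a zero profile row only when explicitly
  allowed), and each convention is pinned by a test.
* KNN probability estimates are vote fractions over 5 neighbours and
  therefore coarse; AUC for the KNN arm is correspondingly step-like.
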