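---
title: "Methods: quantum-inspired feature selection in qgafs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum-inspired feature selection in qgafs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgafs)
```

## The model

`qgafs` implements a quantum-inspired genetic algorithm (QGA) over
fixed-length bitstrings and, on top of it, a wrapper feature-selection stage
for image-classification pipelines. The "quantum" part is a sampling device,
not hardware simulation: each gene $i$ is a qubit, an amplitude pair
$(\alpha_i, \beta_i)$ with $\alpha_i^2 + \beta_i^2 = 1$, and the register of
$m$ qubits induces a product distribution over $\{0,1\}^m$ in which bit $i$
is observed as 1 with probability $\beta_i^2$. One register is kept per
population slot (the "quantum state matrix"). Per generation the algorithm
observes a bitstring from every register, evaluates fitness, rotates each
disagreeing gene of each no-better individual towards the stored best
individual $B$ with the orthogonal gate

$$
\begin{pmatrix}\alpha' \\ \beta'\end{pmatrix} =
\begin{pmatrix}\cos\Delta\theta & -\sin\Delta\theta\\
               \sin\Delta\theta & \ \ \cos\Delta\theta\end{pmatrix}
\begin{pmatrix}\alpha \\ \beta\end{pmatrix},
$$

applies an amplitude-swap mutation, and updates $B$ elitistically. The loop
stops at the generation cap or after a configurable number of stalled
generations.

### Design choices in the open parts of the algorithm

Several parts of this algorithm family are conventionally under-specified,
and the package commits to the following:

* **Rotation-angle policy.** A fixed magnitude $\Delta\theta$ (default
  $0.05\pi$ rad), applied only to genes where the observed bit disagrees
  with $B$ and only for individuals whose fitness does not exceed $B$'s,
  signed to move probability mass towards $B$'s bit. This is the smallest
  policy consistent with "approximate the best individual angularly"; the
  per-gene lookup tables found in parts of the literature add five-plus free
  parameters with no benefit observable at this scale, so they were not
  adopted.
* **Real amplitudes.** Complex amplitudes are admitted by the qubit
  formalism, but the rotation dynamics never leave the real plane, and only
  $\beta^2$ is observable; amplitudes are therefore stored as reals, which
  keeps the normalization invariant trivial to check.
* **Saturation guard.** Rotations are clamped in angle space so that
  $\beta^2$ stays within $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-4}$. Without the guard a gene can rotate past the
  $\beta^2 = 1$ apex and oscillate, or collapse so far that mutation can no
  longer resurrect the other bit value. With it, repeated updates approach
  the target bit monotonically and stop at the bound. Amplitudes
  consequently remain in the first quadrant for the whole run, which is what
  makes the signed-angle rule ("+ towards 1, − towards 0") correct.
* **Mutation operator.** The mutation *rate* (default 1%) needs an
  *operator*; the package uses the quantum-NOT analogue, swapping
  $(\alpha,\beta)\to(\beta,\alpha)$ per gene, which inverts bit
  probabilities and preserves normalization by construction.
* **Elitism and ties.** $B$ is replaced only on strict improvement, so ties
  keep the first-encountered individual and the recorded best-fitness
  trajectory is exactly non-decreasing — an invariant the tests assert on
  stored values, never on recomputation.
* **Initialization.** All genes start at $\alpha=\beta=1/\sqrt2$: the
  uniform superposition, i.e. the maximum-entropy distribution over masks.
* **Defaults for unprinted sizes.** Population 20 and 50 generations are
  the package defaults — large enough that the search reliably matches
  exhaustive search on ≤ 10-bit linear problems, small enough for
  interactive use. Both are ordinary configuration knobs.

Normalization ($|\alpha^2+\beta^2-1| \le 10^{-9}$ per gene) is asserted
inside the main loop after every generation; the worst deviation seen is
reported in the run object. In practice it stays at machine epsilon because
every operation applied is exactly orthogonal or an exact swap.

## The feature-selection stage

QGA-FS encodes a feature subset as the bitstring mask of the columns of an
$n \times d$ feature matrix. The data are first split 80/20 with
stratification; the held-out 20% is read exactly once, by the final
evaluation. On the training portion, a mask's fitness is

$$\mathrm{fitness}(m) = \overline{\mathrm{acc}}_{\mathrm{CV}}(m)
  - \lambda\,\frac{|m|}{d},$$

the stratified $k$-fold (default $k=5$) mean accuracy of a lightweight
surrogate classifier on the masked columns minus a sparsity penalty
(default $\lambda = 0.01$). Folds are drawn once per run, so the fitness
landscape is deterministic and the search is exactly reproducible from the
master seed, which fans out to split/search/head sub-seeds through a fixed
integer derivation.

Choices worth recording:

* **Surrogate classifier.** The default probe is linear discriminant
  analysis rather than multinomial logistic regression. Both are linear
  probes with near-identical decisions on the class-conditional Gaussian
  features this stage assumes, but LDA fits roughly an order of magnitude
  faster, and the wrapper evaluates on the order of $10^3$ masks per run;
  `classifier = "multinom"` remains available. Columns with (near-)zero
  variance — e.g. dead rectified units from the extractor — are dropped
  from the probe fit only, since LDA cannot invert a singular covariance;
  the mask itself is unchanged.
* **Degenerate masks.** The all-zero mask scores 0 without training (the
  fitness must be total for the optimizer), as does a mask on which the
  probe cannot be fit at all.
* **Final model.** The reported metrics come from retraining the classifier
  head — dense(128, ReLU) → dropout(0.5) → softmax — on the training
  portion restricted to the best mask, then a single evaluation on the
  held-out portion. The head is trained with minibatch Adam (learning rate
  0.001, batch 32, ≤ 50 epochs), early stopping on validation loss
  (patience 5, best weights restored) and learning-rate reduction on
  plateau (factor 0.5, patience 5). A stratified 10% of the training
  portion serves as the validation set for these callbacks: the callbacks
  need a validation loss to watch, and 10% is the smallest split that keeps
  per-class counts stable at the sample sizes used here.
* **The head trainer is part of the package.** No dependency provides this
  exact protocol (dropout + Adam + callbacks) for plain feature matrices,
  so it is implemented in base R; at $d \le 10^2$ and $n \le 10^3$ this is
  a few seconds of matrix arithmetic.

## Images and feature extraction

Preprocessing follows the usual transfer-learning contract: bilinear resize
to 128×128 (via `EBImage::resize`), grayscale replicated to three channels,
integer pixel values divided by 255, everything clipped to $[0,1]$, and the
whole map idempotent. The extractor is pluggable behind a small contract
(declared output dimension, deterministic mapping). The packaged default is
a seeded random Gaussian projection of the flattened pixels followed by
rectification — a Johnson–Lindenstrauss-style map that preserves linear
separability of the pixel space with high probability while requiring no
downloads and no GPU. An adapter for a genuine pretrained convolutional
backbone can be dropped in wherever such weights are available; nothing
downstream changes, since the selection stage sees only the feature matrix.

## Synthetic data: what it does and does not emulate

`gen_features()` draws class-conditional Gaussian features: each of $k$
informative columns is assigned one class (round-robin) whose mean is
shifted by $\delta\sigma$ on that column; the remaining $d-k$ columns are
class-independent noise. Each informative feature is thus a noisy
one-vs-rest indicator — individually weak, jointly separating — which is
the regime in which "recover the informative subset" is a well-posed target
for a wrapper search: were the per-feature signal redundant, dropping
informative features would cost nothing and recovery would be undefined.
$\delta = 0$ is the null generator. Labels are balanced to within one
sample, and everything is byte-reproducible from the seed.

`gen_images()` writes PNG directories of geometric motifs (disc, ring,
cross, blank) at fixed positions with intensity jitter and additive pixel
noise, so classes are linearly separable from raw pixels.

What passing tests on these generators shows: that the optimizer finds
optima it provably should, that the wrapper recovers planted signal, that
train/test hygiene holds, and that the metric algebra is exact. What it
does not show: performance on real MRI data — real deep features are
correlated, heteroscedastic and redundant, real classes overlap, and real
informative sets are not planted. The headline accuracies achievable on
public brain-tumor collections with a pretrained backbone are therefore out
of this package's testable scope.

## Metrics

All metrics are computed from the $C\times C$ confusion matrix (rows true,
columns predicted): per-class precision/recall/F1 via one-vs-rest counts,
accuracy as trace/total, Cohen's $\kappa = (p_0-p_e)/(1-p_e)$, and MCC. For
$C>2$ the package reports the covariance generalization of MCC
($n\,\mathrm{tr} - \sum_k t_k p_k$ over the product of marginal deficits),
which reduces *exactly* to the binary formula at $C=2$ — the reduction is
property-tested — and additionally exposes the macro-averaged one-vs-rest
MCC, so both common multiclass readings are available. Zero-denominator
cases (degenerate classes, single-class predictions, $p_e = 1$ without
perfect agreement) uniformly return 0: the metrics must be total functions
even on pathological matrices.

## Problem sizes and tolerances

The test suite and the acceptance script run the study conditions at desk
scale: 20-run batches for stochastic success-rate checks; $n=600$, $d=64$,
$k=8$, $C=3$, $\delta=2$ for feature recovery; $d=8$ with all $2^8-1$ masks
enumerated for the exhaustive-oracle comparison; 120 motif images for the
end-to-end pipeline; 1,000 random confusion matrices against independent
metric oracles at $10^{-12}$; rotation/normalization invariants at
$10^{-12}$/$10^{-9}$. These sizes were chosen so each property is decisively
testable in seconds to tens of seconds on a single CPU.

## Known limitations

* The search assumes a product distribution per register; correlations
  between features are only captured through the shared best individual.
* Fitness is $O(k_{\mathrm{folds}})$ classifier fits per mask; for
  $d \gg 10^2$ or $n \gg 10^4$ the surrogate cost dominates and a cheaper
  probe or subsampled folds would be needed.
* The deceptive trap benchmark is included deliberately as a case the
  rotation-towards-best dynamic can fail: elitist attraction to the
  deceptive basin is a known property of this algorithm family, not a
  defect of the implementation.
* JPEG input is supported through the image-IO backend; the synthetic
  generator emits PNG only.
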