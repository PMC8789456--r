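---
title: "Methods: fusion-based classification of haemorrhage subtypes on CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-based classification of haemorrhage subtypes on CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemofuse)
```

`hemofuse` implements a five-stage pipeline for classifying intracranial
haemorrhage (ICH) subtypes — intraventricular (IVT), intraparenchymal
(IPC), subarachnoid (SAD), epidural (EPI), and subdural (SBD) — on
grayscale CT slices. This vignette is the package's own account of the
science in each stage: the model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and the limitations.

## Denoising: exact median filtering

CT slices carry impulse (salt-and-pepper) and sensor noise; the classic
remedy is the windowed median. The package ships two exact
implementations that agree bit-for-bit:

* `median_filter_naive()` sorts each window (the reference);
* `median_filter_bisection()` keeps, per pixel, a candidate intensity
  range and repeatedly halves it, retaining the half that contains at
  least half of the window's pixels until the range is a single bin.

With an odd window the per-window count is odd (reflect padding keeps it
constant), so the lower median is *the* median, and the bisection's
keep-the-lower-half tie rule reproduces it exactly; the equality is
enforced by a 100-image property test rather than assumed. The window
defaults to 3×3 — CT parenchyma is smooth and larger windows start to
erode thin lesions such as subdural crescents — and the border defaults
to reflect padding, which avoids the dark halo that zero padding paints
along the skull.

## Segmentation: multilevel Otsu driven by seagull optimization

For a histogram with level probabilities $p_i$, thresholds
$t_1 < \dots < t_k$ induce $k+1$ segments with masses $\omega_n$ and mean
intensities $u_n$. The multilevel Otsu criterion is the pairwise
between-class variance

$$ d(t_1,\dots,t_k) \;=\; \sum_{n<m} \omega_n\,\omega_m\,(u_n-u_m)^2, $$

maximized over threshold tuples. Empty segments contribute zero. For
$k=1$ the familiar decomposition
$\sigma^2_{\text{total}} = \sigma^2_{\text{within}} + \sigma^2_{\text{between}}$
holds at every threshold and is tested to $10^{-9}$.

`otsu_exhaustive()` enumerates all tuples (supported for $k \le 3$; ties
broken toward the lexicographically smallest tuple) and serves as the
global-optimum oracle. `otsu_soa()` searches the same objective with the
seagull optimization algorithm (SOA) over $k$ continuous coordinates in
$[1, L-2]$; candidates are sorted and rounded before evaluation, and
candidates whose rounded thresholds collide receive $-\infty$ fitness —
rejection keeps the objective pure rather than silently repairing the
candidate. On 64-level bimodal test images the SOA search recovers the
exhaustive optimum in at least 9 of 10 seeds at $k=1$ and comes within 1%
at $k=2$.

The default is $k=2$ (background / brain tissue / hyperdense lesion),
and the lesion mask is the *highest*-intensity segment, because acute
blood is hyperdense on CT. Both are configurable.

### The SOA update

Each of $m$ agents holds a position $P_s$; the best-so-far position
$P_{bs}$ is elitist (replaced only on strict improvement, so best-so-far
histories are monotone by construction). Per iteration $x$ of
$X_{\max}$:

* control $A = f_c - x f_c / X_{\max}$ decays linearly from $f_c$
  (default 2) to 0;
* per agent, $C_s = A P_s$, $B = 2 A^2 r_d$ with $r_d \sim U[0,1]$, and
  $M_s = B (P_{bs} - P_s)$;
* the distance $D_s = |C_s + M_s|$ (element-wise absolute value: a
  distance is non-negative);
* a spiral draw $\kappa \sim U[0, 2\pi]$, radius $r = u e^{\kappa v}$
  (shape constants $u = v = 1$), and the new position
  $P_s = D_s \cdot (r\cos\kappa)(r\sin\kappa)(r\kappa) + P_{bs}$,
  clipped to the box.

$r_d$ and $\kappa$ are drawn per agent per iteration (maximizing
diversity); the best position is updated synchronously at the end of each
sweep. Objective values that are `NaN`/`NA` are demoted to the worst
fitness; an error is raised only if no agent is finite.

A known limitation worth stating plainly: the update moves every agent
along the ray $\pm D_s$ from $P_{bs}$ with a single scalar spiral factor,
and $D_s$ is component-wise non-negative, so a single step cannot move in
mixed directions relative to the best position. The algorithm still
converges reliably (2-D sphere median best fitness below $10^{-2}$ at
population 30, 300 iterations; $10^{-3}$ accuracy on the 1-D sphere), but
it does not outperform pure random search at an equal evaluation budget
on low-dimensional unimodal objectives — population search earns its keep
here on the multimodal threshold and hyperparameter landscapes, not on
spheres.

## Feature extraction: capsule + inverted-bottleneck fusion

Two encoders are run on the segmented slice and their outputs are
concatenated into one fused vector of length $q = n + m$, 1186 under the
reference configurations. Feature extraction consumes the *masked* image
(filtered intensities inside the lesion mask, zero elsewhere) by default,
with `use_mask = FALSE` to feed the full preprocessed slice.

**Capsule path** (`capsnet_encode()`, $n = 186$). One standard
convolution (8 filters, 9×9, stride 2, ReLU), a primary-capsule strided
convolution (4 capsule maps of dimension 8) whose activations are
reshaped into capsule vectors and squashed,

$$ \mathrm{squash}(v) = \frac{\lVert v\rVert^2}{1+\lVert v\rVert^2}\,
   \frac{v}{\lVert v\rVert}, $$

then dynamic routing to the entity-capsule layer. Routing-by-agreement
initializes logits at zero; each iteration (3 by default) takes a softmax
over output capsules (so couplings sum to one per input capsule — tested
at every iteration), forms each output as the squash of the
coupling-weighted vote sum, and increments each logit by the vote–output
scalar product. The entity layer has 6 capsules of dimension 31 — one
per subtype plus a "no lesion" capsule; the dimension is chosen so that
$6 \times 31 = 186$ combines with the 1000-unit bottleneck head to give
the fused length 1186, the one hard constraint the design honours.

**Bottleneck path** (`bottleneck_encode()`, $m = 1000$). A strided stem
convolution followed by three inverted-bottleneck (MBConv) blocks —
pointwise expansion (×4, SiLU), depthwise 3×3 convolution (same padding,
SiLU), linear pointwise compression, residual when shapes match — then
global average pooling and a linear head to 1000 units. There are no
normalization layers, so all-zero input is handled without guards.

Both encoders are *untrained but seeded*: weights come from a
deterministic He-style initializer, so encodings are reproducible and the
features act as fixed random projections. This is a deliberate desk-scale
choice — the pipeline's discriminative power on synthetic data comes from
lesion geometry surviving the projections, and the classifier (plus its
DHO-tuned hyperparameters) does the supervised work. Random-projection
features of real CT would be much weaker than trained encoders; passing
the synthetic end-to-end test therefore demonstrates the plumbing and the
classifier, not radiological-grade feature learning.

**Entropy selection.** Each fused feature column is discretized into 16
equal-width bins over its observed range and scored by Shannon entropy
$-\sum p \log_2 p$; the `keep` highest-entropy columns (default 250) are
retained, ties to the lower index, constants score zero. Equal-width
binning is the simplest reproducible choice; the bin count only matters
logarithmically for the ranking.

## Hyperparameter tuning: deer hunting optimization

DHO maximizes validation accuracy (the tuning objective) over a box of
classifier hyperparameters — by default $\log_{10} C \in [-1, 3]$ and
$\log_{10}\gamma \in [-5, 1]$. Hunters are guided by a leader $X_l$ (the
elitist best) and a successor $X_s$ (second best of the current
population). Per iteration $j$: wind angle $\theta = 2\pi a$,
$a \sim U[0,1]$; coefficients $Z = \tfrac14 \log(j + 1/j_{\max})\, b$
with $b \sim U[-1,1]$ and $K = 2c$ with $c \sim U[0,1]$; per hunter
$p \sim U[0,2]$. The branch order: $|K| < 1$ takes the successor
(global-search) update $X' = X_s - Zp\,|K X_s - X|$; otherwise $p < 1$
encircles the leader, $X' = X_l - Zp\,|K X_l - X|$; otherwise the angle
update $X' = X_l - p\cos\theta\,|X_l - X|$ widens the search. The angle
used in the third branch is the current iteration's wind angle — the
formulation leaves it open, and this is the documented default. $a, b,
c$ are drawn once per iteration and $p$ per hunter.

A one-point tuning space is evaluated directly and returned; mixed
fixed/free dimensions optimize only the free ones. The tuned
configuration is never worse than the untuned default on the validation
split only in expectation, so the pipeline falls back to the defaults
when tuning is disabled rather than comparing post hoc.

## Classification: fuzzy SVM

The fuzzy SVM weights each sample's slack by a membership
$s_i \in [\sigma, 1]$ ($\sigma = 0.05$), giving the primal
$\min \tfrac12 \lVert w\rVert^2 + C\sum_i s_i \xi_i$ and the dual

$$ \max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j}
   \alpha_i \alpha_j y_i y_j K(x_i, x_j), \qquad
   \sum_i y_i \alpha_i = 0, \quad 0 \le \alpha_i \le s_i C, $$

identical to the C-SVM dual except for the per-sample cap $s_i C$: an
outlier with a small membership simply cannot dominate the boundary.
Memberships default to the centroid-linear scheme
$s_i = 1 - d_i/(d_{\max} + \delta)$ with $d_i$ the distance to the class
centroid and $\delta = 10^{-6} d_{\max}$, clamped to $[\sigma, 1]$; a
uniform scheme ($s_i \equiv 1$) recovers the standard C-SVM exactly,
which is property-tested against an independent reference solver to
$10^{-6}$ on the dual coefficients.

The dual is solved by a sequential-minimal-optimization loop with
maximal-violating-pair working-set selection and per-sample box caps;
termination at KKT gap $10^{-8}$ (solver tolerance), with $10^{-10}$ used
where tests compare against the reference solver at $10^{-6}$. The bias
averages $y_i - f(x_i)$ over free support vectors and falls back to the
KKT midpoint rule (with a warning) when none are free. One caveat on
oracle comparisons: the dual optimum is only determined to roughly
(KKT gap)/$\lambda_{\min}(K)$, so meaningful coefficient-level
comparisons need reasonably conditioned Gram matrices; the test fixtures
are constructed accordingly.

Multiclass uses one-vs-rest (five classes, decision-value argmax, ties to
the earlier class), with memberships recomputed per binary problem. The
default kernel is RBF with $\gamma = 1/(q_{\text{selected}} \cdot
\mathrm{Var}(X))$ when not tuned.

## Evaluation

`confusion()` builds the truth-by-prediction matrix;
`per_class_metrics()` derives one-vs-rest TP/FP/FN/TN per class and
reports sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
TP/(TP+FP), and per-class accuracy (TP+TN)/N — the only accuracy
definition consistent with published per-class tables of this kind. Macro
averages are unweighted means. Zero denominators yield 0 with a
`degenerate` flag. Values are exact internally; `metric_report()` rounds
half-even to 4 decimals only at report time.
`sensitivity_from_counts()` recomputes sensitivity columns directly from
published correct-classification counts, which determine sensitivity (but
not specificity or precision) without the off-diagonal placement.

## The synthetic-data generator

`generate_ich_dataset()` emulates what the pipeline needs from CT and
nothing more: an elliptical skull ring, smoothly varying parenchyma, and
one hyperdense lesion per slice whose geometry depends on the class —
EPI a biconvex lens at the inner skull table, SBD a thin crescent hugging
the skull, IPC a compact parenchymal blob, IVT a small central
(ventricular) blob, SAD two thin curvilinear streaks at mid radius. The
default class counts (IVT 24, IPC 72, SAD 18, EPI 171, SBD 56) mirror
the 341-slice benchmark composition the pipeline targets, scalable by a
factor; the default test size is 64×64 with 512×512 supported.

Intensity design (background 85, tissue 95±5, skull ring 112, lesion
230–250) makes the lesion the unique brightest structure, like a
skull-suppressed slice. This is deliberate: it guarantees that in the
noise-free limit a single Otsu threshold isolates the lesion exactly
(IoU 1 against the ground-truth mask, tested at ≥ 0.95), and that the
low-intensity modes are close enough together that the between-class
criterion always prefers the lesion boundary over splits inside the
background — including for the smallest (ventricular) lesions, whose
mass fraction is below 1%.

Noise is Gaussian (sd 3) followed by salt-and-pepper at rate 0.02
corrupting exactly `round(rate * pixels)` pixels. The geometries are
cartoon proxies motivated by radiological descriptions, not anatomy: no
Hounsfield calibration, no partial-volume effects, no 3-D context, no
real skull texture. A linear classifier on four mask descriptors (area,
eccentricity, boundary-contact fraction, elongation) separates the five
classes at ≥ 90% — the generator guarantees the end-to-end pipeline has
signal to find, so the end-to-end test validates the machinery, not
clinical performance.

## The end-to-end pipeline and problem sizes

`run_pipeline()` chains the stages with a stratified 70/30 train/test
split; when tuning is enabled a stratified quarter of the training part
becomes the validation split for DHO. All randomness descends from the
single config seed (per-image segmentation seeds are derived by offset;
the tuner's seed by a fixed offset), so runs are bit-reproducible.

Default problem sizes were chosen for interactive use: synthetic scale
0.5 (171 slices at 64×64), SOA segmentation with population 15 × 40
iterations per slice, 250 selected features, DHO tuning with 5 hunters ×
8 iterations. A full default run completes in well under a minute on a
single core; the test suite's end-to-end check uses the same
configuration at seed 0 and requires held-out macro sensitivity ≥ 0.85.

## Known limitations

* The encoders are untrained random projections; real-data performance
  would require the optional training loop and real CT volumes, both out
  of scope.
* SOA does not beat equal-budget random search on low-dimensional
  unimodal objectives (see above); it is used where the landscape is
  genuinely multimodal.
* The exhaustive Otsu oracle is limited to $k \le 3$ by combinatorics.
* JPEG input is not supported (PNG and NIfTI only).
* On histograms whose modes are extremely narrow, the between-class
  criterion is flat between the modes to near machine precision, and the
  argmax over that plateau is decided by floating-point noise; the
  package reports the lexicographically smallest maximizer.
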