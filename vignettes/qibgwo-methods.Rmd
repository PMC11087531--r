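---
title: "Quantum-inspired binary grey wolf optimization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired binary grey wolf optimization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qibgwo)
```

This vignette is the package's own account of the methods it implements:
the pack-based optimizers, the binary and quantum-inspired decodings, the
lambda-scaled RBF support vector machine and its optimizer-driven tuning,
the wrapper feature-selection fitness, the evaluation machinery, the
mammogram preprocessing chain, and the synthetic generators that make all
of it testable offline.  It also records the design decisions that were
genuinely open, and what the synthetic experiments do and do not show
about real mammography data.

## The grey wolf optimizer and its binary flag variant

A pack of $n$ wolves searches a bounded box.  After every evaluation the
three best wolves become the leaders $\alpha$, $\beta$, $\delta$ (ties
broken by lower wolf index, so runs are deterministic), and every wolf
moves to the mean of three leader-guided candidates:

$$K_L = |C_L \odot X_L - X|, \qquad
  X_L' = X_L - A_L \odot K_L, \qquad
  X(t+1) = \tfrac13 (X_\alpha' + X_\beta' + X_\delta'),$$

with $A = 2 a r_1 - a$, $C = 2 r_2$, $r_1, r_2 \sim U[0,1]^d$ drawn
fresh per leader per wolf per iteration, and the exploration coefficient
$a = 2 (1 - t/T)$ decaying linearly from 2 to 0.  Positions are clamped
to the box after each update.  One fixed draw order (leaders inner,
wolves outer) makes runs bit-reproducible under a seed.

The reported trajectory is the running best over *everything evaluated*
(elitism), so it is non-increasing by construction even though the pack
itself is greedy and keeps no archive.

The binary variant (`bgwo()`) runs the same dynamics on the unit box and
decodes a position to bits with the flag rule: component $> 0.5$ reads 1
(strictly).  One numerical pathology matters here: on the closed unit
box the origin is absorbing.  If a leader and a wolf both reach exactly
0 in a component, $K = |C \cdot 0 - 0| = 0$ and that component can never
leave 0 again; in practice early high-$a$ excursions clamp many
components to exactly 0 and the search ratchets toward all-zero bits.
We therefore re-seed any component that falls below $10^{-6}$ uniformly
on $[0,1]$ — the same anti-absorption rule the quantum variant needs
for its multiplicative update (below).  Without the rule the flag
variant reliably stalls on 20-bit OneMax; with it the test suite
verifies optimum recovery in at least 8 of 10 seeds at population 10 /
200 iterations, and at least 95% recovery on exhaustive 2–4 bit
problems.

## The quantum-inspired variant

Every wolf carries one qubit per dimension, an amplitude pair $(x, y)$
with $x^2 + y^2 = 1$; $y^2$ is the probability of reading bit 1.  All
qubits start in the equal superposition $(1/\sqrt2, 1/\sqrt2)$.  (The
literal amplitude value $1/2$ sometimes quoted for this scheme violates
the normalization condition — $1/4 + 1/4 \ne 1$ — so any
`amplitude_init` pair is normalised to unit length on input.)

Each iteration draws, per leader, $\zeta = \lambda \pi$ with
$\lambda \sim U[0,1]$ and a modulation $\gamma \sim U[0,1]$.  A wolf's
displacement from leader $L$ becomes a rotation angle

$$\theta_L = \zeta_L \, \gamma_L \sum_d (X_{L,d} - X_d) \cdot 2\pi,$$

and the wolf's qubits are rotated by the y-axis gate
$R_y(\theta) = \begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta &
\cos\theta\end{pmatrix}$ for each of the three leader angles in
$\alpha, \beta, \delta$ order (y-rotations commute, so this equals one
rotation by the summed angle, which is how it is computed).  The
position then updates multiplicatively, $X \leftarrow X \cdot y^2$, and
decodes by the inclusive threshold: bit 1 where $X \ge y^2$.

Design choices that were open:

* The update equations for the qubit scheme are only written for the
  three leaders; the role of the remaining wolves is unstated.  Here
  *every* wolf carries its own qubit register and rotates toward all
  three leaders, which keeps the population dynamics uniform.
* The multiplicative update has an absorbing state at 0: repeated
  multiplication by $y^2 < 1$ drives every component to zero, after
  which the decode can no longer move.  Components below $10^{-6}$ are
  therefore re-seeded uniformly on $[0,1]$, preserving exploration.
* After each iteration the three leaders' bit vectors are combined by a
  per-position majority vote, and (when `s_threshold` is set, default
  0.4) the leaders' continuous consensus is also binarized through the
  logistic transfer $\mathrm{sigm}(p) = 1/(1+e^{-p})$ at threshold $s$.
  Both consensus candidates are evaluated under the same elitism as the
  pack, so the reported optimum is the best solution *ever evaluated* —
  a property the test suite checks against exhaustive enumeration at
  small dimension.
* Whether the threshold decode compares the pre- or post-update
  position is ambiguous in the scheme's usual description; the
  post-update position is used.

Because $\theta_L$ sums the displacement over dimensions, it is a
*scalar* per wolf–leader pair: the rotation carries no per-bit gradient.
This matters for feature selection (below).

One diagnostic knob, `zeta_scale`, multiplies every $\zeta$; setting it
to 0 freezes all rotation gates, which (with $y^2 = 1$) makes the
decode provably stationary — used as an invariant test.

## Benchmark harness

The ten classical test functions (Sphere, Schwefel 2.22/1.2/2.21,
Rosenbrock; Schwefel, Rastrigin, Ackley, Griewank, Penalized) use their
canonical symmetric boxes and optima; the binary optimizers drive them
through a fixed-point encoding (default 16 bits per coordinate, all-zero
bits = lower bound).  `run_trials()` derives the seed of repetition $r$
as `base_seed + r`, so tables are reproducible.  The statistical battery
is the field's standard one: paired Wilcoxon signed-rank tests (all-zero
difference vectors are flagged degenerate rather than tested), Cohen's
$d$ with the pooled standard deviation, a one-way ANOVA, and Tukey's HSD
gated on a significant omnibus.  No attempt is made to reproduce any
published benchmark table's magnitudes: the per-table configuration
(dimension, budget) behind such tables is typically under-specified, so
the harness reproduces the protocol, not the numbers.

## The lambda-scaled RBF SVM

The classifier kernel is

$$k(a, b) = \exp\!\left(-\frac{\lVert a - b\rVert^2}{\sigma^2}\right)
\cdot \lambda ,$$

a Gaussian of width $\sigma$ rescaled by $\lambda$; $\lambda = 1$ is the
standard Gaussian kernel, and scaling $\lambda$ rescales every Gram
entry linearly (tested, along with symmetry and positive
semi-definiteness).  The margin solver is deliberately not re-invented:
with $\lambda = 1$ the kernel is exactly libsvm's radial kernel with
$\gamma = 1/\sigma^2$ and training is delegated to `e1071::svm`; for
$\lambda \ne 1$ the $\lambda$-scaled Gram matrix is handed to
`kernlab::ksvm` as a precomputed kernel.  The two engines agree on
predictions in the $\lambda \to 1$ limit (tested).  Multiclass problems
use one-vs-all: one binary classifier per class (target class = 1, rest
= 0), prediction by the largest decision value — no probability
calibration.

Hyperparameter search minimizes $1 - \text{cv\_accuracy}$ with
stratified $k$-fold folds (per-class fold sizes differ by at most one,
seed-reproducible).  The default space is the standard RBF grid,
penalty $C \in [2^{-5}, 2^{15}]$ and $\sigma \in [2^{-8}, 2^{8}]$, both
log-scaled; $\lambda$ is fixed at 1 unless explicitly searched, since
the penalty/width pair is what drives RBF-SVM performance.  The
continuous optimizer searches the unit square mapped onto those log
ranges; binary optimizers use the same fixed-point decoding as the
benchmarks.

## Wrapper feature selection

The selection fitness is

$$\text{fitness} = q \, P_r(M) + e \, \frac{|R|}{|C|},
\qquad e = 1 - q,\ q = 0.99,$$

where $P_r(M)$ is the wrapper classifier's cross-validated error rate,
$|R|$ the selected-subset size and $|C|$ the total feature count.  The
error weight dominates by design; the size term only breaks ties among
near-equal-error subsets.  Empty subsets get the sentinel fitness
$1 + e$ (worse than any feasible value) and are never returned.  The
wrapper classifier is the lambda-scaled RBF SVM with fixed mid-range
parameters — width scaled to the masked subset size
($\sigma = \sqrt{k}$, cost 10) so sparse masks get a calibrated kernel —
rather than nested hyperparameter optimization, keeping each fitness
evaluation at the cost of one cross-validation; fitness values are
memoized per mask.

On the recovery design used throughout (5 informative of 30 features,
class-mean separation 2 standard deviations, 300 samples), both binary
optimizers recover the informative features reliably (mean recall
$\ge 0.8$ over 10 seeds, tested).  Their parsimony differs sharply:
the flag variant, whose encircling update acts per component, also
prunes noise features (mean false-selection rate $\le 0.3$, tested),
while the quantum-inspired variant retains noticeably more noise
features because its scalar rotation angle gives it no per-bit
selection pressure — its false-selection rate is therefore not bounded
by the test suite.  This is a real and
instructive limitation of the quantum scheme as formulated, not an
implementation artifact; the recall-oriented acceptance check passes
with either optimizer.

## Evaluation conventions

Confusion-matrix metrics are reported as percentages: ACC, SEN
(recall on positives), SPC (recall on negatives) and MCC.  Two
error-rate conventions circulate in the field's reporting — the
balanced-error form $1 - \tfrac12(\text{SEN} + \text{SPC})/100$ and the
complement form $1 - \text{ACC}/100$ — and published tables do not
always say which they used (the two disagree under class imbalance).
`compute_metrics()` therefore reports both, side by side, and never
silently picks one.  A zero factor in the MCC denominator yields MCC 0
with an explicit degenerate flag.  ROC curves sweep thresholds over the
distinct scores in descending order with ties grouped; the trapezoid
AUC equals the Mann–Whitney pair statistic, which the tests verify by
brute-force pair counting and against pROC.

## Mammogram preprocessing

Input images are Portable Gray Maps (P2/P5, comments tolerated, 8- or
16-bit); the reader/writer is bit-exact on round trip because no
installed package covers the format.  Annotation records follow the
MIAS layout (`reference tissue abnormality [severity x y radius]`);
coordinates use the dataset's bottom-left origin and are converted to
top-left row/column on parse (`row = height - y` in 1-based indices).

The chain per image is: median filter (default 3×3) → contrast-limited
adaptive histogram equalization (default clip 2.0, 8×8 tiles; the
source material names the steps but no parameters, so these are the
common defaults) → one 120×120 region per annotation → random 72×72
patches per region.  Median filtering and CLAHE are delegated to
EBImage; its median filter's edge handling is the library's own rather
than explicit reflective padding — the contracts that matter (constant
images fixed, impulses removed, window 1 = identity, range preserved)
are all tested.  Regions near a border are shifted inside, never
padded, so every region is full-size.  Normal-class images carry no
annotated location, so their region is drawn uniformly over the breast
foreground — Otsu's threshold on the median-filtered image, largest
connected component — which reconciles "random within the image" with
"inside the breast region".  Region size is kept fixed at 120×120 with
the annotation radius retained as metadata only (no radius-dependent
rescaling), since a fixed final size is what the downstream classifier
needs.

## Synthetic generators and what they show

`make_phantom()` produces stylized mammograms: a noisy low-intensity
breast disk (mean 60, noise SD 8 on a 0–255 scale); benign masses as
radially symmetric Gaussian blobs (dense, demarcated, roughly
spherical); malignant masses as the same blob with harmonic boundary
jitter and ~12 narrow angular spiculation ridges (irregular shape,
indistinct boundary).  The benign/malignant contrast is geometric and
measurable: the half-maximum contour circularity $4\pi A / P^2$ of
benign masses exceeds that of malignant ones on average (tested over 50
phantoms).  The default corpus layout mirrors MIAS: 207 normal / 63
benign / 52 malignant 1024×1024 images; the test suite and acceptance
script use 256×256 or smaller images and corpora of 8–40 images to keep
runtimes at desk scale (the sizes used are stated in each test).

`make_feature_table()` draws class-conditional Gaussians: informative
features separated by `mean_shift * noise_sigma` between class means,
the rest identical noise; the generator returns the ground-truth mask,
and the two-sample mean difference recovers the designed separation
within 10% at 500 samples per class (tested).

What passing these tests shows — and does not.  The phantoms exercise
the pipeline's geometry (I/O, coordinate conventions, cropping,
filtering, count conservation) and give the classifier a genuinely
learnable normal-vs-abnormal contrast, so the end-to-end check
(synthetic corpus → preprocessing → patches → tuned SVM → held-out
accuracy $\ge 0.9$) validates the plumbing and the tuning loop.  They
do not contain tissue texture, pectoral muscle, calcification
morphology or acquisition artifacts, and benign/malignant phantom
patches are far more separable than real mammographic masses; nothing
here licenses accuracy claims on clinical data.

## Numerical choices

* Leader ties break to the lower wolf index; runs are bit-reproducible
  under `(seed, config, objective)`.
* Qubit norms are enforced to $10^{-9}$; rotation composition holds to
  $10^{-12}$ (both tested over $10^3$ composed rotations).
* Objectives must return finite scalars; a non-finite value aborts with
  the offending position in the message.
* The x- and z-axis rotation gates are provided as (unitary) matrices
  for completeness but are unused by the optimizer, which is y-gate
  only.  (The x-gate is sometimes printed with a real lower-left entry;
  that form is not unitary, so the canonical complex form is used.)
* Trial summaries (`summarize_trials()`) compute exact column means and
  round only at print time — reported "average" rows in the wild
  sometimes do not equal the mean of their printed column, so the
  package always recomputes.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ft <- make_feature_table(feature_table_spec(seed = 1))
sel <- select_features(ft$x, ft$y, optimizer = "bgwo",
                       fs_spec(classifier_cv = 5),
                       max_iterations = 100, seed = 1)
print(sel)
which(ft$informative_mask)   # ground truth
which(sel$selected)          # recovered
```

Problem sizes used by the shipped checks: sphere convergence at
population 30 / 500 iterations over 10 seeds; exhaustive binary checks
at 2–4 bits over 100 random tables (population 10, 200 iterations);
feature-selection recovery at 5-of-30, $n = 300$, 10 seeds (population
8, 50–100 iterations, 5-fold wrapper CV); the phantom pipeline at
20/10/10 images of 256².
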