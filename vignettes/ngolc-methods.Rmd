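---
title: "Goshawk-inspired optimization and derivative-free GRU training: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goshawk-inspired optimization and derivative-free GRU training: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ngolc implements a population metaheuristic — Northern Goshawk
Optimization (NGO) and its Lévy-flight/chaos variant (NGO-LC) — together
with a neuroevolution pipeline in which the full weight vector of a
small gated recurrent unit (GRU) binary image classifier is the
optimizer's decision variable, trained under a mean-squared-error
fitness. This vignette is the package's account of the underlying
models, the tunable parameters, and the design choices made where the
design was genuinely open.

## The optimizer

A population of $N$ candidate solutions $Z_i \in \mathbb{R}^m$ is
initialized uniformly inside the box and evaluated, giving fitness
$P_i$. Each of $T$ iterations applies two phases to every individual,
both with *greedy (elitist) acceptance*: a candidate replaces the
incumbent only when its objective is strictly better, so the population
best is non-increasing and ties keep the incumbent (which makes
trajectories deterministic under a fixed seed).

**Exploration (prey identification).** Individual $i$ picks a prey
$F_i = Z_k$ with $k$ uniform on $\{1,\dots,N\}\setminus\{i\}$. With a
per-dimension step $r \in (0,1)$ and an intensity factor
$I \in \{1,2\}$ drawn once per individual, the candidate is
$$
z^{new}_{i,j} =
\begin{cases}
z_{i,j} + r\,(f_{i,j} - I\,z_{i,j}) & P_{F_i} < P_i\\
z_{i,j} + r\,(z_{i,j} - f_{i,j}) & \text{otherwise.}
\end{cases}
$$
The $I = 2$ branch is what gives the method its strength on
origin-centered objectives: once the population clusters, the move
$z + r(f - 2z)$ contracts positions toward the origin, and greedy
acceptance keeps only contractions that help.

**Exploitation (pursuit).** A multiplicative local perturbation
$z^{new}_{i,j} = z_{i,j} + R\,(2r - 1)\,z_{i,j}$ with per-dimension
$r \in (0,1)$. In baseline NGO the radius shrinks linearly,
$R = 0.02\,(1 - t/T)$ — the printed form of this schedule is garbled in
the source material, and $(2/100)(1 - t/T)$ is the only reading that
yields a radius decaying from 0.02 to 0, matching the original NGO
publication.

**NGO-LC modifications.** Two substitutions define the variant:

1. *Lévy exploration step.* The uniform step $r$ is replaced by a
   heavy-tailed Mantegna draw
   $\alpha = A / |B|^{1/\tau}$ with $A \sim N(0, \sigma^2)$,
   $B \sim N(0, 1)$ and
   $$
   \sigma = \left[\frac{\Gamma(1+\tau)\sin(\pi\tau/2)}
   {\Gamma((1+\tau)/2)\,\tau\,2^{(\tau-1)/2}}\right]^{1/\tau},
   \qquad \tau = 1.5 .
   $$
   At $\tau = 1.5$, $\sigma \approx 0.6966$; at $\tau = 1$ the
   expression collapses to 1. A $B$ that underflows to zero is redrawn.
   **Granularity:** one scalar Lévy factor is drawn *per individual per
   update* and shared across dimensions. This was a genuinely open
   point; we also implemented an independent draw per coordinate and
   found it destroys the algorithm: per-coordinate heavy-tailed factors
   scramble the direction of the toward-prey move, exploration
   candidates are almost never accepted, and the variant stalls orders
   of magnitude above the baseline. The scalar factor preserves the
   line-search structure of the move (and is the more literal reading
   of a step factor written without a dimension subscript), restoring
   the variant's reported behavior. No extra step-size multiplier is
   applied; oversized steps are handled by clipping to the box.

2. *Chaotic exploitation radius.* The shrinking radius $R$ is replaced
   by the state of the chaotic map
   $\gamma_{i+1} = \gamma_i^2 \sin(\pi \gamma_i)$, initialized
   $\gamma_0 \sim U(0,1)$ per run and advanced once per iteration. The
   map's only attractor on $[0,1]$ is 0 and it reaches numerical zero
   within roughly half a dozen iterations from any start, which would
   permanently disable exploitation; by default a state below
   `chaos_floor` ($10^{-12}$) is therefore replaced by a fresh uniform
   draw. The resulting radius sequence alternates short decaying bursts
   with fresh restarts — a self-scheduling mix of coarse and fine
   pursuit steps. Both the re-seeding and a per-individual chaotic
   state are configuration-exposed (`chaos_reseed`,
   `chaos_per_individual`).

**Other numerical choices.** Candidates are clipped coordinate-wise to
the box before evaluation (the source material is silent on bound
handling). Updates within each phase are *synchronous*: all exploration
candidates are formed against the population as it stood at the start
of the pass, then all exploitation candidates — this is what makes a
whole iteration a handful of matrix operations, and the
injected-draw oracle tests use the same semantics. Non-finite
objective values mark a candidate as rejected and raise a warning at
the end of the run. All randomness flows from a single seed through R's
RNG; identical configuration and seed reproduce the run bitwise.

## The benchmark suite

Twelve analytic objectives validate the optimizer (Sphere,
Schwefel 1.2 / 2.20 / 2.21 / 2.22 / 2.23, Rosenbrock, Step, Sum
Squares, Zakharov, Quartic with additive uniform noise, Powell sum),
each with its conventional box bounds and a known minimum of 0. Two
details worth noting:

* the *Step* function here is the continuous variant
  $\sum (x_i + 0.5)^2$, whose minimum sits at $-0.5 \cdot \mathbf{1}$
  rather than the origin — optimum positions are therefore stored per
  function;
* *Quartic* is implemented exactly as printed in the source table,
  $\sum x_i^4 + \mathrm{rand}(0,1)$, without the conventional $i$
  coefficient; its noise term is drawn from the run's seeded RNG stream
  and can be disabled, which the at-optimum tests do.

The run protocol mirrors the published study: population 100,
900 iterations, 20 independent seeded runs per objective, dimension 30,
summarized as best / mean / standard deviation over runs. A reduced
profile (population 20, 200 iterations, 5 runs) is available via
`fast = TRUE` and is the profile the routine test suite exercises;
the full protocol runs in the acceptance script and the dedicated
protocol tests.

## The GRU classifier and its training

The cell is a four-gate GRU: input, update and reset gates, all
hidden-sized,
$$
i_t, z_t, r_t = \mathrm{sigmoid}(W_\bullet [h_{t-1}, x_t] + b_\bullet),
$$
a candidate state
$\tilde h_t = \tanh(W_h (r_t \odot h_{t-1}) + i_t \odot (W_x x_t) + b)$,
and the convex combination
$h_t = z_t \odot h_{t-1} + (1 - z_t) \odot \tilde h_t$, which keeps
$h_t \in [-1, 1]$ for all inputs. The published cell applies the input
gate multiplicatively to $x_t$ inside the candidate; with a hidden size
different from the input size that product is not dimension-consistent,
and the wiring above — gating the candidate's *projected* input
contribution — is the only placement that preserves both the stated
weight shapes and the gate's stated role. The reset gate feeds the
candidate through $r_t \odot h_{t-1}$, the only wiring consistent with
its definition.

Images enter the network as sequences: a standardized $s \times s$
grayscale raster (Rec. 709 luma) is read row by row — $s$ timesteps of
$s$ features in $[0,1]$. A single affine + sigmoid head on the final
hidden state yields the class probability; the decision threshold is
0.5 and "cancerous" is the positive class.

All weights live in one flat vector (fixed ordering, exact round-trip
codec) and are trained by NGO-LC inside the box $[-2, 2]^{n}$ — the
sigmoid and tanh nonlinearities saturate beyond that range, so a larger
box only adds plateau. The fitness of a weight vector is the plain MSE
$\frac{1}{n}\sum_j (d_j - y_j)^2$ over the training set. The published
objective carries an additional $1/\mathrm{pop}$ prefactor mixing the
per-candidate error with the population size; for a single candidate
that factor is a constant and cannot change the argmin, so it is
dropped. The hidden size defaults to 8, keeping the weight vector near
$10^3$ coordinates — small enough for derivative-free search.

## Preprocessing

Random oversampling duplicates minority-class images uniformly with
replacement until class counts match (87/44 becomes 87/87 by adding 43
duplicates); originals are preserved verbatim and duplicates carry a
provenance tag. The pipeline order is fixed as oversample → split →
augment-the-training-split-only: the source material is silent on
ordering, and augmenting before splitting would leak augmented copies
of test images into training.

The seven augmentation operators use the stated parameters: rescaling
by a factor from $\{0.5, 2, 3\}$; warping by an angle in
$[40°, 60°]$, implemented as a horizontal shear about the image center
(the source says only "geometric transformations that distort"; the
operator is pluggable); random cropping, with the unspecified fraction
fixed at 80% of each side (keeping the label-bearing content with high
probability) and resized back; additive Gaussian noise with
$\sigma = 0.2$ interpreted on the $[0,1]$ intensity scale, clipped;
Gaussian blur with $\sigma = 6$ px (shrunk when the kernel would not
fit a small raster); color jitter with maximum deviations 0.4
(contrast), 0.1 (hue), 0.2 (saturation), 0.3 (brightness), where
hue/saturation act in HSV space and degrade gracefully to
brightness/contrast on grayscale rasters; and integer translation in
$[-50, 50]$ px with zero fill, skipped with a warning when the raster
is smaller than the maximum offset. Every output is clipped to
$[0, 1]$; the whole stage is deterministic under a fixed seed.

The stratified 70/30 split draws
$\lfloor 0.7\,n + 0.5 \rfloor$ training samples overall, allocated per
class by largest remainder with ties favoring the positive class, so
each class's training share is within one sample of 70%.

## Evaluation metrics

Accuracy, sensitivity, specificity, precision, F1 and MCC are computed
from the confusion counts on the ×100 scale. Ratios with a zero
denominator are reported as `NA` rather than 0 or an error, mirroring
how degenerate classifiers (e.g. no predicted positives) are reported
in practice. The MCC numerator as printed in the source
($TP \cdot TN - TP \cdot FN$) violates the coefficient's $\pm 1$
bounds; the standard numerator $TP \cdot TN - FP \cdot FN$ is
implemented and unit-tested against the definition.

## The synthetic image generator

The generator stands in for the real two-folder oral-image collection
(87 cancerous / 44 non-cancerous JPEG photographs), which is external
data. It emulates the features the pipeline actually consumes:
two-class structure in a two-folder JPEG tree, RGB rasters in $[0,1]$,
class imbalance on request, and a label-correlated intensity signal —
"cancerous" images carry a pale elliptical patch (irregular border from
low-order harmonic perturbation, random center, eccentricity and
orientation) whose mean intensity exceeds the mucosa-like textured
background by a configured margin (default 0.3 on the $[0,1]$ scale,
with texture amplitude 0.06 and pixel noise 0.02 — contrasts a reader
would call a clearly visible lesion). Classes are therefore separable
by construction, with a margin the tests verify via a simple
central-intensity threshold classifier.

What it does *not* emulate: anatomical variability, specular
highlights, pose and illumination changes, lesion texture, or any
clinically meaningful morphology. Passing tests on these fixtures shows
the pipeline is wired correctly and that the optimizer can actually
train the network on a learnable signal; it says nothing about
performance on real oral photographs. JPEG output is written at
quality 95; compression perturbs pixels (most visibly in chroma), but
the grayscale channel the classifier consumes survives round-trip
within 2/255 on average per image, and labels are carried by the
folder structure, so round-trips never relabel.

## Problem sizes in tests and the acceptance script

The package's own validation choices: the routine test suite exercises
the optimizer at reduced sizes (populations 5–20, up to 200
iterations, dimensions 2–30) plus the full published protocol on the
three objectives whose published summary rounds to 0.00 (Sphere,
Schwefel 2.22, Powell sum; 20 runs each). The learnability check
trains on 40 synthetic 16×16 images with hidden size 8 under the
reduced optimizer profile (population 20, 200 iterations), asserts
≥ 90% training accuracy, fitness below the 0.25 all-0.5-output
baseline, and superiority over a label-permutation control trained
identically. The acceptance script re-runs the full benchmark protocol
and the fixture experiment from scratch.

## Known limitations

* The optimizer's strength on this suite partly reflects the suite:
  multiplicative pursuit steps and the $I = 2$ exploration branch are
  biased toward the origin, where eleven of the twelve optima sit
  (Rosenbrock and Step are the exceptions). Performance on problems
  with optima far from the origin will be less flattering.
* Derivative-free weight search scales poorly; beyond a few thousand
  weights (larger images or hidden sizes) training quality degrades.
* The baseline NGO implemented here is itself a strong optimizer on
  this suite; the published comparison in which the baseline performs
  poorly is not reproducible from the printed information (competitor
  implementations, seeds and initialization details are not given) and
  is out of scope.
* Metrics on the real oral-cancer image collection are not reproduced:
  the data is external, and the published experiments do not state
  seeds or splits. The synthetic-fixture experiment is a property-based
  substitute, not a reproduction.
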