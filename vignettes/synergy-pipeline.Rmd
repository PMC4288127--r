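---
title: "Extracting and comparing muscle synergies from multichannel EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and comparing muscle synergies from multichannel EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsyn)
```

## The problem

A long-standing hypothesis in motor neuroscience is that the central nervous
system builds complex movements from a small set of modules, or *muscle
synergies*: fixed weightings of muscles driven together by a single
time-varying command. For planar arm movements recorded with surface EMG over
seven shoulder muscles — anterior, median and posterior deltoid (AD, MD, PD),
pectoralis major superior and inferior (PMS, PMI), latissimus dorsi (LD) and
teres major (TM) — a recurring finding is that three modules account for most
of the EMG variance: a *co-contraction* module in which every muscle
participates with the same sign, and two *reciprocal* modules in which
muscles oppose each other according to their horizontal or vertical action.

`emgsyn` implements the full analysis chain used to test this hypothesis on
discrete (point-to-point) and discrete-rhythmic (figure-eight) movements:

1. **synthesis** — a forward model that generates multichannel EMG with the
   statistical structure the analysis assumes, so every downstream stage is
   testable against a known ground truth;
2. **preprocessing** — rectification, envelope smoothing, decimation to the
   kinematic clock, per-movement min/max normalization;
3. **decomposition** — per-movement correlation-matrix PCA, retention of the
   first three components, varimax rotation, component time courses and EMG
   reconstruction;
4. **matching** — k-means clustering of loading vectors pooled across
   movements, with a deterministic conflict-reassignment rule;
5. **inference** — Wilks' lambda MANOVA across conditions with per-muscle
   follow-up ANOVAs, plus a cluster-dispersion ANOVA with a planned
   PCA-versus-varimax contrast.

## The generative model

### Kinematics

A figure eight is a Lissajous curve: two perpendicular oscillators in a 2:1
frequency ratio (two cycles on the short axis per long-axis cycle). With
duration $T$ and $f_0 = 1/T$, the upright ("vertical") figure is

$$h(t) = E(t)\, a_h \sin(2 \cdot 2\pi f_0 t + \phi_h), \qquad
  v(t) = E(t)\, a_v \sin(2\pi f_0 t + \phi_v),$$

with $\phi_h, \phi_v \in \{0, \pi\}$ selected so the trajectory leaves the
center into the requested quadrant (UR, UL, DR, DL); the horizontal figure
swaps the roles of the axes. $E(t)$ is a raised-cosine on/off envelope
(default rise time 10% of the duration) that brings start and end speed to
zero, making the gesture *discrete* in the Hogan–Sternad sense — a pure
Lissajous curve would start at nonzero speed. Velocity is analytic (product
rule), not numerically differentiated. The long-axis amplitude defaults to
0.3 m with a 2:1 long:short ratio and $T = 1.5$ s; the experimental
literature specifies neither figure proportions nor duration ("as fast as
possible"), so these are configurable defaults chosen to give realistic peak
speeds of the order of 1 m/s. Point-to-point movements use the standard
minimum-jerk profile (peak speed $1.875\,d/T$), the default model for rapid
reaching.

### From kinematics to EMG

The ground-truth synergy model is a $7 \times 3$ unit-norm weight matrix $W$
following the sign template of the three modules (all-positive
co-contraction; MD/PD/TM versus AD/PMS/PMI with LD near zero; AD/MD versus
PMI/TM with PD/PMS/LD near zero). Default magnitudes follow the
characteristic per-muscle participation pattern of the three modules. The
module commands are

* $c_1(t)$ — tonic gain times the movement envelope (on during movement,
  off at rest; each trial is padded with 0.5 s of rest so this contrast is
  testable),
* $c_2(t), c_3(t)$ — horizontal and vertical endpoint velocity, each scaled
  to unit peak (the reciprocal commands track the velocity components; for a
  vertical figure eight, $c_2$ oscillates at twice the frequency of $c_3$).

The per-muscle activity envelope is $e_m(t) = b_m + g_m \max(0, [W c(t)]_m)$
— half-wave rectified because muscles pull but cannot push. Raw EMG is the
envelope amplitude-modulating band-limited Gaussian noise (nominal
10–450 Hz at 1 kHz sampling), the simplest generative stand-in for the
surface-EMG interference pattern, plus white measurement noise of standard
deviation `noise_sd` × RMS of the envelope (default 0.05). Per-subject
variability is emulated by jittering the weight magnitudes (default sd 0.05)
while preserving the sign template.

Two deliberate simplifications matter when interpreting test results. The
synthetic envelope is an almost-linear rank-3 mixture, so three components
explain ~99% of its variance, whereas real EMG contains unmodelled
physiological variance (the comparable empirical figure is nearer 83%).
And the half-wave rectification interacts with the initial-direction phase,
so a sensitive MANOVA can detect small direction effects in synthetic
loadings that real data did not show; recovery tests are therefore stated in
terms of cosine similarity to the ground-truth columns, not of null effects.

## Preprocessing choices

* **Envelope filter** — "third-order averaging filter with a 20 ms time
  constant" is implemented as a cascade of three identical first-order
  exponential averagers with unit DC gain, each initialized at the signal's
  first value. By default the cascade runs forward and then backward (zero
  phase) so envelope peaks are not delayed relative to kinematics; a causal
  single-pass mode is available (`causal = TRUE`) since either reading is
  defensible.
* **Alignment** — EMG at 1 kHz is decimated to the 100 Hz kinematic clock by
  bin averaging (the ratio must be an integer).
* **Normalization** — per movement and per channel, $(x - \min)/(\max -
  \min)$, so every channel spans exactly $[0, 1]$; the eight point-to-point
  movements of a subject are concatenated first and normalized once, as a
  single movement set. A constant channel is rejected by name rather than
  silently zeroed, because it would break the unit-variance standardization.
* **Differentiation** — velocity is obtained by local least-squares
  fifth-degree polynomial fits over a sliding 11-sample window (110 ms at
  100 Hz; the window length is not dictated by the method and is
  configurable), with one-sided fits at the edges. Fits use a sample-unit
  abscissa for numerical conditioning.

## Decomposition conventions

Channels are standardized with the population convention (denominator $T$;
immaterial at $T \approx 250$ but fixed for reproducibility), and the
correlation matrix $R = ZZ'/T$ is eigendecomposed. Loadings are reported as
variable–component correlations, $\ell_j = v_j \sqrt{\lambda_j}$, the
factor-analysis convention that puts loadings on the familiar $[-1, 1]$
scale; raw eigenvectors are kept for diagnostics. Scores are unit-variance,
$s_j = v_j' Z/\sqrt{\lambda_j}$, and reconstruction inverts the
standardization: $\hat x = \bar x + \sigma\,(L S)$, which is exact with all
seven components. Eigenvector sign is inherently ambiguous; the canonical
rule makes the largest-magnitude loading of every column positive, and all
cross-trial comparisons that should not depend on sign use $|\cos|$
similarity.

Varimax rotation of the three retained columns uses Kaiser's pairwise
planar-rotation algorithm with Kaiser row-normalization (on by default).
Each pairwise step evaluates the stationary angles of the pair criterion and
takes the maximizing one, so the criterion ascends monotonically;
convergence is declared when a full sweep changes the criterion by less than
`tol` (default 1e-8). The rotation is orthogonal, so row communalities,
total explained variance, and the unit variance of the rotated scores are
all preserved — PCA and varimax describe the same subspace and differ only
in basis.

## Matching components across movements

Because PCA orders components by explained variance, the same physiological
module can surface as the first, second or third component in different
trials. All retained loading vectors (3 per movement) are therefore pooled
and clustered with k-means, $k = 3$: Lloyd's algorithm with k-means++
seeding, best of 50 restarts. Since clustering signed loading vectors could
split a module across the sign ambiguity, sign alignment is interleaved with
assignment: a vector is flipped whenever its dot product with its nearest
centroid is negative. Clusters are then relabelled so cluster $j$ is the one
dominated by rank-$j$ vectors.

When two of a movement's three vectors land in the same cluster (a
*conflict*), the vector with the largest distance from that cluster's
centroid is shifted to the cluster left unassigned for the movement. With
all three vectors in one cluster, the farthest moves first (to the nearest
empty cluster) and the rule is re-applied; exact ties break by within-trial
rank, then trial order, so resolution is fully deterministic and terminates
in at most two moves per movement. The per-flavor conflict census and the
per-vector centroid distances (a 6-level factor, PC1–PC3/VM1–VM3) quantify
which decomposition is more stable across movements.

## Inference

* **Normality screen** — one-sample Kolmogorov–Smirnov with estimated mean
  and sd. Estimated parameters invalidate the plain K-S null distribution,
  so the Lilliefors-corrected p-value is the default; plain K-S mode is kept
  for replicating analyses that used it.
* **MANOVA** — Wilks' $\Lambda = \det(E)/\det(E + H)$ with Rao's F
  approximation; for two groups this is exact with $F(p, N - p - 1)$
  degrees of freedom. Per-muscle one-way follow-up ANOVAs run when the
  MANOVA is significant (gate $\alpha = 0.01$), unadjusted by default with a
  Holm option.
* **Dispersion contrast** — one-way ANOVA of centroid distances over the six
  component levels plus a single planned contrast, weights
  $(+1,+1,+1,-1,-1,-1)/3$, tested on $(1, N - 6)$ df: the overall
  PCA-versus-varimax stability comparison.
* **Absolute-loading ANOVA** — participation of muscles across components is
  tested with a fixed-effects two-way ANOVA (muscle × component, trials as
  replicates); full repeated-measures machinery with Scheffé intervals is
  deliberately out of scope.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; the pipeline's master seed fixes all
stage seeds through a documented character-code offset, and `run_pipeline()`
writes a manifest of MD5 checksums that is byte-identical across reruns
(timings go to a separate log). The packaged test suite exercises the full
chain on a default protocol of 7 subjects × 4 directions × 2 repetitions of
figure eights (56 trials) plus one 8-direction point-to-point set per
subject, at 1 kHz EMG / 100 Hz kinematics — sizes chosen to mirror the
factorial layout of a realistic session while keeping a complete run in the
tens of seconds. Statistical calibration checks use seeded Monte-Carlo
designs (e.g. two groups of 31 observations in 7 dimensions, matching the
$F(7, 54)$ two-group design).

```{r example, eval = FALSE}
ds <- make_dataset(default_protocol(discrete = FALSE, seed = 1))
units <- lapply(ds$trials, preprocess_trial)
dec <- lapply(units, decompose_trial, flavor = "pca")
fit <- match_components(dec, "pca", seed = 1)
print(fit)
match_to_ground_truth(fit$centroids, make_synergy_model()$weights)
```

## Known limitations

* The carrier model (amplitude-modulated band-limited noise) ignores
  motor-unit structure, cross-talk and electrode artifacts; passing recovery
  tests on synthetic data shows the analysis chain is self-consistent, not
  that it is robust to every pathology of real recordings.
* The generator does not model biomechanics (moment arms, posture-dependent
  muscle action), so plane and orientation contrasts on synthetic data
  reflect only the weight jitter, not systematic biomechanical effects.
* With nearly equal eigenvalues the principal axes are ill-determined and
  loading vectors may legitimately wander between trials; the matching stage
  mitigates but cannot remove this, which is precisely what the dispersion
  ANOVA measures.
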