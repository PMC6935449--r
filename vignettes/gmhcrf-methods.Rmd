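---
title: "Gaussian-mixture HCRFs: model, training, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-mixture HCRFs: model, training, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

A hidden conditional random field (HCRF) models the posterior of a class
label `v` given an observation sequence `U = (u_1, ..., u_T)` by
marginalizing a latent state chain `l_1..l_T` under globally normalized
potentials. This package realizes the HCRF as one disjoint potential block
per class — the standard discriminative-HMM construction: a prior potential
vector (Q entries), a transition potential matrix (Q x Q), and per-state
emission potentials, with the posterior obtained by normalizing the
per-class forward scores across classes. Prior and transition entries are
*unnormalized log-potentials*: no simplex constraint applies, and adding a
constant to every prior entry of every class provably leaves the posterior
unchanged (tested).

The emission potential of state `l` is the log-density of an M-component
Gaussian mixture with **full** covariance matrices. The classical
moment-feature HCRF instead uses explicit linear and squared features of
each dimension, which is exactly a diagonal Gaussian after completing the
square (the package ships that baseline, plus the exact completion mapping
`occurrence = -0.5 * (log(2*pi*s2) + mu^2/s2)`, `M1 = mu/s2`,
`M2 = -1/(2*s2)`, verified per frame to 1e-12). Full covariances are the
modelling delta this package exists for: when within-frame feature
correlations differ between classes, a diagonal model cannot see them.

Assumptions worth stating: frames enter only through per-state mixture
densities (no autoregressive observation dependence); the latent chain is
first-order; classes share (Q, M, D) but no parameters; sequences are
classified independently.

Conventions that the literature leaves ambiguous and this package fixes:

* transitions apply for t = 2..T; the prior covers t = 1. This makes the
  Gaussian-HMM mapping (prior = log b, transition = log C, emissions copied)
  *score-exact*, which the tests assert against an independently implemented
  scaled probability-domain HMM forward pass.
* prediction ties break toward the lowest index in the model's ordered label
  set (determinism).
* all sequence arithmetic is in the log domain with logsumexp; a
  probability-domain forward pass underflows for realistic T.

## Training

Training minimizes the ridge-regularized conditional negative
log-likelihood with L-BFGS (`stats::optim`, method `"L-BFGS-B"`, no active
bounds) over an unconstrained packing of all parameters:

* prior, transition, means: identity;
* mixture weights: centered softmax logits, so any finite vector decodes to
  simplex weights. Globally normalized potentials could in principle absorb
  an unnormalized scale, but the simplex constraint is what makes the
  mixture HCRF reduce exactly to a Gaussian-mixture HMM under the parameter
  mapping, so it is kept;
* covariances: lower-triangular Cholesky factor with log-diagonal (or log
  variances in the diagonal variant), so every iterate is symmetric positive
  definite by construction. Gradients reach these coordinates by projecting
  the covariance gradient onto symmetric matrices and applying the chain
  rule `dF/dL = 2 * tril(G L)` with the extra `L_ii` factor on the logged
  diagonal.

Gradients are the expected-sufficient-statistics forms: prior gradient =
posterior of `l_1`; transition gradient = summed pairwise state marginals;
weight/mean/covariance gradients combine state marginals with per-frame
mixture responsibilities and the Gaussian derivatives
`dlogN/dmu = Sigma^-1 (u - mu)`,
`dlogN/dSigma = 0.5 (Sigma^-1 (u-mu)(u-mu)' Sigma^-1 - Sigma^-1)`.
Published derivations of these gradient families are frequently corrupted
by normalization and indexing typos; here the *finite-difference oracle* is
the correctness authority — the suite checks 50+ random instances to a
1e-4 relative tolerance (observed worst error ~3e-8).

The complexity contract: one objective+gradient evaluation runs exactly one
forward and one backward pass per (sequence, class) and reuses the cached
`alpha`, `beta`, emission log-densities and responsibilities for every
gradient family. Call counters instrument the passes, and a deliberately
naive reference that recomputes forward/backward per family is shown to pay
at least 5x the passes. Gradient accumulation itself is O(T·Q·M·D) — affine
in T at fixed (Q, M), asserted on measured operation counts; the O(TQ²M)
forward/backward cost is paid once.

### Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| Q | 2 | hidden states per class; unitless count. The source experiments never report theirs; defaults are conventions, overridable everywhere. |
| M | 1 | mixture components per state. |
| l2 | 0.01 | ridge on the unconstrained vector; keeps the objective bounded and covariances away from singularity. |
| lbfgs_memory | 10 | L-BFGS correction pairs (`lmm`). |
| grad_tol | 1e-5 | projected-gradient stopping tolerance. |
| max_iter | 200 | L-BFGS iteration cap; 0 returns the initialization. |
| init | kmeans | seeded k-means of pooled per-class frames into Q·M clusters; covariance = cluster scatter + ridge `1e-6·tr(S)/D·I`. |

Numerical edge handling: k-means requires k strictly below the pool size,
so a pool of exactly Q·M frames assigns one frame per cluster; a non-finite
objective at initialization raises an error advising a larger ridge; a
line-search failure returns the best iterate with a warning rather than
throwing; if every mixture component underflows at some (frame, state) the
responsibilities fall back to uniform 1/M with a warning so line searches
at bad interim parameters survive. The fit's recorded history is the
non-increasing sequence of improving objective evaluations, and the
best-objective iterate is what is returned.

## The synthetic worlds

The generator samples per-class GMM-HMMs ancestrally (state, then
component, then the Gaussian draw) and assigns sequences to pseudo-subjects
round-robin so grouped (leave-subjects-out) cross-validation is
exercisable. Three presets are frozen, all with T = 30 frames,
20 sequences/class, 10 pseudo-subjects:

* **separable** — 3 classes, D = 2, Q = 2, M = 1. Class centers at angle
  `2*pi*k/3`, radius 6; the two states of a class sit at center ± (1.5, 0);
  unit isotropic covariances; transitions [[0.9, 0.1], [0.1, 0.9]]; uniform
  initial law. Class gaps exceed 3 standard deviations: a sequence-level
  classifier should be near-perfect, and the true-parameter Bayes classifier
  measures ≥ 99%.
* **correlated** — 2 classes, D = 2, Q = 1, M = 1. Means (0, 0) and
  (0.25, 0.25); covariances with unit variances and correlation +0.9 vs
  −0.9. The mean offset was chosen once at design time: with T = 30
  independent frames a mean gap of 0.5 already gives a diagonal model a
  per-sequence discriminability of about `0.5·sqrt(2T)` ≈ 3.9 standard
  deviations — nearly perfect classification — which defeats the preset's
  purpose; at 0.25 the diagonal-Bayes classifier loses about 10 accuracy
  points to full-covariance Bayes, so the class difference genuinely lives
  in the correlation structure.
* **hard** — 3 classes, D = 2, Q = 2, M = 2 bimodal states with centers
  ~1.5 standard deviations apart, mixture weights (0.6, 0.4), mildly
  correlated components, weak transitions (0.7/0.3). Exists to exercise
  M > 1 code paths under class overlap; no accuracy claim attaches to it.

What the generator does *not* emulate: temporal smoothness of real video
features (frames are conditionally independent given the state), heavy
tails, label noise, per-subject systematic effects (groups are i.i.d.
relabelings), and any feature-extraction artifacts. A green end-to-end test
therefore establishes that the estimator recovers the structure *its own
model class assumes* — it does not establish performance on real video.

## Evaluation harness

Grouped k-fold assigns whole pseudo-subjects to folds (the
leave-subjects-out protocol); stratified k-fold deals each class
round-robin. Confusion matrices follow the percentage-table conventions:
rows are true classes normalized to 100, the "Average" is the mean of the
diagonal percentages, while pooled accuracy is micro (correct/total), which
equals the sequence-count-weighted mean of fold accuracies (tested to
1e-12). Fold-level model comparison uses an exact two-sided sign-flip
permutation of the Wilcoxon signed-rank statistic (enumeration up to 16
informative folds, normal approximation beyond); the generic
`stats::wilcox.test` was not used because tied fold differences force it
into approximations, whereas the enumeration reproduces textbook extreme
cases exactly (ten uniform positive differences give p = 2/1024).

## Known limitations

* Pure R inner loops: fine at the tested scales (tens of sequences,
  T ≈ 30, Q·M ≤ ~10); a production system at video scale would move the
  forward/backward and accumulation loops to compiled code.
* `pack()` cannot represent exactly-zero mixture weights (softmax logits
  are finite); initialization never produces them and optimization cannot
  reach them.
* No Baum–Welch HMM training; the HMM is shipped as a scoring model (the
  mapping-equivalence oracle) and the true-parameter Bayes classifier plays
  the generative-baseline role on synthetic data.
* Model selection for (Q, M) is out of scope; the defaults are conventions.
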