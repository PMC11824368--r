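---
title: "The two-field method for reaction-path generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-field method for reaction-path generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathweaver)
```

## The model

A reaction path (RP) is treated as a piecewise-linear curve in the flattened
3N-dimensional coordinate space, parameterized by arclength $s \in [0, L]$
from the initial state (IS) to the final state (FS). Two time-independent
vector fields are attached to each path:

* the **transformation-guidance field** $t_t(x)$, the unit tangent at the
  projection $\hat{s}(x)$ of $x$ onto the path, oriented IS$\to$FS. Because
  $s$ is arclength, $\lVert t_t \rVert = 1$ everywhere, and integrating
  $\dot x = t_t(x)$ from the IS reproduces the path;
* the **denoising field** $t_d(x) = x_{\text{near}} - x$, the vector from
  $x$ to its nearest point on the path. It has length units (Å) and
  vanishes on the path.

Generation follows $x \leftarrow x + (t_t + \alpha\, t_d)\,dt$ plus optional
white noise $g\sqrt{dt}\,\xi$. The guidance field alone is unstable: any
prediction error pushes the state off the manifold where the tangent is
meaningful, and errors compound. The denoising term pulls the state back,
exactly as a score model denoises samples. Because the path length is unknown
during generation, a binary stop output replaces the fixed time horizon of
diffusion models: generation halts when the stop head prefers stopping.

When several reference paths share a region, the training target at a
coordinate is the field of the path with the *shortest denoising field*
(the nearest path). This makes the combined field a single-valued function
of position whose integral curves select locally consistent mechanisms, and
it makes path endpoints convergence points of the flow.

### Why the denoising field is a Newton step

Diffusing equal probability mass around the $S$ discretized path points with
an isotropic Gaussian of width $\sigma$ gives the mixture
$p(x,\sigma) = \frac{1}{S}\sum_s \mathcal N(x;\, x_s, \sigma^2 I)$.
Writing $w_s(x)$ for the posterior responsibilities, the score is
$\nabla \log p = \sum_s w_s (x_s - x)/\sigma^2$, i.e.
$\sigma^2 \nabla \log p$ is the responsibility-weighted ("Soft-Nearest")
average of the offsets to the path points — a smoothed denoising field that
converges to $t_d$ computed on the vertex set as $\sigma \to 0$ (when the
nearest point is unique). `newton_residual()` measures the gap between this
smoothed field and the exact Newton ascent step $-H^{-1}\nabla\log p$ of the
log-density:

```{r newton}
p <- make_toy_branches()[[1]]
j <- 50
tang <- p$points[j + 1, 1:2] - p$points[j, 1:2]
tang <- tang / sqrt(sum(tang^2))
x <- p$points[j, 1:2] + 0.3 * c(-tang[2], tang[1])   # interior off-path point
sapply(c(0.2, 0.1, 0.05, 0.025), function(s)
  sqrt(sum(newton_residual(perturbed_mixture(p$points, s), x)^2)))
```

For a single-center mixture the residual is identically zero (one Gaussian's
denoising step *is* its Newton step); for path mixtures it decays with
$\sigma$ at interior points. Two numerical caveats are deliberate parts of
the implementation: the residual is expressed in length units
($t_d + H^{-1}\nabla\log p$ rather than the raw bracket
$H t_d + \nabla\log p$, whose $1/\sigma^4$ prefactor dominates and grows on
practical $\sigma$ grids), and the decay statement concerns points away from
the path *endpoints* — at the density edge one Hessian eigenvalue passes
near zero at intermediate $\sigma$, transiently inflating $H^{-1}$. The
convergence order is reported as a numeric log–log slope estimate (about 2
on these toys), not asserted against a theoretical value.

## Training data: the tube sampler

Training coordinates are produced by an Euler–Maruyama walk
$x \leftarrow x + (t_t + \alpha t_d)\,dt + g\sqrt{dt}\,\xi$ starting from the
IS plus one Gaussian kick of scale $g$, with $\alpha = 1$ (the canonical
Newton-step value; exposed as a knob) and $g \sim U[0, 0.2]$ redrawn each
time a path is selected. The walk traverses the path and settles near the
FS; past the FS the tangent drift is dropped (the tangent is defined on
$s \in [0, L)$ only), so the endpoint is a convergence point with
noise-scale spread rather than an artificial fixed point beyond it. On a
straight path the transverse motion is an Ornstein–Uhlenbeck process with
unit mean reversion, so the stationary transverse variance is $g^2/2$ per
coordinate and the squared transverse radius scales with the number of
transverse dimensions — both checked in the tests.

Each visited coordinate is labeled with the oracle fields of the *nearest*
path of the family, a stop label $t_{\text{fin}} = 1$ iff the projection
falls within 2% of $L$ from the FS end (the stop variable is defined as a
binary output, so a concrete labeling neighborhood is needed, and endpoint
projections clamp there), and a conditional flag
drawn with probability 0.7. Stop labels are rejection-balanced to 1:1.

## Reaction conditions and the sparse graph

Bonds are perceived with the standard covalent-radii rule
(distance $\le 1.2\,(r_i + r_j)$, configurable). The diff between IS and FS
yields broken and formed pairs (set differences) and rotated bonds: bonds
present in both whose largest substituent-pair dihedral change, wrapped to
$[0°, 180°]$, is at least 105° — just under the 120° of an sp³ C–C rotation.
Taking the maximum over *all* substituent pairs (hydrogens included) makes
detection independent of substituent choice and keeps H-only bonds (ethane)
detectable. The 9-component per-edge condition vector encodes
broken/formed/rotated membership, the conditional mask (which zeroes the
first three when off), the IS-link flag, and a one-hot over edge kinds.

Edges follow a sparse-attention layout: up to 128 nearest neighbors within
12 Å (window), 32 seeded draws within 30 Å per receiver (random), one
directed IS$\to$current link per atom (the only place absolute displacement
from the IS enters), and two coordinate-free supernodes connected to all
atoms in both directions (global exchange; their relative coordinates are
zero).

## The field models

The reference model is an exactly E(3)-equivariant graph-attention network
written in plain R. Node features carry invariant scalar channels and
covariant vector channels; edge scalars $S_{ij}$ come from a sinusoidal
distance embedding (64 channels, geometric wavelengths 0.25–30 Å, spanning
the edge cutoffs) concatenated with the condition vector; edge vectors are
the unit relative coordinates. Attention logits are invariant dot products
of query/key edge features; values carry both scalar channels and vector
channels built as scalar gates times $\hat r_{ij}$ and times the endpoint
node vectors; five rounds of softmax aggregation with residual updates and
per-channel-type RMS normalization keep equivariance exact (verified to
machine precision in the tests, asserted at 1e-5). The design restricts
features to scalars and vectors (spherical-harmonic order 1) with
scalar-gated products rather than higher tensor products: the output heads
only require invariants and polar vectors, the gated paths already mix
directions across rounds, and exactness of the symmetry — the property the
architecture exists for — is unaffected. The direction-prediction heads are
treated as polar vectors throughout.

Outputs are decoded by inner products: softmax over projected scalar
features against evenly spaced bins, $[-2, 2]$ Å in steps of 0.1 for the two
signed field magnitudes (a negative magnitude flips the learned unit
direction, which is how a "norm" over a signed array stays coherent) and
$[0.1, 1.0]$ Å for the per-atom uncertainty, so every decoded quantity is
bounded by construction for arbitrary weights. Stop scores pool the mean of
the two supernodes' scalar features (supernodes already aggregate globally).

A dense baseline (`toy_field_model`) serves the 2D toys: two tanh layers on
the concatenated current and IS coordinates, per-atom outputs clamped to the
same 2 Å norm bound, uncertainty squashed into $[0.1, 1.0]$. It makes no
equivariance claim — the toys live in a fixed frame.

## Losses and training

Field targets are modeled per atom as isotropic Gaussians with a predicted
standard deviation shared across XYZ:
$\mathcal L = \sum_a \lVert t_a - y_a \rVert^2 / (2\sigma_a^2) +
3\log\sigma_a$ (+ constants, kept so losses are comparable across runs).
The $\sigma$-stationary point at fixed residual $e$ is
$\sigma^2 = \lVert e \rVert^2/3$, which the tests verify by finite
differences; predicting $\sigma$ lets the model discount structures it
cannot fit instead of distorting easy ones. The stop head uses two-class
softmax cross-entropy. The three losses enter with equal unit weights.

Training (`train_toy_model`) is minibatch Adam with hand-derived
backpropagation — optimizer, rate and batch size are not prescribed by the
method, so standard adaptive-moment defaults are used and exposed. The loop
tracks mean $\lVert t_t - y_t\rVert$ and $\lVert t_d - y_d\rVert$ on the
training split and on a validation split held out by path identity, echoing
the by-composition grouping a molecular dataset would use. The equivariant
reference model is forward-only in this package: every training-loop
property the tests exercise concerns the desk-scale baseline, and
`evaluate_losses()` covers loss evaluation for any model honouring the
prediction contract.

On the three-branch 2D toy (20 000 tube samples, 2000 steps, a held-out
branch), training reduces the train-split errors by roughly an order of
magnitude while the held-out tangent error behaves like the classic
overfitting pattern: it improves early, then stalls and drifts up as the
train error keeps falling. The held-out *denoising* error generally does not
improve at all: an unconditional 2D model asked about a branch it never saw
extrapolates the denoising field of the nearest *training* branch, which is
simply a different function than the held-out branch's own field. This is a
structural limit of the toy setting, not an optimization failure — cross-path
generalization of the denoising field requires the conditional, symmetry-aware
molecular model operating on transferable local geometry, which is exactly
what the 2D baseline lacks. Passing toy tests therefore demonstrate
optimization correctness and in-distribution learning, not transfer to unseen
mechanisms.

## Generation

`generate_path` iterates predict → guide → step from the IS. Classifier-free
guidance is parameterized so $w = 0$ is exactly unconditional and $w = 1$
exactly conditional (the alternative $(1+w)c - w u$ parameterization would
contradict $w = 0$ ignoring the conditions). With orthogonalization on, the
denoising prediction of each branch is orthogonalized against its own
guidance prediction, the guided combination is formed, and the result is
orthogonalized once more against the guided guidance field, so the final
denoising component is orthogonal to the guided tangent to machine
precision. The stop rule $y_f[2] > y_f[1]$ is evaluated after each applied
step; a hard cap (default 400 steps) bounds runaway generations, and
`converged` is only reported when the stop head fired strictly before the
cap. Noise at generation time is optional (`g`, default 0); every stochastic
piece is seeded.

All visited frames constitute the generated path — unlike diffusion
sampling, the trajectory itself is the product, ready as a chain-of-state
initial guess.

## Evaluation criteria

For the alkane dihedral-rotation study the package checks, per generation:
termination (stop before 400 steps), final-state correctness (the recomputed
IS→final diff equals the expected broken/formed/rotated sets exactly), and
path cleanliness (additionally, no frame anywhere along the path shows a
change outside the expected sets — transient breaks that heal still fail).
"Unrelated rotations" reuse the 105° threshold since no separate one is
defined. Cleanliness implies final-state correctness by construction.
`path_distance` is the unaligned root-sum-square over atoms, with RMSD =
distance$/\sqrt N$; frames share the IS coordinate frame, so no
superposition is performed.

## Synthetic fixtures and their scope

`make_toy_branches` builds three constant-curvature arcs of length 2 fanning
out from a shared origin at 120° spacing with curvatures 0.45–0.72 — a
deterministic, closed-form family of curved paths from one IS.
`build_alkane` produces idealized all-anti C$_n$H$_{2n+2}$ chains (C–C
1.54 Å, C–H 1.09 Å, tetrahedral angles); rotation fixtures rotate the
smaller fragment about a chosen bond (ties rotate the fragment of the
bond's second atom), and bond-change fixtures interpolate one pair distance
to/from 3.5 Å. These fixtures are geometric idealizations: no force-field
relaxation, no conformer search, no energies. Tests passing on them verify
the geometry, the labeling, the symmetry properties and the integration
contracts — they say nothing about the chemical accuracy of paths generated
for real systems, which depends on training data this package deliberately
does not ship.

## Numerical choices

* Projection is continuous over segment interiors; equidistant segments and
  paths tie-break to the lowest index (deterministic). Tangents at vertices
  use the following segment; at the final vertex, the preceding one.
* Coordinates are Cartesian Å in the fixed frame of the stored path; the
  oracles perform no alignment or recentering.
* Mixture responsibilities use log-sum-exp; $\sigma$ is floored at 1e-8.
* RMS normalizations add 1e-6; zero-length relative coordinates get zero
  unit vectors; a zero guidance vector passes the denoising field through
  orthogonalization unchanged.
* Duplicate consecutive frames are collapsed when building paths; paths with
  fewer than two distinct frames are rejected.
* Problem sizes in the tests (100 frames per toy branch, 20 000 training
  samples, 2000 optimization steps, 16-seed generation ensembles, butane for
  the equivariance suite) are chosen so the whole suite runs on one desktop
  CPU core in a few minutes while every property remains sharply resolved.

## Known limitations

* The equivariant reference model is untrained and forward-only; it
  demonstrates the architecture's symmetry and decoding contracts, not
  learned chemistry.
* Bond perception is a pure distance rule: no bond orders, aromaticity,
  charge or spin.
* Atom correspondence between IS and FS is trusted, matching the method's
  assumption that nuclei keep their identity along the integration.
* No NEB/String refinement or energy evaluation is included; generated
  paths are initial guesses, not minimum-energy paths.
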