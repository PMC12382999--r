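---
title: "Tracking near-identical animals in microgravity video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking near-identical animals in microgravity video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Video of small model organisms (flies, larval fish) housed in orbital
habitats poses three compounding difficulties for multi-object tracking:
individuals raised together are visually near identical, so appearance alone
cannot separate them at trajectory crossings; microgravity produces sudden
accelerations and sharp turns that break constant-velocity motion priors;
and dense grouping causes frequent occlusions that fragment trajectories
and swap identities. `spacemot` implements a joint detection-and-tracking
pipeline built around three ideas: decouple motion from appearance at the
pixel level, fuse the two streams with typed graph attention that also
carries per-track memory across frames, and recover lost identities with an
embedding-plus-motion re-detection stage.

Everything runs on a single CPU with a deliberately tiny model profile;
the architecture is the object of study here, not a pretrained system.

## Motion decoupling

Each frame is approximated pixel-by-pixel by a local quadratic model
$I(p) \approx \tfrac12 p^\top A p + b^\top p + c$ over a Gaussian-weighted
window (default $5\times5$), with optional ridge penalties
$\lambda\alpha\|A\|_F^2 + \lambda\beta\|b\|^2$ (defaults $\alpha=0.1$,
$\beta=0.01$, $\lambda=1$; only the products matter, so $\lambda$ is a pure
config convenience). For a frame pair the displacement solves
$\bar A\, d = -\tfrac12(b_2 - b_1)$ with the curvatures averaged, the normal
equations aggregated over the same window, ridge-stabilized inversion
(`ridge = 1e-4`), and a small number of fixed-point refinement passes that
re-sample the second frame's fit at the displaced position (default 5; two
passes recover integer shifts, five bring 2 px shifts under 0.1 px median
error on smooth textures). Pixels with near-singular systems return zero
displacement. All windowed operators use reflection padding; coordinates are
0-based with x = column.

Displacements go to polar form ($\rho, \theta$, with $\theta \equiv 0$ where
$\rho = 0$), and adaptive thresholds
$\tau_{low} = \mu_\rho + k_1\sigma_\rho$,
$\tau_{high} = \mu_\rho + k_2\sigma_\rho$ ($k_1 = 1$, $k_2 = 2.5$) computed
from sliding-window statistics classify each pixel as static (0), uncertain
motion (1), or confident motion (2); boundary values fall in class 1. Two
numerical choices matter here:

* **Statistics window.** The window must comfortably exceed an agent's
  motion footprint (blob diameter plus flow support), otherwise the agent
  dominates its own local statistics and classifies itself static. The
  default is $31\times31$ (`motion.stat_window`); our first choice of 15
  failed exactly this way on the `erratic` scenario.
* **Degenerate static input.** With $\mu = \sigma = 0$ the rule would put
  $\rho = 0$ into class 1; a strict floor `motion.min_rho = 1e-6` keeps
  all-static frames entirely in class 0.

Pixels with label $> 0$ form a sparse $(x, y, \rho, \theta)$ set, rasterized
into a dense 2-channel image that feeds the motion-stream backbone.

## Dual-stream features and graph fusion

Appearance frames and motion rasters pass through separate 4-stage backbones
(overlapping $3\times3$ strided patch embeddings, transformer blocks with
spatial-reduction attention) at downsampling ratios 4/8/16/32. The test
profile uses depths 1-1-1-1 and widths 8-16-32-64, randomly initialized;
scale is a config, not a behavior. Stage features are flattened row-major,
projected to a shared width `model.hidden` (16 by default) and summed with a
projected sinusoidal positional encoding over `model.pe_bands = 8` frequency
bands, normalizing coordinates as $(x + 0.5)/W$.

The two query blocks of the current frame plus the per-track memory of the
previous frame form a typed graph processed by three attention families, in
this order per round, each with residual connection and layer
normalization:

1. **temporal** — detection queries attend to same-modality memory and vice
   versa (modality-specific projections);
2. **spatial** — within-frame attention over detection tokens with a learned
   relative-position bias $\phi(\Delta x, \Delta y)$ (two-layer perceptron);
   cross-modality by default (`mhgn.spatial_cross`), restricted to
   k-nearest-neighbor token neighborhoods (`mhgn.k_spatial = 8`) when there
   are more than 64 tokens;
3. **heterogeneous** — an unnormalized sum of per-modality attentions
   linking the appearance and motion blocks.

The attention projections carry no bias terms: the formulas have none, and
key/query biases would be structurally gradient-dead under softmax shift
invariance (the bias MLP's output layer drops its bias for the same reason).
Track queries are then refreshed by a deformable decoder: per head, features
are bilinearly sampled at the track's reference point plus learned offsets
(zero-initialized, so an untrained decoder is plain sampling), combined with
per-head softmax weights. Track memory is an exponential moving average with
momentum `mhgn.mem_momentum = 0.9`.

One protocol flag deserves emphasis: `mhgn.memory_in_graph` (default TRUE)
controls whether live track memory enters the graph at inference. The tiny
training loop extracts features with zero memory (no tracks exist offline),
and a frozen random trunk reacts chaotically to memory tokens it never saw
during training, so evaluations of desk-trained models should set the flag
FALSE for train/inference consistency. At full scale, where the trunk is
trained jointly, the default applies.

## Detection, association and losses

The head has three convolutional branches on each modality's fused grid:
sigmoid center heatmap ($1{\times}1 \to$ ReLU $\to 3{\times}3$), box
regression ($3{\times}3 \to$ ReLU $\to 1{\times}1$, four channels), and tanh
refinement offsets. Peaks are $3\times3$ local maxima of the
appearance-stream heatmap above `head.score_thresh`, ties broken by (score
desc, y asc, x asc); the motion-stream heatmap supplies the per-modality
confidence $c_m$ instead of being averaged into the peak map — averaging
would halve confident appearance peaks whenever agents move slowly. The
fused score is $s \cdot \sigma(\gamma c_h)$ with
$c_h = 2 c_a c_m / (c_a + c_m + \epsilon)$, $\gamma = 2$: a harmonic mean
that punishes modality disagreement.

Association scores every detection-track pair through a two-layer network on
$[U; V; U \circ V; |U - V|]$, sigmoid-squashed, and solves a
maximum-affinity assignment with a dense $O(n^3)$ Hungarian solver written
for this package (validated against brute-force permutation search). Two
design choices harden the untrained regime: affinity weights initialize to a
structured similarity prior ($s \approx 2 - \tfrac4h \sum|U - V|$ plus small
noise), and candidates are motion-gated — a detection must fall within
`tracker.gate_radius` (16 px) of the track's predicted position. Prediction
adds the displacement MLP's output to the observed per-frame velocity.

The multi-task loss is the unweighted sum of a penalty-reduced focal loss on
the heatmap (shape parameters 2 and 4), SmoothL1 on boxes and L1 on offsets
at object centers, $1 - \mathrm{IoU}$ between displaced and true boxes, and
binary cross-entropy on the full (pre-threshold) affinity matrix.

## Track lifecycle and re-detection

Matched tracks refresh position, velocity, and embedding (EMA). Unmatched
active tracks become inactive; inactive tracks terminate after
`tracker.max_inactive_frames` (30) and their ids are never reissued.
Unmatched detections with fused score at or above
`tracker.spawn_score_thresh` (0.4) spawn new identities. Re-detection offers
unmatched detections to inactive tracks: affinity against the stored
embedding, gated by a motion-consistency check around the extrapolated
position $p + v \cdot \mathrm{tsu}$ (gate radius grows with time since
update), Hungarian over the gated matrix, revival above
`tracker.redet_thresh`. The stage is online, per frame — not post-hoc
trajectory stitching.

## Metrics

MOTA is $1 - (\mathrm{FP} + \mathrm{FN} + \mathrm{IDSW})/\mathrm{GT}$ with
per-frame IoU-gated Hungarian correspondence (gate 0.5, config-exposed) and
the CLEAR continuity convention: a surviving previous pairing is kept before
re-matching. IDF1 uses a whole-sequence bipartite matching between GT and
predicted identities maximizing frames of gated overlap. Fragmentation
counts interruptions of otherwise-tracked GT trajectories (trailing losses
are not fragments); a trajectory's lifespan is the inclusive frame range
between first and last GT appearance, MT/ML bounds ($\ge 80\%$, $\le 20\%$)
are inclusive. The test suite cross-checks all event counts against an
independent naive recount with brute-force matching.

## The simulator's stated world

The arena generator reproduces the statistical regime the tracker targets,
not the appearance of any organism: near-identical Gaussian blobs (mild
per-agent intensity jitter), piecewise-constant velocities broken by
Bernoulli-timed random impulses and per-frame random turns, reflective
walls, additive sensor noise, full determinism per seed. Default parameters
(96 px arena, 6 agents, radius 2.5 px, speed 1.5 px/frame, impulse rate 0.1
at magnitude 2, turn sd 0.2 rad, noise sd 0.01) were chosen once as a
plausible small-animal regime. Named scenarios construct specific
challenges: `easy_separated` confines slow agents to private cells
(guaranteed zero overlap), `crossing_pair` scripts a head-on pass with
exactly two full-occlusion frames (symmetric half-step timing), and
`dense_occlusion` / `erratic` stress crowding and impulsiveness. Ground
truth keeps occluded identities (with a visibility flag), the standard
benchmark convention.

A green test on this world establishes that the algorithms are implemented
as specified and behave correctly under their stated assumptions. It does
not establish performance on real flight video: real animals deform, blur,
and differ in texture; real optics add glare and refraction; and the
headline accuracies on real flight video come from GPU-scale training on
real data, which this package deliberately does not attempt.

## Desk-scale training

`train_tiny()` freezes the feature trunk and optimizes only the head
(convolutional branches, displacement MLP, affinity network) with
hand-derived analytic gradients under AdamW (weight decay 0.05) and a
warmup + cosine schedule, full-batch over all consecutive frame pairs plus
one flip/rotation-augmented variant each. The full-scale recipe's learning rate 2e-4
belongs to a ~50k-step schedule; over 200 steps AdamW moves parameters by
roughly `lr` per step, so the desk default is 0.02 — a schedule rescaling
fixed in advance, with warmup at 2% of steps mirroring the full-scale ratio.
The last 20% of pairs are held out and scored before and after training.
Gradient correctness is tested against central finite differences, and
trunk gradient flow is smoke-tested the same way.

## Known limitations

Single grayscale static-camera input; one object class; no multi-scale
flow pyramid (displacements above ~3 px/frame degrade); the learned trunk is
random at test scale, so learned-tracking quality is a smoke signal, not a
benchmark; MOT CSV and plain-text PGM are the only I/O formats bundled
(no video codecs offline).
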