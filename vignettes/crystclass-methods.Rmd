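---
title: "Classifying per-molecule local environments in molecular crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying per-molecule local environments in molecular crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystclass)
```

## The problem

Molecular crystals often crystallize in several polymorphs — distinct
periodic packings of the same molecule — and molecular-dynamics studies of
nucleation, melting and solid–solid transformations need a per-molecule
answer to the question *"which phase does this molecule currently belong
to?"*. `crystclass` provides two supervised classifiers for that task, plus
the surrounding infrastructure: trajectory I/O, periodic neighbor lists, a
coordination-number surface rule, trajectory composition analyses, and a
synthetic-crystal generator that makes the whole pipeline testable without
any simulation data.

Both classifiers output, for every molecule $I$ of a snapshot, softmax
class probabilities

$$P_q(I) = \frac{e^{z_q(I)}}{\sum_{q'=1}^{C} e^{z_{q'}(I)}},$$

over $C$ environment classes (the polymorphs plus a disordered "melt"
class), and the predicted class is the argmax (ties broken toward the
lowest class index and flagged).

## The symmetry-function classifier

Each molecule is first reduced to a **point–vector representation**: a
position $\mathbf r_I$ (a selected atom of the molecule, or optionally the
center of geometry) and one or more intramolecular unit vectors
$\mathbf v_{I;s}$ defined by pairs of atoms. For a rigid molecule this
captures position and orientation with a handful of numbers.

On top of this representation four families of **molecular symmetry
functions** are computed, all sums over neighbor molecules $J$ with
$\mathbf r_{IJ} = \mathbf r_J - \mathbf r_I$ and a smooth cosine cutoff
$f_c(r) = \tfrac12(\cos(\pi r/r_c) + 1)$ for $r \le r_c$ (zero beyond):

* radial Gaussian: $\sum_J e^{-\eta(|\mathbf r_{IJ}| - R_s)^2} f_c(|\mathbf r_{IJ}|)$
* radial cosine: $\sum_J \cos(\kappa |\mathbf r_{IJ}|)\, f_c(|\mathbf r_{IJ}|)$
* orientational (Gaussian in the cosine):
  $\sum_J e^{-\eta(\cos\theta^s_{IJ} - \cos\theta_S)^2} f_c(|\mathbf r_{IJ}|)$
* orientational (cosine):
  $\sum_J \cos\!\big(\kappa(\cos\theta^s_{IJ} - \cos\theta_S)\big) f_c(|\mathbf r_{IJ}|)$

where $\theta^s_{IJ}$ is the angle between the slot-$s$ vectors of
molecules $I$ and $J$ and $\eta, R_s, \kappa, \cos\theta_S, r_c$ are
tunable parameters. The radial families encode packing (density and shell
structure), the orientational families encode relative molecular
orientation — which is what distinguishes polymorphs of similar density.
All four are invariant under global rotation, translation, inversion and
molecule relabeling, which the test suite verifies property-style.

The default descriptor table has **24 entries** (eight radial Gaussians on
an $R_s$ grid of 1–7 Å, four radial cosines, and six of each orientational
family split over two vector slots). The published parameter tables for
urea and nicotinamide live in supplementary material that is not bundled;
the default set reproduces the schema, count and length scales, and users
supply their own table for real systems (`read_descriptor_config()`).

The descriptors feed a deliberately small MLP — two hidden layers of 25
GeLU units and a softmax output — trained with Adam on the cross-entropy
loss until the relative training-loss change over a ten-epoch window falls
below a tolerance. Features are z-scored with training-set statistics
stored in the model: unscaled symmetry functions span orders of magnitude,
which would otherwise dominate initialization. Training is bit-reproducible
for a fixed seed under single-threaded BLAS.

## The graph classifier

The second model learns its own features from interatomic distances and
atom types. Per frame, every atom is a node; directed edges connect all
atom pairs within $r_c = 6$ Å (minimum image under periodic boundaries).

* **Node embedding:** a learnable per-element embedding table followed by
  an affine layer.
* **Edge embedding:** the zeroth-order spherical Bessel basis
  $\sqrt{2/r_c}\,\sin(n\pi r/r_c)/r$, $n = 1..32$ by default, followed by
  an affine layer. All basis functions vanish at the cutoff, so edges fade
  smoothly.
* **Graph convolution:** single-head dot-product attention in the style of
  the TransformerConv operator. Keys and values are computed from the
  source node plus the edge embedding, attention is softmax-normalized over
  each node's incoming edges, and a learnable root/skip term carries the
  node's own state (an isolated node passes through the self path only).
  The aggregated message is projected back to the node width and passed
  through a residual GeLU update with graph layer norm,
  $x' = \mathrm{LayerNorm}(x + \mathrm{Dropout}(\mathrm{GeLU}(\mathrm{FC}(x))))$.
  One or two convolutions are supported; more are known to destabilize
  training, and the receptive-field property (atoms beyond
  $(n_\text{conv}+1)\,r_c$ of a molecule cannot affect its logits) is
  asserted in the tests.
* **Max aggregation:** the molecule embedding is the channel-wise maximum
  of its atoms' final node embeddings — exactly permutation invariant.
* **Heads:** a two-layer GeLU network with layer norm and dropout produces
  the polymorph logits, and optionally a second two-way head for the
  surface/bulk topology label; both share the molecule embedding and are
  trained with an equally weighted sum of cross-entropies.

Training uses Adam, one frame-graph per step, with early stopping at the
minimum of the held-out-frame loss; the returned model is the checkpoint at
that minimum. There is no external autodiff dependency: forward and
backward passes (including attention, layer norm and max-pool routing) are
implemented directly and validated against finite differences during
development and against handwritten small-dimension computations in the
test suite.

### Choices the architecture description left open

* **Residual/norm placement:** post-norm (`LayerNorm` after the residual
  sum) was chosen and is asserted by the manual-oracle test.
* **Attention heads:** one head of `message_dim` channels.
* **Head structure for the combined loss:** two output heads sharing the
  molecule embedding, equal loss weights.
* **Dropout at small width:** the publication-scale defaults
  (256/128-dimensional embeddings, dropout 0.25) are kept as package
  defaults, but the bundled tests train much narrower models where that
  much dropout demonstrably prevents convergence, so the reduced test
  configurations set dropout to zero. Dropout is applied only in training.

## Surface/bulk topology

A molecule is labeled **surface** when its coordination number — the count
of other molecules within $R_c$, with the boundary counting as coordinated
($\theta(0) = 1$; the source convention is unstated) — is smaller than 20,
else **bulk**. $R_c$ defaults to the molecule radius (maximum distance
from the position atom to any atom of the reference conformer — the source
leaves "molecule radius" undefined) plus the graph-convolution cutoff.
The symmetry-function classifier has no topology output because it is
meant to be trained on periodic bulk samples alone; the graph classifier
can learn the label through its optional second head.

## The synthetic-data generator

The fixtures emulate the statistical structure the classifiers assume,
not any real compound:

* Three periodic packings of a rigid three-atom toy molecule (one position
  atom and two vector-defining bonds) that differ in density and
  orientational order: aligned simple cubic (*alpha*, a = 4 Å),
  antiparallel body-centered tetragonal (*beta*, 4 × 4 × 5.6 Å), and a
  herringbone-like packing (*gamma*, 5.4 × 4 × 4.2 Å with ±40° rotations).
  Lattice constants were fixed once so that interior molecules have
  coordination number ≥ 20 within the default $R_c$ — the surface rule
  must label a perfect crystal interior as bulk — and so the three packings
  have well-separated zero-noise descriptor centroids.
* A melt: random sequential insertion with a hard minimum-distance
  constraint and uniformly random orientations.
* Spherical clusters carved from a lattice (non-periodic), with topology
  labels derived from the coordination rule.
* Two-phase slabs pairing two packings along an axis, periodic in all
  directions (two interfaces), with the in-plane strain applied to match
  the phases reported and bounded.
* Thermal noise as per-molecule rigid translations (Gaussian, σ_t) and
  rotations (Gaussian angle about a random axis, σ_r), leaving the
  intramolecular geometry exactly rigid. The training noise in the bundled
  evaluations is σ_t = 0.05 Å, σ_r = 0.05 rad, standing in for
  low-temperature thermal fluctuations; generalization is probed at double
  that, emulating the train-cold/test-warm protocol.

What a green test does **not** establish: the fixtures contain no
force-field physics, no conformational flexibility, no realistic unit
cells, and their class separations are larger than those of real
high-temperature trajectories. They validate the machinery (invariances,
oracles, optimization, bookkeeping), not the published benchmark numbers,
which require the original MD data.

One genuine property of the slab fixture is worth knowing: its two
periodic interfaces are symmetry-equivalent, so a boundary-layer molecule
labeled with the bottom phase can have *exactly* the same environment as
one labeled with the top phase. Labels at the boundary are therefore
ambiguous by construction — slabs are classification targets, not good
training material (`cmd_train` exposes an `include` filter for this
reason).

## Numerical choices

* Minimum image: fractional-coordinate rounding followed by a 3×3×3
  adjacent-image search — exact whenever the cutoff respects the safe
  half-width, which `build_neighbor_list()` enforces by raising an error
  rather than replicating images.
* Neighbor sums run over $J \ne I$ and are truncated at $r_c$; "all other
  molecules" is realized by the cutoff.
* Orientation vectors are normalized to unit length so orientational
  descriptors depend only on angles; this also stabilizes noisy inputs.
* Degenerate orientation vectors (defining atoms closer than $10^{-8}$ Å)
  raise an error naming the molecule.
* Exact probability ties are broken toward the lowest class index and
  flagged in the output.
* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at $10^{-12}$.

## Known limitations

* No analytic descriptor gradients (not needed for classification; they
  would be required for enhanced-sampling bias forces).
* No binary trajectory formats (DCD/XTC) and no bond-topology perception;
  molecules come from explicit ids or fixed-size blocks.
* Flexible molecules with conformer-dependent vectors are out of scope.
* The graph classifier's parameter count depends on the configured widths;
  the publication-scale inventory cannot be reproduced exactly and is
  logged, not asserted.
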