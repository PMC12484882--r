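---
title: "moltask: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moltask: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moltask` implements a chirality-aware geometric deep-learning architecture
for multi-task molecular property prediction and learned conformational
relaxation, entirely in base R with analytic gradients. This vignette
explains the model, the assumptions behind each component, the tunable
parameters and why their defaults were chosen, what the synthetic-data
generators do and do not emulate, and the numerical choices a maintainer
should know about.

## The modeling problem

Drug-discovery property panels (ADMET-style endpoints) have three awkward
features. First, annotation is *imperfect*: each property is measured for
only a subset of the compound collection, so the data form a hypergraph in
which every task is a hyperedge over the molecules it labels. Second, tasks
are heterogeneous — classification and regression, wildly different dataset
sizes and label balances. Third, many properties depend on 3D structure,
including chirality: enantiomers share all interatomic distances yet can
behave completely differently, so any model built from distances alone
(an E(3)-invariant model) is provably blind to the difference. `moltask`
addresses all three: a single shared backbone conditioned on task
meta-information, imbalance-aware losses and a task-balancing sampler, and
an SE(3)-invariant (but reflection-sensitive) geometric encoder.

## Geometric encoding

A conformation is a set of atoms with coordinates in Å. `build_graph()`
connects all pairs within a radius cutoff (default 5 Å) and augments any
node with fewer than `min_neighbors` (default 3) neighbors with its nearest
atoms; if a node's neighbor directions are still nearly coplanar and
unconnected atoms remain, the next-nearest atoms are added until the
directions span 3D. The spanning condition is what the coordinate-update
solver needs; on generic non-planar molecules the augmentation guarantees
it. The cutoff and neighbor count are deliberately exposed as configuration
— there is no canonical choice, and for small rigid molecules the graph is
effectively complete.

Each directed edge $(i,j)$ carries the unit vector
$d_{ij} = (p_i - p_j)/\lVert p_i - p_j\rVert$. For every edge we form the
neighbor cross-product sum

$$c_{ij} = \sum_{k \in \mathcal{N}(i)\setminus j} d_{ij} \times d_{ik},$$

which is independent of neighbor enumeration order and rotates with the
molecule. (Internally the sum collapses to the single cross product
$d_{ij} \times \sum_k d_{ik}$, which is algebraically identical and cheap.)
The chirality-aware torsion angle of an edge is

$$\psi_{ij} = \arcsin\!\left\langle
  \frac{c_{ij}\times c_{ji}}{\lVert c_{ij}\rVert\,\lVert c_{ji}\rVert},
  \; d_{ij}\right\rangle \in [-\tfrac{\pi}{2}, \tfrac{\pi}{2}].$$

$\psi_{ij} = \psi_{ji}$ exactly, the angle is invariant under rotations and
translations, and it changes sign under reflection — the one property a
distance-based featurization cannot have. Edges whose cross-product vectors
nearly vanish (collinear or planar neighborhoods, which are common in real
molecules) are assigned $\psi = 0$ with a validity flag rather than NaN.
The $\arcsin$ argument is clamped to $[-1, 1]$; on well-conditioned inputs
the clamp only absorbs roundoff at the boundary.

Angles are embedded with circular harmonics $\sin(\omega\psi)$ and
$\cos(\omega\psi)$ for $\omega \in \{-\Omega,\dots,\Omega\}$ (default
$\Omega = 4$). The $\omega = 0$ and negative-$\omega$ channels are redundant
($\sin 0 = 0$, $\sin(-\omega\psi) = -\sin(\omega\psi)$) but are retained
for fidelity to the printed definition; the redundancy is harmless behind a
learned affine map. The sine block negates under reflection, the cosine
block does not. Edge lengths get a Gaussian radial basis with `n_basis`
(default 32) centers evenly spaced on $[0, r_\mathrm{max}]$ and width equal
to the spacing. Setting `use_torsion = FALSE` zeroes the harmonic block,
yielding a purely distance-based (reflection-blind) encoder used as an
ablation baseline.

## Coordinate updates by edge projection

Node-wise geometry prediction by direct vector regression is biased by
molecular size when messages are summed over neighborhoods. Instead the
model predicts one scalar $m_{ij}$ per directed edge — the projection of
the node's intended displacement onto $d_{ij}$ — and reconstructs the
displacement per node. The supervision side decomposes a target
displacement $\Delta p^\star_i$ into labels
$u_{ij} = \langle d_{ij}, \Delta p^\star_i\rangle$, which are independent
of neighborhood size and of how the graph was built.

Reconstruction solves, for each node, for the center $c_i$ of a sphere
through the origin that best matches the projection vectors
$v_{ij} = m_{ij} d_{ij}$:

$$\min_{c_i} \sum_{j}\left(\lVert v_{ij} - c_i\rVert^2 -
\lVert c_i\rVert^2\right)^2,$$

with closed-form solution $c_i = (2A_i)^{-1} b_i$ where
$A_i = \tfrac1{|\mathcal N_i|}\sum_j v_{ij}v_{ij}^\top$ and
$b_i = \tfrac1{|\mathcal N_i|}\sum_j (v_{ij}^\top v_{ij})\, v_{ij}$; the
update is $\Delta p_i = 2c_i$. Means rather than sums are used — the
optimum is unchanged and the conditioning is better. When the scalars are
consistent with a common displacement and the directions span 3D, the
displacement is recovered exactly. A ridge `eps` (default $10^{-6}$) is
added to $2A_i$ to cover near-coplanar neighborhoods; a singular system at
`eps = 0` raises an error naming the node. The linear solve includes one
step of iterative refinement; exactness is still ultimately limited by the
condition number of the weighted matrix, which is why degenerate weightings
belong to the regularized regime.

The scalars are predicted by a two-layer GeLU head from the concatenated
head-node, tail-node and edge features. Because those inputs are
SE(3)-invariant and the directions rotate with the molecule, the update is
SE(3)-equivariant by construction. Predicted scalars are per directed edge
and not symmetrized; each node uses only its incoming projections.

## Task routing and the mixture of experts

Task meta-information — an integer id, the supergroup
(absorption/distribution/metabolism/excretion/toxicity/physicochemical/other),
the task type, and either the positive-label ratio $\eta$ (classification)
or the target mean and standard deviation (regression) — is encoded as
[one-hot group ‖ one-hot type ‖ learned id-embedding ‖ statistics with
absent fields zero-filled] and passed through a two-layer MLP to a task
embedding (default dimension 64). This numeric encoding is documented, not
canonical; nothing downstream depends on its details. A linear router plus
softmax turns the embedding into gating weights $\alpha$ over $N_M$ experts
(default 8), and each layer's feed-forward block computes the dense mixture
$\sum_i \alpha_i\,\mathrm{FFN}_i(X)$ — all experts run for all tokens, no
top-k sparsification and no load-balancing loss. The literature sometimes
routes from the raw meta vector; here all meta-processing sits behind one
learned encoder and the router consumes the embedding, which keeps the
router's input space fixed as meta-encoding details evolve.

## Architecture and readout

Each layer applies multi-head self-attention over nodes with an additive
per-edge attention bias derived from the edge features (non-adjacent pairs
share one learned "no edge" bias; attention is never masked), a residual
connection and layer norm, then the expert mixture with another residual
and norm. A block is `n_layers_per_block` such layers followed by one
positional update; the whole block is recycled $S$ times (default 4), and
edge geometry is re-encoded from the updated coordinates between blocks.
Recycle weights are shared by default (`share_recycle_weights`), which is
the usual choice for recycled architectures; the alternative is exposed.

The readout scores each node from [node feature ‖ task embedding], applies
a softmax over the nodes of the molecule, and pools node features with
those attention weights — a size-invariant alternative to sum pooling that
also exposes which atoms the model attends to for a given task
(`node_attention` in the output). Regression and classification use
separate linear heads on this shared embedding; regression predicts on the
z-scored scale, classification through a logistic link.

## Losses, sampler, training

Geometry is supervised only at the final state with an L1 loss between the
last update and the update that would have reached the equilibrium
geometry; the reference state cancels algebraically, so the loss equals
the mean absolute deviation of the final coordinates from equilibrium. The
reduction is a mean over atoms and coordinates, keeping the loss comparable
across molecular sizes. Whether intermediate states should also be
supervised is genuinely open; the package defaults to final-state
supervision and exposes `supervise_blocks` to add per-block edge-level
(label-decomposition) terms.

Classification uses a reweighted binary cross-entropy in which the positive
class is weighted by $1/(2t_+)$ and the negative by $1/(2(1-t_+))$, $t_+$
being the training positive ratio; at $t_+ = 1/2$ this is the standard BCE,
and in expectation each class carries half the weight mass. Regression uses
MAE on z-scored targets. The combined objective is
$L_\mathrm{reg} + \gamma L_\mathrm{cls} + \lambda_\mathrm{geo}
L_\mathrm{geo}$ with $\gamma = 1$ and $\lambda_\mathrm{geo} = 1$ by
default; the geometry term carries its own coefficient because it is
jointly optimized with the property losses rather than folded into them.

Dataset sizes are balanced by interpolating each task's size toward the
mean, $\tilde S_i = (1-\theta)S_i + \theta\bar S$ with $\theta = 0.5$ by
default ($\theta$ has no canonical value; 0.5 splits the difference between
natural and uniform sampling). The sum of adjusted sizes equals the sum of
raw sizes for every $\theta$. Each optimizer step draws one task with
probability proportional to its adjusted size, then a batch of its labeled
molecules — the simplest scheme that honors the sampler frequencies for
mixed task types. Optimization is Adam over the full parameter tree.

### Gradients

All gradients are analytic, implemented layer by layer and verified against
central finite differences in the test suite (agreement to ~1e-11 in a
static-geometry configuration). One deliberate approximation: coordinates
entering the geometry re-encoding between blocks are treated as constants
during backpropagation (a stop-gradient), while the additive coordinate
path $P^S = P^0 + \sum_s \Delta P^s$ is kept, so every block's positional
head receives the geometry-loss gradient. Differentiating through the
re-encoding (graph directions, torsions, the sphere-fit solve, and their
dependence on earlier updates) would couple all blocks through second-order
geometry terms for little practical benefit; recycled architectures
routinely stop gradients at analogous points. The gradient of the sphere
fit itself with respect to the predicted scalars is exact and closed-form.

## Synthetic data: what it does and does not emulate

The generators produce every input the training and evaluation paths need,
at desk scale, with exact ground truth.

**Chiral molecules.** Each molecule is one tetrahedral stereocenter (carbon
with four substituents of distinct atomic number from N, O, F, S, Cl) plus
carbon chains, 5–12 heavy atoms. The label follows a simplified
Cahn–Ingold–Prelog rule: priorities are the atomic numbers of the atoms
bonded to the center (ties by index), and the label is the sign of the
signed volume of the three highest-priority substituents around the center
— which flips under reflection exactly as the full rules do. Geometries are
jittered copies of fixed per-size scaffolds built from one asymmetric core.
Three design points matter:

* A *regular* tetrahedral core makes the neighbor-direction sum at the
  center nearly vanish, so the torsion angles there are numerically
  degenerate and carry no usable handedness signal. The core was therefore
  chosen (by a one-off design search) to maximize the worst-case torsion
  margin at the center.
* Scaffolds are canonicalized so that the label convention and the torsion
  sign convention agree: when they disagree, the two highest-priority sites
  are swapped, which flips the label while leaving the geometry — and hence
  the torsion statistic — untouched.
* Samples whose jittered geometry produces a torsion statistic inconsistent
  with the label (rare), a near-planar center (|signed volume| ≤ 0.05), or
  an atomic clash are rejected and redrawn.

The result is a dataset that is *exactly* separable by the sign of the mean
stereocenter torsion angle, so the chirality classification task is
well-posed by construction, and a distance-only model provably cannot beat
chance on enantiomer pairs. What this does **not** emulate: conformational
flexibility, multiple stereocenters, real substituent diversity, or CIP
corner cases (isotopes, duplicated-atom trees). Passing the chirality tests
shows the encoder transmits handedness, not that the model solves real CIP
assignment.

**Spring-network conformers.** Equilibrium geometries minimize a toy
potential — harmonic bonds (rest length 1.5 Å, k = 4) on a random connected
graph plus a soft-core $r^{-12}$ repulsion between non-bonded pairs —
to a gradient max-norm below 1e-4 (L-BFGS with analytic gradients).
Perturbation adds i.i.d. Gaussian noise per coordinate (default
$\sigma = 0.3$ Å — a substantial excitation relative to the 1.5 Å bonds,
large enough that relaxation is nontrivial but within the harmonic basin).
The bond rest length is uniform so that the equilibrium rule is learnable
from edge lengths; the potential is a stand-in for a classical force field
with well-defined minima and analytic energies, not a chemically accurate
one. A model trained on these molecules demonstrably learns to step toward
equilibrium; that says nothing about transferability to real force fields.

**Multi-task suites.** Labels are deterministic functions of geometry and
composition (radius of gyration, heteroatom fraction, atom count), with
tasks cycling over regression and classification and each task labeling
only a requested fraction of the molecules — the imperfect-annotation
hypergraph structure, not the content, of real property panels. Tasks 1 and
3 are affine images of the same latent so that cross-task correlation
exists by design. Task statistics ($\eta$, $\mu$, $\sigma$) are computed
from the realized labeled subsets.

All generators are pure functions of their parameters and seed.

## Numerical choices and degenerate inputs

* Degeneracy threshold for chirality vectors: $10^{-8}$ on the vector norm.
* Sphere-fit ridge `eps` default $10^{-6}$; singularity at `eps = 0` is an
  error naming the offending node.
* Planar or collinear molecules encode cleanly ($\psi = 0$, invalid flag);
  single atoms bypass the graph entirely (attention over one node is the
  identity, readout attention is 1).
* Coincident atoms and single-atom graphs are hard errors.
* Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ inside the
  classification loss.
* All randomness flows through explicit seeds; library code saves and
  restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes on one CPU: 2,000 molecules for the
R/S classification experiment (80/20 split, ~700 optimizer steps of batch
32 for the encoder + readout configuration), 160 spring-network molecules
(120/40) and 200 steps for the relaxation study, and 1,000+ instances for
the reconstruction exactness checks. The architecture defaults
(hidden 128, 8 heads, 3 layers/block, 4 recycles, 8 experts) describe the
full-size model; the shipped experiments use smaller configurations, which
the config object makes explicit.

## Known limitations

* No bond-order perception, protonation handling, or periodic systems.
* The transformer attention bias uses edge features only — no full
  pairwise spatial encoding; non-bonded pairs share a single learned bias.
* Training is single-threaded CPU R; it is meant for method study and
  testing, not production-scale fitting.
* SMILES embedding requires the external Open Babel binary and is optional
  throughout.
* The reflection-sensitivity guarantees are statements about the encoder's
  symmetry properties on valid (non-degenerate) edges; a molecule whose
  every edge is degenerate (e.g., fully planar) is legitimately
  reflection-invariant.
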