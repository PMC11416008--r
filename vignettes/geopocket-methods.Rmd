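---
title: "GeoPocket: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GeoPocket: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeoPocket)
```

## The problem and the pipeline

Binding site prediction (BSP) asks: given a protein structure `P` and a
number of sites `n`, where do small molecules bind, and which residues line
each site? GeoPocket decomposes the task the way detection-then-segmentation
pipelines do:

1. **Candidate generation.** An external geometric pocket finder (Fpocket)
   proposes `m >> n` candidate pocket atom sets; the candidate center is the
   center of mass of each set (`candidateCenter`). GeoPocket consumes
   Fpocket output directories or plain center tables; it does not
   re-implement the alpha-sphere clustering.
2. **Binding site detection (BSD).** A neural model scores each candidate
   center with a druggability logit; the top `n` by score are kept.
3. **Binding residue identification (BRI).** For each kept site, a second
   model with the same trunk emits one logit per nearby residue; residues
   with logit > 0 form the predicted binding residue set.

Ground truth everywhere is the 4 Å heavy-atom rule: a residue is a binding
residue of a ligand when any non-hydrogen atom pair is closer than 4 Å, and
a candidate center is positive when its distance to the nearest ligand heavy
atom (DCA) is below 4 Å. We use a strict `<` at every distance boundary
(4 / 7.5 / 17 / 30 Å) so that the same convention holds across labeling,
augmentation and evaluation.

## The model

**Per-residue local frames.** Each residue carries a rigid transform
`T_i = (R_i, t_i)` with `t_i` the alpha-carbon position. The rotation is the
standard backbone convention, built by Gram–Schmidt: `e1` along `C - CA`,
`e2` the orthogonalized component of `N - CA`, `e3 = e1 × e2`. Any
orthonormal det-+1 backbone convention preserves the invariance properties
below; the Gram–Schmidt recipe is the field's default and is what we commit
to. Residues with missing or collinear backbones are excluded from contexts
(with a warning), never silently imputed.

**Residue-local grids.** For a candidate center, every residue whose CA lies
within 17 Å is selected as context. Each context residue is voxelized: all
heavy atoms whose local-frame coordinates fall in the cube
`[-D·s/2, D·s/2)^3` are counted into a `D^3` grid (default `D = 16` voxels
of `s = 1 Å`) with half-open bins. The default channel scheme (`default8`)
has element one-hots {C, N, O, S, other} plus backbone/side-chain/CA flags;
an atom therefore deposits into up to three channels, and the pure one-hot
scheme `elements5` is available when a one-count-per-atom grid is wanted.
Grid geometry and channels are not dictated by the underlying method, so
both are carried in `GridSpec` and serialized with every checkpoint.

One numerical subtlety: the atoms of the frame's own residue lie *exactly*
on the local axes (zero coordinates), i.e. exactly on voxel edges, where
floating-point noise from a global rotation could flip the bin. Bin edges
are therefore displaced by a fixed 1e-6 Å — far below the 1e-3 Å precision
of deposited coordinates and far above rigid-motion round-off — which makes
voxelization bit-exactly pose-independent. Gaussian smearing is deliberately
not applied by default: integer counts make the invariance testable exactly.

**CNN.** A three-stage 3D bottleneck residual network (1×1 reduce, 3×3
stride-2, 1×1 expand, projected skip; channels 32/64/128 by default) runs
with shared weights over each grid and global-average-pools into a
`dHidden`-dimensional residue embedding. Batch normalization is omitted:
runs are small-batch and determinism is a design goal.

**Geometric self-attention.** Embeddings `x_i` and frames `T_i` enter a
stack of `L` attention layers (default 4; 8 heads, 4 points, `dHidden` 128).
Per head `h` and point `p`:

- standard weight: `w_std[i,j] = q_i · k_j / sqrt(dHidden)`
- geometric weight: `w_geo[i,j] = (1/sqrt(P)) Σ_p ‖T_i q_i^p − T_j k_j^p‖`
- combined: `w[i,j] = softmax_j((w_std − log(1+γ_h) · w_geo)/sqrt(2))`
- outputs: `o_i = Σ_j w[i,j] v_j` and
  `o_i^p = T_i^{-1}(Σ_j w[i,j] T_j v_j^p)`, concatenated with the point
  norms and mixed by a final linear map.

Choices worth recording:

- The geometric weight uses **unsquared** point distances, exactly as the
  combination above is written; the squared variant (used by the mechanism
  this layer descends from) is available via `squaredDistance` in
  `ModelConfig`.
- The dot-product scaling is `1/sqrt(dHidden)`, not per-head width — again
  the literal form of the expression implemented.
- `γ_h` is stored through a softplus, so `log(1+γ_h)` is always positive
  and the geometric term acts as a distance penalty; it is initialized so
  that `log(1+γ_h) = 1`.
- There is no attention-bias term and no residual connection: a layer is
  exactly the map above.
- Point distances and norms carry an epsilon (1e-12) inside the square
  root so gradients stay finite when two projected points coincide.

Because grids are built in local frames and the point sums are pulled back
through `T_i^{-1}`, every quantity entering the heads is invariant under a
global rigid motion of the structure; the tests assert this end to end over
100 random motions at 1e-4 relative tolerance (and bit-exactly for the
grids themselves).

**Heads and sharing.** The BRI head is a pointwise two-layer feed-forward
map producing one logit per residue (threshold 0). The BSD head is the same
pointwise map followed by a mean reduction over the context. The CNN and
attention layers 1..L−1 form the **shared trunk**; the final attention
layer and the head are task-specific. `transferInit` copies exactly the
shared group and reports the manifest of copied names.

## Training

- **BRI loss:** weighted binary cross-entropy over context residues with
  class weights `w_pos = 1/(2 n_pos)`, `w_neg = 1/(2 n_neg)`, which puts
  half the total mass on each class. When a class is absent its weight is 0
  and the other class carries `1/n`. Soft labels from the augmentation
  (vote fractions) enter the BCE as targets directly; for the weight
  counting a residue with label ≥ 0.5 counts as positive — a binary weight
  rule and soft targets have to be reconciled somewhere, and 0.5 is the
  natural split.
- **BRI training uses positive candidates only**, since at inference the
  BRI model only ever sees sites the BSD model has accepted.
- **BSD training** draws candidates with balanced positive/negative
  sampling (minority resampled with replacement; the sampler is fair to
  within 2% over 10⁴ draws and deterministic under its seed).
- **Transfer:** BSD training initializes its shared trunk from the trained
  BRI model and freezes it for the first `freezeSteps` steps (default one
  quarter of the run in `runTransferExperiment`); frozen parameters
  accumulate no optimizer state.
- **Augmentation auxiliary loss:** when augmented items are supplied, each
  step adds `auxWeight` (default 1, a neutral choice in the absence of a
  stated value) times the mean loss of an equally sized draw from them.
- Optimizer is Adam (lr 1e-3 to 3e-3 in the shipped experiments, batch 4);
  these are conventional small-model settings, recorded in `TrainConfig`
  and serializable to YAML. Two runs with the same config and seed produce
  identical loss curves.

## Homology-based augmentation

Binding-site evidence is transferred from a *seed* database of labeled
complexes to unlabeled single-chain *targets* through sequence alignments
(computed externally, e.g. by HHBlits, and consumed here as pairwise
aligned-position records — from A3M files or explicit TSV tables):

1. Keep ligands associated to exactly one chain (4 Å heavy-atom rule).
2. For each (query chain, ligand, target chain) triplet, the triplet is
   *preserving* when at least half of the query's ligand-contact residues
   are aligned to the target.
3. The *proxy center* on the target is the unweighted mean CA position of
   the aligned partners of those contacts.
4. Fpocket candidates on the target are labeled positive within 7.5 Å of a
   proxy center, negative beyond 30 Å of all of them, and excluded
   otherwise.
5. For each positive candidate, each residue aligned to a supporting
   triplet's contact set receives the fraction of supporting triplets
   covering it (a soft label in (0, 1]); residues without homologous
   evidence receive *no* label and are masked out of the loss rather than
   treated as non-binding — absence of evidence is not evidence of absence.
6. Supporting triplets for voting are those whose proxy center lies within
   the same 7.5 Å threshold of the candidate; votes are uniform (the
   definition is a proportion of triplets, not a quality-weighted sum).

Reducing an MSA to correspondences is done pairwise (query↔each aligned
target) rather than by transitive closure; nothing downstream depends on
more than pairwise structure. The whole labeler is deterministic: inputs
are sorted canonically, so shuffling alignment order cannot change a byte
of the output.

## Evaluation metrics

With `n` ligands and exactly `n` predictions per protein: per-protein
precision is the fraction of predictions that detect some ligand
(DCA < 4 Å), recall the fraction of ligands detected by some prediction,
and the **success rate** is the ligand-count-weighted mean of the F1 of the
two (F1 defined 0 when P = R = 0). The **average IOU** compares each
prediction's residue set with the true binding residues of its DCA-closest
ligand, averaged with the same `Σ n` denominator; the **conditional IOU**
restricts the sum to detected predictions and divides by their count,
returning NaN (with a warning) when nothing is detected. Ties in the
closest-ligand assignment break to the lowest ligand index, and proteins
with zero ligands are excluded with a warning — the formulas are undefined
there. Empty-vs-empty residue sets score IOU 1 (vacuous perfection), empty
vs non-empty 0. All three aggregates are checked against independently
coded brute-force implementations on 200 random records at 1e-12.

`rankProbability(nSites, nTop, nFrequent)` is the closed form
`C(nFrequent, nTop) / C(nSites, nTop)` for the chance that `nTop` uniformly
chosen sites all land in a designated frequent set — e.g.
`rankProbability(15, 5, 6)` ≈ 0.2%, verified in the tests by exhaustive
enumeration of all 3003 subsets. Surveys of the example system report the
site count as either 14 or 15; the function is parameterized so either
reading can be computed.

## The synthetic generator, and what the tests do and do not show

`makeToyProtein` builds an idealized poly-alanine helix (2.3 Å radius,
100°/residue, 1.5 Å rise, so consecutive CAs sit ≈ 3.8 Å apart) with full
N/CA/C/O/CB so every residue has a buildable frame; Gaussian coordinate
noise (default 0.05 Å) keeps geometry generic. `makeToyComplex` plants
small heavy-atom clouds 2.8 Å off the helix surface (so the 4 Å contact
rule holds by construction), one candidate within 4 Å DCA of each ligand,
and decoys at least 10 Å from every ligand atom; labels are then derived
through the supervision rules and verified, not assumed.
`makeAlignmentPair` derives homologous copies by per-residue deletion and
renaming, yielding identity alignments at zero rates. Fixtures are written
in the real external formats (PDB, Fpocket directory layout, TSV
alignments) so the I/O paths are exercised, not bypassed.

What this emulates: the geometry of the labeling rules, the information
structure of the two tasks (residues near a planted ligand are exactly the
positives), and the homology-transfer closure property. What it does not
emulate: real pocket concavity, side-chain chemistry, Fpocket's actual
candidate distribution, structural divergence between homologs, or class
imbalance at database scale. Passing tests therefore demonstrate
correctness of the implementation and its invariances — not benchmark-level
predictive performance on real proteins, which requires full-scale training
on curated complex databases.

Problem sizes in the shipped tests and experiments are deliberately small —
30-residue helices, 8³ grids at 1.5 Å, 16-dimensional embeddings with two
heads/points/layers, 20-complex training sets, a few hundred gradient
steps — chosen so the full suite replays the science in minutes on one CPU
while exercising every code path at the defaults' reduced scale.

## Known limitations

- The frame recipe is a convention; numerical equality with other
  implementations of backbone frames is not guaranteed (all stated
  invariants are convention-independent).
- Whether pocket centers should be mass-weighted or unweighted is
  genuinely ambiguous; mass weighting is the default (the literal reading
  of "center of mass"), `uniform` is one flag away.
- Residues outside the 17 Å context cannot be predicted or penalized even
  if they are within 4 Å of a ligand; this is inherent to context-local
  scoring and surfaces as an evaluation caveat, not a bug.
- Training is plain single-threaded Adam on CPU; the package targets
  method correctness and desk-scale experiments, not GPU-scale training.
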