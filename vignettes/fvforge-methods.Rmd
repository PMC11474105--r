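---
title: "Methods: models, losses and evaluation in fvforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, losses and evaluation in fvforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvforge)
```

fvforge is a from-scratch, CPU-scale implementation of an antibody
variable-region (Fv) structure-prediction stack: a rigid-frame structure
module with invariant point attention (IPA), the region-clamped frame-aligned
point error (FAPE) family of training losses, a binned pLDDT confidence head,
the lDDT-C&alpha; and chain-aligned per-region RMSD evaluation protocol, and a
deterministic SAbDab-style curation pipeline. Every component is exercisable
on seeded synthetic fixtures, so the whole stack is testable without
downloading structures, numbering software, or language-model weights. This
vignette records the model, the conventions, and the design decisions that
were genuinely open.

## The model

A paired Fv is represented as per-residue rigid frames $T_i = (R_i, t_i)$: a
rotation and a translation mapping an idealized local backbone onto global
coordinates. Prediction starts from a "residue gas" — every frame the
identity at the origin — and applies `num_blocks` (default 8) update blocks
with independent weights. Each block runs:

1. **Invariant point attention** over residue pairs. Attention logits sum a
   scalar query–key product, a learned bias from relative-position edge
   features, and a squared-distance term between query and key 3-D points
   that each residue emits in its own frame and maps into global coordinates.
   Point outputs are attended in global space and mapped *back* into the
   receiving residue's frame, which makes the layer's output exactly
   invariant under any global rigid motion of the frame set — the property
   the test suite asserts at 1e-8 (the package computes in 64-bit).
2. A residual + layer-norm update and a small transition MLP.
3. A **backbone update**: six numbers per residue, read as an unconstrained
   quaternion tail $(b, c, d)$ — the quaternion $(1, b, c, d)$ is normalised
   and converted to a rotation, so a zero projection is exactly the identity
   — plus a local translation scaled by `trans_scale` (10 Å), letting the
   network work in O(1) units while residues travel tens of Ångström. The
   final projection is zero-initialised, so an untrained model sits at the
   origin; this is asserted as a contract.

Frames after every block are retained (the trajectory), because the backbone
FAPE term averages over blocks. Rotation gradients are detached between
blocks by default (`stop_rotation_grad`), the stabilisation used by this
architecture family; translations carry gradient throughout.

Input node features are either a one-hot sequence encoding (20 amino acids +
X, plus a two-column chain indicator) or an imported per-residue embedding
matrix. Chains are embedded separately and concatenated heavy-first
(`concat_chain_embeddings()`), mirroring how single-chain protein language
models are applied to paired antibodies. Because running an external language
model is out of scope, `mock_embedder()` provides a deterministic stand-in
whose rows are a pure function of the local 5-mer sequence context, the width
and the seed — the properties the pipeline actually relies on (determinism,
context locality, configurable width; default 1024 to match the documented
external embedder). Edge features are one-hot relative sequence offsets
clipped to ±`clip` (default 32; the clip is not stated by the architecture's
description, so it is a config value), with a dedicated bucket for
cross-chain pairs.

After the final block, the full sequence information is used by a torsion
head that emits raw (sin, cos) pairs for &chi;1–&chi;4, normalised with an
epsilon guard; side chains are rebuilt by rotating idealized rigid groups
about the chi axes (`reconstruct_all_atom()`). The idealized geometry is a
static package table of bond lengths, angles and chi-axis definitions,
rounded from standard crystallographic restraint targets, with aromatic rings
made exactly regular so ring closure is exact; it is a documented repository
asset, not a claim about any particular upstream parameter set.
Reconstruction is a right-inverse of chi measurement for every chi-bearing
residue type (tested at 1e-6 rad), and every template bond is reproduced to
1e-6 Å.

## Conventions

* Coordinates are Ångström, axes right-handed; angles are radians internally
  and degrees only at file/CLI boundaries.
* Backbone frames use Gram–Schmidt with the x-axis along CA→C and the y-axis
  toward N; the frame translation is the CA position.
* Dihedrals follow the IUPAC convention (cis = 0, trans = &pi;), reported in
  (−&pi;, &pi;].
* Chain order is heavy-then-light everywhere, enforced by constructors.
* For 180°-symmetric terminal groups (Asp &chi;2, Glu &chi;3, Phe/Tyr
  &chi;2), the canonical branch is the IUPAC-named atom; the &pi;-flipped
  alternate is surfaced to the torsion loss, which scores the nearer branch.

## Losses

**FAPE.** For frames $i$ and points $j$,
$\mathrm{FAPE} = \mathrm{mean}_{ij}\,\min(\lVert T_i^{-1}x_j^{pred} -
T_i^{-1}x_j^{true}\rVert, c_{ij})/Z$. The clamp $c_{ij}$ is 30 Å when exactly
one of the two residues lies in a CDR and 10 Å otherwise. The normalisation
$Z$ is fixed at 10 Å for both clamp regimes: tying $Z$ to the clamp would
silently rescale the long-range term, so a single documented scale is used
(both behaviours sit behind `build_clamp_matrix()`'s arguments). The total
training FAPE is the average backbone FAPE over all blocks plus the final
all-atom FAPE. In the differentiable training path the final term is
computed on the backbone atoms derivable from frames (N, CA, C); the public
`total_fape()` evaluates the true all-atom term on the reconstructed
structure. During training, 90% of the FAPE weight is clamped and 10%
unclamped, the lineage's recipe for keeping long-range gradients alive once
errors exceed the clamp.

**Torsion loss.** Per valid chi, the minimum over the true and alternate
target of the Euclidean distance between unit (sin, cos) vectors, plus a
0.02-weighted penalty pulling raw norms toward 1. Invariant to 2&pi; shifts
of the targets.

**Violation loss.** Flat-bottom penalties on bond lengths and angles against
the idealized templates (tolerance 12 standard deviations of literature bond
statistics: &sigma; = 0.016 Å for bonds, 1.6° for angles — the source
architecture does not print these, so they are documented config values) and
on non-bonded clashes when interatomic distance falls below the sum of van
der Waals radii minus 1.5 Å. It is exactly zero on template-built geometry
and strictly positive under any single violated constraint.

**pLDDT cross-entropy.** The confidence head projects the final single
representation through an MLP with softmax into 50 equal bins on [0, 1]
(left-closed, last bin right-closed: lDDT $l$ falls in bin
$\min(\lfloor 50l\rfloor, 49)$). The target is the per-residue lDDT-C&alpha;
of the (detached) predicted backbone against the truth; the cross-entropy
enters the total with weight 0.01 and is active in both training stages.

**Stages.** Stage 1 optimises FAPE + torsion (+ 0.01 pLDDT CE) with RAdam
under a cosine-annealing scheduler that warm-restarts every 50 epochs
(minimum learning rate 0 by default; the language-model-embedding profile
lowers the initial rate to 5e-4). Stage 2 adds the violation term and runs at
a fixed 1e-4. Early stopping triggers after 100 epochs without validation
improvement (desk profile: 20), and the best checkpoint is kept. Whether the
torsion supervision extends to backbone torsions is architecture-ambiguous;
chi-only is the default scope here, with backbone ψ/φ/ω supervision left
off.

## Evaluation

**lDDT-C&alpha;** uses a 15 Å inclusion radius measured on the *true*
structure, thresholds 0.5/1/2/4 Å, strict inequalities at both radius and
thresholds (a deviation exactly at a threshold counts as broken), and counts
cross-chain pairs by default (the Fv is one assembly; a flag restricts to
within-chain). It is superposition-free and matches an independent
brute-force double loop to 1e-12 in the tests.

**Per-region RMSD** aligns each chain separately onto the reference by
Kabsch superposition over its backbone atoms (N, CA, C, O — O inclusion is a
flag, since "backbone atoms" is underspecified; alignment uses all backbone
atoms of the chain rather than framework-only, also behind a flag) and
reports the RMSD over each region's backbone atoms under its chain's
alignment. A rigidly transformed copy scores zero in all eight regions.

**Confidence summaries.** Per-residue pLDDT is the expectation of the bin
distribution times 100; region and full-domain scores are unweighted means.
`calibration()` reports plain Pearson and Spearman correlations on paired
(confidence, RMSD) values — computed directly on the scores, the simplest
reading of a per-region correlation table — and signals constant input as an
explicit undefined-correlation warning rather than an NA surprise.
`retention_curve()` retains structures with pLDDT strictly above the
threshold and reports the retained fraction and the fraction of retained
structures below the RMSD cutoff.

## Curation

The pipeline applies, in order: nanobody removal; resolution ("above 3.5 Å"
read strictly, so 3.5 is kept; a missing resolution removes the entry with a
flag rather than keeping it silently); orientation outliers at |z| > 3.5 on
any of the six VH/VL orientation statistics, with means and SDs computed once
on the post-resolution set (no iteration; zero-spread statistics are excluded
with a message); CDRH3 length ("over 30" strict); and species frequency.
The printed species rule — remove species occurring *more* than 15 times —
conflicts with its stated outlier-removal motivation, so both readings are
explicit config modes (`"common"`, the literal default, and `"rare"`);
nothing is silently assumed. Validation selection likewise defaults to the
literal "CDRH3 length > 22" with the direction exposed as config. Validation
entries must be human-annotated with resolution below 2.5 Å; the test set is
a reserved legacy id list plus additional human entries; selection is seeded;
and any training entry sharing *any one* of its six CDR sequences (exact,
case-normalised, same region) with any evaluation entry is removed. The
report accounts for every entry at every stage (removed + retained = input),
and the leakage property is exhaustively checkable.

## Synthetic fixtures: what they do and do not show

`make_mini_fv()` builds two chains of idealized backbone geometry — extended
strands for framework, compact helical turns for CDRs, chains placed 25 Å
apart — with synthetic IMGT numbering covering all eight regions and seeded
random sequences. Fixtures are bitwise-reproducible per seed, pass all
structure invariants, and score exactly zero violation loss. The default
sizes (24 residues per chain; CDR lengths 4/4/6/4/4/4) are chosen so every
region carries several residues while the whole suite stays CPU-fast; the
geometry makes no attempt at a real immunoglobulin fold, canonical loop
conformations, or realistic sequences. Passing tests on these fixtures
therefore demonstrate the *correctness of the machinery* — geometry algebra,
loss contracts, metric protocols, pipeline accounting, and that the
architecture can be optimised — not predictive accuracy on real antibodies,
which would require training on experimentally resolved structures at scale.

`make_curation_table()` plants every filter violation deliberately (each
planted entry fails exactly one stage) and exports oracle labels, so
per-stage removal counts are exactly predictable. `make_calibration_set()`
plants retention counts (e.g. 32 of 100 above threshold, 26 of those below
cutoff, giving exactly 0.32 and 0.8125) and an anti-monotone pattern for rank
checks.

## Numerical choices and the training demonstration

The structure module and losses are written against a small reverse-mode
autodiff tape (`R/autodiff.R`), whose primitives behave as plain numeric
operations when nothing is tracked — inference and training share one code
path — and whose gradients are verified against central finite differences,
including through the full training loss (IPA, frame composition, quaternion
map, clamped FAPE, torsion and CE terms). RAdam follows the published
rectification rule; the scheduler is cosine annealing with warm restarts.

`overfit_smoke()` is the desk-scale proof that geometry, losses and gradients
cooperate: a 2-block model (node width 24, 2 heads) is overfit to a single
32-residue mini-Fv for 500 steps at base learning rate 5e-2. With the frozen
seeds this reaches a maximum per-region backbone RMSD around 0.3 Å — the
suite asserts < 1.0 Å — in roughly two minutes on one CPU. Problem sizes
throughout the tests (fixtures of 24–48 residues, 200-entry curation tables,
100-structure calibration sets) were chosen as the smallest sizes that still
exercise every region and every filter meaningfully.

Degenerate inputs are handled explicitly: collinear N/CA/C triplets raise a
degenerate-geometry error; a zero raw (sin, cos) pair yields a finite angle
through the epsilon guard; deviations exactly at an lDDT threshold count as
broken (strict <); ties in the torsion loss's two branches resolve to the
canonical branch; empty region scopes report absent values, never zero; and a
non-finite training loss aborts with a diagnostic log rather than continuing.

## Known limitations

* No recycling, no MSA processing, no ensemble prediction, and no
  physics-based refinement — out of scope by design.
* The mock embedder is a determinism/shape stand-in, not a learned
  representation; results with it say nothing about language-model quality.
* The differentiable violation term used in stage-2 training covers peptide
  bonds and C&alpha; clashes; the full bond/angle/clash evaluation is the
  (non-differentiable) `violation_loss()`.
* Weights trained at desk scale on synthetic fixtures are demonstrations of
  optimisation behaviour only.
* mmCIF output covers the `atom_site` loop only — sufficient for round-trips
  through standard readers, not a full PDBx writer.
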