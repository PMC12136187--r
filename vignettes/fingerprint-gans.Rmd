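---
title: "Fingerprint GANs: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint GANs: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and their
assumptions, the parameters that matter, what the synthetic data generators
do and do not emulate, the numerical choices made where the design was
genuinely open, and the known limitations. The companion README shows a
worked example; the quantities referred to here are the ones computed by the
test suite and by `scripts/acceptance.R`.

## 1. The modelling idea

A molecule is represented as a fixed-length binary fingerprint. The default
scheme is MACCS: a dictionary of predefined structural keys, each bit
flagging the presence of one substructure pattern. Open Babel emits the 166
canonical keys with key $k$ at position $k$; the package stores fingerprints
at 168 positions, with the positions above the native key range held at
constant zero. The padding reproduces the 168-bit tensor shape used
throughout; it carries no chemical information and is harmless to every
similarity computation. The path-based FP2 scheme (1024 bits, linear
fragments up to length seven) serves the substructure-screening stage.

Generation is adversarial. A generator $G$ maps standard-normal noise
$z \in \mathbb{R}^{100}$ to a vector in $[0,1]^{168}$; a discriminator $D$
maps a fingerprint to two class scores. They are trained on the minimax
objective

$$\min_G \max_D \; \mathbb{E}_{x\sim p_\text{data}}[\log D(x)]
  + \mathbb{E}_{z\sim p_z}[\log(1-D(G(z)))]$$

with the usual two-step alternation: per mini-batch, $D$ is updated on a
real batch (positive label) and a generated batch (negative label) with $G$
frozen; then $G$ is updated through the frozen $D$ with positive labels on
its own samples (the non-saturating form of the generator loss). The loss is
two-class cross-entropy on a softmax output — not binary cross-entropy on a
single logit — matching the stated training configuration of the protocol
this package implements; the optimiser is Adam with an L2 penalty on weight
matrices only.

The conditional variant appends a one-hot class label to both the noise
(generator input) and the fingerprint (discriminator input). Training on
actives and inactives with the label as condition lets sampling request the
active class.

For compound-series design the generator's output is passed through a mask
layer: with `mask` equal to 1 at the feature bits of a common core and
`unmask = 1 - mask`,

$$\text{lambda}(x) = x \odot \text{unmask} + \text{mask},$$

so masked positions equal exactly 1 in every sample (the sigmoid output lies
in $[0,1]$, making 1 an exact fixed point) and all other positions pass
through unchanged. The operation is idempotent and the generator gradient is
multiplied by `unmask`, so pinned bits receive no learning signal.

## 2. Architectures

Six named discriminator variants are declared in a versioned YAML table
(`inst/extdata/architectures.yaml`): LeNet5, AlexNet, ZFNet and
VGGNet11/13/16. Each starts with a dense projection to the fingerprint
length (the input layer is dense by design), reshapes to a one-channel 1-D
signal, applies the variant's convolution/pooling stack, and ends in a
two-unit dense head. Three translation decisions were open and are ours:

* **Dimensionality.** The canonical image architectures are 2-D; a
  fingerprint has no meaningful 2-D grid, so 2-D kernels are translated to
  1-D kernels of the same extent (11/7/5/3 as in the originals).
* **Channel widths.** The published widths were sized for 224×224×3 images.
  They are scaled down here (e.g. AlexNet 8–24 channels, VGG 8–64) so the
  models suit a 168-position signal; the exact widths are recorded in the
  YAML table, and VGGNet13/11 are VGGNet16 with tagged layer groups removed,
  which also fixes the parameter-count ordering VGG11 < VGG13 < VGG16.
* **Normalisation.** The local-response normalisation of AlexNet/ZFNet is
  omitted. Batch normalisation is deliberately confined to the generator:
  batch statistics in an adversarial discriminator let it separate real from
  generated samples by *batch composition* rather than content, and the
  generator step (an all-generated batch) then sees a different
  normalisation than the discriminator step (a mixed batch). This failure
  mode was observed directly during development — discriminator and
  generator losses both collapsed toward zero simultaneously — and
  disappears with a normalisation-free discriminator.

The generator reverses the convolutional path: a dense projection of the
noise to a 21-position multi-channel signal, four convolutional blocks
(kernel 3, batch normalisation, leaky ReLU with slope 0.2), nearest-
neighbour ×2 upsampling between the first three blocks (21 → 42 → 84 → 168),
and a final one-channel convolution with a sigmoid output. Transposed
convolution and upsample-plus-convolution are equally faithful "reversals";
the latter was chosen for its simplicity and freedom from checkerboard
artefacts. Default channel widths are 8/8/8/8 — ample for the marginal and
low-order structure the fingerprint task requires, and sized so a full
training run stays in the minutes range on one CPU.

## 3. Training protocol and its parameters

`fp_training_config()` carries the protocol defaults:

| parameter | default | role |
|---|---|---|
| `d_epochs` | 100 | stand-alone discriminator pretraining epochs |
| `gan_epochs` | 800 | adversarial epochs (one full pass of the real set each) |
| `batch_size` | 32 | mini-batch size |
| `d_learning_rate` | 1e-6 | Adam rate of D inside the GAN loop |
| `g_learning_rate` | 1e-3 | Adam rate of G |
| `pretrain_learning_rate` | 1e-3 | Adam rate for stand-alone classification |
| `l2_coeff` | 1e-4 | L2 kernel penalty (weights only) |

Two of these need justification:

* **`pretrain_learning_rate`.** The 1e-6 discriminator rate is an
  adversarial-balance setting that only makes sense over very long runs
  (hundreds of epochs over tens of thousands of mini-batches). For
  *independent* discriminator benchmarking it is hopeless: a few thousand
  Adam steps at 1e-6 move the weights by a small fraction of their
  initialisation scale. Stand-alone training therefore uses its own rate,
  defaulting to Adam's customary 1e-3.
* **Scaled-down adversarial runs.** The package's reference short protocol —
  used by the test suite and the acceptance script — is 200 epochs on 2000
  real fingerprints with rates 1e-4 (D) and 1e-3 (G). The rate was scaled
  up together with the step budget (about 25k generator updates instead of
  175k): at 1e-6 a short run leaves the discriminator essentially at
  initialisation and the adversarial signal is noise. This choice was fixed
  before any quantitative run and is not tuned per dataset.

The epoch is defined as one full pass over the real set (the alternative —
one mini-batch per "epoch" — is not what `gan_epochs` means here). Per-epoch
shuffling and the noise vectors are drawn once from the run seed and reused
across epochs (a fixed noise table of one $z$ per real sample per step
type). Consequences: runs are bit-reproducible from the seed; with both
learning rates zero the training loop is an exact identity (the per-epoch
losses are constant, which the test suite asserts); and fresh noise at
sampling time still produces unseen fingerprints. L2 regularisation applies
to dense and convolution weight matrices, never to biases or normalisation
parameters. Adam's moment parameters are 0.9/0.999 with $\epsilon=10^{-8}$.

Continuous generator outputs become bits by thresholding at 0.5. The
protocol never states how its continuous outputs were binarized; 0.5 is the
symmetric choice, binarization is monotone in the threshold, and masked
positions (exactly 1) survive any threshold below 1.

Initialisation is Glorot-uniform from the run seed; biases and batch-norm
offsets start at zero, batch-norm gains at one. Batch-norm running
statistics (momentum 0.9, $\epsilon=10^{-5}$) are updated only while the
owning network is the one being optimised, and inference uses the running
statistics.

## 4. Data preparation

**Decoy matching.** Given actives and a candidate pool with molecular weight
(g/mol) and logP, both properties are z-scored jointly (they are on
incommensurate scales — the protocol is silent on standardisation), the
first principal component is fitted on the actives (the actives' property
distribution is the matching target; the protocol does not say which set
defines the component), pool members are projected onto it, and `n_select`
decoys are drawn without replacement with probability proportional to a
Gaussian kernel density estimate of the active scores (Scott's rule-of-thumb
bandwidth) evaluated at each pool member's score. A small floor (1e-12) on
the weights keeps degenerate pools drawable; zero-variance property columns
are an error.

**Stratified folds.** `stratified_kfold()` partitions rows with per-fold
class counts within one of exact proportionality. The per-class remainders
are distributed cyclically *across* classes, so total fold sizes are as
equal as possible: the reference 7002/9998 two-class vector yields ten folds
of exactly 1700 rows with 700 or 701 actives. (The protocol's own
description of the per-fold test size contains an arithmetic inconsistency —
one tenth of 17000 is 1700, not 1400; exact partitioning is implemented.)

## 5. What the synthetic generators emulate — and what they do not

`make_synthetic_fpset()` produces labeled fingerprints whose actives carry a
planted signature: 20 signature bits on with probability 0.9 in actives and
0.1 in inactives, all other bits Bernoulli(0.3) in both classes. The
defaults emulate a balanced screening set (2000 + 2000) whose classes are
separable by key patterns, with a realistic overall key density (drug-like
molecules typically set 40–60 of the 166 MACCS keys; background 0.3 gives a
comparable popcount). `make_synthetic_library()` decorates scaffold
templates with small substituents; a configurable fraction is built on
templates containing a planted pyrazole-carboxamide core (a synthetic
stand-in for a lead-series MCS — the reference cores exist only as images),
and ground-truth containment is recorded per molecule.

These fixtures make every pipeline stage testable offline, but they are
independent-bit models: real fingerprints have strong key correlations
(hierarchical keys, co-occurring substructure patterns), heavier popcount
tails, and their actives/decoys differ in many correlated keys rather than a
clean signature block. Passing the fixture-based tests demonstrates that the
mechanics are correct — the GAN can match per-bit marginals and class-
conditional structure, the mask guarantee holds, search and confirmation are
exact — not that the models reach any particular performance on DrugBank,
ChEMBL or ZINC data.

**MACCS keys are not substitution-monotone.** One subtlety surfaced by the
fixtures: the fingerprint of a bare core (encoded as a molecule) may contain
hydrogen-count keys that vanish once attachment points are substituted — the
planted core's free amide sets the primary-amine/amide key, which none of
its N-substituted analogues have. Key-based screening with raw pattern bits
would therefore produce false negatives. `mcs_screen_bits()` intersects the
pattern's bits with exemplar molecules containing the pattern, keeping only
substitution-stable keys; the FP2 path-based screen used by
`mcs_confirm_hits()` does not have this problem (heavy-atom paths of a
subgraph are paths of every supergraph), and exact subgraph matching always
has the final word.

## 6. Evaluation and search

The four generation metrics follow their set definitions: uniqueness
(distinct bit-vectors / samples; every bit-vector counts as valid — validity
is a SMILES-level concept that does not apply to fingerprints), novelty
(unique samples not in the training set / unique samples), diversity (one
minus mean pairwise Tanimoto), similarity (mean Tanimoto over the full
generated × training cross product; the protocol's wording is ambiguous
between cross-product mean and per-query maxima — the mean is implemented,
and per-library-molecule maxima are what the search module reports).
Pairwise metrics are exhaustive up to `max_pairs` (default 2 × 10⁶ pairs,
exhaustive for ≤ 2000 fingerprints) and switch to a seeded uniform pair
subsample above it, flagged on the result and evaluated in fixed-size chunks
so memory stays bounded.

Tanimoto similarity of two all-zero fingerprints is defined as 0, not 1: an
all-zero generated fingerprint must never rank as a perfect hit.

AUC uses the Mann–Whitney rank statistic with midranks for ties; accuracy,
precision, recall and F1 derive from the 0.5-threshold confusion counts and
are mutually consistent by construction.

`search_library()` reports, per library molecule, the maximum Tanimoto score
over all queries ("at least X% maximum structural similarity"), counts
distinct library molecules per threshold band — so band counts are
non-increasing and hit sets nested by construction — and optionally filters
by a molecular-weight window first. Candidate ranking sorts by similarity,
then QED, then molecule id (a deterministic tie-break). Unparsable SMILES in
a library are skipped and counted, not fatal.

Drug-likeness properties come from Open Babel: molecular weight from
standard atomic masses, Wildman–Crippen logP, Ertl TPSA. QED is the weighted
geometric mean of eight desirability functions with the published
asymmetric-double-sigmoid parameters (shipped as plain-text tables under
`inst/extdata/`). Three descriptor definitions are approximations relative
to other toolkits: rotatable bonds use the plain non-terminal/non-ring
single-bond SMARTS (no amide exclusion), aromatic rings are counted as
5/6/7-membered aromatic-ring SMARTS matches, and two of the 116 published
structural-alert patterns (disconnected-component counts) are not
expressible in Open Babel's SMARTS dialect and are omitted. On a reference
drug panel the resulting QED agrees with other implementations to about
±0.01; no result in this package depends on QED beyond ranking.

## 7. Numerical and interface choices

* **Bit indexing** is 1-based in the R API (R convention); serialized
  bitstrings are unseparated 0/1 strings with position 1 written first.
* **Engine.** The networks are dense/1-D-convolution/max-pool/batch-norm/
  upsample stacks with all parameters in one flat vector; forward, backward
  and Adam run as compiled RcppArmadillo kernels with fused per-batch entry
  points. Backpropagation is verified against central finite differences
  over every parameter of a mixed-layer network (relative error below 1e-4;
  exact to ~1e-7 on smooth activations — ReLU-family kinks at exactly-zero
  pre-activations are a measure-zero subgradient choice shared by all
  frameworks).
* **Max-pool ties** resolve to the earliest window position; pool gradients
  scatter to the argmax only.
* **Degenerate inputs** are errors with named offenders: unparsable SMILES
  report the offending id and string, non-finite losses abort with the epoch
  and step, single-class data cannot train the conditional model or an AUC.
* **Problem sizes.** The test suite and acceptance script run the scaled
  protocol (200 epochs × 2000 fingerprints, 10 000-sample mask checks,
  5000-molecule search fixtures) — sizes chosen so the full suite completes
  in minutes on a single CPU while remaining far above the regime where the
  assertions could pass accidentally.

## 8. Known limitations

* Fingerprints cannot be decoded into structures; the library search is the
  decoding step, so the reachable chemical space is bounded by the library
  searched.
* The 168-bit MACCS representation discards counts and stereochemistry;
  two distinct molecules can share a fingerprint.
* The GAN learns what the discriminator can see; on the synthetic fixtures
  this is dominated by per-bit marginals and the signature block. No claim
  is made about higher-order structure of real chemical fingerprints.
* Docking, interaction-profile scoring, free-energy methods and experimental
  validation — the downstream filters of the full discovery pipeline this
  generative core belongs to — are out of scope.
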