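---
title: "Template-based backbone reconstruction with a stacked denoising autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based backbone reconstruction with a stacked denoising autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Template-based modelling predicts the structure of a target protein from the
solved structures of homologous proteins.  `prsda` implements a
reconstruction approach in which, instead of copying or averaging template
coordinates, a *per-target* neural network is trained to map crude
conformations of the target to a refined backbone.  The training signal comes
entirely from template structures: a large ensemble of perturbed "decoy"
conformations of each template is generated, and a stacked denoising
autoencoder (SDA) is trained to map every decoy back to its template's native
coordinates.  At test time a neutral extended chain of the target sequence
(or any crude conformation) is pushed through the trained network and the
output coordinates are written as a standard PDB backbone.

A conformation of an $L$-residue protein is represented by the flat vector of
its backbone-atom coordinates.  Each residue contributes 13 numbers: the
$x,y,z$ positions of N, C$\alpha$, C and O (12 values) plus one residue-type
channel, so the network input width is $L \times (12+1)$.  The residue-type
channel maps each standard amino acid to $i/20$ with $i$ its 1-based position
in alphabetical one-letter order (A = 1, ..., Y = 20); unknown codes map to 0.
Any fixed injective map into $(0,1]$ would do; this one is reproducible
without a lookup table.

Before encoding, every structure in a training set is superposed onto the
first template native (Kabsch least-squares fit) so all conformations share
one coordinate frame, and coordinates are min-max normalized into the unit
box,

$$x_\text{new} = \frac{x - X_\min}{X_\max - X_\min},$$

with a **single isotropic scale** $N = X_\max - X_\min$ fitted over *all*
coordinate components of *all* structures (decoys and natives jointly).
Under one isotropic scale every pairwise distance shrinks by exactly $1/N$,
so normalized space preserves relative geometry in 3D and one inverse map
returns model output to Angstrom.  A per-axis or per-structure scale would
break both properties; this is the reason the package fits one global scale.

The network is a tied-weight stacked autoencoder.  Each layer encodes
$y = S(Wx + b)$ with the logistic sigmoid $S$, and decodes affinely with the
transposed weights, $z = W^\top y + b'$ — no output nonlinearity (a clamp of
the output into $[0,1]$ exists as an opt-in flag, off by default).  Three
hidden layers shrink by the decrease ratios 0.9, 0.8, 0.7:
$h_1 = \lfloor 0.9\,d \rfloor$, $h_2 = \lfloor 0.8\,h_1 \rfloor$,
$h_3 = \lfloor 0.7\,h_2 \rfloor$ for input width $d$ (for example
$d = 780 \to 702 \to 561 \to 392$ at $L = 60$).

Training has two phases:

* **Layer-wise denoising pretraining.**  Each layer in turn learns to
  reconstruct its clean input from a corrupted copy in which coordinate
  entries are masked to zero with probability 0.3 (squared-error objective,
  mini-batch SGD).  Masking-to-zero was chosen as the noise model because it
  mirrors the zero-fill convention for vacant template positions, so the
  network sees the same kind of missingness at training time that real
  padded templates produce.  Residue-type channels are never corrupted.
  Deeper layers consume the previous layer's *clean* encodings.
* **Supervised fine-tuning.**  End-to-end mini-batch gradient descent on the
  coordinate RMSD between the network output and the template-native label,

  $$\mathrm{RMSD} = \sqrt{\frac{\sum_{k=1}^{n} (X_k - x_k)^2 + (Y_k - y_k)^2 + (Z_k - z_k)^2}{n}},$$

  where $n$ counts *atoms* (not channels).  Residue-type channels and
  zero-filled vacant positions are excluded from the sum.  Fine-tuning inputs
  are not corrupted (noise lives in pretraining only); a
  `finetune_corrupt` flag enables it for experimentation.

The analytic gradients of this objective through the mirrored tied-weight
stack are the package's most load-bearing numerical component; they are
verified against central finite differences to a relative tolerance of
$10^{-5}$ in the test suite.

## Decoy generation

The original workflow produced template decoys with an external
fragment-based generator.  What matters to the learner is only the
generator's observable role: a diverse ensemble whose CA RMSD to the native
spans a wide band (3–13 Å), some decoys close to the template, some far.
`prsda` reproduces that role with a transparent mechanism: random phi/psi
pivot rotations at random residues, accumulated until the superposed CA RMSD
reaches a per-decoy target drawn uniformly from the band, with kick size
shrinking near the target to limit overshoot.  Rejection keeps every decoy
inside the band, and the per-decoy targets make the ensemble approximately
uniform across it (each third of the band holds at least 20% of the decoys
for ensembles of 100+).  Externally generated decoy sets can be imported
from a directory of PDB files instead (`import_external_decoys()`), so the
bespoke generator is a default, not a constraint.

By default 500 decoys are generated per template, or 1000 when exactly one
template is available, matching the method's stated study conditions.

## Reconstruction at test time

The crude test-time input is an extended chain of the target sequence built
by internal-to-Cartesian (NeRF) construction with torsions
$\varphi = +135°$, $\psi = -135°$, $\omega = 180°$ and standard idealized
bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å;
configurable via `backbone_geometry()` or a YAML table).  This
$\varphi/\psi$ sign combination is the method's stated convention; it is the
mirror of the more common extended state ($-135/+135$), and both are plain
arguments to `build_extended_chain()`, so either convention is one flag away.

How the extended chain enters the normalized frame is genuinely open (it
shares no geometry with the training set, so superposition is meaningless).
The package translates its centroid onto the training-set centroid and clips
any feature values that still fall outside the unit box into $[0,1]$,
logging how many were clipped.  When the crude input *is* a structure of the
target (e.g. a held-out decoy), it is instead Kabsch-superposed onto the
stored reference template before normalization.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_native()` builds native-like backbones from idealized
secondary-structure torsions (helix $-57/-47$, strand $-135/+135$, mixed
alternating blocks with short loops) with 3° Gaussian torsion jitter,
clash-checked at the CA level (no non-neighbour pair under 3 Å).  Together
with the decoy generator this makes every stage of the pipeline testable
with no downloads.  It emulates realistic local geometry (bond lengths,
CA–CA spacing, secondary-structure torsion statistics) and ensemble
diversity, but **not** side-chain packing, real loop irregularity,
non-ideal bond geometry, or the evolutionary relationship between a target
and an imperfect template.  Passing the synthetic end-to-end test therefore
demonstrates that the learning machinery can recover a native from a wide
decoy ensemble — the robustness property — not that reconstruction accuracy
on real template sets matches the benchmark tables, which require external
structure data and template searches.

## Defaults, units and numerical choices

| Parameter | Default | Unit | Why |
|---|---|---|---|
| decoys per template | 500 (1000 if single) | – | stated study conditions |
| decoy RMSD band | 3–13 | Å | stated input-quality range |
| hidden ratios | 0.9 / 0.8 / 0.7 | – | stated architecture rule |
| pretrain | 100 epochs/layer, lr 0.05, mask 0.3 | – | unstated; standard SDA practice |
| fine-tune | 300 epochs, lr 0.01, batch 20, lr halved every 50 epochs | – | unstated; see below |
| extended-chain torsions | +135 / −135 / 180 | deg | stated convention |
| stopping | fixed epoch count | – | reproducibility (no early stopping) |

The fine-tuning step size follows a step-decay schedule (halved every 50
epochs) rather than staying constant.  The RMSD objective is a square root,
so its gradient has near-constant magnitude close to the minimum;
constant-step SGD therefore orbits the optimum at a distance proportional to
the step size, and the orbit radius — not the data — ends up setting the
final accuracy, with run-to-run quality depending on where the orbit lands.
Diminishing steps are the textbook remedy and cut the final training loss by
roughly a factor of twenty at identical cost in our experiments;
`lr_decay = 1` restores a constant rate.

Other numerical choices: weight initialization uniform in
$\pm\sqrt{6/(n_\text{in}+n_\text{out})}$, seeded; optional pretraining can
be disabled (`pretrain = FALSE`) to train from random initialization; RMSD
loss at exactly zero has an undefined gradient, which is defined as zero;
a decoy RMSD band unreachable for a given chain length errors out after a
retry budget of $50n$ attempts rather than looping forever; superposition
requires at least 3 non-collinear points and rejects degenerate input; the
GDT score uses the standard iterative-superposition heuristic (seeds from
all windows of length 3/5/7 plus the global fit, refitting on within-cutoff
atoms to a fixed point, then a k-nearest refit sweep from each seed's final
fit) — exhaustive subset enumeration is exponential and is used only as a
test oracle on fixtures of 12 residues or fewer.  GDT-TS
averages cutoffs 1, 2, 4, 8 Å; the single-cutoff `gdt()` at 2 Å matches the
benchmark table's GDT(2) convention.

Vacant (unaligned) template positions are zero-filled in Angstrom space,
flagged, and excluded from superposition, scale fitting and the training
loss; the alternative (including them as literal zeros in the loss) would
let padding dominate the objective for short alignments.  With several
templates the loss mask is the intersection of their covered positions.

Every stochastic step (native generation, decoys, initialization, batch
shuffling, masking) derives its seed from one master seed, so the whole
pipeline is bit-reproducible; rerunning `run_pipeline()` with the same
configuration reproduces the output PDB byte for byte.

## Problem sizes

The packaged end-to-end experiment (`robustness_experiment()`) uses a
60-residue mixed-motif native, 500 training decoys spanning 3–13 Å, the
default training schedule, and 20 held-out decoys as test inputs.  These
sizes exercise the full method — the 780-wide input layer matches a small
real protein — while a desk machine trains the model in minutes.  Unit
tests use 8–40-residue fixtures and reduced epoch counts; the oracle
comparisons (Kabsch vs. brute-force rotation search, GDT vs. exhaustive
enumeration, gradients vs. finite differences) run on 5–12-point fixtures
where the exact reference is computable.

## Known limitations

* The trained map is target-specific: a model trained for one target length
  cannot be applied to another sequence length.
* With a single template the supervised objective drives outputs toward that
  template's native; accuracy on real targets is therefore bounded by
  template quality, and targets whose natives differ structurally from all
  templates (flexible loops, domain motion) reconstruct poorly.
* The affine decoder can emit values outside the unit box; the optional
  clamp trades that for saturation at the box faces.
* The GDT heuristic is a lower bound on the combinatorial optimum, as in
  standard implementations.
* Backbone O placement assumes a planar trans carbonyl; side chains are out
  of scope throughout.
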