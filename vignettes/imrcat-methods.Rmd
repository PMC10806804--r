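---
title: "Functional-invariant molecular representations for adsorption-energy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-invariant molecular representations for adsorption-energy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imrcat)
```

## The problem

Adsorption energies of surface reaction intermediates computed with density
functional theory depend systematically on the exchange–correlation
functional: PBE-D3, RPBE, BEEF-vdW and SCAN+rVV10 can disagree by tenths of
an eV for the same species on the same surface. A regression model trained
on energies from one functional therefore entangles two things: the shared
chemistry of how a molecular fragment binds to the surface, and the
idiosyncrasy of the particular functional. `imrcat` implements a
representation-learning route around this: a Siamese neural network is
trained on *within-functional pairwise energy differences* pooled over
several functionals (or over a perturbed-functional ensemble), so that its
subnetwork output — the invariant molecular representation (IMR) — captures
the functional-independent structure. Conventional regressors fit on the
IMR then predict adsorption energies for a functional that was never seen
during representation training.

## Data model and fingerprints

Species are C/H surface intermediates written in a restricted SMILES
dialect: bare `C` atoms take implicit hydrogens up to the carbon valence of
4, bracket atoms such as `[CH2]` leave the remainder of the valence
dangling as *free valence* toward the surface (classes C0–C3; a bare
carbon with four dangling bonds is outside the supported family and is
rejected). Two fingerprint families are built directly on the parsed graph:

* **flat24** — 24 whole-graph counts: total H and C; carbons per
  free-valence class C0–C3; total free valence; C–C bonds by order;
  C–H bonds by carbon class; and C–C bonds by unordered class pair. The
  published description of this fingerprint fixes its information content
  but not the exact 24-slot layout, so the layout here (documented in
  `flat_schema()` and versioned `flat24/v1` in CSV headers) is a faithful
  reconstruction, not a bit-identical copy.
* **morgan24** — circular environments per atom out to radius 2, hashed
  iteratively from the atom invariant (element, hydrogen count, free
  valence, degree, incident bond orders) and folded modulo 24 into binary
  presence bits. Whether the reference vectors were binary or counts is
  not stated; binary is used and recorded in the schema version
  (`morgan24/v1-binary`). Identifiers come from a fixed 31-bit polynomial
  string hash, so fingerprints are bit-reproducible across platforms.

Externally computed embedding fingerprints (e.g. from a pretrained SMILES
language model) enter through `load_embeddings()`; training such a model is
out of scope.

## The Siamese model

For a pair of species $(a, b)$ and a functional $f$, the training target is
$\Delta E = E_f(a) - E_f(b)$. The model is

$$\widehat{\Delta E}(a,b) = h\big(\phi(x_a) - \phi(x_b)\big),$$

where $\phi$ is a feedforward subnetwork ($d \to 32 \to 32 \to k$, tanh
hidden layers) shared by both branches, and $h$ is a readout head
($k \to 8 \to 1$) with tanh activations and **no bias terms anywhere**.
Because tanh is odd and the head is bias-free, $h(-z) = -h(z)$ exactly, so
swap antisymmetry $\widehat{\Delta E}(a,b) = -\widehat{\Delta E}(b,a)$ and
$\widehat{\Delta E}(a,a) = 0$ are structural identities of the
architecture, not learned approximations — the package asserts them to
machine precision. The head consumes the *difference* of the twin outputs
rather than their concatenation for the same reason: energy differences are
the supervision signal, and the difference form carries the antisymmetry
guarantee.

The loss is the mean absolute error over pairs. Optimisation is full-batch
Adam in two learning-rate stages ($5\times10^{-3}$, then $1.5\times10^{-3}$
resuming from the best weights; at most 1000 epochs in total) with early
stopping on a 10% pair-level holdout monitored every 5 epochs (per-stage
patience 60 and 120 epochs). The two-stage schedule exists because the
pair sets differ by an order of magnitude between strategies: the
leave-one-functional-out pair set is small enough that large Adam steps
make the final representation erratic from trial to trial, while the
ensemble strategy's 50-fold pair set is smooth; the gentler schedule is
robust for both. Full-batch rather than minibatch
descent is a deliberate choice: every pair loss factors through the
embeddings of at most a few dozen species, so one epoch costs a handful of
matrix products, the gradient is exact, and — together with an internal
canonical sort of the pair list — training is bitwise reproducible and
invariant to the order in which pairs were supplied. Seeds control weight
initialisation and the holdout draw; a NaN loss aborts with the offending
configuration echoed.

Three training strategies select the pair source:

* **FFM** (leave-one-functional-out): pairs from every functional except
  the test functional, all species.
* **BEM**: 50 ensemble members drawn without replacement (per trial) from
  the perturbed-functional ensemble, each treated as a pseudo-functional.
* **FSM** (control): pairs of the test functional itself, restricted to
  the current trial's training-split species — the "no extra functionals"
  baseline.

In FFM and BEM the Siamese network sees all species on the *training*
functionals, including species that later fall in the test split of the
test functional. This is intended transductive behaviour, not label
leakage: no energy of the test functional ever reaches representation
training.

## Representations and evaluation protocol

Three representation providers share one transform contract: **Original**
(raw fingerprints), **PCA** (centred principal components retaining 98% of
the variance for 24-length fingerprints, 90% for wide embeddings; fit on
the training split only), and **IMR** (the trained subnetwork). "Approximately
98%" is operationalised as the smallest $k$ whose cumulative
explained-variance ratio reaches the threshold, and the IMR width is set to
the same $k$ so the comparison is at matched capacity.

Each evaluation trial splits the test functional's species 2:1 (test size
$= \mathrm{round}(n/3)$; 40 synthetic species give 27 train / 13 test, the
46-species family gives 31/15). Four regressors — ridge and elastic net
(`glmnet`), kernel ridge (closed-form RBF solve with median-heuristic
bandwidth) and support vector regression (`e1071`) — are tuned by seeded
5-fold cross-validation on the training split with mean validation MAE as
the objective, then refit and scored on the test split by MAE and by the
$D^2$ score $1 - \sum|y-\hat y| / \sum|y-\mathrm{median}(y_{\mathrm{train}})|$.
Features are z-scored with training statistics before every regressor.
Across 10 trials, IMR is compared against each baseline with a two-sided
Welch t-test at $\alpha = 0.05$ (a paired test is available, since all
representations share each trial's split; the unpaired default matches the
protocol's bare "t-test"). Hyperparameter grids, fold seeding and the
split rounding are configuration, not hard-coded.

## The synthetic generator

No accession exists for the published 46-species Pt(111) table, so the
package ships a generator that emulates the statistical structure the
method assumes. With $x(s)$ the flat24 fingerprint:

$$E_f(s) = a_f\, g(s) + b_f + u_f \cdot x(s) + \varepsilon, \qquad
  g(s) = \beta \cdot x(s),$$

a shared latent energy $g$, per-functional scale/offset $(a_f, b_f)$, a
per-functional random linear distortion $u_f$ (entry scale
`distortion_scale`, default 0.1 eV), and observation noise (0.05 eV).
Ensemble members are built the same way around $g$ with a smaller
distortion scale (0.03 eV), making the ensemble *less diverse* than the
functionals — the property that makes 50 ensemble draws roughly as
informative as 3 real functionals. Defaults: 40 species drawn from the
complete enumerated C≤3 intermediate family (117 species), 4 functionals
with slopes 0.94–1.05 and offsets within ±0.22 eV.

The latent coefficients deserve a note, because they decide whether the
synthetic study can discriminate between representations at all. They
combine a free-valence term (−0.9 eV per dangling bond, the order of
linear-scaling slopes for CH$_x$ fragments on Pt) with per-bond terms of
1–2 eV for triple bonds and mixed-hybridisation C–C backbone bonds. These
backbone-bond motifs are *sparse* across the intermediate family, so a
large part of the energetically decisive structure lies outside the
directions of largest fingerprint variance. That is a design requirement,
not a tuning knob: if the latent loads only on high-variance features
(e.g. total free valence alone), 98%-variance PCA is a nearly lossless
compression, every representation is equivalent for an exactly linear
target, and the comparison the package exists to make becomes vacuous.

## What the synthetic study does and does not show

Because the generator is *exactly linear* in the full fingerprint and the
training split (27 species) exceeds the fingerprint rank, ridge on the raw
fingerprints is close to Bayes-optimal on synthetic data; no compressed
representation, IMR included, can beat it there. The synthetic study
therefore probes the claim at matched capacity — IMR against PCA at the
same dimension $k$ — where the supervised representation reliably wins
(lower test MAE in ≥ 8 of 10 seeds under both FFM and BEM at the default
conditions, and higher $D^2$). The published real-data result is stronger
(IMR also beats the raw fingerprints, whose $D^2$ is near or below zero);
that pattern reflects non-linearity of real adsorption energetics in
fingerprint space, which a linear generator cannot express. For the same
reason, making the functional distortion *large* in the generator favours
the baselines, not IMR: a linear idiosyncrasy is perfectly learnable from
the test functional's own training energies, while the invariant
representation discards it by construction. Passing synthetic tests shows
the machinery separates shared structure from linear functional
idiosyncrasy at realistic magnitudes; it does not certify real-data error
levels.

## Numerical choices and degenerate inputs

* Pair orientation is canonical (`species_a < species_b` by id); the
  trainer re-sorts pairs, so results are independent of input order.
* Feature scaling inside the Siamese model and before the regressors uses
  training-set statistics; zero-variance columns get unit scale.
* Kernel ridge centres the target and solves $(K + \lambda I)\alpha = y$
  directly; a zero median pairwise distance falls back to unit bandwidth.
* `d2_score` returns a flagged `NA` when the null deviance is zero
  (constant test energies) instead of dividing by zero; t-tests on two
  degenerate equal samples return $p = 1$ by convention.
* Integrated gradients use the midpoint rule (exact for quadratic
  predictors) with central finite differences through the *entire*
  prediction chain, so kernel and support-vector heads are attributable
  identically to linear ones; the default baseline is the all-zero
  fingerprint (the empty molecule), recorded in every report. The
  published analysis does not report its baseline or step count, so
  agreement with it can only be qualitative.
* Carbons with free valence 4 are rejected rather than clamped; aromatic
  SMILES are rejected with a clear error.
* PCA at threshold $t$ never discards a positive-variance component that
  is needed to reach $t$; ties are impossible because the cumulative ratio
  strictly increases over positive-variance components.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full protocol at the
study conditions (40 species, 10 trials, FFM and BEM with 50-of-2000
ensemble draws) with the ridge regressor, and exercise all four regressors
on smaller instances (8–18 species, 1–2 trials). These sizes were chosen
so a complete run finishes in minutes on one CPU while still executing
every code path at the full pair counts (FFM 3×780 pairs, BEM 50×780
pairs per trial).

## Known limitations

* The flat24 layout is a reconstruction; bit-identity with the published
  figures is not guaranteed (the schema version in every output allows
  alternates to coexist).
* The SMILES dialect covers C/H intermediates with ring closures; aromatic
  and heteroatom chemistry is out of scope.
* The Siamese architecture and optimiser were never published; the
  defaults here (32–32 subnetwork, 16-unit odd head, full-batch Adam) are
  this package's choices, exposed in `siamese_control()`.
* Synthetic energies are linear in the fingerprint by construction; see
  the section above for what that implies about baseline comparisons.
* FSM attributions are expected to diverge from FFM/BEM (they see a single
  functional); the package reports them without attempting to reconcile.
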