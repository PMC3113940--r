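---
title: "Predicting stability changes upon mutation with stabscan"
author: "stabscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting stability changes upon mutation with stabscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabscan)
```

## The model

A point mutation replaces the wild-type amino acid $s_w$ at one position of
a folded protein by a mutant type $s_m$.  The induced change in folding
free energy, $\Delta\Delta G$ (kcal/mol, positive = destabilizing), is
predicted from the wild-type structure alone as a weighted combination of
sixteen terms:

$$
\Delta\Delta G_P \;=\; \sum_{i=1}^{13} \alpha_i(A)\,\Delta\Delta W_i
\;+\; \alpha_{14}(A)\,\Delta V_+ \;+\; \alpha_{15}(A)\,\Delta V_-
\;+\; \alpha_{16}(A),
$$

where the $\Delta\Delta W_i$ are differences of knowledge-based
statistical potentials, $\Delta V_\pm$ are the positive and negative parts
of the residue-volume change, and every coefficient is a logistic
(sigmoid) function of the relative solvent accessibility $A$ of the
mutated residue:

$$
\alpha_i(A) \;=\; \frac{f_i}{1 + e^{-r_i (A - c_i)}} + b_i .
$$

The sigmoid form interpolates each term's weight smoothly between a
protein-core regime (low $A$) and a surface regime (high $A$): the physics
of a buried substitution (packing, cavity formation) differs from that of
an exposed one (solvation, entropy), and the data are allowed to decide
where and how sharply the transition happens.  With 16 coefficients of 4
parameters each, the full model has 64 parameters ($c_i$ in percent
accessibility, $r_i$ per percent, $f_i$ and $b_i$ dimensionless).

### Residue descriptors

Each residue of a parsed structure carries four descriptors:

* `s` — the amino-acid type (20 states);
* `t` — a discrete torsion domain: the backbone $(\phi,\psi)$ pair is
  mapped to one of seven regions of the Ramachandran plane (helical `A`,
  extended `B`, polyproline-II `P`, left-handed helical `L`, gamma `G`,
  epsilon `E`, other `O`), with a dedicated `U` label for chain termini,
  chain breaks (peptide C–N distance above 2.5 Å) and missing backbone
  atoms.  The region boundaries are fixed constants
  (`TORSION_DOMAINS`); the literature offers several essentially
  equivalent partitions and no canonical one, so ours is a documented
  choice, checked by the property that canonical helix and strand angles
  land in their boxes and that every angle pair gets exactly one label;
* `a` — relative solvent accessibility in percent: the residue's
  solvent-accessible surface area (Shrake–Rupley sphere sampling, probe
  1.4 Å, 960 Fibonacci-lattice points per atom) divided by its reference
  area in an extended Gly-X-Gly tripeptide (Tien et al. 2013 theoretical
  maxima), clipped to $[0, 100]$.  Doubling the point count moves values
  by well under 2 percentage points on our fixtures;
* `d` — for residue pairs, the distance between side-chain geometric
  centers (mean of the side-chain heavy atoms; C$\alpha$ for glycine),
  recorded for pairs within 8 Å that are at least 2 positions apart along
  the chain.

### The 13 statistical potentials

The potentials measure correlations between descriptor combinations in a
collection of known structures, through the inverse-Boltzmann transform.
For a descriptor pair $(v, w)$,

$$
W(v,w) = -kT \,\ln
\frac{\big(F(v,w)+p\big)\,\big(F+pB\big)}{\big(F(v)+pB_w\big)\,\big(F(w)+pB_v\big)},
$$

with $F$ the observed counts, $p$ a pseudocount (default 1) added to every
joint cell (all marginals are computed from the smoothed table, which is
exactly the expression above), $B$ the number of cells, and $kT$ fixed at
0.593 kcal/mol (298 K) — any other temperature only rescales the energies
and is absorbed by the trained weights.  Triplet terms use the standard
coupling form

$$
W(v,w,x) = -kT \,\ln
\frac{P(v,w,x)\,P(v)\,P(w)\,P(x)}{P(v,w)\,P(v,x)\,P(w,x)},
$$

which vanishes whenever the three descriptors carry no joint information
beyond their pairwise couplings.  The 13 terms are `st`, `as`, `sd`,
`sds`, `stt`, `sst`, `aas`, `ass`, `ast`, `asd`, `std`, `asdas`, `stdst`:
same-residue couplings (`st`, `as`, `ast`), couplings of consecutive
sequence neighbors (`stt`, `sst`, `aas`, `ass`), and distance-mediated
pair couplings (`sd`, `sds`, `asd`, `std`).  The two composite terms
`asdas` and `stdst` couple the joint (a,s) — respectively (s,t) — states
of the two partners with their distance; treating them as triplets over
composite alphabets is our reading of a formalism whose original
definition is not fully published, and is flagged as such.  Higher-order
couplings are deliberately not included.

Binning: accessibility uses 5 bins (0–5–15–30–50–100 %), distance 0.5 Å
bins over 3–8 Å.  These are configurable (`binning_scheme()`); the
defaults are coarse enough that desk-scale structure collections populate
them.

The mutation energy $\Delta\Delta W_i$ is the difference in the structure's
total term energy with $s_m$ substituted at the mutated position, torsion,
accessibility and distances held at wild-type values.  Only tuples
involving the mutated position contribute; the package computes exactly
those, and a test asserts equality (to $10^{-9}$ kcal/mol) with full
re-scoring of the structure.

### Volume terms

$\Delta V = V_m - V_w$ from mean residue volumes (Chothia 1975);
$\Delta V_+ = \Delta V\,H(\Delta V)$ models the strain of accommodating a
larger side chain, $\Delta V_- = \Delta V\,H(-\Delta V)$ the cavity left
by a smaller one.  Statistical potentials, derived from well-packed native
structures, cannot see such defects, which is why these two terms are
separate.

## Training

The parameters minimize the root-mean-square error

$$
\sigma = \sqrt{\tfrac 1N \sum_m \big(\Delta\Delta G_{M,m} -
\Delta\Delta G_{P,m}\big)^2}
$$

over a dataset of measured mutants.  Records are first filtered: mutations
involving proline (backbone geometry changes the model cannot describe),
destabilizing by more than 5 kcal/mol (likely structural rearrangement),
or flagged as heme-protein or pseudo-wild-type measurements are excluded.

The objective is nonlinear only through $(c_i, r_i)$: given those, the
model is linear in $(f_i, b_i)$.  `fit_parameters()` exploits this by
variable projection — an L-BFGS-B search over the 32 nonlinear parameters
(bounds $c \in [0, 100]$, $r \in [-5, 5]$; `parscale` 25 and 0.1 to make
the two groups comparably scaled), with the 32 linear parameters solved
exactly by least squares at every step.  The gradient of the concentrated
objective is analytic: because the inner solve is an exact minimizer, the
envelope theorem makes the partial derivative at fixed $(f, b)$ exact.
The best of `restarts` seeded initializations (default 8; the first start
is a fixed neutral configuration, the rest draw $c \sim U(5,60)$,
$r \sim U(-1,1)$) is returned, so the whole fit is deterministic given the
seed.  `history` records the objective at each accepted improvement and is
nonincreasing by construction.

Degenerate inputs are handled by the linear algebra: rank-deficient inner
designs (e.g. $r_i = 0$ making a sigmoid column collinear with its
intercept) get pivoted coefficients set to zero, and a single-record
dataset is fit exactly.

### Parameter reduction

`reduce_parameters()` implements an iterative uncertainty-driven
reduction: the model is refit on bootstrap resamples (default 20), each
active parameter's dispersion across resamples relative to its mean
magnitude is computed, and the worst parameter above the threshold
(default 1.0) is frozen — a frozen $f$ becomes 0, collapsing that sigmoid
to the constant $b$ (its now-inert $c$ and $r$ are frozen with it); frozen
$c$, $r$ or $b$ keep their bootstrap mean.  The model is refit after every
freeze and the loop stops when nothing exceeds the threshold.  The active
count strictly decreases per iteration.  This realizes the idea of
eliminating ill-determined parameters without claiming to reproduce any
particular published parameter set.

### Validation protocol

`cross_validate()` runs seeded k-fold cross-validation (default 5;
optionally grouping all mutants of a protein into one fold) and reports,
per fold and averaged, Pearson $R$ and $\sigma$ on training (`_d`) and
validation (`_c`) sets, with and without exclusion of the 10 % of pairs
with the largest absolute error.  `retrain_without_training_outliers()`
adds the second round: records mispredicted by more than 1.5 kcal/mol in
*every* initial run are removed from the training folds only, the folds
are refit, and validation sets stay untouched so the averages are
comparable.  `baselines()` supplies the two reference predictors: a seeded
permutation of the measured values, and the constant dataset mean (whose
RMSE is the population standard deviation).  `binned_rmse()` profiles the
error along the predicted or measured axis in 0.25 kcal/mol bins,
dismissing bins with fewer than 10 pairs; `stabilizing_specificity()`
reports, among mutations predicted below a threshold, the fraction
measured stabilizing.

## Sequence optimality

A systematic scan predicts all 19 substitutions at every position.  The
per-position optimality score

$$
\Gamma_i = \sum_m \Delta\Delta G_{P, w_i \to m}\,
H\!\big(-\Delta\Delta G_{P, w_i \to m}\big)
$$

sums the predicted-stabilizing changes only ($H$ the Heaviside function;
"stabilizing" means strictly negative, so equality at zero contributes
nothing).  $\Gamma_i = 0$ marks a position where no substitution is
predicted to help — a stability-optimal residue — while strongly negative
$\Gamma$ flags a structural weakness.  `flag_weak_positions()` uses
$\Gamma \le$ threshold (default −5 kcal/mol) so the boundary value is
flagged; `stratify_gamma()` uses strict $\Gamma <$ threshold to match the
threshold-row convention of tabulated analyses, and cross-classifies
user-supplied residue labels (e.g. catalytic vs other; the package takes
any labeling, it does not curate one) with the core/surface split at 10 %
relative accessibility ($a < 10$ is core, $a \ge 10$ surface).  Secondary
structure is accepted as an optional external annotation for plotting
only.

## The synthetic generator

Real training sets of measured $\Delta\Delta G$ values are curated from
the literature and not redistributable, and published trained weights are
not deposited.  The package therefore ships a generator that reproduces
the *structure* of the problem with full ground-truth knowledge:

* `make_toy_structure()` builds ideal-geometry backbones (helix −57/−47,
  strand −120/+130, or mixed blocks of eight) with seeded 5° Gaussian
  torsion jitter, random 20-type sequences, and one pseudo-centroid
  side-chain atom per non-glycine residue at an amino-acid-specific
  distance from C$\alpha$ (scaling with the cube root of the residue
  volume).  Every descriptor the method uses is computable and the files
  are byte-deterministic given the seed.
* `ground_truth_model()` derives potentials from such a toy collection
  and pairs them with documented sigmoid parameters
  (`default_truth_params()`).  The default truth has its transition at
  $c = 45\,\%$ — inside the accessibility range the toys actually produce
  — with most weights shrinking toward the surface and two growing, and
  an independent term chosen so that simulated datasets reproduce the
  majority-destabilizing skew of experimental mutant collections (about
  90 % of simulated $\Delta\Delta G_M > 0$, spread ±1.4 kcal/mol, all
  values ≤ 5 kcal/mol so the set passes the training filter unchanged).
* `simulate_mutant_dataset()` samples distinct mutations uniformly
  (prolines excluded, mirroring the filter), sets
  $\Delta\Delta G_M = \Delta\Delta G_P^{\text{truth}} + \mathcal N(0,
  \sigma_{\text{noise}})$, and resamples any record that would exceed the
  +5 kcal/mol cutoff.

What the toys do *not* emulate: tertiary packing (accessibility never
reaches the deep-core values of globular proteins), real side-chain
rotamers, experimental noise structure (heteroscedastic, condition-
dependent), or any relationship between sequence and fold.  Passing the
closed-loop tests therefore demonstrates the correctness of the machinery
— descriptors, potentials, deltas, fitting, validation — not predictive
accuracy on real proteins, which would require retraining on a measured
dataset.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at sizes a
laptop handles in seconds to a few minutes: 8 toy structures of 45
residues for potential derivation, 2 000 training / 500 held-out mutants
at noise 0.3 kcal/mol for recovery (held-out correlation against the
noiseless truth ≥ 0.95; validation RMSE at the noise floor), 1 000
mutants for the 5-fold protocol, 200–1 000 seeds for shuffle-baseline
nulls.  Tolerances: energy bookkeeping identities at $10^{-9}$ kcal/mol;
serialization round-trips bit-exact (doubles written as 17-significant-
digit decimals); torsion/accessibility invariance under rigid-body motion
at the 10⁻³ Å precision of PDB coordinates.

Known limitations: prediction quality on real structures depends entirely
on the structure collection used to derive potentials and the mutant set
used to train weights — the package ships machinery and synthetic ground
truth, not a pretrained model; backbone relaxation upon mutation is
outside the model, which is why prolines are flagged; NMR ensembles use
MODEL 1 only; mmCIF input is not supported.
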