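---
title: "Predicting residue solvent accessibility with mixed-descriptor logistic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting residue solvent accessibility with mixed-descriptor logistic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsalogit)
```

## The model and its assumptions

`rsalogit` classifies protein residues as buried or solvent accessible from
sequence- and homology-derived descriptors. The response is defined by
thresholding the relative solvent accessibility (RSA): a residue with RSA
strictly below the threshold is buried (*Y* = 0), otherwise accessible
(*Y* = 1). The conventional threshold is 20% relative exposure; 25% is a
commonly used alternative, and `binarize_rsa()` accepts any positive value.
RSA values are consumed, not computed: they come from NACCESS (or DSSP)
runs on the query X-ray structure, and values slightly above 100% — which
NACCESS produces for extended residues — are accepted.

The probability of accessibility is modelled with a logistic regression
whose linear predictor mixes quantitative descriptors and dummy-coded
categorical ones:

$$\mathrm{logit}\, p_i = \beta_0 + \sum_q \beta_q d_{qi} + \sum_j \beta_j X_{ji}$$

Residues are treated as independent observations. That assumption is wrong
in detail — neighbouring residues are correlated — but it is the standard
simplification for this model family, and the adjacent-query-neighbour
(AQN) factors recover part of the local context. The model makes no use of
coordinates at prediction time; structure enters only through the RSA
labels used for fitting and evaluation.

Fitted probabilities become binary calls at a 0.5 cutoff, inclusive at the
boundary (a residue with *p* exactly 0.5 is called accessible). The cutoff
is configurable per model spec.

## Descriptors

Homology descriptors are computed from a profile of aligned homolog
residues. The input is a BLAST-style tabular file carrying, per hit, the
bit score and the gapped aligned query/subject strings. Hits are filtered
by *relative* bit score: only hits scoring at least 40% of the best hit
(inclusive) are retained. A chain with at least ten surviving hits has
*optimum homology*; below that the homology descriptors are considered
unreliable and only non-homology models are applied to the chain.

At each query position *k*, the retained hits contribute their aligned
subject residues. Gap characters and non-standard letters are excluded from
both numerator and denominator of every descriptor — a gap is evidence of
nothing, and treating it as a 21st residue type distorts the entropies.
With $P_{jk}$ the frequency of type *j* among the $N_k$ aligned residues:

- **E20** $= -\sum_{j=1}^{20} P_{jk}\ln P_{jk}$, the Shannon entropy over
  residue types, in nats (range 0 to $\ln 20 \approx 3.00$);
- **E6**: the same after pooling counts into six physicochemical classes
  (range 0 to $\ln 6 \approx 1.79$);
- **FSHP**: the fraction of aligned residues in the strongly hydrophobic
  set {V, L, I, F, Y, M, W};
- **FSR**: the fraction in the small set {G, A}.

Positions with $N_k = 0$ get missing homology descriptors and are excluded
from any model that needs them, even inside an optimum-homology chain.

Two choices here were genuinely open and are worth recording. First, the
six-class partition: the literature convention this follows is aliphatic
{A, V, L, I, M, C}, aromatic {F, W, Y, H}, polar {S, T, N, Q}, basic
{K, R}, acidic {D, E} and conformationally special {G, P}; since reduced
alphabets vary between authors, `aa_class_scheme()` accepts any
six-way partition, and the scheme in force is an explicit argument of
`entropy6()`. Second, the entropy base: entropies are in nats. Two-state
accuracy is invariant to the base (a base change rescales one coordinate of
a fitted linear predictor), but coefficient magnitudes are not, so the unit
is recorded in every model JSON.

Sequence-only descriptors need no homologs: the residue type **AA**
(treatment-coded with valine baseline — on a full data set, 19 indicator
variables ordered alphabetically by three-letter code), the adjacent query
neighbours **AQN** at positions *k −* 1 and *k +* 1, and the externally
computed disorder propensity **LGDP** in [0, 1]. AQN at a chain terminus is
coded as a distinguished `boundary` level rather than a fabricated residue;
exactly two records per chain carry it. An undefined (`X`) residue is
substituted by alanine *only* when it appears as a neighbour; records whose
own identity is `X` are dropped from fitting and evaluation with a logged
count. Named specs bundle the standard descriptor sets: `"classic"`
(E20+E6+FSR+FSHP+AA), `"comprehensive"` (E6+FSR+FSHP+AA+LGDP+AQN) and
`"non_homology"` (LGDP+AA+AQN).

## Fitting and inference

`fit_logistic()` maximizes the Bernoulli log-likelihood by iteratively
reweighted least squares (Newton–Raphson), the standard GLM algorithm,
stopping when the relative log-likelihood change falls below 1e-10 (at most
100 iterations, with step-halving to keep the iteration monotone near
separation). Standard errors come from the inverse observed information at
the optimum; Wald $z = \beta/\mathrm{SE}$ is referred to the standard
normal for two-sided p-values, reported raw (no multiple-testing
correction), and $\exp(\beta)$ gives odds ratios. There is no
regularization anywhere: complete separation and rank deficiency are error
states, flagged with diagnostics naming the offending columns, never
silently penalized. The test suite cross-checks coefficients and standard
errors against an independent GLM solver and verifies the score-equation
identity (mean fitted probability equals the observed accessible fraction)
to 1e-8.

A linear least-squares baseline (`fit_linear_baseline()`) regresses the
*continuous* RSA on one quantitative descriptor plus AA: one common slope,
per-residue-type intercepts, classification by thresholding the predicted
RSA. It exists as the classical comparison point for the logistic model —
on noiseless data generated with a common slope it recovers that slope to
machine precision, which the acceptance checks exploit.

## Two-branch evaluation

Accuracy is the plain two-state fraction correct × 100, counting both
classes. Test chains are partitioned by homology status; the homology model
scores the optimum branch, a non-homology model the rest, and
`evaluate()` refuses to apply a homology-descriptor model to non-optimum
records — the branch policy is explicit, never defaulted. The all-proteins
number is the residue-count-weighted mean of the branch accuracies (residue
pooling, not per-protein averaging). Strata additionally reported:
oligomer / non-oligomer chains, oligomer residues with likely interfacial
residues removed, and the interfacial residues alone. Accuracy differences
are coded `M` (below −0.5), `O` (within ±0.5) or `P` (above +0.5)
percentage points.

A residue is *likely interfacial* when its single-chain RSA exceeds its
complex-context RSA by more than `min_delta`. The default `min_delta` is 0
— any positive difference counts as a measurable increase — because no
principled nonzero default exists; it is a configurable parameter in
percentage points. For oligomer chains the gold-standard label uses the
complex-context RSA, since the biological unit defines the physically
meaningful exposure.

## The synthetic data generator

`simulate_records()` / `simulate_fixture()` generate the entire input stack
with known ground truth, so every pipeline stage is testable offline. Per
chain, alignment columns are drawn from a symmetric Dirichlet-multinomial
whose concentration varies per position ($10^{U(-1.5,\,0.7)}$), producing
the realistic mix of near-conserved and fully variable columns; the query
residue is drawn from the same column distribution. Bit scores are spread
over (0.25, 1] of the best score so the 40% filter genuinely removes hits.
Labels are drawn from a logistic model at known coefficients — by default
the published classic-model fit shipped with the package — and each label
gets a consistent continuous RSA (uniform below the threshold for buried,
above it for accessible), so the linear baseline is testable against the
same truth.

Default conditions (fixed once, stated here as the package's choices):
24 chains of 80–250 residues; hit depth Poisson(30), with 15% of chains
drawn sparse (Poisson(4)) so the non-optimum branch is populated at small
chain counts; gap probability 0.05; undefined-residue probability 0.005,
matching the under-1% rate typical of real FASTA records; half the chains
oligomeric; one-fifth of oligomer residues interfacial, with single-chain
RSA raised by a uniform 5–30 percentage points; and an interfacial label
noise of 0.1 — with that probability an interfacial residue's label is
flipped relative to what its descriptors predict, reproducing the
few-point accuracy drop observed at real interfaces. Everything is
deterministic in the seed; the test suite asserts byte-identical fixture
directories and pipeline outputs across reruns.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: phylogenetic correlation among subject
sequences (hits are exchangeable draws), composition bias along real
chains, any structural realism in which residues are exposed, informative
LGDP or AQN signals (both are pure noise under the default truth, so
non-homology models score in the high 50s on fixtures rather than the low
70s reachable on real data), and real BLAST score distributions. The
fixtures validate the *computations*; accuracy figures on real proteins
require real alignments and structures.

## Numerical choices and degenerate inputs

- Entropy uses the $0\ln 0 = 0$ convention; single-type columns give
  exactly 0.
- $N_k = 0$ positions yield missing descriptors, never zeros; missing
  values propagate as exclusions with logged counts, not as imputations.
- The logistic log-likelihood is computed in overflow-safe form, and
  predicted probabilities use the stable inverse logit (η = ±40 gives
  0/1 without overflow).
- Model JSON is written with 17 significant digits so coefficients
  round-trip bit-for-bit.
- Dummy columns are ordered alphabetically within each factor; refits on
  permuted rows reproduce coefficients to 1e-8.
- Classification and burial thresholds are boundary-inclusive on the
  accessible side (RSA = threshold → accessible; p = cutoff → accessible).
- Prediction with a stored model rejects factor levels unseen at fit time
  by name rather than guessing a coefficient of zero for them.

## Problem sizes

The shipped checks run at desk scale, chosen to keep the full suite in the
low tens of seconds: entropy oracle sweeps over 1000 random columns,
parameter recovery at n = 20 000 residues, Wald-interval coverage at 300
replicates of n = 400, and train/test pipeline runs of 20–40 chains
(roughly 3000–7000 residues). These sizes are the package's own choices
for routine verification; all of them scale up by changing
`fixture_config()` arguments.

## Known limitations

LGDP is strictly an input — the Ising-model disorder calculation that
produces it is not reimplemented here, and a Beta-distributed stub stands
in for it in fixtures (labelled synthetic throughout). Oligomer status is a
per-chain input flag, not derived from coordinates. FASTA↔structure
residue-numbering reconciliation is sequential with an explicit mapping
hook rather than an alignment heuristic; mismatched residues are dropped
and counted. The package never runs BLAST, NACCESS or disorder predictors;
it defines the file dialects it consumes precisely so those tools can be
run once, upstream.
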