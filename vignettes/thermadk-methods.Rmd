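---
title: "Methods: structural descriptors, phylogenetic models, and contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural descriptors, phylogenetic models, and contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermadk)
```

thermadk analyses molecular-dynamics snapshots of adenylate kinases (ADKs)
from prokaryotes with different thermal preferences. This vignette explains
the models and procedures the package implements, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the synthetic-data validation does and does not demonstrate.

## Study structure the package assumes

Each species carries an optimal growth temperature (OGT, °C) that assigns
it to a thermal group — psychrophile (OGT ≤ 20), mesophile (20, 40],
thermophile (40, 80], hyperthermophile (> 80). Boundary values go to the
colder group, because the psychrophile definition is an inclusive "up to
20 °C" and the warmer boundaries are resolved the same way for symmetry;
`classify_thermal_group()` implements exactly this rule. Each group is
simulated at one *native* temperature: 280, 300, 330 or 355 K. Metadata
further record the ADK type (monomeric or trimeric) and LID-domain length
(short or long). A time-calibrated species tree stands in for the ADK gene
tree throughout, since gene trees for this enzyme are typically too weakly
supported to use directly.

All internal geometry is in ångström (the PDB's native unit); parameters
quoted in nm (the 0.5 nm contact cutoff, the 0.14 nm probe) are converted
once at the configuration boundary (`adk_config()`), never inside
computations.

## Structural descriptors

**RMSF.** Frames are superposed on an iterated mean structure (two
mean/fit iterations, seeded by the first frame, alpha-carbon selection)
with the Kabsch algorithm, which guarantees the least-squares-optimal
proper rotation. Then
`RMSF_i = sqrt(mean_t ||r_i(t) − ⟨r_i⟩||²)`. The single per-protein RMSF
used downstream is the unweighted mean over alpha carbons — the reduction
is not uniquely dictated by the quantity itself, so the package fixes and
documents this choice.

**SASA.** Shrake–Rupley with a 1.4 Å probe and 960 sphere points per atom
placed by the golden-spiral construction, which is deterministic for a
given point count so results are bit-reproducible. The radius table is a
fixed per-element set (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å);
hydrogens are included when the file contains them. SASA is computed over
all protein atoms, not just alpha carbons, matching the standard
definition. At 960 points the lone-sphere error is below 0.5 % and the
960-vs-9600-point difference on multi-atom fixtures is below 1 %; note the
estimate is rotation-invariant only up to this discretisation (~0.1 %).

**Radius of gyration.** Unit-weight RMS distance of alpha carbons from
their centroid, per frame, averaged over frames.

**Replicate aggregation.** Descriptors are averaged within a replicate
(over frames or residues), then across replicates; the standard error of
the replicate mean is the "measurement uncertainty" the meta-analytic
models consume. SE rather than SD is used because the models need the
uncertainty of the *mean* estimate; a single replicate yields a flagged
missing SE rather than a silent zero.

## Side-chain contacts

Only four contact types exist in this accounting: salt bridges
(negative–positive), and the positive–polar, negative–polar and
polar–polar combinations. Arg/Lys are positive, Asp/Glu negative,
Asn/Gln/Ser/Thr/Tyr polar; His, Trp, Cys and Met are deliberately outside
the polar set, like-charge pairs are not contacts, and protonation states
are ignored. The interacting-group atom sets (carboxyl CG/OD1/OD2 and
CD/OE1/OE2, guanidinium CZ/NE/NH1/NH2, ammonium NZ, amide CG/OD1/ND2 and
CD/OE1/NE2, hydroxyl OG/OG1/OH) are exemplified rather than enumerated in
the literature conventions this follows; the table above is the package's
documented assumption.

A frame contact is an unordered residue pair at sequence separation ≥ 2
(adjacent residues are excluded — the target is side-chain interactions,
not backbone neighbours; the separation is configurable) whose group-centre
distance is ≤ 5 Å. Persistence requires presence in ≥ 50 % of frames,
pooled across concatenated replicates; a pair present in exactly half the
frames is kept ("less than 50 %" is excluded). A per-replicate mode is
available behind a flag for sensitivity analysis. Persistent contacts are
keyed by the 1-based alignment columns of the two residues, which makes
contacts comparable across proteins; the mapping refuses to proceed if the
ungapped alignment row disagrees with the structure-derived sequence.

For trimeric proteins, contacts are computed within the first chain only
(inter-chain contacts would have no alignment-column identity); chain count
is recorded in metadata and whatever topology the file contains is
simulated/analysed as-is.

## Phylogenetic PCA

The trait matrix X (species × descriptors) is modelled as multivariate
Brownian motion on the tree with Pagel's λ scaling the off-diagonal
covariance: C(λ) keeps tip variances and multiplies shared paths by λ. λ is
estimated by maximising the profile log-likelihood (GLS mean and ML
covariance profiled out) with bounded scalar optimisation on [0, 1] at
tolerance 1e-6, and the interior optimum is guarded against the boundary
values. Components come from the eigendecomposition of the evolutionary
covariance `R = (X − 1a)ᵀ C(λ)⁻¹ (X − 1a)/(n − 1)`; scores are the
mean-centred data projected on the loadings.

Because the descriptors have incommensurate units (Å, Å², counts), the
default analyses z-scored traits ("standardized" mode); a raw-covariance
mode is available. On a star tree the procedure reduces exactly to
ordinary PCA, which the tests verify to 1e-8, and the implementation is
cross-checked against an independent R implementation of GLS-based
phylogenetic PCA.

## Bayesian phylogenetic mixed models

Three response families share one Gaussian hierarchy
`w = Xβ + Zu + ε`, `u ~ N(0, σ²_phylo C*)`, with C* the tree covariance
rescaled to unit height so σ²_phylo lives on the trait scale (this also
conditions the linear algebra):

- **Gaussian meta-analytic** — each observation carries a known
  measurement-error variance se²; the likelihood is
  `y_i ~ N(x_iᵀβ + u_sp(i), σ²_e + se_i²)`, implemented by sampling a
  latent error deviate per observation (conjugate), so all remaining
  updates stay conjugate.
- **Poisson** — `y_i ~ Pois(exp(η_i))` with
  `η_i = x_iᵀβ + u_sp(i) + e_i`; the latent log-rates are updated with an
  adaptive random-walk Metropolis step (tuned toward ~40 % acceptance
  during burn-in), everything else conjugate. Interspecific contact-count
  models do not include the within-species temperature offset.
- **Threshold (probit liability)** — a binary state is present iff its
  latent liability `l_i ~ N(β₀ + u_sp(i), 1)` is ≥ 0. The residual
  liability variance is not identifiable and is fixed to 1. Liabilities
  are sampled as one-sided truncated normals via the inverse CDF *on the
  log scale*: tail-clamped samplers silently break the truncation when the
  liability scale grows, which inflates the phylogenetic variance without
  bound — an instability this parameterisation avoids measuring
  incorrectly.

Priors: β ~ N(0, 1e10) (effectively flat); σ²_e ~ inverse-Gamma(0.001,
0.001); the phylogenetic variance uses parameter expansion
`u = α·v`, `v ~ N(0, η² C*)`, `α ~ N(0, 10³)`, `η² ~ IG(0.001, 0.001)`,
so σ²_phylo = α²η² mixes well near zero. The exact constants are the
package's documented choice of "relatively uninformative"; they are
deliberately of the family used by the phylogenetic-MCMC tradition this
pipeline follows. With no data the samplers return these priors, which the
tests verify.

Full-scale chain defaults per family mirror that tradition: Gaussian 10⁶
generations / 10⁵ burn-in / thin 100; Poisson 5×10⁷ / 5×10⁶ / 15 000;
threshold 5×10⁵ / 5×10⁴ / 50, three chains each, chain c seeded as
seed + c. The `mcmc_control(scale = )` knob scales these down; the
validation suite runs the samplers at c. 10³–10⁴ generations with 60–105
observations, sizes at which the calibration experiments below are
statistically meaningful while a full run stays in the minutes range.

**Diagnostics and selection.** `ess()` is the autocorrelation-sum
estimator with Geyer's initial-positive-sequence truncation; `psrf()` is
the classic Gelman–Rubin between/within ratio; `hpd_interval()` is the
narrowest window containing ⌈0.95 n⌉ sorted samples. A fit is accepted
only if every parameter reaches ESS ≥ 1000 and PSRF < 1.1 at full scale
(the thresholds are arguments, scaled runs use proportionally smaller ESS
floors). Model selection enumerates all fixed-effect subsets × the phylo
toggle (32 models for 4 candidates), rejects non-converged fits, excludes
any model whose non-intercept coefficient HPD covers zero, and ranks the
survivors by DIC = 2·mean D(θ_s) − D(θ̄). For the non-Gaussian families
the deviance is evaluated conditionally on the latent effects (the
"conditional DIC" convention); this is fixed and documented because mixing
conventions makes DICs incomparable. If no model survives the HPD filter,
the intercept-only models compete by DIC as an explicit fallback.
`r2_nakagawa()` computes marginal/conditional R² from the variance of the
fitted fixed part against the summed variance components; the Poisson
family adds the lognormal observation-level variance `log(1 + 1/λ̄)`;
measurement-error variances are excluded from the denominator by default
(toggleable) since they are nuisance noise, not biology.

## Contact probability and average networks

For each (thermal group, contact type) binary matrix, each column's
presence probability is 0 or 1 when constant, otherwise the fraction of
pooled posterior intercept samples ≥ 0 from an intercept-only threshold
model on the group's induced subtree (rescaled to unit height). This
quantity is a posterior confidence about the sign of the phylogenetically
corrected liability, *not* a calibrated estimate of the marginal presence
frequency: for a generating marginal probability away from 0.5 it
saturates toward 0/1 as information accumulates. The synthetic-recovery
experiments quantify this (mean estimate within 0.15 of a generating 0.8 on
58-tip trees at scaled-down chains); users comparing probabilities across
groups should read them as evidence strength, not frequency estimates.

Networks keep edges with probability ≥ 0.4 ("at least", so the boundary is
included), with 0.7 as a stricter companion cutoff; node layout is a
deterministic circle ordered by alignment column, with no claim to match
structural positions — domain annotation (LID, NMPbind, CORE column
ranges) is user-supplied where wanted.

## The synthetic-data generators

The generators define the validation conditions and are pure functions of
(configuration, seed):

- `simulate_tree()` — pure-birth ultrametric trees rescaled to unit
  height.
- `simulate_metadata()` — thermal-group frequencies hit 8/38/16/8 of 70
  (rescaled for other tip counts) exactly, with OGTs drawn uniformly
  within each group's range; LID (21 short) and type (12 trimeric) come
  from Brownian liabilities thresholded at the target proportions, giving
  both traits phylogenetic autocorrelation, as observed in real ADK data.
- `simulate_trajectory()` — a deterministic helical toy backbone with
  isotropic Gaussian fluctuations whose sd grows linearly in temperature
  (default 0.25 Å at 280 K, +0.003 Å/K — flexibility rising with
  temperature); planted contacts place group centres 3.5 Å apart in an
  exact fraction of frames and 9 Å otherwise, each pair in its own lateral
  region so pairs cannot cross-react. No physics is claimed; only the
  fluctuation and contact statistics matter downstream.
- `simulate_descriptor_dataset()` — `y = Xβ + u + e + meas`, u Brownian on
  the tree; the default design gives five monomeric species the full
  8-temperature ladder (280–367.5 K in 12.5 K steps, native temperature
  substituted for its nearest rung) and everyone else one native row:
  70 + 5×7 = 105 rows. Default effect sizes (`adk_truth()`): positive
  interspecific (0.001 nm/°C) and intraspecific (0.002 nm/°C) slopes on an
  RMSF-like response, −0.02 nm short-LID offset, phylogenetic sd 0.02 nm,
  residual sd 0.01 nm, replicate SE 0.005 nm — chosen once as a realistic
  echo of the qualitative pattern (flexibility increases with temperature;
  compactness barely responds), all configurable.
- `simulate_contact_matrices()` — liabilities `intercept + b + e` with
  Brownian b (variance 1, matching the threshold model's residual scale)
  and the intercept set to `qnorm(p)·sqrt(1 + σ²_phylo)` so the marginal
  presence probability is exactly p.

**What passing the validation shows — and what it does not.** The
generators reproduce the *statistical structure* the analyses assume:
phylogenetic signal, known slopes, measurement error, liability-governed
contacts, exact design arithmetic. They do not reproduce force-field
physics, real ADK geometry, sequence evolution, or alignment uncertainty.
Green tests therefore certify that the estimators recover truth when the
model family is correct at these problem sizes; they cannot certify
robustness to model misspecification in real trajectories.

## Numerical choices and degenerate inputs

- Kabsch rejects (near-)collinear selections rather than returning an
  arbitrary rotation; the returned rotation always has determinant +1.
- PDB alternate locations resolve to the highest-occupancy conformer
  (ties: first encountered); waters and common ions are dropped on read.
- Non-ultrametric trees are accepted with a warning (the check is
  advisory), negative branch lengths and duplicate tips are errors.
- λ outside [0, 1] is an error (no extrapolation); singular C(λ) aborts
  with a jitter suggestion rather than silently regularising.
- Constant binary responses are refused by `fit_threshold()` — their
  probability is 0/1 by definition and is short-circuited by
  `column_probability()`.
- All-zero design columns and non-finite responses abort before sampling.
- Every generator and sampler takes an explicit seed; chains use
  seed + chain-index, so any reported number is reproducible from the
  master seed.

## Known limitations

- The MCMC samplers are single-threaded pure R; at full-scale settings
  (10⁶–5×10⁷ generations) a 32-model sweep is an overnight job, not an
  interactive one.
- The threshold-model contact probability inherits the estimator's
  saturation behaviour discussed above.
- SASA is O(atoms × neighbours × sphere points) without spatial hashing —
  fine for single-domain proteins, slow for very large complexes.
- Inter-chain contacts of trimeric ADKs are detected but deliberately kept
  out of the alignment-keyed matrices.
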