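# thermadk

Analysis pipeline for studying how prokaryotic **adenylate kinases (ADKs)**
adapt to temperature at the structural level. The package takes molecular
dynamics trajectory snapshots (multi-model PDB), a species time tree
(Newick), a master amino-acid alignment (FASTA) and per-protein metadata,
and asks three questions:

1. Do ADKs from psychrophilic, mesophilic, thermophilic and
   hyperthermophilic species occupy different regions of structural
   parameter space?
2. How do flexibility (RMSF) and compactness (SASA, radius of gyration)
   respond to temperature *within* and *across* species, once measurement
   error and phylogeny are accounted for?
3. Are specific side-chain contacts (salt bridges, charged–polar and
   polar–polar contacts) associated with thermal adaptation?

It is aimed at structural bioinformaticians and molecular evolution
researchers who have simulation snapshots in hand and want the downstream
comparative statistics to be reproducible and tested.

## What it computes

**Structural descriptors** (`compute_rmsf`, `compute_sasa`, `compute_rgyr`,
`descriptor_row`). Per-residue RMSF after iterated Kabsch superposition on
the mean structure, Shrake–Rupley solvent-accessible surface area (probe
1.4 Å, 960 quasi-uniform sphere points), and the alpha-carbon radius of
gyration — each with replicate means and standard errors.

**Side-chain contacts** (`detect_frame_contacts`, `occupancy_filter`,
`map_to_alignment`, `build_contact_matrices`). Residue pairs whose
interacting-group centres (carboxyl, guanidinium, ammonium, amide,
hydroxyl) come within 0.5 nm are classified as `sb` (negative–positive),
`pos-pol`, `neg-pol` or `pol-pol`; contacts present in less than 50 % of
pooled frames are discarded; survivors are keyed by alignment-column pairs
so they can be compared across proteins.

**Phylogenetic PCA** (`phylo_pca`). PCA of the evolutionary covariance
`R = (X − 1a)ᵀ C(λ)⁻¹ (X − 1a) / (n − 1)`, where `C(λ)` is the Brownian
tree covariance with Pagel's λ scaling the off-diagonals; λ is estimated by
maximising the multivariate Brownian profile likelihood on [0, 1].

**Bayesian phylogenetic mixed models** (`fit_gaussian_mev`, `fit_poisson`,
`fit_threshold`). MCMC (Gibbs / Metropolis-within-Gibbs) samplers for

- Gaussian *meta-analytic* models
  `y_i ~ N(x_iᵀβ + u_sp(i), σ²_e + se_i²)` with known per-observation
  measurement-error variances,
- Poisson log-link latent models for contact counts, and
- probit *threshold* models for contact presence/absence, residual
  liability variance fixed to 1,

each with an optional phylogenetic random intercept
`u ~ N(0, σ²_phylo C)` sampled with a parameter-expanded prior. Model
comparison follows the HPD-then-DIC rule (`enumerate_models`,
`select_model`): candidate models whose 95 % HPD interval for any
non-intercept coefficient includes zero are excluded, and the survivor with
the lowest DIC wins; `r2_nakagawa` reports marginal/conditional R².
Convergence is policed with `ess` (≥ 1000) and `psrf` (< 1.1).

**Average contact networks** (`column_probability`,
`build_average_network`, `network_summary`). For every alignment-column
contact in every thermal group, a phylogenetically corrected presence
probability — the fraction of posterior intercept samples ≥ 0 from the
threshold model (trivially 0/1 for constant columns) — and the networks of
contacts with probability ≥ 0.4 (or a stricter 0.7).

**Synthetic data with known truth** (`simulate_tree`, `simulate_metadata`,
`simulate_trajectory`, `simulate_descriptor_dataset`,
`simulate_contact_matrices`, `simulate_alignment`). Generators that emulate
the study design — 70 species in 8/38/16/8 thermal groups, 21 short-LID and
12 trimeric proteins, a temperature ladder (8 temperatures, 280–367.5 K) for
five designated species, liability-governed contacts — so the whole pipeline
can be validated end to end.

## Worked example

```r
library(thermadk)

tree <- simulate_tree(70, seed = 1)
meta <- simulate_metadata(tree, seed = 1)
dat  <- simulate_descriptor_dataset(tree, meta, adk_truth(), seed = 1)

fit <- fit_gaussian_mev(
  dat, "rmsf", se = "se", fixed = c("tnat_C", "delta_T", "lid"),
  species = "species", tree = tree,
  control = mcmc_control("gaussian_mev", n_iter = 4000, burn_in = 1200,
                         thin = 2, n_chains = 2, seed = 1)
)
tidy(fit)
#> # A tibble: 6 × 7
#>   term           estimate std.error hpd.lower hpd.upper   ess  psrf
#>   <chr>             <dbl>     <dbl>     <dbl>     <dbl> <dbl> <dbl>
#> 1 (Intercept)   0.131     0.00454    1.23e- 1  0.141    1942. 1.000
#> 2 tnat_C        0.00162   0.0000879  1.44e- 3  0.00178  1111. 1.00
#> 3 delta_T       0.00205   0.0000634  1.93e- 3  0.00217  1871. 1.000
#> 4 lidshort     -0.0186    0.00344   -2.54e- 2 -0.0118   2800  1.000
#> 5 sigma2_phylo  0.0000418 0.0000430  2.86e-11  0.000130  528. 1.00
#> 6 sigma2_e      0.000130  0.0000238  8.63e- 5  0.000178 1465. 1.00

r2_nakagawa(fit)
#> # A tibble: 1 × 2
#>   r2_marginal r2_conditional
#>         <dbl>          <dbl>
#> 1       0.932          0.949
```

The intraspecific slope (`delta_T`, response change per °C of displacement
from the native temperature) recovers its generating value (0.002 nm/°C)
tightly, and the short-LID offset recovers −0.02 nm. The interspecific
slope (`tnat_C`, change per °C of native temperature) lands at 0.0016
against a generating 0.001 — on a single 70-species tree the realised
phylogenetic deviations partially align with native temperature, which is
exactly why the calibration experiments below average over many trees. All
95 % HPD intervals exclude zero: the same structure of evidence the real
analysis produces — flexibility rising with temperature both within and
across species, with a LID-length offset. `r2_nakagawa(fit)` splits the
explained variance into the fixed-effect share and the additional
phylogenetic share, and `glance(fit)` adds DIC and convergence
diagnostics.

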