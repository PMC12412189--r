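---
title: "Biaxial aortic mechanics: model, fitting and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biaxial aortic mechanics: model, fitting and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamech)
```

## The problem this package addresses

Thoracic aortic aneurysm (TAA) in Marfan syndrome develops while the aorta
is still maturing, so diameter alone cannot separate normal growth from
disease. `aortamech` implements a complete analysis chain for passive
biaxial inflation-extension tests of mouse aortas on a pressure myograph:
from raw pressure-diameter-force traces, through constitutive-model fitting,
to physiologic biomechanical metrics and cohort-level regression models that
ask *which* metrics track the deformed inner diameter in wildtype (WT)
versus fibrillin-1-deficient (MU) vessels.

Because raw myograph datasets of this kind are rarely deposited, the package
also contains a first-class forward simulator. Every stage of the analysis
can therefore be validated end-to-end against synthetic cohorts with known
ground truth.

## Kinematics and experimental stresses

The vessel is an incompressible thick-walled cylinder deforming without
shear. With unloaded inner/outer diameters $D_i$, $D_o$ and length $L$, and
loaded values $d_o$ (tracked by the myograph camera) and $l$:

$$\lambda_z = l/L, \qquad
  d_i^2 = d_o^2 - (D_o^2 - D_i^2)\,L/l, \qquad
  \lambda_\theta = \tfrac12\!\left(\frac{d_i}{D_i} + \frac{d_o}{D_o}\right),
  \qquad \lambda_r = \frac{1}{\lambda_\theta \lambda_z}.$$

The mid-wall average Cauchy stresses follow from equilibrium of the
pressurized, axially loaded tube:

$$\sigma_\theta = \frac{P\,d_i}{d_o - d_i}, \qquad
  \sigma_z = \frac{4f + P \pi d_i^2}{\pi\,(d_o^2 - d_i^2)}.$$

Internal units are fixed at mm, mN, kPa and seconds, so mN/mm$^2$ = kPa and
stresses, moduli and strain-energy densities share one unit
(1 kPa = 1 kJ/m$^3$). Pressures are converted at ingest with
1 mmHg = 101.325/760 kPa. The instrument is assumed to track the *outer*
diameter, the standard myograph configuration; a directly tracked inner
diameter is accepted through the `d_i` argument of `compute_state()`.

## The constitutive model

The wall is modeled with a two-fiber-family HGO strain-energy density:
an isotropic Neo-Hookean matrix (attributed to elastic fibers) plus two
symmetric exponential fiber families at $\pm\alpha$ from the
circumferential direction (attributed to collagen):

$$W = \frac{c}{2}(I_1 - 3) +
      \sum_{j=1}^{2} \frac{k_1}{2k_2}\left(e^{k_2 (I_{4j}-1)^2} - 1\right),$$

with $I_1 = \lambda_\theta^2 + \lambda_z^2 + \lambda_r^2$ and
$I_{4j} = \lambda_\theta^2\cos^2\alpha_j + \lambda_z^2\sin^2\alpha_j$.
Parameters: $c > 0$ (kPa), $k_1 > 0$ (kPa), $k_2 > 0$ (dimensionless
nonlinearity), $\alpha \in [0^\circ, 90^\circ]$.

Predicted stresses come from $\sigma = 2F(\partial W/\partial C)F^T - pI$
with the Lagrange multiplier eliminated by the radial traction condition
$\sigma_{rr} = 0$. This matches the Laplace-type mean experimental stresses
the model is regressed against, which neglect the radial stress; a
$\sigma_{rr} = -P/2$ mid-wall compromise is available through the `sigma_r`
argument for sensitivity checks. Fibers only bear load in extension
($I_4 > 1$) by default (`tension_only`); physiologic states here always
have $I_4 > 1$, so the switch matters only at near-unloaded states.

Numerical conventions:

* below $k_2 < 10^{-8}$ the fiber energy switches to its series expansion
  $\tfrac{k_1}{2} q^2 (1 + k_2 q^2/2 + k_2^2 q^4/6)$, $q = I_4 - 1$, keeping
  the $k_2 \to 0$ (quadratic-fiber) limit exact, and `expm1()` is used in
  the exact branch to avoid cancellation;
* exponents $k_2 q^2 > 700$ abort with an overflow error naming the record,
  rather than returning `Inf`;
* angles are degrees at every interface, radians internally.

### Incremental moduli

The circumferential and axial incremental moduli, the package's measures of
material stiffness at the physiologic state, are

$$\zeta_\theta = 4\lambda_\theta^2 \frac{\partial W}{\partial C_{\theta\theta}}
  + 4\lambda_\theta^4 \frac{\partial^2 W}{\partial C_{\theta\theta}^2},$$

and analogously in $z$. The derivatives are taken with the radial component
eliminated first ($C_{rr} = 1/(C_{\theta\theta}C_{zz})$): differentiating at
frozen $\lambda_r$ would ignore the incompressibility reaction and make the
isotropic part of $\zeta_\theta$ independent of $\lambda_r$, which is
inconsistent with reading $\zeta$ as the stiffness of an incompressible
material about its operating point. The unconstrained variant remains
available (`constrained = FALSE`) for sensitivity analysis. In the
Neo-Hookean limit the closed form reduces to
$\zeta_\theta = 2c(\lambda_\theta^2 + \lambda_r^2)$, i.e. $4c$ at the
reference state — a useful analytic anchor used by the test suite, which
also verifies the general closed form against central finite differences of
$W$.

## Fitting

For one sample, the third loading limb of each of the six test protocols is
pooled (limbs are segmented on the smoothed driven variable — pressure for
inflation protocols, stretch for axial protocols — with a centered
moving-average window of 5 samples and ties broken to the earliest index).
The fit minimizes the normalized error

$$\mathrm{error} =
 \frac{\sum_i (\sigma_{\theta,exp} - \sigma_{\theta,pred})^2}{\sum_i \sigma_{\theta,exp}^2}
 + \frac{\sum_i (\sigma_{z,exp} - \sigma_{z,pred})^2}{\sum_i \sigma_{z,exp}^2}$$

plus a penalty that keeps the Neo-Hookean matrix carrying at least 10 % of
the predicted circumferential stress:
$\mathrm{penalty}(i) = 0.1 - \sigma_{\theta,iso}/\sigma_{\theta,total}$
whenever that share falls below 0.1, and the objective is
$\mathrm{error} + \sum_i \mathrm{penalty}(i)^2$.

**Penalty convention.** The iso share is ill-defined where the predicted
total stress vanishes, and it is *negative* at near-zero-pressure records of
any inflation protocol run at axial stretch above one (equilibrium at
$P = 0$ forces $\sigma_\theta = 0$, and tension-only fibers then require a
negative matrix contribution). The package therefore clamps the per-record
penalty to $[0, 0.1]$: records with non-positive predicted total stress, or
a negative iso share, carry the maximal penalty 0.1. Without the clamp the
penalty diverges on exactly the records every experiment contains, and the
true parameters of a simulated sample would score arbitrarily badly.

**A property worth knowing.** Even clamped, the penalty makes the estimator
*regularized rather than consistent*: wherever a record's iso share passes
through $(0, 0.1)$ the penalty has a gradient at the true parameters, and
the fitted optimum is displaced toward parameter sets with a healthier
matrix share. On simulated data the displacement ranges from negligible
(when only flat, capped records are active) to large for strongly
fiber-dominated truths. This is a property of the method, not a defect of
the optimizer: with bench data every sample is regularized the same way,
and the penalty is what keeps the matrix/fiber split interpretable in terms
of elastin and collagen. The acceptance suite measures this bias directly
via simulate-then-fit round trips.

The optimizer is L-BFGS-B on $(\log_{10} c, \log_{10} k_1, \log_{10} k_2,
\alpha)$ with bounds $c \in [1, 200]$ kPa, $k_1 \in [0.1, 500]$ kPa,
$k_2 \in [10^{-3}, 50]$, $\alpha \in [0^\circ, 90^\circ]$ — a search box
spanning the magnitudes reported for murine aortas, not a constraint on
reporting — from 10 seeded Latin-hypercube starts (objective tolerance
`factr = 100`, i.e. ~$10^{-14}$ relative). Goodness of fit is the pooled
coefficient of determination over both stress directions; the alternative
reading $1 - \mathrm{error}/2$ is not used.

Samples are screened after fitting: within each vessel cohort (ages and
genotypes pooled), a sample whose $c$, $k_1$, $k_2$, $\alpha$ or $k_1/k_2$
lies more than 3 SD from the cohort mean is excluded from all downstream
analyses. Which quantities the rule covers is configurable; the default is
the five reported fit quantities.

## Physiologic metrics

Each sample is evaluated at its own operating point:

* the **in vivo axial stretch**, estimated as the stretch at which axial
  force is invariant to inflation — least-squares slopes of $f$ versus $P$
  at each tested stretch, zero located by linear interpolation between
  bracketing stretches (the bench definition gives no numeric criterion, so
  slope-zero interpolation is the package's rule);
* the **group mean blood pressure** for the sample's genotype and age, from
  the packaged pressure table (WT: 99, 106, 104, 106 mmHg; MU: 96, 109,
  105, 104 mmHg for 1–4 months).

The deformed inner diameter is linearly interpolated from the
pressure-diameter data of the third loading limb at the in vivo stretch
(pressure steps are dense, ~3 mmHg, so higher-order interpolation buys
nothing testable; extrapolation outside the limb is refused). Stresses,
stored energy and moduli are then evaluated from the *fitted model* at that
state — the iso/aniso splits only exist model-side — with the experimental
Laplace stresses at the interpolated state emitted as comparison columns.
If a sample's estimated in vivo stretch sits more than 0.01 from the
nearest inflation protocol's fixed stretch, the nearest protocol is used
with a warning. Evaluating at the data-interpolated state (default) versus
the model-equilibrium state differs negligibly for well-fitted samples;
both are available.

## The forward simulator

`solve_equilibrium()` inverts the analysis chain: given parameters,
geometry, a fixed axial stretch and a pressure, it root-finds the outer
diameter at which the model's circumferential stress balances the Laplace
stress (bracketing root-finder, $10^{-10}$ mm tolerance; the bracket falls
back to the incompressibility feasibility limit at high axial stretch), and
returns the axial force from the axial equilibrium. The simulated schedule
mirrors the bench protocol: three inflation ramps 0–150 mmHg at the in vivo
stretch and ±0.15 around it (within the bench practice of 0.1–0.2), and
three stretch sweeps at 50, 100, 150 mmHg, each rendered as three
triangular cycles with 50 points per limb; limbs are identical before
noise.

The in vivo stretch of a simulated sample is the *model-implied*
force-invariance stretch, found by root-finding the force–pressure slope
over $\lambda_z$. This keeps the simulator self-consistent: re-estimating
the in vivo stretch from the rendered traces recovers the value the
schedule was centered on. Group differences in the in vivo stretch are
therefore emergent properties of the constitutive parameters, not dials.

Virtual cohorts draw per-sample parameters log-normally (mean-parameterized,
CV 15 %) around cell means built from a WT-ASC baseline
($c = 35$ kPa, $k_1 = 20$ kPa, $k_2 = 0.8$, $\alpha = 30^\circ$,
$D_i = 1.0$ mm, $D_o = 1.2$ mm, $L = 3$ mm) and multiplicative group
effects: MU cells have a softer matrix, weaker but more nonlinear fibers
and larger diameters; DSC cells are smaller, more nonlinear and more
axially oriented; with age the vessel grows and stiffens. These defaults
reproduce the qualitative group structure of real WT/MU aortas (including
an emergent lower in vivo stretch in MU), and measurement noise defaults to
SD 5 µm on diameter and 0.05 mN on force — instrument-level values chosen
once as realistic. Validation never relies on the effect sizes themselves,
only on round-trip recovery of whatever was drawn. Each virtual animal
contributes an ASC and a DSC sample sharing its `animal_id`.

A draw can land on a vessel for which the bench session is physically
unperformable: with axially dominant, stiff fibers there is no
zero-circumferential-stress configuration at the highest scheduled axial
stretch, so the protocol could never be unloaded to 0 mmHg. Such draws are
rejected and redrawn deterministically from the same cell distribution
(per-sample seed streams, at most 20 attempts) — the virtual analogue of
only mounting vessels the protocol can actually be run on.

What the simulator does *not* emulate: residual stress / opening angles,
smooth-muscle tone, viscoelastic rate dependence (loading rates are
metadata only), wall heterogeneity, and measurement artifacts beyond
additive Gaussian noise. Passing tests therefore demonstrate correctness of
the analysis chain, not robustness to every bench pathology.

## Cohort statistics

* **Standardization**: metrics are z-scored column-wise with the
  *population* SD (denominator $n$), within the modelled subset
  (per-genotype for the diameter models). The transformation parameters are
  stored for back-conversion.
* **Three-way ANOVA**: fixed-effects factorial age × vessel × genotype with
  all interactions; Type III sums of squares with sum-to-zero contrasts by
  default (Type I available); percent variation is $100\,SS/SS_{total}$
  including the residual, an exact partition for balanced designs.
* **Diameter models**: forward-stepwise regression of the standardized
  deformed inner diameter on the standardized metrics, with a random
  intercept per animal (each animal contributes its ASC and DSC rows); the
  fallback to fixed effects is automatic when no animal repeats. Entry: the
  candidate with the smallest Wald p-value (Satterthwaite df in the mixed
  case) enters while that p-value clears a Bonferroni-corrected threshold
  $\alpha/m$, $m$ the number of candidate metrics (fixed family). The
  correction is the package's choice: it keeps the probability of *any*
  spurious entry per step at $\alpha$, whereas raw thresholding of the
  minimum of $m$ p-values admits a noise predictor in roughly
  $1-(1-\alpha)^m$ of steps (23 % for five candidates) and makes "exact
  model recovery" an unfair ask of the procedure. Raw entry is available
  via `multiplicity = "none"`; both thresholds are arguments.
  A candidate whose entry would push any VIF to 3 or above triggers the
  collinearity rule: the member of the conflicting pair with the higher
  standalone contribution to the response is kept, the other is excluded
  from further consideration.
* **Relative contributions**: each selected predictor's share of the
  adjusted $R^2$ is its average marginal $R^2$ gain over all entry orders
  (LMG-style), rescaled to sum to the model's adjusted $R^2$. For the mixed
  models, $R^2$ is the marginal (fixed-effects) variance share and the
  adjustment is the usual sample-size correction; the definition is printed
  in the report.

Two readings were genuinely open and are resolved as follows: the source
protocol's "Z-stack normalization" phrase is read as z-score
standardization (the only standard interpretation; the term otherwise names
a microscopy acquisition mode), and the unstated random-effects structure
is a random intercept per animal — the only repeated-measures structure in
the design.

## Problem sizes used in validation

The test and acceptance suites use: 200 random draws for the
stress–energy and moduli oracles; 100 draws for the equilibrium-solver
oracle; 20 simulated samples (noiseless and noisy) for the
simulate-then-fit round trip, with truths drawn over the realistic murine
range $c \in [10, 80]$ kPa, $k_1 \in [2, 80]$ kPa, $k_2 \in [0.1, 5]$,
$\alpha \in [15^\circ, 55^\circ]$ (the span of the cohort generator's
cells; corners of the full search box describe experiments with no
force-invariance stretch below $\lambda_z = 2.2$ and are not physical
study conditions); 100 seeded replicates at $n = 200$ for
planted-predictor recovery; and a 128-sample virtual cohort for the
end-to-end determinism and scaling check.

## Known limitations

* The penalized fit is a biased estimator for fiber-dominated tissues (see
  above); comparisons should always be within-method.
* The mean (Laplace) stress treatment ignores transmural gradients and
  residual stress; metrics are mid-wall averages.
* The in vivo stretch estimate interpolates the force–pressure slope
  linearly between three tested stretches; its curvature bias grows when
  the true value sits near the edge of the tested range.
* Sex is carried through the data model but, as in the underlying
  experimental design, not modelled statistically.

## A minimal session

```{r example, eval = FALSE}
params <- hgo_parameters(c = 35, k1 = 20, k2 = 0.8, alpha = 30)
geom <- unloaded_geometry(D_i = 1.0, D_o = 1.2, L = 3.0)

# forward: one virtual sample, six protocols
s <- simulate_sample(params, geom, seed = 7)

# inverse: pool third loading limbs, fit, evaluate at 106 mmHg
ds <- build_fit_dataset(s$traces, geom)
fit <- fit_hgo(ds, seed = 1)
state <- physiologic_state(s$traces, geom, s$lambda_iv,
                           mmhg_to_kpa(106))$state
evaluate_metrics(state, fit$params, P_eval = mmhg_to_kpa(106))

# a full virtual cohort and its statistics
res <- run_pipeline(cohort_design(n_per_cell = 2, seed = 1))
res$models$MU
```
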