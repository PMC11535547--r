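---
title: "A mechanistic synovium model for simulating rheumatoid-arthritis trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic synovium model for simulating rheumatoid-arthritis trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasim)
```

## The model

`rasim` simulates established, stable rheumatoid arthritis as a well-mixed
1 mL volume of inflamed synovium. Nine cell populations (fibroblast-like
synoviocytes, endothelial cells, macrophages, Th1, Th17, Treg, cytotoxic
T cells, B cells, plasma cells; densities in cells/mL) and seventeen soluble
mediators (TNF-α, IL-6, IL-17, IL-12, IL-23, IL-1β, IFN-γ, GM-CSF, BAFF,
IL-10, TGF-β, RANTES, MIP-3α, MCP-1, VEGF, a lumped cell-adhesion-molecule
factor CAM, and autoantibody; ng/mL) evolve by ordinary differential
equations:

* each **cell** gains density by zeroth-order proliferation and influx from
  the circulation and loses it by first-order apoptosis,
  `d(cell)/dt = kg·f_prolif + kIn·f_influx − kdeg·f_apop·cell`;
* each **mediator** is secreted by its source cells in proportion to their
  densities and cleared first-order,
  `d(med)/dt = F·Σ_cells k_sec·cell·f_sec − clr·med`.

Every `f_*` is a multi-cytokine regulation factor
`(1 + ProRate)·(1 − AntiRate)`, where ProRate and AntiRate are sums of
saturating Hill terms `vm·c^s/(c^s + km^s)` over the cytokines regulating
that process, capped at 10 (pro) and 0.75 (anti). The caps bound any
regulated rate between 0.25× and 11× its baseline; both caps are
configurable (`cap_policy()`), and with an anti cap of 0.9 the floor is
0.1× baseline. The cap applies to the *sum*, not to individual terms, so
strongly co-stimulated processes saturate.

Zeroth-order proliferation balanced against first-order death is what lets
the system settle into a finite dynamic steady state representing a
patient's stable disease; disease severity is encoded by where that steady
state sits.

Two structural special cases:

* **Essential mediator.** IFN-γ secretion by Th1 cells requires IL-12; the
  rate is multiplied by a gate `c/(c + km_gate)` that vanishes without
  IL-12 rather than receiving a fold-change bonus (`essential_gate()`).
* **CAM.** The adhesion-molecule factor is not secreted; it relaxes quickly
  toward a saturating (Hill, exponent 2) function of endothelial density
  with half-max at the midpoint of the endothelial literature range,
  representing adhesion-molecule expression on the endothelium.

B cells feed plasma cells through a first-order differentiation flux
(`kdiff_BCells_PlasmaCells`), up-regulated by IL-6.

### Network wiring

The regulatory wiring is reconstructed mechanically from the names of the
129 cohort-varied parameters (`parameter_bounds()`): a name like
`IL6SecFLS_MaxbyIL17` declares one edge (IL-17 up-regulates IL-6 secretion
by FLS) whose maximal fold effect is the varied parameter. Group names
expand to one edge per member cell under a shared parameter: `TCell*`
covers Th1/Th17/CTL, `Lympho*` adds Treg and B cells, `Leuko*` additionally
macrophages. Qualified names such as `RANTESSecFLS_byTNFa_MaxbyIFNg`
(IFN-γ modulating the TNF-α-driven component of RANTES secretion) are
flattened to plain edges on the same secretion process; modeling
conditional co-stimulation separately would require interaction terms the
effect aggregation deliberately excludes.

Edge signs are not encoded in the names and were assigned once from
standard immunology: IL-10 and TGF-β are inhibitory on effector-cell
proliferation, influx and pro-inflammatory secretion (but TGF-β drives
Treg proliferation and VEGF secretion); survival factors act as
anti-apoptotic edges on their dependent cells (BAFF for B cells, IL-6 for
T and plasma cells, VEGF for endothelium, and GM-CSF, IFN-γ and TNF-α for
synovial macrophages — wiring TNF-α as a macrophage survival/activation
signal is also what makes TNF neutralization deplete macrophages rather
than protect them, consistent with the clinical efficacy of anti-TNF
agents). Everything else is a positive driver. All signs live in one
table (`ANTI_SIGN_PARAMS`) and are serialized with the network, so a
different reading is a one-line configuration change.

### Default numerical parameterisation

Literature tables fix the score parameters, the varied-parameter bounds and
the plausibility ranges. Everything else defaults as follows, chosen once:

* **Edge half-max `km`** — the regulator's *reference concentration* (the
  geometric midpoint of its literature range). Each effect is therefore
  half-engaged in typical disease, and because baseline concentrations vary
  by orders of magnitude across the cohort, individual patients span the
  whole saturating curve. This is the single most consequential default:
  placing `km` far below the reference saturates every effect and produces
  a cohort in which no therapy can move the score, which is clinically
  untenable.
* **Edge slope** — 1 (least-assumption Hill form).
* **Edge `vm`** — geometric midpoint of that parameter's bounds.
* **Apoptosis rates** — converted from percent-apoptosis assays via
  `apoptosis_rate()` (`ln(100/(100−pct))/t`); Th1 uses the
  activation-induced-cell-death datum of 15% in 6 h, 0.65/day; structural
  cells turn over more slowly (FLS 0.05/day, endothelium 0.069/day).
* **Mediator clearance** — from reported half-lives, minutes–hours for
  cytokines (8.3–33.3/day), weeks for autoantibody (0.033/day).
* **Secretion split** — where several cell types secrete one mediator, the
  reference flux is split by fixed weights (macrophages dominate TNF-α,
  FLS dominate IL-6, etc.); the weights matter only for the reference
  patient, since cohort sampling rescales each cell's secretion
  independently.
* **Influx share** — 20% of each immune cell's production at reference
  (none for FLS and plasma cells), reflecting the dominance of in-situ
  proliferation.

### The reference patient is calibrated in closed form

`reference_patient()` solves for baseline proliferation, influx and
secretion rates such that the fully coupled steady state sits exactly at
the geometric midpoints of the literature density and concentration
ranges. Because every regulation factor depends only on the state, and the
target state is known, each baseline is simply the required steady-state
flux divided by the regulation factor evaluated at the target — no
iteration, no tolerance. With regulation removed the same construction
collapses to the decoupled closed forms `(kg + kIn)/kdeg` and
`flux/clearance`, which the tests exploit as oracles. These baselines are
re-derived, not copied from any published patient, and the steady state —
not the baseline values — is the calibrated object.

## Solvers

Time courses use `deSolve::lsoda` (stiff-capable) on a compiled
right-hand side, relative tolerance 1e-8 (1e-6 for cohort-scale trial
simulation, where the readout is a score quoted to two decimals), absolute
tolerances 1e-3 cells/mL and 1e-9 ng/mL, restarting at dose times where
bolus PK makes the forcing discontinuous. Steady states are declared when
the scaled derivative norm `max |dy/dt|/|y|` falls below 1e-6/day.

For cohort work the package first runs a damped fixed-point (Picard)
iteration on the production/removal balance in log space (damping 0.5),
verifying the candidate against the same residual norm and falling back to
integration when it fails — the fixed route is ~100× faster and agrees
with the integrator wherever both converge (tested). Rates are computed
from non-negative-clipped states while linear removal terms use the raw
state, so small negative excursions self-correct; trajectories are
reported floored at zero.

## Drugs

Drug exposure is linear compartmental PK solved in closed form
(superposition of per-dose bi-exponentials): methotrexate (MTX) a
two-compartment model with weekly oral bolus (15 mg), adalimumab (ADA) a
one-compartment model with first-order subcutaneous absorption (40 mg
Q2W), tocilizumab (TCZ) a two-compartment intravenous model (8 mg/kg Q4W,
70 kg default). Numeric PK parameters are population values from the
published PK literature of each drug, shipped as configurable defaults;
the package's quantitative claims rest on closed-form PK invariants
(dose-proportionality, superposition), not on any particular set. Synovial
drug concentration is a quasi-equilibrium fraction (default 0.3) of the
central concentration.

Pharmacodynamics:

* **MTX** acts through three Hill effects of the bioavailability-scaled
  central concentration, sharing the calibrated parameterisation
  (vm 0.5, km 1e-5 mg/L, slope 2): secretion by all cells except Tregs is
  multiplied by `(1 − effect)`, Treg secretion by `(1 + effect)`, and
  immune-cell influx by `(1 − effect)`. With the tiny km, exposure is
  effectively saturating over the dosing interval, so MTX acts as a
  sustained ~2-fold damper on cytokine output.
* **ADA** binds TNF-α at equilibrium; the free fraction solves the binding
  quadratic with mass conservation (`ada_free_tnf()`), and free — not
  total — TNF-α drives every TNF-α regulation edge. Binding is modeled in
  the synovium, where TNF-α acts in this model. Clearance still acts on
  total TNF-α (drug-complexed cytokine is assumed to clear similarly).
* **TCZ** blocks the IL-6 receptor; without an explicit receptor species,
  the same fold reduction in signaling is imposed by dividing IL-6
  clearance by `kd/(tcz + kd)`, so steady-state IL-6 falls by exactly that
  factor at fixed secretion.

Affinities default to in-vitro values converted to mass units (ADA–TNF-α
~15 ng/mL; TCZ ~0.37 mg/L).

## Clinical score layer

The model DAS28-CRP is a weighted sum of saturating per-cell terms,
`Σ w_c · x^γ/(x^γ + Km^γ)` with γ = 2.5 and published per-cell weights and
half-max densities; positive weights sum to 10, and Tregs enter with
weight −0.5. Two defaults resolve gaps in the published parameterisation:
the Treg term uses the same Hill transform as the other cells (its printed
form omits it, but a Km and γ are published for Tregs, and a raw-density
term would be unbounded below; `score_parameters(treg_hill = FALSE)`
preserves the literal reading), and the CTL half-max, which is not
published, defaults to the geometric midpoint of the CTL density range.

ACR20/50/70 are percent reductions of the model DAS28-CRP from baseline
(≥20/50/70%); response flags use the published thresholds (remission
< 2.6, low disease activity < 3.2, change > 1.2). An inadequate responder
(IR) is a patient with < 50% reduction and post-therapy score > 3.2.

## Virtual cohort and Vpop calibration

`sample_cohort()` draws the 129 varied parameters log-uniformly within
their bounds (the published distributions are displayed on log axes; the
sampling law is configurable). `filter_plausible()` solves each
candidate's steady state and keeps patients whose nine cell densities all
lie inside the literature ranges and whose baseline score exceeds 3.2
(trial entry criterion); mediator ranges are advisory only — excursions
are counted, not excluding, because tissue cytokine measurements are far
less reliable than biopsy cell counts.

Joint plausibility is rare under global log-uniform sampling (fractions of
a percent at desk scale — the narrow endothelial range alone is a strong
filter), so the pipeline enriches: it resamples log-uniformly inside
shrunken boxes around plausible seeds (`enrich_cohort()`), exactly the
published workflow's answer to under-represented phenotypes. A second,
response-targeted form of enrichment resamples in tight, progressively
shrinking boxes around the strongest responders to each therapy
(hill-climbing over rounds), because deep responders — patients whose
inflammation collapses under cytokine blockade — occupy small corners of
parameter space that global sampling misses at desk scale.

Trials are simulated from each patient's own steady state to the readout
week (MTX week 12; ADA and TCZ week 24; the ACR and DAS readouts are taken
at one common week per trial). TCZ runs on the methotrexate inadequate
responders, as in the trial it is calibrated to.

**Placebo correction.** Observed response fractions mix drug and placebo
response. Assuming independence, `P_obs = P_d + P_p − P_d·P_p`, so the
drug-attributable fraction is `P_d = (P_obs − P_p)/(1 − P_p)`
(`placebo_correct()`); this probabilistic variant is the assumed reading
of the correction recommended in the trial-calibration literature. All
endpoint targets are corrected this way from the published arm
percentages.

**Selection.** `select_vpop()` draws ~300 patients whose baseline-score
distribution and placebo-corrected endpoint fractions match the targets:
an importance-weighted initial draw toward the baseline normal (weights
`dnorm(das; μ, σ)/density(das)`, the prevalence-weight analogue), refined
by simulated annealing on member swaps against the summed squared
normalized residuals. TCZ quantities are evaluated on the selection's
MTX-IR subset. Any selector meeting the tolerance contract (±0.3 on
baseline means, ±5 percentage points on endpoint fractions) is conformant;
the residual report (`tidy()` on the selected population) states achieved
versus target for every quantity, and a selection that cannot reach a
target is flagged rather than hidden.

### What the desk-scale generator does and does not emulate

The defaults (`vpop_pipeline()`: 5,000-candidate base cohort, pool of
~900, Vpop of 300) are a desk-scale rendition of the published
200,000 → 50,000 → 300 workflow; the full sizes are one preset away but
change wall-clock time, not code paths. The synthetic cohort emulates
between-patient variability as independent log-uniform parameter draws —
real patients correlate their parameters; it contains no measurement
noise, no dropout, no placebo arm of its own (placebo response enters only
through the corrected targets), and no disease progression. Passing
calibration therefore shows the mechanistic layer can reproduce
population-level trial statistics under the stated variability model — not
that it predicts individual patients.

Two structural caveats on the tocilizumab arm deserve emphasis. First,
deep-response phenotypes (ACR70-level collapses, remission) are rare and
reachable only through the hill-climbing enrichment. Second, and more
fundamentally: because this model *defines* ACR categories as percent
change of the model DAS28-CRP, remission (post-score < 2.6) from any
baseline above ~3.25 necessarily implies an ACR20 response, so the
selected fraction in remission can never materially exceed the ACR20
fraction. The placebo-corrected tocilizumab targets demand the opposite
ordering — the correction shrinks ACR20 strongly (25% placebo ACR20
response) but barely touches remission (2% placebo remission) and thereby
inverts the raw arms. No subpopulation of this model family can satisfy
both corrected targets inside ±5 points simultaneously; the annealed
selector converges to the boundary compromise (both fractions midway
between their targets), and the residual report states the miss rather
than masking it. A score layer in which ACR and DAS28 were distinct
measurements would dissolve the tension; within the percent-change
definition it is intrinsic.

## Sensitivity analysis

`local_sensitivity()` re-solves the steady state with each parameter
doubled and halved and reports percent changes of the score, sorted for a
tornado plot (`autoplot()`); non-converged perturbations are flagged, not
dropped. `sobol_indices()` implements the Saltelli scheme
(`n·(k + 2)` evaluations) with the centered first-order estimator and the
Jansen total-order estimator, bootstrap confidence half-widths, and
pairwise NA handling; it is validated against analytic variance
decompositions (additive linear and Ishigami functions) before use on the
model. `sobol_analysis()` samples in log-parameter space (the bounds span
orders of magnitude) with steady-state DAS28-CRP as the output; base
sample 256 at desk scale, with the published 10,000 a parameter away.
Pre-therapy disease severity is the analyzed output; therapy-response
sensitivity can be composed from the same pieces.

## Numerical and degenerate-input conventions

* Regulation edges are summed in a canonical order (regulator, then
  target), making aggregation independent of edge list order bit-for-bit.
* `hill(0, …) = 0` exactly, including fractional slopes (the `0^s/0^s`
  limit is taken as 0).
* A zero dose, an absent therapy and a `"none"` protocol are all the
  identity on the dynamics.
* Patients are immutable parameter vectors; unknown names and negative
  rates are rejected at construction, as is any nonzero FLS influx
  (structural cells do not migrate).
* Selection with a pool smaller than the requested Vpop falls back to
  sampling with replacement and reports it; an empty entry-criterion
  subset is an explicit error.
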