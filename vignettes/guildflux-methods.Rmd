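---
title: "Methods: guild-resolved analysis of coupled anammox / n-DAMO reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild-resolved analysis of coupled anammox / n-DAMO reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildflux)
```

## The model

Nitrogen removal in a membrane-biofilm reactor coupling anammox with
nitrite/nitrate-dependent anaerobic methane oxidation (n-DAMO) is described
by three guild reactions, taken with their conventional molar coefficients:

* anammox: NH4+ + 1.32 NO2- -> 1.02 N2 + 0.26 NO3- + 2.03 H2O
* bacterial n-DAMO: 3 CH4 + 8 NO2- + 8 H+ -> 3 CO2 + 4 N2 + 10 H2O
* archaeal n-DAMO: CH4 + 4 NO3- -> CO2 + 4 NO2- + 2 H2O

Everything in the stoichiometry module is linear algebra on these
equations.  Writing `S` for the species-by-reaction coefficient matrix and
`e` for the vector of reaction extents (mmol of written-equation turnover
per litre per day), net volumetric species rates are `r = S e`.
`partition_fluxes()` inverts this relation on the three measured nitrogen
species (NH4, NO2, NO3) only.  Methane and dinitrogen are deliberately
left out of the solve: the fitted extents *predict* methane consumption
(`3 e_DB + e_DA`) and dinitrogen production (`1.02 e_AN + 4 e_DB`), so a
measured methane rate is an out-of-sample check of the three-reaction
model rather than an input to it.

The reporting rates follow the field convention: `r_AN = 1.32 e_AN`
(nitrite removal by anammox), `r_DB = 8 e_DB` (nitrite removal by n-DAMO
bacteria, with the 3-CH4 equation as the extent unit), `r_DA = 4 e_DA`
(nitrate removal by n-DAMO archaea).  Consumption is negative in rate
vectors; the three reporting rates are positive removal rates.

### The nitrogen-balance slack

The anammox equation as conventionally printed is about 0.02 mol N short
per unit extent because the biomass-assimilation term is omitted.  The
`reaction()` constructor therefore checks the nitrogen-atom balance against
a slack of 0.05 mol N by default — wide enough to accept the printed
equation, tight enough to reject typos of a whole coefficient — and a
strict mode (`n_slack = 0`) rejects it.  The batch integrator books the
missing 0.02 mol N per anammox extent into an explicit biomass-nitrogen
sink so that total nitrogen (dissolved species + cumulative N2-N +
biomass-N) is conserved to 1e-6 relative, which the tests enforce.

### Units

Nitrogen species are carried as mg N/L (the monitoring convention) and
converted with N = 14.0067 g/mol; the solver works in mmol/L/d; methane is
reported both in mmol/L/d and mg/L/d (16.043 g/mol).  Unit invariance of
the partition (solve in either basis, same extents to 1e-9) is a tested
property.

### Solvers and degeneracy

The exact solver is an LU solve of the 3x3 restricted system; it reports
negative extents as a recorded warning rather than an error, because a
noisy rate vector can legitimately fall outside the cone spanned by the
three reactions.  The `nnls` solver (a small Lawson–Hanson active-set
implementation) minimises `||S e - r||` subject to `e >= 0` and equals the
exact solution whenever that solution is nonnegative (tested).  A singular
restricted system under the exact solver raises an error advising `nnls`.

## Reactor kinetics

`simulate_batch()` integrates `dC/dt = S v(C)` with multiplicative Monod
kinetics per guild, `v_g = vmax_g * prod_s C_s / (K_s + C_s)`, using
fixed-step RK4 with recursive step-halving when a substrate would cross
zero.  A fixed-step integrator was chosen over an adaptive library solver
for bit-level reproducibility; the convergence test (halving `dt` moves the
endpoint by < 1e-4 relative) guards the step-size choice.

Parameter provenance matters here:

* bacterial n-DAMO methane half-saturation defaults to 2.6 uM, a
  literature respirometry value;
* the archaeal methane half-saturation defaults to 26 uM — ten times the
  bacterial value, the *minimum* consistent with the reported
  at-least-one-order-of-magnitude affinity gap;
* ammonium/nitrite/nitrate affinities are **not** constrained by the study
  design this package supports.  They default to 1 mg N/L each as
  config-exposed placeholders, and every result that depends on them is
  simulation-only.  We deliberately did not import further literature
  values as fixed truths.

Methane can deplete (closed bottle, the batch default) or be pinned at a
fixed dissolved concentration (membrane-fed).  The simulator is well-mixed:
biofilm counter-diffusion stratification is out of scope, so bulk
quantities are the only quantitative claims the simulator supports.

### Steady state and the "excess capacity" scenario

`solve_steady_state()` finds the chemostat fixed point
`(C_in - C)/HRT + S v(C) = 0` by damped Newton iteration with backtracking
and positivity projection, converging the balance residual below 1e-10 of
the volumetric loading (tested at 1e-8).

One design point deserves record.  In a *well-mixed* model, giving all
three guilds the same large vmax does not reproduce the >95% removal seen
in practice: n-DAMO bacteria (8 NO2 per extent) then out-compete anammox
for nitrite, ammonium passes through unconsumed, and the efficiency caps
near 63%.  Real systems avoid this through biofilm stratification and
affinity differences, which a bulk model cannot express.  We therefore
define "excess capacity" relative to each guild's stoichiometric *duty* at
the operating point: the anammox duty is the molar ammonium loading, the
archaeal duty processes the 0.26 NO3 by-product (duty = 0.26/4 of the
anammox duty), and the bacterial duty mops up the regenerated nitrite
(duty = 4/8 of the archaeal extent).  With every vmax at 10x its duty the
steady state removes ~98.7% of total nitrogen, and the result is not a
knife-edge: any duty multiple from 2x to 50x gives 98.1–98.7%.  The
anammox-only configuration converges to ~88.8%, just under the
stoichiometric ceiling `100 x (2.32 - 0.26)/2.32 = 88.79%` computed by
`anammox_max_efficiency()`.

## Metatranscriptomic quantification

Alignment filtering implements two dialects verbatim: the metagenomic rule
removes alignments with aligned length <= 90% of the read length *or*
identity <= 0.97 (equality removed), while the metatranscriptomic rule
removes on strict inequality at 95%/97% (equality survives).  Both
thresholds are parameters; the dialect only sets the comparison operator
and defaults.

TPM is the length-normalised count rate rescaled to one million:
`TPM_i = (c_i/L_i) / sum_j (c_j/L_j) * 1e6`.  The aggregation hierarchy
is: gene complex = arithmetic mean of subunit TPMs; reaction = sum over
alternate complexes (e.g. nitrate reduction = nar + nap); pathway =
arithmetic mean over its reactions.  Two conventions required a decision:

* **Gene copies.**  How multiple CDS copies of one subunit combine before
  averaging is not standardised; we sum copies per subunit, then average
  subunits, treating gene dosage as additive signal.  The two-stage
  computation is tested against an explicit oracle.
* **Missing parts.**  A subunit or reaction that is absent contributes 0
  *and* raises a flag, so "not encoded" is distinguishable from
  "expressed at 0" — mirroring the orange-cell convention of expression
  heatmaps.

Per-genome relativization divides each CDS TPM by the genome's median TPM.
The common caption phrasing for such heatmaps is internally ambiguous
("relativized by median" vs "a value of one means two times the median");
we implement both, with `log2(TPM/median)` as the default (under which a
value of one *is* twice the median) and the plain ratio as an option, and
assert neither as anyone's exact computation.  Zero-TPM CDS are flagged
undetectable rather than mapped to minus infinity.

MAG summaries: the expression fraction of a genome is the summed TPM of
its CDS over the 1e6 total (percentages over genomes plus unbinned sum to
100, a tested invariant); relative abundance is mapped reads over total
trimmed reads with the unassigned remainder reported.

## Diversity

`shannon()` is `H = -sum p ln p` in nats (base-2 is an option, never the
default).  `mann_whitney_u()` uses midranks; for total n <= 12 the
two-sided p-value is exact by full enumeration of all group assignments,
`p = min(1, 2 min(P(U <= u), P(U >= u)))`, otherwise the normal
approximation with tie and continuity corrections.  The tie policy and
corrections are the standard construction, documented as our choice since
upstream implementations vary.  The exact branch is tested against an
independent brute-force enumerator for every group size up to 6 + 6, and
against `stats::wilcox.test` in the tie-free case.  Counts are normalised
internally; no rarefaction is applied.

## What the synthetic data emulate — and what they do not

The generators produce the three kinds of input the pipeline needs, each
with known ground truth and a fixed seed (one RNG substream per call,
caller's stream untouched):

* `gen_reactor_series()`: steady-state monitoring of a continuous reactor
  at HRT 1 d.  The default test scenario (influent 250 mg N/L ammonium +
  360 mg N/L nitrite; extents 14 / 0.8 / 0.9 mmol/L/d) is a high-loading
  operating point with moderate effluent residuals — deliberately *harder*
  for recovery than a polished reactor whose effluent is near zero, since
  multiplicative noise (CV 5%, the typical precision of colorimetric
  nitrogen assays) scales with the residual.  Negative draws are clamped
  at zero and counted.
* `gen_expression_counts()`: multinomial per-CDS counts with probability
  proportional to genome fraction x within-genome transcript weight x CDS
  length, so TPM aggregation recovers the fractions in expectation.
  Within-genome weights are log-normal (sdlog 1) to give non-trivial
  medians for the relativization tests.
* `gen_abundance_profiles()`: symmetric Dirichlet compositions whose
  concentration parameter controls evenness, hence Shannon index.

None of these emulate sequencing error, rRNA carry-over, mapping
ambiguity, assembly or binning artefacts, or biofilm spatial structure.  A
green test therefore establishes that the *computations* are correct on
data whose generative model matches the method's assumptions — not that
the upstream bioinformatics of any real dataset would be recovered.
Headline biological numbers from deposited sequencing data (community
abundances, expression fractions, observed Shannon values) are outside
what desk-scale synthetic data can certify, and the package does not
assert them.

## Numerical choices and limitations

* Exact 3x3 solve via LU; NNLS handles degeneracy and noise outside the
  feasible cone.
* RK4 positivity handling by recursive halving (depth <= 30) with a final
  clamp only within 1e-9 mmol/L of zero; nitrogen drift is checked at
  1e-6 relative.
* Newton steady-state: forward-difference Jacobian, backtracking halving,
  positivity projection; non-convergence is an error carrying the last
  residual, never a silent result.
* Steady-state rates from series use the period mean of the effluent by
  default (per-sample partitioning then averaging gives the same extents
  for this linear pipeline; both routes are exercised in tests).
* The well-mixed simulator cannot express nitrite competition outcomes
  that depend on biofilm stratification; treat competitive coexistence
  results as qualitative.
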