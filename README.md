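# guildflux

Guild-resolved analysis of nitrogen-removal bioreactors that couple
**anammox** (anaerobic ammonium oxidation) with **n-DAMO**
(nitrite/nitrate-dependent anaerobic methane oxidation).

## The problem

Anammox alone cannot remove all nitrogen: per unit turnover of

```
NH4+ + 1.32 NO2- -> 1.02 N2 + 0.26 NO3- + 2.03 H2O
```

0.26 of the 2.32 mol N consumed re-emerges as nitrate, capping total
nitrogen (TN) removal at `100 x (2.32 - 0.26)/2.32 = 88.79% < 90%`.
Feeding methane closes the loop through two further guilds:

```
3 CH4 + 8 NO2- + 8 H+ -> 3 CO2 + 4 N2 + 10 H2O    (n-DAMO bacteria)
CH4 + 4 NO3-          -> CO2 + 4 NO2- + 2 H2O     (n-DAMO archaea)
```

Archaea recycle the anammox nitrate back to nitrite; bacteria and anammox
consume the nitrite; the coupled system can exceed 95% TN removal.

For engineers and microbial ecologists monitoring such reactors, the
package turns measurements into guild-resolved quantities:

* **Flux partitioning** — writing `S` for the species x reaction
  stoichiometric matrix and `e` for reaction extents (mmol/L/d), measured
  net rates `r` over {NH4, NO2, NO3} are inverted via `S e = r`
  (exact LU or non-negative least squares) into the field-standard rates
  `r_AN = 1.32 e_AN`, `r_DB = 8 e_DB`, `r_DA = 4 e_DA`, with methane
  consumption (`3 e_DB + e_DA`) and dinitrogen production
  (`1.02 e_AN + 4 e_DB`) *predicted* out-of-sample.
* **Kinetic simulation** — multiplicative Monod kinetics
  `v_g = vmax_g prod_s C_s/(K_s + C_s)` per guild; fixed-step RK4 batch
  (closed-bottle) trajectories and Newton-solved chemostat steady states,
  with nitrogen conservation enforced.
* **Metatranscriptomics** — alignment filtering (metagenomic `<=` and
  metatranscriptomic `<` dialects), TPM, and the CDS -> gene complex
  (subunit mean) -> reaction (alternate sum) -> pathway (mean)
  aggregation, plus per-MAG expression fractions, relative abundance and
  genome-median relativization.
* **Diversity** — Shannon `H = -sum p ln p` and an exact/midrank
  Mann–Whitney U test (full enumeration for n <= 12).
* **Synthetic data** — seeded generators with known ground truth for all
  of the above, so the whole pipeline is testable offline.

## Worked example

Partition a (synthetic, seeded) steady-state monitoring series of a
high-loading reactor back into guild fluxes:

```r
library(guildflux)

cfg <- reactor_config(hrt_days = 1,
                      influent = c(NH4 = 250, NO2 = 360, NO3 = 0))
gen <- gen_reactor_series(
  c(anammox = 14, ndamo_bacteria = 0.8, ndamo_archaea = 0.9),
  cfg, noise_cv = 0.05, n_samples = 50, seed = 42)

rates <- net_rates_from_series(gen$series, cfg, mode = "steady_state")
part  <- partition_fluxes(convert_rates(rates, "mmol"), solver = "nnls")
part
#> <flux_partition> (solver: nnls)
#>   extents [mmol/L/d]: anammox = 14.01, ndamo_bacteria = 0.7963, ndamo_archaea = 0.9005
#>   r_AN = 18.49, r_DB = 6.371, r_DA = 3.602 mmol N/L/d
#>   predicted CH4 = 3.29 mmol/L/d, predicted N2 = 17.47 mmol/L/d
#>   residual max |.| = 3.55e-15 mmol/L/d

anammox_max_efficiency(guild_reactions()$anammox)
#> [1] 88.7931
```

The true extents (14, 0.8, 0.9 mmol/L/d) are recovered to well under 2%
from 50 noisy samples at 5% CV.  `predicted CH4` is the methane demand
implied by the fitted nitrogen fluxes — in a real campaign you compare it
with the measured methane consumption as an out-of-sample check of the
three-reaction model.

A command-line interface covers the same stages
(`partition | simulate | tpm | aggregate | diversity | generate`):

```sh
Rscript -e 'quit(status = guildflux::main_cli())' partition \
  --series series.tsv --config reactor.yaml --solver nnls --out part.tsv
```

## Documentation

The methods vignette (`vignettes/guildflux-methods.Rmd`) records the
model, unit policy, kinetic parameter provenance, numerical choices, what
the synthetic generators do and do not emulate, and known limitations.
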