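# phagesim

An individual-based, stochastic simulation of lytic bacteriophages
coevolving with their bacterial hosts in a phosphorus-limited chemostat.
It is aimed at microbial ecologists and modellers who want to ask how
competition–defense trade-offs shape phage–host population dynamics and
long-term coexistence: every cell and every virion is an explicit
individual carrying heritable trait genes, so resistance, host range and
adsorption efficiency evolve rather than being imposed.

## The model in brief

A chemostat of volume *V* (1 µL default) holds dissolved phosphorus
*P_d*, hosts and virions. Phosphorus is counted in host-equivalent units
(*P·V/P_h* ≈ 855 at defaults). Each 1 h step applies, in order: nutrient
exchange *P_d ← P_d + ω(P_d⁰ − P_d)*; a host round (washout ω, death
δ_h with biomass recycling, metabolic loss ε_h·m, Monod growth
μ_h·α_n·g_α·P_d / (1 + α_n·g_α·P_d) drawn from the shared pool, division
with mutation once m > 1); and a virus round (washout, decay δ_v, then a
random-order scan of hosts where each pair infects with probability
C·V). Infection is lytic: the host's biomass returns to the pool and the
consumed virion leaves κ = 10 progeny.

The interaction kernels encode the trade-off:

- compatibility `C_t = exp(−|g_α − g_β| / g_ν)` — infection requires the
  host's nutrient-affinity gene to match the virus's adsorption gene,
  with a broad host range g_ν forgiving mismatch;
- virulence `V_t = min(1, β_n · g_β / g_ν)` — adsorption strength pays
  off most for narrow-host-range viruses.

Each kernel has a "random" null (per-pair uniform draw; the virulence
null is scaled to the adsorption magnitude β_n) so trade-off-driven and
structureless infection can be compared at matched intensity.

## Worked example

```r
library(phagesim)

p <- sim_params()           # reference conditions: 36 h, omega = 0.2/h
normalize_params(p)
#> Normalized simulation parameters
#>   horizon T = 36 h, omega = 0.2 /h, P = 71 umol-P/L, V = 1e-06 L
#>   inoculum: 46 hosts, 810 viruses (VHR = 17.6)
#>   kernels: compatibility = tradeoff, virulence = tradeoff
#>   normalized: P_units = 855.4, alpha_n = 0.16, beta_n = 6.2e-05

tr <- run_simulation(p, seed = 1)
subset(tr$records, t %in% c(0, 8, 18, 28, 36))[, c("t", "N_h", "N_v", "P_d")]
#>   t  N_h  N_v       P_d
#>   0   46  810 820.06967
#>   8 1239  701  20.03669
#>  18 1081 4111 103.34217
#>  28 1041 9094 134.37732
#>  36 1120 6625  84.69779
```

With the 1 µL vessel these numbers are directly cells (or virions) per
microlitre: the 46 inoculated hosts bloom to ~1,240 by hour 8 as they
draw the dissolved phosphorus down to ~20 host-equivalents, the virus
population grows into the bloom (4,100 by hour 18, peaking ~9,000), and
the partially resistant host population settles near the washout-limited
carrying capacity while the viral bloom stalls.

Ensembles, sweeps and the long-term factorial reproduce the model's
population-level results:

```r
en <- run_ensemble(p, n_reps = 30, master_seed = 1)
en
#> Ensemble of 30 replicates, 36 h (master seed 1)
#>   final mean N_h = 1164.6 (sd 31.1), mean N_v = 6734.2 (sd 1469.6)
crash_recovery_stats(en$records$mean_Nh)[c("first_peak", "crash", "recovery_peak")]
#> $first_peak 1249.6   $crash 1010.3   $recovery_peak 1164.6

diversity_timeseries(tr)[c(1, 19, 37), ]
#>   t H_g_alpha H_g_nu H_g_beta
#>   0     0.000  0.000    0.000
#>  18     1.852  0.087    0.066
#>  36     2.439  0.110    0.108
```

The host-affinity entropy rising from 0 to ~2.4 nats records the
diversification of the host population under viral selection; the viral
genes diversify far more slowly at their default mutation rates.

A thin command-line front end is installed with the package
(`exec/phagesim`): verbs `run`, `ensemble`, `sweep`, `factorial` and
`entropy`, each taking `--config` (YAML, one key per `sim_params()`
field), `--seed` and `--out`.

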