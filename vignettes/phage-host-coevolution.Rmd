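---
title: "An individual-based model of lytic phage–bacteria coevolution in a chemostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of lytic phage–bacteria coevolution in a chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagesim)
```

## The model

`phagesim` simulates a well-mixed chemostat of volume $V$ (1 µL by
default) in which lytic bacteriophages and their bacterial hosts coevolve
under limitation by a single elemental resource, phosphorus. Every
individual is represented explicitly. A host $h_i$ carries a biomass
$m_i$ and one heritable trait, the nutrient-affinity gene
$g_\alpha \in [0,1]$; a virion carries two heritable traits, a host-range
("memory") gene $g_\nu \in [0,1]$ and an adsorption gene
$g_\beta \in [0,1]$. All phosphorus bookkeeping is done in
*host-equivalent units*: one unit is the maximum phosphorus content $P_h$
of a single cell, so the total budget in the vessel is
$P_{\mathrm{units}} = P V / P_h$ (about 855 host-equivalents at the
default $P = 71\,\mu$mol-P L$^{-1}$). The per-pair rate coefficients are
normalized to the simulated volume, $\alpha_n = \alpha / V$ and
$\beta_n = \beta / V$. With the 1 µL default the simulated abundances
read directly as cells (or virions) per microlitre.

Time advances in fixed 1 h steps, and every rate expressed in h$^{-1}$
acts as a per-step probability; configurations with a different step
length are rejected rather than rescaled, because the rate-to-probability
identification only holds at unit steps. Each step has three phases:

1. **Nutrient exchange.** Dissolved phosphorus relaxes towards its
   initial level at the dilution rate:
   $P_d \leftarrow P_d + \omega (P_d^{(0)} - P_d)$. A closed system is
   $\omega = 0$.
2. **Host round.** Hosts are processed one at a time in a fresh random
   order. Each host is washed out with probability $\omega$ (its biomass
   leaves the vessel), otherwise dies with probability $\delta_h$ (its
   biomass returns to $P_d$), otherwise pays a metabolic loss
   $\epsilon_h m_i$ into $P_d$ and then takes up a Monod growth gain
   $$\Delta m_i = \mu_h \frac{\alpha_n g_\alpha P_d}{1 + \alpha_n g_\alpha P_d},$$
   drawn from the *current* pool (capped at the available $P_d$, so the
   pool can be exhausted mid-round but never go negative). A host whose
   mass exceeds 1 divides into two daughters of half its mass; with
   probability $\pi_h$ the daughters' genotype mutates to a
   $\mathcal{N}(g_\alpha, \sigma_h)$ draw clamped to $[0,1]$.
3. **Virus round.** Virions are processed in a fresh random order. Each
   is washed out with probability $\omega$, otherwise decays with
   probability $\delta_v$. A surviving virion scans the surviving hosts
   in random order; each pair infects with probability $C \times V$,
   where $C$ is the compatibility kernel and $V$ the virulence kernel.
   The first infection lyses the host (its biomass recirculates into
   $P_d$ immediately), consumes the virion, and produces $\kappa$
   progeny, each of which mutates both genes jointly with probability
   $\pi_v$ (independent $\mathcal{N}(\cdot, \sigma_v)$ draws, clamped).
   Progeny are buffered and join the population only after the round, so
   a burst cannot re-infect within the step it was released.

## Infection kernels and the competition–defense trade-off

The trade-off kernels couple the competitive host trait to the viral
attachment traits:

$$C_t(g_\alpha, g_\nu, g_\beta) = \exp\!\left(-\frac{|g_\alpha - g_\beta|}{g_\nu}\right),
\qquad
V_t(g_\nu, g_\beta) = \min\!\left(1, \frac{\beta_n\, g_\beta}{g_\nu}\right).$$

Compatibility is maximal when the host's affinity gene matches the
virus's adsorption gene, and a broad host range (large $g_\nu$) forgives
mismatch; virulence rewards strong adsorption and a *narrow* host range.
Hosts therefore face a competition–defense trade-off only dynamically:
moving $g_\alpha$ away from the viral $g_\beta$ confers resistance, and
viruses can chase by moving $g_\beta$, paying for breadth through
$V_t$. Two numerical guards apply: $g_\nu$ is floored at
`gene_floor_eps` ($10^{-9}$) wherever it appears in a denominator (with
$g_\alpha = g_\beta$ compatibility is still exactly 1, the correct
limit), and $V_t$ is clamped to 1 because it is used as a probability.

Each kernel has a null ("random") counterpart that severs the link to
the genotypes. Random compatibility draws a fresh $\mathrm{U}(0,1)$
number per pair. Random virulence draws uniformly on $[0, \beta_n]$:
the null randomizes the genotypic ratio $g_\beta / g_\nu$ of $V_t$
while keeping the physical adsorption scale. The scale matters — a
virulence drawn from the full unit interval would make the average
encounter infectious with probability $\tfrac14$, and at the default
inoculum (810 virions, 46 cells) every host would be lysed in the first
hour of every random-virulence scenario, which is not a meaningful null
model of this system. With the adsorption-scaled null, random-virulence
systems differ from their trade-off counterparts only in the *structure*
of infection, not its magnitude, and the long-term contrasts below are
attributable to the trade-off itself.

## How the engine evaluates pairs

A naive implementation of the virus round draws two uniforms for each of
up to $N_v \times N_h$ pairs per step ($\sim 10^7$ at bloom scales).
The engine instead uses an exact algebraic reduction. Per pair,
"compatible with probability $C$, then infect with probability $V$" is a
single Bernoulli event with probability $C V$. For a given virion, $V$
is constant across hosts (for $V_t$ it depends only on the virion's own
genes; for the random null its per-pair marginal is $\beta_n / 2$), so
the number of consecutive pair failures under the bound $V$ is
geometric, and only the "landed" pairs need a compatibility decision.
Landed hosts are drawn uniformly without replacement among the hosts
that virion has not yet examined — exactly the distribution induced by
scanning a uniformly random host permutation. Expected work per virion
drops from $O(N_h)$ to $O(N_h V)$ draws. The test suite verifies the
reduction against a literal two-uniforms-per-pair loop written in R,
comparing post-round host, virus and nutrient moments across hundreds of
replicate rounds in all kernel modes, and checks the exact
$\tfrac14$ per-pair infection rate of the fully random configuration at
$\beta_n = 1$.

All stochastic draws come from R's global RNG, so a `(parameters, seed)`
pair reproduces a trajectory bit for bit. Ensembles derive replicate
seeds from a master seed by seeding once and sampling the 31-bit range
without replacement (`replicate_seeds()`), so any replicate can be
re-run in isolation; sweeps and factorials derive one sub-seed per grid
point the same way, making grid points order-independent.

## Default study conditions

The package defaults are the model's reference conditions: a 36 h
horizon, $\omega = 0.2$ h$^{-1}$, 46 hosts and 810 virions inoculated
(virus-to-host ratio 17.6), monomorphic initial genotypes
$g_{\alpha 0} = g_{\nu 0} = g_{\beta 0} = 0.1$, host masses uniform on
$[\tfrac12, 1]$, $\mu_h = 0.738$ h$^{-1}$, $\alpha = 1.6\times 10^{-7}$
L h$^{-1}$, $\beta = 6.2\times 10^{-11}$ L h$^{-1}$, $\kappa = 10$,
$\delta_h = \epsilon_h = \delta_v = 1.4\times10^{-2}$ h$^{-1}$, host
mutation $(\pi_h, \sigma_h) = (0.06, 0.05)$ per division and virus
mutation $(\pi_v, \sigma_v) = (0.006, 0.005)$ per progeny virion.
Long-term experiments extend the horizon to 720 h (30 days) and compare
closed ($\omega = 0$) against open ($\omega = 0.2$) systems over the
$2 \times 2$ kernel factorial.

Under these conditions the simulated dynamics show the canonical
infection cycle: a host bloom to $\sim$1,200 cells µL$^{-1}$ limited by
the phosphorus budget, a virus-driven crash (deeper and earlier at
higher virus-to-host ratio), regrowth dominated by hosts whose
$g_\alpha$ has escaped the viral $g_\beta$, and a viral bloom of order
$10^4$ µL$^{-1}$ that stalls once mean compatibility collapses. In this
implementation the recovered host population is largely resistant, so
it converges to the washout-limited carrying capacity
($\sim$1,200 µL$^{-1}$) rather than remaining virus-suppressed; the
corresponding viral blooms are accordingly modest. Long term, the
trade-off compatibility kernel is what sustains coexistence: closed
trade-off systems keep declining virus populations alive past 30 days,
random-compatibility closed systems collapse entirely (kill-the-winner
without refuge), and open fully-random systems lose their viruses early
while hosts persist.

## Trait diversity

`shannon_entropy()` bins gene values into `n_bins` equal-width bins on
$[0,1]$ (50 by default) and returns $-\sum_k p_k \ln p_k$ over occupied
bins. The bin count and the natural-log base are conventions, not model
content; entropies are only comparable at a fixed binning, which is why
`diversity_timeseries()` refuses a bin count different from the one the
trajectory was recorded with. An extinct population has no trait
distribution: those steps yield `NA`, never 0 (0 means monomorphic).
Along default trade-off runs the host-affinity entropy rises from 0 (the
monomorphic inoculum) as mutation plus virus-driven selection diversify
the population.

## Numerical and design choices

* **Processing order.** Individuals are shuffled every round and
  processed sequentially with immediate state mutation; a host lysed
  mid-round is unavailable to later virions. Shuffling removes index
  bias that a fixed order would introduce through the shared nutrient
  pool and host removal.
* **Virion survival is per step, not per pair.** Washout and decay are
  evaluated once per virion per step; evaluating them inside the pair
  loop would make virion survival depend on host abundance,
  contradicting the definition of $\delta_v$ as a rate.
* **Daughter mutation is a single shared event.** One Bernoulli
  $(\pi_h)$ and one Gaussian draw apply to both daughters of a
  division. Progeny virions, in contrast, mutate independently, so one
  burst can contain mutant and wild-type virions.
* **Boundary handling.** Gaussian mutations are clamped to $[0,1]$
  (chosen over reflection for simplicity; at the default step sizes the
  two differ only in the mass piled onto the boundary). Division is
  strict ($m > 1$).
* **Nutrient exhaustion.** Growth is capped at the available $P_d$ per
  host, sequentially, so the pool cannot go negative within a round.
* **Washout biomass is lost.** Biomass of washed-out hosts leaves the
  vessel (tracked in `cumulative_outflow`); only death and lysis recycle
  biomass into $P_d$. The ledger
  $P_d + \sum_i m_i + \text{outflow} - \text{inflow} = P_{\mathrm{units}}$
  holds to floating precision at every step, and exactly
  $P_d + \sum_i m_i = P_{\mathrm{units}}$ in closed systems (virions are
  massless in the budget).

## What the tests do and do not show

The test suite and the acceptance script run the model at desk scale:
ensembles of 30 replicates (20 for the 720 h factorial, 8 for the
long-run diversity direction) instead of 100, which leaves ensemble
means of abundances accurate to a few percent at bloom scales but makes
threshold-crossing statistics (e.g. the largest washout rate at which a
rare replicate still carries virions at 36 h) inherently seed-sensitive
near the persistence edge. The synthetic dynamics emulate a nutrient-
limited batch/chemostat infection cycle; they do not emulate features of
the companion plate-reader data such as non-infectious virion fractions,
lag phases, optical-density saturation, or measurement noise, so
agreement with the simulated host curves is qualitative (shape and
ordering by virus-to-host ratio), and `read_experimental_csv()`
deliberately performs no unit conversion from OD600.

## Known limitations

* No spatial structure, latency/lysogeny, or multiple infection; one
  limiting element only.
* Host escape through $g_\alpha$ is fast relative to viral chase through
  $g_\beta$ at the default mutation parameters, which caps viral blooms
  of order $10^4$ µL$^{-1}$ and lets recovered hosts reach carrying
  capacity; systems whose recovered hosts remain substantially
  susceptible would show larger viral populations and a lower host
  recovery plateau.
* Elevated host mutation ($\pi_h$, $\sigma_h$ an order of magnitude
  above default) suppresses the viral bloom entirely in this
  implementation — resistance outruns the epidemic — so "more host
  evolution" here always helps the hosts.
* Entropy-based diversity depends on the binning convention and says
  nothing about which traits coexist, only how spread each marginal
  distribution is.
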