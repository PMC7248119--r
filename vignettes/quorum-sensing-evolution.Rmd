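---
title: "Evolving quorum-sensing strategies in silico: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving quorum-sensing strategies in silico: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumsim)
```

`quorumsim` evolves populations of digital bacteria whose cooperative
behaviour is under quorum-sensing (QS) control. This vignette is the
package's own account of the model, the parameters that matter, the
numerical choices, and what the desk-scale experiments shipped with the
package do and do not demonstrate.

## Signal dynamics and the cooperation decision

A sub-population ("group") sits at a stationary cell density $N$
(cells/µL). Each founder lineage $g$ contributes signal at basal rate
$p_g$ (µM/s per unit density); with auto-regulation, perceived signal
feeds back on production through a saturating term with half-saturation
$K$ and feedback ratio $r_g$:

$$\frac{dS}{dt} \;=\; \sum_g p_g\!\left(1 + r_g\,\frac{S}{K+S}\right) N_g \;-\; (u+m)\,S,$$

where $u$ is the signal decay rate, $m$ an optional mass-transfer loss
(both µL/s), and $N_g$ the density share of lineage $g$. Signal
equilibrates fast relative to births and deaths, so the simulator uses
the equilibrium directly. Writing $A=\sum_g p_g N_g$ and
$B=\sum_g p_g r_g N_g$, the equilibrium solves

$$(u+m)\,S^2 + \big((u+m)K - A - B\big)\,S - AK = 0 .$$

The product of the roots is $-AK/(u+m)\le 0$, so there is exactly one
non-negative root whenever $A>0$; `signal_equilibrium_auto()` returns
it in closed form. Three numerical conventions:

* $B = 0$ takes a dedicated branch returning $A/(u+m)$, so the
  no-feedback case is *bit-identical* to `signal_equilibrium()`
  (floating-point square roots would otherwise differ in the last ulp);
* $A = 0$ returns $S^\*=0$ even when $B>0$: without basal production the
  feedback loop has nothing to amplify from $S(0)=0$, although the
  quadratic formally acquires a second root;
* `integrate_signal_ode()` (lsoda, via deSolve) exists only as an
  independent oracle; the test suite checks closed form against
  trajectory endpoints to a relative $10^{-6}$ over randomized
  parameter sweeps.

An individual turns its cooperative phenotype ON where the perceived
signal strictly exceeds its threshold, $S^\* > S_{Th}$; ties are OFF.
Optionally the perceived signal carries multiplicative log-normal noise
(`noise_sd`), off by default — the deterministic switch is the baseline
model and noise is exposed for sensitivity studies only.

Units follow the field's printed arithmetic ($p$ in µM/s per
cell-density unit, $u$ in µL/s) rather than a strict dimensional
analysis; all internal checks use the same bookkeeping, e.g.
$4.37\times10^{-9} \times 5.0016\times10^{4} / 10^{-4} \approx 2.19$ µM.

## Groups, payoffs, and the generational loop

Each generation a propagule pool of `pool_size` individuals is shuffled
into groups. Founder counts are drawn as $\max(\mathrm{Poisson}(\lambda),1)$
(mean $\lambda + e^{-\lambda}$; 2.135 at $\lambda=2$); a zero-truncated
Poisson is available as a config alternative (mean
$\lambda/(1-e^{-\lambda})$), and `fixed_g` pins the count exactly —
`fixed_g = 1` is the clonal limit. If the pool runs out mid-draw the
last group takes the remainder. The group's density is split equally
over its founders ($N_g = N/G$); the split rule is symmetric and
exposed in the configuration rather than hard-coded.

Every founder is evaluated across a grid of testing densities —
by default 100 points evenly spaced (linear scale) from $10^{1.5}$ to
$10^{5}$ cells/µL, whose median $5.0016\times10^{4}$ doubles as the
default critical density $N_{Th}$. The payoff at density $N$ is

$$\text{baseline} + [N > N_{Th}]\; B_{coop} f \;-\; [\text{ON}]\; C_{coop} \;-\; C_{sig}\, p_{\mathrm{eff}},$$

with $f$ the group's cooperating fraction at that density,
$p_{\mathrm{eff}} = p$ without feedback and
$p(1 + r S^\*/(K+S^\*))$ with it — induced production is itself costly,
so feedback is only worth expressing where it buys coordination.
Fitness is the arithmetic mean payoff over the grid. The benefit is
linear in $f$ with a hard density step: the minimal form consistent
with a threshold-dependent public good in which being OFF inside a
cooperating group pays (the cheat's margin). Default magnitudes —
baseline 1000, $B_{coop}=300$, $C_{coop}=100$, $C_{sig}=2\times10^{10}$
— were chosen once so that production optima fall in the
$10^{-9}$–$10^{-8}$ µM/s range interior to the trait box; all are
overridable.

Selection is Wright–Fisher-like: `pool_size` offspring are drawn by
multinomial sampling with weights $\max(W_i - \min_j W_j,\ \varepsilon)$
($\varepsilon$ tied to the payoff range; a uniform draw if all payoffs
are equal, which logs as drift). Shifting by the generation minimum
keeps weights valid when payoffs go negative while preserving order;
the raw-payoff alternative would make selection intensity depend on the
arbitrary baseline. Offspring mutate each unfrozen trait independently
(probability 0.1/trait) by Gaussian steps, reflected at the bounds
$[0, 10^{-7}]$ for $p$, $[0, 50]$ for $S_{Th}$, $[0, 10]$ for $r$.
Constitutive cheats ($p=0$, $S_{Th}=S_{max}$, immutable) can be
injected at a per-generation rate, replacing random offspring so the
pool size never changes.

Two mutation choices deserve emphasis:

* **Step sizes.** $p$ and $S_{Th}$ mutate with SD 2 % of their bound
  range; $r$ with SD 10 %. The selected optima of $p$ and $S_{Th}$ lie
  within a few 2 %-steps of anywhere in their boxes, whereas useful
  feedback ratios sit most of the way across the $r$ box; an equal step
  fraction makes feedback effectively unevolvable on the package's
  desk-scale timescales. Larger $r$ steps (25 %) were not better: the
  mutational load of scattered feedback ratios destroys the very
  coordination feedback is supposed to buy.
* **When $r$ evolves.** The feedback ratio mutates only in `qs_auto`
  mode; in the other modes `qs_config()` freezes it, since feedback is
  the third evolving trait only in the auto-regulation experiments.

The initial pool is `pool_size` copies of one genotype. The default
start ($p=10^{-8}$, $S_{Th}=1$, $r=0$) cooperates but is badly
mis-tuned — it switches on far below the critical density — so
selection sees a coordination gradient from generation one. A
never-cooperating start (low $p$, high $S_{Th}$) sits in a fitness
valley many mutational SDs wide: production only decays under its cost
and the threshold drifts neutrally, so nothing adapts on any observable
timescale. Discovering cooperation *de novo* is a different (and much
harder) evolutionary problem than tuning it, and this package studies
the tuning.

## Analyses

* `on_fraction_curve()` — fraction of the pool ON at each testing
  density (each individual alone by default); a converged clonal
  population shows a step at $N_{Th}$.
* `constraint_regression()` — OLS of evolved mean $S_{Th}$ on evolved
  mean $p$ across conditions, reported next to the parameter-free
  prediction $N_{Th}/u$.
* `cooperative_investment()` / `assortment_analysis()` /
  `compare_slopes()` — investment is operationalised as the fraction of
  grid densities at which an individual is ON inside its group's signal
  context, which confines it to $[0,1]$ and makes it comparable across
  modes (the field's "investment" is not pinned down more precisely);
  assortment is the OLS of group-mean on individual investment, and the
  slope comparison is the standard pooled-OLS interaction F-test.
* `price_decomposition()` — exact two-level Price bookkeeping: groups
  weighted by parent counts, $W_g$ the mean realised offspring count,
  between-group term $\mathrm{Cov}_g(W_g,\bar z_g)/\bar W$ and
  within-group-plus-transmission term
  $E_g[W_g(\bar z'_g-\bar z_g)]/\bar W$; mutation's transmission bias
  lands in the within term (and is ≈ 0 because mutation is unbiased).
  The identity between + within = total holds to $10^{-10}$ by
  construction and is fuzz-tested.
* `spandrel_assay()` — $S^\*(m) = pN/(u+m)$ at fixed density, with the
  ON boundary $m^\* = pN/S_{Th} - u$ (`NA` when the strain can never
  turn on).

## Desk-scale experiments and their honesty limits

The full-scale study conditions (pool 5,000; 5,000 generations; 30
replicates) take hours per sweep. The package's own tests and the
acceptance script run the same machinery at desk scale, with problem
sizes chosen once and documented here:

* **Coordination line**: clonal evolution, pool 500, 300 generations,
  six signalling costs spanning $5\times10^{8}$–$10^{10}$; evolved
  means over the last 50 generations. R² comes out ≈ 0.999 with slope
  within ~5 % of $N_{Th}/u$.
* **Coercion hump**: mixing ladder at $C_{sig}=2\times10^{9}$, 500
  generations, 5 replicates: evolved $p$ and $S_{Th}$ at $\lambda=2$
  exceed clonal values, and payoff at $\lambda=4$ sits at baseline.
* **Auto-regulation rescue**: $\lambda=4$, $C_{sig}=5\times10^{8}$,
  500 generations, 5 paired replicates per arm, $r$ evolving vs frozen.
  The low signalling cost is deliberate: at desk scale, higher costs
  collapse no-feedback cooperation so early that feedback has no time
  to evolve, and the comparison would measure only the collapsed state.
* **Assortment at $G=5$**: $C_{sig}=5\times10^{8}$, snapshot at
  generation 120, investments pooled over 5 replicates per arm. At this
  scale five-founder groups eventually lose cooperation in *both* arms,
  so the snapshot is taken while cooperation still segregates.
  "Tighter" is read as a steeper assortment slope and higher R² with a
  significant ANCOVA interaction; the auto arm also has larger total
  investment variance, so raw residual variance is not the right
  tightness metric here.

What passing these tests shows: the model's comparative statics — cost
tunes the whisper, mixing buys coercion then collapse, feedback buys
assortment and rescues payoff at the margin — are reproducible from
scratch in minutes. What they do not show: the full-scale quantitative
endpoints (e.g. feedback ratios evolving to ≈ 8 under intermediate
mixing) and anything about real bacteria, whose costs, benefit shapes,
and mutational spectra are not these defaults. The generator emulates
density-structured, well-mixed patches with equilibrated signal; it has
no space within groups, no growth-density feedback, no multi-signal
architectures, and no receptor-level kinetics.

Other defaults a user may want to revisit: $K=1$ µM (not derivable from
the headline arithmetic, always read from the configuration);
log-normal perception noise off; the founder-count law (`max1` vs
`ztpois` — the two printed mean group sizes 2.13 and 4.07 are each
matched exactly by a different law, so both are provided and the choice
is explicit in the config).

## Reproducibility mechanics

Every run takes a mandatory integer seed; replicate seeds derive
deterministically from it. Records stream to a schema-versioned CSV,
configurations round-trip losslessly through YAML (unknown keys are
errors), and re-feeding an emitted config reproduces the run
bit-for-bit. The CLI (`inst/scripts/qsim`) wraps `run_replicates()`,
`summarize_last_k()` and `spandrel_assay()` without adding semantics.
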