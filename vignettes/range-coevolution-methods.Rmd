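---
title: "Methods: range coevolution models and time-shift statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range coevolution models and time-shift statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevorange)
```

This vignette is the package's own account of its models, statistics
and numerical choices: what is assumed, which knobs matter, where the
design was genuinely open and how we decided, and what the synthetic
data can and cannot tell you about real experiments.

## The ecological model

Susceptible hosts $X$ and infected hosts $Y$ follow a standard SI
formulation with density-dependent births:

$$\frac{dX}{dt} = X\,(a(u) - q(X+Y)) - bX - \beta(u,v)XY, \qquad
  \frac{dY}{dt} = \beta(u,v)XY - (\alpha + b)Y.$$

Crowding ($q$, per density per time) reduces births only; infected
hosts do not reproduce and do not recover; infection adds mortality
$\alpha$ on top of the background death rate $b$. Host resistance range
$u$ and parasite infectivity range $v$ live on $[0,1]$.

Three ingredients couple the traits to the ecology:

* **Infection kernel.** $\beta(u,v) = \beta_0(v)\,\sigma((v-u)/s_k)$
  with $\sigma$ the logistic function. A parasite whose range exceeds
  the host's resistance range infects at close to its maximum rate; at
  $v = u$ it achieves exactly half of it; hosts with higher $u$ resist
  stronger parasites. The steepness $s_k$ (trait units, default 0.11)
  sets how sharp the range boundary is. A smooth sigmoid was chosen
  over a step so that selection gradients exist everywhere; any other
  smooth, monotone kernel could be swapped in at `transmission_rate()`.
* **Cost of resistance.** $a(u) = a_{\max} - (a_{\max}-a_{\min})
  z^{c_h}$, $z$ the normalised trait. $a_{\min}$ (default 2.0, per
  time) is the severity knob: it is the birth rate of a maximally
  resistant host, so lowering it makes broad resistance expensive.
* **Cost of infectivity range.** $\beta_0(v) = \beta_{\max} -
  (\beta_{\max}-\beta_{\min}) z^{c_p}$: broad-range parasites transmit
  less well on any one host (defaults 11 down to 6.8 per density per
  time).

The endemic equilibrium is closed-form: $X^* = (\alpha+b)/\beta$ and
$Y^* = (a(u) - b - qX^*)/(q+\beta)$, used whenever the parasite clears
its invasion threshold at the disease-free density $X_{df} =
(a(u)-b)/q$; otherwise the resident is disease-free. Equilibria are
verified by substitution (tolerance $10^{-9}$) and, in the tests, by
long-horizon integration with `deSolve`.

## Invasion analysis

A rare mutant host or parasite grows at

$$s(u_m) = a(u_m) - q(X^*+Y^*) - b - \beta(u_m, v)Y^*, \qquad
  r(v_m) = \beta(u, v_m)X^* - (\alpha + b),$$

both zero at the resident (neutrality, asserted to $10^{-9}$).
Selection gradients are the mutant-trait derivatives at the resident,
available analytically and by central differences (step $10^{-5}$ trait
units; the two agree to $10^{-6}$ relative in the tests). The
trait dynamics used for classification weight each gradient by an
evolutionary speed times the evolving population's density (mutation
supply): $\dot u \propto s_h X^* g_h$, $\dot v \propto s_p Y^* g_p$.

**Relative speeds.** The package default is host:parasite speeds of
1:0.5. This was a genuinely open design choice, and it matters: with
exactly symmetric speeds the host's destabilising kernel-curvature term
and the parasite's stabilising one cancel identically in the trace of
the Jacobian for this kernel/cost family, so the singular point can
never undergo a Hopf bifurcation, whatever the other parameters. A
modest asymmetry — here the parasite evolving at half the host's rate,
as plausible as any other choice given that per-capita mutational input
differs between partners — breaks the cancellation and lets the model
express the full repertoire of dynamics. The speeds are exposed
everywhere (`speeds =`), and users studying a specific system should
set them from data.

## Singular points, classification, and continuation

`find_singular_point()` runs damped Newton iteration on the analytic
gradients (residual tolerance $10^{-10}$), with a coarse multistart
over the endemic region when no guess is supplied;
`find_singular_points()` enumerates distinct roots when a
stable/unstable pair coexists. Iterates are clamped to the trait box;
a converged point within $10^{-5}$ of a bound is rejected as a boundary
artefact, and leaving the endemic region signals absence.

Classification combines convergence stability (eigenvalues of the
weighted-gradient Jacobian, central differences with inward-shifted
stencils near the bounds) with evolutionary stability (second
derivative of invasion fitness in the mutant trait): `CSS`,
`branching_host`/`branching_parasite`, `hopf_unstable` (complex pair,
positive real part), or `repeller`.

`scan_parameter()` tracks the point along a one-parameter grid using
the previous solution as the next guess, falling back to root
enumeration (preferring the attractor: stable, then branching, then
Hopf) when the branch is lost. Sign changes of the leading real part
between adjacent grid values become bifurcation brackets;
`detect_hopf()` refines the complex-pair ones by bisection to
$10^{-4}$ of the scanned range. This grid continuation replaces a
dedicated continuation package: for one-parameter sweeps of a
two-trait system it is accurate and keeps the package free of binary
dependencies.

**Regime labels describe the attractor, not the algebra.** A stable
point pinned within 2% of the bounds is labelled `range_minimised` /
`range_maximised` even though it is formally a CSS or branching point;
at the lower bound the parasite's range is allowed to sit up to three
kernel widths above the host's, because $v - u \sim s_k$ is what "both
ranges minimised" looks like under a sigmoidal kernel (the parasite
must keep its range a kernel width above the host's to persist). An
unstable focus is `cycles` only while its limit cycle is bounded: the
label integrates the deterministic trait flow (Euler steps with
adaptive step length, 30,000 steps) and reports a boundary regime once
the cycle has been lost through the homoclinic connection. If the flow
crosses the parasite-persistence boundary (the host out-runs the
parasite), the label follows where the host ended up.

With the shipped defaults the cost-severity sweep (`a_min` rising from
1.05 to 3.35) passes through `range_minimised`, `branching`, `cycles`
(Hopf at $a_{\min} \approx 2.069$), and `range_maximised`; the
crowding sweep (`q` falling from 4 to 0.1) mirrors it. The defaults
were selected, by mapping the model's parameter space, precisely so
that one parameter set exhibits all four regimes along both axes;
they are a demonstration set, not a calibration to any organism.

## The trait-substitution simulator

`simulate_coevolution()` discretises each trait onto a 51-point
lattice and alternates ecological relaxation (multi-strain SI dynamics
via `lsoda`, horizon 200 time units — in cyclic ecological regimes the
end state is simply used as-is) with mutation events: cull strains
below $10^{-6}$ absolute density, pick the mutating species by the
speed weights, pick a parent proportional to density, and introduce a
mutant one lattice step up or down (uniform, reflecting at the bounds,
merging onto occupied strains) at $10^{-3}$ of the species' mean
resident density. Host extinction truncates the run; parasite
extinction flags it and continues host-only. Everything is driven by
one seeded generator, so a seed reproduces a trajectory exactly.

`classify_regime()` reads the post-burn-in density-weighted mean-trait
series: boundary regimes need both species within 2 lattice steps of a
bound for 90% of events (with the same kernel-width allowance for $v$
at the lower bound); `cycles` needs at least 3 alternating excursions
exceeding 5 lattice steps peak-to-trough (counted against running
extrema, so slow drifts don't fool it); `branching` needs two strains
of one species, more than 2 steps apart, each holding 10% of the
species' density for a quarter of the run.

A caveat the labels make visible: close to (but on the stable side of)
the Hopf bifurcation, demographic stochasticity keeps exciting the
weakly damped focus, and simulations show noise-sustained quasi-cycles
whose amplitude grows as the bifurcation approaches. The deterministic
Hopf bracket therefore separates damped from self-sustained cycling,
not oscillation from quiescence; the end-to-end tests probe simulation
points well inside the minimised and cycling regimes for that reason.
Simulation sizes used throughout (1,200 events, 51 strains) were chosen
so several cycle periods fit inside a run.

## The time-shift statistics

`mean_infectivity()` reduces a cross-infection tensor to one mean per
(population, phage time, bacteria time) cell — 400 assays per cell at
the canonical design.

* **ARD slope.** `fit_time_shift_model()` fits mean infectivity on
  centred continuous phage time and time shift with population blocks
  and population × covariate interactions, and tests the
  treatment-level shift effect against the population × shift stratum:
  F on $(1, n_{pop}-1)$ df — the exchangeability argument makes this
  valid under between-population slope heterogeneity, which the tests
  confirm by simulation (nominal 5% size under a heterogeneous null).
  Treating populations as fixed blocks with the interaction stratum as
  the error term reproduces the random-population test without a
  mixed-model dependency. Per-population slopes come from separate
  regressions, with Holm-corrected decisions.
* **Range-FSD mean squares.** Per population, a two-way categorical
  ANOVA of the 6 × 6 cell means; with one observation per cell the
  interaction is the residual stratum, and main effects are F-tested
  against it. Because a directional trend also inflates the main
  effects (shown constructively in the tests), range FSD is only
  flagged when a main effect is significant *and* that population's
  shift slope is not. Treatment comparisons use Welch's t with
  Welch–Satterthwaite df.
* **Specialism inconsistency.** For each interior focal transfer, all
  earlier transfers pool into *past* and later ones into *future*
  (all enemy clones weighted equally regardless of era size); each
  clone's era means give $\sum_{pairs}\sigma_1\sigma_2(1-\rho_{12})$.
  Conventions: population-form standard deviations (denominator $n$
  over the era columns), zero-variance pairs contribute nothing (their
  correlation is undefined), unordered pairs counted once. The
  statistic is invariant to additive shifts and quadratic under
  scaling, and is zero exactly when all finite-variance clones are
  perfectly correlated — crossing reaction norms are what it measures.
* **Phenotype complexes.** Binary profiles are clustered
  agglomeratively on squared Euclidean distance normalised by profile
  length (the mismatch fraction, so the 80% similarity threshold is
  scale-free), with average linkage — the linkage was an open choice;
  average linkage makes the "mean within-complex similarity ≥
  threshold" reading exact and is verified in the tests against a
  naive re-implementation. Cluster ids are deterministic (relabelled by
  lowest member index).

## The synthetic-data generator

`generate_community()` emulates the canonical serial-transfer design:
two nutrient treatments × 6 replicate populations, transfers
2, 4, …, 12, 20 phage and 20 bacteria clones per time, full crossing
(14,400 binary assays per population), plus a 2% assay-error flip.

* `ard`: clone range levels are drawn around a mean escalating at 0.1
  range units per transfer (both species), and a phage infects iff its
  level is at least the bacterium's — the nested gene-for-gene rule
  that matches the nested generalism such systems show. Clone spread
  0.15 around the mean; these scales put mean infectivity near 0.5 and
  make the escalation comfortably detectable, which is what a
  positive-control generator should be.
* `range_fsd`: identical machinery, but the mean follows a cosine with
  period 10 transfers and amplitude 0.3, phase-symmetric about the
  window midpoint so its linear trend over the design is exactly zero
  — fluctuation without escalation *by construction*, not by accident
  of the window.
* `specialism_fsd`: a matching-allele layer. Clones carry one of four
  alleles; matching raises the infection probability by the contrast
  (default 0.6). Allele counts cycle with full amplitude along
  *orthogonal* composition directions for the two species, which keeps
  the population mean infectivity constant across every time pair
  (exactly, before noise) while clone reaction norms cross — the three
  signatures are separated by construction, each generator regime
  carrying exactly one of them.
* `noise`: i.i.d. Bernoulli(0.5); `mixed`: `ard` in high-nutrient,
  `range_fsd` in low-nutrient populations.

`sample_from_simulation()` instead draws clones from a simulated
trajectory (probability proportional to strain density) and assays
them through the model's kernel as an infection probability, bridging
the mechanistic and statistical halves.

**What passing tests do and do not show.** The generator produces
pure, single-signature regimes with homogeneous clone spreads,
independent assays, and no phylogenetic or spatial structure; real
cross-infection data mix signatures, share clones across cells, and
carry correlated assay error. Detection rates estimated here (e.g. the
arms-race slope detected in ≥ 90% of generated communities) are
properties of these generative settings, not of any empirical system.

## Degenerate inputs and edge conventions

Zero-variance groups in Welch's t return $t = 0, p = 1$ (equal means)
or $p = 0$ (unequal). Holm on an empty p-value vector returns an empty
decision vector. Boundary focal times raise an error (no past or no
future era). Tensors are validated for binary outcomes, complete clone
crossing and duplicate rows on read, and written in a canonical row
order so CSV round-trips are byte-identical. Host non-viability
($a(u) \le b$) aborts equilibrium computation; the parameter validator
normally precludes it by requiring $a_{\min} > b$.

## Known limitations

* The concrete functional forms (logistic kernel, power-law costs) are
  one reasonable smooth family; results about *where* bifurcations sit
  are family-specific even though the four-regime structure is not.
* Hopf position depends on the speed ratio; the 1:0.5 default is a
  declared choice, not an inference.
* The grid continuation tracks one branch plus enumerated alternates;
  it does not compute cycle amplitudes or two-parameter bifurcation
  surfaces.
* The statistics operate on cell means, matching the canonical
  analysis; clone-level binomial error propagates only into the
  inconsistency statistic.
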