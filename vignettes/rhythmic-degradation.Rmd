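---
title: "Rhythmic degradation of circadian proteins from steady proteolysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic degradation of circadian proteins from steady proteolysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadeg)
```

## The problem

Circadian proteins are periodically produced and must be degraded by exactly
as much as they are synthesized over every ~24-h cycle; otherwise their
abundance would drift. Writing the balance as

$$\frac{dx}{dt} = g(t) - r(t)\,x(t), \qquad x(t) = x(t+T),$$

periodicity forces $\langle g \rangle_t = \langle r x \rangle_t$: the average
synthesis flux — the *proteosynthetic cost* — equals the average degradation
flux. Because $g(t) \ge 0$, any sustainable degradation rate obeys
$r(t) \ge \max(-x'/x,\, 0)$ pointwise. A *constant* rate must therefore sit at
the decline maximum $\max_t[-x'/x]$ all day, which for sharp circadian
waveforms is expensive: the corresponding cost lower bound is
$c_g = \max_t[-x'/x] \cdot \langle x \rangle_t$ (`cg()`). A *rhythmic* rate
that is high only during the falling phase can undercut $c_g$ substantially.

The package's central question is mechanistic: does a rhythmic degradation
rate require rhythmic post-translational machinery? The models here show it
does not — with constant pools of ubiquitin ligases (and optionally kinases,
phosphatases, deubiquitinases), the *realized* degradation rate
$r(t) = r_0 \cdot [\text{ubiquitinated fraction}]$ oscillates spontaneously,
because enzymes with finite binding affinity cannot instantly ubiquitinate the
surge of newly translated protein in the rising phase. Prior
phosphorylation requirements amplify this lag and hence the rhythmicity,
cutting the cost further.

## The models

Five mass-action variants share a ubiquitination core (free protein,
ligase-bound unmodified, ligase-bound ubiquitinated, free ubiquitinated,
deubiquitinase-bound), with free-enzyme concentrations eliminated through
constant pool totals $\bar u, \bar v$:

* **phospho-independent** (`rhs_phospho_independent()`): ubiquitination
  requires only ligase binding;
* **mono-/multisite phospho-dependent** (`rhs_phospho_dependent()`): an
  $n$-site kinase chain must complete before the ligase binds;
* **multi-route** (`rhs_multiroute()`): each of the four phosphostates has
  its own ligase pool and degradation route;
* **realistic PER2** (`rhs_per2()`): the four-state FASP chain with per-state
  ubiquitination through a shared ligase pool, plus the separate
  β-TrCP-site route with its own pool (30 state components).

The realized degradation rate is always
$r(t) = \sum_i r_{i,0}\,(\text{ubiquitinated components}_i)/x(t) \le r_0$,
and its rhythmicity is summarized as
$\alpha_D = (\max_t r - \min_t r)/\max_t r$ (`alpha_D()`).

### Profile-constrained simulation

Changing a kinetic parameter in a forward simulation changes both $r(t)$ and
the abundance waveform $x(t)$, confounding the comparison. The package
therefore also implements the constrained mode (`constrained_simulate()`):
$x(t)$ is held exactly at a prescribed `periodic_profile`, the free
unmodified pool is eliminated via
$x_0 = x(t) - (\text{all other substrate components})$, the remaining states
are integrated to a periodic steady state, and the synthesis profile is
recovered from the balance $g = x' + r x$. The combination of profile and
parameters is *biologically infeasible* when any of $g(t)$, $x_0(t)$, or a
free-enzyme concentration goes negative; infeasible results are flagged, not
silently dropped.

In dimensionless terms ($U$, $Y$ the scaled ligase and kinase activities,
$R(t) = -(1/r_0)\,x'/x$ with daily extrema $R_{\max}, R_{\min}$), a waveform
can only be sustained when $U \gtrsim R_{\max}$ and, with phosphorylation,
$Y \gtrsim R_{\max}$ (`feasibility_lower_bounds()`). Rhythmicity $\alpha_D$
grows monotonically as $U$ or $Y$ is reduced toward that edge.

### Closed-form approximations

When the ubiquitination block equilibrates fast relative to the period and
enzyme sequestration is negligible, the ubiquitinated fraction follows
quasi-steady-state closed forms: the leading form
$D = [1 + (1-R)/U]^{-1}$ (`D_qss()`), a Michaelis–Menten-corrected form with
substrate saturation (`D_qss_mm()`), the mono-phosphorylation form
(`D_qss_phospho()`), and the $n$-site chain polynomial $\eta_n$
(`D_qss_multisite()`), whose $n=1$ case reduces algebraically to the mono
form. From the multisite polynomial, the smallest site activity
$\min_i(K_i Y)$ dominates the temporal variation of $D$ — the slowest kinase
step sets the attainable rhythmicity and cost. `check_validity_conditions()`
evaluates the applicability conditions as ratio statistics with a
configurable reading of "much less than" (default ratio ≤ 0.1); the package's
tests assert agreement with the full ODE only on parameter sets passing that
screen, where the sup-norm deviation stays below 10%.

## Parameters that matter

* `r0` (1/h): degradation rate of ubiquitinated protein; the hard ceiling of
  $r(t)$ and the natural rate unit. Benchmark value 1.3/h.
* `u_bar`, `a0`, `a1`, `q` (nM, 1/nM/h, 1/h, 1/h): together set
  $U = (a_0/r_0)\,q/(a_1+q)\,\bar u$, the scaled ubiquitination activity.
  The benchmark constants ($a_0 = 234.9$, $a_1 = 17880.6$, $a_2 = 15347.2$,
  $q = 262.2$, $\bar u = 0.22$ nM) give $U \approx 0.57$.
* `y`, `k` per site: $Y = (k_1/r_0)\,y$, the scaled kinase activity, with
  site ratios $K_i = k_i/k_1$. Scan fits tie $k_1 = \dots = k_n$ by default
  because the minimum rate dominates; an untied override exists.
* Solver tolerances `rtol = atol = 1e-5`; periodic steady state is declared
  when the state at consecutive period boundaries changes by less than 1e-4
  in relative sup-norm (at most 50 periods in constrained mode, an error if
  never reached). The feasibility screen uses a relative margin of 1e-9 on a
  dense 0.05-h output grid; both are configurable.
* Quadrature and extremum location use a dense 0.01-h grid with local
  continuous refinement (`min_constant_rate()`); period integrals are
  trapezoidal on the union of the operand grids.

## Empirical pipeline

`read_timeseries()` ingests replicated CSV time series.
`fit_profile_spline()` fits a cubic smoothing spline to the replicate means
with the smoothing strength expressed as a residual-sum bound — the smoothest
curve whose residual sum of squares equals the bound, found by root-finding
over the spline's smoothing parameter — then closes the curve into a periodic
profile. `tim_stage()` chains normalization (reference-time convention, e.g.
CT 18 for abundance, CT 0 for the ubiquitinated fraction rescaled to 1),
spline fitting and the decline profile $-x'/x$ with its peak phase.

`build_empirical_rate_profile()` constructs the empirical rate profile
$r_E(t)$ from sparse degradation-rate measurements as the pointwise maximum
of (a) the linear inter-/extrapolation of the measurements (terminal
segments continued linearly), (b) the waveform floor $\max(-x'/x, 0)$,
optionally pre-smoothed with a centered moving window when the spline
derivative is noisy, and (c) the minimum observed rate as a global lower
bound. The order — smooth the floor, then take maxima, then apply the lower
bound — is a documented package choice; the construction rule itself does not
fix it.

Simulated and empirical rates are compared with the overlap similarity
$S = \int \min(r, r_E)\,dt / \int \max(r, r_E)\,dt$ (`similarity_S()`), and
`scan_parameters()` / `optimize_parameters()` explore parameter space by
log-uniform sampling and Nelder–Mead refinement in log-parameter space, with
infeasible evaluations penalized at $10^6(1 + \text{violation})$ so the
simplex retreats into the feasible region.

## Proteome stage and statistics

For proteome tables, `protein_cg()` computes each oscillating protein's
constant-rate cost bound $c_g$ from a spline of its relative series times its
absolute abundance, subject to an eligibility rule (at least seven points
across replicates and more than two consecutive gaps under 6 h; the package
reads the "more than two" clause as *at least three* qualifying gaps and
isolates that reading behind the single predicate `series_eligible()`).
`fcost_aggregate()` turns the aggregates into the bound $F_{\mathrm{cost}}$
on the synthesis share of oscillating proteins; with the published
mouse-liver sums it returns ≈0.19 from a ≈4% abundance share. Comparisons of
phosphoprotein fractions across $c_g$ bins (`bin_by_cg()`) are run inside an
abundance-controlled window ($3.0\times10^4$–$5.4\times10^5$ copies/cell by
default) where both groups follow a truncated power law
$P(\chi) \propto \chi^{-\gamma}$ with $\gamma \approx 1$
(`powerlaw_exponent()` is the truncated-Pareto maximum-likelihood estimator).

Four randomization procedures share the add-one convention
$p = (\text{count}+1)/(N+1)$, with the raw bound string (e.g. "P < 1e-4")
reported when no null draw reaches the observed statistic:
similarity–cost rank-correlation permutation, size-matched phosphoprotein
enrichment resampling, the adjacent-bin fold-change dominance test of the
$c_g$–phosphofraction association, and the empirical cost-proximity test.
The Spearman permutation test's default tail follows the observed sign
(matching how a strong negative association is reported); that adaptive
choice is deliberately *not* calibrated, and the fixed-tail mode
(`alternative = "less"`) is the calibrated test. The fold-change dominance
event is multivariate for more than two bins, so its null p-value is
conservative there by construction; the package's calibration checks run it
with two bins, where it reduces to a one-sided exceedance.

## Synthetic data

The generators stand in for the study's third-party datasets and define the
study conditions used by the tests:

* `make_profile()` builds waveforms $x(t) = \mu(1 + b\,w(t))$ with $w$ a
  sign-preserving power of a sinusoid (sharpness ≥ 1), time-warped by a
  smooth periodic map for asymmetry; `profile_with_target_Rmax()` inverts the
  construction by bisection to hit a prescribed decline maximum, enabling
  boundary tests at $U \approx R_{\max}$.
* `make_noisy_timeseries()` applies multiplicative lognormal noise
  (abundance data are ratio-scale, so multiplicative error is the natural
  model) with a given coefficient of variation, independently per replicate.
* `make_synthetic_proteome()` draws abundances from the truncated power law
  ($\gamma = 1$, bounds matching the mouse-liver control window), marks an
  oscillating fraction with generated waveform series, and draws phospho
  labels from a logit model whose abundance and waveform-sharpness
  coefficients are zero under the exchangeable null — the calibration null of
  the statistics above — and positive to inject detectable couplings.

All generators are pure functions of their specification and seed.

What the synthetic data do *not* emulate: measurement-process artifacts
(batch effects, censoring at detection limits, non-stationary noise),
waveforms outside the sinusoid-power family (e.g. double peaks), and the
actual PRR7/PER2/TIM waveform shapes beyond their class. Passing tests
demonstrate correctness of the algorithms under the stated statistical
structure, not agreement with any particular organism's data.

## Problem sizes and numerical choices

The shipped tests run the approximation screen on 50 compliant parameter
sets, the feasibility screen on 100 random waveforms, the
phospho-amplification ensemble on 100 parameter sets across $n = 0..4$, the
recovery study on a 2,000-sample scan plus simplex refinement, and the
calibration studies on 500 replicates at 199 null iterations; these sizes
give stable medians and Kolmogorov–Smirnov checks at desk scale. Ties in
discrete null statistics make exceedance p-values conservative, so the
calibration nulls use tables large enough (1,000–5,000 proteins) that the
statistic's granularity is well below the Kolmogorov–Smirnov resolution.
Degenerate inputs are rejected loudly rather than patched: all-zero rate
vectors (undefined $\alpha_D$), identically zero rate pairs (undefined $S$),
constant vectors in rank correlations, empty subsets, and non-positive
profiles are hard errors.

## Known limitations

* The closed forms cover $V = Z = 0$ (no deubiquitinase/phosphatase); with
  active removal enzymes only the full ODE path applies, and their effect on
  rhythmicity is condition-dependent.
* The realistic PER2 variant ships with the full FASP-chain/β-TrCP-site
  equation structure but no canonical parameterization; users supply or
  sample parameters.
* No stochastic simulation, delay equations, explicit mRNA dynamics, or
  spatial/nucleocytoplasmic compartments: $g(t)$ subsumes everything
  upstream of translation.
* Degradation inhibited (rather than promoted) by phosphorylation is out of
  scope.

## A worked example

```{r example, eval = FALSE}
p <- make_profile(waveform_spec(rel_amplitude = 0.5))
pars <- ub_params(u_bar = 0.22, a0 = 234.9, a1 = 17880.6, a2 = 15347.2,
                  q = 262.2, r0 = 1.3)
sim <- constrained_simulate(p, pars)
sim$alpha_D                      # spontaneous rhythmicity, steady enzymes
sim$cost                         # proteosynthetic cost <r x>
cg(p)                            # the constant-rate cost bound
# adding a mono-phosphorylation requirement amplifies the rhythm
simp <- constrained_simulate(p, pars, phospho_params(n = 1, y = 152.7,
                                                     k = 0.013))
simp$alpha_D
```
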