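---
title: "Leaf hydraulics of C3 and C4 grasses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf hydraulics of C3 and C4 grasses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasshydro)
```

## The scientific problem

C3 and C4 grasses run their leaves on different hydraulic economies. The C4
carbon concentrating mechanism permits high photosynthetic rates
(`A_area`) at much lower stomatal conductance (`g_s`), so a C4 leaf that
keeps a C3-like hydraulic supply ends up with a disproportionately high
ratio of leaf hydraulic conductance to stomatal conductance
(`K_leaf:g_s`, "hydraulic hyper-efficiency"). That surplus supply lets the
leaf operate at higher (less negative) water potential, keeping stomata
open — which matters disproportionately for C4 plants because their
assimilation responds steeply to stomatal closure. `grasshydro` implements
the quantitative machinery needed to study this contrast end to end:

1. **Anatomy to conductance** — theoretical xylem conductance of the
   parallel grass vein system from measured conduit geometry.
2. **Partitioning** — splitting measured `K_leaf` into its xylem (`K_xc`)
   and outside-xylem (`K_oxc`) components, vulnerability fits and P50,
   trait ratios, species-mean aggregation, pathway contrasts, outlier
   screening.
3. **Simulation** — a coupled hydraulic–stomatal–photosynthetic model
   stepped through a soil dry-down.
4. **Comparative statistics** — PGLS with ML Pagel's lambda,
   simulation-based phylogenetic ANOVA, phylogenetic RMA.
5. **Synthetic data** — a generator producing trees, traits, anatomy and
   vulnerability curves with the statistical structure the analysis
   assumes, so everything is testable without measured data.

## Models

### Conduit and leaf xylem conductance

A xylem conduit of elliptical cross-section with full axes $a$ and $b$ has
theoretical conductivity (Poiseuille's law for ellipses)

$$k_t = \frac{\pi}{64\,\mu}\,\frac{a^3 b^3}{a^2 + b^2},$$

with $\mu$ the viscosity of water at 25°C ($8.9\times10^{-10}$ MPa s).
Axes are interpreted as full diameters: with $a=b=2r$ the expression
reduces *exactly* to the circular Hagen–Poiseuille form $\pi r^4/(8\mu)$,
which the test suite checks to $<10^{-12}$ relative error. Volumetric
conductivities are converted to molar units with the molar density of
liquid water ($5.556\times10^{7}$ mmol m$^{-3}$), giving
mmol m s$^{-1}$ MPa$^{-1}$.

Per vein order, $k_t$ sums over all conduits: type I (wide) and type II
(narrow) xylem plus the single protoxylem lacuna in the major orders (1°,
2°); type II only in the minor orders (3°, and 4° in those C4 Panicoideae
that evolved a fourth order). The whole-leaf, area-normalised conductance
of the xylem conduit lumina is

$$K_{xc} = \frac{\sum_o k_t(o)\, D_v(o)}{0.5\,LL^2} \Big/ 0.71,$$

with $D_v$ the order's vein density (mm mm$^{-2}$), $LL$ leaf length (m)
and 0.71 a shape-area correction for linear leaves. The printed form of
the denominator is typographically ambiguous between $0.5\,LL^2$ and
$(0.5\,LL)^2$; we default to the former (the literal reading of the
displayed formula) and expose the alternative through
`ll_convention = "half-then-square"` — the two differ by exactly a factor
of two, so sensitivity checks are trivial.

Construction cost per order is the wall-volume index
$CC = \pi\, CD^e\, CN\, D_v$ with $e = 1$ for constant wall thickness; an
exponent $e < 1$ is exposed for the case of proportionally thinner walls
in wider conduits. Sheath metrics follow the half-circumference
approximation: perimeter $(D/2)\pi N$ per order averaged over the orders
possessing that sheath, and surface area, projected area and volume per
leaf area $D\pi D_v N$, $D D_v N$, $(D/2)^2 \pi D_v N$. The sheath-mean
divisor is the number of orders actually possessing the sheath, which
generalises the fixed three-order (bundle sheath) and four-order (mestome
sheath) layouts to pathways lacking a sheath on some orders.

### Partitioning

Xylem and outside-xylem pathways act in series:
$1/K_{leaf} = 1/K_{xc} + 1/K_{oxc}$, so
$K_{oxc} = (1/K_{leaf} - 1/K_{xc})^{-1}$, defined only when
$K_{xc} > K_{leaf}$ (otherwise `outside_xylem_conductance()` raises an
infeasible-partition condition rather than returning a negative
resistance). Vulnerability curves are fitted as
$K_{leaf} = K_{max} + a\,\Psi_{leaf}$ by OLS; P50 is the potential at
half the fitted intercept, $-K_{max}/(2a)$. OLS is the default because
the P50 definition operates on the fitted intercept and slope; an SMA
variant is available for sensitivity since slope estimators differ under
noise. In the meta-analysis aggregation, species means are unweighted
means across studies, and `K_leaf:g_s` is computed from the aggregated
means but only for species where at least one study reported both traits
— a ratio cannot be manufactured from disjoint studies. Dixon's Q (the
Q10 gap/range variant, two-sided critical values embedded for
$n = 3\ldots30$) screens small species sets for single outliers.

### Photosynthesis and stomatal coupling

The C3 model is the Farquhar two-limitation form at fixed irradiance:
$A = \min(W_c, W_j)(1-\Gamma^*/C_i) - R_d$ with
$W_c = V_{cmax} C_i/(C_i + K_c(1+O/K_o))$ and
$W_j = J C_i/(4C_i + 8\Gamma^*)$. Below the compensation point,
photorespiratory release makes $A < -R_d$; at $C_i = 0$ we return the
continuous limit of the expression, keeping $A$ continuous and
non-decreasing over the whole $C_i$ range (an invariant the tests
enforce). The C4 model is the enzyme-limited skeleton
$A = \min(V_{pmax} C_i/(C_i+K_p),\; V_{cmax}) - R_d$: mesophyll
conductance and bundle-sheath leakiness are treated as non-limiting,
consistent with the carbon concentrating mechanism removing mesophyll
diffusion limitation (a `leakiness` hook exists but is inert).

Assimilation couples to stomata through the supply line
$A = (g_s/1.6)(C_a - C_i)$; the unique intersection with the demand curve
is found by bracketed bisection to a residual below $10^{-8}$
µmol m$^{-2}$ s$^{-1}$ and is cross-checked in tests against a
$10^6$-point grid scan.

Default kinetic parameters are representative 25°C textbook values, not
estimates from any particular experiment — C3: $V_{cmax}=60$, $J=120$,
$K_c=404.9$, $K_o=278.4$ (mmol mol$^{-1}$), $O=210$, $\Gamma^*=42.75$,
$R_d=1$; C4: $V_{pmax}=55$, $K_p=120$, $V_{cmax}=45$, $R_d=1$ (all rates
µmol m$^{-2}$ s$^{-1}$, Michaelis constants µmol mol$^{-1}$ unless
noted). The C4 values were chosen once so the enzyme-limited model keeps
its defining qualitative behaviour on the relevant range: a much steeper
$A$–$C_i$ response than C3 throughout $C_i \in (0, 200]$ (PEP
carboxylation stays limiting to $C_i \approx 540$) and a nearer-linear
coupled $A(g_s)$, while the wet-soil C4:C3 assimilation ratio (~1.8)
stays inside the 1.6–2.2 band reported for real pathway contrasts. All
parameters are overridable per scenario, including from YAML configs.

### The dry-down simulator

The simulator is deliberately quasi-static: at each step the leaf water
potential solves the steady-state balance

$$K_{leaf}(\Psi_{leaf})\,(\Psi_{soil}-\Psi_{leaf}) \;=\;
  g_s(\Psi_{leaf})\cdot\mathrm{VPD}/P_{atm},$$

with the sigmoidal stomatal response
$g_s = g_{max}/(1+\exp((\Psi_{gs50}-\Psi_{leaf})/c))$ (the sign
convention is fixed so drying closes stomata; the midpoint is
$\Psi_{gs50}$, steepness $c > 0$ in MPa) and the linear hydraulic decline
$K_{leaf} = \max(K_{max}+a\,\Psi_{leaf},\; K_{floor}K_{max})$, whose
small floor (default 5% of $K_{max}$) keeps the supply function positive
at extreme dehydration. The wettest root is selected by marching from
$\Psi_{soil}$ downward to the first sign change and bisecting to a
residual below $10^{-8}$ mmol m$^{-2}$ s$^{-1}$. Soil water then depletes
by the transpired volume out of a finite bucket, with Campbell retention
$\Psi_{soil} = \Psi_e\,\theta_{rel}^{-b}$ (defaults $\Psi_e = -0.002$
MPa, $b = 6$, bucket 2500 mol m$^{-2}$, chosen so a dry-down resolves in
hundreds of steps). A fully dynamic model with capacitances would add
transients but the quantities of interest here are curves against
$\Psi_{soil}$, which the quasi-static reduction reproduces while
remaining analytically testable (supply–demand residual checkable at
every reported step; step-halving changes trajectories by less than 1%
point-wise). VPD comes from temperature and relative humidity by the
Tetens formula; the two standard environments (0.5 kPa: 20°C/78.6% RH;
3 kPa: 30°C/29.5% RH) are built in.

Four default plant types isolate the role of the supply:demand ratio:
reference C3 ($g_{max}=0.32$ mol m$^{-2}$ s$^{-1}$, $K_{max}=8$ mmol
m$^{-2}$ s$^{-1}$ MPa$^{-1}$) and C4 ($g_{max}=0.16$, $K_{max}=8$ — i.e.
a twofold higher $K_{leaf}$:$g_s$), plus two swap scenarios built by
rescaling $K_{max}$ (never $g_{max}$) so each pathway runs with the
other's ratio. Stomatal sensitivity and P50 are identical across types,
reflecting the statistically similar hydraulic vulnerability of C3 and C4
grasses; pathway differences enter only through $g_{max}$, $K_{max}$ and
the photosynthesis model. `calibrate_conductance()` optionally rescales
$K_{max}$ (preserving P50) so a scenario operates at a target
$\Psi_{leaf}$ at field capacity.

### Comparative statistics

All phylogenetic machinery is computed from first principles on top of
`ape` tree structures. Shared root-to-MRCA path lengths are accumulated
in a single post-order sweep; Pagel's lambda multiplies the off-diagonal
covariance only. PGLS maximises the full Gaussian likelihood (profiled
over coefficients and scale) on a 201-point lambda grid followed by
golden-section refinement — robust, derivative-free and reproducible;
when a boundary and an interior value differ by less than $10^{-6}$
log-likelihood units the interior value is reported, so boundary maxima
are always explicit. Coefficient tests use $t$ statistics with $n-k$
degrees of freedom. The phylogenetic ANOVA simulates its null by
Brownian motion along the tree with group labels held fixed and reports
$p = (1+\#\{F_{sim} \ge F_{obs}\})/(n_{sim}+1)$; the parametric variant
(PGLS on a group indicator) is also exposed. Phylogenetic RMA computes
variances and the covariance in the $V^{-1}$ metric about GLS means;
the slope is $\mathrm{sign}(r)\,\mathrm{SD}(y^*)/\mathrm{SD}(x^*)$,
which collapses to classical RMA on a star tree. Regression tables
log-transform traits that are strictly positive and span more than an
order of magnitude (power-law form), a convention that can be disabled.

## The synthetic generator

`generate_dataset()` emulates the *structure* the analysis assumes: a
pure-birth (Yule) ultrametric tree; C4 arising on a requested number of
independent edges (nested or merging selections are rejected and
resampled, and the achieved origin count is always verifiable with
`count_c4_clades()`); traits built as
(C3 mean) × (C4 fold effect) × exp(Brownian deviation) × lognormal noise
with unit mean — multiplicative because the traits are positive and
ratio-scaled; per-order conduit anatomy from pathway-typical templates
with 5% jitter; and linear vulnerability curves with Gaussian noise
truncated at zero.

Default C3 means ($g_s = 0.30$ mol m$^{-2}$ s$^{-1}$, $K_{leaf} = 8$ mmol
m$^{-2}$ s$^{-1}$ MPa$^{-1}$, $A_{area} = 18$ µmol m$^{-2}$ s$^{-1}$,
$D_v = 5$ mm mm$^{-2}$) and fold effects ($g_s\times0.29$,
$K_{leaf}\times1$, $A_{area}\times1.6$, $D_v\times1.8$) encode the
headline pathway contrasts this analysis is designed to detect. Fold
effects apply to primitive traits only; contrasts in derived ratios
follow arithmetically (published per-trait contrasts come from
overlapping but non-identical species sets, so no single fold map can
reproduce every reported ratio simultaneously — test fixtures therefore
configure explicit maps, e.g. $g_s\times0.5$ with $K_{leaf}\times1$ for
a twofold ratio contrast at equal $K_{leaf}$). Within-species variance
structure of real measurements is not estimated by the generator; its
noise model is a stand-in. Consequently, passing tests demonstrate that
the estimators recover *known injected structure* under idealised noise
— not that any particular field dataset satisfies the models.

## Numerical choices and degenerate inputs

* Ellipse axes are canonicalised ($a \ge b$), so conductivity is
  symmetric in the two measured axes.
* Exactly constant vulnerability curves report a no-decline signal (P50
  absent) instead of a sign read off floating-point noise.
* `couple_diffusion(gs = 0)` returns the zero-flux state with $A$ clamped
  to $[-R_d, 0]$.
* Zero-VPD dry-downs stop after one step (the soil can never dry).
* Dixon's test refuses $n$ outside $[3, 30]$ and zero-range data.
* Absent sheath tissue raises a distinct condition — never silently zero.
* All generators are deterministic under a fixed seed; the pipeline
  manifest (per-file MD5, seed, config hash) is byte-identical across
  reruns of the same configuration.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to make Monte-Carlo answers stable: 27-species trees for
the common-garden-like fixtures and 332 for the meta-analysis-like one;
200 replicate noisy vulnerability curves; 100-replicate Brownian
simulation studies for slope recovery on 100-tip trees; 500 null
replicates (199 simulations each) for the ANOVA type-I calibration on a
50-tip tree; dry-downs at half-hour to one-hour steps over a few hundred
steps per trajectory.

## Limitations

* The dry-down model has no stem/root embolism, refilling, capacitance,
  nocturnal transpiration or leaf energy balance; kinetic constants are
  fixed at 25°C and temperature enters through VPD only.
* The C4 model omits explicit bundle-sheath CO2 dynamics and leakiness.
* No sigmoidal/exponential vulnerability forms; the linear fit is the
  operating assumption for grasses at high water potentials.
* No OU or rate-shift evolutionary models, no ancestral state
  reconstruction, no tree inference; transverse (5°) veins are excluded
  from vein density by definition.
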