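---
title: "Estimating membrane permeability from permeant trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane permeability from permeant trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

# The problem

Small molecules such as molecular oxygen and water cross lipid bilayers
often enough that their permeability can be measured directly from
equilibrium trajectories, without biased sampling.  `memperm` implements the
two standard estimators and the machinery around them:

* the **counting method**, $P = r / (2 c_w)$, where $r$ is the bidirectional
  crossing rate per unit area and $c_w$ the permeant concentration in the
  water phase.  It is nearly assumption-free (Fick's law for a symmetric
  membrane) but needs many observed crossings;
* the **inhomogeneous solubility-diffusion (ISD) model**,
  $$\frac{1}{P} = e^{-\beta F_{\mathrm{ref}}}
    \int_{-h/2}^{+h/2} \frac{dz}{e^{-\beta F(z)} D_\perp(z)},$$
  which assumes one-dimensional diffusive transport on the free-energy
  profile $F(z)$ with position-dependent normal diffusion $D_\perp(z)$.

$F(z)$ comes from the occupancy histogram,
$F(z) = -k_B T \ln p(z)$, referenced to its mean over a configurable
water zone.  $D_\perp(z)$ and the lateral profile $D_\parallel(z)$ are not
observable from occupancy; they are inferred by a Bayesian analysis of
binned transition counts (below).  All lengths are in Ångström, times in
ps, energies in kcal/mol; permeabilities are reported in cm/s
(1 Å/ps = $10^4$ cm/s), and $k_B = 0.0019872041$ kcal/(mol·K).

# Crossing events

Coordinates are membrane-centered: $z = 0$ at the bilayer midplane,
periodic over the box height $H$, with the single water slab spanning the
wrap.  The membrane interior is $|z| < h/2$; a transit counts as a
*crossing* only when the permeant enters through one dividing surface,
visits the midplane region $|z| < z_{\mathrm{mid}}$ (default 4 Å), and
exits through the other surface.  Re-exit through the entry surface is a
*rebound*.  A permeant already inside the membrane at $t = 0$ has an
unknown entry side; assuming memoryless exit, its first escape contributes
$1/2$ crossing on average, and the event detector logs it as an
*initial escape* weighted 0.5 in the effective count.  A jump between the
two water phases within one saved frame whose minimum image passes through
the slab, or a transit whose midplane visit fell between saved frames, is
classified *unresolved* and excluded from the count — these are
save-interval artifacts, rare at the default 1 ps save interval.

Two conventions deserve explanation:

* **Wraps through water.**  Because the water slab is periodic, a permeant
  can move from the "upper" to the "lower" water without touching the
  membrane.  The detector toggles the side label on such wraps and emits no
  event; otherwise every wrap would fabricate a crossing.
* **Characteristic times.**  The entrance time $\tau_{\mathrm{entr}}$ is
  measured from surface entry to the *first* midplane visit, and the escape
  time $\tau_{\mathrm{esc}}$ from that first visit to the surface exit.
  With this convention $\tau_{\mathrm{esc}}$ includes all subsequent
  midplane re-visits, so it exceeds $\tau_{\mathrm{entr}}$ even for a flat
  (non-trapping) membrane — time reversal pairs $\tau_{\mathrm{entr}}$ with
  the *last*-visit-to-exit segment, not the first.  We keep the first-visit
  convention because it is what makes midplane trapping visible: a
  last-visit convention would force the two times to be equal in
  distribution for every equilibrium system.  Consequently the package's
  trapping diagnostic is the ratio $\tau_{\mathrm{esc}}/\tau_{\mathrm{entr}}$
  *relative to its flat-membrane baseline*, not the absolute comparison of
  the two times.

The 95% confidence interval on the counting permeability is a Poisson
exact interval on the effective crossing count by default; when three or
more replicate simulations are supplied, a t-interval across replicate
estimates is used instead and labeled as such.

# Bayesian inference of F, D⊥ and D∥

Transitions between $n$ z-bins over lag times $\tau$ (defaults: 100 bins;
$\tau$ = 20, 30, 40, 50 ps) are modeled with a periodic nearest-neighbor
Smoluchowski rate matrix
$$R_{i\pm1,i} = \frac{D_{i\pm1/2}}{\Delta z^2}
  \exp\!\big(-\beta (F_{i\pm1} - F_i)/2\big),$$
with interface diffusion taken as the mean of adjacent bins and the
diagonal fixed by probability conservation.  The construction obeys
detailed balance exactly, so $\exp(\tau R)$ is computed by
eigendecomposition of the symmetrized generator
$S = e^{+\beta F/2} R \, e^{-\beta F/2}$ (a symmetric tridiagonal-plus-
corners matrix whose off-diagonals are simply $D_{i+1/2}/\Delta z^2$).

Profiles are parameterized by cosine series over the box:
10 basis functions for $F$ (the constant is gauge and not sampled) and 6
for $\ln D_\perp$ and $\ln D_\parallel$ — the exponential parameterization
keeps both diffusion profiles positive without constraints.  Lateral
displacements are modeled on a disc of radius $R_{\max}$ with a reflecting
wall: Bessel mode $k$ (with $x_k$ the $k$-th zero of $J_1$, $x_0 = 0$)
relaxes under $R^{(k)} = R - \mathrm{diag}(D_\parallel(z_i)\, x_k^2 /
R_{\max}^2)$, and the start is treated as a point at $\Delta r = 0$, so the
joint probability of (end bin, radial bin) is
$\sum_k [\exp(\tau R^{(k)})]_{ji} \, w_k(b)$ with $w_k$ the $J_0$ weights
integrated over the radial bin.  Defaults follow standard practice: 50
modes, 100 radial bins, $R_{\max} = 50$ Å.  Truncating the mode sum can
produce tiny negative cell probabilities near the $J_0$ nodes (Gibbs
ringing); these are floored at $10^{-12}$, while structural zeros are
judged on the $k = 0$ (z-marginal) propagator and veto the parameters with
a $-\infty$ log-likelihood.

Sampling is a Metropolis random walk over all coefficients with flat
priors ($|a_k| \le 10\,k_BT$; ln-D coefficients within $\pm 4$ of a
data-driven initial estimate from the short-lag mean squared
displacement).  Proposal scales adapt during burn-in toward a 20–40%
acceptance rate and are then frozen; chains for different lags are
independent.  Per-bin diffusion values are extrapolated to infinite lag by
an ordinary least-squares fit against $1/\tau$ (the intercept); the linear
form is a pragmatic choice — for genuinely Markovian data the per-lag
profiles are lag-independent and the intercept coincides with their mean,
while short-time memory shows up as a monotone lag dependence that the
intercept removes to first order.

# Transport summaries

From $F$ and the diffusion profiles the package reports, besides the ISD
permeability: the anisotropy profile $D_\parallel(z)/D_\perp(z)$ with
propagated uncertainty; an effective radial permeability
$$P_\parallel = \frac{1}{h^2} \int_{-h/2}^{+h/2}
  e^{-\beta (F - F_{\mathrm{ref}})} D_\parallel(z)\, dz,$$
a convention chosen to be dimensionally a permeability and to reduce to
$D_\parallel / h$ for a homogeneous membrane (outputs carry the convention
tag); and a companion lateral-distance estimate
$L_\parallel = \sqrt{4 \langle D_\parallel\rangle_m \tau_{\mathrm{esc}}}$
with $\langle\cdot\rangle_m$ the Boltzmann-weighted membrane average —
also a labeled convention, cross-checkable against the trajectory-based
root-mean-square lateral displacement between entry and exit.

The partition coefficient
$K(h) = \frac{1}{h}\int_{-h/2}^{+h/2} e^{-\beta(F - F_{\mathrm{ref}})} dz$
depends on the assumed membrane thickness $h$, which is genuinely
ambiguous; the package therefore emphasizes *ratios* of partition
coefficients between systems, which are insensitive to $h$ whenever the
profiles differ mainly deep inside both membranes (the acceptance suite
verifies <1% ratio variation over a ±3 Å sweep for such a pair while the
individual $K$ values vary by >10%).

# Pathways and oximetry

The three-nearest-neighbor classifier resolves *where* permeants sit
laterally: the distance between a permeant and a lipid chain is the
minimum over (heavy atom, chain carbon) pairs under the lateral periodic
minimum image; the three closest chains give the class `3-<type>` when all
share a lipid type, else `Mix`, accumulated in 1 Å z-slabs and normalized
per slab.  Ties at the third neighbor are broken by (distance, chain id)
so repeated runs agree bitwise.  A sterol counts as a single chain; each
acyl chain of a two-chain lipid is its own chain.

The oximetry surrogate measures the oxygen population $n_{O_2}(r)$ within
a contact radius $r$ of a probe site (counting oxygen *atoms*, with a
molecule-counting mode for sensitivity analysis), normalized by the
water-phase concentration of the same system, and forms the between-system
ratio $I(r)$ at $r = 4.5$ Å by default.  On the experimental side,
power-saturation curves are fit to
$$I = I_0 \sqrt{P} \big/ \big(1 + (2^{2/3} - 1) P / P_{1/2}\big)^{3/2},$$
where $P_{1/2}$ is the microwave power at which the first-derivative
amplitude falls to half its unsaturated extrapolation.  Initial guesses
come from the low-power linear region and the amplitude maximum (which
sits at $P_{1/2}/(2(2^{2/3}-1))$); relaxation-rate ratios are formed from
condition differences (oxygen-exposed minus inert) before dividing, with
errors propagated in quadrature.

# The synthetic-data generator

Validation needs data whose truth is known.  `simulate_permeants`
propagates independent permeants with the overdamped Itô equation
$$dz = \big[-\beta D_\perp(z) F'(z) + D_\perp'(z)\big] dt +
  \sqrt{2 D_\perp(z)}\, dW,$$
(Euler–Maruyama, default step 0.05 ps, saved every 1 ps), with lateral
free diffusion at $D_\parallel(z)$.  Profiles are exact cosine series, so
the generator sits *inside* the model class the Bayesian analysis assumes
— which is precisely what makes full-loop recovery a sharp test.  The
spurious-drift term $D_\perp'(z)$ is not optional: an ablation switch
exists only to demonstrate that omitting it biases the sampled density
toward low-diffusion regions (the test suite checks both directions).
Initial positions are drawn from the Boltzmann distribution of $F$ by
default, so the initially-inside 0.5-crossing rule is exercised.

The built-in profile shapes are qualitative fixtures: an "oxygen-like"
spec with a midplane well of about −1.5 kcal/mol and head-group
shoulders, and a "water-like" spec with a ~6 kcal/mol central barrier and
a shallow metastable dip.  The toy microdomain membrane places vertical
chain columns on a triangular lattice with a compact ordered-chain domain
surrounded by boundary channels, and records the ground-truth class of
every placed permeant from the three laterally nearest lattice sites — an
assignment independent of the carbon-based classifier it validates.

What the generator deliberately does **not** emulate: solvent memory and
inertial effects (the dynamics are strictly Markovian), permeant–permeant
interactions, lipid mechanics, or any coupling between lateral position
and the free-energy profile.  Passing tests therefore demonstrate the
*estimators* are correct for diffusive transport; on real trajectories the
counting and Bayesian estimates can differ genuinely, because molecular
dynamics contains non-diffusive short-time behavior that the ISD model
ignores.  That difference is a physical diagnostic, not a bug, and the
package reports both estimators side by side for that reason.

# Numerical choices and problem sizes

* Quadrature is composite trapezoid on the (uniform) bin grid with the
  integration limits interpolated; full-box integrals use the midpoint
  rule, which is exact for periodic grids.
* Never-visited histogram bins carry an `Inf` sentinel: excluded from the
  water-reference average, weight zero in Boltzmann integrals, an error
  inside any membrane-window integral.
* Profiles are not symmetrized by default (asymmetry is a convergence
  diagnostic); a symmetrize option exists for diagnostics only.
* The matrix exponential uses the symmetrized eigendecomposition
  throughout; for the parameter ranges reachable under the priors the
  conditioning ($e^{\pm\beta F/2}$) is benign.
* Test problem sizes were chosen to make every stochastic check pass with
  a comfortable statistical margin while the whole suite stays fast: e.g.
  the full Bayesian recovery loop runs 24 permeants for 30 ns on a 50 Å
  box with 25 z-bins, 10 Bessel modes and a 25 Å radial cutoff.  The
  reduced cutoff accompanies the reduced mode count: with $K$ modes the
  finest resolvable radial scale is roughly $R_{\max}/K$, and the lag-20
  displacement scale of ~3 Å needs $R_{\max}/K \lesssim 2.5$ Å.
* Recovery achieved under those conditions: free energy within 0.3
  $k_BT$ RMS, $D_\perp$ within 10% and $D_\parallel$ within 15% on all
  bins — the tolerances asserted by the acceptance suite.

# A worked example

```{r example, eval = FALSE}
sp   <- default_profile_spec("oxygen_like", H = 60)
run  <- synthetic_run_spec(sp, n_permeants = 40, total_ps = 20000, seed = 1)
tr   <- simulate_permeants(run)
geom <- membrane_geometry(h_half = 16, H = 60)

pmf  <- estimate_pmf(tr, n_bins = 60, geometry = geom)
cw   <- water_concentration(40, pmf, A = 3600, trajs = tr, geometry = geom)
logs <- lapply(tr, detect_events, geometry = geom)
counting_permeability(logs, c_w = cw)

gt   <- evaluate_profiles(sp, pmf$z)
D    <- diffusion_profiles(pmf$z, gt$D_perp, D_par = gt$D_par)
permeability_isd(pmf, D, h = 32)
```

# Known limitations

The Bayesian module assumes uniform save intervals and a single diffusing
species per run; the radial likelihood treats the lateral start as a point
(adequate when $R_{\max}$ is much larger than the radial bin width); the
infinite-lag extrapolation is linear in $1/\tau$ and will not capture
strongly non-linear memory; and the pipeline's non-Bayesian path fills the
diffusion profiles from the generator's ground truth, which is only
meaningful for synthetic systems.  Imported trajectories must already be
wrapped and membrane-centered (helpers are provided), and binary MD
formats are out of scope — adapters should emit the package's plain
tabular dialect.
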