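---
title: "Chemically controlled condensation: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemically controlled condensation: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensr)
```

# The model

`condensr` studies a minimal question: how do chemical reactions that switch
a phase-separating monomer between an active and an inactive form control
the growth and dissolution of its condensate droplets? The motivating
experimental systems are DNA nanostar condensates, where an "invader" strand
deactivates a sticky end (reducing the nanostar valency below the
condensation threshold) and an "anti-invader" strand removes the invader and
restores activity. The package treats the problem at mean-field level, which
is enough to reproduce the qualitative phenomenology: dose-dependent
dissolution, non-monotonic regrowth, surface- vs volume-limited dissolution,
and the suppression of condensation by partially deactivated monomer pools.

## Species and reactions

Five fields live on a periodic grid: active monomer $n$, inactive monomer
$n_0$, inhibitor $I$, activator $A$ and waste $W$, all volume-fraction-like
and dimensionless. Two reversible mass-action reactions couple them:

$$n + I \underset{k_b}{\overset{k_f}{\rightleftharpoons}} n_0, \qquad
  n_0 + A \underset{h_b}{\overset{h_f}{\rightleftharpoons}} n + W .$$

Three linear combinations are conserved exactly: total monomer $n + n_0$,
total inhibitor $I + n_0 + W$, and total activator $A + W$. The integrator
audits all three at every snapshot.

## Free energy

Only the active monomer phase separates. The local free-energy density is a
symmetric regular-solution (lattice-gas) form over the composition simplex
$(n, n_0, s)$ with solvent $s = 1 - n - n_0$:

$$f(n, n_0) = n\ln n + n_0 \ln n_0 + s \ln s
  + \chi\, n\, s + X\, n\, n_0 .$$

$\chi$ is the active-monomer self-interaction; the symmetric one-species
mixture demixes for $\chi > 2$, with spinodal compositions
$n = \tfrac12\left(1 \pm \sqrt{1 - 2/\chi}\right)$ and binodal compositions
solving $\ln\frac{n}{1-n} = \chi(2n - 1)$. $X$ is the active-inactive
cross-interaction, the single knob that decides what deactivated monomers do:
$X < 0$ attracts them into droplets (co-condensation), $X > 2$ expels them
(the critical interaction of the symmetric binary sub-mixture), and the
intermediate range lets them enter droplets *without* contributing binding
energy - which is what makes partial deactivation such an efficient
dissolution mechanism.

This form was chosen because it is the simplest free energy that pins both
anchor values ($X = 0$ and $X = 2$) analytically and reduces to standard
regular-solution results in every one-species limit. It is pluggable: any
function `(n, n0, params) -> list(f, df_dn, df_dn0)` assigned to
`params$free_energy_fn` replaces it throughout the package (a
Ginzburg-Landau quartic is exercised in the test suite).

Logarithms are floored at `eps_log` ($10^{-9}$) inside the integrator so
that transient excursions to the simplex boundary stay finite; all stability
and common-tangent computations use the unfloored analytic expressions,
which agree with the floored ones everywhere in the interior.

## Dynamics

The active monomer follows conserved Cahn-Hilliard dynamics with mobility
$M$ and interfacial coefficient $\kappa$; the other four species are simple
Fickian diffusers (they carry no interfacial energy):

$$\partial_t n = M \nabla^2\!\left(\partial_n f - \kappa \nabla^2 n\right)
  + R_n, \qquad
  \partial_t c = D_c \nabla^2 c + R_c \quad (c \in \{n_0, I, A, W\}).$$

Time is nondimensionalized so that the forward inhibition rate times the
monomer concentration scale equals one ($k_f = 1$); lengths are in grid
units (unit spacing). A constant-mobility transport of the *logarithmic*
chemical potential of $n_0$ would be singular as $n_0 \to 0$ (exactly the
state every scenario starts in); in the dilute limit the degenerate-mobility
form of that transport is Fick's law, which is what the package integrates.

# Numerics

The integrator is a first-order semi-implicit (IMEX) spectral scheme on the
periodic grid: the stiff $\kappa\nabla^4$ term, the Fickian diffusion and a
linear splitting term $S\,\nabla^2 n$ (`stab`, default $2\chi$) are treated
implicitly in Fourier space; the nonlinear local chemical potential and the
chemistry are explicit. The splitting constant buys stability at the default
step `dt` without changing the fixed points; the dispersion-relation test is
run at small `dt`, where the scheme's growth rates match the analytic
$\omega(q) = -Mq^2\!\left(f''(\bar n) + \kappa q^2\right)$ to better than
2%. Spectral transport conserves each field's spatial mean to machine
precision, so the three reaction invariants drift only through the explicit
chemistry (measured: relative $10^{-12}$ over $10^4$ steps). A finiteness
check after every step converts overflow into an error naming the step.

Injections of inhibitor or activator are instantaneous concentration
additions, either uniform or restricted to the dilute phase (below the
binodal-midpoint threshold). Dilute-phase-only increments are softened with
a one-cell Gaussian before being added - the kernel is positive and
mean-preserving, so the requested mass is added exactly while the spectral
transport of the sharp mask edge does not ring.

Degenerate inputs are handled explicitly: a zero-noise initialization stays
exactly uniform; a scenario without injections is a plain
coarsening run; `M`, `kappa` and `dt` must be positive, grids at least
16 cells per edge.

# Study conditions

`reference_params()` freezes the conditions used by the validation suite and
the worked examples; they were chosen once, for physical reasons:

| parameter | value | why |
|---|---|---|
| $\chi$ | 2.5 | moderate quench: binodal 0.145/0.855, spinodal 0.276/0.724; deep enough for robust droplets, shallow enough that sub-unity inhibitor doses cross the boundary |
| $X$ | 1 | middle of the open interval $(0, 2)$: inactive monomers enter droplets but do not bind |
| $k_f, k_b$ | 1, 0.1 | toehold-mediated invasion is strongly forward-biased |
| $h_f, h_b$ | 1, 0.01 | displacement of the invader is nearly irreversible; activation must push the composition back inside the spinodal for regrowth to be possible at all |
| $n_{\text{tot}}$ | 0.35 | inside the spinodal, droplet (minority-phase) morphology |
| $M, \kappa, D$ | 1 | unit transport scales; $D_I$ is varied $0.1 \to 100$ for the diffusion study |
| grid | $64^2$, unit spacing | resolves 5-15 droplets; a run of 1400 time units takes well under a minute |
| `dt` | 0.2 (scenario runs) | stable with `stab = 5`; halved or quartered where fine temporal resolution of fast dissolution is measured |

The canonical scenarios mirror the invasion/anti-invasion protocol:
equilibrate 400 time units from uniform + $10^{-3}$ noise, inject inhibitor
at $0.25\times/0.5\times/1\times$ the monomer amount, and for regrowth
inject the matching activator dose 100 time units later - late enough that
the $1\times$ sample is fully dissolved (so regrowth must renucleate many
small droplets) while the $0.5\times$ sample still contains remnants that
simply regrow. That timing difference *is* the mechanism behind the
non-monotonic dose dependence of regrowth speed.

Because the dynamics is deterministic (no Cahn-Hilliard-Cook noise),
renucleation after complete dissolution amplifies the residual numerical
inhomogeneity left by the dissolved state rather than thermal fluctuations.
The regrowth lag this produces is qualitatively the right physics
(nucleation-dominated, slow mean-size growth) but its duration should not be
read quantitatively.

# Stability analysis and phase diagrams

Homogeneous steady states of the reaction network are computed from the two
equilibrium conditions plus the three conservation laws - a closed-form
quadratic without activator, one outer bisection over the waste
concentration with it (residuals below $10^{-10}$ on 1000 random totals).
A composition is classified two-phase by the spinodal criterion: the
$(n, n_0)$ Hessian of $f$ has a negative eigenvalue, which for this $f$
reduces to a negative determinant. Phase diagrams over (total inhibitor,
$\chi$) chain the two steps; with $k_f = k_b$ the two-phase region shrinks
monotonically with inhibitor - the "chemical analogue of raising
temperature".

Two constructions need coexistence rather than instability and use the
common tangent. First, the partitioning of a *tracer* amount of inactive
monomer between the coexisting one-species phases: equal chemical potential
gives the partition coefficient
$K(X) = \frac{1-n_d}{1-n_l}\,e^{-(X-\chi)(n_d-n_l)}$, which crosses 1
exactly at $X = 0$ - the co-condensation boundary is located numerically as
that root. Second, exclusion: inactive monomers are expelled from the dense
phase when the solvent-free active/inactive sub-mixture itself demixes; the
minimum curvature of $x\ln x + (1-x)\ln(1-x) + X x(1-x)$ crosses zero at
$X = 2$, found by bisection. The suppression threshold (the inactive:active
ratio at which a mixed pool leaves the two-phase region) is a scan plus
bisection to $10^{-3}$ on the spinodal criterion, with two guards: a
co-condensing inactive species ($K > 1$, i.e. $X < 0$) reports "no finite
threshold" directly, and the scan stops while at least 5% solvent remains,
because a homogeneous state that only restabilizes at solvent exhaustion is
the fully condensed branch, not a suppressed mixture. At the reference
conditions, with the active concentration fixed $1.5\times$ above its
one-species spinodal threshold, it evaluates to $\approx 0.56$. The
operating point is the main sensitivity: moving the active concentration
between $1.3\times$ and $1.7\times$ of threshold, or $\chi$ between 2.4 and
2.6, moves the ratio over roughly 0.4-0.8.

# Morphometry

Droplets in simulated fields are connected components (8-connectivity,
periodic wrap merged) of $\{n > \text{threshold}\}$ with the threshold fixed
parameter-free at the binodal midpoint (0.5 for the symmetric free energy);
components under 4 cells are discarded as interface noise. Centroids and
second moments of wrap-crossing droplets use circular unwrapping, valid for
droplets smaller than half the domain. Tracking across frames assigns each
droplet to the predecessor track of maximum pixel overlap (ties: larger
overlap, then lower label id); per-droplet dissolution half-times are
linearly interpolated between frames, with disappearance treated as reaching
zero area at the next frame. Power-law fits are ordinary least squares in
log-log space; the exponent ranges used to *label* dissolution regimes
(surface- vs volume-driven) are configuration, not claims. The
interface-sharpness statistic - the mean gradient magnitude over
threshold-crossing cells - is what distinguishes shrinking sharp droplets
(slow inhibitor diffusion) from blurring ones (fast diffusion).

# The micrograph quantification pipeline

The image side re-implements an edge-based condensate detector in the exact
order: Gaussian smoothing (`gaussian_sigma`, default 2 px) -> Sobel
magnitude -> Otsu threshold on the magnitude -> cleanup -> thinning to
1-px edges (Zhang-Suen) -> fill of enclosed regions -> binary opening
(disk, default radius 1; removes unenclosed lines and speckles) -> disk
dilation (default radius 5 px) -> 8-connected labeling. Out-of-focus
objects have soft edges whose gradients fall below the Otsu threshold, so
detection is focal-plane selective.

Two robustness choices are package decisions. The cleanup step removes
edge components under 5 px; it deliberately does *not* close gaps, because a
closing fills the 1-2 px central gradient minimum of objects near the
resolution limit, after which thinning reduces them to a dot that the
opening erases - with closing, micron-scale objects are undetectable.
Second, Otsu's method always splits its histogram, so a frame containing
only noise would be binarized into dense speckle; the threshold therefore
has a floor of `edge_floor` (default 3) times the median Sobel magnitude,
i.e. of the noise-gradient level. On rendered scenes the Otsu threshold sits
5-40x above the median, so the floor never engages when real edges are
present; on blank frames it removes all spurious detections.

Measurements are per-label area (um^2 via the user-supplied pixel size, for
which no instrument default is assumed), equivalent diameter
$2\sqrt{A/\pi}$, eccentricity from second moments, and centroid.
Border-touching objects are kept by default (switchable). The
zero-condensate rule for a pooled condition reads: fewer than 16 condensates
AND (mean equivalent diameter <= 1.5 um OR total area < 28.32 um^2).
The conjunction-of-count-with-size parse guarantees that a few large
droplets are never declared zero; the 28.32 um^2 constant is kept verbatim
as the conventional value even though sixteen 1.5-um disks sum to
28.27 um^2 - the discrepancy is documented, not corrected. All three
constants and the parse live in `quant_config()`. Normalization divides
droplet areas by the pre-invasion mean area, totals by the pre-invasion
total, counts by the pre-invasion count. Box summaries use the
linear-interpolation quantile convention with 1.5 IQR whiskers; the
uncertainty of normalized means uses a half-sample bootstrap - three seeded
sub-samples of $\lfloor n/2 \rfloor$ observations drawn without replacement,
with the SEM taken over the three sub-sample means.

# The synthetic-scene generator

Scenes are the package's ground-truth instrument: near-circular bright
droplets (default log-normal diameters, median 3 um, sigma-log 0.4, within
0.5-20 um) on a dark background at 0.11 um/px (a typical 60x oil-immersion
sampling). Each droplet is drawn with the spherical-cap profile
$I(\rho) = I_0\sqrt{1 - (\rho/r)^2}$ - the chord-length projection of a
uniformly fluorescent sphere - then blurred (in-focus sigma 1.5 px;
out-of-focus objects get 4x the blur and half the contrast), summed onto the
background, and degraded with Poisson shot noise plus Gaussian read noise.
Rendering is bit-deterministic per seed. Time-course experiments emit 8
images per time point with truth tables; dissolution shrinks radii linearly
to zero, coarsening removes droplets while conserving total truth area
exactly, regrowth nucleates and grows them.

What the generator does *not* emulate: a physical PSF (defocus is a single
Gaussian scale, not a z-dependent Airy pattern), camera fixed-pattern noise,
fluorophore bleaching, droplet fusion during acquisition, and any claim that
the synthetic size distribution matches a particular experiment. Passing
the pipeline tests on these scenes therefore demonstrates correctness of
the *algorithmic chain* (segmentation geometry, unit conversion, filtering,
statistics) under controlled optics, not instrument-level accuracy on real
micrographs.

# Known limitations

* **Small-object area bias.** The final radius-5 dilation adds ~1.1 um to
  every diameter at 0.11 um/px, while the pre-dilation edge mask under-reads
  radii by only ~2-4 px (the thinned Otsu band is centred slightly inside
  the intensity rim). Net effect, measured on synthetic scenes: about +37%
  area at 3 um, +11% at 5 um, under 10% from ~8 um up. Detection of 1-um
  objects works and overestimates their diameter, as expected for a
  dilation-compensated edge method. Comparisons of *normalized* areas are
  unaffected to first order, which is why downstream metrics normalize.
* **Deterministic field dynamics.** No thermal noise; nucleation out of a
  metastable (between binodal and spinodal) composition does not occur, and
  renucleation timing after complete dissolution is qualitative.
* **Dimensionality.** Routine runs and defaults are 2-D; 3-D grids are
  supported by the same spectral code (volumetric labeling reports "area"
  as voxel counts per slice), but all validation figures are 2-D. The
  qualitative claims exercised by the tests are dimension-independent.
* **No hydrodynamics.** Coarsening proceeds by diffusive ripening;
  coalescence by advective flow is absent, so late-time growth exponents
  should not be compared to experiments with mobile droplets.
* **Mean-field chemistry.** Reaction rates use local concentrations;
  stochastic copy-number effects, relevant for very small droplets, are out
  of scope.
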