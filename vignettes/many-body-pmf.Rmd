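---
title: "Learning coarse-grained many-body potentials of mean force from mean forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning coarse-grained many-body potentials of mean force from mean forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpmf)
```

## The model

`cgpmf` builds effective coarse-grained (CG) interaction potentials for
spherical particles (ligand-stabilized nanoparticles, colloids in a polymer
bath) from the bottom up. The CG representation keeps one site per particle
— the center of mass of its rigid core — and asks for the potential of mean
force (PMF) $\Phi(\mathbf R^N)$: the free energy of a fixed CG configuration
with every other degree of freedom (ligand beads, polymer coils) thermally
averaged out. Thermodynamic consistency fixes $\Phi$ up to a constant: its
negative gradient must equal the *mean force* on each frozen site,

$$\mathbf F_I \;=\; -\nabla_I \Phi(\mathbf R^N)
           \;=\; \Big\langle \textstyle\sum_{i \in I} \mathbf f_i \Big\rangle_{\mathbf R^N},$$

the ensemble average of the total instantaneous force on the core unit in
the fine-grained (FG) system with all core centers held fixed.

The PMF is expanded in per-site contributions
$\Phi = \sum_K \Phi_K$, each a *linear* combination of Behler–Parrinello
symmetry functions (SFs) describing the local environment of site $K$:
$\Phi_K = \sum_J \omega_J\, G_J(K)$. Applying the chain rule, the model
force is

$$F_{I,\alpha} \;=\; -\sum_K \sum_J \omega_J\,
      \frac{\partial G_J(K)}{\partial R_{I,\alpha}},$$

which is linear in the weights $\omega_J$, so force matching reduces to
ordinary least squares: each training row is one Cartesian component of one
site's mean force in one configuration; the column for descriptor $J$ holds
$-\sum_K \partial G_J(K)/\partial R_{I,\alpha}$. Because the model is
linear, the scalar many-body PMF is then available in closed form from the
same weights — no reaction coordinate and no thermodynamic integration is
ever needed, and Monte Carlo simulation (which needs energies, not just
forces) becomes possible directly.

The reference state is infinite dilution: an isolated particle has all
neighbor sums empty, so $G_J = 0$ and $\Phi \to 0$ exactly as all pair
distances exceed the cutoff. Consistently, the regression carries **no
intercept** — the mean force vanishes for isolated particles, and the
additive constant of the PMF is identically zero with this reference.
Training sets must therefore include dilute configurations where the mean
forces vanish; all generators in this package produce them.

## Descriptors

Two families, both sharing the smooth cosine cutoff
$f_c(r) = \tfrac12[\cos(\pi r/R_c) + 1]$ for $r \le R_c$ (value and slope
both vanish at $R_c$):

* radial: $G^{(2)}(I) = \sum_{J \ne I} e^{-\mu (R_{IJ} - R_s)^2} f_c(R_{IJ})$,
  a Gaussian shell of width $\sim \mu^{-1/2}$ at distance $R_s$;
* angular: over neighbor pairs of the center $I$,
  $$G^{(3)}(I) = 2^{1-\xi} \sum_{J<K} (1 + \lambda\cos\theta_{JIK})^{\xi}\,
    e^{-\mu_a (R_{IJ}^2 + R_{IK}^2 + R_{JK}^2)}\,
    f_c(R_{IJ})\, f_c(R_{IK})\, f_c(R_{JK}),$$
  with $\lambda = \pm 1$ selecting the angle of maximal response and $\xi$
  the angular resolution.

Gradients are analytic and continuous; the test suite verifies every
implemented formula against central finite differences on randomized small
configurations, together with the exact sum rule
$\sum_I \nabla_I G_J(K) = 0$ (translation invariance), rotation
equivariance, and continuity as a particle crosses the cutoff.

Numerical guards: $\cos\theta$ is clamped to $[-1, 1]$ before
exponentiation; pair distances below $10^{-9}\,\sigma_c$ raise a
degenerate-geometry error; periodic evaluation demands every box edge be at
least $2 R_c$ so the minimum-image convention is unambiguous (smaller boxes
are an error, never silent double counting). Neighbor enumeration is
brute-force $O(N^2)$ throughout: every system this package targets has
$N \le 500$ sites, where cell lists would add bookkeeping without
measurable gain.

All internal lengths are in units of the core diameter $\sigma_c$ and
energies in $k_BT$; file headers record units and loaders refuse
mismatches.

## Descriptor pools and selection

A large candidate pool is laid out as a Cartesian product of parameter
lists (`build_pool()`); `np_pair_pool()` and `np_cluster_pool()` provide
the 330-candidate radial pool and the 100 + 64 radial/angular pool used for
the nanoparticle studies, with $R_c = 2.5\,\sigma_c$. For depletion
systems, `ao_pool(q)` scales shifts and widths to the interaction window
$[\sigma_c, (1+q)\sigma_c]$: Gaussian shifts at $q/8$ spacing and widths
from much broader than the window down to a few times finer than the shift
spacing. The nanoparticle pools are tuned to interactions of range
$\sim \sigma_c$; reusing them unscaled on a window of width $0.1\,\sigma_c$
would leave the force curve unresolved.

Selection is greedy forward selection on correlations: the first pick
maximizes the squared Pearson correlation $c^2$ with the target; each later
pick maximizes the increase of the squared multiple correlation $R^2$, and
the procedure stops when the best increase falls below `delta_r2_min`.
Internally the candidates are residualized against the selected set
(Gram–Schmidt), which is algebraically identical to the regression-residual
form of $R^2$ and numerically stabler than inverting the correlation matrix
$\mathbf c^T \mathbf R^{-1} \mathbf c$; the matrix form is retained in
`multiple_r2(..., method = "corrmatrix")` and the two are tested to agree
to $10^{-10}$. Ties break toward the lowest column index, all-zero columns
are dropped with a logged count, and the first pick is always taken so the
stopping rule acts on increments only.

The stopping default is `delta_r2_min = 1e-4`; the shipped depletion
studies use `1e-6` because their quadrature-generated forces are
noise-free, so smaller increments are still signal. Pushing further
(`1e-8`) starts selecting near-collinear sharp Gaussians whose oscillations
are unconstrained between training separations — the classic symptom of
overfitting an interpolation basis — and is not a default anywhere.

Weights are fit by QR-based least squares on the raw (unstandardized)
selected columns so $\omega_J$ keeps physical units; rank-deficient
selections drop the offending columns with a warning. Diagnostics report
the fraction of centered target variance explained and the RMSE in
$k_BT/\sigma_c$.

## Fine-grained reference simulators

### Ligand-capped nanoparticles

The FG nanoparticle is a rigid spherical core decorated with bead-spring
ligands on a Fibonacci lattice of grafting sites. Non-bonded beads interact
through a solvent-quality-modified Lennard-Jones potential: the repulsive
branch $u_{\rm LJ}(r) + (1-s)\,\epsilon$ below the minimum and the scaled
attractive branch $s\,u_{\rm LJ}(r)$ beyond, truncated at
$r_c = 1.2\,\mathrm{nm}$; $s = 0$ is the purely repulsive
Weeks–Chandler–Andersen limit (good solvent), $s = 1$ the full
Lennard-Jones (an extremely bad solvent). Bonds and angles are harmonic
with the $K (x - x_0)^2$ convention (no $\tfrac12$), matching the stated
constants ($K_b = 149.3787$ kcal mol$^{-1}$ nm$^{-2}$, $b_0 = 0.47$ nm,
$K_\theta = 2.9876$ kcal mol$^{-1}$, $\theta_0 = 180^\circ$) at
$T = 300$ K, all converted to reduced bead units
($\sigma_b = 0.47\,\mathrm{nm}$, energies in $k_BT$).

Mean forces are sampled with the cores *frozen* — position and orientation
— by BAOAB Langevin dynamics of the ligand beads (time step
$0.004\,\tau$, friction $1/\tau$), after a capped steepest-descent pass
removes construction overlaps. Freezing orientations is stronger than
constraining only the centers of mass; for quasi-spherical coronas the
orientational relaxation couples weakly to the radial mean force, and it
removes any need for rigid-body integration. The core acts on beads as a
single surface-shifted WCA sphere; core–core interactions are neglected
(for small cores they are much weaker than the ligand-mediated forces).
The mean force on a core is the time average of the bead–core reactions
plus the grafting-bond reactions; errors come from ten-block averaging.

Two geometries are built in: the full-scale particle (275 core beads, 275
five-bead ligands, 1650 beads — long-running, kept for completeness) and a
desk-scale default of 42 three-bead ligands on a $3\,\sigma_b$ core, which
preserves the surface coverage (about 6.7 ligands/nm² against 5/nm² at full
scale) while making a two-body mean-force scan a matter of seconds per
distance. At this reduced scale the per-ligand corona cohesion is weaker
than at full scale, so the package's bad-solvent reference point is the
$s = 1$ limit (at full scale the same switch already shows at $s = 0.3$);
the good-solvent point stays $s = 0.1$. The qualitative contrast — purely
repulsive versus
deep attractive well — is the property being exercised, and it is robust
across seeds.

The two-body PMF is recovered from a distance scan by the symmetrized
projection $F_m(R) = \tfrac12\langle(\mathbf F_I - \mathbf F_J)\cdot
\hat{\mathbf R}_{IJ}\rangle$ and trapezoid integration from the largest
scanned distance inward, $\Phi^{(2)}(R) = \int_R^{\infty} F_m\,dR'$ with
$\Phi^{(2)}(R_{\max}) = 0$.

### Colloid–polymer mixtures (Asakura–Oosawa)

Hard-sphere colloids of diameter $\sigma_c$ in a reservoir of mutually
ideal polymer coils of diameter $q\,\sigma_c$ at packing fraction
$\eta_p^r$. Ideality makes the model exactly solvable around fixed
colloids: the polymer density at any accessible point equals the reservoir
density, so the mean force on colloid $I$ is a contact integral of the
ideal-gas pressure over its exclusion sphere of radius
$(\sigma_c + \sigma_p)/2$,

$$\beta\mathbf F_I = -\rho_p \oint_{S_I} \chi(\mathbf r)\,
  \hat{\mathbf n}(\mathbf r)\, dA,$$

with $\chi$ the indicator that the surface point lies outside every other
colloid's exclusion sphere. `ao_mean_forces()` evaluates this by a ring
decomposition: on each ring of constant colatitude the blocked arcs are
intervals with closed-form endpoints, so the azimuthal integral is exact
and only the polar direction is discretized (midpoint rule, 2000 rings by
default; relative accuracy $\sim 10^{-4}$). Arcs from different blockers
are summed directly, which is exact while the blocked caps are pairwise
disjoint — guaranteed for $q < 2/\sqrt3 - 1 \approx 0.155$, and checked at
run time; overlapping caps (possible at large $q$ with three near-contact
colloids) fall back to seeded Monte Carlo surface sampling. For two
colloids the integral reduces to the classic Asakura–Oosawa overlap-volume
potential, implemented independently in `ao_analytic_depletion()` as the
closed-form oracle; quadrature and oracle agree to better than 1% across
the depletion range, and at $q = 1$, $\eta_p^r = 0.5$ the contact value is
$\beta W(\sigma_c) = -1.25$.

Two study settings ship with the package. At $q = 1$, $\eta_p^r = 0.5$,
many-body depletion effects are strong and the pair model is trained on a
two-colloid separation ladder (dense across the depletion window, sparse
zero-force anchors beyond). At $q = 0.1$ the exclusion caps cannot triply
overlap, so the *exact* mean forces are pairwise additive — a stringent
test: a many-body model trained on 10-colloid clusters must agree with the
pair model, leaving a triplet-and-higher correction $\Phi^{(3+)} \approx 0$
in rigid triplet/quartet scans. The reservoir packing fraction for this
study is $\eta_p^r = 0.05$, chosen so the contact well is
$\mathcal O(1)\,k_BT$, comparable to the $q = 1$ study; the pairwise-limit
test then probes the geometry of the method, not a pathological energy
scale. Cluster training configurations are drawn from a
confinement-diameter ladder (a harmonic spherical wall, removed before
recording) sampled *with* the two-body depletion attraction: a purely
hard-sphere sampler almost never visits the near-contact pairs that an
attractive equilibrium system populates, and without them the sharp end of
the basis is unconstrained exactly where the scans evaluate. Which sampler
generated a configuration has no bearing on its mean forces — those always
come from the quadrature.

## Monte Carlo engine

`mc_run()` performs Metropolis sampling with single-particle translations
and, in NPT, volume moves uniform in $\ln V$ once per sweep with the
$P\Delta V$ and $(N{+}1)\ln(V'/V)$ acceptance terms. Because $\Phi$ is a
sum of per-site terms with cutoff $R_c$, a move of particle $i$ changes
$\Phi_K$ exactly for the sites within $R_c$ of its old or new position
(plus $K = i$); the engine re-evaluates that set through the same code path
used by `evaluate_pmf()`, and the incremental total is checked against a
full recomputation at the end of every run (agreement to $10^{-8}$
relative is asserted in the tests; in practice it is at machine precision).
Step sizes are tuned toward a 0.2–0.5 acceptance window during
equilibration only and frozen for production, preserving detailed balance.
A box shrinking below $2R_c$ aborts the run. An optional hard-core
diameter rejects overlapping moves — required when the learned potential
describes only the polymer- or solvent-mediated part of the interaction of
hard particles, as in the depletion studies; the learned basis is smooth
and says nothing about $r < \sigma_c$, which the training never visits.

A tabulated-pair-potential back-end (`model = list(r =, u =)`) provides an
independent route for cross-checks: at $q = 0.1$ the pair correlation
function of the model-driven run matches the one driven by the analytic
depletion table within histogram noise.

Rigid-geometry scans (`geometry_scan()`) evaluate a many-body model and a
pairwise-summed two-body model on triplet (T, L) and quartet (SQ)
configurations with two particles fixed and a probe moved along
geometry-specific paths, reporting
$\Phi^{(3+)} = \Phi_{\rm many} - \Phi_{\rm pairsum}$. For any radial-only
model evaluated on its own pair sum, $\Phi^{(3+)} \equiv 0$ identically —
a structural check in the test suite.

## What the synthetic data do and do not emulate

The quadrature depletion forces are exact (noise-free) up to a controlled
discretization, so fits on them probe representation and selection, not
statistical robustness. The Langevin nanoparticle forces carry realistic
sampling noise but come from a reduced geometry: shorter ligands, smaller
cores, frozen orientations, no explicit solvent, no core–core van der
Waals attraction. Passing tests therefore demonstrate that the machinery —
descriptors, gradients, selection, regression, closed-form PMF, MC — is
correct and that the physics it extracts (solvent-quality switch,
depletion well depth and range, pairwise limit) is right at these scales;
they do not certify force-field accuracy for any particular laboratory
system, which requires full-scale reference simulations.

Problem sizes used by the shipped tests and the acceptance script, chosen
so the full pipeline runs in minutes on one core: 69-point separation
ladders for pair training; 50 ten-colloid clusters for many-body training;
N = 108 particles and a few thousand sweeps for the MC checks; 11 scan
distances with 38 000 Langevin steps each for the nanoparticle solvent
contrast. Every stochastic stage derives its stream from the global seed
plus a stage tag, so whole pipelines are bit-reproducible.

## Known limitations

* Single species only; no species-pair-resolved symmetry functions and no
  descriptors for anisotropic particles.
* Plain least squares by design: no regularization and no uncertainty
  quantification on the weights.
* The angular-descriptor printed convention adopted here is the standard
  wide form (prefactor $2^{1-\xi}$, Gaussian over all three triplet
  distances, triple cutoff); the finite-difference oracle validates the
  implementation independently of that choice.
* The ring quadrature for depletion forces requires pairwise-disjoint
  blocked caps; dense many-colloid systems at $q \gtrsim 0.155$ must use
  the Monte Carlo surface integration.
* NPT volume moves rescale all coordinates and re-evaluate the total
  energy; at one volume attempt per sweep this costs a constant factor,
  acceptable at $N \le 500$.
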