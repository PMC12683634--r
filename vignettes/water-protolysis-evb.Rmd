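---
title: "Modelling water protolysis energetics with a two-state EVB droplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling water protolysis energetics with a two-state EVB droplet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Water protolysis, `2 H2O -> H3O+ + OH-`, is the rate-limiting step of the
autoxidation of l-DOPA, including l-DOPA residues mis-incorporated into
proteins in place of tyrosine.  The subsequent hydroxide attack and
cyclization are fast by comparison, so the question of whether a protein
environment accelerates or suppresses l-DOPA autoxidation reduces to how
that environment changes the free-energy cost of splitting a hydrogen-bonded
water dimer into a contact hydronium-hydroxide ion pair.

`protolysis` implements the desk-scale machinery for this question in three
layers:

1. **Reference thermodynamics** (`rate_to_barrier()`, `autoprotolysis_keq()`,
   `assemble_protolysis_profile()`, ...): converts measured rate constants,
   concentrations and pKa values into an experimentally anchored bulk-water
   reaction profile.
2. **Two-state EVB sampling and estimation** (`build_droplet()`,
   `run_schedule()`, `us_profile()`, `calibrate_evb()`): a toy aqueous
   system whose reaction free-energy profile along the energy-gap coordinate
   can be calibrated to the reference energetics.
3. **Charged-solvation cycle algebra** (`solve_ion_cycle()`,
   `transfer_gap()`, `born_correction()`, ...): finite-size corrections and
   counterion thermodynamic cycles used to cost the alternative pathway in
   which a hydroxide ion is formed in bulk water and transported to the
   reactive site.

## Reference thermodynamics

Transition-state theory (Eyring-Polanyi, transmission coefficient one)
relates a first-order rate constant to an activation free energy,
$\Delta G^\ddagger = -k_B T \ln(k h / k_B T)$.  The autoxidation kinetics
measured at 37 °C (`k = 2.56e-7` 1/s, half-life 752 h) give
$\Delta G^\ddagger = 27.55$ kcal/mol.

The protolysis reaction free energy comes from the dimensionless
mole-fraction equilibrium constant at pH 7 and 25 °C,
$K_{eq} = (x_{H_3O^+})(x_{OH^-}) \approx 3.25\times 10^{-18}$ with the mole
fraction of liquid water taken as unity (equivalently, a 55.345 M standard
state), giving $\Delta G_0 = -k_B T \ln K_{eq} = 23.88$ kcal/mol.  The pKa
route $k_B T \ln(10)(15.7 + 1.7)$ agrees to within rounding.  Combining
$\Delta G_0$ with the measured barrier of the reverse (recombination)
reaction, 2.33 kcal/mol, places the controlling forward transition state at
**26.21 kcal/mol**.  `assemble_protolysis_profile(23.88, 2.33, 0.59)` builds
the five-point diagram: reactant dimer (0), first proton-transfer TS, the
contact-ion-pair intermediate, the structural (Grotthuss) proton-diffusion
TS, and the separated-ion plateau.

Two deliberate conventions:

* **Temperature is always an explicit argument.**  The familiar "1.38"
  prefactor is $k_B T\ln 10$ at about 301.6 K, and is inconsistent with
  penalties evaluated at 310.15 K; baking it in as a constant would make the
  package reproduce rounding errors rather than physics.  Defaults are
  298.15 K for the autoprotolysis equilibrium and 310.15 K for the kinetic
  and pH-penalty arithmetic, both overridable.
* **The 0.59 kcal/mol final-step barrier is stored as an annotation**, not
  recomputed from its simulated rate constant of $1.8\times10^{13}$ 1/s:
  that rate exceeds $k_B T/h$, so the Eyring inversion would return a
  negative barrier; the prefactor of the simulation it came from is unknown.

## The two-state EVB model

The reaction is represented by two diabatic states: a reactant force field
(two intact waters) and a product force field (hydronium + hydroxide), with
energies $\epsilon_1$ and $\epsilon_2$.  The coupled ground state is the
lowest eigenvalue of a 2x2 Hamiltonian with off-diagonal coupling $H_{ij}$,
and the product diabat carries a constant gas-phase shift $\alpha$.  The
reaction coordinate is the energy gap $\Delta\epsilon = \epsilon_1 -
(\epsilon_2+\alpha)$.

The force field (AKMA units: kcal/mol, Å, e) follows the parameter table of
the water-protolysis EVB setup:

* per-state atomic charges (water O/H: -0.80/+0.40; hydronium O/H:
  -0.08/+0.36; hydroxide O/H: -1.01/+0.01), see `evb_atom_types()`;
* Lennard-Jones parameters stored as square roots of A and B and combined
  geometrically (so the table's 762.89 for a water oxygen is
  $\sqrt{582000}$, the TIP3P value);
* Morse potentials on every O-H bond, with $E(r_0)=0$ (diabatic energies
  only matter up to the $\alpha$ shift);
* Buckingham repulsion $C e^{-\beta r}$ ($C_{ij}$ geometric, $\beta = 1.58$
  1/Å) replacing the LJ term on the two reactive pairs (transferring
  hydrogen against each oxygen), applied identically in both states;
* a flat-bottom restraint on the reactive O···O distance (2.5-3.5 Å,
  10 kcal/mol/Å², energy $k(d-b)^2$ outside the bounds);
* weak positional restraints (0.5 kcal/mol/Å²) on the two reactive oxygens
  and a half-harmonic spherical wall on all oxygens confining the droplet.

The bonded Morse/angle parameters are not part of the nonbonded parameter
table above; they are package choices documented
in `protolysis_topology()`: $D = 102.9$ kcal/mol and $\beta = 2.287$ 1/Å
(matching a typical O-H Morse curve and an SPC/Fw-like harmonic stiffness
at $r_0$), $r_0 = 0.9572$ Å for water/hydroxide and $0.982$ Å for
hydronium, and angle terms $E = k(\theta-\theta_0)^2$ with
$k = 37.95$ kcal/mol/rad², $\theta_0 = 104.52^\circ$ for water and
$k = 35$, $\theta_0 = 111.6^\circ$ for hydronium.

One numerical guard departs from the bare parameter table: a pure
$C e^{-\beta r}$ repulsion is always overwhelmed by the $-1/r$ Coulomb
attraction at sufficiently short range (the Buckingham catastrophe).  The
reactive pairs therefore keep a small $A/r^{12}$ core with
$A = 2$ kcal·Å¹² — under 0.25 kcal/mol at any physically visited distance
(> 1.2 Å) but an impenetrable wall below ~0.8 Å.

## Sampling: mapping potential and Langevin droplet

Sampling is driven by the linear mapping potential
$V(\lambda) = \lambda\,\epsilon_1 + (1-\lambda)\,\epsilon_2$, $\lambda = 1$
being the pure reactant potential; the schedule runs from 1 to 0.  Note
that $V$ uses the *raw* product diabat: adding $\alpha$ would shift each
window's potential by a constant, leaving all forces and trajectories
unchanged.  Both coupling parameters therefore enter only at analysis
time, which is what makes calibration cheap (see below).

`build_droplet(n_waters, radius, seed)` packs a droplet with the reactive
hydrogen-bonded dimer at its centre (O···O = 2.8 Å) and solvent waters at
random non-overlapping positions.  Dynamics is Langevin with the BAOAB
splitting (friction default 1/ps, time step 1 fs, 300 K) — chosen over
weak-coupling thermostats for its configurational-sampling accuracy at this
scale; with zero friction it reduces to velocity Verlet and conserves
energy, which the test suite checks.  All randomness flows through R's RNG
under an explicit seed: a (topology, frame, config, seed) tuple fully
determines every output bit.  All water molecules are flexible
(Morse + angle) for force-field uniformity, unlike rigid reference water
models — a documented deviation that the calibration step absorbs.

Default problem sizes are deliberately desk-scale: 20-60 waters in an
8-10 Å droplet, 51 windows of $\Delta\lambda = 0.02$ at 1-2 ps of
production each, started from a transition-state-equilibrated frame and run
bidirectionally outward (toward reactant and product) to minimize
hysteresis bias.  A full schedule takes on the order of a minute on one
CPU.

## Free-energy estimation

* `zwanzig_increment()` implements one-sided exponential averaging with
  log-sum-exp shifting everywhere an exponential average appears.
* `bar_estimate()` solves the self-consistent Bennett acceptance-ratio
  equation and reports the standard asymptotic variance; it flags (but does
  not refuse) non-overlapping work distributions.  For near-deterministic
  work distributions both estimators degrade gracefully to the mean work.
* `us_profile()` combines the staged $\lambda$ free energies (BAR between
  adjacent windows by default) with umbrella-sampling reweighting of each
  window onto the coupled ground state, binned on the gap coordinate
  (default 5 kcal/mol bins, at least 10 samples per contributing
  window-bin; both configurable).  Bins receiving contributions from
  several windows use a count-weighted average.  The profile is anchored
  with the reactant minimum at exactly zero.
* `locate_stationary_points()` identifies the reactant minimum, the
  transition state (highest interior maximum with at least 0.5 kcal/mol of
  prominence, to reject bin-level noise) and the product feature.  When an
  environment yields no distinct product minimum — only an ascending
  slope — the interior point of lowest positive slope (the shoulder) is
  identified as the transition state, mirroring how featureless enzymatic
  profiles are read.  A profile with no interior feature is reported as
  such, not as an error; for monotone profiles the free energy at the
  diabatic crossing, `profile_at_gap(p, 0)`, is the robust barrier proxy.

The whole stack is validated against a closed-form oracle: a two-parabola
(Marcus-type) diabatic model with equal curvatures, whose mapping-potential
ensembles are exact Gaussians (`sample_marcus_records()`) and whose coupled
surface can be solved by grid search (`marcus_reference()`).  Because the
gap is linear in the Marcus coordinate, the free-energy profile must equal
the adiabatic potential up to a constant — so barriers and reaction free
energies from `us_profile()` are checked against the grid truth to a few
tenths of a kcal/mol, including the $H = 0$ cusp cases with their textbook
$(\lambda_M + \Delta G_0)^2/4\lambda_M$ barrier.

## Calibration

`calibrate_evb()` adjusts $(H_{ij}, \alpha)$ until the measured profile
reproduces target energetics — for bulk water, the experimentally anchored
(26.21, 23.88) kcal/mol.  $\alpha$ chiefly moves the reaction free energy
and $H_{ij}$ chiefly the barrier.  Since the sampled trajectories do not
depend on either parameter, re-analysis of stored records under trial
parameters is *exact* reweighting, and the search is a damped Newton
iteration with a finite-difference Jacobian on a deterministic objective;
it typically converges in a handful of iterations on a single sampling
round.  A resample hook can re-check the converged parameters on fresh
windows (capped at 10 rounds).  Auto-initialization places the diabatic
crossing at the $\lambda = 0.5$ window's mean gap.

On the synthetic Marcus sampler with planted parameters the calibration
recovers both to within a few percent; on the droplet it converges to the
bulk-water targets to within the 0.1 kcal/mol tolerance.  The resulting
droplet parameters are a self-consistency surface for *this* toy water
model — they are not expected to equal coupling constants fitted in other
simulation programs with different solvent sizes and boundary models.

## Solvent response

The physical reason a nonpolar or conformationally restrained environment
raises the protolysis barrier is the loss of solvent reorganization that
stabilizes the emerging ion pair.  The package exercises this claim
qualitatively: freezing every atom outside the reactive dimer
(`sampler_config(frozen_solvent = TRUE)`) in a reactant-equilibrated
configuration removes the solvent response, and the resulting profile no
longer develops a product basin — it climbs monotonically, and its free
energy at the diabatic crossing lies well above that of the fully
responsive droplet in every replica.  The enzymatic barriers themselves
(tens of thousands of protein atoms, 100 ns of MD) are outside this
package's scope.

## Charged-solvation cycles

Charging a system in a finite or periodic simulation cell leaves
well-understood finite-size artifacts.  `born_correction()` implements the
spherical-boundary continuum term $-\frac{166}{R}\frac{\epsilon-1}{\epsilon}
(q_B^2-q_A^2)$ and `ewald_charge_correction()` the periodic tinfoil
self-energy term $\frac{k_e \xi}{2L\epsilon}(q_B^2-q_A^2)$ with
$\xi = -2.8374$.  For single-ion hydration free energies the package uses
the counterion-cycle construction: charging hydroxide with a sodium
counterion in the same and in the opposite direction makes the self-energies
cancel, and half-sum/half-difference isolate $\Delta G_{OH^-}$ and
$\Delta G_{Na^+}$ (`solve_ion_cycle()`).

The packaged table `hydration_cycles()` carries the reference hydration
legs for H2O and OH- in bulk water and at the MAO A reactive site —
regenerating it is a cluster-scale alchemical-MD campaign and is out of
scope here (the estimation machinery itself is validated on synthetic
records instead).  From that table `transfer_gap()` reproduces the ledger:
$\Delta G_{OH^-}(\text{water}) = -120.22$ kcal/mol; liquid-vacuum
interface-corrected single-ion values of -101.22 (OH-) and -104.68 (Na+)
kcal/mol, comparable with experiment; a water-molecule transfer term of
-2.9 kcal/mol; hydroxide transfer penalties of 7.7 (counterion-cycle
route) and 6.3 (direct-leg route) kcal/mol — the report labels these two
estimates by computation route, since the two numbers are easily swapped
in prose while their average is unambiguous — and a total
hydroxide transfer gap of 9.9 kcal/mol.  Adding the 23.88 kcal/mol cost of
forming the hydroxide in bulk water (`pathway_budget()`) shows the
formation-plus-transport pathway is a lower bound of ~33.8 kcal/mol, ruling
it out as a competitive channel.  Uncertainties propagate in independent
quadrature throughout.  The ~0.1 kcal/mol ion-ion interaction and 0.03
kcal/mol self-contribution noted for the finite box are below the table's
uncertainties and are ignored by default (an analytic Coulomb-at-distance
annotation can be added by hand if desired).

## What the synthetic generators do and do not emulate

The Marcus generator produces exact Boltzmann samples of an idealized
two-parabola solvent coordinate: it validates estimator correctness, not
force-field realism (no anharmonicity, no multi-dimensional solvent
response, no hysteresis between chained windows).  The droplet emulates the
essential physics — explicit solvent electrostatics, flexible bonds, a
confined droplet boundary — but not bulk dielectric screening, Grotthuss
chains of several reactive waters, or an enzyme matrix.  Tests passing on
these systems demonstrate that the machinery is correct and self-consistent
at desk scale; they do not demonstrate quantitative transferability to
condensed-phase or enzymatic free energies.

## Numerical choices, in one place

* Constants: $k_B = 0.0019872041$ kcal/mol/K, $k_B/h = 2.0837\times10^{10}$
  1/s/K, $k_e = 332.0636$ kcal·Å/mol/e²; the Born "166" is $k_e/2$ kept
  literal.
* Exponential averages: log-sum-exp shifted, always.
* Gap binning: uniform; stationary points are reported on bin centres;
  reactant anchoring is exact by construction.
* Ties and degeneracies: the highest of several interior maxima wins; a
  barrierless coupled Marcus surface returns a flagged result
  (`has_barrier = FALSE`), and monotone profiles return
  `has_feature = FALSE` rather than erroring.
* Divergence guard: |V| > 1e8 kcal/mol aborts a window naming the step.
* Replicas: profile uncertainties are best assessed as SEM over >= 5
  independent seeds (ten is typical in production EVB work); the test suite uses
  5 for the solvent-response sign test.

## Known limitations

* The droplet water model is flexible and unpolarizable, its surface is a
  simple half-harmonic wall, and there is no long-range electrostatics
  treatment — adequate for a 20-60 water droplet, by design not for bulk.
* The FEP/US combination follows standard EVB practice (count-weighted
  window contributions per bin); other stitching conventions would shift
  featureless regions slightly but agree on the oracle checks.
* `calibrate_evb()` assumes the targets are attainable on the sampled gap
  range; it reports an unconverged result with diagnostics otherwise.
* The shipped hydration table is an input dataset, not a recomputation.
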