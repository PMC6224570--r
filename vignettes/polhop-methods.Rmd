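---
title: "Methods: surface-hopping photochemistry in the strong light-molecule coupling regime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-hopping photochemistry in the strong light-molecule coupling regime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`polhop` simulates what happens to a photoswitch when the photon it absorbs
is not free but confined: a two-electronic-state molecule (S0, S1) strongly
coupled to one quantized cavity mode. The total Hamiltonian is

$$\hat H = \hat H_\mathrm{mol} + \omega_\mathrm{ph}\left(\hat b^\dagger \hat b + \tfrac12\right) + g\, \hat{\boldsymbol\mu}_{S_0S_1}(Q)\cdot\boldsymbol\lambda\,(\hat b^\dagger + \hat b),$$

truncated at photon occupation 1, giving the uncoupled product basis
$\{|S_0,0\rangle, |S_1,0\rangle, |S_0,1\rangle, |S_1,1\rangle\}$. The
dipolar interaction couples states differing by one photon through the
transition dipole projected on the field polarization,
$V(Q) = g\,\boldsymbol\mu(Q)\cdot\boldsymbol\lambda$: the rotating pair
$(|S_1,0\rangle, |S_0,1\rangle)$, whose mixing creates the lower and upper
polaritons $|-\rangle, |+\rangle$ with Rabi splitting $2|V|$ at resonance,
and the counter-rotating pair $(|S_0,0\rangle, |S_1,1\rangle)$, retained
beyond the Jaynes-Cummings approximation, which produces the Lamb shift of
the outer states. Under this truncation the two pairs are *exactly* block
separated; the package treats that as a structural property and the test
suite verifies the numeric 4x4 solution against the closed-form 2x2 blocks
to 1e-12 hartree. Dipole self-energy and permanent-dipole terms of the full
dipolar gauge are deliberately omitted (extended Jaynes-Cummings level).

Because $V(Q)$ depends on geometry through $\boldsymbol\mu(Q)$, the
polaritonic splitting is itself a function of the nuclear coordinates. Two
consequences drive everything else in the package:

* where the uncoupled surfaces cross ($E_1 - E_0 = \omega_\mathrm{ph}$) the
  polaritonic gap equals $2g|\boldsymbol\mu\cdot\boldsymbol\lambda|$;
* where additionally the projected dipole vanishes - for an out-of-plane
  polarization this happens at *planar* geometries - the gap closes exactly:
  a polaritonic conical intersection. `locate_pci()` finds it by root
  finding on the planar line; `scan_ppes()` maps the surfaces.

# The shipped molecular models

The electronic-structure contract (`evaluate()`) supplies adiabatic
energies, gradients, the transition-dipole vector and gradient, and the
diabatic-to-adiabatic mixing angle. Two analytic instances ship:

**`azo2d`**, a two-dimensional azobenzene-like surrogate in the
torsion/bend plane $(\theta, \alpha)$, built from a 2x2 diabatic matrix

$$H_{11} = A_0\sin^2\theta + \tfrac{c_{cis}}{2}(1+\cos\theta) + \tfrac{k_0}{2}(\alpha-\alpha_0)^2,\quad
H_{22} = E_v - A_1\sin^2\theta + \tfrac{k_1}{2}(\alpha-\alpha_1)^2,\quad
H_{12} = \gamma_{12}\cos\theta,$$

with $\boldsymbol\mu = (0, 0, \mu_0\sin\theta)$. Defaults
($A_0 = 1.6$, $c_{cis} = 0.6$, $E_v = 2.8$, $A_1 = 1.4$ eV,
$\alpha_0 = 115^\circ$, $\alpha_1 = 130^\circ$, $\gamma_{12} = 0.15$ eV,
$\mu_0 = 1$ au) give a trans/cis ground-state double well, an S1 surface
descending toward an electronic conical intersection on the twisted
($\theta = 90^\circ$) line at $\alpha \approx 110^\circ$, a bend that
modulates the gap, and an out-of-plane dipole that vanishes *exactly* at
planar geometries (the sine is snapped to zero at floating-point multiples
of $\pi$ so the dipole-forbidden point is exact, not 1e-16).

Parameters not fixed by those defaults were set once from timescale
targets and never revisited: the bend force constants
$k_0 = k_1 = 8.73$ eV/rad$^2$ with bend inertia $1.25\times10^4$ au give a
30 fs bending period ($k = I(2\pi/T)^2$), and the torsional inertia
$1.5\times10^5$ au makes the S1 torsional descent from the trans well to
$\theta = 90^\circ$ take roughly 100 fs (estimated from the inverted
curvature $2A_1$ at planarity). One consequence of the surrogate's exact
$\theta \to -\theta$ symmetry is worth flagging: trajectories leave the
trans well in both torsional directions, so the *ensemble-averaged*
torsion stays near $180^\circ$ and the oscillation coordinate shows its
periodicity mainly along the bend. Claims about "oscillation" in the tests
are therefore made on the bend component, the polariton populations, and
the per-trajectory hop statistics, not on the averaged torsion.

**`curve1d`**, a one-dimensional avoided crossing
($H_{11} = A\tanh Bx = -H_{22}$, $H_{12} = Ce^{-Dx^2}$, constant dipole),
used for Landau-Zener validation, fewest-switches internal-consistency
checks, and the exact-wavepacket comparison.

The surrogate reproduces the qualitative features a strong-coupling
photoisomerization mechanism needs; it makes *no* claim of quantitative
agreement with reparameterized semiempirical azobenzene surfaces, whose
reduced 2-D potentials (all other coordinates relaxed on S1) have no
closed form. Quantitative yields are correspondingly out of scope; the
acceptance contract tests properties and trends.

# Dynamics

Nuclei follow Newton's equations (velocity Verlet, default
$\Delta t = 0.1$ fs) on the active polaritonic surface; the force is the
Hellmann-Feynman gradient
$\nabla E_\Gamma = \sum_{ij} C_{i\Gamma}C_{j\Gamma}\nabla H_{ij}$,
combining electronic gradients on the diagonal with
$g\,\boldsymbol\lambda\cdot\nabla\boldsymbol\mu$ on the coupling entries -
the standard recipe for states mixed by a geometry-dependent off-diagonal
coupling (as in spin-orbit-coupled dynamics).

The electronic wavefunction is propagated in the adiabatic polaritonic
basis by local diabatization (LD): per step the polaritonic overlap matrix
$S_{\Gamma\Gamma'} = \sum_{ij} C_{i\Gamma}(t)\,C_{j\Gamma'}(t+\Delta t)\,
s^{el}_{ij}\,\delta_{n_i n_j}$ is Loewdin-orthogonalized to $T$, and the
amplitudes advance with the unitary
$U = T^\top \exp[-i\,\overline{Z}\,\Delta t]$,
$\overline{Z} = \tfrac12(E(t) + T\,E(t+\Delta t)\,T^\top)$. For the
shipped two-state models the electronic overlaps are exact rotations by
the mixing-angle difference. Hops follow Tully's fewest switches adapted
to LD: the probability of leaving the active state $k$ is
$\max[0, (|A_k|^2 - |A_k'|^2)/|A_k|^2]$, partitioned among targets by
their positive population gain over the step; accepted hops rescale the
momenta isotropically (LD computes no nonadiabatic-coupling vector, so
there is no direction to rescale along), and frustrated hops leave state
and momenta unchanged. Overcoherence across repeated crossings is damped
by the energy-based decoherence correction: non-active amplitudes decay
with $\tau_l = \frac{1}{|E_l - E_k|}\left(1 + \frac{\alpha}{E_{kin}}\right)$,
$\alpha = 0.1$ hartree by default, with the active amplitude renormalized;
the correction is switchable (`decoherence = FALSE`) and is off in the
internal-consistency tests, which probe the bare fewest-switches scheme.

Two implementation choices deserve explanation:

* **Trivial crossings.** When the coupling vanishes exactly ($g = 0$, or
  $\boldsymbol\mu\cdot\boldsymbol\lambda = 0$ at planar geometries),
  uncoupled surfaces cross without interacting and the energy-sorted state
  labels swap identity within one step. The engine re-identifies the active
  state through such crossings by its dominant overlap row
  ($|S_{a,j}|^2 > 1/2$, $j \ne a$), logged as a relabel (not a hop). This
  is the standard cure for the trivial-crossing problem and is what makes
  the $g = 0$ run *bitwise* identical to a photon-free two-state reference.
* **Hand-rolled small-matrix numerics.** All 4x4 algebra uses a cyclic
  Jacobi eigensolver that skips exactly-zero off-diagonal entries and a
  Newton-Schulz Loewdin orthogonalization. Exact zeros then never perturb
  partial sums, so at $g = 0$ the 4-state run performs, on its occupied
  2x2 block, literally the same floating-point operations as the 2-state
  reference run (which retains the constant $\omega/2$ zero-point so the
  energies are directly comparable; a constant shift has no dynamical
  effect). Jacobi at $n \le 4$ converges to machine precision, comfortably
  inside the 1e-12 eigen-oracle tolerance.

Randomness: one master seed; trajectory $k$ draws its hop stream from a
splitmix64-scrambled child seed (`child_seed(master, k, 0)`), the
thermostat uses stream 1, and photon-loss resampling uses separate R-side
seeds - so ensembles are order-independent and every draw is reproducible
cross-platform (no `std::` distributions). Exactly one uniform is consumed
per step whether or not a hop is attempted, which keeps paired runs
aligned. A conservation watchdog flags (not silently drops) any trajectory
whose total energy drifts beyond a tolerance (default 0.5 eV).

# Initial conditions

Ground-state phase points come from a single thermostatted trajectory at
300 K (10 ps, first 1 ps discarded, snapshots every 10 fs). The default
thermostat is per-degree-of-freedom Langevin (BAOA splitting) with a 5 fs
friction time. Two deliberate deviations from the obvious choices:

* *Why Langevin rather than global stochastic velocity rescaling:* the
  surrogate's torsion and bend are nearly separable, and a global
  kinetic-energy rescaling exchanges energy between modes only through the
  weak anharmonic coupling - measured 10 ps kinetic-energy averages then
  fluctuate with ~13% relative sd. Per-dof Langevin is ergodic for
  quasi-harmonic systems; it is also what the thermostat literature the
  field actually cites for this purpose describes. Stochastic velocity
  rescaling remains available (`thermostat = "svr"`).
* *Why a 5 fs friction time:* equilibrium snapshots are exact canonical
  draws at any friction; friction only sets sampling efficiency. 5 fs makes
  the kinetic energy decorrelate well within the 10 fs snapshot stride.
  Even so, a *single* 10 ps average of the kinetic energy of a 2-dof system
  carries ~2.5% statistical error (the instantaneous kinetic energy of two
  degrees of freedom fluctuates by 100% of its mean), which a user should
  keep in mind when judging equipartition from one short run.

Vertical excitation is Franck-Condon: coordinates and momenta unchanged,
active state set to the upper polariton (the higher-energy member of the
rotating pair, identified by block character with a $|S_1,0\rangle$
tie-break), amplitudes reset to a unit vector on it.

# Cavity losses

Photon escape (rate $\kappa = 1/\tau_c$) is applied *a posteriori* to the
stored lossless swarm, replicating each trajectory five times: at every
step the loss probability is
$p_\mathrm{cav} = \frac{\Delta t}{\tau_c}\,|C^{\Gamma}_{S_0,1}(t)|^2$ - the
photonic ground-electronic weight of the *active* state - and a sub-threshold
uniform draw collapses the replica onto $|S_0,0\rangle$ and stops it
(back-transfer after a loss is neglected). This reproduces the two
signature behaviours: exponential decay at rate $\approx\kappa$ while the
system is photon-like, and protection (an effective rate far below
$\kappa$) while the excitation hides in $|S_1,0\rangle$ - which is why the
polaritonic population oscillations survive lifetimes as short as tens of
fs. Whether the uncoupled-state population curves should average over all
replicas or only survivors is ambiguous in the source material; the output
table carries both accountings (`pop_*` and `pop_*_surv`).

# Observables

Polaritonic populations are active-state fractions; uncoupled-state
populations are ensemble means of the active state's composition
$|C_i^\Gamma|^2$ (the accounting consistent with the loss weights), with
the amplitude-based polaritonic variant (`amp_*`, mean $|A_\Gamma|^2$)
emitted alongside. The quantum yield counts trajectories that both reached
the lowest polaritonic state and ended in the cis region
($|\theta| < 90^\circ$; the $90^\circ$ boundary counts as trans);
still-excited trajectories are non-reactive and reported separately, since
the source protocol is silent about them. "Oscillating" trajectories are
those with at least two accepted $|-\rangle \leftrightarrow |+\rangle$
hops (configurable), and the oscillation coordinate is the per-time mean
of $(\theta, \alpha)$ over that subset.

# The exact oracle

A split-operator grid propagator validates the surface-hopping engine on
1-D models. It works in the *diabatic* electronic $\otimes$ photon basis -
the representation in which the kinetic operator is diagonal and all
couplings are potential-like; propagating in the adiabatic basis would
silently discard the derivative couplings. The diabatic 4x4 potential is
reconstructed exactly from the model contract
($H_\mathrm{dia} = U_2\,\mathrm{diag}(E_0, E_1)\,U_2^\top$ from the mixing
angle, dipole rotated likewise) and is unitary-equivalent to the engine's
Hamiltonian; its pointwise eigendecomposition uses base R `eigen`,
independent of the engine's Jacobi code. Validation: free-packet
dispersion to 1e-6, harmonic revival at the analytic period, Landau-Zener
transmission within 0.02 in the formula's validity regime (coupling
support inside the linear-diabat zone, velocity evaluated at the
crossing), and self-convergence under grid/timestep refinement to 1e-4.
The headline engine check places a Gaussian on the upper polariton of a
cavity-coupled 1-D model, with the FSSH ensemble sampling
$x \sim N(x_0, \sigma)$, $p \sim N(p_0, 1/2\sigma)$: final lower-polariton
populations agree within 0.10.

# Numerical choices and degeneracies

Energies are hartree and angles radians internally; interfaces use eV,
fs, degrees (g, dipoles in au everywhere). Eigenvalues sort ascending with
exact ties broken by dominant uncoupled character (photon number, then
electronic index). Eigenvector signs are fixed against the previous
solution along a trajectory (largest-magnitude overlap positive).
`polaritonic_gradient()` raises a classed error (`polhop_degeneracy`)
within 1e-10 hartree of a polaritonic degeneracy rather than returning an
arbitrary rotation of the degenerate pair; the engine itself never
evaluates there in practice because exact degeneracies occur only at
zero-coupling crossings handled diabatically. The Loewdin step refuses
overlap matrices farther than 0.5 from orthogonality (a symptom of an
overlong timestep). Hop-probability edge cases: active population below
1e-12 gives probability zero; an accepted hop needs the full energy gap
available in kinetic energy.

# What a green test does and does not establish

The synthetic surrogate reproduces mechanism-level features: polaritonic
avoided crossings whose position is set by the photon energy, a trap that
quenches torsional progress when the crossing lies far from the
Franck-Condon point (photon energy 1.3 eV), faster funneling when it lies
near it (2.2 eV), earlier ground-state recovery than the weak-coupling
reference, and loss-resistant population oscillations. Green trend tests
establish exactly these orderings on this surrogate with the shipped
parameters - not the published yields of real azobenzene, not
frequency-resolved yield curves, and not any collective (many-molecule)
effect. Known limitations: two electronic states only; two nuclear degrees
of freedom; one cavity mode; losses post-processed rather than integrated
into the dynamics; the overlap-based decoherence scheme of the LD
literature is represented by its energy-based stand-in.
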