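---
title: "The sarclat half-sarcomere model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sarclat half-sarcomere model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sarclat simulates one half-sarcomere of striated muscle as a spatially
explicit, stochastic spring lattice, to ask how the radial spacing of the
myofilament lattice — a quantity measurable *in vivo* by x-ray diffraction
as the d10 spacing — modulates the net mechanical work of cyclically
activated muscle. This vignette is the package's own account of the model,
its parameters, and the choices made where the design was genuinely open.

## The model

**Geometry.** The simulated unit is 4 myosin-containing thick filaments and
8 actin-containing thin filaments (the vertebrate-style 2:1 arrangement,
thin filaments at the trigonal interstices of the hexagonal thick-filament
lattice), with periodic boundary conditions in the lattice plane so that
each thick filament interacts with 6 thin filaments. Filaments are chains
of linear springs: thick segments of 14.3 nm rest length and 2020 pN/nm,
thin segments of 12.2 nm and 1760 pN/nm. Each thick node carries a crown of
three myosin heads 120° apart azimuthally, successive crowns rotated by the
60°/60°/0° pattern; 60 crowns per thick filament give 720 heads at the
defaults. Thick filaments are anchored at the M-line (x = 0), thin
filaments at the z-disk (x = half-sarcomere length); titin ties each thick
filament tip to the z-disk.

Each head is assigned one facing thin filament by azimuth (alternating
between the two flanking lattice directions by crown parity, which balances
the load exactly: every thin filament serves 90 heads). On its facing
filament, only every third thin node is an eligible binding site for heads
of a given thick filament — 3 × 12.2 ≈ 36.6 nm, the target-zone repeat,
out of register with the 14.3 nm crown repeat — with eligibility rotating
among the three thick filaments surrounding each thin filament.

**Crossbridges.** A head is a torsional spring (kθ = 4000 pN nm/rad²) at
its base in series with a linear spring (kr = 16 pN/nm) in the arm. The
states of the three-state cycle differ in rest geometry: weak
(rW = 19.93 nm, θW = 47.16°) and strong (rS = 16.4 nm, θS = 73.2°); the
power stroke is this change of rest angle and length, an ~8.8 nm axial
swing of the tip. The bound-head geometry is set by the axial offset dx
between anchor node and site and the face-to-face actin-myosin gap am:
r = √(dx² + am²), θ = atan2(am, dx). We take the site's radial coordinate
to be the face-to-face gap itself: the weak-state rest tip has a radial
reach rW·sin θW ≈ 14.6 nm, which is commensurate with the ~15 nm gap the
model centres on, so heads can actually reach sites. (Measuring the gap
centre-to-centre, 12.5 nm larger, would put every site ~13 nm beyond
thermal reach and silence the model entirely.)

**Kinetics.** Unbound heads are thermally forced every step: r and θ are
drawn from the Boltzmann distribution of the two independent quadratic
springs, r ~ N(rW, √(kT/kr)), θ ~ N(θW, √(kT/kθ)), kT = 4.11 pN nm.
Transition rates (1/ms), with U₁ = E_weak/kT − ΔG_weak and
U₂ = E_strong/kT − ΔG_strong:

* binding: r₁₂ = AP · (τ e^(−d²) + r₀), τ = 72, r₀ = 0.005, with d the
  **axial** separation between the thermally displaced tip and the nearest
  eligible unoccupied site;
* unbinding, by detailed balance: r₂₁ = (τ e^(−d²) + r₀) e^(U₁), with d
  now the axial separation between the site and the weak-rest tip. The
  baseline r₀ is what makes r₂₁ ≈ r₀ e^(distortion/kT) diverge at extreme
  strain — the "infinite well" that prevents unphysically strained heads
  from persisting;
* power stroke: r₂₃ = A (1 + tanh(C + D (U₁ − U₂))), A = 0.8, C = 6,
  D = 0.2, and its reverse r₃₂ = r₂₃ e^(U₂ − U₁);
* detachment (the irreversible, ATP-consuming step): r₃₁ = G·E_strong/kT +
  H with G = 0.6, H = 0.02, and r₁₃ = 0.

Per-step transition probabilities are 1 − e^(−r·dt), with competing exits
apportioned by rate. Site occupancy is strictly one-to-one.

Two readings of d were possible; we use the axial separation because (i)
the rate functions are defined and plotted as functions of axial
separation, and (ii) with a Euclidean distance the radial mismatch between
tip reach (14.6 nm) and gap suppresses binding as e^(−mismatch²), making
spacings of 12 or 17 nm essentially passive — which contradicts the
phenomenon the model exists to study (strong, spacing-dependent activity
across 12–17.5 nm). With the axial reading, the radial spacing acts through
the bound-state distortion energies, i.e. through unbinding, stroke
probability and force, which produces the expected spacing dependence.

AP (actin permissiveness, the lumped Ca²⁺/troponin/tropomyosin gate)
multiplies the whole binding rate, so AP = 0 is a fully passive lattice.
It does not multiply r₂₁: unbinding follows detailed balance of the
unblocked chain, otherwise bound heads could never release after the Ca²⁺
transient and a twitch would never relax.

r₃₁ is driven by the strong-state **distortion** energy (option
`r31_shifted` switches to the full, baseline-shifted free energy). With the
shifted form low-distortion strong heads persist for ~H⁻¹ = 50 ms,
accumulate by the hundreds and brace against lengthening, which inverts the
lattice-spacing dependence of net work; the distortion form preserves it
and is the default.

**Force balance.** After the transitions, every free node's axial position
is adjusted until the net axial force on it (adjacent segment tensions,
crossbridge loads, titin at the thick tips) is below 0.1 pN. The solver
sweeps filaments, solving each chain by a tridiagonal Newton step with
crossbridge and titin loads linearised; for the frozen-attachment problem
this decreases the elastic energy monotonically and reproduces a direct
linear solve to 10⁻⁶ nm (both are tested). Net force is read as the tension
in the M-line-proximal segment of each thick filament.

**Titin.** F = a e^(b ΔL), a = 220 pN, b = 0.0045 nm⁻¹, with ΔL the
end-to-end length change from the rest configuration (tip to z-disk,
including the radial offset). The exponential never vanishes, so the rest
lattice carries a titin preload of ~a per filament, equilibrated into the
chains; because titin is conservative this offset contributes no net work
over a closed cycle. (The alternative — a slack length chosen so the rest
force is zero — would contradict the printed law, which fixes F(ΔL=0) = a.)

**Lattice spacing is an input, not an output.** There is no radial force
balance: d10 is prescribed, either constant, slaved to axial strain through
a Poisson ratio ν (Δd = d(1 − (1 + ΔL/L)^(−ν)); ν = 0.5 is isovolumetric
and conserves d10²·L exactly), or interpolated from a user-supplied
periodic (cycle fraction, d10) table such as a digitised *in vivo* trace.
Conversions between d10 and the face-to-face gap subtract both filament
radii (8 + 4.5 nm) from the centre-to-centre distance: (2/3)·d10 for the
vertebrate lattice and d10/√3 for invertebrate flight muscle. The printed
"1/3·d10" for invertebrate muscle is inconsistent with its own worked
pairs (47.6 ↔ 15 nm, 45.9 ↔ 14 nm), which all satisfy d10/√3 − 12.5; we
use the hexagonal-geometry factor 1/√3.

## Activation and protocols

Activation is a Gaussian pulse AP(t) = APmax e^(−((t − tp)/w)²) with
APmax = 0.73, tp = 40 ms, w = 14 ms for the isolated twitch. (The pulse is
a Gaussian, i.e. the exponent is negative; the divergent positive-exponent
form that sometimes appears in print cannot be meant.) In work loops the
pulse repeats every strain cycle with onset at φ·T and peak 13 ms later,
wrapped to the nearest pulse image. A causal biexponential form
(1 − e^(−t/τr)) e^(−t/τd), emulating Ca²⁺ influx and re-uptake, is also
implemented; the Gaussian is the default because its parameters are the
printed ones. The two differ at the phase extremes: the Gaussian's
symmetric left tail puts activation into late lengthening when the onset
sits there (φ ≈ 0.8), which in our hands suppresses the positive-work peak
at that phase, while the biexponential recovers it but shifts the trough;
neither choice reproduces the full reference phase profile (see
Limitations).

Work loops are sinusoidal, L(t) = L0 (1 + (strain_pp/2) cos 2πft), 25 Hz
and 10% peak-to-peak about a 2.5 µm sarcomere by default, so t = 0 is
maximum length and the start of shortening (φ = 0). Each trial runs 20
cycles; net work is computed per cycle as W = −(1/ρ)∮σ dε (trapezoidal)
and averaged; the first cycle is kept. Stress uses the hexagonal unit-cell
area per thick filament, σ = F/(n_thick · (2/√3) d10²), with
ρ = 1060 kg/m³; the reference work values depend on an unpublished
normalisation, so absolute J/kg comparisons inherit this convention.

Sweep drivers cover activation phase (0–0.95), constant spacing
(12–18 nm), crossbridge stiffness (0.5×/1×/1.5× on either spring) and
titin exponential stiffness (b = 0.004–0.010 nm⁻¹), with per-point seeds
derived deterministically from a master seed.

## Calibration of the free-energy drops

ΔG_weak and ΔG_strong (the free-energy drops of the bound states, in kT)
are not printed anywhere and must be calibrated. The stated anchor is the
isometric tetanus: a mean steady-state crossbridge force of ~8–10 pN.
With the default stiffnesses this window turns out to be bracketed rather
than attainable: each strongly bound head carries ~80 pN (the springs are
deliberately stiffer than single-molecule estimates), while the mean over
all bound heads saturates near 7 pN however the drops are chosen — so the
anchor constrains but does not pin the values. We therefore fixed them
once, on the qualitative tetanus/twitch anchors: the strong state should
contribute a share of tetanic force comparable to the weak state (the
stiffened springs and faster stroke exist precisely to ensure this), the
twitch must relax completely after the pulse, and tetanic stress should be
of order 100 mN/mm². This gives ΔG_weak = 2 kT and ΔG_strong = 140 kT.
ΔG_strong of this size means the stroke gate (the tanh) is saturated for
every bound geometry; past ~140 kT its exact value no longer changes the
dynamics. The value is far above single-ATP thermodynamics: with
kθ = 4000 pN nm/rad² the strong-state distortion at binding-accessible
geometries is ~100 kT, so any functioning cycle needs effective drops of
that scale — these are effective model parameters, not hydrolysis
energies. Work-loop outcomes were never used in this calibration.

## Numerical choices

* **Timestep.** dt = 0.0125 ms by default (3200 steps per 40 ms cycle).
  The work integral converges roughly linearly in dt: at coarse steps a
  head that binds during sliding is dragged a full step's sliding distance
  (6 nm at dt = 1 ms) before it can detach, and this numerical drag
  dominates the loop area — at dt = 1 ms it is an order of magnitude
  larger than the converged work. The default is the smallest step for
  which the full acceptance recomputation stays a desk-scale job
  (~15 s per 20-cycle condition); halving it still moves net work near the
  sign-flip conditions by more than 5%, which the dt-halving check reports
  honestly. The convergence study is reproducible with:

```{r}
library(sarclat)
for (dt in c(0.1, 0.05, 0.025, 0.0125, 0.00625)) {
  w <- simulateWorkLoop(workLoopProtocol(n_cycles = 8, dt = dt),
                        runConfig(), seed = 21)
  cat(sprintf("dt = %.5f ms: %.3f J/kg\n", dt, w$work_mean))
}
```

* **Solver.** Residual tolerance 0.1 pN per node, at which work integrals
  are insensitive to the solver; the uniqueness and oracle tests run at
  10⁻⁷ pN. Newton diagonals are clamped to the stabilising sign so the
  passes cannot diverge on the (mildly non-convex) torsional terms.
* **Ties.** Nearest-site ties break toward the M-line; candidate sites are
  the axially nearest eligible node and its two neighbours one target-zone
  repeat away, skipping occupied nodes.
* **Determinism.** All randomness flows through R's RNG; a seed makes
  every trajectory bit-reproducible, and sweep points derive their seeds
  from the master seed.
* **Degenerate inputs.** Thermal draws with r ≤ 0 are redrawn; rates are
  capped so e^(U) overflow saturates the step probability at 1; strain
  ≤ −1 and infeasible d10 conversions are rejected.

## What the simulations do and do not emulate

The drivers generate the study conditions themselves (no external data):
isometric twitch and tetanus at rest length, and 25 Hz / 10% work loops
with phase, spacing, stiffness and titin sweeps. They emulate the
stochastic, spatially coupled crossbridge ensemble of an insect flight
muscle half-sarcomere with prescribed lattice kinematics. They do **not**
emulate: emergent radial force balance (spacing never responds to binding),
z-disk confinement or fluid forces, thin-filament cooperativity (AP is
uniform), Ca²⁺-dependent titin, sarcomere-to-sarcomere heterogeneity, or
the large passive stress of real muscle. Passing tests therefore show the
lattice-spacing mechanism inside this model family, not a quantitative
reconstruction of any particular muscle.

## Known limitations

* **Amplitude compression.** At the converged timestep the net-work
  landscape has the expected structure — a trough near φ = 0.5, most
  positive work near the ends of the phase range, monotonically increasing
  work over 12–16 nm with a sign change near 15–16 nm — but its amplitude
  is several-fold smaller than the reference values the model family
  reports (e.g. tenths of J/kg where J/kg are expected), and the sign
  change sits about 1 nm higher. The absolute scale is sensitive to the
  unpublished free-energy drops, the site-eligibility density, the
  activation form and the stress normalisation; with the printed constants
  fixed and the drops calibrated on tetanus only, this is the landscape
  the model produces, and we report it as such rather than re-tuning
  toward the target numbers.
* **Phase peak.** With the (default) symmetric Gaussian pulse the φ ≈ 0.8
  positive-work peak is attenuated; the causal biexponential recovers it
  at the cost of the trough position.
* Strong heads carry ~80 pN each — an order above single-molecule myosin —
  an inherited consequence of the stiffened two-spring head.
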