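# sarclat

Spatially explicit, stochastic simulation of a muscle half-sarcomere, built
to ask one question: **can nanometre-scale changes in the radial spacing of
the myofilament lattice change the net mechanical work of a cyclically
contracting muscle?**

In striated muscle, force is produced by myosin heads on the thick
filaments binding actin sites on the thin filaments across a radial gap
that x-ray diffraction measures as the d10 lattice spacing. That gap is not
constant *in vivo* — in many muscles it tracks sarcomere strain with an
effective Poisson ratio — and because binding, state transitions and force
all depend on the head's two-spring geometry, a ~1 nm offset in spacing can
in principle retune the whole ensemble. sarclat is for muscle biophysicists
who want to probe that mechanism under dynamic, locomotion-like conditions
(work loops at insect flight-muscle frequencies and strains), where it
cannot be isolated experimentally.

## The model

One half-sarcomere is a periodic hexagonal lattice of 4 thick and 8 thin
filaments, each a chain of linear springs (thick: 14.3 nm / 2020 pN nm⁻¹
segments; thin: 12.2 nm / 1760 pN nm⁻¹), clamped at the M-line and z-disk
respectively, with an exponential titin element F = a·e^(bΔL) from each
thick tip to the z-disk. 720 myosin heads (60 crowns × 3 per thick
filament, rotated 60°/60°/0°) are two-spring elements — torsional
kθ = 4000 pN nm rad⁻², linear kr = 16 pN nm⁻¹ — cycling through a
three-state scheme (unbound ⇌ weakly bound ⇌ strongly bound, the power
stroke being a change of rest geometry from rW = 19.93 nm, θW = 47.16° to
rS = 16.4 nm, θS = 73.2°). Rates:

    r12 = AP (τ e^(−d²) + 0.005)        τ = 72 ms⁻¹
    r21 = (τ e^(−d²) + 0.005) e^(U1)
    r23 = A (1 + tanh(C + D (U1 − U2))) A = 0.8, C = 6, D = 0.2
    r32 = r23 e^(U2 − U1)
    r31 = G E_strong/kT + H             G = 0.6, H = 0.02
    r13 = 0

with d the axial tip-to-site separation, Ui the strain-dependent state free
energies, and AP ∈ [0,1] an "actin permissiveness" lumping Ca²⁺/troponin/
tropomyosin gating. Each timestep applies thermal (Boltzmann) forcing of
unbound heads, stochastic transitions, the prescribed length and lattice
spacing update, and an axial force balance of every filament node. Lattice
spacing is an input: constant, slaved to strain via
Δd = d(1 − (1 + ΔL/L)^(−ν)), or a prescribed periodic d10 trajectory.
Net work per cycle is W = −(1/ρ)∮σ dε with σ the lattice force over the
hexagonal unit-cell area (2/√3)·d10² per thick filament.

See the methods vignette (`vignettes/half-sarcomere-model.Rmd`) for the
full account, including the calibration of the two unprinted free-energy
drops and the known limitations.

## A worked example

Simulate a work loop with activation at the start of lengthening
(phase 0.5) — the classic brake-like condition — and an isometric tetanus:

```r
library(sarclat)
cfg <- runConfig()
wl <- simulateWorkLoop(workLoopProtocol(phase = 0.5, n_cycles = 5, dt = 0.05),
                       cfg, seed = 1)
print(wl)
#> work loop: 25 Hz, 10% peak-to-peak strain, phase 0.50, 5 cycles
#>   lattice: constant, d10 47.63 nm (AM 15.00 nm)
#>   net work -2.087 +/- 0.105 J/kg (mean +/- s.d. over 5 cycles)

tet <- simulateTetanus(cfg, duration = 200, seed = 1)
print(tet)
#> sarclat tetanus trace: 16001 samples over 200 ms
#>   peak stress 201.49 mN/mm^2 at t = 147 ms
#>   plateau: 984.0 pN (93.90 mN/mm^2), 34.1 weak / 1.7 strong heads,
#>   3.70 pN per bound and 73.22 pN per strongly bound crossbridge
```

The work loop is net-negative (−2.1 J kg⁻¹): activating as the sarcomere
begins to lengthen makes the crossbridge ensemble resist stretch, i.e. the
muscle acts as a brake. The tetanus settles at ~94 mN mm⁻² with a few tens
of weakly bound heads and a steady trickle of strongly bound,
force-producing heads carrying ~73 pN each. `wl$series` holds the full
time series (length, strain, stress, activation, state counts);
`wl$work_per_cycle` the per-cycle work.

Sweeps, e.g. net work versus constant actin-myosin spacing:

```r
sweepNetWork("lattice", grid = 12:17, config = cfg,
             protocol = workLoopProtocol(n_cycles = 10), seed = 100)
```

A thin command-line driver with the same functionality is installed at
`inst/cli/sarclat` (subcommands `twitch`, `tetanus`, `workloop`,
`sweep {phase|lattice|stiffness|titin}`).

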