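---
title: "Deriving and validating Amber parameters for boronates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating Amber parameters for boronates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boronparam)
```

## The problem

General-purpose organic force fields carry no parameters for boron, so
molecular dynamics of boric acid esters and boronates requires deriving
the bonded terms from quantum-chemical reference data: harmonic bond and
angle constants from a Hessian, Fourier torsion terms from a
potential-energy-surface scan, plus atom-typing conventions (sp² boron
typed `B`, boron-bound oxygen typed `ob`) and Lennard-Jones parameters
adopted from earlier boron work (Rmin/2 = 1.98 Å, ε = 0.034 kcal/mol for
B; the GAFF oxygen values Rmin/2 = 1.6612 Å, ε = 0.2100 kcal/mol for
`ob`). `boronparam` implements that workflow end to end, together with the
validation metrics used to judge the result, and a synthetic-data layer so
every stage can be exercised and tested without external QM or
crystallographic inputs.

## The potential and its evaluation

The package evaluates the standard Amber functional form

$$E = \sum_{\mathrm{bonds}} K_r (r - r_{eq})^2
    + \sum_{\mathrm{angles}} K_\theta (\theta - \theta_{eq})^2
    + \sum_{\mathrm{dihedrals}} \frac{V_n}{2}\left[1 + \cos(n\Phi - \gamma)\right]
    + \sum_{i<j}\left[\frac{A_{ij}}{R_{ij}^{12}} - \frac{B_{ij}}{R_{ij}^{6}}
    + \frac{q_i q_j}{\epsilon R_{ij}}\right]$$

with $K_\theta$ in kcal·mol⁻¹·rad⁻² ($\theta_{eq}$ stored in degrees),
impropers using the same cosine form (n = 2, γ = 180° at the planar boron
center), and the frcmod conventions: the per-term barrier is the printed
$V_n$ with the ½ applied at evaluation, divided additionally by the IDIVF
divider; multi-term torsions are chained on disk by negative
periodicities. Nonbonded choices, all Amber defaults because the source
protocol is silent on them: Lorentz–Berthelot combination on Rmin/2,
geometric on ε; 1-2 and 1-3 pairs excluded, 1-4 pairs scaled by scnb = 2.0
(van der Waals) and scee = 1.2 (electrostatics); Coulomb constant
332.0522173 kcal·Å·mol⁻¹·e⁻²; dielectric ε = 1 (vacuum); cutoff 999 Å,
i.e. effectively none. When several torsion paths cross the same central
bond, each path receives the full matched term set divided by IDIVF.

Gradients are analytic for every term (the torsion gradient uses the
standard |b₂|-weighted normal-vector formulas), and the test suite holds
them to finite differences at 10⁻⁶ relative over random conformers. The
Hessian is central differences of that analytic gradient (step 10⁻⁴ Å,
symmetrized); the minimizer is L-BFGS-B restarted until the RMS Cartesian
gradient drops below `gtol` (default 10⁻⁴ kcal·mol⁻¹·Å⁻¹) — the contract
is the gradient norm, not the optimizer identity.

## Seminario extraction

For bond i–j, let $M = -\partial^2 E/\partial r_i \partial r_j$ (the 3×3
interatomic block, symmetrized) with eigenpairs $(\lambda_m, v_m)$. The
stretch stiffness is $k = \sum_m \lambda_m |\hat u_{ij}\cdot v_m|$ and the
Amber constant is $K_r = k/2$: the functional form $K_r(r-r_{eq})^2$ has
curvature $2K_r$, and this factor-of-two convention is what makes the
closed-loop recovery on an isolated harmonic bond exact — tools differ on
it, so it is worth stating prominently. $r_{eq}$ is the geometric
distance. For angle i–j–k the unit normal
$\hat u_N = \hat u_{ji}\times\hat u_{jk}/\lVert\cdot\rVert$ defines the
in-plane perpendiculars $\hat u_{PA} = \hat u_N\times\hat u_{ji}$ and
$\hat u_{PC} = \hat u_{jk}\times\hat u_N$, and the two arm stiffnesses
combine in series,

$$\frac{1}{k_\theta} = \frac{1}{R_{ji}^2\sum_m\lambda_m^{ij}|\hat u_{PA}\cdot v_m^{ij}|}
 + \frac{1}{R_{jk}^2\sum_m\lambda_m^{kj}|\hat u_{PC}\cdot v_m^{kj}|},\qquad
 K_\theta = k_\theta/2 .$$

Instances sharing a type tuple are averaged with an unweighted mean.
Hessians are accepted in hartree·bohr⁻² (converted with 627.509474
kcal·mol⁻¹ per hartree and 0.529177210903 Å per bohr, ≈ 2240.877) or
kcal·mol⁻¹·Å⁻², as a full 3N×3N whitespace matrix or a packed lower
triangle under a one-line header.

**Known limitation (by construction).** This is the plain Seminario
projection, deliberately without the "modified Seminario" cross-arm
correction. The interatomic block of a molecular Hessian contains
contributions from *every* term involving both atoms, so at a center
where several angles share an arm — the planar B(ob)₃ core is the worst
case, with all three angle gradients coplanar — the projected sums count
neighboring angles' stiffness and the recovered $K_\theta$ is biased
high, by tens of percent for the stiffest shared-arm angles of the
fixture (and the `ob–c3` bond picks up a smaller positive bias through
the angle terms at the ester carbon and oxygen). The package's tests
document this quantitatively: recovery is exact for an isolated bond,
within ~1% for an isolated angle with stiff arms, and systematically high
on the fully coupled fixture. Users comparing against tools implementing
the modified method should expect their angle constants to be smaller.

## Torsion fitting

The target is the pointwise difference between a QM scan and the MM
energy of the *same geometries* with the fitted dihedral's own terms
zeroed (`zero_dihedral()`); no re-minimization is done, matching a rigid
scan whose QM geometries are reused directly. The model is
$\sum_n (V_n/2)(1+\cos(n\Phi-\gamma_n))$ with one term per candidate
periodicity, $V_n \ge 0$, and phases restricted to {0°, 180°} (GAFF
practice; sign flips are expressed through the phase). The objective is

$$\sum_i\left(e^{QM}_i - e^{MM,0}_i - E_{model}(\phi_i) - K\right)^2$$

with K at its analytic optimum (the mean residual), so the fit depends
only on the profile shape and is exactly invariant to any constant added
to the QM energies — whether the original protocol normalized energies
beforehand or fit an offset is not stated, and the analytic-K choice is
this package's resolution of that open point.

The genetic stage encodes one barrier and one binary phase per candidate
periodicity; defaults (chosen once, as ordinary GA practice — the source
protocol names no hyperparameters): population 64, 300 generations, 10%
elitism, tournament selection, uniform crossover, Gaussian barrier
mutation with σ = 10% of the sampling scale (v_max = 6 kcal/mol), phase
flips at 5%, and a mandatory seed recorded in the result. The champion is
refined by Nelder–Mead simplex (Brent line search in one dimension) over
the barriers only, with negative barriers excluded by a quadratic
penalty; the refined objective never exceeds the start's. Finally terms
are pruned greedily: a term is dropped whenever removing it and
re-refining costs less than 0.05 kcal/mol RMSE (the parsimony threshold
per extra term; candidate periodicities default to {1, 2, 3}). Given
fixed phases the model is linear in the barriers, so the noiseless
closed loop is convex and the hybrid recovers generating coefficients to
≈10⁻¹¹ kcal/mol; with Gaussian noise the recovered barriers scatter at
the noise scale and the fitted curve stays within 3σ of the target.

## Validation metrics

`rmsd_ad` is the Kabsch-superposed RMSD (SVD with the determinant
correction; degenerate collinear sets are flagged) over a selection that
defaults to the boron core — the boron atom plus its three bonded
neighbors, this package's reading of "the first three atoms directly
adjacent to the boron"; a full-molecule selection is available.
`rmsd_l` and `rmsd_a` are superposition-free RMSDs over bond lengths and
bond angles; angles centered on a trivalent boron span its improper plane
and are classified out-of-plane — excluded from the main RMSD-A value and
reported separately (the parenthesized column of the report), since the
exact out-of-plane definition behind published tables is not given and
this center-based rule is the simplest one consistent with them. Atom
correspondence is by input order; no graph matching. `make_report`
appends an Average row of unweighted arithmetic means; it accepts either
structure pairs or precomputed per-structure rows, so published
per-molecule values can be fed straight through the same reporting path.

## Dynamics

Leapfrog integration (dt default 0.002 ps) with Berendsen velocity
scaling $\lambda = \sqrt{1 + (dt/\tau)(T_0/T - 1)}$, τ = 0.5 ps, and
SHAKE on bonds to hydrogen: those bonds are constrained *and their energy
terms removed from the potential* (the Amber `ntc = 2` semantics), with
degrees of freedom 3N − 3 − N_constraints after center-of-mass removal.
Velocities initialize from Maxwell–Boltzmann with the center-of-mass
momentum projected out. Heating is a staged ramp, by default 100 K
increments ending at 325 K with configurable stage durations (the source
protocol states the increments but not the durations). Frames carry an
on-step energy estimate (potential at the pre-step positions, kinetic
energy from the mean of adjacent half-step velocities) so NVE
conservation can be measured honestly; the suite bounds the drift of the
harmonic diatomic at dt = 10⁻⁴ ps over 10⁴ steps below 10⁻⁴ kcal/mol.
Production-scale simulation is out of scope: runs here are picoseconds on
one CPU (the acceptance run uses a 3 ps ramp plus 52 ps at 325 K, sizes
chosen to make the thermostat statistics meaningful at desk scale), not
the hundreds of nanoseconds of a real study.

## The synthetic generator — what it does and does not emulate

`build_fixture("diethoxyborinic_acid")` constructs HO–B(OC₂H₅)₂ (19
atoms, 18 bonds) from ideal internal coordinates (the published
equilibrium lengths and angles, ±90° ethoxy-arm torsions to keep the arms
apart), typed by the boron conventions and wired with exactly the
published boron parameters: the three bond and five angle terms, both
fitted two-term torsions, the improper (40.5, 180°, 2), and the B/ob
Lennard-Jones values. Terms the source leaves to GAFF (c3–c3, c3–h1
bonds, the plain organic angles and torsions) are GAFF-typical filler
values flagged as synthetic provenance, as are the partial charges — a
placeholder set summing to zero, since the reference ESP charges exist
only graphically. Masses default to standard atomic weights (B = 10.81).

From the fixture the generator derives the three closed loops the tests
run: (A) minimize the bonds+angles surface and take its numerical Hessian
— the harmonic ground truth for Seminario recovery (this choice isolates
the harmonic terms; adding torsion and nonbonded terms would only add
further cross-contamination to an already-biased projection); (B)
rigid-rotation torsion scans on the −180°…180° 5° grid (73 points) with
pseudo-QM energies built as zeroed-MM baseline + known Fourier truth +
arbitrary offset + optional Gaussian noise; (C) Gaussian-perturbed copies
of the minimized structure standing in for experimental references. All
three are seeded and deterministic.

What passing these loops shows: the extraction, fitting, energy,
superposition and reporting machinery are mutually consistent and match
independent oracles. What they do not show: anything about real QM
Hessians (anharmonicity, coupling patterns beyond a harmonic force
field), real ESP charge sets, relaxed-scan effects, or crystal-packing
distortions in experimental references — the pseudo-experimental
perturbation is isotropic white noise, which real thermal/packing error
is not.

## Numerical choices and degenerate inputs

Angle gradients clamp sin θ at 10⁻¹⁰; near-linear angles are the user's
responsibility (none occur in the fixtures). Torsions with collinear
inner triples have undefined sign and are not protected beyond the
resulting large gradients; the Seminario angle routine rejects collinear
arms outright (|sin θ| < 10⁻⁶), and bonds shorter than 10⁻⁶ Å or
nonbonded pairs closer than 10⁻⁶ Å are errors. frcmod round-trips are
exact to the printed precision (10⁻³ tolerance in tests); mol2
round-trips hold coordinates to 10⁻⁴ Å and charges to 10⁻⁶. Improper
quadruples are stored center-third with peripherals sorted by type label
then index (a deterministic Amber-style ordering); duplicate term
insertion replaces the existing term with a warning. Atom indices are
1-based throughout, matching both R convention and the mol2 on-disk
numbering. All tests and the acceptance script run on fixed seeds; the
GA, the velocity draws and every perturbation are reproducible from a
single integer.

## Command line

The installed `exec/boronparam` script exposes the pipeline as
subcommands (`typing`, `seminario`, `fit-dihedral`, `frcmod`, `minimize`,
`validate`, `md`, `fixtures`); each stochastic output records its seed in
a provenance header. The R functions documented above are the primary
interface; the script is a thin veneer over them.
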