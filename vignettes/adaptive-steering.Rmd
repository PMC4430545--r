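---
title: "Adaptive steered pulling: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive steered pulling: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivepull)
```

## The problem

Stretching a folded peptide between two extensions and asking "what is the
free-energy cost?" is a classic steered molecular dynamics (SMD) problem.
A harmonic guide $k(\xi(x) - \lambda(t))^2/2$ drags the reaction coordinate
$\xi$ (here, an end-to-end distance) as $\lambda(t)$ moves at constant
velocity, and the external work

$$ W = \int k\,(\lambda(t) - \xi)\, v \, \mathrm{d}t $$

is accumulated along each nonequilibrium trajectory.  The Jarzynski
equality converts an ensemble of such works into the equilibrium potential
of mean force (PMF):

$$ F(\lambda) = -k_B T \,\ln\Big\langle e^{-W(\lambda)/k_B T}\Big\rangle. $$

Because the exponential average is dominated by rare low-work
trajectories, the estimator converges slowly when the work spread grows —
which it inevitably does over a long pull.  Staged, adaptive variants
attack exactly this: break the path into segments, estimate the PMF per
stage while the work spread is still small, and *contract* the ensemble
between stages.  This package implements the two canonical contractions:

* **Naive adaptive steering** (`run_naive_asmd`): after each stage, keep
  the single trajectory whose final work is closest to the stage's
  Jarzynski free energy (the *JE criterion*), and restart all trajectories
  of the next stage from its coordinates *and velocities* with fresh noise
  streams.
* **Full-relaxation adaptive steering** (`run_fr_asmd`): between stages,
  relax every trajectory at fixed extension.  The guide never moves during
  relaxation, so the external work is *exactly* zero and the Jarzynski
  average is untouched; no trajectory is discarded.

Rather than an all-atom force field, the package evaluates everything on
analytic toy systems with exact oracles (`reference_pmf`), so that every
claim the estimators make can be checked against quadrature or closed
forms.  All-atom engines can be attached in principle through the same
segment interfaces, but nothing in the tested core depends on one.

## Units and parameters

Units are fixed package-wide: Angstrom, kcal/mol, picosecond, Kelvin, amu,
with $k_B = 0.0019872041$ kcal/(mol K) and the conversion
1 kcal/mol = 418.4 amu A$^2$/ps$^2$.  Defaults mirror the conventional
helical-peptide stretching protocol:

| parameter | default | meaning |
|---|---|---|
| guide spring $k$ | 7.2 kcal/(mol A$^2$) | stiff-spring pulling constant |
| friction $\gamma$ | 5 ps$^{-1}$ | Langevin damping |
| timestep | 0.002 ps (2 fs) | BAOAB step |
| stages | ten 2 A segments, 13 to 33 A | stage plan |
| $t_\mathrm{relax}$ | 100 ps | constrained relaxation per stage |
| velocity | given in A/ns | converted to A/ps internally |

The literature quotes the pulling constant as "7.2 kcal/mol" without
length units; we interpret it as kcal/(mol A$^2$), the standard stiff-spring
convention, and leave it configurable.  The relaxation time default is
deliberately *not* convergence-checked — it reproduces the conventional
choice, and the caller can raise it.

## Integrator and work accounting

`steered_segment` integrates BAOAB-splitting Langevin dynamics.  BAOAB was
chosen (over e.g. the NAMD-style BBK thermostat, whose details are not
fully specified in the SMD literature) for its superior configurational
accuracy at large timesteps; at $\gamma = 0, T = 0$ it reduces to velocity
Verlet, which the tests exploit as a symplectic-limit energy-conservation
oracle.  Work is accumulated in the thermodynamic-integration form
$\mathrm{d}W = k(\lambda - \xi)\,v\,\mathrm{d}t$ with trapezoidal
quadrature — exact for integrands linear in $t$, and $O(\mathrm{d}t^2)$
otherwise (verified by a step-halving test).  Work and $\xi$ are reported
on a $\lambda$ grid (default spacing 0.1 A) by linear interpolation
between steps; the endpoints are recorded exactly, and the work at the
first grid point is exactly zero.

Constrained relaxation is realized two ways, both doing literally zero
work (`relax_segment`): `"freeze"` (default) pins the pulled coordinate's
atoms and removes the guide, matching the description of fixing the chain
endpoints; `"hold"` keeps the guide spring active at fixed $\lambda$.
Which one is "right" is unspecified in the source protocol (the fate of
the spring during relaxation is not stated); we default to the freeze
because it is the literal reading, and expose the alternative.

## Randomness and reproducibility

A master seed is mapped to per-(stage, trajectory, phase) streams by
iterated Lehmer mixing (`stream_seed`), with phases for equilibration,
pulling, relaxation and optional velocity resampling.  Every stochastic
call is preceded by seeding from this map, so full runs reproduce
bit-identically, while every trajectory still sees an independent noise
sequence.  One consequence: a staged run with $t_\mathrm{relax} = 0$ is
*statistically* equivalent to an unstaged pull but not bit-identical to
it, because streams restart at stage boundaries.  The algebraic content —
carried-ensemble assembly equals one-shot Jarzynski estimation on the
summed works — is asserted exactly in the tests instead.

At the naive contraction the selected trajectory's velocities are cloned,
not resampled (the literal protocol); `resample_velocities = TRUE`
switches to a Maxwell-Boltzmann redraw.

## Assembling the global PMF

For contracted (naive) runs each stage PMF starts at zero and the global
curve chains them with cumulative offsets — continuous at boundaries by
construction.  For carried (full-relaxation) runs this would be *wrong*:
$-\ln\langle e^{-(a_i+b_i)}\rangle \ne -\ln\langle e^{-a_i}\rangle -
\ln\langle e^{-b_i}\rangle$ when stage works are correlated across stages
through the surviving trajectories.  `assemble_pmf` therefore rebuilds the
per-trajectory cumulative works and applies the Jarzynski average
globally, which reduces exactly to single-stage estimation on the
concatenated path.  Stage PMFs are evaluated on the shared $\lambda$ grid
(stiff-spring identification of the guide position with the reaction
coordinate), not on a time grid.

## The quadrature oracle

`reference_pmf` computes
$F(\lambda) = -k_BT \ln \int e^{-[U(x) + k(x-\lambda)^2/2]/k_BT} dx$ by
composite trapezoidal quadrature for one-dimensional potentials, over
$[x_\mathrm{lo} - 10\sigma,\ x_\mathrm{hi} + 10\sigma]$ where the bounds
cover the guide positions and potential minima and $\sigma$ is the thermal
width of the stiffest quadratic term.  Convergence is verified internally
by grid refinement (failure raises a numerical error with diagnostics,
tolerance $10^{-6}$ kcal/mol).  The restriction to 1D is deliberate: the
oracle must stay simple enough to trust.  The 3D bead-spring chain is
instead validated against closed forms (its harmonic limits) and the
estimator properties.  For harmonic $U = a x^2/2$ the oracle reproduces
the Gaussian closed form $\Delta F(0 \to L) = a k L^2 / (2(a+k))$ to
$10^{-6}$, which in turn anchors the end-to-end acceptance tests.

## The synthetic structure world

`generate_helix_fixture` builds an N, H, C$\alpha$, C, O backbone (five
atoms per residue — no side chains, no end caps) from ideal internal
coordinates by NeRF chain extension.  With textbook helical dihedrals
($\varphi = -57^\circ, \psi = -47^\circ$) a 10-residue chain shows exactly
the canonical six i$\to$i+4 hydrogen bonds under the 4 A / 140$^\circ$
geometric criterion; the fully extended chain shows none.  Because the
caps are omitted, the fixture's atom count (5 per residue) intentionally
does not match a capped decapeptide's 104 atoms.  Both conventional
end-to-end tag pairs are exposed — terminal backbone nitrogens and
first/last C$\alpha$ — since both definitions are in circulation; neither
is privileged.

`generate_solvated_fixture` appends three-site pseudo-waters: a requested
number at ideal hydrogen-bond geometry to distinct peptide sites
(construction-verified so that each adds exactly one peptide-solvent
bond), the rest far from the peptide.  This emulates *counting* around an
equilibrated solvation shell, not water physics: no water-water
interactions, no density, no dynamics.  A green test on these fixtures
establishes that the detection, classification, weighting and histogram
logic is correct — it says nothing about real solvation structure.

## Hydrogen-bond analysis choices

* The detection criterion is donor-acceptor heavy-atom distance $\le$ 4 A
  and D-H$\cdots$A angle $\ge 140^\circ$ with the vertex at the hydrogen.
  The angle phrasing in the literature ("between the hydrogen, donor, and
  acceptor") is ambiguous; the standard D-H$\cdots$A convention is used,
  and a non-default vertex choice is messaged at runtime.  Whether the
  4 A cutoff applies to the donor-acceptor or hydrogen-acceptor distance
  also varies between tools; we use donor-acceptor, configurable.
* Contact classes use the *unsigned* residue offset $|j - i| \in
  \{3, 4, 5\}$, robust to labelling direction.
* "Weighted according to the work averages" is interpreted as normalized
  Jarzynski weights $w_i \propto e^{-W_i/k_BT}$, evaluated per extension
  point with each trajectory's accumulated work at that extension and
  computed in log space so that works far beyond $k_BT$ never underflow
  to 0/0; `weighting = "plain"` gives the unweighted mean for comparison.

## Numerical corner cases

* Jarzynski averaging always goes through log-sum-exp; the naive
  exponential mean is only used in tests, where both must agree to
  $10^{-10}$ whenever the naive form is representable.
* `je_select` ties break to the lowest trajectory index.
* Degenerate requests fail loudly: empty ensembles, non-finite works,
  hydrogens without a linked donor, coincident tagged atoms (undefined
  reaction coordinate), diverged integration (non-finite coordinates are
  reported with time of failure).
* Hold-mode and relaxation segments return work as the literal constant
  `0`, not an accumulated near-zero.

## What the toy acceptance runs fix, and why

These are the package's "stated world" — chosen once, before the tests
were frozen:

* Closed-form recovery: harmonic $a = k = 1$, pull 0 to 2 A at 20 A/ns
  (pull time 100 ps $\gg 1/\gamma$ = 0.2 ps), 100 trajectories, 10 ps
  equilibration: slow enough that the dissipation is a small fraction of
  $k_BT$ and the three estimators must all land within three jackknife
  standard errors of 1 kcal/mol.
* Quadrature agreement: tilted double well $h = 2$, $w = 1$,
  $c = 0.4$ kcal/mol with guide $k = 10$ and mass 10 amu — parameters for
  which the total potential stays single-welled as the guide crosses the
  barrier, so a 10-stage, 100-tps run at 50 A/ns can track the oracle
  within 0.5 $k_BT$ everywhere.
* Convergence phenomenology: symmetric double well pulled fast
  (2000 A/ns) versus slow (200 A/ns) at 100 versus 800 trajectories per
  stage over 20 replicate master seeds.  Fast pulling dissipates a few
  $k_BT$, which makes the finite-sample Jarzynski bias visible at 100 tps
  and measurably smaller at 800 tps and at the slower velocity — the
  qualitative convergence pattern expected of staged pulling estimators.

## Known limitations

* No all-atom force fields, electrostatics, implicit-solvent models or
  water dynamics; quantitative peptide PMFs are out of scope by design.
* The quadrature oracle is 1D.
* The bead-spring chain is a caricature: harmonic bonds plus i$\to$i+4
  Gaussian contact wells, no excluded volume, no angles.
* Jackknife standard errors are a convenience utility, not an error model.
* The solvated fixtures test counting logic, not solvation physics.
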