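# adaptivepull

Staged nonequilibrium pulling in R: steered Langevin dynamics with
Jarzynski free-energy estimation, the two canonical adaptive staging
schemes — **naive adaptive steering** (stage-wise ensemble contraction by
the Jarzynski-equality criterion) and **full-relaxation adaptive steering**
(zero-work constrained relaxation between stages, no contraction) — plus
geometric hydrogen-bond pathway analysis with work-weighted averaging.

## Who this is for

Anyone studying free-energy profiles along a pulled coordinate (peptide
unfolding being the motivating case) who wants the *estimators* — not an
all-atom engine — as verifiable, reusable components.  The package runs
entirely on built-in analytic toy systems (harmonic, double-well,
tilted double-well, a 3D bead-spring chain) whose constrained free energy
is known exactly by quadrature, so that every property of SMD, staged
pulling, and the Jarzynski average can be tested against an independent
oracle on one CPU.

## The core quantities

A harmonic guide `k (xi(x) - lambda(t))^2 / 2` pulls the reaction
coordinate `xi` while `lambda` moves at velocity `v`; each trajectory
accumulates external work `dW = k (lambda - xi) v dt`.  The potential of
mean force follows from the Jarzynski equality,

    F(lambda) = -kB T ln < exp(-W(lambda) / kB T) >,

evaluated by log-sum-exp over the work ensemble.  In naive adaptive
steering, the trajectory whose stage-end work is closest to the stage's
`F_end` seeds the next stage; in full-relaxation mode all trajectories
relax at fixed extension (exactly zero work) and continue.  Hydrogen bonds
are detected geometrically (donor-acceptor distance <= 4 A, D-H...A angle
>= 140 degrees), classified as i->i+3 / i->i+4 / i->i+5 helical contacts
or peptide-solvent, and averaged with Jarzynski weights
`w_i ~ exp(-W_i / kB T)`.

Units package-wide: Angstrom, kcal/mol, ps, K, amu; velocities in A/ns.

## Worked example

Pull a tilted double well (barrier 2 kcal/mol, tilt 0.4 kcal/mol/A)
from -2 to 2 A in ten stages of 100 trajectories, then compare with the
exact quadrature oracle:

```r
library(adaptivepull)

pot   <- make_potential(potential_spec("tilted_double_well", h = 2, w = 1, c = 0.4))
sys   <- list(potential = pot, state = system_state(-2))
steer <- steering_protocol(k = 10, lambda_start = -2, lambda_end = 2, velocity = 50)
plan  <- stage_plan(lambda_start = -2, lambda_end = 2, n_stages = 10,
                    tps = 100, master_seed = 7, t_equil = 20)

res <- run_naive_asmd(sys, steer, plan, langevin_params(masses = 10), verbose = TRUE)
#> stage 1: N=100 <W>=-2.2225 F_end=-2.2228 selected=26
#> stage 2: N=100 <W>=-1.0776 F_end=-1.0780 selected=29
#> ...
#> stage 10: N=100 <W>=2.3034 F_end=2.3031 selected=99

res$pmf
#> <pmf_curve> 41 points, lambda [-2, 2] A, dF = 1.0316 kcal/mol

oracle <- reference_pmf(pot, k = 10, res$pmf$lambda, temperature = 300)
max(abs(res$pmf$F - oracle$F))
#> [1] 0.01470917   # 0.025 kBT across the full profile
```

Each log line reports the stage's trajectory count, mean end work, the
stage Jarzynski free energy, and which trajectory the JE criterion
selected to seed the next stage.  The assembled 41-point profile ends at
+1.03 kcal/mol (wells at -1 and +1 A differ by roughly the tilt times the
well separation) and tracks the exact constrained free energy to within
0.015 kcal/mol everywhere — far inside the 0.5 kBT acceptance band.

Hydrogen-bond analysis runs on synthetic fixtures:

```r
fr <- generate_helix_fixture(10)            # ideal alpha-helix backbone
classify_contacts(detect_hbonds(fr), fr)
#>  i3  i4  i5  other_intrapeptide  peptide_solvent
#>   0   6   0                   0                0
sv <- generate_solvated_fixture(fr, n_waters = 50, hb_placed = 3, seed = 42)
classify_contacts(detect_hbonds(sv), sv)[["peptide_solvent"]]
#> [1] 3
```

## Command line

```sh
BIN=$(Rscript -e 'cat(system.file("exec/adaptivepull", package = "adaptivepull"))')
Rscript $BIN run --config run.yaml --mode asmd --tps 100 --seed 1 --out run/
Rscript $BIN pmf --in run/ --out pmf.tsv
Rscript $BIN oracle --config run.yaml --out oracle.tsv
Rscript $BIN fixtures --nres 10 --waters 50 --hb 3 --seed 1 --out helix
Rscript $BIN hbonds --pdb helix.pdb --out counts.tsv
```

Configs are YAML (or JSON) with blocks `system`, `steering`, `langevin`,
`plan`, `mode`, `seed`, `out_dir`; omitted settings fall back to the
standard protocol defaults (ten 2 A stages spanning 13-33 A, k = 7.2,
gamma = 5/ps, dt = 2 fs, t_relax = 100 ps).  Every run writes TSV outputs
plus a `manifest.json` with file checksums, config hash and seed; reruns
are byte-identical.  Exit codes: 0 success, 2 config error, 3 numerical
failure.

## Package layout

- `R/potentials.R`, `R/reference-pmf.R` — toy systems and the quadrature oracle
- `src/dynamics.cpp` — BAOAB integrator with work accounting (Rcpp)
- `R/jarzynski.R` — work ensembles, log-sum-exp JE estimator, JE-criterion selection
- `R/asmd.R` — stage plans, SMD / naive / full-relaxation drivers, PMF assembly
- `R/fixtures.R`, `R/hbond.R` — backbone/solvation fixtures, H-bond detection and profiles
- `R/io.R`, `R/cli.R`, `inst/exec/adaptivepull` — config, TSV round-trips, provenance, CLI
- `vignettes/adaptive-steering.Rmd` — models, assumptions, and design choices
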