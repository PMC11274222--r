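# radkin — kinetic analysis of radical-scavenging absorbance decay

Antioxidant capacity assays monitor the quenching of a stable, strongly
coloured free radical — DPPH (2,2-diphenyl-1-picrylhydrazyl, 517 nm) or
galvinoxyl (Glv, 428 nm) — by UV-Vis absorbance over time: as antioxidants
in a plant infusion donate hydrogen atoms, the radical's absorbance decays.
`radkin` is for analysts who want more than a single endpoint percentage
from such traces: it fits competing kinetic laws to the full decay curve,
selects the best-supported model, and extracts rate constants and a latent
initial antioxidant level.

## Models

Each absorbance–time trace is fitted with four candidate laws by bounded
nonlinear least squares (Levenberg–Marquardt):

**Parallel first-order, 1–3 channels (FO1/FO2/FO3)**

    y(t) = y0 + Σᵢ Ar(i) · exp(−t / tᵢ),   i = 1..m,  m ∈ {1, 2, 3}

with amplitudes `Ar(i)` (AU), time constants `tᵢ` (s, rate constants
`1/tᵢ`), and offset `y0`; components are reported fastest-first.

**Integrated second-order with unequal initial levels (SO)** — the
bimolecular step `AH + r· → P` with `dAr/dt = −k·Ar·AAH` integrates to

    Ar(t) = Ar(0) · (AAH(0) − Ar(0)) · E / (AAH(0) − Ar(0) · E),
    E     = exp(−k·t·(AAH(0) − Ar(0)))

where `k` (1/(AU·s)) is the rate constant, `Ar(0)` the initial radical
absorbance and `AAH(0)` the initial antioxidant level in
absorbance-equivalent units — the quantity of interest for estimating how
much antioxidant a sample contained. Model comparison is by R², with a
parsimony guard on the nested exponential ladder (a higher-order FO model
must improve R² by more than 0.001).

A synthetic-data module simulates single traces and the full
2 sources × 4 dilutions × 2 radicals assay layout with known ground truth,
so the whole pipeline is benchmarked by parameter recovery. The
closed-form SO law is verified against independent adaptive ODE
integration (`deSolve`).

## Worked example

Simulate one noisy trace under second-order truth (k = 0.01, Ar(0) =
1.1219, AAH(0) = 1.7, σ = 0.005 AU), fit all candidate models, and estimate
the antioxidant level:

```r
library(radkin)

cfg <- simulation_config("SO", so_params(k = 0.01, ar0 = 1.1219, aah0 = 1.7),
                         noise_sigma = 0.005, seed = 42, radical = "DPPH",
                         sample_id = "KDPPH2.5")
tr  <- simulate_trace(cfg)
cmp <- fit_all(tr)
cmp
#> <kinetic_model_comparison> KDPPH2.5
#>   FO1  R^2 = 0.992218  RSS = 0.3021   converged = TRUE
#>   FO2  R^2 = 0.999305  RSS = 0.02699  converged = TRUE
#>   FO3  R^2 = 0.999329  RSS = 0.02605  converged = TRUE
#>   SO   R^2 = 0.999351  RSS = 0.0252   converged = TRUE   <- selected
#>   selected SO (R^2 = 0.999351) among converged {FO1, FO2, FO3, SO};
#>   nested FO ladder kept FO2 at delta_R^2 = 0.001

summary(cmp$fits[["SO"]])
#> Kinetic fit: SO model, sample KDPPH2.5
#>       Estimate Std. Error
#> k    0.0100416    0.00007
#> ar0  1.1235862    0.00160
#> aah0 1.6993930    0.00621
#>
#> n = 1001 points, residual sigma = 0.005025 AU
#> R^2 = 0.999351, Pr(R^2 = 0) = 0, converged: TRUE

estimate_antioxidant_level(cmp$fits[["SO"]])$aah0
#> [1] 1.699393
```

The second-order model wins (it generated the data); the rate constant is
recovered to 0.4 %, and the latent antioxidant level `AAH(0)` to 0.04 % of
the truth. The reported `Pr(R^2 = 0)` is the overall-regression F-test
p-value — zero to many decimal places for any decent fit on 1001 points.

A full 16-cell study runs through the pipeline in one call:

```r
report <- run_pipeline(list(design = study_design()), seed = 1)
report$summary            # one row per trace: model, k, ar0, aah0, R², p
write_report(report, "out/")
```

A thin command-line wrapper (`inst/cli/radkin.R`) exposes `simulate`,
`fit`, `recover` and `report` subcommands over the same functions.

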