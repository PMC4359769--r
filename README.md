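# stemkinetics

Compartmental kinetic analysis of radiotracer transport in plant stems from
dynamic PET time-activity curves.

When a bolus of a positron-emitting tracer such as [¹⁸F]fluoride is fed into
a cut petiole, it is carried up the stem by xylem bulk flow while a small
fraction is irreversibly bound along the way (likely in the apoplast). A
dynamic PET scan of the plant yields, for each stem region of interest
(ROI), a time-activity curve (TAC) — activity per vertical millimetre of
stem, normalized by the administered activity, over a schedule of 20 × 1 min
and 8 × 5 min frames. This package turns those TACs into physiological
transport parameters. It is aimed at plant-imaging groups running dynamic
PET (or PETIS-style) tracer studies.

## Model

The observed concentration at a stem position is split into a free and an
irreversibly trapped compartment,

    M(t) = G(t) + B(t),        dB/dt = sv · G(t) = sv · (M(t) − B(t)),

with B(0) = 0 and a single rate constant **sv**, the trapping probability
per unit time (1/s). sv is solved from the late-time final condition
B(t_f) = M(t_f) (all free tracer has cleared the ROI by t_f = 55 min),
integrating the rate equation over the frame mid-times with an implicit
trapezoidal march and bisecting on sv.

The free curve G = M − B is then reduced to a **mean arrival time** per ROI,

    T = ∫₀^UB t G(t) dt / ∫₀^UB G(t) dt,

truncated at UB, the falling half-height of G (limiting the moment to the
first ~50–70 % of the free tracer suppresses late-time model error). An
ordinary least-squares fit of ROI position on arrival time gives the
transport velocity **V** (mm/s), and **s = sv / V** (1/mm) is the trapping
probability per unit stem length. A leading-edge half-height arrival
estimator is available as a cross-check, and an 80 %-trapped-fraction
refit (`target_fraction = 0.8`) probes sensitivity to the final condition.

A forward simulator (`sim_truth()`, `observe_plant()`, `simulate_cohort()`)
generates synthetic plants — a smoothed rectangular bolus advected at
constant velocity with exponential per-length trapping, observed through
the PET frame schedule with multiplicative counting noise — and is used
throughout the tests for parameter recovery.

## Worked example

Simulate a plant with known transport parameters (v = 0.368 mm/s,
s = 0.00084 1/mm, so sv = s·v ≈ 0.00031 1/s) at 5 % frame noise, and fit
it:

```r
library(stemkinetics)

sim <- observe_plant(sim_truth(v = 0.368, s = 0.00084,
                               noise_cv = 0.05, rng_seed = 7))
fit <- fit_transport(sim$curves, sim$manifest)
fit
#> Stem transport fit for plant 'synthetic' (6 ROIs, mean_arrival)
#>   trapping rate  sv = 0.000318 +/- 1.3e-05 1/s
#>   velocity        V = 0.374 mm/s (2.25 cm/min), R^2 = 0.998
#>   trapping/length s = 0.000849 1/mm
```

The fitted trapping rate (0.000318 1/s vs the true 0.000309), velocity
(0.374 vs 0.368 mm/s) and trapping per length (0.000849 vs 0.00084 1/mm)
recover the simulated truth to a few percent despite the noise. `summary()`
lists the per-ROI fits, `plot()` shows the fitted free/trapped curves and
the time-position regression, and `simulate()` round-trips a fitted plant
back through the generator.

Per-plant results aggregate across a cohort in the conventional table
layout (here for the bundled published estimates from a three-plant
*Brassica oleracea* [¹⁸F]fluoride study):

```r
cat(render_results_table(reference_plants()), sep = "\n")
#> Plant               Age (days)  Activity (MBq)  Admin. duration (s)  ROIs  sv (1/s)       V (mm/s)    s = sv/V (1/mm)
#> ------------------  ----------  --------------  -------------------  ----  -------------  ----------  ---------------
#> RBo019              20          3.18            240                  6     0.000287(220)  0.326       0.00088
#> RBo021              20          8.53            300                  8     0.000191(58)   0.566       0.00034
#> RBo026              26          9.96            180                  5     0.000280(29)   0.214       0.00131
#> Mean (s.d., n = 3)  22.0(35)    7.2(36)         240(60)                    0.000253(54)   0.369(180)  0.00084(49)
```

i.e. a cohort trapping rate of 0.000253 ± 0.000053 1/s (1.5 %/min), a
velocity of 0.37 ± 0.18 mm/s (2.21 cm/min) and a trapping fraction of
0.00084 ± 0.00049 1/mm (0.84 %/cm).

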