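# efsgait

Temporal gait parameters from electrostatic field sensing (EFS) signals.

A walking body carries a quasi-static charge, and every step perturbs the
electric field around it. A passive electrode placed a few metres away picks
up the resulting displacement current — no sensors on the body, no cameras,
no pressure mat. `efsgait` is a simulation and analysis toolkit for this
measurement principle, aimed at researchers in low-cost gait analysis who
want to study the method's timing accuracy against a conventional
force-sensitive-resistor (FSR) insole reference:

- a physics-based forward model of the induced-current signal and of the
  FSR insole voltage, driven by a common ground-truth gait schedule;
- the two foot-event detectors — a three-step threshold/derivative/offset
  segmentation of the pressure signal, and peak/trough extraction on the
  electrostatic signal;
- per-cycle temporal gait parameters and agreement statistics
  (event-timing errors, gait-cycle accuracy, Pearson correlation with
  qualitative grading, ICC(2,1) test–retest reliability).

## The model

The body (charge `Q_B`) forms a capacitance to ground through the shoe
soles, `C_f = 2 ε_s S_s / d_e`, in parallel with residual capacitances to
the surroundings. With the foot at height `h(t)` above ground and an
equivalent sole–ground plate area `S_s(t)`, the body potential is

    U_B(t) = Q_B · (ε_a S_s + h(t) C_f) / (C_f ε_a S_s)
           = Q_B · ( 1/C_f + h(t) / (ε_a S_s(t)) )

and the current through an electrode coupled to the body by capacitance `C`
is the displacement current

    I(t) = C · dU_B/dt  ∝  (1/S_s) dh/dt − (h/S_s²) dS_s/dt .

`I(t)` peaks when the foot-lift velocity is maximal (foot-off, the
*separate event*, SE) and dips most sharply when the landing foot's growing
contact area collapses the potential (heel strike, *initial contact*, IC).
The acquisition chain converts `I` to volts across a 10 GΩ sampling
resistor (10 mV/pA), low-pass filters at 20 Hz (zero phase in the
simulator, so event timing is never shifted) and samples at 1 kHz.

From detected events, each gait cycle yields

    Tg = IC(m+1) − IC(m),   Ts = SE(n) − IC(m),   Tw = Tg − Ts,
    C  = 2 · 60 / Tg  (steps/min),   RS = Ts/Tg,   RW = Tw/Tg .

## Worked example

```r
library(efsgait)

cfg <- pipeline_config(pace = "normal", n_cycles = 50, seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)
print(res)
#> <pipeline_result> normal pace, 50 cycles (seed 42)
#>  EFS IC errors:  <event_error_stats> n = 47 matched (0 unmatched), -25.00 +/- 0.28 ms, range [-25.5, -24.6] ms
#>  EFS SE errors:  <event_error_stats> n = 46 matched (2 unmatched), 24.99 +/- 0.31 ms, range [24.5, 25.6] ms
#>  Cycle accuracy: <cycle_accuracy> n = 46 cycles, error 0.00 +/- 0.79 ms, accuracy 99.96%
#>  Concurrent validity: <gait_pearson> r = 0.9999 (p = 2.89e-88, n = 46): excellent
```

The pipeline simulated both channels from one hidden gait schedule, trimmed
2 s from each end of the recording, ran both detectors and compared them.
The EFS events carry a small systematic offset against ground truth (the
current extremum sits where the foot's vertical velocity peaks, ~25 ms into
the fast lift/landing), but the offset is common to every cycle, so
cycle durations cancel it: the per-cycle `Tg` error against the pressure
pipeline is 0 ± 0.8 ms, an accuracy of 99.96%, with an excellent Pearson
grade.

```r
summarize_params(res$efs_params)
#> # A tibble: 6 × 6
#>   parameter     mean      sd      min      max     n
#>   <chr>        <dbl>   <dbl>    <dbl>    <dbl> <int>
#> 1 tg_ms     1221.    73.1    1104.    1371        46
#> 2 ts_ms      786.    52.2     691.     900        46
#> 3 tw_ms      435.    38.5     360.     517.       46
#> 4 cadence     98.6    5.83     87.5    109.       46
#> 5 rs           0.644  0.0216    0.605    0.689    46
#> 6 rw           0.356  0.0216    0.311    0.395    46
```

Mean `Tg` ≈ 1.2 s and cadence ≈ 99 steps/min are the normal-pace regime;
`rs` is biased high by the same ±25 ms event offsets (stance appears
~50 ms longer on the EFS channel), which is why cycle-level quantities,
not phase durations, are the method's headline output.

`autoplot(res$efs_trace, events = res$efs_events)`,
`autoplot(res$ic_errors)` and `plot_agreement(res$paired)` draw the trace
with event markers, the error histogram, and the paired-cycle scatter;
`tidy()`/`glance()` return the statistics as tibbles. A thin CLI wrapping
the same functions is installed as `exec/efsgait`
(`efsgait pipeline --pace normal --n-cycles 100 --seed 42 --out-dir out/`).

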