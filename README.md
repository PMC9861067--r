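# ssavmd

Non-contact extraction of respiration and heart rate from ultra-wideband
(UWB) impulse-radar echoes, for anyone building or evaluating radar
vital-sign monitors without continuous access to hardware: the package
pairs the full processing chain with a physics-based echo simulator so
every stage can be exercised against known ground truth.

## The method

Chest motion $d(t) = d_0 + A_r \sin(2\pi f_r t) + A_h \sin(2\pi f_h t)$
phase-modulates the radar return, so the slow-time signal at the chest's
range gate carries spectral lines at the breathing rate $f_r$, the heart
rate $f_h$, their harmonics $k f_r$, $l f_h$, and intermodulations. The
cardiac displacement $A_h$ is an order of magnitude weaker than breathing,
and the 3rd/4th respiratory harmonics fall inside the heartbeat band, so a
naive spectral read-out fails. The chain implemented here:

1. **SVD clutter suppression** — decompose the fast-time x slow-time echo
   matrix $R = U \Lambda V^{\mathsf T}$ and rebuild it from the second
   singular component: $\Lambda_{11}$ captures static clutter + DC, the
   trailing components capture noise.
2. **Maximum distance gate** — pick the row maximising
   $E_m = \sum_i R[m,i]^2$; its slow-time slice is the vital-sign signal.
3. **SSA denoising** — Hankel-embed with window $L$ (400 for a 50 s,
   20 Hz record), SVD, keep the leading $r = \mathrm{round}(0.1\,L)$
   components, reconstruct by anti-diagonal averaging.
4. **VMD** — split the signal into $k = 5$ narrowband modes by ADMM with
   Wiener-filter mode updates
   $\hat u_k = (\hat f - \sum_{i \ne k}\hat u_i + \hat\lambda/2) /
   (1 + 2\alpha(\omega-\omega_k)^2)$ and power-centroid frequency updates,
   the first mode pinned at DC.
5. **Rate estimation** — classify modes into respiration and heartbeat
   (rejecting respiratory harmonics within ±0.08 Hz of $2$–$4 f_r$), read
   each rate as a zero-padded, quadratically interpolated spectral peak.

See `vignettes/ssa-vmd-vital-signs.Rmd` for the model, parameter
rationale, and numerical choices.

## Worked example

Simulate a subject at 0.6 m breathing at 0.267 Hz with a 1.5 Hz heartbeat
under 0 dB chest-return SNR, then run the full SSA-VMD chain:

```r
library(ssavmd)
record <- run_pipeline(default_pipeline_config(seed = 1))
record
#> <run_record> method ssa-vmd, seed 1
#>   gate 103 (0.655 m); SSA L=400 r=40; VMD centres (Hz): 0.000, 0.262, 0.289, 0.811, 1.563
#>   respiration 0.265 Hz (truth 0.267), heartbeat 1.498 Hz (truth 1.500)
```

The record shows the chain's decisions: the selected range gate lands on
the chest (0.655 m vs the true 0.6 m, within the pulse width), SSA used
its L = 400 / r = 40 defaults, VMD placed modes at DC, the respiration
line (two fragments at 0.26/0.29 Hz), the 3rd respiratory harmonic
(0.81 Hz, rejected by the classifier) and the heartbeat; both rates come
back within 0.002 Hz of truth.

Published per-subject comparison tables (five subjects at 0.6 m, contact
finger-clip reference) ship as fixtures:

```r
compare_methods(heart_rate_table("0.6m"))
#>  subject seed standard_fh_hz vmd_hz ssa_vmd_hz vmd_error_hz ssa_vmd_error_hz
#>        A   NA          1.400  1.357      1.357       -0.043           -0.043
#>        B   NA          1.250  1.513      1.217        0.263           -0.033
#>        ...
#> mean absolute error: VMD 0.115 Hz, SSA-VMD 0.045 Hz
```

The same function runs live paired comparisons on simulated cohorts:
`compare_methods(simulate_subjects(5, seed = 1), seeds = 1:3)`.

A thin CLI over these functions lives at `inst/cli/ssavmd.R`
(`simulate`, `run`, `compare` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the SSA grouping
count at window length 400, and the mean absolute heartbeat-frequency
error (Hz) of the full SSA-VMD pipeline over five simulated 50 s subjects
at 0.6 m whose ground-truth heart rates are the published 0.6 m standard
values (0 dB chest-return SNR, five noise seeds per subject). Results are
written as JSON to `--out`.
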