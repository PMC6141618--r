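# fidustab

Low-light fiducial tracking and active sample stabilization for
single-molecule fluorescence microscopy, implemented end to end against a
simulated instrument.

Sub-nanometer single-molecule measurements are ruined by slow mechanical
drift of the sample relative to the optics. One remedy reflects a weak laser
off a fixed fiducial (an AFM tip apex), reads the back-scattered spot on a
quadrant avalanche photodiode, and commands a piezo stage to cancel the
measured motion in real time. The distinguishing idea is the **discrete
contour-intersection lookup map**: instead of fitting the detector response
with polynomials, a small scan region is divided into evenly spaced
iso-signal contours of the two normalized difference channels,

  h = (left − right) / total,   v = (bottom − top) / total,

and the intersections of the contour grids tie each (h, v) pair to a known
sample position. The intersection coordinates are packed into 32-bit words
(16-bit X | 16-bit Y) and stored as an ordered 40,000-entry array (200
contours per channel over 100 nm × 100 nm, ~0.5 nm between intersections),
so converting a live detector sample to a position is a rounding operation
and one memory access. Samples arrive at 1 MHz; non-overlapping 100-point
averaging yields kHz-scale tracking, and an integral feedback loop

  command ← command − gain × (tracked − setpoint)

drives a resonance-limited piezo stage (340 Hz, 20 kHz servo) to hold a
user-chosen setpoint. The package simulates the whole instrument — detector
response fields, band-limited drift, stage dynamics, confocal imaging of
fluorescent emitters — so the method, not the hardware, is what gets tested.

## What's in the package

| Area | Entry points |
|---|---|
| Instrument simulator | `qapd_response_model()`, `scan_image_pair()`, `sample_stream()`, `drift_model()` / `make_drift()`, `stage_state()` / `step_stage()`, `render_raster()` |
| Map builder | `compute_levels()`, `extract_contour()`, `find_intersections()`, `pack_entry()` / `unpack_entry()`, `build_map()` |
| Tracker | `signal_to_index()`, `lookup_position()`, `track_stream()` |
| Feedback | `feedback_config()`, `correction()`, `run_closed_loop()`, `run_step_test()` |
| Fluorescence | `fit_gaussian_2d()`, `detect_spots()`, `localize_apex()`, `measure_drift()` |
| Analysis | `rms_about()`, `amplitude_spectrum()`, `extract_steps()`, `effective_lowpass()`, `fit_step_histogram()` |
| Drivers / I/O | `experiment_config()`, `run_experiment()`, `read_map()` / `write_map()`, `read_trace()` / `write_trace()`, `read_image()` / `write_image()`, plus a thin CLI at `inst/cli/fidustab` |

## Worked example

Build the default map, hold the setpoint for 10 seconds against the default
drift, and benchmark a ±4 nm setpoint step test:

```r
library(fidustab)

model <- qapd_response_model()
map <- build_map(scan_image_pair(model), n_levels = 200)
map
#> Contour-intersection map: 200 x 200 levels, 40000 entries
#>   region: [-50, 50] x [-50, 50] nm
#>   placeholders: 5972 (14.93%), mean NN spacing: 0.523 nm

rec <- run_closed_loop(model, map, feedback_config(), duration = 10, seed = 42)
rec
#> Closed-loop record: 10 s at 5900 Hz (59000 ticks)
#>   feedback on 100% of ticks; 0 placeholder lookups; 0 clamped ticks
#>   RMS about setpoint while on: 0.133 nm (X), 0.123 nm (Y)

run_step_test(model, map, axis = "x", step_nm = 4, n_positions = 250,
              samples_per_position = 200, feedback_on = TRUE, seed = 42)
#> Step test: X axis, 4 nm commanded, 250 positions x 200 samples, feedback on
#>   measured step: 4.0045 +/- 0.0771 nm (mean +/- sd of 249 steps)
#>   accuracy: 4.5 pm, precision: 77.1 pm
#>   note: dwell 0.017 s is shorter than the stage settling time 0.0294 s
```

Reading the numbers: without feedback this drift model wanders tens of
nanometers in 10 s; with the loop closed the tracked position stays within
~0.13 nm RMS of the setpoint — the residual is dominated by the ~0.5 nm
grid quantization of the map and the detector noise surviving 100-point
averaging, not by drift. In the step test the mean measured step differs
from the commanded 4 nm by 4.5 pm (accuracy) and the spread of the 249
measured steps is 77 pm (precision). The dwell note is expected: the
benchmark protocol's 17 ms wait is shorter than the stage's 29 ms settling
time, so it is recorded with the result.

The methods vignette (`vignettes/methods.Rmd`) documents the response
model, the drift and stage calibrations, the stability analysis behind the
default feedback gain, and the numerical choices (level nudging, packing,
weighted Gaussian fitting).

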