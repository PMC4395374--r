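# cardioswi

Susceptibility-weighted imaging (SWI) reconstruction and analysis for
detecting **intramyocardial hemorrhage (IMH)** in multi-echo gradient-echo
cardiac MR.

After reperfused myocardial infarction, hemorrhagic blood products shorten
the effective transverse relaxation time T2\* and shift the local resonance,
leaving a focal *negative* phase signature. `cardioswi` implements the
reconstruction chain that exploits this:

1. **Magnitude + high-pass filtered phase** — per-echo, per-coil inverse 2-D
   FFT; sum-of-squares coil combination for magnitude; homodyne phase
   filtering (divide the full-resolution complex image by its low-pass
   filtered version, using an N = 64 point radial squared-Hanning k-space
   window) so smooth background phase cancels while focal lesion phase
   survives.
2. **SWI** — the negative-phase mask

   ```
   mask(x,y) = (pi + phi(x,y)) / pi    for -pi < phi < 0
             = 1                       otherwise
   ```

   raised to N multiplications (N = 3 or 6) and applied pixelwise:
   `SWI = |I| * mask^N`, darkening hemorrhage beyond its magnitude contrast.
3. **TE-averaging** — arithmetic mean of the nTE longest-echo images
   (nTE = 1 is the longest echo alone; a 12-echo series yields 11 multi-echo
   averages), trading susceptibility contrast against noise; an inverted
   grayscale display makes the lesion hyperintense, LGE-like.
4. **T2\* mapping** — ROI decay curves fitted with the offset exponential
   `S(TE) = So exp(-TE/T2*) + C` by bounded multi-start Levenberg–Marquardt
   least squares, over AHA-style 6/6/4 short-axis sectors.
5. **Metrics** — `Contrast = (S1 - S2)/S1` and `SDNR = (S1 - S2)/STD`
   between adjacent myocardium (S1) and lesion (S2), with STD from a
   signal-free noise ROI; 50%-of-maximum threshold volumetry with enclosed
   hypointense-core inclusion, reported as % of LV myocardium.

Because no patient raw data ship with the package, a **synthetic multi-coil
multi-echo k-space phantom** (annular myocardium T2\* 34.1 ms, blood pool,
focal lesion T2\* 16.2 ms with negative focal phase, 12 echoes 2.3–15.5 ms,
complex Gaussian noise) provides exact ground truth for every stage.

Intended users: MR physicists and image-analysis researchers prototyping
susceptibility-based cardiac reconstruction, and anyone needing a fully
controlled testbed for homodyne-filtered phase pipelines.

## Worked example

```r
library(cardioswi)

spec <- phantom_spec()            # paper-style LV phantom, SNR ~30, seed 1
k    <- simulate_kspace(spec)     # 12 echoes x 4 coils of complex k-space
es   <- reconstruct(k)
mag  <- sos_magnitude(es)         # combined magnitude per echo
ph   <- hpf_phase(es)             # homodyne high-pass filtered phase
rois <- phantom_rois(spec)

report <- sweep_report(mag, ph, rois)
subset(as.data.frame(report), n_te %in% c(1, 9),
       select = c(source, n_te, contrast, sdnr))
#>       source n_te  contrast     sdnr
#> 1  magnitude    1 0.3803285 11.58415
#> 9  magnitude    9 0.2796533 29.49464
#> 13      swi3    1 0.7220139 12.39839
#> 21      swi3    9 0.6711939 39.52559
#> 25      swi6    1 0.8739737 13.61201
#> 33      swi6    9 0.8484153 45.38017
```

Reading the table: at the longest echo alone (`n_te = 1`) the lesion already
shows 38% magnitude contrast; six phase-mask multiplications raise it to
87%. Averaging the nine longest echoes costs a little contrast but nearly
triples SDNR for every source, and SWI keeps its contrast advantage
throughout — the behavior the method is built around. `plot_sweep(report)`
draws the full sweep.

ROI T2\* fits on the same magnitude images separate the tissues:

```r
roi_curve <- function(roi) decay_curve(mag$echo_times,
  sapply(seq_along(mag$echo_times),
         function(e) mean(mag$data[, , e][rois[[roi]]])), roi)
fit_t2star(roi_curve("lesion"))
#> <t2star_fit:lesion> T2* = 13.75 ms, So = 0.9137, C = 0.1014 (rms 0.00382)
fit_t2star(roi_curve("remote"))
#> <t2star_fit:remote> T2* = 33.53 ms, So = 0.9836, C = 0.0199 (rms 0.000758)
```

The lesion (ground truth 16.2 ms) fits short, the remote wall (34.1 ms)
long; the small lesion ROI and the magnitude noise floor account for the
residual bias, which vanishes as noise goes to zero (see the tests).

The full chain — simulate, reconstruct, SWI, TE-average, metrics, sector
T2\* — also runs as one call writing NIfTI/CSV/JSON outputs:

```r
run_pipeline(list(n_te = 9), "out/")
```

or from a shell via the thin CLI `inst/cli/cardioswi.R`
(`simulate | reconstruct | swi | combine | t2star | metrics | run`).

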