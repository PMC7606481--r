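# angioperf

Perfusion angiography for the interventional suite: deconvolution-free,
per-pixel bolus tracking on 2-D digital subtraction angiography (DSA) cine
runs, built to quantify whether an intra-arterial intervention (e.g.
verapamil infusion for cerebral vasospasm) actually improved brain
perfusion — rather than judging success from vessel caliber alone.

Every pixel of a DSA run carries a contrast time-intensity curve
C<sub>x,y</sub>(t). After baseline subtraction, `angioperf` derives six
parametric maps per study:

| metric | definition |
|---|---|
| AT  | arrival time: upward crossing of 5% of peak leading to the maximum |
| TTP | time of the (earliest) curve maximum |
| TTD | last downward crossing of 5% of peak after the maximum |
| MTT | full width at half maximum of the curve |
| CBV | ∫C<sub>x,y</sub> dt / ∫C<sub>AIF</sub> dt (relative blood volume) |
| CBF | CBV / MTT (central volume principle, relative flow) |

with the arterial input function C<sub>AIF</sub>(t) sampled along a
manually placed line spanning the injected vessel. Study pairs are screened
by automated QC (same view, same geometry, rigid-motion score from phase
correlation on baseline frames, full bolus transit captured), vascular
territories (MCA/ACA/PCA/vertebrobasilar) are summarized as pixel
distributions and compared pre vs post with Welch tests, and jointly
normalized red–yellow–blue–black maps are rendered for side-by-side review
(red = better perfusion, by convention). A gamma-variate digital flow
phantom with dense-grid ground truth makes the whole pipeline testable
without any patient data.

Formats: DICOM (uncompressed little-endian, multi-frame or single-frame
series, including FrameTimeVector timing and MONOCHROME1 inversion),
TIFF/PNG frame directories, PNG/JSON ROI masks, CSV/JSON tables.

## Worked example

Generate the default synthetic pre/post pair (128×128, 40 frames at
0.25 s; post kinetics shifted by vasodilation-scale deltas), analyze it and
inspect the recovery:

```r
library(angioperf)
res <- cmd_selfcheck(seed = 1)
#>   roi metric truth_delta recovered_delta abs_error sign_ok significant
#> 1 MCA     at      -0.568          -0.590   0.02201    TRUE        TRUE
#> 2 MCA    ttp      -1.158          -1.164   0.00628    TRUE        TRUE
#> 3 MCA    mtt      -1.100          -1.080   0.02027    TRUE        TRUE
#> 4 ACA     at      -0.595          -0.616   0.02054    TRUE        TRUE
#> 5 ACA    ttp      -1.050          -1.043   0.00702    TRUE        TRUE
#> 6 ACA    mtt      -0.849          -0.814   0.03451    TRUE        TRUE
#> selfcheck: PASS
```

Each row compares a programmed territory change (dense-grid analytic
ground truth, seconds) with the change recovered by the full pipeline —
contrast conversion, window detection, AIF extraction, voxel-wise maps,
Welch pre/post comparison. Arrival, peak and transit shortenings of 0.6 to
1.2 s are recovered to within a few hundredths of a second and declared
significant with the correct sign.

The same pipeline runs on real data:

```r
res <- cmd_analyze("pre_run.dcm", "post_run.dcm",
                   masks = list("mca.json"), aif = c(120, 510, 160, 510),
                   out_dir = "out")
res$comparisons          # per-metric delta_mean, 95% CI, Welch p, significance
```

`out/` then holds the QC report (JSON), float-TIFF metric maps, the
validity mask, jointly normalized rendered PNGs with colorbar metadata and
the summary/comparison CSV tables. A thin command-line wrapper with the
same verbs (`analyze`, `single`, `phantom`, `selfcheck`) is installed at
`system.file("cli", "angioperf.R", package = "angioperf")`.

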