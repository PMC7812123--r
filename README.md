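# endocastr

Quantitative comparison of the brain surface with the endocast (the cast of
the inner bony braincase) of the same individual.

Endocasts are the only direct evidence of brain evolution in extinct taxa, so
paleoneurology needs to know how faithfully an endocast records the shape of
the brain and the position of its sulci. `endocastr` implements the full
comparison pipeline used in quantitative brain/endocast studies of extant
humans, and ships a synthetic phantom generator with exact ground truth so the
whole chain is testable without clinical data:

1. **Register and segment** — normalized mutual information (NMI,
   \((H(A)+H(B))/H(A,B)\)) rigid registration of the MRI-like and CT-like
   volumes; deformable-sphere (shrink-wrap) extraction of the *brain hull*
   and the endocast; exact resampling to a fixed face budget (100,000 faces
   by default).
2. **Detect and label sulci** — per-vertex principal curvatures
   \((k_\max, k_\min)\) and extremality coefficients from local cubic fits;
   sulcal imprints traced as *ravine lines* (zero crossings of the
   extremality \(e_\min\) where \(k_\min < -\tau_k\)); labels assigned from a
   reference curve set.
3. **Compare** — rigid + uniform-scale alignment (ICP), then a smooth
   kernel deformation of the hull onto the endocast (control points +
   momenta, varifold data term); labelled brain curves are transported
   through the deformation and matched to endocast curves by the mean
   closest-point curve distance \(d(c_E, C_B) = \mathrm{mean}_{p \in c_E}
   \min_{q \in C_B^{\text{same label}}} \lVert p - q \rVert\) with the
   criterion \(d < 10\) mm. Outputs are the count statistics TC-E, NS-E,
   TC-B, NS-B, NC-EB, NS-EB, an extrapolated distance map and a 0–5 mm
   displacement map.

## Worked example

Run the pipeline end to end on a phantom with no dropped sulci and no
superior-region mismatch (the "easy" recovery condition):

```r
library(endocastr)
cfg <- pipeline_config(
  phantom = list(drop_fraction = 0, superior_smoothing = 0,
                 sinus_ridge_height = 0, depth_attenuation = 0),
  seed = 11)
run <- run_pipeline(cfg, "my_run")
attr(run, "results")$report
#> match_report [phantom]: TC-E 8, NS-E 8, TC-B 10, NS-B 10, NC-EB 8, NS-EB 0 (tau = 10 mm)
```

All 10 carved grooves are recovered on the brain hull (TC-B 10); 8 are
detected on the endocast, and every one of them is matched by the transported
brain curve of the same label within 10 mm (NC-EB = TC-E, NS-EB = 0). The run
directory contains the volumes (NIfTI), surfaces (PLY, including the distance
and displacement maps as per-vertex scalars), curve sets (JSON), the summary
CSV and a manifest.

Feeding a published five-individual count table through the summary
arithmetic:

```r
tab <- human_count_table()
reports <- lapply(seq_len(nrow(tab)), function(i)
  match_report(tab[i, "TC-E"], tab[i, "NS-E"], tab[i, "TC-B"],
               tab[i, "NS-B"], tab[i, "NC-EB"], tab[i, "NS-EB"],
               specimen = tab$specimen[i]))
summarize_reports(reports)
#>   specimen TC-E NS-E TC-B NS-B NC-EB NS-EB matched-pct
#> 1       I1  139   15  149   17   110    10    79.13669
#> 2       I2  169   18  153   17   118    23    69.82249
#> 3       I3  178   16  193   19   165     5    92.69663
#> 4       I4  152   18  165   17   118    16    77.63158
#> 5       I5  249   17  174   18   204    15    81.92771
#> 6     Mean  177   17  167   18   143    14    80.24302
```

The mean row reproduces the published means (NC-EB 143, TC-B 167, NS-EB 14)
and the mean matched fraction of 80%. (The TC-E column mean is 177.4, which
rounds to 177; the published table prints 178 for it.)

A thin shell wrapper over the same pipeline lives at
`inst/scripts/run_pipeline.R`.

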