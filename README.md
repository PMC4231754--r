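# srnakin

Kinetics and inference for ribosome-modulated small-RNA silencing in
bacteria.

Trans-acting small RNAs (sRNAs) such as RyhB silence their targets by
base-pairing at the mRNA 5'UTR, usually right next to the ribosome binding
site (RBS), repressing translation and triggering codegradation of the
sRNA–mRNA pair. Because sRNA and ribosome act on the same stretch of RNA,
the strength of ribosome binding can either *hinder* silencing (competition
for the site) or *help* it (bound ribosomes effectively recruiting the
sRNA). The two hypotheses make opposite quantitative predictions for how
silencing efficacy and cell-to-cell expression noise depend on translation
efficiency, so a library of reporter targets with graded RBS strengths can
discriminate them. `srnakin` packages the whole quantitative program for
people who study post-transcriptional regulation quantitatively: the
kinetic model, its noise analysis, synthetic versions of the three assay
modalities, the matching estimators, and the inference step that outputs a
competition/recruitment verdict.

## The model

A three-state description of the target's interaction region (naked,
ribosome-bound, sRNA-bound) coarse-grains into mass-action kinetics for
mRNA *m*, sRNA *s* and protein *p*:

```
dm/dt = α_m − β_m m − k s m
ds/dt = α_s − β_s s − k s m
dp/dt = γ m − β_p p
```

with ribosome-dependent effective rates (x = RBS affinity):

```
β_m = β_m0 (1 + wx)/(1 + x)
k   = k0 (1 + xy) / ((1 + x)(1 + z + xyz))
γ   = γ0 x/(1 + x)
```

`y/w < 1` is the competition mode, `y/w > 1` the recruitment mode. The
leakage rate λ = β_m β_s / k sets silencing sharpness; b = γ/β_m is the
protein burst size, and without sRNA the noise obeys η = (1 + b)/⟨p⟩.
Fluctuations come from the linear noise approximation `J C + C Jᵀ + N = 0`,
with an exact Gillespie simulator (compiled) as the independent oracle.

## Worked example

```r
library(srnakin)

## recruitment-mode parameters, silenced regime (printed preset)
p <- preset_params("fig2", y = 100, alpha_s = 2)
unlist(steady_state(p))
#>            m             s             p residual_norm
#> 5.227235e-02  1.020909e+01  1.568171e+00  8.881784e-16
efficacy(p)
#> [1] 47.82643
```

At RBS affinity x = 1 the sRNA represses the target ~48-fold (steady state:
0.05 mRNAs, 10.2 sRNAs, 1.6 proteins per cell). Fold repression is maximal
at an intermediate affinity — the recruitment-mode fingerprint:

```r
find_max_efficacy(p)[c("x_opt", "efficacy_opt")]
#> $x_opt
#> [1] 3.136426
#> $efficacy_opt
#> [1] 59.82794
```

The end-to-end synthetic study (generate a 10-variant RBS library, simulate
plate reader + flow cytometry + decay qPCR, estimate, fit, classify):

```r
rep <- run_pipeline(pipeline_config(truth_y = 100), seed = 1)
rep
#> Pipeline report (seed 1 )
#>   truth y = 100 -> mode fit: recruitment (y_hat = 255)
#>   noise signature: on = non-declining, off = declining
#>   mean fitted half-life: 1.57 min
rep$mode_fit$ci_log10_yw
#> [1] 1.967463 2.766412
```

Reading: from the noisy synthetic library the pipeline recovers the
recruitment verdict (the bootstrap CI for log10(y/w) sits above 0 and
covers the truth, log10(100) = 2), the anomalous non-declining noise
signature in the presence of sRNA versus the declining no-sRNA noise, and
the 1.6-min mRNA half-life of the decay modality. With
`truth_y = 0.01` the same pipeline returns the competition verdict and
monotone declining noise.

## Command line

```sh
Rscript -e 'srnakin::cli_main()' predict  --preset fig2 --y 100 --outdir out
Rscript -e 'srnakin::cli_main()' simulate --seed 1 --n-variants 10 --outdir out
Rscript -e 'srnakin::cli_main()' estimate --outdir out
Rscript -e 'srnakin::cli_main()' fit      --outdir out --alpha-s-ratio 1
Rscript -e 'srnakin::cli_main()' run      --seed 1 --y 100 --outdir out
```

`predict` writes efficacy/noise curves (CSV), `simulate` writes the three
synthetic datasets plus truth sidecars (CSV + JSON), `estimate` per-variant
expression/efficacy tables, `fit` the mode-fit JSON, `run` the full
pipeline report.

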