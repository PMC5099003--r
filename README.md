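# cuffwss

Wall shear stress (WSS) metrics of atherogenic flow for the tapered-cuff
mouse carotid model.

A constrictive cuff tapering from 500 µm to 250 µm (a 75% areal stenosis)
placed around one carotid artery creates low shear upstream, high shear
inside the taper, and oscillatory, multidirectional shear downstream —
and, with it, vulnerable-type plaque upstream and stable-type plaque
downstream. `cuffwss` is for researchers who need to turn time-resolved
WSS vector fields τ(x, t) on triangulated lumen surfaces into the regional,
cohort-level shear statistics that discriminate those flow environments.

## What it computes

Per surface node, over one cardiac cycle sampled at N exported instants:

| metric | definition | captures |
|---|---|---|
| TAWSS | (1/N) Σᵢ ‖τᵢ‖ | shear magnitude (Pa) |
| OSI | ½(1 − ‖Σᵢτᵢ‖ / Σᵢ‖τᵢ‖) | 180° reversal, 0–0.5 |
| RRT | ‖(1/N) Σᵢτᵢ‖⁻¹ | near-wall residence (1/Pa) |
| transWSS | (1/N) Σᵢ \|τᵢ·q\|, q = n×p/‖n×p‖ | multidirectionality (Pa) |
| SAD | mean angle to neighbouring nodes' vectors | spatial direction change (rad) |
| LSI | max(0, (θ_L − TAWSS)/θ_L) | atherogenically low shear |
| HSI | max(0, (TAWSS − θ_H)/TAWSS) | atherogenically high shear |

with p the unit time-mean WSS vector and n the outward normal. The LSI/HSI
thresholds are calibrated from the contralateral control vessel:
θ_L = exp(m − 0.67 s), θ_H = exp(m + 0.67 s), where m and s are the mean
and sample SD of ln TAWSS over the control nodes — the bottom and top 25%
of a log-normal shear distribution.

The package also provides: STL read/write and structured tube meshing;
cylindrical parameterization; segmentation into the four analysis regions
(upstream outside plaque, upstream plaque [1.6 mm before the cuff], cuff,
downstream, with distally anchored control regions); a seeded synthetic
generator of paired instrumented/control vessels with pulsatile
quasi-steady Poiseuille shear, a parametric downstream vortex and
log-normal spatial heterogeneity; control-scaled regional comparison
tables with one-sided t tests; en-face (axial × circumferential) map
export; and a small CLI (`exec/cuffwss`).

## Worked example

```r
library(cuffwss)

# one synthetic mouse: paired instrumented + control carotid
mouse <- synth_mouse(seed = 1)
thr <- fit_thresholds(tawss(mouse$control$field))
thr
#> TAWSS thresholds: low 5.572 Pa, high 8.318 Pa (mean_log 1.918, sd_log 0.299)

# seven-mouse cohort -> region/metric table -> scaled comparisons
cohort <- synth_cohort(7, seed = 1)
tab <- cohort_region_table(cohort)
summ <- summarize_cohort(tab)
subset(summ$comparisons,
       region %in% c("upstream_plaque", "downstream") &
       metric %in% c("OSI", "tSS", "LSI", "HSI"))
#>           region metric mean_instrumented fold_factor p_one_sided stars
#>  upstream_plaque    OSI             1.000       1.000    5.00e-01
#>  upstream_plaque    tSS             1.000       1.000    5.00e-01
#>  upstream_plaque    LSI             3.805       3.805    2.59e-12   ***
#>  upstream_plaque    HSI             0.162       0.162    1.00e+00
#>       downstream    OSI            43.809      43.809    0.00e+00   ***
#>       downstream    tSS            19.073      19.073    2.76e-15   ***
#>       downstream    LSI             6.405       6.405    9.18e-16   ***
#>       downstream    HSI             0.121       0.121    1.00e+00
```

Reading the output: values are region means scaled by the control cohort
mean, so controls sit at 1 by construction. Upstream of the cuff only the
low shear index is elevated (3.8× control, p ≪ 0.001) while reversal (OSI)
and multidirectionality (tSS) sit at their floor — shear *magnitude* is
disturbed, direction is not. Downstream, the vortex drives OSI and tSS far
above control alongside low shear — both magnitude and direction are
disturbed. That asymmetry is the flow signature that separates the
vulnerable-plaque from the stable-plaque environment.

`run_full_pipeline(pipeline_config(), "out/")` writes the full artifact
set: STLs, field CSVs, per-mouse thresholds JSON, metric CSVs, the
region-metric table, comparisons CSV, en-face grids and a run log. Re-runs
with the same config are byte-identical.

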