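# ctbone

Micro-CT bone morphometry for longitudinal fixation studies.

When bone specimens are stored for years in a preservation fluid, repeated
micro-CT scans can reveal whether the fixative itself is changing the bone:
formalin storage swells mineralized tissue and leaches mineral (lowering the
X-ray linear attenuation coefficient µ), while ethanol storage leaves bone
essentially unchanged. `ctbone` turns a series of reconstructed attenuation
volumes (values in mm⁻¹, isotropic voxels) into the standard morphometric
parameters and their baseline-relative drift:

* **Segmentation** — Otsu threshold maximizing between-class histogram
  variance, with a *single common threshold* across the whole scan series
  (pooled histograms), followed by 26-connectivity speckle removal.
* **Compartments** — morphological separation of the cortical shell and the
  trabecular lattice with Euclidean ball structuring elements (exact
  distance-transform morphology in compiled code); the two classes
  partition the bone mask exactly.
* **Regions** — delineation of the proximal epiphysis+metaphysis (EM) zone,
  diaphysis and distal EM zone from the envelope's cross-sectional area
  profile (or at fixed fractions).
* **Morphometry** — TV, BV, Ct.BV, Tb.BV (voxel counting, mm³), BV/TV (%),
  and µ.B / µ.Ct / µ.Tb as the **median** attenuation of each bone class;
  trabecular values are suppressed in regions holding under 2% of the total
  trabecular volume (the diaphysis, in practice).
* **Longitudinal analysis** — percent-change-from-baseline curves
  `100·(x(t) − x(0))/x(0)`, first/last endpoint tables, and an empirical
  measurement-error band derived from a stable control series.
* **Synthetic phantom** — a parametric long bone (flared cortical shell,
  rod-lattice trabeculae, marrow cavity) with a programmable fixation drift
  model (saturating-exponential swelling and attenuation loss), so the full
  pipeline is testable against exact ground truth without any scan data.

Volumes travel as NIfTI (bitwise round-trip) or multi-page float TIFF with a
JSON sidecar (voxel size, day, units); series are described by a YAML
manifest; reports are CSV.

## Worked example

Simulate a formalin-like storage series on the default phantom
(160 × 141 × 141 voxels at 9 µm; cortical µ 1.288 mm⁻¹) and recover the
programmed drift:

```r
library(ctbone)

spec <- phantom_spec(seed = 1)
sim  <- simulate_fixation_series(spec, formalin_model(),
                                 days = c(0, 400, 900, 1565))
rec  <- analyze_series(sim$volumes)
ep   <- endpoint_differences(rec)
subset(ep, region == "whole")
```

```
  region parameter      first       last difference_percent
1  whole        TV 1.06701689 1.15991482           8.706322
2  whole        BV 0.51081905 0.55504675           8.658193
3  whole     Ct.BV 0.41908387 0.45595013           8.796869
4  whole     Tb.BV 0.09173517 0.09909661           8.024667
5  whole      mu_B 1.27401044 1.20579470          -5.354410
6  whole     mu_Ct 1.28785934 1.21956740          -5.302748
7  whole     mu_Tb 0.86036386 0.83515549          -2.929966
```

The programmed end-of-series changes were +8.6% bone volume and −5.3%
cortical attenuation: the pipeline recovers both to a fraction of a
percentage point, and the same run with `ethanol_model()` (all drifts zero)
stays within 0.2 points of zero everywhere — the formalin/ethanol contrast
the method is built to measure. `write_report()` and
`write_endpoint_table()` render these tables with absent trabecular cells
as empty/`-`, and `plot_change_curves()` draws the per-region drift curves.

A thin command-line wrapper for scan series on disk lives in
`inst/scripts/run-series.R`:

```sh
Rscript inst/scripts/run-series.R --manifest series.yaml \
    --out morpho.csv --endpoints endpoints.csv
```

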