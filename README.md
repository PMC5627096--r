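# pingnet

Social network inference from passive acoustic telemetry, across receiver
detection ranges.

Arrays of acoustic receivers record when a tagged animal's transmitter
pings within range. Co-detections are widely used to infer social
associations in animals that cannot be observed directly (sharks and other
marine fish especially), but the receiver's detection radius — anywhere
from a few metres for an animal-borne proximity logger to ~400 m for a
standard fixed receiver — silently becomes part of the association
definition: inside a large radius, a solitary animal and a resting group
leave identical co-detection records. `pingnet` is for behavioural
ecologists and biotelemetry analysts who want to build such networks
rigorously and to quantify how much detection range distorts them.

## What it computes

* **Gambit of the group**: detections → clock-aligned 10-min bins per
  receiver → group observations → hourly sampling periods.
* **Simple ratio index** per dyad,
  `E_AB = x / (x + y_AB + y_A + y_B)`,
  where `x` counts sampling periods with A and B in one group, `y_AB`
  periods with both observed but never together, and `y_A`, `y_B` periods
  with only one of the pair seen. `E_AB` ∈ [0, 1].
* **Data-stream permutations**: serial swaps of individuals between groups
  of the same sampling period (group sizes and individual sighting
  frequencies preserved), driving tests of non-random association on the
  mean and CV of the indices.
* **Between-network comparison**: Mantel correlation of aligned matrices,
  and consistency of individuals' weighted-degree ranks via the
  sum-of-variances statistic SV_O against its randomized distribution SV_R.
* **An agent-based simulator** (rest bouts at reef sites, social site
  choice, 90 s tag delay, range-dependent detection, animal-borne
  receivers) with a ground-truth contact network, so the whole chain is
  testable end to end.

## Worked example

Simulate one season at a shark aggregation (two social blocks of five plus
five solitary individuals; one 400 m receiver, two 10 m receivers, a 4 m
proximity logger on `PJ01`) and compare the networks each receiver type
infers — here a scaled-down 7-day run:

```r
library(pingnet)
scen <- preset_jervis2012(duration_days = 7, seed = 42, step = 120)
rep <- run_comparison_study(scen, n_perm_null = 500,
                            n_perm_mantel = 199, n_perm_consistency = 500)
print(rep)
#> networks:
#>           network n_individuals n_groups n_periods mean_obs mean_p cv_obs  cv_p
#>              VR2W            15     1008       168   0.7898  1.000  0.161 1.000
#>           SUR-10m            15     1687       168   0.1262  1.000  1.307 0.002
#>             Proxi            13      557       102   0.0692  0.361  1.476 0.922
#>  Proxi-restricted            13      512        94   0.0699  0.248  1.472 0.894
#>
#> comparisons:
#>                   comparison mantel_r mantel_p   sv_o sv_r_mean   sv_p status
#>             Proxi vs SUR-10m    0.467    0.010 0.6736    1.2171 0.0220     ok
#>                Proxi vs VR2W    0.373    0.015 0.4740    0.4740 1.0000     ok
#>              SUR-10m vs VR2W    0.258    0.010 0.7130    0.8720 0.0259     ok
#>    Proxi vs Proxi-restricted    0.999    0.005 0.0208    0.0131 0.8383     ok
#>  SUR-10m vs Proxi-restricted    0.477    0.005 0.5486    1.1216 0.0200     ok
```

Reading the output: the 400 m network (`VR2W`) is nearly saturated (mean
index 0.79 — almost everyone is "associated" with everyone) and its CV
test finds no structure (`cv_p = 1`), while the 10 m receivers recover
strongly non-random associations (`cv_p = 0.002`). The proximity logger
agrees best with the 10 m network (Mantel r 0.47 vs 0.37 against the
400 m network), and individuals keep consistent degree ranks between the
small-range networks (`sv_p ≈ 0.02`) but not against the 400 m network
(`sv_p = 1`). Over replicate simulations these gaps are the package's
headline result: large detection ranges blur social structure. p-values
come from add-one permutation rules, so 0.002 at 500 permutations is the
floor "stronger than every null sample".

Matrix heat maps (upper triangles, shared colour scale):

```r
export_heatmaps(rep$matrices[c("Proxi", "SUR-10m", "VR2W")], "heatmaps/")
```

## Command line

```sh
inst/cli/pingnet simulate --config cfg.txt --out data/     # detections.csv etc.
inst/cli/pingnet compare  --config cfg.txt --out report/   # Table-style TSV report
inst/cli/pingnet sweep    --config cfg.txt --replicates 20 --out sweep/
```

where `cfg.txt` is flat `key: value` text (`preset: jervis2012`,
`duration_days: 7`, `seed: 42`, ...); see `?read_run_config`.

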