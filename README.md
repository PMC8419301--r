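# econet

Does a region's position in the national *economic* network predict how
its *health-care* productivity evolves? `econet` implements the full
analysis chain for that question on province-year panels:

1. **Gravity model** — inter-regional attraction
   `R_ij = GDP_i·P_i·GDP_j·P_j / d_ij²` from regional masses and pairwise
   distances;
2. **Network construction** — each row of the gravity matrix is
   thresholded by its own mean (strict inequality), producing a binary
   directed economic network and its density;
3. **Node metrics** — indegree/outdegree, the clustering coefficient
   `2E_i/(k_i(k_i−1))` on the symmetrized graph, and in-link eigenvector
   centrality (max-normalized principal eigenvector of `Aᵀ`);
4. **DEA–Malmquist** — input-oriented radial DEA over three health-care
   inputs (institutions, personnel, beds) and two outputs (bed
   utilization, outpatient visits), chained into the geometric-mean
   Malmquist index with its full decomposition
   `tfpch = effch × techch`, `effch = pech × sech`;
5. **Regression & typology** — pooled OLS of TFP change on each network
   metric with region and year controls, and a PCA + k-means grouping of
   provinces with silhouette-based selection of the number of groups.

A synthetic province-panel generator (`generate_panel()`) plants a known
frontier, inefficiency process, network effect and three-group typology,
so every stage is validated by parameter recovery, not just unit tests.
The package is tidyverse-native: every stage takes a data frame and
returns a tibble, results have `tidy()`/`glance()`/`autoplot()` methods,
and `run_pipeline()` writes every intermediate plus a reproducible JSON
manifest.

## Worked example

```r
library(econet)

sim <- generate_panel(synthetic_config())   # 31 units, 2013-2018
ap  <- analysis_panel(sim$panel)            # tfpch + network metrics per unit-year
descriptives(ap)
#>      variable   n   mean      sd   min    max
#> 1       tfpch 155  0.993  0.0695 0.849  1.199
#> 2    indegree 155 10.484 10.7778 0.000 25.000
#> 3 eigenvector 155  0.238  0.3391 0.000  1.000
#> 4  clustering 155  0.449  0.0474 0.374  0.567
```

155 rows: 31 provinces × 5 transition years. TFP change averages just
below 1 — the planted 0.99-per-year frontier regression — and spreads with
the planted network effect. The three single-regressor models print in the
conventional journal layout:

```r
fit_tfp_models(ap)
#> Variables    TFP change  TFP change  TFP change
#> indegree     0.001       -           -
#>              (1.390)     -           -
#> eigenvector  -           0.026       -
#>              -           (1.458)     -
#> clustering   -           -           0.181
#>              -           -           (1.620)
#> Constant     0.953***    0.955***    0.882***
#>              (57.657)    (61.774)    (16.525)
#> Observations 155         155         155
#> Region       Control     Control     Control
#> Year         Control     Control     Control
#> Adj R-squared 0.137      0.138       0.141
```

and the typology recovers the three planted groups (scattered periphery,
polycentric central belt, compact core):

```r
cl <- select_k_and_cluster(pca_features(unit_summary(ap)), seed = 1)
cl
#> <cluster_result> chosen k = 3 (mean silhouette 0.738)
#>   cluster     n
#> 1       1    10
#> 2       2    16
#> 3       3     5
autoplot(cl)           # groups in PCA space
plot_k_diagnostics(cl) # elbow + silhouette curves
```

`published_malmquist_means()` ships a published province-mean Malmquist
component table for China's provincial health system (2014–2018) as a
worked example for `check_decomposition()`, which verifies that printed
components recompose (`effch × techch → tfpch` at table precision).

End to end, with every intermediate written to disk:

```r
run_pipeline(pipeline_config(out_dir = "run1"))
```

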