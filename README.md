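# dcnet

Differential connectivity of gene co-expression networks from
two-condition time-course expression data.

## The problem

Circadian time-course experiments profile the same transcriptome under two
light regimes — typically an ambient light–dark cycle (**LD**) and constant
darkness (**DD**) — over a dozen timepoints with a few biological
replicates. Genes central to the light response often do not change their
own trajectory much; instead their *co-expression neighbourhood*
reorganizes when the rhythm collapses. `dcnet` is for researchers who want
to find those genes: it quantifies, per gene, how many highly correlated
partners it has in each condition and ranks genes by the change.

## The method

For each condition the package builds a hard-threshold correlation network
over wavelet-domain representations of the expression profiles:

1. average biological replicates; optionally collapse probes to genes;
2. min–max normalize every record to [−1, 1]:
   x′ⱼ = 2 (xⱼ − x_min)/(x_max − x_min) − 1 (constant records map to 0);
3. screen records by the Euclidean distance between their LD and DD
   profiles, keeping the high-distance tail above the knee of the sorted
   curve (or above a manual threshold);
4. apply a level-1 discrete wavelet transform (Mallat; Haar by default,
   db2/db3 optional) giving each profile a 12-dimensional frequency vector
   [C₁..C₆, D₁..D₆];
5. compute Pearson correlations r_ij between frequency vectors within each
   condition and connect i–j when τ ≤ |r_ij| ≤ 1 (τ = 0.7), giving each
   probe a degree (connectivity) l_i = Σⱼ l_ij;
6. score each probe by m_i = l_i(LD) − l_i(DD), summarize the branches by
   the square ratios S± = Σ± m_i² / Σ m_i², and select key probes from the
   extreme tails of the sorted difference curve (knee detection, or manual
   inclusive thresholds).

A strongly negative m_i flags a gene that is far more embedded in the
network under constant darkness.

## Worked example

```r
library(dcnet)

# study-like synthetic experiment: 300 probes, 12 timepoints x 2 days,
# 3 replicates, one 30-probe module tight only in constant darkness
sim <- simulate_dataset(sim_config(seed = 1))
fit <- dcnet(sim$dataset, screen = FALSE)
summary(fit)
#> Differential-connectivity network model: LD - DD
#> records analysed: 300 of 300
#> connectivity differences m = l(LD) - l(DD):
#>   negative (more connected in DD): 131
#>   positive (more connected in LD): 129
#>   zero: 40
#> square ratios: S_neg = 95.69%, S_pos = 4.31%
#> key probes: 39 negative (m <= -5), 61 positive (m >= 3)

head(sort(coef(fit)), 5)
#> P0023 P0012 P0013 P0003 P0005
#>   -34   -32   -32   -31   -31
```

The negative square ratio dominating (95.69%) says the squared degree
changes are carried almost entirely by genes *gaining* connectivity in
darkness — here, the planted module: all 30 of its members are recovered
in the selected negative tail (`m ≤ −5`, 39 probes). `plot(fit)` draws the
sorted distance and difference curves with their selection thresholds.

Real data enter through `read_expression_table()` (TSV/CSV with
`<condition>_<time>_<replicate>` columns) or `read_series_matrix()` (GEO
series-matrix text plus an explicit sample map), and published knee values
can be supplied directly, e.g.
`dcnet(ds, screen_threshold = 3.996, neg_threshold = -19.88, pos_threshold = 10)`.
`run_pipeline("config.yaml")` (or the `exec/dcnet` script) runs the whole
chain and writes node/edge tables, GraphML and a `report.yaml` with every
intermediate count.

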