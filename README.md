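# granulofit

Decomposition of bimodal starch granule size distributions from
Coulter-counter measurements.

## The problem

Wheat endosperm starch contains two granule classes: large discoid
**A-type** granules (~18–20 µm equivalent spherical diameter) and small
spherical **B-type** granules (~6–7 µm). A Coulter counter sizes each
particle by electrical impedance, and granule phenotypes are reported on
the **volume-weighted** size distribution — the volume of granules at
each diameter relative to total granule volume — which is bimodal in
wheat. Quantifying a genotype therefore means splitting that curve into
its two components and summarising each.

`granulofit` is for researchers who phenotype cereal starch: it fits the
per-bin percent-volume curve with the constrained mixture

> f(x) = (1 − w_B) · N(x; μ_A, σ_A) + w_B · LogN(x; m_B, s_B),
> with exp(m_B + s_B²/2) < μ_A,

by least squares on bin-integrated densities, and reports per sample the
A-type mean diameter (μ_A), the B-type mean diameter
(exp(m_B + s_B²/2)), the B-type granule content (100·w_B, the percentage
of starch volume present as B-type granules) and granule number per mg
starch. Distributions measured before B-type initiation (12 days after
flowering) are recognised automatically and fitted with the A component
only (B fields reported as `na`). Genotypes are compared per metric with
one-way ANOVA + Tukey or Kruskal–Wallis + Nemenyi (selected by an
explicit assumption gate) and summarised as compact letter displays.

Because instrument data rarely travel with published phenotypes, the
package includes a seeded synthetic granule-population generator that
emulates Coulter-counter measurements (multinomial counting noise on a
log-spaced 2–60 µm grid, biological replicate jitter) with wild-type and
plastid-division-mutant presets at three developmental stages, so the
entire pipeline runs and is tested end to end with no external data.

## A worked example

```r
library(granulofit)

cfg <- run_config(
  mode    = "synthetic",
  presets = c("WT_mature:3", "parc6_mature:3"),  # 3 biological replicates each
  seed    = 7
)
run <- run_pipeline(cfg)
run$metrics[, c("genotype", "replicate", "a_mean_diameter",
                "b_mean_diameter", "b_content_pct")]
```

```
  genotype replicate a_mean_diameter b_mean_diameter b_content_pct
1       WT         1           19.55           6.109         40.21
2       WT         2           17.79           6.012         39.89
3       WT         3           18.77           5.691         40.21
4    parc6         1           23.09           9.500         69.67
5    parc6         2           22.30           8.366         70.50
6    parc6         3           22.99           8.359         68.53
```

Each row is one fitted biological replicate. The wild type centres on a
19 µm A-type peak, a 6 µm B-type mean and ~40% B-type content; the
plastid-division mutant shows larger granules of both classes and
~70% B-type content. The genotype comparison:

```r
run$comparisons[["mature_b_content_pct"]]
```

```
<comparison_result> anova_tukey: omnibus statistic 2570, p = 9.064e-07 (alpha 0.05)
  group     mean        se n letters
1 parc6 69.56966 0.5713887 3       a
2    WT 40.10142 0.1070546 3       b
```

Distinct letters mean the genotypes differ in B-type content at
alpha = 0.05 under the selected test (here ANOVA + Tukey).
`render_report(run, "out")` writes the metrics, comparison and
aggregate-curve TSVs plus a mean ± SE distribution plot per timepoint.
A thin command-line wrapper with `run`, `simulate`, `decompose` and
`compare` subcommands is installed at `inst/scripts/granulofit`.

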