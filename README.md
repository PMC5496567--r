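# lakeweb

Seasonal food-web assembly and analysis for lake communities.

Long-term monitoring of a lake rarely yields a complete community census:
phytoplankton, zooplankton, macroinvertebrates and fish are each surveyed
over different, only partially overlapping multi-year windows, while diet
knowledge accumulates from gut-content analyses and the literature.
`lakeweb` turns such incomplete records into a single *idealized averaged
year* — pooled monthly composition, averaged abundances, cumulative links —
realises a binary food web for every month, and asks how web structure
reorganises across the year. It is aimed at community ecologists working
with species-resolved qualitative (binary) webs.

## What it computes

For each monthly web with S nodes and L directed links (resource →
consumer, the direction of energy flow):

* a panel of qualitative network descriptors: S, L, link density L/S,
  connectance C = L/S², fractions of top/intermediate/basal species,
  omnivore and cannibal fractions, standardized generality and
  vulnerability (mean and SD), prey-averaged trophic levels
  (TL = 1 for basal nodes, else 1 + mean TL of resources), characteristic
  path length and clustering of the undirected projection;
* nonmetric multidimensional scaling of the months on Bray–Curtis
  distances after Wisconsin double standardization, minimizing Kruskal's
  stress-1 = √(Σ(d̂ − δ)² / Σδ²) with disparities d̂ from
  pool-adjacent-violators isotonic regression — implemented natively, with
  restarts, primary/secondary tie handling and Shepard-plot output;
* least-squares fitting of environmental and community variables onto the
  ordination, with permutation p-values (add-one convention);
* month-to-month Sørensen similarity of link sets, 2|A∩B|/(|A|+|B|), a
  data-driven two-season partition of the months (hierarchical clustering;
  the bigger-web cluster is "summer"), and the partition of links into
  year-round / summer-only / winter-only classes;
* Bayesian Shannon diversity H′ = −Σ pᵢ ln pᵢ per group and month, from the
  exact Dirichlet–multinomial posterior with 95% credible intervals;
* Kruskal–Wallis seasonal contrasts for every descriptor, with both
  percent-change conventions ((summer−winter)/winter for seasonal means,
  (max−min)/max for month extremes) and year-to-year composition
  similarity checks.

A configurable synthetic-community generator (`generate_community()`)
plants a known two-season structure — winter-absent insect taxa,
non-overlapping sampling windows, gut-content labelling — so the entire
pipeline is testable end to end without any external data.

## Worked example

```r
library(lakeweb)
res <- run_all(run_config(seed = 1))
res$seasons
#> Two-season partition (by web structure, not calendar):
#>   summer: Jan Feb Mar Apr Oct Nov Dec
#>   winter: May Jun Jul Aug Sep
```

The run summary collects the headline quantities:

```r
str(res$summary[c("S_min", "S_max", "S_decrease_pct",
                  "L_min", "L_max", "L_decrease_pct",
                  "mean_connectance_pct", "L_increase_pct")])
#> S range 63-82 (-23.2%), L range 371-618 (-40.0%)
#> mean connectance 9.30%, summer/winter mean L 585.4 / 392.4 (+49.2%)
```

Reading: pooling the synthetic record gives monthly webs of 63–82 nodes;
from the largest to the smallest month the web loses 23.2% of its nodes
and 40.0% of its links, while connectance stays nearly flat at 9.3% —
shrinking and link thinning happen together, which is exactly the
seasonal simplification signal the pipeline is built to detect. The
partition above was derived from link-pattern similarity alone, yet it
recovers the generator's planted May–September winter, and the
descriptor-based NMDS clustering agrees on 12/12 months
(`res$summary$clustering_agreement`).

Environmental correlates confirm the gradient:

```r
subset(res$envfit, variable == "water_temperature")
#>            variable       dir1 dir2    r2      p_perm
#> 4 water_temperature -3.56e-06   -1 0.805 0.004995005
```

and the seasonal contrasts quantify it per descriptor:

```r
head(res$contrasts$contrasts[c("descriptor", "ratio", "increase_pct", "H", "p")])
#>   descriptor ratio increase_pct     H       p
#> 1          S 1.208        20.80 8.400 0.00375
#> 2          L 1.492        49.19 8.077 0.00448
#> 3         LD 1.235        23.51 8.077 0.00448
#> 4          C 1.022         2.22 0.534 0.46490
```

Links and link density differ sharply between the seasons (p < 0.005);
connectance does not — the web rescales rather than rewires its density.

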