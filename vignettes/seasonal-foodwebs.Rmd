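---
title: "Seasonal structure of lake food webs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal structure of lake food webs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lakeweb` reconstructs and analyses the seasonal dynamics of a lake
community's food web from the kind of data long-term monitoring programmes
actually produce: monthly abundance records collected over several years,
with each organism group (phytoplankton, zooplankton, macroinvertebrates,
fish) surveyed over a different, only partially overlapping window, plus a
cumulative table of who eats whom assembled from gut-content analyses and
the literature. This vignette explains the model and procedure in each
stage, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The idealized averaged year

Multi-year records with non-overlapping windows cannot support a month-by-
month time series of complete webs. The package therefore collapses the
record into one *idealized averaged year*:

* **Composition is pooled**: a taxon is present in idealized month *m* if
  it was recorded in month *m* of *any* sampled year.
* **Abundances are averaged**: the abundance for (taxon, month) is the
  arithmetic mean over the years in which it was recorded, keeping each
  group's native unit (ind/ml for plankton, ind/0.5 m&sup2; for
  macroinvertebrates, ind/100 m&sup2; for fish).
* **Link knowledge is cumulative**: the diet table is a property of the
  taxon pair, not of a date.

One wrinkle is cadence: fish are typically netted bimonthly, so some
months may have no fish sampling in any year. Dropping the whole fish
assemblage from such a month would create artificial holes, so
`pool_idealized_year()` lets those months inherit the group's presence and
mean abundances from the nearest sampled month in the same calendar
season (`gap_fill = TRUE`, the default); every inheritance is recorded in
the returned `gap_filled` table and raised as a warning. The calendar
winter used here (`winter_months = 5:9`, austral winter) only steers this
imputation; the analysis stages derive their seasons from the data.

The monthly web for month *m* is then purely qualitative:
nodes = pooled presence in *m* plus the permanent basal resources
(detritus, periphyton, ...), links = all cumulative links whose two
endpoints are both present. No abundance threshold is applied; the webs
are binary by construction.

## The descriptor panel

`descriptor_vector()` computes, for one monthly web with S nodes and L
directed links (stored resource &rarr; consumer):

| descriptor | definition |
|---|---|
| `S`, `L` | node and link counts (self-links count in L) |
| `LD` | link density L/S |
| `C` | connectance L/S&sup2; |
| `frac_top`, `frac_intermediate`, `frac_basal` | fractions of S with no consumers / both / no resources (self-links ignored) |
| `frac_omnivore` | fraction consuming resources at &ge;2 distinct integer-rounded trophic levels |
| `frac_cannibal` | fraction with a self-link |
| `gen_mean`, `gen_sd` | mean/SD over consumers of (resources per consumer)/LD |
| `vul_mean`, `vul_sd` | mean/SD over resources of (consumers per resource)/LD |
| `mean_TL`, `max_TL` | prey-averaged trophic levels |
| `cpl` | characteristic path length of the undirected simple projection, averaged over reachable pairs only |
| `cc` | mean local clustering coefficient over nodes of degree &ge; 2 (0 if none) |

Prey-averaged trophic level is TL = 1 for basal nodes and
TL = 1 + mean(TL of resources) otherwise, solved as a linear system;
if the system is singular (pure consumer loops) a damped fixed-point
iteration to 1e-10 takes over. A consumer with no diet path down to a
basal node has no defined level and is flagged `NA`; resources with
undefined levels are excluded from a consumer's prey average.
Cannibalistic self-links are excluded from the trophic-level solve and
from the top/intermediate/basal classification, but count in `L` and
`frac_cannibal`. An isolated node is classified basal — a resource whose
consumers are absent in a month is still a resource — with a message.

The panel is configurable (`run_config(descriptors = ...)`): any subset
can be fed to the ordination and the seasonal contrasts.

## Ordination: NMDS implemented in full

The 12 monthly descriptor vectors are compared by nonmetric
multidimensional scaling on Bray–Curtis dissimilarities after Wisconsin
double standardization (each column divided by its maximum, then each row
by its sum), the standard chain for heterogeneous ecological variables.
The NMDS optimizer is implemented inside the package because the stress
function and its tie handling are the analytical substance of this stage;
external implementations are used only as independent cross-checks in the
test suite.

Each restart alternates two steps until the stress decrease falls below
`tol`:

1. **Isotonic regression**: disparities are the least-squares
   non-decreasing fit (pool-adjacent-violators, `pava()`) of the current
   configuration distances against the rank order of the input
   dissimilarities. Kruskal's *primary* tie treatment is the default
   (within a block of tied input values the fitted disparities may be
   unordered); *secondary* treatment (tied inputs share one disparity) is
   available via `ties = "secondary"`.
2. **Guttman transform**: the configuration is updated by the standard
   majorization step with the disparities as target distances.

Stress is Kruskal's stress-1,
sqrt(&Sigma;(d&#770; &minus; &delta;)&sup2; / &Sigma;&delta;&sup2;).
One restart starts from the metric (classical scaling) solution and
`n_restarts` (default 100) from random configurations; the best final
stress wins. The returned scores are centred, rotated to principal axes,
and given a deterministic sign convention, so a fixed seed yields
byte-identical output. Reported fit measures are `nonmetric_R2`
= 1 &minus; stress&sup2; and `linear_R2` = squared Pearson correlation
between disparities and configuration distances (the Shepard-plot fit).

With only 12 points and low-contrast panels, NMDS can reach (near-)zero
stress through a *degenerate* configuration — most points collapsing to
one location. `nmds()` warns when stress falls below 1e-3 on data with
genuine contrast; treat such ordinations with suspicion. A related
practical caveat: a descriptor that is a ratio of very small counts (the
cannibal fraction, when a web holds a single cannibalistic taxon) can be
pure shot noise, and Wisconsin's column-maximum step will amplify it into
the dominant component of the Bray–Curtis distances. All-zero columns are
dropped (`prepare_descriptors()`), but thin non-zero columns are kept, and
with them an outlier month can occasionally dominate the ordination.

`envfit_vector()` fits an external variable (an environmental series,
a group density, a diversity estimate) onto the 2-D scores by least
squares: the arrow is the unit vector of regression coefficients, r&sup2;
the squared multiple correlation, and significance comes from permuting
the variable across points, with the add-one convention
p = (1 + #{permuted r&sup2; &ge; observed}) / (n_perm + 1) so p is never
zero. The default is 1,000 permutations.

## Link-pattern similarity and the two-season partition

Independently of the descriptor panel, the identity of the interactions is
compared month to month with Sørensen similarity of link sets,
2|A&cap;B| / (|A| + |B|) (two empty sets count as identical, with a
warning). Average-linkage hierarchical clustering of 1 &minus; similarity,
cut at two clusters, yields the seasonal partition; the cluster holding
the month with the most links is labelled *summer*, so the seasons are
defined by web structure, not by the calendar. The linkage is configurable
(complete, Ward) via `extract_seasons(method = )`.

The same two-cluster extraction applied to the NMDS scores gives a second,
descriptor-based partition; `season_agreement()` reports the fraction of
months the two assign identically (label swaps resolved). For the
score-based clustering the pipeline uses Ward linkage (`ward.D2`):
ordination coordinates are Euclidean, where minimum-variance linkage is
the standard choice, and unlike average linkage it does not shear off a
single outlying month as its own cluster.

Realized links are finally partitioned into three disjoint classes —
observed in both seasons, summer-only, winter-only — which together
exhaust every link realized in at least one monthly web.

## Bayesian Shannon diversity

Within each group and month the pooled counts are modelled as one
multinomial draw; the prior over taxon proportions is a symmetric
Dirichlet. With that prior the posterior is Dirichlet(counts + &alpha;) in
closed form, so `shannon_posterior()` samples it *exactly* (gamma draws,
default 4,000) and computes H&prime; = &minus;&Sigma;p&#7522; ln p&#7522;
per draw; the point estimate is the posterior mean and the 95% credible
interval the 2.5%/97.5% quantiles. "Uninformative" is read as
&alpha; = 1 (flat over the simplex); &alpha; = 1/S (Perks-style) is
available via `alpha = "perks"`. An independence-Metropolis MCMC mode
(5,000 iterations, burn-in 1,000, proposal = posterior parameters raised
to 0.9) is retained purely as a fidelity cross-check of the exact sampler;
the test suite verifies the two agree within Monte-Carlo error.

Mean densities are not integers; `diversity_table()` multiplies them by an
effort constant (default 10) and rounds before forming the posterior. The
constant trades off fidelity of small densities against over-confidence:
scaling counts up narrows the posterior, so the default keeps fish counts
(a few individuals per 100 m&sup2;) at realistic magnitudes.

## Seasonal contrasts

`seasonal_contrasts()` compares every descriptor between the data-derived
summer and winter months with the tie-corrected Kruskal–Wallis rank-sum
test (chi-square approximation, as standard). The month clusters are small
(typically 7 vs 5), where the chi-square approximation is rough; an exact
permutation p-value over all assignments of months to the observed group
sizes is available with `exact = TRUE`. Two percent-change conventions
deliberately coexist and every output labels its own: seasonal mean
changes are reported relative to the winter mean,
(summer &minus; winter)/winter, while month-extreme changes are relative
to the maximum, (max &minus; min)/max. No multiple-testing correction is
applied across descriptors, but a Holm-adjusted column is emitted
alongside. `interannual_similarity()` supplies the year-on-year Sørensen
check of composition stability that justifies pooling years at all.

## The synthetic generator

`generate_community()` produces a full dataset with planted two-season
structure so every downstream stage can be tested without any external
data. Defaults are the study conditions the generator emulates:

* **Richness**: 25 phytoplankton, 10 zooplankton, 40 macroinvertebrate,
  10 fish taxa, plus 4 permanent basal resources.
* **Layered master web**: basal resources are eaten by zooplankton and
  macroinvertebrates; phytoplankton by zooplankton, macroinvertebrates and
  fish; zooplankton and macroinvertebrates by macroinvertebrates and fish;
  fish only by other fish — so a fish is never a zooplankter's resource.
  Every consumer gets at least one resource from a strictly lower layer
  (trophic levels always defined), a target of 12 resources per consumer
  (chosen to put connectance in the ~9–10% regime typical of
  species-resolved lake webs), and a 5% chance of a cannibalistic
  self-link for macroinvertebrates and fish.
* **Seasonality**: winter is May–September. A macroinvertebrate is absent
  from all winter months with probability 0.3 (univoltine insects leaving
  the water as terrestrial adults); other groups with probability 0.05.
  Independently, each remaining (taxon, month) cell of the schedule is
  dropped with probability 0.10 — month-to-month turnover and imperfect
  detection, set to reproduce a within-group monthly richness coefficient
  of variation near 11%.
* **Sampling windows**: phytoplankton monthly mid-2009 to early 2014,
  zooplankton monthly for one year, macroinvertebrates monthly for 14
  months, fish bimonthly over four years — deliberately non-overlapping to
  exercise the pooling logic.
* **Abundances**: lognormal around group-typical densities with a summer
  multiplier of 1.8 for fish and 1.3 for zooplankton (other groups 1).
* **Link origins**: 42% of links labelled `gut_content` in expectation,
  preferentially (twice the base odds) on links consumed by fish or
  chironomid-like macroinvertebrates — the taxa whose diets a field
  programme resolves by gut contents.

Because links are presence-driven (a link is realized in month *m* iff
both endpoints are present), the winter web is structurally an
impoverished subset of the summer web — the planted effect the pipeline
must recover. What the generator does **not** emulate: population
dynamics (no predator–prey feedbacks), ontogenetic diet shifts, body-size
structure, spatial heterogeneity, and observation error in the link table
itself. Passing the recovery tests therefore shows the pipeline detects
seasonal presence-driven rewiring; it does not validate the method against
dynamical or size-structured effects.

## Numerical choices and degenerate inputs

* Stress optimization stops when the per-iteration decrease falls below
  1e-9 or stress increases (the best configuration is kept), capped at 500
  iterations per restart.
* PAVA is the exact stack algorithm (weighted block pooling), not an
  approximation.
* Sørensen similarity of two empty link sets is 1 (identical emptiness),
  with a warning, keeping the 12&times;12 matrix total.
* A degenerate similarity matrix (all off-diagonal values equal) cannot be
  clustered and is an error.
* Zero-link webs have an undefined gut fraction (`NA` with a warning).
* Permutation p-values use the add-one convention; their lower bound is
  1/(n_perm + 1).
* Every stochastic stage takes an explicit seed; the pipeline derives one
  stream per stage from the master seed, so any stage can be rerun in
  isolation and two runs with one seed agree byte for byte.

## Problem sizes

The default pipeline (one community, 12 webs of roughly 60–85 nodes and
350–650 links, 100 NMDS restarts, 1,000 envfit permutations, 4,000
posterior draws per group-month) runs in well under a minute on one CPU.
The test suite's deeper simulations use 500 random small webs for the
descriptor oracle, 20 generator seeds for parameter recovery, 2,000
null-variable simulations for envfit calibration, and 1,000 multinomial
replicates for credible-interval coverage — sizes chosen to keep the whole
suite within a few minutes while leaving Monte-Carlo error well inside the
asserted tolerance bands.

## Known limitations

* The descriptor panel is one defensible qualitative set; analyses that
  depend on a different panel should configure it explicitly.
* Kruskal–Wallis on 7-vs-5 months has limited power and a rough chi-square
  null; prefer `exact = TRUE` for small clusters.
* NMDS on 12 points is expressive enough to be degenerate; check the
  stress warning and the Shepard data (`delta`/`dhat`) before interpreting
  an ordination.
* The gap-fill imputation assumes within-season stability of the
  bimonthly-sampled group; it is logged so it can be audited or disabled.
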