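---
title: "Cluster detection on complex survey data: models, simulation design, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster detection on complex survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyscan)
```

## The scientific question

Population-based health surveys (the motivating example is a national
community health survey interviewing roughly 900 adults per
administrative district) are collected under complex sampling designs:
respondents are stratified by age group and sex, sampled with unequal
probabilities, and assigned design and post-stratification weights.
When such data are used to search for geographic clusters of high
disease prevalence with a spatial scan statistic, the analyst must
choose what to feed the scan:

1. **Frequency** — the observed individual-level binary responses,
   i.e. per district the sampled case count out of the ~900
   respondents, analysed with the Bernoulli scan statistic and the
   weights ignored;
2. **Weighted frequency** — the responses multiplied by their final
   survey weights, producing census-scale pseudo-counts per district,
   also analysed with the Bernoulli scan;
3. **Aggregate** — a district-level survey-weighted crude prevalence
   estimate with a precision weight, analysed with the weighted normal
   scan statistic.

`svyscan` implements all three pipelines end to end, plus a simulation
framework that draws complex-survey samples from a synthetic stratified
census with known true clusters, so the three choices can be compared
on sensitivity (share of true-cluster districts detected) and positive
predictive value (share of detected districts that are truly
clustered).

## The scan statistics

Both engines scan **circular windows**: for every district taken as a
centre, candidate clusters are the nested prefixes of the remaining
districts ordered by Euclidean centroid distance (ties broken by
district id), up to the maximum scanning window size (MSWS), a fraction
of the total size fixed at 50% by default.

**Bernoulli model.** For a window with `c` of the `n` observations as
cases, against `C` cases among `N` overall, the log-likelihood ratio
compares separate inside/outside case probabilities (maximum-likelihood
estimates `c/n` and `(C-c)/(N-n)`) with a common probability `C/N`,
and is set to 0 unless the inside rate exceeds the outside rate
(high-rate scan; the convention `0 log 0 = 0` applies):

$$\mathrm{LLR} = c\log\tfrac{c}{n} + (n-c)\log\tfrac{n-c}{n}
 + c_o\log\tfrac{c_o}{n_o} + (n_o-c_o)\log\tfrac{n_o-c_o}{n_o}
 - C\log\tfrac{C}{N} - (N-C)\log\tfrac{N-C}{N},$$

with $c_o = C - c$, $n_o = N - n$. Window sizes are measured on the
observation totals, so MSWS caps the share of the population at risk.

**Weighted normal model.** District rates are modelled as
$y_i \sim N(\mu, \sigma^2 / w_i)$ with known precision weights $w_i$.
With weighted means inside/outside/overall and pooled variance
estimates $\hat\sigma_1^2$ (two-mean) and $\hat\sigma_0^2$ (one-mean),
the statistic is $(n/2)\log(\hat\sigma_0^2/\hat\sigma_1^2)$ when the
inside mean exceeds the outside mean, else 0. It is invariant to
rescaling all weights by a constant. Window sizes are measured in
districts (MSWS caps the number of districts), and a window must be a
proper subset of the map. $\hat\sigma_1^2$ is floored at `1e-12`:
perfectly separated rates would otherwise give an unbounded ratio; the
floor also defines the statistic as 0 for constant data.

**Monte Carlo inference.** The observed maximum LLR is ranked among
the maxima of `R` null replicates (default 999): for the Bernoulli
model the `C` cases are re-allocated across districts conditional on
the district totals (multivariate hypergeometric, equivalent to
permuting case labels over all `N` individuals); for the weighted
normal model the `(rate, weight)` pairs are permuted jointly across
district locations, following the model's source formulation. Any
cluster with statistic $\lambda$ gets
$p = (1 + \#\{\text{replicate max} \ge \lambda\})/(R+1)$, so p-values
take only the values $m/(R+1)$. `R = 999` resolves $\alpha = 0.05$
comfortably; the engine refuses `R < 19`.

**Reporting.** Candidate windows within the maximum reported cluster
size (MRCS) are selected greedily in decreasing LLR order (ties: the
smaller window, then the lower centre id), keeping a window only if it
shares no district with a previously kept one. Reporting stops at the
first non-significant cluster, but the most likely cluster is always
reported. MRCS may be a fixed fraction (default: equal to MSWS) or
`"gini"`: for each candidate MRCS the significant clusters' observed
versus expected shares (case shares vs population shares for the
Bernoulli model; weighted-rate shares vs weight shares for the
weighted normal, the natural analogue of a count-model collection) are
turned into a Lorenz curve, and the candidate maximising the Gini
coefficient is used, ties going to the smallest candidate, with MSWS
as the fallback when nothing is significant. Gini selection is off by
default in simulation runs, where MRCS = MSWS = 50% keeps iterations
comparable.

## The synthetic study conditions

The simulation emulates the structure of the motivating study without
its (unpublished) real geography:

* **Region**: 250 districts on a jittered rectangular lattice (jitter
  a quarter of the lattice spacing, below the half-spacing bound that
  guarantees tie-free neighbour orderings). District census totals are
  log-normal with median 200,000, clipped to [20,000, 1,000,000];
  `sdlog = 0.6` gives the order-of-magnitude spread between small and
  metropolitan districts typical of national district systems. Totals
  are split into 8 age-by-sex strata with fixed shares
  (0.10, 0.13, 0.13, 0.09, 0.10, 0.13, 0.14, 0.18) — census stratum
  shares are not published, and any fixed split preserves the
  weighting mechanics.
* **True clusters**: model A, one compact 18-district cluster anchored
  in the upper-right quadrant; model B adds a disjoint 12-district
  cluster near the map centre. Each cluster is an anchor plus its
  nearest neighbours, so true clusters are deliberately compact. Note
  a structural consequence: such a cluster is *exactly* one of the
  engine's circular windows, which makes detection on the lattice
  slightly easier than on a real map whose irregular (e.g. coastal)
  clusters no circle matches; sensitivity and PPV here are therefore
  upper ends of what real geography would give, and this is the main
  feature of real data the generator does not emulate.
* **Outcomes**: prevalence 0.3 inside true clusters, 0.2 outside,
  constant across strata; census outcomes `Y_kj ~ B(N_kj, p_k)`.
  Individuals are never materialised — sampling without replacement is
  done with hypergeometric draws, which is distributionally identical
  and far cheaper.
* **Samples**: district sample sizes uniform on 900–920 (redrawn each
  iteration; the scheme is the simplest consistent with "between 900
  and 920"); stratum allocation multinomial with scenario proportions
  (1: SRS, i.e. census shares; 2: the health survey's actual age-sex
  proportions; 3: a more dispersed scheme over-sampling middle ages);
  design weight `N_kj/(n_k q_kj)`; post-stratification ratio
  calibration to the census, so the final weight is `N_kj/n_kj` and
  `sum_j n_kj w^final_kj = N_k` holds to machine precision. Strata
  that happen to draw no respondents carry no weight and are excluded
  from the sums (weights are undefined at `n_kj = 0`).
* **Aggregate inputs**: survey-weighted crude prevalence per district;
  the precision weight defaults to inverse estimated variance from the
  stratified binomial formula with a continuity floor
  `p(1-p) >= 1/(4 n_kj^2)` (keeping weights finite at observed rates
  of 0 or 1); a sample-size weight is available as an alternative,
  since the original study does not state which weight variable its
  aggregate analysis used.
* **Weighted-frequency rounding**: half-to-even at the district level,
  the least distorting way to obtain the integer counts the Bernoulli
  engine needs.

The cluster-sampling stage of the real survey (probability-
proportional-to-size selection of areas, systematic household
sampling) is deliberately not modelled, matching the simplification
of the study being emulated; nor are age adjustment or non-response.

## Evaluation

Per iteration, `D` is the union of districts in significant reported
clusters and `T` the union of true-cluster districts (model B is
scored against the 30-district union, as the study reports one figure
per scenario). Sensitivity is `|T ∩ D|/|T|`; PPV is `|T ∩ D|/|D|`,
undefined when `D` is empty. Undefined PPVs are excluded from the PPV
mean and reported as a count (PPV is a conditional proportion;
imputing 0 is available behind a flag for sensitivity analysis).
Summaries are means and sample standard deviations (denominator
`n - 1`) over iterations.

## Orchestration and problem sizes

`run_scenario()` fixes one hypothetical population per scenario
(regeneration per iteration is available as a robustness option) and
redraws samples each iteration; `run_grid()` crosses the two truth
models with the three sampling scenarios. All randomness derives from
a master seed: iteration `i` samples with seed `master + i` and each
variant's scan uses `master + i + 100000·v`, so per-variant results do
not depend on which other variants run, and identical configurations
give byte-identical outputs.

The package's own reference runs use 50 iterations with 499 Monte
Carlo replicates per scan for the scenario-level summaries and 199
replicates for decision-level checks (type-I error, full-grid
ordering); at `alpha = 0.05` the significance decision is already
well resolved at these replicate counts, and scenario means change
only in the third decimal relative to 100-iteration, 999-replicate
runs. The compiled scan core evaluates roughly 31,000 windows per
replicate on the 250-district map.

## Numerical and design notes

* Distance ties in window construction are broken by ascending
  district id; LLR ties in reporting by the smaller window, then the
  lower centre id — all deterministic.
* The Bernoulli high-rate indicator is evaluated as
  `c * (N - n) > (C - c) * n` to avoid division; window statistics for
  observed data are computed by a vectorised R path and replicate
  maxima by the compiled path, and the two are cross-checked in the
  tests along with brute-force enumeration oracles on small maps.
* A degenerate permutation replicate with zero rate variance yields a
  statistic of 0 by the variance-floor convention.
* The multinomial allocation redraws (with a warning) in the
  measure-zero event that a stratum's sample exceeds its population.

## Known limitations

* The synthetic lattice reproduces compactness, district count, and
  population heterogeneity, but not real adjacency structure or
  irregular cluster shapes; as noted above, this flatters all three
  data types slightly and mostly the individual-level frequency
  approach, whose detected windows on a real map spill over cluster
  boundaries more than on a lattice.
* The weighted normal permutation null carries observed outlier rates
  into every replicate, which is exactly why the aggregate approach is
  conservative about secondary clusters; users scanning very small
  maps (< ~20 districts) should expect discrete, coarse p-values.
* Only high-rate (hot-spot) scans are implemented; low-rate scanning,
  elliptic windows, space-time scanning and covariate adjustment are
  out of scope.
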