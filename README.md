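# fracshift

Non-parametric detection and ranking of treatment-induced protein
redistribution across fractionation profiles.

## The problem

Gradient fractionation experiments (density-gradient ultracentrifugation,
size-exclusion chromatography, or subcellular compartment separation)
measure, for each protein, an intensity profile over an ordered series of
fractions, in several replicates and under two conditions — for example
RNase-treated versus mock-treated lysate. A protein whose in-gradient
distribution shifts after RNase digestion is an RNA-binding or
RNA-dependent protein; a protein that relocates between compartments after
a stimulus is being re-targeted. The analytical task is to decide, per
protein, whether the treated and untreated distribution profiles differ
reproducibly, to rank thousands of proteins by the strength of the
evidence, and to describe each shift's direction and character — all
without assuming a parametric (e.g. Gaussian) peak model, which fits real
profiles poorly near gradient boundaries and for multi-peak complexes.

`fracshift` is for proteomics groups analysing such experiments: it takes
a quantified protein × (sample, fraction) intensity table and a design
table and returns a ranked candidate list with permutation-based
significance estimates and shift descriptors.

## The method

Per protein *i*, each replicate profile is smoothed with a small moving
average along the fraction axis and normalized to a probability
distribution *P<sub>j</sub><sup>i</sup>(x)* over fractions *x* = 1..*F*;
condition means *P̂<sub>±</sub><sup>i</sup>(x)* are averages of the valid
replicate distributions. Profiles are compared with the Jensen-Shannon
distance (log base 2, so JSD ∈ [0, 1]; 0 = identical, 1 = disjoint
support):

    M(x)      = (P(x) + Q(x)) / 2
    D(P‖Q)    = Σₓ P(x) log₂(P(x) / Q(x))
    JSD(P‖Q)  = √( (D(P‖M) + D(Q‖M)) / 2 )

Statistics computed per protein:

- **Effect size** — JSD(P̂₊ ‖ P̂₋) between the condition means.
- **ANOSIM R** — from the matrix of pairwise JSDs between all replicate
  profiles, midranked: R = (r̄_B − r̄_W) / ((n(n−1)/2)/2), the difference
  between mean between-condition and mean within-condition dissimilarity
  ranks. R ∈ [−1, 1]; 1 means perfect condition separation. Being
  rank-based, R is insensitive to the scale of the distances.
- **Permutation p-values** — exact enumeration of the distinct
  treatment/control label assignments (10 for a balanced 3 v 3 design,
  (2n)!/(2(n!)²) in general) gives a per-protein ("local") p-value, which
  cannot reach 0.05 with three replicates; pooling the permuted R values
  of all proteins gives a "global" sampling null, per-protein p-values via
  the add-one estimator, and Benjamini–Hochberg adjusted q-values.
- **R cutoff** — the 95th percentile of the pooled permutation null,
  used to filter candidates.
- **Shift descriptors** — position-wise relative entropy
  w<sub>t</sub>(x) = P̂<sub>t</sub>(x) log₂(P̂<sub>t</sub>(x)/M(x)) against
  the mixture of the two means; the temperature-scaled soft-argmax
  S<sub>t</sub> = Σₓ softmax(β·w<sub>t</sub>)(x)·x locates each
  condition's strongest change; the **relative fraction shift**
  RPS = S₊ − S₋ (negative = leftward/lighter); and the **relative
  distribution change** RDC = H(P̂₊) − H(P̂₋), the Shannon-entropy
  difference in bits (positive = broader after treatment).

Proteins are ranked by decreasing R, then decreasing effect-size JSD.

## Worked example

```r
library(fracshift)

sim <- simulate_dataset(simulation_config(n_proteins = 40,
                                          shifted_fraction = 0.25,
                                          seed = 42))
fit <- run_analysis(sim$dataset, analysis_config(seed = 42, beta = 50))
fit
#> <fs_analysis> 40 proteins (40 testable), R cutoff 0.4074 (95 percentile), 11 passing

head(as.data.frame(fit$results)[, c("protein_id", "anosim_r", "effect_jsd",
     "relative_fraction_shift", "relative_distribution_change",
     "p_global", "p_adj", "rank")], 3)
#>   protein_id anosim_r effect_jsd relative_fraction_shift relative_distribution_change p_global  p_adj rank
#> 1      P0038        1      0.906                   -4.38                       0.0323  0.00277 0.0111    1
#> 2      P0018        1      0.900                   -4.24                       0.0387  0.00277 0.0111    2
#> 3      P0037        1      0.896                   -4.11                      -0.0475  0.00277 0.0111    3

benchmark_ranking(fit$results, sim$truth)$auroc
#> [1] 1
```

The simulation injected a 4-fraction leftward shift into 25 % of the
proteins. The top-ranked proteins all reach R = 1 (every between-condition
profile pair is more dissimilar than every within-condition pair), their
effect-size JSD is ~0.9 (nearly disjoint mean profiles), the estimated
shift of about −4.2 fractions recovers the injected −4 (soft-argmax
estimates carry a small discretization bias), the near-zero entropy
differences show the peaks moved without broadening, and the ranking
separates shifted from unshifted proteins perfectly (AUROC 1). The derived
R cutoff of 0.407 (95th percentile of 360 pooled permuted R values) lets
11 of 40 proteins through.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/fracshift.R simulate --n-proteins 40 --seed 42 --out sim/
Rscript inst/cli/fracshift.R analyze --intensities sim/intensities.tsv \
    --design sim/design.tsv --treatment treatment --beta 50 --seed 42 --out out/
Rscript inst/cli/fracshift.R cutoff --json out/export.json --percentile 95
```

## Output formats

`results.tsv` / `candidates.tsv` columns:

| column | meaning |
|---|---|
| `protein_id` | protein identifier from the input table |
| `anosim_r` | ANOSIM R statistic in [−1, 1] |
| `effect_jsd` | JSD between condition mean distributions, [0, 1] |
| `relative_fraction_shift` | S₊ − S₋ in fractions; negative = leftward; empty in categorical mode |
| `relative_distribution_change` | entropy difference H(P̂₊) − H(P̂₋) in bits |
| `rank` | 1 = strongest candidate; empty for untestable proteins |
| `p_global` | add-one permutation p-value against the pooled null |
| `p_adj` | Benjamini–Hochberg adjusted `p_global` |
| `testable_flag` | `true`/`false`; untestable rows carry empty statistics |
| `p_local` | exact (or Monte-Carlo) per-protein permutation p-value |
| `mean_within_jsd_treatment` / `_control` | mean pairwise replicate JSD per condition (reproducibility diagnostic) |
| `reason` | why a protein is untestable, if it is |

`bubble.tsv` holds the plot-ready triple x = shift, y = entropy change,
size = effect JSD plus optional group tags. `export.json` is a
self-contained document (`schema_version` "1.0") with the config echo, the
fraction axis, the sample table, per-protein records (statistics,
replicate and mean distributions, valid-sample mask), the pooled null R
values and the derived cutoff; `manifest.json` records tool version, seed,
input MD5 digests and counts.

A note on preprocessing: missing cells are treated as zero intensity at
profile level (a message reports how many). If imputation is wanted it
must happen upstream; a common eligibility rule restricts imputation to
proteins within the 95 % lowest mean within-condition JSD (i.e. proteins
whose replicates agree well), which is the diagnostic the
`mean_within_jsd_*` columns expose.

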