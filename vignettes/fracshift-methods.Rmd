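---
title: "Detecting protein redistribution across fractionation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein redistribution across fractionation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracshift)
```

## The model

A fractionation experiment measures, for each protein $i$, an intensity
profile over fractions $x \in \{1,\dots,F\}$ in replicate $j$ under two
conditions $t \in \{+,-\}$ (treatment and control). `fracshift` treats
each profile, after smoothing and normalization, as a probability
distribution $P^i_j(x)$ — "where along the gradient is this protein's
mass?" — and asks whether the treated and untreated distributions differ
reproducibly.

This framing makes three assumptions worth stating. First,
normalization discards total abundance: a protein that changes amount but
not localization is invisible by design. Second, profiles are
compositional — only relative mass across fractions matters — so replicate
noise is noise on the probability simplex, not additive noise on
intensities. Third, the test is non-parametric: no peak-shape model is
fitted, which trades some power under ideal Gaussian peaks for robustness
to boundary pile-ups (e.g. ribosome-scale complexes accumulating in the
last fraction) and irregular multi-peak profiles.

### Distance between profiles

Profiles are compared with the Jensen-Shannon distance with base-2
logarithms,

$$M(x) = \tfrac12\left(P(x)+Q(x)\right), \qquad
D(P\|Q) = \sum_x P(x)\log_2\frac{P(x)}{Q(x)}, \qquad
\mathrm{JSD}(P\|Q) = \sqrt{\tfrac12\left(D(P\|M)+D(Q\|M)\right)},$$

a bounded metric on distributions: 0 for identical profiles, 1 for
disjoint support. (The bounds follow from the equations; descriptions
that attach 0 to "disjoint" invert the convention.) Because each KL term
is measured against the mixture $M$, the distance is always finite and is
not destabilised by the many exact zeros typical of gradient data. The
distance is pluggable (`register_distance()`), but JSD is the default and
the only shipped choice.

### Significance: rank-based ANOSIM with permutation nulls

For each protein the pairwise JSDs between all valid replicate profiles
(both conditions pooled) form a dissimilarity matrix. ANOSIM midranks the
$n(n-1)/2$ dissimilarities and contrasts between- versus within-condition
mean ranks:

$$R = \frac{\bar r_B - \bar r_W}{\left(n(n-1)/2\right)/2} \in [-1, 1].$$

$R = 1$ means every between-condition pair is more dissimilar than every
within-condition pair. Midranks are used for ties (standard rank-test
practice); consequently $R$ is invariant under any strictly increasing
transform of the distances.

Significance comes from label permutations. The number of *distinct*
assignments of $n_+ + n_-$ samples to two groups is
$\binom{n_++n_-}{n_+}$, halved when balanced because $R$ is symmetric in
the group labels: $(2n)!/(2(n!)^2)$, which is 10 for a balanced
3 v 3 design. The per-protein ("local") exact p-value includes the
identity assignment, so its floor at 3 v 3 is $0.1$ — three replicates
can never reach $\alpha = 0.05$ protein by protein. The "global" mode
therefore pools the permuted $R$ values of all testable proteins into one
sampling null (assuming permuted $R$ of different proteins share a
distribution — the same kind of information-sharing assumption moderated
tests make across genes) and computes per-protein p-values with the
add-one estimator $p = (1 + \#\{R_{null} \ge R_{obs}\})/(1 + N)$,
followed by Benjamini–Hochberg adjustment across testable proteins.

Design choices in this area that the literature leaves open, resolved
here: the identity assignment is *excluded* from the pooled null by
default (`include_identity_in_null = FALSE`), because including observed
labelings would contaminate the null with true signal; the test is
one-sided (large $R$); exact enumeration is used while the per-protein
assignment count is at most `exact_limit` (default 10\,000), with seeded
Monte-Carlo sampling beyond. Pooling distinct assignments rather than all
$(2n)!$ label orderings changes nothing: every distinct assignment occurs
with equal multiplicity among the orderings, so all percentiles agree.
Over a complete enumeration with the identity included the pooled $R$
values average to zero exactly, a symmetry the test suite checks to
$10^{-12}$.

Candidate selection uses a percentile (default the 95th, linearly
interpolated) of the pooled null as an $R$ cutoff, rather than a fixed
universal threshold: the null $R$ spread differs between experiments with
different noise, so the cutoff adapts to the dataset. The cutoff ranks
candidates; it does not control a stated error rate.

### Shift descriptors

Where and how did the distribution change? Both condition means are
scored against their mixture $M$ with the position-wise relative entropy
$w_t(x) = \hat P_t(x)\log_2(\hat P_t(x)/M(x))$ (0 where
$\hat P_t(x)=0$), whose sum is exactly $D(\hat P_t\|M)$. The expected
position of the strongest change is the temperature-scaled soft-argmax

$$S_t = \sum_x \frac{e^{\beta w_t(x)}}{\sum_{x'} e^{\beta w_t(x')}}\,x,$$

and the relative fraction shift is $\mathrm{RPS} = S_+ - S_-$ (negative =
leftward, towards lighter fractions). The relative distribution change
$\mathrm{RDC} = H(\hat P_+) - H(\hat P_-)$ (Shannon entropy, bits) is
positive when treatment broadens the distribution and negative when it
sharpens. RPS, RDC and the effect-size JSD together form the standard
bubble-plot triple (x, y, bubble size).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `kernel_size` | 3 | fractions | moving-average smoothing window (odd); forced to 1 on categorical axes |
| `beta` | 1 | 1/bits | soft-argmax temperature; larger → closer to hard argmax |
| `cutoff_percentile` | 95 | % | percentile of the pooled null used as R cutoff |
| `permutation_mode` | exact | — | exact enumeration vs Monte-Carlo |
| `n_monte_carlo` | 999 | draws | Monte-Carlo sample size |
| `exact_limit` | 10000 | assignments | per-protein count above which Monte-Carlo is used |
| `include_identity_in_null` | FALSE | — | whether observed labelings enter the pooled null |
| `seed` | 1 | — | seed for every stochastic step |

On `beta`: $S_t$ is a softmax expectation over *all* $F$ positions, so
positions with $w_t \approx 0$ pull $S_t$ towards the profile centre
$(F+1)/2$ unless $\beta\,\max w$ is large. The $w$ values of typical
normalized profiles are a few tenths of a bit, so at $\beta = 1$ RPS is a
strongly shrunken (conservative) shift indicator, useful for ranking
direction; quantitative shift-length estimates need $\beta$ large enough
that the softmax concentrates — $\beta \approx 50$ recovers injected
integer shifts to within ~0.1 fraction for sharp peaks in the simulations
below. `beta` must be chosen per dataset; it trades robustness to
plateau-like $w$ profiles (low $\beta$) against localisation accuracy
(high $\beta$). A second caveat is intrinsic to the statistic, not to
$\beta$: when the two condition peaks overlap substantially (peak width
not small against the shift distance), the $w_t$ maxima are pushed away
from the opposing peak and RPS overshoots the true displacement; and for
a symmetric broadening without displacement the $w_+$ maxima sit in two
symmetric flanks, so a large $\beta$ would pick one flank arbitrarily
while a small $\beta$ correctly averages to "no shift". Interpret the
shift direction only when effect size and $R$ are clearly discernible.

On `kernel_size`: smoothing is a uniform moving average with
*zero-padding* at the gradient boundaries — no protein mass exists
outside the measured range, and mass the window loses at the edges is
restored by the subsequent normalization (the choice matters only for
boundary-peaked profiles, where it slightly flattens the edge). The
default of 3 is the smallest non-trivial window. On categorical axes
(subcellular compartments) neighbouring bins are not ordered, so the
kernel is forced to 1 and only order-free statistics (effect JSD, RDC,
ANOSIM) are reported; RPS and $S_t$ are not applicable.

## Degenerate inputs and numerical conventions

Missing intensity cells become zero before smoothing (absence of MS
signal treated as absence of the protein in that fraction; the count is
reported). Imputation, if wanted, belongs upstream; the
`mean_within_jsd_*` diagnostics support the common eligibility rule of
imputing only proteins within the 95 % lowest mean within-condition JSD.
All-zero sample profiles cannot be normalized and are marked invalid; a
protein stays testable while both conditions keep ≥ 2 valid samples, and
condition means divide by the number of *valid* samples so they remain on
the simplex. Untestable proteins are never dropped silently — they carry
an explicit reason, sort after all ranked proteins, and are excluded from
the BH denominator (they have no p-value). Information-theoretic
conventions: $0\log 0 = 0$ everywhere; the infinite KL branch is guarded
but unreachable against mixtures; the soft-argmax subtracts
$\max(\beta w)$ before exponentiating for overflow safety. Permutation
p-values include the identity (local) or use the add-one form (global),
so no p-value is ever 0. Ranking ties break by decreasing effect JSD,
then ascending protein identifier, making the order total and
reproducible; percentiles use linear interpolation (`quantile()` type 7).

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the phenomenology the statistics rely on:
localized bell-shaped peaks (discretized Gaussians, default width 1
fraction — sharp, well-localized complexes) at random in-range positions;
treatment moving a fraction $\varphi$ of the mass by $\Delta$ fractions
with optional broadening (partial shifts emulate complexes of which only
a subpopulation redistributes); replicate noise as Dirichlet
(perturb-and-renormalize) draws on the simplex with concentration
$\propto 1/\texttt{noise}$, because normalized profiles are
compositional; whole-sample missingness; and log-normal total-intensity
variation between replicates. At `noise = 0` replicates are exact copies
of their condition mean, including totals. Peak positions are drawn so
both the base and the shifted peak fit inside the axis; a shift for which
no admissible positions exist is a configuration error.

It does not emulate peptide-level acquisition effects (LFQ/iBAQ quirks,
shared peptides), irregular multi-peak or boundary-piled real profiles,
fraction-to-fraction carryover, or correlated noise between neighbouring
fractions. Passing the simulation-based tests therefore shows the
statistics recover the structure they model — localized partial shifts
under compositional noise — not that every real profile shape is handled
gracefully.

## What the tests establish

The test suite verifies, among others: the hand-derived values of the
distance and entropy primitives; metric axioms of the JSD on $10^4$
random simplex triples (symmetry exact, triangle inequality to
$10^{-12}$); agreement of ANOSIM R with an independent community-ecology
implementation and with brute-force oracles on random instances;
enumeration counts against the closed forms for group sizes 2–4; the
exact zero mean of complete enumeration nulls; and, on simulated data
(problem sizes chosen to exercise the method at realistic scale: 50–500
proteins, $F = 20$, 3 v 3 and 4 v 4 replicates), recovery of injected
shifts ($|\mathrm{RPS} - \Delta| < 0.25$ at zero noise with
$\beta = 50$; Spearman correlation of RPS with $\Delta \ge 0.9$ at low
noise), ranking of truly shifted proteins (AUROC $\ge 0.95$ in the
strong-shift scenario, shifted median rank below unshifted), and type-I
control of the global p-values on pure-null data (false-positive fraction
within the 95 % binomial interval around 0.05 at 500 proteins, 4 v 4 —
a design whose exact enumeration resolution, $1/35$, lies below 0.05).

## Known limitations

Abundance-only changes are invisible after normalization. Three
replicates cannot yield per-protein significance; the global mode buys
power by assuming exchangeable permuted $R$ across proteins, which mild
heterogeneity violates only weakly but strong heterogeneity (mixed
designs, very different tie structures) would bias. The percentile
cutoff is a ranking device, not an error-rate guarantee. Soft-argmax
shift lengths are biased for broad or strongly overlapping peaks (see
above) and RPS reports a direction even for near-identical profiles —
filter on $R$ and effect size before interpreting it. The interfaces
deliberately exclude GUI/serving concerns; the CLI exposes every
configuration key as a flag rather than a separate config-file schema.
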