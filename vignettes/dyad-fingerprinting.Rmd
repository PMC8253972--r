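---
title: "Parent-child dyad fingerprinting: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-child dyad fingerprinting: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadprint)
```

## The question and the statistic

Given a cohort of matched parent–child pairs ("dyads") with one brain
feature vector per subject — functional connectivity (FC) edges, regional
gray matter volumes (GMV), or their concatenation (COMB) — we ask whether a
child can be matched to their own parent from these vectors alone. The
similarity between child $i$ and parent $j$ is the Pearson correlation
$S(i,j)$ of their feature vectors. The identification score is the
*winning rate*: for each child, the fraction of the $N-1$ stranger parents
whose similarity is exceeded by the own parent's, with exact ties given
half credit; the cohort *accuracy* is the mean winning rate.

Two properties motivate this statistic over conventional rank-1
fingerprinting. First, its chance level is exactly 50% for every cohort
size, so accuracies are comparable across datasets and subgroups of
different $N$; rank-1 identification has chance level $1/N$. Second, it
uses the whole ranking rather than only the top rank, which buys
statistical power: a parent ranked second among 84 still contributes 82/83
rather than zero. The two statistics agree at the ceiling — winning-rate
accuracy is 1 exactly when rank-1 accuracy is 1, since both require the
diagonal to be the strict row maximum. The package also provides the
Monte-Carlo "sampling procedure" formulation (draw a random child and a
random stranger parent, score the pairwise comparison), which converges to
the winning rate as draws increase and is useful mainly as a definitional
cross-check.

Identification is child-centric by default (a child's vector is correlated
against all parents), matching the design in which each child is the probe;
`direction = "parent"` transposes the comparison.

## Inference

*Bootstrap.* The 95% CI of accuracy comes from 1,000 iterations, each
subsampling 90% of the dyads **without replacement** and recomputing the
statistic on the retained sub-matrix of similarities; the interval is the
2.5th/97.5th percentile of the draws. This is the subsampling scheme the
framework defines, and we implement it exactly. A known limitation follows
from the construction: the spread of the statistic across 90% subsamples of
one cohort is substantially smaller than the sampling variability of the
statistic across cohorts (for a null cohort at $N = 84$ roughly 0.011
versus 0.034), so these intervals describe the stability of the estimate
under subject dropout rather than frequentist coverage of the population
value — under a true null they contain 50% in only about half of replicate
cohorts. Tests that probe coverage document this behaviour.

*Permutation.* Significance against chance uses 1,000 uniform random
permutations of the parent assignment (fixed points allowed — the standard
exchangeability null; derangements would slightly distort it). P-values use
the add-one convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_\text{perm})$, so $p$ is never zero and the floor at 1,000 permutations
is $1/1001$, reportable as $p < 0.001$. Per-network analyses generate their
null separately for each feature mask, so differing mask sizes are
accounted for.

*Paired network comparisons.* Contrasts between modalities, ages, sexes, or
phenotype halves are paired t-tests across the network-level accuracies
(10 networks plus the whole-brain entry, hence $df = 10$), with a
paired-difference Hedges' $g = J\,\bar d/s_d$, $J = 1 - 3/(4\,df - 1)$. The
$g$ variant on paired differences is a documented choice; the averaged-
variance variant is not implemented.

## Edge measures

With each subject's vector standardized to zero mean and unit sample SD
across its own features, the dyad product $\phi_{ii}(f) = X_i^{c}(f)
X_i^{p}(f)$ decomposes the similarity: $\sum_f \phi_{ii}(f)/(M-1) =
S(i,i)$. The empirical probability that stranger products beat the dyad
product,
$$P_i(f) = \frac{\#\{j \ne i: \phi_{ji}(f) > \phi_{ii}(f)\} +
                \#\{j \ne i: \phi_{ij}(f) > \phi_{ii}(f)\}}{2(N-1)},$$
is floored at $1/(2(N-1))$ (a clean sweep is treated as "less than one
losing comparison") so that the differential power $DP(f) = \sum_i -\ln
P_i(f)$ stays finite. The denominator is $2(N-1)$: each dyad has exactly
$N-1$ strangers per comparison direction. Group consistency
$\bar\phi(f)$ is the mean dyad product — features high in everyone, hence
unhelpful for telling dyads apart.

Two conventions deserve note. Standardizing each subject's vector before
taking products is applied by default because without it the products are
dominated by feature scale and no longer decompose the Pearson similarity
the rest of the framework uses; `standardize = FALSE` gives raw products
for sensitivity analyses. Percentile selection (`top_percentile`) keeps a
feature when the fraction of features with values less than or equal to
its value exceeds the requested percentile; this empirical-CDF rule keeps
all ties at the cut, selects exactly the top feature of 400 distinct values
at the 99.75th percentile, and approaches "all features" as the percentile
approaches zero — interpolated quantile definitions satisfy none of these
simultaneously.

## Preprocessing utilities

Motion scrubbing removes each frame with FD > 0.5 mm together with its
predecessor and the two following frames; windows are clipped at the series
boundaries, and overlapping windows from consecutive offenders are unioned.
The motion distribution vector is a 20-bin histogram of FD over $[0, 1]$ mm
in 0.05 steps (values above 1 mm clipped into the last bin), normalized to
sum to 1; since downstream comparison is by Pearson correlation, which is
location- and scale-invariant, the counts-versus-proportions choice cannot
change any accuracy. Confound residualization regresses each feature column
on an intercept plus the confounds by OLS. The top-25% motion exclusion
removes dyads whose child is in the top quarter of mean FD at any provided
timepoint, excluding all subjects tied at the cut (conservative). Phenotype
outliers are scores strictly above mean + 1.5 sample SD (denominator
$n-1$); note that for a vector of $n-1$ identical values plus one outlier
this threshold lands exactly on the outlier, so the strict rule retains it
— a boundary case that cannot occur with continuous data. Median splits
send ties at the median to the lower half (deterministic); any strictly
monotone transform of the scores, such as the square-root transform applied
to testosterone, leaves the split unchanged.

## The synthetic cohort generator

The generator exists because real parent–child neuroimaging cohorts are
access-restricted; it reproduces the statistical structure the analysis
assumes, not real brains. Parents are drawn as $p_i(f) \sim N(\mu_f, 1)$;
children as
$$c_i(f) = \alpha_f\,(p_i(f) - \mu_f) + \sqrt{1 - \alpha_f^2}\,
\varepsilon_{if} + \mu_f, \qquad \varepsilon_{if} \sim N(0,
\sigma_\text{noise}),$$
the minimal Gaussian shared-component model with exact target correlation:
with $\sigma_\text{noise} = 1$, $\mathrm{corr}(c_i(f), p_i(f)) = \alpha_f$.
Defaults are chosen once to emulate a realistic dyad-cohort design: $N = 84$ dyads
(with the cohort's 45/39 son/daughter ratio), a 268-node parcellation
(35,778 FC edges, 268 GMV regions) grouped into 10 functional networks, two
possible child timepoints, and per-feature transmission
$\alpha = (\text{FC } 0.003,\ \text{GMV } 0.046)$. These small per-feature
values are deliberate: identifiability accumulates over features roughly as
$\Phi(\alpha\sqrt{M/2})$, so at whole-brain feature counts they place
whole-brain winning-rate accuracy in the mid-60s (FC) and low-70s (GMV)
percent range — the regime reported for parent–child identification —
rather than at the ceiling. Discriminative features (elevated
$\alpha_f$), group-consistent features (a shared mean offset $\mu_f$ of
random sign, which raises $\bar\phi$ without aiding identification),
per-network overrides, per-timepoint alphas, and covariate-linked alpha
deltas (by sex or by the upper half of a phenotype score) are all
plantable, and the full ground truth is returned. Testosterone-like scores
are generated on a squared scale and square-root transformed downstream;
the CBCL-like score is the mean of two simulated subscores.

What the generator does *not* emulate: covariance between features (edges
are independent given the parent; real FC has strong community structure),
heavy-tailed or site-dependent noise, age-related mean shifts, and any
genuine biology of transmission. Passing tests therefore certify the
statistical machinery — chance-level calibration, monotone dependence on
transmission strength, resampling validity, planted-effect recovery — not
claims about real cohorts.

## Numerical choices and degenerate inputs

Ties in similarity earn half credit, which keeps the null expectation at
exactly 50% even on degenerate (e.g. constant) inputs; ties are
measure-zero for continuous data. Zero-variance feature vectors are an
error naming the subject, as is an empty feature mask or a mask below three
features. Missing values are errors, not imputed, matching the exclusion-
based handling of incomplete subjects. Edge features are labelled by their
node pair (`"a-b"`), and every mask keys on labels, never positions, so the
internal lower-triangle ordering (row-major over $i > j$) is a private
convention with no effect on results. Asymmetric input matrices are
rejected with the worst-offending entry named. Cohort constructors require
$N \ge 3$ and a bijective dyad map; subgroup analyses additionally require
three dyads per subgroup. In subgroup splits the stranger set is restricted
to the subgroup by default (each half is analysed as its own cohort), with
`strangers = "all"` available since the alternative reading — scoring each
child against every parent — is also defensible.

One saturation effect matters when interpreting simulations: once
$\alpha\sqrt{M}$ is large the winning rate reaches 1.0 exactly (at
$M = 500$ this happens already near $\alpha = 0.4$, where the probability
that any single stranger comparison is lost is of order $10^{-11}$), so
accuracy comparisons across strong-transmission settings must use feature
counts below saturation to be informative; the monotonicity property tests
use $M = 50$ for this reason.

## Problem sizes used in the test suite

The suite exercises the cohort-scale statistics where the property demands
it (null calibration at $N \in \{10, 84\}$ with 200 replicate cohorts;
alpha recovery at $M = 2000$; bootstrap behaviour at $n_\text{boot} =
1000$) and otherwise verifies exact oracles at small sizes (3-dyad
enumerations, 4–8 dyad brute-force correlation loops), keeping the default
run inside a few minutes on one CPU. The pipeline demo uses a 12-node
cohort purely to exercise the plumbing.

## Known limitations

The subsampling CI limitation discussed above; no analytic CI for the
accuracy statistic; Pearson similarity only (no Spearman or cosine
variants); no image-level preprocessing (the package starts from extracted
feature tables); the best-modality count test uses an explicit
uniform-thirds null as its chance model; and the Hedges' $g$ variant is the
paired-difference form.
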