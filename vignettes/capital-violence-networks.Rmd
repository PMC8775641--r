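---
title: "Estimating capital–violence networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating capital–violence networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

## The scientific problem

Survey studies of sexual violence ask whether a woman's stock of social,
economic and human capital — how often she is in contact with family,
friends, neighbours, religious communities and other networks; her
socio-economic level and economic dependence; her own and her partner's
education; her endorsement of traditional gender stereotypes — protects
her from, or exposes her to, sexual victimization in four interpersonal
spheres: public spaces, the workplace, the educational environment, and
the couple relationship.

`capnet` implements the full analysis pipeline such a study needs:

1. **Variable construction** (`derive_outcome()`, `score_stereotypes()`,
   `cronbach_alpha()`, `binarize()`): each sphere's yes/no items collapse
   into a lifetime indicator; a 13-item Likert stereotype scale is scored
   after reverse-coding its egalitarian items; everything is dichotomized
   for network estimation.
2. **Ising network estimation** (`fit_nodewise()`): a signed weighted
   network over all 15 analysis variables, estimated by nodewise
   L1-penalized logistic regression with EBIC model selection (the eLasso
   approach).
3. **Bootstrap stability** (`bootstrap_networks()`): nonparametric
   resampling of respondents to check that edge weights are stable.
4. **Two-mode analysis** (`split_by_sign()`, `centrality_table()`): the
   factor × outcome coefficient block is split by sign into a bipartite
   *protection* network (negative coefficients: more of the factor, less
   violence) and a *risk* network (positive coefficients), and nodes are
   ranked by two-mode normalized degree and closeness.

Because the underlying survey micro-data are external, the package ships a
synthetic-data module that makes every stage testable at desk scale, plus
the published 11 × 4 coefficient table as a fixture so the two-mode stage
can be validated cell-for-cell against the published centrality tables.

## The Ising model and its estimator

The joint distribution over binary analysis variables
$x \in \{0,1\}^p$ is the Markov random field

$$P(x) \propto \exp\Big(\sum_j \tau_j x_j + \sum_{j<k} \omega_{jk} x_j x_k\Big),$$

with node thresholds $\tau_j$ and symmetric pairwise couplings
$\omega_{jk}$. Its full conditionals are logistic regressions:
$P(x_j = 1 \mid x_{-j}) = \mathrm{logit}^{-1}(\tau_j + \sum_k \omega_{jk}
x_k)$, so each $\omega_{jk}$ can be estimated by regressing node $j$ on
the remaining nodes. `fit_nodewise()` does this with an L1 penalty along
a 50-point log-spaced grid from $\lambda_{\max}$ (the smallest penalty
that zeroes all slopes, verified by the KKT condition
$\lambda_{\max} = \max_k |x_k'(y-\bar y)|/n$) down to
$0.01\,\lambda_{\max}$, and selects each node's model by the extended BIC

$$\mathrm{EBIC}_\gamma = -2\ell + k\log n + 2\gamma k \log(p-1),$$

with $\gamma = 0.25$ by default. Ties in the EBIC minimum are broken
toward the first (largest-$\lambda$, sparsest) grid position for
deterministic reproducibility. The two directed estimates per pair are
symmetrized by the **AND** rule (edge only if both are nonzero; default)
or the **OR** rule (either), the weight being their average in both
cases. We chose {0,1} rather than {−1,+1} states so that the logistic
slopes estimate the couplings directly; the {−1,+1} equivalent has
couplings $\omega/4$ and thresholds $\tau/2 + \sum_k \omega_{jk}/4$.

The lasso path itself is computed by `glmnet` (no standardization —
predictors are already 0/1; convergence tolerance `1e-7`, iteration cap
`1e4`); the package's contribution is the nodewise orchestration, EBIC
selection, symmetrization, and everything downstream. Published
applications of this estimator sometimes report fully dense
factor × outcome blocks, which EBIC-sparsified fits essentially never
produce; `gamma = 0` (plain BIC) and a smaller `lambda_min_ratio` give a
denser mode for qualitative comparison.

### Choosing between AND and OR

The AND rule is deliberately conservative: an edge must survive selection
from both sides. On planted models whose outcomes are rare (5–17%
prevalence, matching the study conditions), that conservativeness shows
up exactly where theory predicts — the regression of a *factor* on the
others carries little information about a rare outcome, so weak
factor–outcome edges are sometimes selected in only one direction. On
the reference planted design (effect size 0.5, n = 5000) the AND rule
recovers about 86% of planted bipartite signs and makes *no* sign errors;
the OR rule recovers essentially all of them. The package therefore uses
the OR rule for sensitivity-oriented recovery benchmarks and keeps AND as
the estimation default; the test suite asserts both that OR recovery is
at least 90% and that AND never flips a sign and is always a sub-network
of OR.

## Synthetic data

Two generators serve two different purposes.

**`sample_ising()`** draws from a known Ising model by sequential-scan
Gibbs sampling (Rcpp), with full conditionals as above. Defaults: 200
burn-in sweeps, one retained row per 10 sweeps — generous for the
coupling magnitudes used here (|ω| ≤ 2), and verified in the test suite
against exact enumeration (`enumerate_distribution()`, feasible to
p = 15): total-variation distance below 0.02 at 10⁵ retained samples for
p ≤ 4. This generator carries real dependence and is what the estimator
is validated on.

**`make_planted_model()`** builds the validation ground truth: the
factor × outcome coupling block takes the sign pattern of the published
coefficient table (21 negative, 23 positive cells) at a chosen magnitude
(default 0.5 — a moderate conditional log-odds ratio), factor–factor
couplings default to none (`within_block_density = 0`; the bipartite
block is the object under study), and thresholds are calibrated so
outcome prevalences match the study's reported 17%, 5.9%, 12% and 6.4%
and factors sit near 50%. Calibration starts at the mean-field solution
$\tau_j = \mathrm{logit}(p_j) - \sum_k \omega_{jk} p_k$ and refines it
with four pilot Gibbs runs of 2000 rows each; it is deterministic given
the seed.

**`generate_survey_like()`** draws raw survey *columns independently*
from the published marginal distributions (outcome prevalences; contact
frequencies; stereotype item distributions; socio-economic and education
levels). Two marginals the source tables do not print — economic
dependence and partner education — use package-chosen plausible
distributions (a 40/35/25 low/medium/high split, and the respondent's own
education distribution, respectively), and contact-frequency rows that do
not sum to 100% (item nonresponse) are renormalized. Because draws are
independent, this generator tests *plumbing* (loading, validation,
scoring, binarization, end-to-end reproducibility), not dependence
recovery; passing those tests says nothing about how the estimator would
behave on the real survey's joint distribution, multistage sampling
design, or missingness patterns — all out of scope here.

## Variable-construction conventions

Where the source analysis is silent, the package fixes conventions and
documents them:

- **Missing data**: listwise deletion of respondents with any missing
  analysis variable, with the deletion count logged (`binarize()`
  messages it). No imputation.
- **Dichotomization**: binary items map no/yes to 0/1; ordinal, Likert
  and numeric score variables split at their sample median with ties
  assigned to 0. When the median *is* the top observed level (heavily
  skewed variables — e.g. 90% of respondents report weekly family
  contact), nothing lies above it and ties join the 1 side instead, so
  the column reads "at least the median level" and both classes stay
  nonempty. How ordinal capitals entered the published model is
  undisclosed, so this is a documented divergence risk, not a claim of
  equivalence.
- **Contact frequencies** are ordered never < yearly < monthly < weekly
  (frequency order, not questionnaire column order) before the median
  split.
- **Reverse coding**: the two egalitarian stereotype items ("may
  participate in a social activity...", "can choose her friends...") are
  reverse-coded ($x \to 6 - x$) so higher scores always mean stronger
  traditional-stereotype endorsement.
- **Outcome windows**: each sphere indicator is a single any-yes over its
  items, with no time stratification.
- A respondent with some but not all stereotype items missing gets the
  mean of her available items; only all-missing yields a missing score.

## Two-mode centrality and the unreachable-distance convention

After the sign split, edge weights are discarded: any nonzero
coefficient, however small, creates one unweighted bipartite edge (the
published risk table counts a cell of magnitude 0.013 as an edge).
For a node whose own mode has $n_\mathrm{same}$ members and the opposite
mode $n_\mathrm{other}$:

- **degree** = (incident edges) / $n_\mathrm{other}$;
- **closeness** = minimum possible farness / actual farness, where the
  minimum farness is $n_\mathrm{other} + 2(n_\mathrm{same}-1)$ (every
  opposite-mode node at distance 1, every same-mode node at distance 2)
  and actual farness sums BFS geodesics over all other nodes.

Disconnected pairs need a finite stand-in distance. The package assigns
**the maximum finite geodesic in the network plus one** — a convention
reverse-engineered empirically: it reproduces every published centrality
value including the isolated nodes (closeness 0.34 for a 15-node network
of diameter 4, i.e. numerator 24 over farness 14 × 5). The alternative
convention (distance = node count) is available behind the `unreachable`
argument. A network with no edges at all has no finite geodesic; all
off-diagonal distances are then set to 1 by convention (logged), which is
degenerate and only occurs for empty inputs. The published tables use the
label "Education networks" for the node the coefficient table calls
"Educational level"; structural position confirms they are the same node,
and node names in this package follow the coefficient table.

An independent Floyd–Warshall implementation in the test suite confirms
the closeness values on hundreds of random bipartite graphs, and the
published tables are reproduced cell-for-cell (60 values at 2-decimal
rounding) from the shipped coefficient fixture.

## Bootstrap

`bootstrap_networks()` resamples *respondents* with replacement
(B = 1000 in the motivating analysis; tests use B = 200), refits the
entire nodewise pipeline per replicate, and reports per-edge means,
2.5%/97.5% quantiles and inclusion proportions. Replicates where a column
becomes constant are dropped and counted rather than redrawn — redrawing
would bias the resampling distribution. Replicate $b$ draws its indices
under seed $\mathrm{seed} + b$, so a run is reproducible and individual
replicates can be recomputed in isolation. Concordance is summarized by
the rank correlation between bootstrap means and sample weights over the
sample network's edges; exact-zero sample weights are excluded from the
rank correlation because they are pure ties.

## Problem sizes used in the test suite

The suite validates each claim at the smallest scale that makes it
sharp: enumeration oracles at p ≤ 4 with 10⁵ Gibbs draws; estimator
recovery on the 15-node planted design at n = 5000 over 10 seeds; null
specificity at n = 2000 over 20 seeds; bootstrap concordance at n = 5000,
B = 200; closeness oracles on 200 random graphs with at most 12 nodes.
These sizes were chosen as the package's own validation design.

## Known limitations

- The published network itself is not reproducible without the external
  survey micro-data and its undisclosed preprocessing; the package treats
  the published coefficient table as input for the two-mode stage and its
  prevalences as generator calibration targets only.
- The survey-like generator has independent columns; it cannot exercise
  dependence recovery (the Ising generator does).
- Median-split dichotomization discards ordinal information; hybrid
  (mixed ordinal/binary) graphical models are out of scope.
- No survey weights or multistage design: synthetic respondents are
  i.i.d. draws.
- Layout (`fruchterman_reingold()`) is cosmetic, seeded for
  reproducibility, and never feeds any statistic.
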