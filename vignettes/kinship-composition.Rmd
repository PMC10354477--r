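---
title: "Kinship composition of social units: models, criteria and machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship composition of social units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincomp)
```

## The problem

Mean pairwise relatedness is the standard group-level summary of kinship
structure, but it is a central tendency: a group of three first cousins and
a group containing a half-sibling pair plus an unrelated cousin both have
mean relatedness $\bar r = 0.125$, yet one consists entirely of kin dyads
and the other mixes kin and non-kin. `kincomp` implements *kinship
composition* — a group-level label recording whether the same-sex adult
dyads of a social unit are all kin (`RELATED`), all non-kin (`UNRELATED`)
or both (`MIX_RELATED`) — together with the continuous alternative, the
proportion of kin dyads, and the comparative machinery needed to analyse
such labels across species.

```{r}
cousins <- pedigree(
  id   = c("GM","GS","A","B","C","FA","FB","FC","x1","x2","x3"),
  dam  = c(NA, NA, "GM","GM","GM", NA, NA, NA, "A","B","C"),
  sire = c(NA, NA, "GS","GS","GS", NA, NA, NA, "FA","FB","FC"))
u <- social_unit("cousin_trio", c("x1","x2","x3"), "F")
classify_composition(cousins, u, policy = "permissive")
```

## Pedigree relatedness

Relatedness is computed from pedigrees, not markers. The kinship
coefficient $f(i,j)$ — the probability that homologous alleles drawn one
from each individual are identical by descent — follows the standard
tabular recursion in topological order,
$f(i,i) = \tfrac12\,(1 + f(d_i, s_i))$ and
$f(i,j) = \tfrac12\,(f(d_i,j) + f(s_i,j))$ for $j$ not a descendant of
$i$, with unknown parents contributing zero. Dyadic relatedness is the
numerator coefficient $r = 2f$.

Numerical/design choices:

* **No inbreeding normalization by default.** The comparative sources
  treat founders as outbred and never invoke inbreeding; the normalized
  form $2f/\sqrt{(1+F_i)(1+F_j)}$ is available via `normalized = TRUE`.
  How inbred dyads should be *classified* is genuinely unstated in the
  source literature; the package computes their $r$ but takes no stance.
* **Founders are mutually unrelated by definition**, and unknown parents
  behave as fresh unrelated founders. This is what makes truly unrelated
  units hard to certify from shallow field pedigrees.
* Evaluation order is topological with ties broken by id sort; the order
  cannot change the value (the recursion is order-invariant on DAGs) but
  fixes byte-level determinism of outputs.
* Correctness is checked against a *gene-dropping* oracle: founder alleles
  are transmitted through the pedigree in Monte Carlo, and IBD sharing is
  compared to the recursion within 3 standard errors.

## The two-generation kin criterion

A same-sex dyad is **kin** if one member is the other's parent or
grandparent, or if the two share at least one known parent or known
grandparent. Anything deeper is invisible to the criterion, which keeps it
usable with the shallow pedigrees that exist for wild populations while
remaining conservative with respect to the $r \ge 0.125$ kin-bias
threshold: on complete two-generation pedigrees every dyad with
$r \ge 0.125$ is kin, and the weakest dyads the criterion admits are
half-cousins at $r = 0.0625$.

Because it is easier to show that two individuals share a recent ancestor
than to show that they do not, the negative call depends on a
**completeness policy** the user must choose:

* `strict` (default): `NON_KIN` only when both individuals have both
  parent links and all four grandparent links known; otherwise
  `UNDETERMINED`. (Completeness is about *links*, not distinct ids — a
  dyad whose grandparents coincide is still fully documented.)
* `permissive`: `NON_KIN` whenever no shared known ancestor exists,
  mirroring the source criterion literally.

`strict` can only soften a `permissive` `NON_KIN` into `UNDETERMINED`;
the two policies never disagree on `KIN`.

## Unit composition

`classify_composition()` labels a unit from its dyad statuses and reports
the dyad counts and the continuous proportion of kin dyads.
`INCONCLUSIVE` is a deliberate fourth outcome for units containing any
undetermined dyad: a library must surface unclassifiable units rather than
silently dropping them, as a data-collection protocol can. A unit of two
can never be `MIX_RELATED` (it has one dyad), and the labels partition all
outcomes.

For units known only through marker-based relatedness estimates,
`classify_from_clusters()` implements the genetic-cluster rule: if some
line (matriline / birth cohort / breeding line) has positive mean
within-line estimated relatedness and some pair of lines has zero-or-
negative mean between-line relatedness, the unit demonstrably contains
both kin and non-kin and is `MIX_RELATED`; every other configuration is
`INCONCLUSIVE` — this evidence route can never certify `RELATED` or
`UNRELATED`. The threshold `epsilon` separating "positive" from
"zero/negative" defaults to 0 with a `1e-9` numerical tolerance, the
literal reading of the rule. With unbiased noisy estimates, a between-line
mean whose expectation is exactly 0 falls on either side of 0 with equal
probability, so analyses of noisy data should set `epsilon` between the
expected unrelated (0) and related ($\ge 0.25$ for half-sibs) means; the
test suite uses 0.1 for that reason.

## The synthetic world

`simulate_unit_pedigree()` breeds forward in time from founding females
over discrete, non-overlapping generations: philopatric recruitment, new
unrelated sires each generation (complete skew with `single_sire`, or
uniform choice among `n_sires` males), optional immigration of one
unrelated adult female per generation, configurable litter sizes (fixed,
or zero-truncated Poisson) and offspring sex ratio. Immigrants are
represented exactly as field pedigrees represent them — founders with
unknown parents — which reproduces the real difficulty of certifying
unrelated units. Defaults (2 breeding females, litter 2, 2 generations,
even sex ratio) describe a small plural-breeding unit.

Ground truth is derived from the construction records (the parent links
the simulator itself laid down), through a code path independent of the
classifier under test, and the suite requires 100% agreement with
`classify_composition()` on noiseless data across all three regimes:

* founders only → `UNRELATED`;
* one founding line, no immigration → `RELATED`;
* immigrants alongside native descendants → `MIX_RELATED`.

**What the generator does not emulate:** overlapping generations, age
structure and mortality, dispersal *out* of the unit, and marker-level
genotypes. A green recovery test therefore establishes that the classifier
matches the stated construction, not that it would classify any real
society correctly.

**Direction-of-effect check.** The comparative prediction is that
monotocy and immigration push units away from being fully related. In a
single-cohort unit, strict monotocy removes within-cohort maternal kin
entirely, so its end state is `UNRELATED`, not `MIX_RELATED`; the
`MIX_RELATED` fraction alone is consequently non-monotone in litter size
(we verified this empirically before freezing the test). The sign check
in the suite therefore tracks the *not-fully-related*
(`MIX_RELATED` + `UNRELATED`) fraction, which must be non-increasing in
litter size and non-decreasing in immigration rate across a 3×3 sweep.

`noisy_relatedness()` adds unbounded Gaussian noise to true $r$
(estimates may be negative, as with marker estimators), and
`simulate_binary_trait()` evolves a two-state character along a tree under
the symmetric chain, with flip probability
$\tfrac12(1 - e^{-2qt})$ per branch.

## The packaged species table

`inst/extdata/species_table1.csv` is a transcription of the published
species-level table: 22 sex/species rows (17 female, 5 male) covering 18
species, each carrying the composition label, counts of populations,
units and datapoints, mean adult unit size (± sd where available), and
dispersal/breeding/litter covariates. Aggregation is
**mean-of-species-means** (each sex/species row is one datapoint), and
standard deviations use the $n-1$ denominator; these two choices exactly
reproduce the published unit-size statistics (3.2 ± 1.5 for related,
26.3 ± 15.2 for mix-related female units) and rounding happens only at
presentation. `crosscheck_counts()` recomputes the totals and *reports*
the discrepancies it finds (the row sums give 65 female datapoints from
60 units, against printed totals of 67 and 62, which themselves disagree
with the printed grand total); it corrects nothing. A checksum test
guards the transcription.

## Comparative machinery

All of this is reimplemented from first principles; only newick parsing,
tip pruning and the branch-length covariance come from `ape`.

**Mk likelihood.** For the symmetric two-state chain the transition
probabilities are $p_{\rm same}(t) = \tfrac12(1 + e^{-2qt})$,
$p_{\rm diff}(t) = \tfrac12(1 - e^{-2qt})$; `mk_loglik()` is Felsenstein
pruning with a stationary $(\tfrac12,\tfrac12)$ root prior (the source
analysis does not state one). The implementation is tested against
brute-force enumeration of all internal-node assignments on trees of up
to six tips at `1e-10`.

**Rate estimation.** `mk_fit()` maximizes the profile by bounded 1-D
search. The profile flattens into a saturation plateau as
$q \to \infty$, which can trap a plain golden-section search, so the
optimum is first bracketed on a 30-point log grid. Constant characters
return $q = 0$ with a boundary flag.

**Stochastic mapping.** Internal node states are sampled from their joint
conditional distribution (pruning pass, then preorder sampling); branch
paths conditional on endpoints are sampled by *uniformization*. With
dominating rate $q$ the jump chain of the symmetric process is the
deterministic flip, so every virtual event is a real change and the
number of changes on a branch is Poisson($qt$) restricted to even or odd
values according to endpoint parity — an exact, always-terminating
sampler (rejection sampling stalls for small $q$ or long branches). The
parity law, the Fitch parsimony lower bound, and agreement of sampled
node frequencies with enumeration marginals are all tested.

**Phylogenetic Bernoulli regression.** `fit_phyloglm()` fits
$\mathrm{logit}\,P(y_i = 1) = \beta_0 + \beta_1 x_i + u_i$ with
$u \sim \mathcal N(0, \sigma^2 C)$, where $C$ is the shared-path
covariance scaled to unit diagonal so $\sigma^2$ reads as phylogenetic
variance on the logit scale. Priors default to $\mathcal N(0, 10^2)$ on
coefficients and half-normal(0, 5) on $\sigma$ — the original analysis
used package defaults it never printed, so ours are explicit and
configurable. Sampling is Metropolis-within-Gibbs: adaptive random-walk
updates for $\beta$ and $\log\sigma$, and site-wise updates for $u$
proposed from the conditional prior so the acceptance ratio reduces to a
single observation's likelihood ratio. Four chains of 5000 post-warmup
draws after 2000 warmup iterations are the defaults; split-chain
$\hat R < 1.05$ declares convergence, and non-convergence warns rather
than failing silently. With $\sigma$ fixed at 0 the model reduces to
ordinary Bayesian logistic regression, which the suite verifies against a
maximum-likelihood oracle and through an approximate frequentist coverage
check of the 95% credible interval under a null slope.

## Declared limitations

* The published posterior numbers (unit-size effect 6.6, CI 1.0–17.1;
  litter-size effect −9.0, CI −24.2–9.0; 18.3 mean state changes) depend
  on an external mammalian supertree and unprinted priors and are **not**
  reproduced; property-based checks substitute, and the end-to-end
  acceptance test runs the same pipeline on the packaged table with a
  random coalescent stand-in tree (labelled synthetic) purely to exercise
  the machinery.
* Cross-pedigree dyads are incomparable (an error), inbred-dyad
  classification is deliberately unspecified, and individual-based
  fission–fusion societies and cross-sex dyads are out of scope.
* Branch-length units and any tree transformations used upstream of the
  published regression are unstated; `fit_phyloglm()` normalizes $C$ to a
  correlation matrix, which absorbs overall tree scale but not shape.
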