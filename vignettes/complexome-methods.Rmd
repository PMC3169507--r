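---
title: "Methods: bipartite complexome analysis and global optimization"
author: "complexome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite complexome analysis and global optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexome)
```

## The representation

A complexome — the protein complexes of an organism together with their
component proteins — is modelled as a bipartite network. Complexes and
proteins are the two node types; a complex is linked to every protein that
is one of its components. Memberships carry a role, `core` or `attachment`:
cores are the stable skeleton of a complex, attachments associate with it
more promiscuously. The two one-mode projections summarize shared
membership: in the protein projection two proteins are linked with weight
equal to the number of complexes they share, in the complex projection two
complexes are linked with weight equal to the number of proteins they
share. The strength of a node, `s_i = sum_{j in V_i} w_ij`, extends the
degree to weighted links.

Degree and strength distributions of TAP-MS-derived complexomes are far
more homogeneous than those of binary interaction networks; cumulative
distributions `P(k) = sum_{k' >= k} p(k')` are compared against the
exponential form `p(k) ~ exp(-k/k0)` and a power law by least squares on
the log-transformed cumulative values (`fit_cumulative()`,
`compare_fits()`). Least squares on log-cumulative values is the simplest
criterion that reproduces the visual straight-line test on semi-log or
log-log axes; no maximum-likelihood machinery is attached because the
comparison is a model preference, not a hypothesis test. The largest
observed degrees sit in a finite-size tail; `tail_cut` excludes degrees
above a chosen value from the fit, and the package's own tests use it to
keep truncation artifacts out of parameter recovery checks.

## Abundance estimation by linear programming

Let `p_i` be the measured copy number of protein `i` (arbitrary units) and
`c_j` the unknown copy number of complex `j`, with `S_ij` the number of
copies of protein `i` in complex `j`. In an ideal balance every protein is
exactly consumed by complex formation:

    p_i = sum_j S_ij c_j .

With many more proteins than complexes this system is over-determined, so
the balance is relaxed to an availability constraint — a cell cannot use
more of a protein than it has — and the total leftover is minimized:

    minimize  DA = sum_{i in K} ( p_i - sum_j S_ij c_j )
    subject to  sum_j S_ij c_j <= p_i  for i in K,   c_j >= 0,

where `K` is the set of proteins with known positive abundance. Only core
memberships enter `S`: attachments are shared widely and would inflate the
estimates. The stoichiometric counts default to 1 (binary membership), the
usual approximation when true stoichiometries are unavailable; a `copies`
column is honoured when present. Proteins with zero recorded abundance are
treated like unknowns — outside `K`, imposing no constraint — because a
zero measurement cannot distinguish absence from detection failure.

Two reconstructions deserve note. The objective is taken as the plain sum
of nonnegative leftovers (an L1 deviation under the availability
constraint); squared deviations would change the solution only on
degenerate faces and would abandon the linear-programming structure the
method is built on. Second, conditions (rich and minimal media) are solved
as independent programs; nothing couples copy numbers across media.

The program is solved by a dense tableau simplex written for this package
(`lp_max`): with nonnegative right-hand sides the all-slack basis is
feasible, so no phase-1 is needed; entering variables take the most
negative reduced cost with lowest-index tie-breaks, switching to Bland's
rule after a long degenerate stretch. The run is deterministic for a fixed
column order. Its optima are checked in the test suite against exhaustive
vertex enumeration and, where tractable, a literal fine-grid search.

Complexes with no core member in `K` are *undetermined*: no constraint
mentions them and any value would leave `DA` unchanged, so they are fixed
at 0 and flagged rather than silently reported. After solving, unknown
protein abundances are imputed through the ideal balance,
`p_hat_i = sum_j S_ij c_j` (`impute_abundance()`), carrying an
`undetermined` provenance flag when every complex of the protein was
undetermined. Set-cover-like LPs often have degenerate optimal faces;
`solve_abundance(..., intervals = TRUE)` reports per-complex `[min, max]`
copy numbers over the optimal face via lexicographic re-optimization
(coverage first, then the coordinate), surfacing non-uniqueness instead of
hiding it.

## Function assignment by minimum set cover

`Fp_ik = 1` records that protein `i` carries function `k` (hierarchical
dotted codes in the FunCat style, e.g. `10.03.03`); `Fc_jk = 1` that
complex `j` does. The constraint is that every function of an annotated
protein must be carried by at least one complex containing it:

    sum_j U_ij Fc_jk >= 1   whenever Fp_ik = 1,

with `U` built from *all* memberships — allowing every alternative cover
makes the assignments that survive minimization more credible. In the
spirit of parsimony the number of complexes assigned each function is
minimized, independently per function:

    minimize  m_k = sum_j Fc_jk .

The global problem therefore decomposes into one minimum set cover
instance per function code, each solved exactly by depth-first branch and
bound (branching on the element covered by fewest candidates, greedy upper
bound, counting lower bound). Codes are treated as atomic labels during
optimization; hierarchy truncation is applied only in reporting, so
category tables never feed back into the covers.

Minimum covers are rarely unique. An assignment is *high-confidence* (HC)
when the complex belongs to every optimal cover of its instance, decided
exactly: forbid the complex and re-solve — if the optimum strictly worsens
(or the instance becomes infeasible) the complex is essential. This
force-and-resolve test characterizes membership in all optima without
enumerating them; the test suite confirms it against full subset
enumeration.

The alternative objective (`min_proteins`) minimizes the number of core
proteins newly reached by the chosen complexes, with ties broken by fewer
complexes — the natural formalization of "fewest newly assigned proteins"
given that new protein functions propagate through core memberships only.

Assigned complex functions are then re-substituted: protein `i` is
conjectured to perform `k` when it lacks the annotation but is a **core**
member of an assigned complex (attachment membership is too weak a basis
for transferring function). Both raw and HC assignment sets are supported
as the source, since either choice is defensible; `hc_only = TRUE` is the
conservative default. Every assignment can be traced to its annotation
donors — the already-annotated components that forced the cover — which is
the provenance chain behind every new prediction.

## Projected degree distributions by generating functions

For an uncorrelated bipartite network (joint degree distribution equal to
the product of the marginals), a protein's projected degree is, up to rare
repeated partners, the sum over its memberships of (complex size − 1),
where sizes at the end of a random membership follow the size-biased
distribution. In generating-function form the projected distribution is
the composition `G_protein(G_excess(x))`; the package evaluates it by
repeated convolution truncated at `k_max` (default 512) with
renormalization and a warning whenever more than `1e-6` of mass is lost.
The closed form printed in the original derivation is not recoverable from
the source text, so the composition is reconstructed from the standard
uncorrelated-bipartite framework; the forced cases (all memberships 1,
all sizes 3 ⇒ degree exactly 2, and the like) pin the construction down.

The consistency check simulates a configuration-model bipartite graph and
compares its empirical projected-degree distribution with the prediction
by total variation (TV) distance. The check uses unit-decay exponentials,
`p(k) ~ exp(-k)`, for both membership counts and sizes — the same
functional form the theory assumes — at 2,000 proteins. The TV tolerance
of 0.05 demands inputs whose finite-sample TV floor sits below it: a
2,000-draw empirical distribution over a wide support cannot come closer
than ≈ 0.05 to *any* prediction, so wide-mean inputs would measure
sampling noise, not the theory. With unit-decay inputs the observed TV is
≈ 0.01–0.02 across seeds, and the systematic error (simulation against
prediction at 100,000 proteins) is below 0.01. The predicted distribution's
upper tail is log-linear with R² > 0.999, the exponential-like tail the
theory anticipates. What the repeated-partner approximation ignores —
protein pairs sharing several complexes — deflates empirical degrees
slightly; at these densities the effect is inside the sampling floor.

## The synthetic complexome generator

`generate_complexome()` is the package's test bed: every stage of the
pipeline can be verified against planted truth without external data. Its
defaults emulate the curated yeast complexome: 491 complexes, 1,491
proteins, mean complex size 13.41, mean protein membership 4.42, 325
function codes, rich (YEPD) and minimal (SD) media. Complex sizes and
membership counts are drawn from truncated geometric distributions — the
discrete exponential, matching the observed degree shapes — and wired by a
stub-pairing configuration model with repair of parallel edges. Each
complex labels a fraction of its members core (default 0.25, the
approximate ratio of the observed core-only mean degree 1.28 to the
overall 4.42), with at least one core per complex so every complex has a
skeleton.

Planted copy numbers are log-normal (meanlog `log(500)`, sdlog 1),
emulating the molecules-per-cell scale and spread of genome-wide yeast
abundance data; the second condition multiplies them by a log-normal
ratio (sdlog 0.5). Protein abundances are the core-formed demand plus
*nonnegative* exponential surplus with mean 10% of the demand: one-sided
noise keeps the planted truth feasible under the availability constraint,
which is what real leftovers (unassembled pools, measurement surplus) look
like from the LP's point of view. Functions are planted one complex per
code, copied to the complex's core proteins, and masked at a 20% dropout
rate to create the "unknowns" the pipeline is asked to fill in. Dropout
and the log-normal parameters are not reported properties of the source
data; they were fixed once at values a yeast proteomics practitioner would
call unremarkable.

What the generator does *not* emulate: the isoform/socio-affinity
clustering that produced the real core/attachment calls, correlated
degrees, shared-subunit stoichiometries, or condition-dependent membership
changes. Passing tests on synthetic data therefore demonstrate the
correctness of the algorithms under the stated degree structure, not the
biological accuracy of any particular yeast inference.

## Validation harness

Proteins with known values are split uniformly into training and test sets
(`|train| = round(p n)`, half away from zero — the rounding convention is
otherwise arbitrary and is recorded here). For abundance, the LP is solved
on training abundances only, the masked proteins are imputed, and their
relative deviations `alpha_i = |p_hat_i − p_i| / p_i` are ranked against a
random-pairing null (estimated values permuted across test proteins, 200
replicates by default, per-rank mean and central 95% band). For functions,
test proteins' annotations are hidden, the cover pipeline runs on the
training annotations, and predictions for test proteins are scored as the
fraction of predicted (protein, function) pairs present in the held-out
truth and the fraction of predicted-for proteins with at least one correct
function — both for raw and HC outcomes, always with their
numerator/denominator counts, since percentages on small denominators
mislead. HC metrics are not forced to dominate raw ones; only the
set-containment HC ⊆ raw is asserted.

## Numerical choices and problem sizes

Tolerances: simplex pivots and feasibility use `1e-9`; solution/oracle
comparisons `1e-6`; pmf normalization `1e-12` after renormalization.
Rankings break ties lexicographically on node id, the only reproducible
convention. Deterministic runs everywhere: fixed lexicographic variable
order in both solvers, seeds threaded through every random step, and the
generator restores the caller's RNG state.

The test suite and the acceptance script run the full pipeline at the
default study scale (491 × 1,491) for network statistics, abundance and
function assignment, and validation; oracle-equivalence checks use 100
random instances of up to 4 complexes × 8 proteins (LP, against vertex
enumeration, plus the literal 0.01-step grid where the dimension allows)
and up to 15 candidate complexes (set cover, against full subset
enumeration); the generating-function check uses 2,000 proteins. These
sizes were chosen so each oracle remains exact, and the whole suite runs
in well under a minute.

## Known limitations

* The LP reports one optimal vertex; degenerate faces are surfaced via
  intervals, not resolved.
* HC status is relative to the given membership and annotation tables; a
  missing complex can make a tied assignment look forced.
* The power-law comparison is a least-squares preference, not a
  statistical test of the power-law hypothesis.
* Stoichiometry inference and kinetic modelling on top of the abundances
  are out of scope; `copies > 1` is honoured but never estimated.
* The hypergeometric annotator sometimes used as an external baseline for
  function assignment is not reimplemented here.
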