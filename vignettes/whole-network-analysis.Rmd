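---
title: "Whole-network analysis of service delivery systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-network analysis of service delivery systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgnet)
```

## The problem

Child welfare and healthcare services are delivered by networks of
organizations -- municipalities, schools, general practitioners, specialized
youth care providers and others -- that must refer clients to one another.
Whole-network studies of such systems survey a *boundary spanner* (a
representative employee) of every organization on a bounded roster and ask
two relational questions: with which organizations does yours have contact at
least once a year, and with which does it exchange client referrals?  The
analysis then characterizes each network's **differentiation** (how many
organizations, sectors and tasks it comprises) and **integration** (how
interconnected it is), and ranks organizations by centrality to see whether
the legally designated *gatekeepers* actually occupy coordinating positions.

`orgnet` implements this pipeline end to end: survey ingestion, respondent
aggregation, nonresponse handling, symmetrization, metric panels, centrality
rankings and sector-level aggregation, plus a synthetic survey generator that
supplies fully specified test-beds with known ground truth.

## From survey records to an adjacency matrix

The raw data are directed claims `(respondent, reporter organization, named
organization, layer)`.  Three steps turn them into the symmetric 0/1 matrix
the measures are defined on:

1. **Respondent collapse** (`collapseRespondents`).  Cell $(i, j)$ of the
   organization-level report matrix is 1 iff *at least one* boundary spanner
   of organization $i$ named $j$ in that layer.  An organization counts as
   *responded* iff at least one of its respondents answered the questionnaire
   at all; a separate response register keeps an all-negative answer (a
   respondent who named nobody) distinguishable from nonresponse.  The
   "at least one respondent" rule is a deliberate interpretation: surveys of
   multi-respondent organizations routinely have partial respondent coverage,
   and treating any answered questionnaire as an organizational response is
   what makes response percentages computed at the organization level
   consistent with respondent-level administration.

2. **Labeled reconstruction** (`labeledReconstruction`).  Nonresponding
   organizations have empty rows but appear in the columns of responding
   reporters.  Their rows are filled by transposing the corresponding column
   restricted to responding reporters: what others said about them is entered
   as a reciprocal relationship.  Dyads between two nonrespondents are
   unrecoverable and stay 0; every such dyad is flagged in the adjacency's
   provenance layer, and `reconstructedShare()` reports their share as a
   data-quality figure.

3. **Any-link union symmetrization** (`symmetrizeUnion`).
   $A_{ij} = \max(R_{ij}, R_{ji})$: a tie exists if either side reported it,
   so unconfirmed unidirectional reports count.  This maximizes information
   under partial response at the cost of possibly overestimating ties.

The pipeline applies reconstruction before symmetrization.  For the union
rule the two orders provably coincide -- reconstruction copies
$R_{ji}$ into $R_{ij}$, and the union then takes the elementwise maximum
either way -- and the suite asserts that coincidence on random
partially-responded report matrices, so the ordering is a presentation
choice, not a modeling one.

## The measures

All metrics are computed directly from their formulas on the 0/1 matrix (no
graph library in the computation path; `igraph` appears only as an
independent cross-check in the tests and for GraphML export).

* **Ties** are counted over *ordered* pairs: `countTies` returns twice the
  undirected edge count.  This convention is forced by internal consistency
  of the standard comparison tables, where `ties / n` equals the printed
  average degree and `ties / (n(n-1))` the printed density.
* **Density** $= T / (n(n-1))$, **average degree** $= T / n$, with $T$ the
  ordered tie count.
* **Isolates** are zero-degree rows; **active organizations** are the rest,
  with the percentage rounded to an integer as in the tables.
* **Degree centrality** is the row sum; the normalized form divides by
  $n - 1$ with isolates included in $n$, so it is a fraction in $[0, 1]$.
* **Degree centralization** uses Freeman's undirected form
  $\sum_i (d_{\max} - d_i) \,/\, ((n-1)(n-2))$: 0 for regular graphs, 1 for
  a star.  Isolates are included in $n$.  Source studies rarely print the
  formula they used; this denominator is the symmetric default of the
  standard whole-network tools, and the implementation is validated against
  the star/cycle closed forms and a naive-loop oracle rather than against
  any published centralization value.

Rounding happens only at rendering: densities to 3 decimals, average degree
to 2, centralization to 3, percentages to integers.

## Sector aggregation and strength coding

`aggregateToSectors` counts, for every unordered pair of distinct sectors
$A \ne B$, the present ties among the $|A| \cdot |B|$ possible inter-sector
organization pairs; within-sector fractions (over $|A|(|A|-1)/2$ pairs) are
computed identically but kept in a separate table, since sector-level
diagrams conventionally show between-sector edges only (a flag merges them
back).  The realized fraction is binned by the fourfold scheme: under 20% of
possible ties is 0 (no relation), then 1 (weak), 2 (average), and at least
60% is 3 (strong).  The verbal scheme overlaps at the 20/40/60% boundaries;
`codeStrength` resolves this with half-open intervals so that an exact
boundary takes the *higher* code (0.20 maps to 1, 0.60 to 3), anchored by
the "at least 60%" wording of the top class.  Sectors absent from a network
simply do not appear.  Tie conservation -- between-pair plus within-sector
present counts summing to the network's undirected edge count -- is asserted
property-style.

## The synthetic survey generator

No raw whole-network survey of this kind is publicly deposited, so the
generator is first-class, tested code that defines the study conditions for
every downstream stage:

* **Roster.** Sector counts are apportioned deterministically from a weight
  vector (largest remainder): the sector mix is the *design* composition of
  a network, not a random draw, and this guarantees that the default
   11-sector scheme is fully represented at realistic sizes.  The default
  weights are skewed so that specialized youth care dominates the roster
  (as it does empirically, e.g. 94 of 135 members) while gatekeeping
  front-office sectors are small.  Sectors whose members have limited
  working areas (general practitioners, education, childcare, municipal
  officers) get 2--5 boundary spanners; the 2--5 range is a free choice, as
  published studies report only that such organizations had several
  respondents (one had thirty general practitioners).
* **Ground truth.** The contact layer is a two-block core--periphery
  Bernoulli graph.  Defaults: 10% of organizations are core (gatekeeper-task
  organizations first), with tie probabilities 0.90 within the core, 0.50
  core--periphery and 0.08 within the periphery; the referral layer retains
  each contact tie with probability 0.65.  With few parameters this
  reproduces the empirically observed ranges (densities roughly 0.12--0.35,
  centralizations roughly 0.4--0.7 at $n$ = 75--135), which is the reason a
  block model was chosen over, say, a configuration model.
  `expectedContactDensity()` gives the closed-form expected density, and the
  suite checks convergence of realized densities to it within Monte-Carlo
  error.
* **Reports.** Each boundary spanner responds with probability 0.57 (the
  midpoint of typical 52--68% response).  A responding organization's
  *primary* respondent reports every true incident tie; additional
  respondents observe each tie with probability 0.8.  This keeps
  OR-aggregation across respondents nontrivial while preserving an exact
  invariant: at full response the pipeline recovers the ground truth
  *exactly* in both layers (under fully independent 0.8 observation no such
  exactness could hold, because all reporters of a tie could miss it).
  Respondents report only true ties by default; a `report_noise` parameter
  (default 0) injects false positives for robustness experiments.

What the generator does *not* emulate: name ambiguity and recall error in
respondent answers, longitudinal evolution, trust or governance covariates,
and any dependence of response on network position.  Passing tests therefore
demonstrate the correctness of the pipeline's algebra and its statistical
behavior under a clean reporting model -- not robustness to the messier
failure modes of real survey data.

## Numerical and degenerate-input choices

* Metrics raise errors rather than return conventions outside their domain:
  density needs $n \ge 2$, centralization $n \ge 3$.
* Self-reports and unknown layer labels are validation errors, never
  silently dropped; a report naming an organization off the roster names it
  in the error.
* Percentage rounding uses R's `round()` (half-to-even); none of the
  reproduced table values sits on a .5 boundary.
* Centrality rankings break ties deterministically by organization id.
* An all-missing report matrix is legal and reconstructs to the zero matrix.
* All generator randomness flows from one integer seed; each stage re-seeds
  deterministically from it, and the pipeline derives per-network seeds from
  the master seed, so runs are byte-identical replayable.

## Problem sizes in the test suite

The suite validates metrics against naive-loop oracles on 200 random graphs
of up to 20 nodes and exhaustively on all labeled graphs with up to 5 nodes;
reconstruction/symmetrization order coincidence on 100 random report
matrices; block-model density convergence on 50 replicates at $n = 200$; and
full pipeline runs at the emulated sizes $n$ = 135, 86, 75.  These sizes
were chosen to cover the regimes the method is used in while keeping the
whole suite fast enough to run habitually.

## Limitations

The any-link rule plus labeled reconstruction can only overestimate or
exactly recover ties incident to respondents, and can never recover a dyad
between two nonrespondents; comparisons across networks with very different
response rates therefore mix measurement regimes, which is why the pipeline
logs the reconstructed-dyad share per network.  Degree-based measures were
preferred by the source literature precisely because they are local and
robust to missing data; betweenness and closeness are deliberately out of
scope (closeness is undefined on disconnected networks, and both are
sensitive to nonresponse).  No inference about network effectiveness or
outcomes is attempted.
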