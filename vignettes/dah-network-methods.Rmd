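---
title: "Methods: modelling development assistance for health as a weighted directed network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling development assistance for health as a weighted directed network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dahnet)
```

## The system being modelled

Development assistance for health (DAH) moves through a three-role
structure. Sources — national treasuries, multilateral member contributions,
private funders — disburse to channels — bilateral agencies, multilateral
institutions, NGOs, foundations, public–private partnerships — which
disburse to recipient countries. A single organization can occupy more than
one role (a multilateral can be funded as a channel and act as a source of
onward flows; a recipient country can also donate), and disbursements are
disaggregated by health area (HIV/AIDS, malaria, maternal health, ...; 22
labels by default).

`dahnet` represents one year of this system as a directed weighted graph:
nodes are actors, each edge points from the funder to the funded, and the
weight is the total amount (constant USD) flowing over that tie in the year.
Three projections are built per year:

* **source→channel bipartite** — out-degree of a source counts the channels
  it funds; in-degree of a channel counts its funders;
* **channel→recipient bipartite** — out-degree of a channel counts the
  countries it funds; in-degree of a country counts the channels funding it;
* **unimodal** — all actors in one node set. Each record deposits its amount
  on both of its hops, so the unimodal total edge weight is exactly twice
  the record total. This two-hop deposit rule is a declared convention: the
  alternative (weighting hops differently) is not recoverable from how such
  aggregated flow data are usually described, and the rule keeps weight
  accounting trivially checkable.

Parallel flows (over health areas, duplicate pairs) are pre-summed, so
graphs are simple. Self-loops — an actor funding itself after identifier
canonicalization — are retained as data but excluded from every metric:
they are never on a shortest path (their transformed cost is set to
infinity) and they count in no degree.

## Actor typology

Actors carry one of four categories — PUBLIC (national governments,
multilaterals), PRIVATE (individuals, enterprises), CSO (NGOs, public
charities/NPOs, family and corporate foundations), PPP (global health
networks and initiatives) — and a subgroup consistent with the category.
Resolution order in `assign_typology()`: membership of a configured PPP
name-list overrides everything; then the registry entry; then an
ISO3-shaped identifier is typed PUBLIC / national_government. That last
convention deserves a note: recipient countries are network actors, but an
organizational typology does not naturally cover them; typing them as
national governments keeps the unimodal graph fully typed, while a per-year
`roles` attribute (source/channel/recipient, non-exclusive) records
function. In `permissive` mode (default) unresolvable identifiers are typed
UNKNOWN with a warning; `strict` mode makes them an error, which is what
fixtures and pipelines should use.

## Generalized closeness centrality

The package's central metric is the tuned closeness
\[
C_C^{w\alpha}(i) = \Big[\sum_j d^{w\alpha}(i,j)\Big]^{-1},
\qquad
d^{w\alpha}(i,j) = \min_{\text{paths } i \to j} \sum_{\text{hops}}
  (1/w_\text{hop})^{\alpha},
\]
computed by Dijkstra's algorithm on the transformed costs (all costs are
strictly positive, so there are no negative-edge concerns), with no
normalization by \(N-1\).

Why this distance? The closeness formula alone does not pin down
\(d^{w\alpha}\); the cost transform \((1/w)^\alpha\) is the standard
generalization for weighted networks in which tie weight means capacity
rather than cost. It is the only reading under which \(\alpha\)
interpolates the two classical limits — \(\alpha = 0\) gives hop-count
(binary) distance, \(\alpha = 1\) gives classic weighted distance on costs
\(1/w\) — and it satisfies a clean scale law: multiplying all weights by
\(c > 0\) multiplies every finite distance by \(c^{-\alpha}\) and every
closeness by \(c^{\alpha}\). The default \(\alpha = 0.5\) weighs the number
of ties and their intensity equally; at that value a two-hop route over
ties of weight 9 (cost \(2 \times 1/3\)) beats a direct tie of weight 1
(cost 1). The test suite verifies the implementation against an exhaustive
simple-path enumeration oracle on a thousand random digraphs and against
independent BFS and Floyd–Warshall implementations at the limits.

Two conventions are deliberately configuration, not fixed truth, because
aid networks are sparse and directed:

* **Unreachable pairs.** Read literally, one unreachable target makes the
  distance sum infinite and the closeness 0 — on a sparse directed graph
  that zeroes almost every node. The default `reachable_only` policy sums
  over the targets a node actually reaches (a node reaching none scores 0);
  the literal reading is available as `zero_if_any_unreachable`.
* **Direction.** "How quickly an actor reaches the rest of the system"
  suggests outgoing distances along the money flow; `direction = "in"` and
  `"undirected"` are available.

A known consequence of unnormalized reachable-only closeness: an actor
reaching only a handful of targets over very heavy ties can outscore a
far-reaching hub, because nothing penalizes a small reachable set. Rankings
should be read with this in mind (or compared across policies); the package
reports the metric as defined rather than silently normalizing.

Ranking is ordinal (1..k, descending value) with lexicographic tie-break on
actor id, making rank tables deterministic and invariant to input row
order.

## The synthetic generator

Real disbursement-tracking datasets of this kind are request-only, so the
package generates flow tables with the structural features the analysis
assumes. The calibrated default (`default_config_mdg_era()`) encodes, at
desk scale, the stylized facts of the 1990–2015 landscape:

| Feature | Default | Why |
|---|---|---|
| Window | 1990–2015, annual | the MDG-era study window |
| Annual total | log-linear 7e9 → 36e9 USD | reported growth of DAH |
| Public share of source amounts | 0.945 → 0.813, linear | reported 1990/2015 anchors |
| Public share of channel amounts | 0.924 → 0.499, linear | reported anchors; PPP channel share ramps to 0.15 by 2015 |
| Actors | 20/4/6/0 (PUBLIC/PRIVATE/CSO/PPP) + 40 recipients → 60/30/190/15 + 40 | ~4.8× growth in distinct actors, CSO ramp 2005–2011, PPP entry 2000 |
| Cause-specific CSOs | 1/3 of channel-capable CSOs | reported one-third single-area share |
| Unspecified endpoints | 2% of records | exercises the drop filter |
| Records | ~5 per active organization + 2 per recipient, per year (~20k total) | desk scale: seconds to generate, minutes to analyse |

The interpolation between share anchors is linear; the true in-between
shape is not recoverable from published figures, so monotone linearity is a
package choice, not an empirical claim.

Design principle: **deterministic structure, stochastic placement.**

* Actor activation is deterministic from the growth schedule (ids created
  at scheduled years, never retired), so per-year active-actor counts are
  exact, and every role-capable actor and every recipient is guaranteed at
  least one record per active year (channel-capable actors two, so a
  multi-cause channel demonstrably carries ≥ 2 areas).
* The cause-specific flag is likewise a quota: exactly `round(p · n)` of
  channel-capable CSOs (identities randomized) are dedicated to one health
  area. At ~126 CSO channels a Bernoulli draw of the flag would have a
  sampling standard deviation of ~0.04 on the realized fraction — larger
  than any sensible check tolerance — whereas the quota makes the rate a
  property of the configuration, matching how actor counts are handled.
* Record placement is stochastic: each non-coverage record draws its source
  and channel categories from the share schedules and its actor within the
  category by preferential attachment on accumulated strength (probability
  ∝ 1 + in-strength for channels), reproducing heavy-tailed flow
  concentration. Amounts are drawn log-normally (sdlog 1.2) and then
  refitted by iterative proportional scaling (RAS) so that the per-year
  source-category and channel-category amount marginals match the schedules
  and the year total is exact; one guaranteed record per active
  category-pair cell gives the fit full support, so it converges. The
  relative fitting tolerance is 1e-13.
* A configured fraction of non-coverage records has its source or recipient
  relabelled UNSPECIFIED (coverage records are exempt so activation counts
  stay exact after cleaning).

The generator is a pure function of its configuration (which contains the
seed): one RNG stream, caller state untouched, byte-identical reruns.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: real actor identities and their idiosyncratic
portfolios; geographic and political structure in who funds whom;
multi-year persistence of specific ties beyond what preferential attachment
induces; donor-side earmarking patterns across health areas; currency
deflation (a single constant-USD column is assumed); and reporting noise
other than the unspecified-endpoint mechanism. Tests against synthetic data
validate the *pipeline and metrics*, not empirical claims about the real
landscape.

## Numerical and degenerate-input choices

* Amounts: negative amounts are a parse error; zero-amount records are kept
  by the reader and dropped at aggregation (they are not flows).
* A year with no records yields an empty graph; metrics on it return empty
  vectors; a single-node graph has closeness 0.
* Edge weights must be strictly positive in metric computations (enforced);
  weight totals are conserved per projection and checked on random inputs.
* Graph exports (GraphML via igraph, GEXF 1.2 via a small XML writer,
  edge-list CSV) write weights at full double precision so round trips are
  lossless.
* All CSV outputs are written with fixed full-precision formatting, making
  pipeline runs byte-identical under a fixed seed.

## Problem sizes

The shipped configuration generates ~335 actors and ~20,000 records over 26
years — large enough that the share, growth and concentration features are
measurable with tight tolerances, small enough that the full pipeline runs
in seconds and the complete test suite (including a 1000-graph
oracle-equivalence sweep for the closeness core) in well under a minute.
Oracle checks use digraphs of at most 7 nodes, the practical ceiling for
exhaustive simple-path enumeration.

## Limitations

The typology is coarse (four categories; a government and its bilateral
agency are distinct ids unless a registry maps them); the closeness
rankings inherit the reachable-only caveat above; bipartite closeness is
not produced by default (the unimodal graph is the natural domain for a
system-wide reach metric); and no statistical inference is attached to
centrality differences — the package computes descriptive network
quantities.
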