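---
title: "Methods: network perturbation signatures for herb-disease mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network perturbation signatures for herb-disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmap)
```

## The problem

Multi-ingredient herbs perturb many protein targets at once, some activated
and some inhibited. If a disease's expression state is summarised as a
ranked list of differentially expressed genes, a herb whose perturbation
*reverses* that ranking — pushing the disease's up-regulated genes down and
its down-regulated genes up — is a candidate therapeutic. herbmap scores
that reversal, and searches for herb *combinations* that maximise it.

The pipeline has four stages: build a signed perturbation signature per
herb, diffuse it over a protein-protein interaction (PPI) network, match
its extreme genes against disease profiles with a Kolmogorov-Smirnov (KS)
statistic, and (optionally) run a genetic algorithm over herb subsets.

## Perturbation signatures and two-step diffusion

Each ingredient contributes `+1` for every target it activates and `-1`
for every target it inhibits. A herb's initial signature is the genewise
sum of its ingredients' signatures, weighted by the ingredient's content
fraction when that is known and by 1 when it is not; a combination's
signature is the sum over its herbs. We deliberately do not renormalise a
herb whose contents are partly known: the weight rule is applied literally,
and `herb_signature()` flags the mixed-scale case in its log output so the
user can decide whether the mixture is meaningful for their library.

The initial signature `c` is then spread over the PPI network in exactly
two steps. With adjacency `A` (binary, symmetric, zero diagonal) and
degrees `D`, one step sends `c_i / D_i` from node `i` to each of its `D_i`
neighbours:

    c'_j = sum_i A_ij * c_i / D_i        (step 1)
    c''_j = sum_i A_ij * c'_i / D_i      (step 2, the final signature)

Two properties make this usable as a matching substrate. It conserves
signed mass on graphs without isolated nodes (each node redistributes its
value exactly), and it is linear, so the final signature of a combination
equals the sum of its members' final signatures. The combination search
exploits that linearity: per-herb final signatures are computed once and
combinations are scored by summing columns.

Numerical conventions:

* There is no self-retention term. A node keeps none of its own value in
  step 1 (the diagonal of `A` is zero); it can receive value back in step
  2 through 2-hop paths.
* Nodes with degree zero define `c_i / D_i := 0`: they neither emit nor,
  by symmetry, receive. Any mass they carried is reported as lost with a
  warning. Real interactomes rarely contain such nodes, but synthetic or
  filtered inputs can.
* Node order is frozen at network construction (first appearance in the
  edge list) and used for every matrix computation, so runs are
  reproducible bit for bit.
* Targets absent from the network are dropped before diffusion, with a
  logged count. Diffusion is only defined on network nodes; silently
  keeping out-of-network targets would make signatures incomparable across
  networks.

## Extreme signatures and the matching score

From a final signature we keep the `t` most positively and `t` most
negatively perturbed genes (`h_top`, `h_bottom`), with `t = 250` by
default at interactome scale. The value of `t` trades specificity against
stability and is exposed as an ordinary parameter; since the KS statistic
depends only on relative positions (`t/n`), tests and desk-scale examples
use `t = 25` on a few-hundred-gene universe, which preserves the geometry
of the full-scale setting.

Tie handling deserves a note. Both extreme sets come from one ordering —
intensity descending, gene symbol ascending (C locale) — with the top set
taken from the head and the bottom set from the tail. Breaking ties
lexicographically *within each set independently* could make the two sets
overlap on a flat plateau of identical values; taking head and tail of a
single ordering keeps them disjoint whenever at least `2t` genes exist,
which is an invariant the matching stage relies on.

Matching uses the signed KS enrichment statistic of the connectivity-map
family. For a gene set with sorted hit positions `V(1) < ... < V(t')` in a
profile of `n` genes:

    a = max_j [ j/t' - V(j)/n ]
    b = max_j [ V(j)/n - (j-1)/t' ]
    ES = a  if a > b,  else  -b

and the Total Matching Score of a signature against a profile `d` is

    TMS = ( ES(h_top) - ES(h_bottom) ) / 2   in [-1, 1].

Positive TMS means the herb mimics the disease ranking; negative TMS means
it reverses it (the therapeutic direction). TMS is not forced to zero when
the two enrichment scores share a sign — some connectivity-map variants do
that, but the plain difference is used here.

Signature genes missing from a profile's universe are dropped and the
retained count `t'` is used in the denominators; a pair is scored only if
both retained sets are non-empty, and the retained counts are reported per
pair. Cross-platform gene universes rarely coincide exactly, so this is
the common case, not an edge case.

## The permutation null

Significance of an observed `TMS_0` is the fraction of random signatures
that score at least as extremely: draw `2t` distinct genes from the
*profile's* universe, split them at random into top/bottom halves of size
`t`, and count `N = #{ |TMS_perm| >= |TMS_0| }` over `n_perm = 10,000`
draws; `p = N / n_perm`. Two choices are deliberate:

* The null draws from the profile universe, not the PPI universe. The
  statistic only sees positions within the profile, so drawing from a
  larger universe would merely shrink `t'` at random — a different (and
  less interpretable) null.
* `p` may be exactly 0 when `N = 0`; the result then carries a note
  recording the resolution bound `< 1/n_perm` rather than substituting a
  pseudocount.

Under the null the p-value is approximately uniform; the test suite checks
that the fraction of `p < 0.05` over 1,000 null trials stays in
`0.05 ± 0.02` at `n_perm = 1,000`.

## Genetic-algorithm combination search

Solutions are fixed-length inclusion vectors over the herb library (a
member set, not a stored signature matrix — linearity makes the two
equivalent and the set form is far cheaper). Each generation:

1. every solution is scored by the combination-level `|TMS|` (or `-TMS`
   clamped at zero under `objective = "negative_tms"`);
2. the best `elitism_count` (default 1) solutions are copied unchanged,
   which makes the best-fitness trace non-decreasing by construction;
3. parents are drawn by roulette selection, `P_i` proportional to fitness,
   with a uniform fallback when all fitnesses are zero;
4. uniform crossover (probability 0.9) and per-bit mutation (rate `1/L`)
   produce offspring;
5. every candidate is repaired: an empty set gains a random herb, a
   contraindicated pair loses its weaker member (by cached singleton
   fitness, ties at random), an oversized set loses random members.

Repair rather than rejection keeps the population size constant and never
stalls on heavily constrained libraries; contraindications are enforced at
initialisation *and* after every operator, so no emitted solution can
violate them. Termination is `max_generations` (default 200) or
`stall_generations` (default 20) without best-fitness improvement beyond
`1e-12` — a float-safe strictness threshold, not a tolerance on the score
itself. Operator defaults follow the customary settings of the
evolutionary-computation literature and are all configurable in
`ga_config()`; the default size cap of 8 herbs keeps the search well-posed
while comfortably covering the 2-5-herb range where useful combinations
concentrate.

The default objective is `abs_tms`. A maximal `|TMS|` can in principle be
a strong *mimic* rather than a reversal, so the search also reports the
sign of the best TMS, and `negative_tms` is available when only the
therapeutic direction is wanted.

All randomness of a run flows from `config$seed` through one generator,
so runs are bitwise reproducible.

## Literature co-occurrence

Given a corpus of `N` articles (default 22,188,039), `K` mentioning a
disease, `n` mentioning a herb and `k` mentioning both, the upper-tail
hypergeometric probability

    P = 1 - sum_{i=0}^{k-1} C(K,i) C(N-K, n-i) / C(N,n)

is computed with `stats::phyper()`, whose log-space internals keep
corpus-scale inputs finite; `k = 0` gives exactly 1 and no continuity
correction is applied. The test suite checks the implementation against
full enumeration of every valid configuration with `N <= 12`.

## Disease profiles

Profiles are ranked gene lists, most up-regulated first. When built from
probe-level statistics, each gene keeps its minimum-p probe (ties: larger
absolute fold change, then probe id). All ranking ties break by ascending
gene symbol in the C locale — an arbitrary but platform-independent rule
that makes profile construction deterministic.

## What the synthetic generators emulate — and what they do not

`make_network()` draws preferential-attachment (default) or uniform
random graphs, reconnects stray components and labels nodes as synthetic
gene symbols. The default density of 4 edges per node is a compromise:
real curated interactomes are denser still (mean degree around 20), while
very sparse scale-free graphs leave many leaves with identical two-step
signatures, degenerating the extreme-set machinery. `make_herb_library()`
emulates the herb/ingredient/target structure of a curated library at
desk scale (30 herbs, 2-5 ingredients each, 3-10 targets per ingredient,
half activating).

The planted fixtures realise the framework's core premise in its cleanest
form: `make_planted_reversal_profile()` ranks genes by the *negated* final
signature of one herb (plus optional Gaussian noise on the fold changes),
so that herb is the strongest reverser by construction;
`make_planted_synergy_fixture()` does the same for the sum of two herbs'
signatures, making the pair beat either member alone.

Passing these tests shows the machinery is correct and the search can
recover planted structure. It does *not* show that real diseases behave
like negated herb signatures: real profiles carry platform noise, batch
effects, partially overlapping gene universes and biology that no additive
Gaussian model captures. Results on real data stand or fall with the
quality of the target annotations and expression profiles supplied.

## Problem sizes used by the test suite

The suite runs at desk scale by choice: networks of 150-300 nodes,
libraries of 8-30 herbs, `t` of 15-25, GA populations of 30-40 over at
most 30 generations, permutation calibration at 1,000 x 1,000 draws, and
one full-cardinality contract check (502 signatures x 189 profiles without
permutation). These sizes preserve every scale-free property of the
statistics (`t/n` ratios, null geometry) while keeping any single test in
seconds to a couple of minutes.

## Known limitations

* Modes are consumed as given (+1/-1); predicting targets or their
  direction of action is upstream of this package.
* Edges are unweighted and undirected; no confidence scores, no directed
  signalling, no longer random walks or restart diffusion.
* Gene identifiers are case-sensitive strings with no alias resolution.
* The herb-by-disease score matrix receives no multiple-testing
  correction; the permutation p is reported raw at a 0.05 flag.
* Dose is not modelled beyond optional per-herb weights in a combination.
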