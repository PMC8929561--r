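---
title: "Timeline-based protein structure networks and allosteric scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timeline-based protein structure networks and allosteric scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnet)
```

## The model

A protein structure network maps atoms -- or groups of atoms, typically
residues -- to nodes, and physical interactions to edges. Classical network
analyses assign each edge a scalar (a weight, or nothing at all), discarding
the conformational history of the interaction. This package instead attaches
to every edge an *interaction timeline*: a vector with one non-negative
integer per frame of a structure ensemble, recording whether (for atom-atom
edges, 0/1) or how often (for residue-residue edges, a small count) the
interaction is realised in that frame. An ensemble can be the models of a
multi-model PDB file or the frames of an MD trajectory; a single structure is
the degenerate case where every timeline has length one.

Atom-level timelines are binary indicators per interaction type
(carbon-carbon contact within a distance cutoff; hydrogen bond within
distance and angle cutoffs). Residue-level timelines are frame-wise sums of
the atomic timelines between the two residues, so a value of 3 in a frame
means three simultaneous atomic interactions. A node pair may be connected
by several edges of different types, and the adjacency matrix per type is
symmetric and binary.

## Information scores: ECF, NCF, DNCF

The working hypothesis for allosteric relevance: a residue can only have an
observable allosteric function if its conformational states are correlated
with conformational changes of its immediate environment, and those states
are encoded in the interaction timelines. The *edge neighbour correlation
factor* (ECF) of an edge is the sum of the mutual information, in bits,
between its timeline and the timeline of each neighbouring edge -- edges
separated from it by at most a single node, i.e. sharing an endpoint,
including parallel edges of another interaction type but excluding the edge
itself (no self-information). Mutual information is estimated by the
plug-in (maximum-likelihood) method over the joint histogram of per-frame
states, with the raw integer counts as states and no binning: residue-level
counts are small integers, so the alphabets stay small.

The *node correlation factor* (NCF) of a node is the sum of the ECF scores
of its adjacent edges. It is deliberately local: only directly neighbouring
interactions are compared, which bounds the number of correlation terms and
suppresses the spurious long-range correlations that accumulate when every
residue pair is compared.

The *difference NCF* (DNCF) compares two ensembles of the same system --
typically ligand-bound and free. Edges are matched across the two networks
by location (same residue pair, same interaction type). Each
mutual-information term becomes the target-pair term minus the
location-matched reference-pair term, each estimated within its own
ensemble; the two ensembles may therefore have different frame counts.
Written over the union of the state alphabets, states unobserved in one
ensemble carry zero probability there and contribute nothing, so each term
reduces exactly to `I(X;Y) - I(Xref;Yref)` -- the implementation exploits
this and the tests verify it against the literal union-alphabet summation.
Target edges with no reference partner contribute their full target-pair
information (the absent reference is treated as a constant timeline);
reference-only edges contribute nothing. This makes DNCF asymmetric under
swapping target and reference exactly when the topologies differ; on
identical topologies it sign-flips, a property the test suite asserts.

NCF and DNCF values are reported in raw bits rather than min-max normalised,
so absolute thresholds (e.g. a core-set cutoff in bits) remain meaningful
across networks.

## Centrality scores: BC and CPLC

Betweenness centrality (BC) and characteristic path length centrality
(CPLC) operate on a simple unweighted undirected graph: the multi-edge
timeline network is collapsed so that one edge connects two nodes wherever
any interaction type is ever present. Interaction magnitude is deliberately
ignored; these methods are intended for single structures, where timelines
are length-one. On MD-derived ensembles rare, spurious contacts would enter
the graph with the same weight as stable interactions, which is the
motivation for the information scores above.

BC sums, over unordered node pairs, the fraction of shortest paths passing
through a node (endpoints excluded). CPLC measures the change of the
characteristic path length `L` -- the mean shortest-path distance over
connected unordered pairs -- when a node is deleted: `CPLC_i = L - L_i`.
Both are min-max normalised across nodes, with an all-equal score vector
mapping to all zeros so degenerate graphs produce a determinate result.

**Disconnection convention.** `L` is undefined when pairs are disconnected.
We average over connected pairs only, before and after deletion, which keeps
CPLC finite when a deletion fragments the graph; an edgeless graph gets
`L = 0`. The alternative -- scoring disconnecting deletions as missing -- is
exposed via `cplc(..., drop_disconnecting = TRUE)` so the two conventions can
be compared; published descriptions of the score do not fix this choice.

## Numerical and design choices

* **Canonical edge order.** Edges are stored with endpoints in lexicographic
  order and iterated deterministically, so scores are bit-reproducible.
  Symmetric double sums over ordered pairs are implemented over unordered
  canonical edges; a literal ordered-pair enumerator of the neighbourhood
  indicator (with the Kronecker-delta exclusion of the focal edge) serves as
  the test oracle for this reduction.
* **Sidechain definition.** Backbone is N, CA, C, O (plus terminal OXT) and
  their hydrogens; everything else, including CB, is sidechain; glycine has
  no sidechain atoms. Sidechain-exclusive networks keep only edges whose
  contributing atoms are all sidechain atoms -- at residue grain the flag is
  computed from the contributing atomic records at aggregation time.
* **Occupancy** is the fraction of frames with count > 0 (not the mean
  count); occupancy-based edge filtering uses it, e.g. to drop interactions
  present in less than 0.1% of the frames for display or to de-noise
  centrality graphs.
* **Hydrogen bonds.** Donor--acceptor chemistry comes from a fixed table for
  the standard amino acids (backbone N donates except proline; backbone
  O/OXT accepts; the usual sidechain donors/acceptors). Geometry: heavy-atom
  distance <= 3.5 Å and donor-H-acceptor angle >= 135 degrees, with
  hydrogens taken from the file (attachment = same residue, within 1.25 Å).
  Structures without hydrogens fall back to the distance criterion alone and
  the records are flagged `approximate` -- deterministic, with no force-field
  dependent hydrogen placement; the deviation is visible to the user.
* **Contacts** are carbon-carbon pairs in different residues within the
  cutoff (default 5 Å, the upper edge of attractive van der Waals range);
  no sequence-neighbour exclusion is applied by default, but
  `min_residue_separation` makes it available.
* **Plug-in estimation bias.** The maximum-likelihood MI estimate of
  independent binary series is positively biased with mean approximately
  `1/(2T ln 2)` bits; `2T ln(2) I` is asymptotically chi-squared with one
  degree of freedom. No bias correction is applied (none is standard for
  this score); the property tests calibrate against the chi-squared null
  quantile rather than the mean, since an estimate falls below its own mean
  only about two-thirds of the time.
* **ROC/PR conventions.** Thresholds sweep the distinct observed scores with
  a closed `>=` predicate and ties entering together; higher score means
  predicted allosteric. The ROC curve is anchored at (0,0); the PR curve is
  anchored at recall 0 with the precision of the highest threshold (no
  extrapolated point). Both areas use trapezoidal integration. The
  "optimal" threshold minimises the Euclidean distance to the (FPR 0,
  TPR 1) corner, ties resolved toward the higher threshold.
* **Grain for scoring.** Information scores default to residue-grain
  networks (one node per residue); atomic records are retained through
  aggregation so single nodes can be split back to atoms for mixed-grain
  analysis.

## What the synthetic generators emulate

`generate_coupled_timelines()` draws a master Bernoulli series and a partner
that copies it per frame with a set coupling probability -- the minimal model
of two interactions that share information. Coupling 1 duplicates the master
(MI equals the master's entropy); coupling 0 gives independence (MI at the
bias floor). Defaults are occupancy 0.5 -- the maximum-entropy, hardest-case
rate -- and the coupling/length regime used in the recovery experiments
(coupling 0.8, 2000 frames).

`generate_hub_network()` plants that coupling on the two edges incident to
one node of a ring (every node has degree 2, so degree alone cannot reveal
the hub); the hub should attain the top NCF rank. The recovery test demands
this in at least 95% of 100 seeds.

`generate_toy_ensemble()` builds a multi-model coordinate ensemble of
pseudo-residues spaced 20 Å apart, with one carbon contact oscillating
across the 5 Å boundary and one backbone hydrogen bond oscillating across
the 135-degree angle boundary on a known square-wave schedule, so extraction
can be checked against construction exactly.

These generators are geometric and statistical, not physical: no force
field, no solvent, no correlated backbone motion, and timeline coupling is
i.i.d. across frames (no autocorrelation, unlike real MD). A green test
therefore establishes that the estimators and extractors compute what they
claim on data with known ground truth -- not that the scores predict
allostery in any particular protein; that judgement rests on the benchmark
evaluation against experimentally derived labels.

## Known limitations

* The benchmark label/score tables for the PDZ2 system and the NMR
  structures they refer to are third-party supplementary data and are not
  redistributed here; the acceptance checks that re-derive the published
  AUC values run only when those files are supplied locally (see
  `tests/testthat/test-acceptance.R` for the expected layout).
* The PDB reader handles the common fixed-column ATOM/HETATM layout with
  MODEL blocks; mmCIF and trajectory binary formats are out of scope.
* No continuous-variable MI estimators, transfer entropy or weighted
  centralities; frame clustering is not implemented.
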