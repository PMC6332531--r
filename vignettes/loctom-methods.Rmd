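---
title: "Location-aware topological overlap for protein module detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-aware topological overlap for protein module detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loctom)
```

## The problem

Clustering a protein interaction network (PIN) is a standard route to
predicting protein complexes: complexes appear as densely interconnected
modules. But a PIN aggregates interactions detected anywhere in the cell,
while physical interaction requires spatial co-occurrence. Two nuclear
proteins that both bind a membrane receptor in separate assays share a
"partner" that can never mediate an indirect association between them in
vivo. `loctom` addresses this by making subcellular localization a
first-class ingredient of network preprocessing.

## Localization model

Annotations are reduced to six major compartments — nucleus, cytoplasm,
membrane, extracellular, mitochondria, secretory-pathway — via a raw-label
merge map shipped as YAML (`location_merge_map()`), with the Golgi
apparatus, endoplasmic reticulum, endosome, peroxisome, lysosome, vacuole
and vesicles pooled into the secretory-pathway label. Mitochondria is kept
as its own major compartment; annotation sources disagree on whether to
pool it with the secretory pathway, and keeping it separate preserves a
biologically distinct organelle (users can supply their own map to pool
it). Major labels are fixed points of the map, so re-applying it is a
no-op. A protein may carry several major locations; proteins may also be
unannotated, in which case they share a location with nothing — the
conservative reading, since fabricating co-localization would leak
unfiltered edges into every downstream stage. Unknown raw labels are an
error by default (`unknown = "drop"` logs and drops them), because silent
label loss corrupts the filter invisibly.

## Co-localization filtering and overlap scores

`build_clpin()` keeps exactly the edges whose endpoints share a major
location. Nodes left isolated are dropped by default so that the
co-localized network's protein count reflects what survives, mirroring how
curated human networks shrink under this filter.

`tom_matrix()` scores pairs by topological overlap,

$$\mathrm{TOM}(i,j) = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

shared partners plus the direct edge, normalized by the smaller degree so
scores fall in [0, 1]. The sum index excludes $i$ and $j$: a protein is
never its own interaction partner, and self-pairs in input files are
stored out of the graph and excluded from degrees. (Computing the
numerator as a matrix square with a unit diagonal would count the direct
edge twice for adjacent pairs; the zero-diagonal adjacency square used
here matches the summation definition exactly, and a brute-force
double-loop oracle pins this down in the tests.)

`ltom_matrix()` gates each numerator term on co-localization: a shared
partner $u$ counts only when $i$, $u$, $j$ are annotated to a common
compartment ($\sigma(i,u,j) = 1$), the direct edge only when $i$ and $j$
co-localize ($\sigma'(i,j) = \sigma(i,i,j)$). The denominator is
unchanged, so $\mathrm{LTOM} \le \mathrm{TOM}$ pointwise, with equality
when every protein shares every location. Both matrices set the diagonal
to 1 by convention.

`impute_network()` turns scores into candidate interactions: every
non-adjacent pair scoring at least $\tau$ becomes a new edge tagged
`imputed = TRUE`; no proteins are added, and original edges are retained.
How high-overlap pairs become edges is not pinned down by any published
rule we could adopt, so the threshold is explicit and configurable:
$\tau = 0.5$ by default (a pair must overlap in at least half of the
smaller neighbourhood), with a `top_k` mode for users who want to hit a
target edge count. $\tau \le 0$ is rejected — it would add every pair
sharing any neighbor.

## Module detection

`detect_modules_greedy()` maximizes cohesiveness

$$f(V) = \frac{w_{in}(V)}{w_{in}(V) + w_{bound}(V) + p\,|V|}$$

by local search: seeds are the not-yet-covered nodes in descending degree
(ties broken by ID); each step takes the single vertex addition or
removal that most increases $f$; clusters stop at a local maximum and
near-duplicates are merged when their overlap score
$\omega = |A \cap B|^2 / (|A||B|)$ reaches 0.8. This is a documented,
deterministic simplification of the overlapping-neighbourhood-expansion
family of clusterers — reproducing any particular binary's seed selection
or significance filter is a non-goal; the contract is correctness of
$f(V)$ and recovery of planted modules. The penalty default $p = 2$ is
the customary choice for modelling undetected interactions; published
pipelines rarely state their value, so it is exposed as a parameter.

`detect_modules_mcl()` implements Markov clustering: expansion (squaring
the column-stochastic flow matrix) alternating with inflation (entrywise
power, column renormalization) until the flow stabilizes. Self-loops are
added before normalization — the standard device preventing period-2
oscillation on bipartite structures (a bare edge A–B never converges
without them). Entries below 1e-8 are pruned after inflation for
tractability; on pathological inputs pruning can in principle change the
result, which is why it is documented and configurable. Clusters are the
connected components of the converged flow's support: hard and
non-overlapping.

`filter_modules()` applies the inclusive reporting filter (size ≥ 10,
internal density ≥ 0.25 by default); inclusive bounds match the
convention of benchmark tables reporting "size >= 10".

## Evaluation and enrichment

`sn_ppv_acc()` computes clustering-wise sensitivity
$\mathrm{Sn} = \sum_j \max_i t_{ij} / \sum_j w_j$, positive predictive
value $\mathrm{PPV} = \sum_i \max_j t_{ij} / \sum_i \sum_j t_{ij}$ and
$\mathrm{Acc} = \sqrt{\mathrm{Sn} \cdot \mathrm{PPV}}$ from the
module-complex overlap table $t_{ij}$. The weight $w_j$ is the size of
reference complex $j$ — the standard complex-wise sensitivity
denominator, which keeps Sn in [0, 1] — and reference complexes are not
shrunk to the analyzed network's proteins, the conservative choice. A
PPV denominator of zero (no module touches any complex) defines PPV = 0.

`hypergeom_test()` gives the upper-tail probability of observing $t$ or
more gene-set members in a module (computed through `phyper`, stable in
log space); `bh_adjust()` applies Benjamini–Hochberg step-up;
`ors_report()` summarizes a module set by its overrepresentation score
(fraction of modules with adjusted $P$ strictly below 0.01), the fraction
of modules containing any gene-set member, and the distinct gene-set
members covered by significant modules — counted once even when modules
overlap. The background defaults to the analyzed network's protein set,
not the genome; both the full gene set and its background-annotated
subset are exposed as coverage denominators, since either convention
appears in practice.

## Scale-free assessment

`fit_power_law()` fits $p(k) \sim k^{-\gamma}$ to positive degrees with
nonzero observed frequency. The default is least squares of
$\log p(k)$ on $\log k$ **weighted by the count at each degree**: in an
unweighted fit every degree value gets one vote, so the long sparse tail
(degrees seen once) dominates and biases $\gamma$ low by roughly 0.1–0.2
at realistic sample sizes; count weighting removes this while remaining a
transparent straight-line fit. The unweighted fit (`method = "ls"`) and a
discrete truncated maximum-likelihood estimate (`method = "mle"`) are
available for comparison.

## Synthetic study conditions

`generate_synthetic()` emulates the structure the analysis assumes:
disjoint dense modules (within-module edge probability `p_in = 0.6`) on a
sparse Bernoulli background (`p_out = 0.01`) over 300 proteins, six
planted modules of 10–15 members, each with a home compartment its
members carry with probability 0.9, one or two labels per protein, seed
42. These defaults are the package's reference conditions: module sizes
and densities sit in the range of curated complexes, and 0.9 coherence
encodes "interacting proteins are prone to share a compartment" without
making the filter trivial. The planted catalog is returned as ground
truth and the first module's members double as a gene set for enrichment
tests. The generator is a pure function of its spec (Mersenne-Twister,
seed pinned, global RNG state untouched); an optional
preferential-attachment background supplies heavy-tailed degrees for
exponent-recovery tests.

What the generator does **not** emulate: hub proteins spanning
compartments, annotation noise/incompleteness correlated with degree,
overlapping complexes, and database-specific artefacts. Passing the
planted-recovery tests therefore shows the pipeline recovers
compartment-coherent dense modules under clean conditions, not that it
matches any particular database's module counts.

## Problem sizes and numerical choices

The shipped tests run oracle comparisons exhaustively over all graphs on
four nodes and on random annotated graphs up to seven nodes (500 draws),
bound properties on 200 random graphs up to 60 nodes, exponent recovery
on three samples of 50,000 degrees, and the full pipeline on the default
300-protein conditions — sizes chosen so the entire suite completes in
about a minute while still exercising every contract. Ratio computations
match the brute-force oracles to 1e-12; integer quantities match exactly.
Cohesiveness ties during greedy growth are broken deterministically
(improvements must exceed 1e-12), making two runs bit-identical.

## Known limitations

- The greedy clusterer is a simplified variant; exact agreement with any
  published clustering binary is out of scope.
- Identifier mapping (gene↔protein, across databases) is the user's
  responsibility; IDs are compared as case-sensitive strings.
- The imputation threshold is a modelling choice, not an estimated
  quantity; different τ give nested edge sets (monotonicity is tested)
  but different module sets.
- MCL pruning can alter clusters on adversarial inputs; set
  `prune = 0` to disable.
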