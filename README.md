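# loctom

Protein–protein interaction (PPI) networks pool interactions detected
anywhere in the cell, yet two proteins can only physically interact where
they co-occur. `loctom` is an R package for systems biologists who want to
exploit subcellular localization when predicting protein complexes from a
PPI network. It implements a location-aware preprocessing pipeline:

1. **Co-localization filtering.** A global PIN (GPIN) is restricted to the
   edges whose endpoints share at least one of six major compartments
   (nucleus, cytoplasm, membrane, extracellular, mitochondria,
   secretory-pathway), giving the co-localization PIN (CLPIN). Raw
   compartment annotations are merged to the six majors through a shipped,
   user-replaceable YAML map.
2. **Overlap scoring.** Every protein pair is scored with the topological
   overlap measure

   TOM(i,j) = ( Σ_{u≠i,j} a_iu a_uj + a_ij ) / ( min(k_i, k_j) + 1 − a_ij )

   and with its locational extension, in which a shared partner u counts
   only if i, u, j are annotated to a common compartment (σ(i,u,j) = 1)
   and the direct edge only if i and j co-localize (σ′(i,j) = 1):

   LTOM(i,j) = ( Σ_u a_iu a_uj σ(i,u,j) + a_ij σ′(i,j) ) / ( min(k_i, k_j) + 1 − a_ij )

   LTOM ≤ TOM ≤ 1 pointwise.
3. **Imputation.** Non-adjacent pairs scoring at least τ (default 0.5) are
   added as candidate interactions — no new proteins — yielding the
   TOM-imputed (TOPIN) or LTOM-imputed (LTOPIN) network.
4. **Module detection.** A cohesiveness-guided greedy clusterer
   (f(V) = w_in / (w_in + w_bound + p·|V|), overlapping modules) and
   Markov clustering (MCL) are provided, with the usual size ≥ 10 /
   density ≥ 0.25 reporting filter.
5. **Evaluation and enrichment.** Module sets are benchmarked against a
   reference complex catalog via clustering-wise sensitivity, positive
   predictive value and their geometric mean (Sn, PPV, Acc = √(Sn·PPV));
   gene-set overrepresentation per module uses the upper-tail
   hypergeometric test with BH-FDR adjustment, summarized by the
   overrepresentation score (ORS = fraction of modules significant at
   0.01).

A seeded synthetic generator produces localization-annotated networks with
planted, compartment-coherent modules, so the whole pipeline is testable
without any database download.

## Worked example

```r
library(loctom)

syn   <- generate_synthetic(synthetic_spec())       # 300 proteins, 6 planted modules
clpin <- build_clpin(syn$network, syn$localization) # co-localization filter
lt    <- ltom_matrix(clpin, syn$localization)       # location-aware overlap scores
ltopin <- impute_network(clpin, lt, tau = 0.5)      # add high-scoring pairs
mods  <- detect_modules_greedy(ltopin, p = 2)       # overlapping modules
sn_ppv_acc(mods, syn$catalog)
#> # A tibble: 1 × 5
#>      sn   ppv   acc n_predicted n_reference
#>   <dbl> <dbl> <dbl>       <int>       <int>
#> 1 0.926     1 0.963          51           6
```

Against the planted ground truth, the best-matching modules cover 92.6% of
the planted members (Sn), every detected module maps cleanly into a single
planted complex (PPV = 1), and the geometric accuracy is 0.963. On the toy
five-protein network (`fig2_fixture()`) where partner P2 fails to
co-localize with the interacting pair, `tom_matrix()` gives TOM(A,B) = 1
while `ltom_matrix()` gives LTOM(A,B) = 0.75 — the location-aware score
discounts the non-co-localized shared partner.

Enrichment of a gene set (e.g. cancer genes) in the detected modules:

```r
ors_report(mods, syn$gene_set, ltopin)   # hypergeometric + BH, ORS summary
```

A thin command-line wrapper over the same functions lives at
`exec/loctom.R` (subcommands `filter`, `impute`, `cluster`, `evaluate`,
`enrich`, `stats`, `synth`, `run`; YAML config; JSON provenance records
next to every output).

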