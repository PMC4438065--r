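# cranet — anatomical network analysis of skull bone-contact networks

`cranet` is an R package for studying the morphological organization of
the skull through the topology of its bone contacts. A skull is modeled
as an undirected, unweighted network: nodes are bones, links are the
physical articulations (sutures and synchondroses) between them, coded
1/0 in a symmetric adjacency matrix. From that model the package

* **identifies connectivity modules** — groups of bones with more
  contacts among themselves than to the rest of the skull — by
  hierarchical clustering of pairwise *topological overlap* (TO), scoring
  every dendrogram cut with Newman's modularity

  Q = (1/2K) Σᵢⱼ [Aᵢⱼ − kᵢkⱼ/2K] δ(mᵢ, mⱼ)

  and keeping the maximum-Q partition; modularity strength is summarized
  as M = (number of modules) × Q;

* **quantifies morphological complexity** with five network parameters:
  number of bones N, number of contacts K, density D = 2K/(N(N−1)),
  mean clustering coefficient C (triangular contact motifs), and degree
  heterogeneity H = var(k)/mean(k) (anisomerism: how unequal bones are
  in their connectivity);

* **tests for co-evolution of modularity and complexity** (the
  near-decomposability hypothesis — that modular organization promotes
  the evolution of complexity) on a calibrated phylogeny, using
  Abouheif's permutation test and Blomberg's K for phylogenetic signal,
  and Pearson correlations of Felsenstein's independent contrasts
  (through the origin) between M and each complexity parameter;

* **generates synthetic data** — bilaterally symmetric skull-like
  networks with optional planted module structure, pure-birth
  phylogenies, and Brownian-motion traits — so every stage of the
  pipeline can be exercised and calibrated without external data.

Intended users are morphologists and evolutionary biologists working
with discrete anatomical codings, and anyone needing a deterministic,
seedable implementation of TO-based community detection with
modularity-Q partition selection.

## Worked example

Generate a 23-bone skull with planted cranial / midfacial / palatal
organization, profile its complexity, and recover its modules:

```r
library(cranet)

layout <- list(blocks = c(1,1,1, 2,2,2, 3,3,3, 1,1, 2,2, 3),
               p_within = 0.8, p_between = 0.08)
net <- generate_skull(n_pairs = 9, n_midline = 5, seed = 7,
                      modular_layout = layout,
                      bone_names = primate_bone_names(), taxon = "demo")
complexity_profile(net)
#> Complexity profile: demo
#>   N = 23  K = 72  D = 0.2846  C = 0.6967  H = 0.2530
#>   (H convention: population/variance_over_mean )

hierarchical_modules(net)
#> Connectivity modules: demo
#>   3 module(s), Q = 0.5544, M = 1.6632  (TO: open_neighborhood, linkage: average)
#>   [1] neurocranial: par_l par_r tem_l tem_r zyg_l zyg_r occ sph
#>   [2] midfacial: lac_l lac_r nas_l nas_r nch_l nch_r fro eth
#>   [3] palatal: pal_l pal_r pmx_l pmx_r max_l max_r vom
```

The profile says this skull realizes 72 of the 253 possible bone
contacts (D ≈ 0.28), has dense triangular motifs (C ≈ 0.70) and fairly
even bone connectivity (H ≈ 0.25). Module detection recovers the three
planted regions exactly and labels them by their anchor bones
(occipital → neurocranial, ethmoid → midfacial, palatines → palatal);
Q ≈ 0.55 means within-module contacts far exceed the degree-preserving
random expectation, and M = 3 × Q ≈ 1.66 summarizes both the number and
the sharpness of the modules.

A full comparative study — per-taxon modules and complexity, the
taxa × {M, N, K, D, C, H} trait table with six-number summaries,
Abouheif signal tests for all six parameters, and the five PIC
correlations of M against complexity — runs through one call:

```r
nets <- lapply(1:8, function(i)
  generate_skull(9, 3 + (i %% 4), seed = i, taxon = paste0("t", i)))
report <- run_study(nets, generate_tree(8, seed = 99),
                    n_permutations = 1000, seed = 42)
report                       # printed summary
write_study_report(report, "study_out")   # report.json, traits.tsv, summary.tsv
```

Real codings are read with
`read_skull_network("taxon.csv", "csv_matrix")` (labeled 0/1 CSV
matrices; tab-separated edge lists and GraphML are also supported) and
`read_newick_tree("tree.nwk")` for the calibrated phylogeny.

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end analysis from
scratch on a seeded 20-taxon synthetic cohort at real primate skull
scale (21–24 bones per skull, contact density ≈ 0.25, pure-birth
20-tip tree, 1000 permutations per signal test) and writes its JSON
output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

Every exported function carries full help; the methods vignette
(`vignettes/anatomical-networks.Rmd`) documents the model, the TO and
H conventions, the partition-selection procedure, the comparative
tests, what the synthetic generators do and do not emulate, and known
limitations.
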