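# triomics

Three-way tensor decomposition and weighted co-expression analysis of
gene expression measured over two crossed factors — the motivating case
being a panel of sugarcane genotypes sampled along culm developmental
stages (internodes), with per-genotype agronomic traits such as sugar
and fibre content.

The package is for analysts who have a genes × samples count (or TPM)
matrix, a sample design table (genotype, internode, replicate) and a
trait table, and who want to answer two questions:

1. **How is expression variation structured across the two factors?**
   The replicate-mean expression values are arranged in a genotype ×
   gene × internode array *X* and decomposed with the Tucker3 (three-way
   PCA) model
   
   *x*<sub>ijk</sub> = Σ<sub>p</sub>Σ<sub>q</sub>Σ<sub>r</sub>
   *a*<sub>ip</sub> *b*<sub>jq</sub> *c*<sub>kr</sub> *g*<sub>pqr</sub> +
   *e*<sub>ijk</sub>,
   
   with orthonormal component matrices *A* (genotypes), *B* (genes), *C*
   (internodes) and a core array *G*.  Because the loadings are
   orthonormal, *g*<sub>pqr</sub>² is exactly the share of fitted
   variation carried by component triple (p, q, r), which makes the core
   a variance-partitioning device: elements whose genotype component is
   constant are internode main effects, elements whose internode
   component is constant are genotype main effects, and the rest is
   interaction.
2. **Which co-expressed gene modules track the traits, and which genes
   are trait-specific candidates?**  A weighted co-expression network is
   built from scratch: unsigned adjacency |cor|^β with β selected by
   scale-free topology fit, topological overlap (TOM), Ward clustering
   with a deterministic branch-selection module cut, module eigengenes,
   module/gene–trait correlation statistics, and the restrictive
   filtration *top-k genes by |r| ∩ target module ∖ antagonistic
   module*.

A synthetic-data generator (`sim_config()`, `simulate_experiment()`)
produces the full design — negative-binomial counts whose log-scale
means carry a planted Tucker3 structure, planted co-expression modules,
and traits tied to module activity — with complete ground truth, so
every stage of the pipeline can be validated against known answers.

## Worked example

Simulate a 10-genotype × 4-internode × 3-replicate experiment with two
antagonistic 60-gene modules, then run both analysis streams:

```r
library(triomics)

cfg <- sim_config(n_genotypes = 10, n_genes = 500, n_internodes = 4,
                  n_replicates = 3, true_ranks = c(2, 3, 2), seed = 42,
                  module_spec = list(
                    list(size = 60, trait_effect = 1,  inter_gene_cor = 0.9),
                    list(size = 60, trait_effect = -1, inter_gene_cor = 0.9)))
sim <- simulate_experiment(cfg)

counts <- filter_min_count(sim$counts, min_count = 10, min_fraction = 0.70)
logcpm <- normalize_log(counts, tmm_factors(counts), mode = "CPM")

tensor <- build_threeway_array(logcpm, sim$metadata)
fit <- tucker3(tensor, ranks = c(2, 3, 2))
summary(fit)
#> Tucker3 model, ranks (P, Q, R) = (2, 3, 2)
#>   tensor: 10 genotypes x 500 genes x 4 internodes
#>   explained variance: 71.4%  (converged after 7 sweeps)
#>
#> Leading core elements (6 of 12):
#>      p q r          g fitted_share total_share
#> g111 1 1 1 123.523704        73.5%       52.5%
#> g222 2 2 2 -68.413351        22.6%       16.1%
#> g231 2 3 1  17.631636         1.5%        1.1%
#> ...
```

The model explains 71.4% of the centred expression variation; the
dominant core element g111 (73.5% of the fitted SS) couples the first
component of every mode — with the leading genotype component constant
across genotypes, this is expression change along the culm shared by all
genotypes.

```r
net <- network_config(power = 4, min_module_size = 40)
tom <- tom_similarity(adjacency(logcpm, net$power))
modules <- detect_modules(tom, net)
modules
#> Module assignment: 500 genes, 3 module(s) + grey
#> turquoise      blue     brown      grey
#>       319        61        60        60

eig <- module_eigengene(logcpm, modules)
module_trait_relation(eig, sim$traits)
#>      module trait      r       p   n
#> 1 turquoise trait -0.016 8.6e-01 120
#> 2      blue trait -0.513 2.1e-09 120
#> 3     brown trait  0.606 2.3e-13 120
```

The two planted modules surface as `brown` (positively correlated with
the trait, r = 0.61) and `blue` (negatively, r = −0.51); the large
`turquoise` module is the tensor-driven background and is unrelated to
the trait (r = −0.02).

```r
gs <- gene_significance(logcpm,
                        setNames(sim$traits$trait, sim$traits$sample_id),
                        "sugar")
ms <- module_significance(gs, modules)
ms
#>      module trait n_genes mean_gs unassigned
#> 1     brown sugar      60  0.4971      FALSE
#> 2      blue sugar      61  0.4186      FALSE
#> 4      grey sugar      60  0.0634       TRUE
#> 3 turquoise sugar     319  0.0476      FALSE

top <- top_k_by_significance(gs, k = 50)
cand <- trait_specific_candidates(top, modules,
                                  target = ms$module[1], exclude = "none")
head(as.data.frame(cand), 5)
#>   rank      gene module     r    gs        p
#> 1    1 gene_0018  brown 0.598 0.598 5.83e-13
#> 2    2 gene_0053  brown 0.577 0.577 5.45e-12
#> 3    3 gene_0043  brown 0.575 0.575 6.54e-12
#> 4    4 gene_0004  brown 0.572 0.572 8.53e-12
#> 5    5 gene_0054  brown 0.563 0.563 2.20e-11
```

All 41 candidates fall inside the planted trait-linked module (its genes
are `gene_0001`–`gene_0060`), i.e. the filtration recovers exactly the
genes that were simulated to drive the trait.

`run_pipeline()` executes the same workflow end-to-end from files
(counts TSV, metadata and trait CSV) and writes every artifact plus a
JSON manifest with seeds and md5 hashes for bit-identical reruns.

## Package tour

| Stage | Functions |
| --- | --- |
| Simulation | `sim_config`, `simulate_tucker_tensor`, `simulate_counts`, `simulate_traits`, `simulate_experiment` |
| Pre-processing | `tmm_factors`, `normalize_log`, `filter_min_count`, `filter_zero_fraction`, `build_threeway_array`, `sample_pca`, `expression_dendrogram`, `autoscale_traits` |
| Three-way analysis | `tucker3` (+ `print`/`summary`/`coef`/`fitted`/`residuals`/`plot`/`simulate` methods), `tucker3_grid`, `choose_model`, `hosvd_init`, `unfold`/`refold`, `explained_variance`, `core_contributions`, `partition_main_effects`, `tucker3_model` |
| Co-expression | `network_config`, `pick_soft_threshold`, `adjacency`, `tom_similarity`, `detect_modules`, `module_eigengene`, `module_trait_relation`, `gene_significance`, `module_significance` |
| Gene selection | `positive_subset`, `top_k_by_significance`, `trait_specific_candidates`, `module_overlap` |
| I/O & workflow | `read_expression`/`write_expression`, `read_metadata`, `read_traits`, `write_newick`, `write_tucker3`, `run_pipeline` |

The methods vignette (`vignettes/threeway-coexpression.Rmd`) documents
the model, every tunable parameter with its default and rationale, the
synthetic-data generator's assumptions, and known limitations.
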