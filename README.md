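# ixp — integrative expression profiling over reordered interaction networks

`ixp` is an R package for network-guided feature transformation in two-class
expression classification. It targets a blind spot of gene-by-gene analysis:
groups of interacting genes that shift *coordinately but weakly*, each one
too noisy to reach significance on its own. The package arranges the genes
of a disease-specific protein-interaction subnetwork along a line with an
ant-colony-optimization reordering (ACOR) heuristic, so that interacting
genes occupy neighbouring positions, and then integrates each sample's
expression along that axis with a Gaussian influence function. Adjacent weak
genes superpose into peaks a classifier can use.

Given an ordering π of the N network genes, degree-derived weights
w<sub>g</sub> ∈ (0, 1], and a sample's expression x<sub>g</sub>, the
integrated profile is

> F(i) = Σ<sub>g</sub> w<sub>g</sub> · x<sub>g</sub> ·
> exp( −(i − π(g))² / 2σ² ),  σ = r · b,  i = 1…N

with horizontal influence coefficient r ∈ [0, 1) and base bandwidth b
(positions). At r = 0 this is exactly the raw weighted profile in position
order. The ordering minimises (heuristically) the linear arrangement cost
Σ<sub>(u,v)∈E</sub> |π(u) − π(v)| via pheromone-biased ant walks, density
ranking, and strictly-improving local search. Random-walk (PageRank-style)
ranking, neighbourhood-Jaccard hierarchical clustering, and random
permutations are built in as comparison orderings, and a linear-SVM
train/test harness sweeps r across all of them.

All user-facing functions are pipe-friendly: edge lists, seed lists,
orderings, weights and sweep results are tibbles; fitted orderings and sweep
grids have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

The built-in generator produces a planted-partition interaction network
(4 modules × 10 genes) with two-class expression in which half the modules
carry weak coordinated shifts (0.4 sd per gene) and two singleton markers
carry strong shifts:

```r
library(ixp)

case <- generate_case(synth_config(seed = 7))
case$network
#> <ppi_network> 40 genes, 173 edges

ord <- acor_reorder(case$network, acor_params(seed = 7))
glance(ord)
#> # A tibble: 1 × 4
#>   n_genes  cost initial_cost refinement_gain
#>     <int> <int>        <int>           <int>
#> 1      40   676         2487            1811

linear_arrangement_cost(case$network, random_order(case$network, seed = 7))
#> [1] 2371
```

The ant-colony ordering compresses the total edge length from a
random-permutation baseline of ~2400 down to 676 — interacting genes now sit
next to each other, and `plot_reordered_adjacency(case$network, ord)` shows
the familiar block-diagonal seriation pattern.

The classification harness transforms train and test sets along each
ordering and scores a linear SVM over a grid of influence coefficients:

```r
sw <- run_sweep(case$train, case$test, case$network,
                r_grid = c(0, 0.3, 0.6, 0.9),
                methods = c("acor", "random"), seed = 7)
sw
#> # A tibble: 8 × 3
#>   method     r accuracy
#>   <chr>  <dbl>    <dbl>
#> 1 acor     0      0.875
#> 2 acor     0.3    0.875
#> 3 acor     0.6    0.85
#> 4 acor     0.9    0.875
#> 5 random   0      0.875
#> 6 random   0.3    0.95
#> 7 random   0.6    0.9
#> 8 random   0.9    0.925
```

Accuracies at r = 0 are identical across methods by construction (the delta
kernel makes the ordering a mere column permutation). A single 40-sample
test split carries roughly ±0.06 of binomial noise, so per-replicate
rankings like the one above fluctuate; the package's conclusions about
ordering methods are drawn from replicate averages (see the methods
vignette, `vignettes/ixp-methods.Rmd`, which also documents where the
smoothing gain does and does not appear at this problem scale).
`autoplot(sw)` draws the accuracy-vs-r comparison figure.

A command-line wrapper over the same functions ships in `inst/cli/ixp`
(subcommands `simulate`, `build-net`, `reorder`, `transform`, `sweep`).

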