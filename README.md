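# mitocompare

Pairwise comparison of annotated fungal mitochondrial genomes:
composition and strand skews, region partitioning and size-expansion
decomposition, per-gene K2P and Nei–Gojobori (1986) Ka/Ks under the
mold mitochondrial genetic code, tRNA variation by cloverleaf domain,
group-I intron position classes, exact/tandem/interspersed repeats,
gene-order breakpoint distance, and neighbor-joining phylogenies with
bootstrap support — plus a fully parameterised synthetic genome
generator that provides exact ground truth for every stage.

## Worked example

Generate a known-truth genome pair (a ~66.7 kb and a ~77.1 kb
AT-rich circular genome, 16 vs 24 group-I introns) and run the full
pipeline:

```r
library(mitocompare)

pair <- generate_pair(generator_spec(seed = 42))
pair$truth$sizes
#>     a     b 
#> 66702 77133

dir <- tempfile()
res <- run_all(pipeline_config(genomes = list(pair$a, pair$b),
                               out_dir = dir, seed = 1))

res$composition$a
#> 66702 bp | GC 21.66% AT 78.34% | AT skew -0.01 | GC skew -0.02
```

Where do the extra ~10 kb of genome B come from? The expansion
decomposition attributes the size difference to region categories
(percent, summing to 100; intron gain dominates by construction):

```r
round(res$decomposition$contributions, 1)
#> protein_coding            rna       intronic     intergenic 
#>          -16.6            0.0          140.0          -23.3
```

Per-gene divergence for the 15 shared core genes, fastest first
(`rps3` fastest and `atp9` slowest by construction; `atp8` carries
only synonymous change):

```r
head(res$divergence[order(-res$divergence$k2p),
                    c("gene", "length_a", "length_b",
                      "k2p", "ka", "ks", "ka_ks")], 5)
#>    gene length_a length_b    k2p     ka     ks ka_ks
#> 15 rps3     1506     1518 0.1560 0.1467 0.2051 0.715
#> 14 nad6      642      642 0.1322 0.1144 0.2132 0.536
#> 7  cox3      810      810 0.1084 0.1107 0.0959 1.154
#> 9  nad2     1734     1734 0.0629 0.0564 0.0896 0.629
#> 10 nad3      417      396 0.0580 0.0619 0.1344 0.461
```

tRNA variable sites localised to cloverleaf domains (the generator
plants 6 acceptor-stem, 4 D-arm, 2 T-arm and 1 anticodon-arm
mutation):

```r
res$trna$domain_totals
#>   acceptor_stem           d_arm   anticodon_arm variable_region 
#>               6               4               1               0 
#>           t_arm           other 
#>               2               0
```

Gene order is collinear, so expansion — not rearrangement — explains
the size difference:

```r
res$breakpoints
#>             synthetic_A synthetic_B
#> synthetic_A           0           0
#> synthetic_B           0           0
```

Every stage also writes a TSV table plus a human-readable
`summary.md` to the output directory (`core_gene_divergence.tsv`,
`intron_position_classes.tsv`, `expansion_decomposition.tsv`,
`supermatrix.nex`, …).

Real annotated genomes are consumed the same way, via GenBank flat
files:

```r
res <- run_all(pipeline_config(paths = c("genomeA.gb", "genomeB.gb"),
                               out_dir = "out"))
```

See the vignette (`vignettes/mitogenome-comparison.Rmd`) for the
method details and design notes.
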