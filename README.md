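# homeologr

Detecting and dating allopolyploidy from a handful of low-copy nuclear
gene trees is a recurrent problem in plant systematics: polyploid taxa
carry pairs of *homeologs* (one copy per parental subgenome, tagged A and
B), and the question is whether those pairs arose by hybridization
between identifiable diploid lineages — and whether once or twice — or
merely by duplication and differential loss.  `homeologr` is an R
toolkit for systematists and evolutionary geneticists that scores these
competing scenarios by gene-tree/network reconciliation and implements
the companion analyses such a study needs: ancestral-state stochastic
mapping of discrete traits, ploidy classification from karyotypes and
homeolog copy counts, and SNP-based diversity analysis by
identity-by-state distances and classical multidimensional scaling.

## The score

A hybridization hypothesis — a rooted phylogenetic network *N* with at
most two hybridization nodes — is expanded into its multi-labeled
**MUL tree** *M(N)*: every taxon below a hybridization appears once per
parental subgenome.  A gene family *G* (a rooted binary gene tree with a
copy-to-species map) is embedded into *M(N)* by the LCA mapping after
assigning each copy of a repeated species to one subgenome leaf, and the
duplication–loss parsimony cost is minimized over assignments σ:

```
cost(G, N) = min over σ  [ c_D · D(G, M(N), σ) + c_L · L(G, M(N), σ) ]
score(N)   = Σ over families  cost(G_i, N)
```

with unit event costs by default.  Losses are charged on the host tree
restricted to the taxa sampled in each family, so sampling gaps are not
penalized.  A family congruent with the network scores 0; lower total
scores are better.  Hypotheses with zero, one and two events are
enumerated around a backbone tree, scored, and ranked; the *preferred*
hypothesis is the one with fewest events within a small score margin
(default 5) of the minimum — extra reticulations must earn their keep.

## Worked example

Simulate four gene families on the bundled eight-taxon network (one
hybridization between the diploids `P` and `S` giving rise to the
polyploids `H1`, `H2`), then scan all candidate scenarios:

```r
library(homeologr)

net <- toy_allopolyploid_network()
dec <- homeologr:::network_events(net)
T1  <- graft_clade(dec$backbone, dec$events[[1]]$clade, "P")  # A-side tree
T2  <- graft_clade(dec$backbone, dec$events[[1]]$clade, "S")  # B-side tree

fams <- simulate_gene_families(net, n_families = 4,
                               dup_rate = 0.2, loss_rate = 0.2, seed = 1)
scan <- run_scan(list(T1, T2), polyploid_taxa = c("H1", "H2"),
                 candidate_parents = c("P", "S"), families = fams)
scan
#> <scan_report> 308 hypotheses; best score 1; preferred: N1:PxS
#> # A tibble: 5 × 4
#>   label     n_events total_score delta
#>   <chr>        <int>       <dbl> <dbl>
#> 1 N1:PxS           1           1     0
#> 2 N1:D2xP          1           9     8
#> 3 N1:D2|SxP        1           9     8
#> 4 N1:D1xS          1          13    12
#> 5 N1:D1|PxS        1          13    12

scan$best_per_events
#> # A tibble: 3 × 4
#>   label        n_events total_score delta
#>   <chr>           <int>       <dbl> <dbl>
#> 1 T1                  0          21    20
#> 2 N1:PxS              1           1     0
#> 3 N2:D2xP|D2xP        2          23    22
```

The generating one-event network (`N1:PxS` — hybridization between the
pendant edges of `P` and `S`) is ranked first with total score 1 (a
single residual loss across the four families); the best
no-hybridization tree costs 20 more, and no two-event scenario does
better, so the one-event hypothesis is preferred.  Individual families
reconcile congruently against the true MUL tree:

```r
mul_reconcile(fams[[1]], network_to_multree(net))
#> <recon_result> fam1: 0 duplication(s), 0 loss(es), cost 0
```

The companion stages follow the same style:

```r
pg2c_to_mb1c(1.99)                      # 2C pg -> 1C Mb: 973.11
classify_ploidy(c(20, 28, 40, 60, 21))  # "2x" "4x" "4x" "6x" "unknown"
```

`stochastic_map()` / `summarize_maps()` sample and summarize discrete
character histories; `read_vcf() |> filter_variants() |> ibs_distance()
|> classical_mds() |> assign_groups()` is the diversity pipeline;
`run_pipeline()` drives any stage from a YAML config and writes a JSON
run record.

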