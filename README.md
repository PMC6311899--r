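# sigpath

Infer which receptor-driven signaling pathways a transcriptome could be
running.  `sigpath` is aimed at molecular biologists with (a) a
confidence-scored protein–protein interaction table (STRING-style
`protein1 protein2 combined_score`), (b) curated lists of receptors
(R), kinases (K) and transcription factors (TF), and (c) an RNA-seq
expression matrix for the cells of interest.

## Method in brief

High-confidence interactions (`combined_score ≥ 700`) become a directed
graph whose edges follow signal flow — R→K, K→K, K→TF, plus one
bridging R→R hop for receptors without direct kinase contact — weighted
by `1000 − combined_score`.  For every (R, TF) pair the minimum-weight
*complete path* (3–7 nodes, pattern `R(→R)→K…→TF`) is kept; the paths
rooted at one receptor form its *pathway*, and all-housekeeping paths
(genes expressed in ≥ 75% of a multi-tissue panel at
`log2(FPKM+1) ≥ 1.5`) are dropped.  Against a replicate-averaged query
profile, a path is *potential* when all members are expressed; with
`p_i` the fraction of path *i*'s members above a high-expression
threshold, a pathway with `n` retained paths (one per downstream TF)
scores

    A_s = ( Σ_{i=1..n} p_i ) / n ,   0 ≤ A_s ≤ 1,

and pathways are ranked by `A_s` (ties: `n`, then symbol).  A
permutation test — shuffle gene labels against values, re-run, compare
high-ranked counts — estimates the false-positive rate of the calls.

## Worked example

```r
library(sigpath)

roles <- load_molecule_roles(c("R1", "R2"), c("K1", "K2"),
                             c("TF1", "TF2"))
ppi <- as_interactions(data.frame(
  a = c("R2", "R1", "K1", "K1", "K2"),
  b = c("R1", "K1", "K2", "TF1", "TF2"),
  combined_score = c(720L, 900L, 750L, 800L, 900L)))
bg <- shortest_rk_tf_paths(build_signaling_graph(ppi, roles))
as.data.frame(bg)
#>   receptor            path      roles total_weight terminal_tf
#> 1       R1       R1>K1>TF1     R>K>TF          300         TF1
#> 2       R1    R1>K1>K2>TF2   R>K>K>TF          450         TF2
#> 3       R2    R2>R1>K1>TF1   R>R>K>TF          580         TF1
#> 4       R2 R2>R1>K1>K2>TF2 R>R>K>K>TF          730         TF2

profile <- expression_profile(
  c(R1 = 5, K1 = 4, K2 = 2, TF1 = 6, TF2 = 1, R2 = 0.5))  # cutoff 1.5
potential <- filter_potential_paths(bg, profile)
pathway_activity(potential, profile, high_threshold = 4.5)
#>   receptor n activity_score
#> 1       R1 1      0.6666667
```

R2 (0.5) and TF2 (1.0) are below the 1.5 expression cutoff, so only
`R1>K1>TF1` survives; two of its three members (R1 = 5, TF1 = 6) clear
the 4.5 threshold, hence one pathway with `n = 1` and `A_s = 2/3`.

## Command line

```sh
exec/sigpath simulate --seed 5 --out-dir sim/
exec/sigpath build-graph --ppi sim/ppi.tsv --receptors sim/receptors.txt \
    --kinases sim/kinases.txt --tfs sim/tfs.txt --out graph.json
exec/sigpath housekeeping --panel sim/panel.tsv --out hk.txt
exec/sigpath build-background --graph graph.json --housekeeping hk.txt \
    --out background.tsv
exec/sigpath score --background background.tsv \
    --expression sim/expression.tsv --high-threshold 5.5 --out-prefix res
exec/sigpath fpr --background background.tsv \
    --expression sim/expression.tsv --high-threshold 5.5 \
    --reps 10 --seed 1 --out fpr.json
```

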