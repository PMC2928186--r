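# exdiv

Distance measures for cross-species gene expression divergence.

When the same tissues are profiled in two species, each pair of
one-to-one orthologs gives two expression vectors over homologous
tissues, and their dissimilarity can be treated as an evolving trait.
Different distances see different things: the Euclidean distance on
relative expression, `d_E = sqrt(sum_j (x^R_hj - x^R_rj)^2)`, reacts to
uniform coordinate-wise divergence; the correlation distance
`d_cor = 1 - r` reacts to the absence of concerted changes and ignores
level entirely; and on binarized profiles the **generalized-average (GA)
family**

    d_Aλ = 1 - X_mn / B_λ,   B_λ = ((m^λ + n^λ)/2)^(1/λ)

(`m`, `n` the one-counts, `X_mn` the scalar product, `B_λ` their power
mean) spans Simpson (λ → −∞), Ochiai (λ = 0), Dice (λ = 1) and
max-overlap (λ → +∞) dissimilarities. `exdiv` implements the transforms
(relative expression, mean-threshold binarization, expression entropy),
the four measures, moment-based selection of GA exponents, average-link
clustering of cross-species tissue samples with strict cherry scoring,
an empirical random-pair (derangement) null for calling conserved
ortholog pairs at a chosen significance level, and a synthetic
two-species generator with known ground truth. It is aimed at anyone
comparing expression profiles across species who needs to know — and
show — what their chosen distance actually rewards.

## Worked example

```r
library(exdiv)

sim <- generate_paired_expression(synthetic_config(seed = 11))
res <- run_divergence_analysis(sim$expr1, sim$expr2, sim$pairs,
                               alpha = 0.01, seed = 12)

unlist(res$summary$pairing_scores)
#>          euclidean        correlation binary_correlation                 ga
#>                  8                  8                  8                  8

unlist(res$summary$conserved_counts)
#>          euclidean        correlation binary_correlation                 ga
#>                 99                674                975                975

res$scan$selection
#> $min_skewness
#> [1] "ga(Inf)"
#> $min_kurtosis
#> [1] "binary_correlation"
#> $max_kurtosis
#> [1] "ga(-Inf)"

res$summary$entropy_quartile_n
#> [1] 788

res$contrast$median_diff
#> [1] -527.7768
```

Reading the output: all 8 homologous tissue pairs are recovered as
cherries of the average-link tree under every measure (`pairing_scores`);
at the 1% level against the random-pair null the correlation distance
calls far more ortholog pairs conserved than the Euclidean distance
(`conserved_counts`); the moment scan flags the λ → ∞ GA member by
skewness and the binary correlation by kurtosis; the upper entropy
quartile of 3152 genes holds exactly 788 genes; and the Euclidean-called
conserved genes sit about 528 linear intensity units *below* the
correlation-called ones in median mean expression — Euclidean
conservation is dominated by uniformly low, near-background profiles,
correlation conservation by concerted tissue-specific programs.

A thin command-line wrapper is installed as `exec/exdiv`
(`exdiv simulate --out DIR`, `exdiv analyze --expr1 ... --expr2 ...
--orthologs ... --out DIR`); all results are plain TSV/Newick/JSON files
plus a `run_summary.json` provenance record of every convention in
force.

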