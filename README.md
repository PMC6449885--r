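# mirdap

Ranking candidate miRNA–disease associations by similarity-based neighbour
recommendation.

Biological confirmation of a miRNA–disease association is slow and costly,
so computational ranking of candidate miRNAs is used to prioritise
experiments. `mirdap` builds a miRNA similarity network from shared target
mRNAs using an information-entropy kernel — a target `t` occurring `n(t)`
times among `N` unique miRNA–mRNA interactions carries weight
`-p(t) log2 p(t)` with `p(t) = n(t)/N`, and

    SM(A,B) = 2 H(T_A ∩ T_B) / (H(T_A) + H(T_B))

so that sharing *rare* targets counts most. Same-family pairs are boosted:
`miRNAsim = SM · (1 + FAM)`. Disease similarity blends the same kernel on
disease–gene interactions with Wang-style MeSH-DAG semantic similarity
(ancestor contributions decaying by Δ = 0.5 per edge). Candidate pairs are
scored by k-nearest-neighbour votes in both spaces,

    FC(i,j) = β [α s1(i,j) + (1−α) s2(i,j)] + (1−β) S_disease(i,j),

where `s1` is the vote of the `k1` most similar miRNAs, `s2` the vote of
`i`'s genomic cluster (miRNAs within 20 kb), and `S_disease` the vote of the
`k2` nearest diseases. Defaults: α = 0.5, β = 0.8, k1 = 50, k2 = 30. The
package includes leave-one-out cross-validation with pooled rank-threshold
ROC curves, cold-start (isolated disease / miRNA) evaluation, an α/β grid
sweep, and a seeded synthetic-data generator with planted block structure so
the whole pipeline is testable without downloads.

## Worked example

The shipped ten-interaction fixture (miRNAs A–E, targets g1–g4; also under
`inst/extdata/toy10/` as plain-text files):

```r
library(mirdap)
toy <- toy10_bundle()

profile_entropy(toy$mirna_targets, "A")
#> [1] 0.9931569
mi_similarity(toy$mirna_targets)["A", "B"]
#> [1] 0.5176374
semantic_similarity(toy$mesh)["dA", "dB"]
#> [1] 0.75
```

A's targets g1 and g2 have global rates 0.2 and 0.4, giving 0.9932 bits;
A and B share only g2 (0.5288 bits), so their similarity is
`2·0.5288 / (0.9932 + 1.0499) = 0.5176`. In the MeSH chain dR → dA → dB,
the shared ancestors of dA and dB contribute `(1.5 + 0.75) / (2·1.5) = 0.75`.

End-to-end on a seeded synthetic dataset with planted block structure:

```r
bundle <- simulate_mda(seed = 7)           # 50 miRNAs, 20 diseases, 5 blocks
fit <- fit_bundle(bundle)
cv <- mda_loocv(fit)
glance(cv)
#> # A tibble: 1 × 5
#>     auc mean_disease_auc n_folds alpha  beta
#>   <dbl>            <dbl>   <int> <dbl> <dbl>
#> 1 0.926            0.922     154   0.5   0.8

rank_candidates(fit, "dis011", top_k = 3)
#> # A tibble: 3 × 3
#>    rank mirna  score
#>   <int> <chr>  <dbl>
#> 1     1 mir025 0.240
#> 2     2 mir027 0.191
#> 3     3 mir044 0.185
```

The cross-validated AUC of 0.926 says the recommender recovers the planted
co-association structure; `dis011` belongs to planted group 3, and the top
two candidates (`mir025`, `mir027`) are non-associated miRNAs from block 3
— exactly the planted ground truth. `autoplot(cv)` draws the ROC curve, `tidy(fit)` returns the
full score table, and `isolated_disease_eval(fit, "dis011")` scores the
cold-start setting. A thin command-line front end ships in
`inst/cli/mirdap.R` (subcommands `stats`, `predict`, `loocv`, `simulate`).

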