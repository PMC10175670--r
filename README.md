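# mirdisnet

Prediction of miRNA-disease associations from a sparse bipartite
association network, for computational biologists studying miRNA
involvement in disease. Curated databases such as HMDD v2.0 record only a
few percent of the possible miRNA-disease pairs (5430 associations over
495 miRNAs x 383 diseases, 97.14% sparsity); `mirdisnet` ranks the
unlabelled pairs by fusing similarity and topology evidence:

1. **Disease semantic similarity** over ontology DAGs. Ancestor `x` of
   disease `d` contributes `W1_d(x) = max over children x' in DAG(d) of
   0.5 * W1_d(x')` (with `W1_d(d) = 1`) under the decaying scheme, and
   `W2_d(x) = -log(n(x)/|D|)` under the information-content scheme;
   pairwise similarity is
   `FS(A,B) = sum over shared x of (W_A(x) + W_B(x)) / (Df(A) + Df(B))`,
   averaged across the two schemes.
2. **Gaussian interaction-profile (GIP) kernels**
   `K(a,b) = exp(-gamma ||p_a - p_b||^2)` on association-matrix rows and
   columns, with `gamma = gamma' / mean(||p_i||^2)`; the kernel backfills
   pairs whose semantic or functional similarity is missing.
3. **Feature compression and propagation**: each node's feature vector
   (integrated-similarity row concatenated with its association profile,
   width `n_m + n_d`) is compressed to a 128-dimensional code by one of two
   independent sigmoid autoencoders; the codes propagate through a 2-layer
   GCN on the unified bipartite graph
   (`H_{i+1} = sigma(D^{-1/2}(A+I)D^{-1/2} H_i W_i)`), and a pair is scored
   `sigmoid(<h_m, h_d>)`, trained with binary cross-entropy on balanced
   positive/negative pairs.

Evaluation is leakage-free k-fold cross-validation over the known
associations (similarities, features and autoencoders are rebuilt per fold
from the training matrix) with AUC, AUPR, MCC, F1, precision and recall. A
seeded synthetic generator plants low-rank structure so the whole pipeline
is testable without any download.

## Worked example

```r
library(mirdisnet)

# A small synthetic dataset with planted rank-3 structure
spec <- synthetic_spec(n_m = 60, n_d = 40, latent_rank = 3, density = 0.05,
                       ontology_depth = 4, branching = 3, seed = 7)
ds <- simulate_mda_dataset(spec)
sum(ds$a)
#> [1] 120

# 3-fold cross-validation of the full pipeline (reduced epochs for speed)
cfg <- mda_config(ae_hidden = 128L, code_dim = 32L, ae_epochs = 60L,
                  gcn_hidden = c(24L, 16L), gcn_epochs = 100L)
cv <- run_cross_validation(ds$a, ds$onto, ds$fm, k = 3, seed = 11,
                           config = cfg)
cv$summary
#> # A tibble: 6 × 4
#>   metric     mean sd_sample sd_population
#>   <chr>     <dbl>     <dbl>         <dbl>
#> 1 auc       0.83     0.0321        0.0262
#> 2 aupr      0.774    0.0240        0.0196
#> 3 mcc       0.578    0.111         0.0906
#> 4 f1        0.796    0.0561        0.0458
#> 5 precision 0.763    0.0427        0.0349
#> 6 recall    0.833    0.0722        0.0589
```

The mean AUC of 0.83 says the pipeline recovers most of the planted signal
at this small size: a held-out true association outranks a held-out
non-association 83% of the time. `tidy(cv)` returns the per-fold metric
tibble, `glance(cv)` a one-row summary, and `autoplot(cv)` a per-fold dot
plot. A final model for ranking candidate partners of one node:

```r
model <- fit_mda(ds$a, ds$onto, ds$fm, seed = 23, config = cfg)
rank_candidates(model, mirna = "m001", candidates = colnames(ds$a), top_k = 5)
```

which returns a tibble of the five highest-scoring diseases for miRNA
`m001` with scores, ranks and 0.5-threshold verdicts.

## Command line

`inst/cli/mirdisnet.R` wraps the package for shell use:

```sh
Rscript inst/cli/mirdisnet.R simulate --out-dir data --n-mirna 100 --n-disease 80 --seed 1
Rscript inst/cli/mirdisnet.R evaluate --associations data/associations.tsv \
    --ontology data/ontology.tsv --fm data/functional_similarity.tsv \
    --k 5 --seed 1 --out-dir results
```

Commands: `simulate`, `similarity`, `train`, `evaluate`, `predict`. Every
command writes a resolved-config dump with seeds for exact reproduction.

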