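# adverank

Prediction and ranking of drug–side-effect associations from a
heterogeneous graph of drugs and side-effects.

Adverse drug events are a primary reason drugs fail in clinical trials, and
screening candidate drug–side-effect associations computationally helps
prioritize what to test. `adverank` takes a binary drug–side-effect
association matrix **A** (N<sub>r</sub> × N<sub>s</sub>), two drug–drug
similarity matrices **D**<sup>che</sup> (chemical substructure) and
**D**<sup>dis</sup> (disease/function based), and a side-effect similarity
matrix **S**, and scores every unobserved pair with two complementary
learned modules fused into one probability.

## The model

Two heterogeneous graphs (one per drug-similarity modality) are built with
the block adjacency

```
I^rho = [ D^rho  A ]
        [ A^T    S ]
```

whose row *v* is node *v*'s raw attribute vector.

1. **Context encoder** — a multi-layer, multi-head graph transformer. Each
   node attends separately over its *same-type* neighborhood (top-`nt` most
   similar nodes, self included) and its *cross-type* neighborhood
   (associated nodes, up to `nk`), with an edge-semantic matrix per edge
   class (drug–drug similarity, side-effect–side-effect similarity,
   association) inside the attention score `K W_E q`. A shared tanh
   bottleneck attention fuses the two neighbor categories (weights β sum
   to 1), a residual projection re-injects the raw attributes, a 1×1
   convolution fuses the two graphs, and a softmax head on the
   concatenated pair encoding yields the encoder probability.
2. **Capsule scorer** — the raw pair embeddings of both graphs are stacked
   into a 4 × N<sub>total</sub> map, passed through two convolution stages
   (`nf` 2×2 filters, then `w` view groups), folded position-wise into
   P = 2·N<sub>total</sub> primary capsules of dimension `w`, and routed by
   agreement (coupling coefficients softmax-normalized per primary capsule,
   squash nonlinearity ‖v‖ = ‖o‖²/(1+‖o‖²)) onto two digit capsules whose
   norm softmax is the capsule probability.

Both modules train independently with Adam on their own cross-entropy
losses (hand-derived analytic backpropagation, verified against finite
differences in the test suite); scores fuse only at prediction time:

```
y = gamma * y_encoder + (1 - gamma) * y_capsule,   gamma = 0.3
```

Evaluation follows balanced-negative-sampling five-fold cross-validation
with per-drug AUC, AUPR, and recall@k (k = 30…240), averaged over drugs and
folds. See `vignettes/adverank-methods.Rmd` for the full account.

## Worked example

```r
library(adverank)
dat <- generate_synthetic(synthetic_spec(nr = 30, ns = 50, n_blocks = 3,
                                         density = 0.15, seed = 11))
cfg <- adverank_config(nt = 6, nk = 6, heads = 2, dims = c(16, 16), att_dim = 8,
                       nf = 6, w = 4, capsule_dim = 8,
                       encoder_epochs = 30, encoder_lr = 5e-3,
                       encoder_batch_size = Inf,
                       capsule_epochs = 8, capsule_lr = 1e-2,
                       folds = 3, recall_ks = c(10, 20, 30), seed = 11)
cv <- cross_validate(dat$A, dat$D_che, dat$D_dis, dat$S, cfg, seed = 11)
print(cv)
#> 3-fold cross-validation (per-drug averaged metrics)
#>   mean AUC  0.7680   (fold range 0.7380-0.7937, permuted null 0.5080)
#>   mean AUPR 0.2932
#>   recall: recall_at_10=0.615 recall_at_20=0.814 recall_at_30=0.924

model <- adverank_fit(dat$A, dat$D_che, dat$D_dis, dat$S, cfg, seed = 11)
head(rank_candidates(model, "drug_003"), 5)
#>    drug_id side_effect_id     score rank
#> 1 drug_003         se_012 0.5598961    1
#> 2 drug_003         se_021 0.5476136    2
#> 3 drug_003         se_015 0.5462524    3
#> 4 drug_003         se_019 0.5210359    4
#> 5 drug_003         se_010 0.5161412    5
```

The mean per-drug AUC of 0.77 on this deliberately small, lightly trained
3-fold demo sits well above the permutation null of 0.51; the ranking table
lists, for one drug, the side-effects not yet known to be associated,
ordered by fused score. On the package's standard 60 × 120 planted
benchmark with `benchmark_config()`, five-fold mean per-drug AUC is ≈ 0.92
(null ≈ 0.49); that run takes ≈ 9 minutes on one CPU.

## Command line

A thin CLI over the same functions ships at `inst/cli/adverank.R`
(subcommands `simulate`, `train`, `evaluate`, `rank`):

```sh
Rscript -e 'adverank::cli_main()' simulate --out data/ --nr 60 --ns 120 --seed 1
Rscript -e 'adverank::cli_main()' evaluate --a data/a.tsv --d-che data/d_che.tsv \
    --d-dis data/d_dis.tsv --s data/s.tsv --out results/
Rscript -e 'adverank::cli_main()' rank --model results/model.rds --drug drug_007 --top 15
```

Matrices are exchanged as TSV with identifier header row and column
(`read_matrix_tsv()` / `write_matrix_tsv()`); `run_pipeline()` drives the
whole simulate → cross-validate → rank flow from one YAML/list config and
writes `metrics.json`, `loss_trace.csv`, `rankings.tsv`, and a `manifest.json`
with the config hash.

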