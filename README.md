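# ccimpute

Imputation of dropout events in single-cell RNA-seq expression matrices via
consensus-clustering similarity.

## The problem

Single-cell RNA-seq count matrices are dominated by zeros. Some are
biological (the gene is simply not expressed in that cell), but many are
*dropouts*: transcripts present in the cell that the capture and
amplification steps failed to record. Dropouts blur the distances between
cells and degrade everything downstream — clustering, embeddings, marker
detection. An imputation method has to walk a line: recover the missing
signal without inventing structure, and without touching measurements that
were actually made.

## The method

`ccimpute` treats imputation as a similarity problem and derives the
similarity from consensus clustering:

1. **Preprocess.** Remove genes expressed in no cell, normalize each cell to
   counts-per-million (every non-empty cell sums to 10^6), and work in
   `log2(CPM + 1)` space.
2. **Weighted Spearman distances.** Each cell's expression vector is
   weighted-ranked with per-gene weights `w_i` (the gene's variance across
   cells). The rank of element *j* is `a_j + b_j`, where
   `a_j = Σ_i w_i · [β_i < β_j]` and, for a tied group of size *n* with mean
   weight `w̄`, `b_j = (n + 1)/2 · w̄`. Rank vectors are compared with the
   weighted Pearson correlation ρ and converted to a distance `d = 1 − ρ`.
3. **PCA + consensus K-means.** The N × N distance matrix is centered,
   scaled, and decomposed by SVD. K-means (best of many seeded random
   restarts, Lloyd iterations) is run on a family of sub-datasets — the
   first 2, 3, …, *d* component columns, at most 15 of them — and the runs
   are averaged into a consensus matrix `C`, where `C[i, j]` is the fraction
   of runs that co-clustered cells *i* and *j*.
4. **Weighted voting.** `C` is thresholded (default 0.65), the diagonal
   dropped, and rows renormalized into voting weights. For every zero entry,
   similar cells vote with their weights — positive if they express the
   gene, negative otherwise. A strictly positive vote sum marks a dropout.
5. **Linear-system imputation.** Each dropout becomes the weighted mean of
   the same gene in the voting cells. Because dropouts may depend on other
   dropouts, the per-gene problem is solved exactly as
   `(I − P_DD) x_D = P_DO e_O`. Non-zero entries pass through bit-identical.

The package also ships a Splatter-style negative-binomial simulator with
known group labels and a ground-truth dropout mask, and the evaluation
metrics used to benchmark imputation: adjusted Rand index, average
silhouette width, and the zero-change fraction (how many zeros a method
rewrites to values ≥ 0.5 in count space).

## Worked example

```r
library(ccimpute)

sim <- simulate_counts(sim_params(), seed = 1)
sim
#> simulated scRNA-seq data: 2000 genes x 500 cells, 4 groups
#> dropout rate: 0.419 of non-zero true counts

t0  <- preprocess_counts(sim$counts)
fit <- ccimpute(t0, k = 4, cfg = ccimpute_config(restarts_small = 50), seed = 1)
fit
#> ccimpute fit: 1971 genes x 500 cells, k = 4
#> dropouts imputed: 151750 of 463522 zero entries (threshold 0.65 )

evaluate_imputation(t0, fit$imputed, sim$counts, sim$labels, k = 4, seed = 1)
#>  ari_before ari_after silhouette_before silhouette_after zero_change_fraction
#>        0.49     0.991           0.00348           0.0821                0.327
```

Reading the numbers: 42% of the truly expressed entries were lost to
dropout. On the raw data, PCA + K-means recovers the four simulated
populations poorly (ARI 0.49); after imputation recovery is near-perfect
(ARI 0.991) and the true-label silhouette width rises from 0.003 to 0.082.
The method achieved this while rewriting only 33% of the zero entries —
everything it left alone, including every non-zero measurement, is
unchanged.

A command-line front end with `simulate`, `preprocess`, `run` and
`evaluate` subcommands is installed at `inst/scripts/ccimpute`:

```sh
Rscript inst/scripts/ccimpute simulate --out-dir data --seed 1
Rscript inst/scripts/ccimpute run -i data/counts.mtx -k 4 -o imputed.csv --seed 1
```

Every `run` writes a JSON manifest (config + seed + versions) sufficient to
reproduce its output byte-for-byte.

## Vignette

`vignettes/ccimpute-methods.Rmd` documents the model, the parameter
defaults and the reasoning behind them, what the simulator does and does
not emulate, and the package's numerical choices and limitations.
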