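# strkernel

Weighted string kernels for alignment-free protein sequence comparison.

## The problem

Remote homologs — proteins sharing a fold at well under 30% sequence
identity — are where alignment-based sequence comparison breaks down, and
exactly where fold recognition is needed. `strkernel` implements an
alignment-free alternative: a weighted k-mer convolution kernel that
compares two sequences through *all* pairs of their gap-free k-mers,
scored by a positive-definite amino-acid similarity matrix on the raw
(odds-ratio) scale.

For sequences $S$, $T$ of lengths $n$, $m$ and a residue kernel
$K_1 = SM^{\beta}$ (entrywise power):

$$K_3(S,T) = \sum_{k=1}^{\min(k_{max},n,m)} \omega(k) \sum_{S_k \in S} \sum_{T_k \in T} \prod_{l=1}^{k} K_1(s_{i+l-1}, t_{j+l-1}),$$

normalized to $\hat K_3 = K_3(S,T)/\sqrt{K_3(S,S) K_3(T,T)}$ (so
$\hat K_3(S,S) = 1$) with induced metric $D = \sqrt{2 - 2\hat K_3}$. The
per-k sums are computed by an $O(n m k_{max})$ dynamic program. The
default weighting $\omega(k) = 1/((n-k+1)(m-k+1))$ (the "mean" scheme)
averages k-mer contributions and removes sequence-length bias; defaults
$\beta = 0.2$, $k_{max} = 10$.

Because the kernel is differentiable in $K_1$, the matrix itself can be
*learned*: given sequence pairs with distance-like structure-similarity
scores $Y$ (e.g. structure-alignment SAS values), `fit_kernel_matrix()`
minimizes the Pearson correlation between kernel values and $Y$ toward
−1 by gradient descent on the Cholesky factor $K_1 = LL^{\top}$, which
keeps the matrix positive definite at every iterate. The package also
provides ROC/AUC evaluation of fold recognition, PCA of substitution
matrices (with correlation against user-supplied amino-acid index
scales), seeded synthetic-data generators, and a command-line interface.

The bundled `bl62()` matrix is the raw-scale (frequency-ratio) kernel
matrix underlying BLOSUM62, in full double precision.

## Worked example

Simulate a small fold-structured set (3 folds × 6 members descended from
random ancestors, 25% per-site divergence), compare all pairs, and score
fold recognition:

```r
library(strkernel)

fs <- simulate_fold_dataset(n_folds = 3, members_per_fold = 6,
                            ancestor_length = 60, mutation_rate = 0.25,
                            seed = 59)
km <- pairwise_kernel_matrix(fs, bl62(), kernel_params(beta = 0.2, kmax = 10))
fold_roc(km, fs$labels)
#> ROC analysis: AUC = 0.9722 (45 positive, 108 negative pairs)
```

An AUC of 0.97 says same-fold pairs are ranked above different-fold pairs
almost perfectly. The degenerate all-ones matrix, which carries no residue
information, collapses every normalized kernel value to 1 and recognition
to coin-flipping — AUC exactly 0.5000 under the tie-corrected
Mann–Whitney rule.

A single pair in detail:

```r
string_kernel(fs$sequences[["F1_01"]], fs$sequences[["F1_02"]],
              bl62(), kernel_params(beta = 0.2, kmax = 10))
#> String kernel profile (beta = 0.2, kmax = 10, scheme = mean)
#>   K3(S,T) = 7.5898   Khat3 = 0.731519   D = 0.732777
```

`Khat3` is the normalized similarity in [0, 1]; `D` the metric distance in
[0, √2]. A between-fold pair from the same set scores lower
(`Khat3 = 0.690`, `D = 0.787`).

Learning the matrix from planted supervision (60 random sequences, scores
that decrease affinely in a planted kernel plus noise) recovers an almost
perfect correlation from the uninformative identity start:

```r
seqs <- random_sequences(60, 30, seed = 1)
sup  <- simulate_supervision(seqs, n_pairs = 60, noise_sigma = 0.05, seed = 1)
fit_kernel_matrix(sup, seqs)
#> Learned residue kernel matrix
#>   training pairs: 60   kmax = 2, scheme = mean
#>   objective P: -0.7588 -> -1.0000 in 63 iterations (converged)
```

PCA of the bundled matrix concentrates 75.5% of its variance in three
components:

```r
sm_pca(bl62())
#> PCA of substitution matrix 'BL62'
#>   variance explained (%): 54.4, 14.2, 6.9, 5.7, 4.7 ...
#>   first three components: 75.5%
```

## Command line

A thin launcher wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","strkernel",package="strkernel"))')" \
    allpairs --fasta seqs.fasta --beta 0.2 --kmax 10 --out pairs.tsv
```

Subcommands: `pair`, `allpairs`, `optimize`, `pca`, `roc`, `simulate`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's self-contained headline
quantities from scratch — the unit self-similarity of the normalized
kernel over random sequences at the default operating point, and the
collapse of the normalized kernel to 1 under the all-ones matrix with the
mean weighting scheme — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/weighted-string-kernels.Rmd` documents the model and its
assumptions, the weighting schemes, the Cholesky-parametrized
optimization and its division-free gradients, what the synthetic
generators do and do not emulate, and the package's numerical
conventions.
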