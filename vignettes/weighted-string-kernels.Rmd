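---
title: "Weighted string kernels for protein sequences: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted string kernels for protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strkernel)
```

## The model

Protein fold recognition from sequence alone is hard precisely where it
matters: remote homologs can share a fold with under 10% sequence identity,
where alignment-based scores carry little signal. `strkernel` implements an
alignment-free alternative: a convolution string kernel that compares two
sequences through *all* of their k-mers rather than through one optimal
alignment.

The kernel is built in three layers. Let $S = (s_1,\dots,s_n)$ and
$T = (t_1,\dots,t_m)$ be sequences over the 20-letter amino-acid alphabet,
and let $SM$ be a symmetric positive-definite substitution matrix on the
*raw* (odds-ratio) scale — not log-odds, since entries must multiply, not
add.

1. **Residue kernel.** For a strictly positive exponent $\beta$,
   $K_1(a, b) = SM(a, b)^\beta$ (entrywise, the Hadamard power). $\beta$
   compresses the dynamic range of the matrix; it is the first tuning
   parameter.
2. **k-mer kernel.** For two gap-free k-mers,
   $K_2^k = \prod_{l=1}^{k} K_1(s_{i+l-1}, t_{j+l-1})$ — a convolution
   kernel on strings of length $k$. No gaps, no gap penalties: this removes
   a whole family of parameters at the cost of ignoring indels.
3. **Sequence kernel.** $K_3^k(S,T)$ sums $K_2^k$ over all
   $(n-k+1)(m-k+1)$ k-mer pairs, and
   $K_3(S,T) = \sum_{k=1}^{\min(k_{max},n,m)} \omega(k)\, K_3^k(S,T)$
   combines the per-k values with positive weights $\omega(k)$.

The reported similarity is the correlation-normalized kernel
$$\hat K_3(S,T) = \frac{K_3(S,T)}{\sqrt{K_3(S,S)\,K_3(T,T)}},$$
which satisfies $\hat K_3(S,S) = 1$ for every sequence, and the induced
metric $D = \sqrt{2 - 2\hat K_3} \in [0, \sqrt 2]$.

Per-k values are computed by a dynamic program over the $n \times m$ grid
of residue similarities: layer $k$ holds the products of $K_1$ along
diagonal runs of length $k$, obtained from layer $k-1$ by one shifted
elementwise product, so a full profile costs $O(n\,m\,k_{max})$ time and
$O(n\,m)$ memory. Each normalized value runs the program three times, for
$(S,T)$, $(S,S)$ and $(T,T)$; all-vs-all computations cache the
self-kernels. A brute-force enumeration (`k3_fixed_k`) is retained as an
independent oracle and is tested against the dynamic program on hundreds of
random small instances.

## Parameters and defaults

* **`beta` (default 0.2, dimensionless).** Entrywise exponent on the
  substitution matrix. Values near 0.1–0.2 spread the amino acids along
  physico-chemically meaningful directions (see the PCA below) and give the
  best fold recognition in our experience; very small values make the
  kernel insensitive to residue identity altogether.
* **`kmax` (default 10, residues).** Longest k-mer considered. The k range
  is truncated at $\min(k_{max}, n, m)$, and the fixed-k kernel is defined
  as 0 when $k$ exceeds the shorter sequence, so the weighted sum is well
  defined for short inputs.
* **`scheme` (default `"mean"`).** Choice of $\omega(k)$:
  `uniform` ($\omega = 1$), `degree`
  ($\omega(k) = 2(k_{max}-k+1)/(k_{max}(k_{max}+1))$, which sums to 1), or
  `mean` ($\omega(k) = 1/((n-k+1)(m-k+1))$, the average k-mer
  contribution). The mean scheme is the default because it removes the
  sequence-length bias: under the uniform and degree schemes, raw kernel
  magnitudes grow with sequence length, and with small $\beta$ the
  normalized kernel ends up ranking pairs mostly by length difference —
  seemingly decent recognition numbers for entirely uninteresting reasons.
  A useful diagnostic of this degeneracy is the all-ones matrix: under the
  mean scheme every weighted per-k term equals 1 exactly, every normalized
  kernel value is 1, and fold recognition collapses to an AUC of exactly
  0.5 under the tie rule below. (We note the per-k *terms* are each 1, so
  the unnormalized weighted sum is $k_{max}$, not 1; the claim that matters
  is at the normalized level, and that is what the tests assert.)

The bundled matrix `bl62()` is the raw-scale (odds-ratio) kernel matrix
underlying BLOSUM62 — target frequencies over background-frequency
products, in full double precision as distributed with NCBI BLAST+. It is
symmetric positive definite with smallest eigenvalue above 1, so it is a
valid residue kernel without further processing. Raw BLOSUM count tables
are sometimes row-normalized to unit row sums; that operation breaks
symmetry and hence the kernel property, so the package exposes it only as
the explicit, clearly-flagged `normalize_rows()` and never applies it
implicitly.

## Learning the residue kernel from structural supervision

The kernel is differentiable in the entries of $K_1$, which turns the
substitution matrix itself into a learnable object. Given pairs of
sequences with a distance-like structure-similarity score $Y$ (for example
a structure-alignment SAS value, where lower means more similar), collect
the normalized kernel values $X$ and minimize the Pearson correlation
$P(X, Y)$ — pushing it toward $-1$, since a good similarity should be
large exactly when the structural distance is small.

Design choices, made where the problem itself does not dictate one:

* **Positive definiteness via the Cholesky factor.** $K_1 = LL^\top$ with
  $L$ lower triangular; the optimizer moves $L$, so every iterate is
  automatically positive semi-definite, and a sign-preserving floor of
  $10^{-8}$ on $|L_{ii}|$ keeps $L$ invertible, hence $K_1$ strictly
  positive definite. The floor value is our choice; anything comfortably
  above machine epsilon and far below working-scale entries behaves
  identically.
* **$\beta$ is fixed at 1 during the fit.** The learned object is $K_1$
  itself; a free exponent would not be jointly identifiable with the
  matrix entries (raising the matrix to $\beta$ and learning it directly
  are reparametrizations of each other).
* **Division-free gradients.** The derivative of $K_3$ with respect to
  $K_1(a,b)$ accumulates, over aligned positions $(i,j)$ carrying residues
  $(a,b)$, the products of the *other* factors of every k-mer through
  $(i,j)$. These are assembled from prefix products $F_a$ (runs ending at
  $(i-1,j-1)$) and suffix products $B_b$ (runs starting at $(i+1,j+1)$):
  $\sum_{a+b+1 \le k_{max}} \omega(a{+}b{+}1) F_a B_b$. The naive trick of
  dividing the full product by the central factor fails at zero entries —
  and the identity matrix, the canonical starting point, is mostly zeros —
  so the forward/backward form is not an optimization but a correctness
  requirement. The Pearson derivative is closed-form, the normalized
  kernel uses the quotient rule over the three per-pair programs, and the
  chain to $L$ is $(\nabla_{K_1} + \nabla_{K_1}^\top)L$ on the lower
  triangle. All of it is validated against central finite differences on
  randomized instances.
* **Optimizer.** Plain gradient descent with Armijo backtracking
  (sufficient-decrease constant $10^{-4}$, shrink 0.5, the accepted step
  doubled as the next trial). Nothing in the problem demands more, and a
  monotone line-search method makes the "objective never increases"
  invariant a theorem rather than a hope. Stopping: objective decrease
  below $10^{-6}$, gradient norm below $10^{-6}$, or 500 iterations.
  Self-kernel values and self-gradients are cached per unique sequence
  within each iteration.

`fit_kernel_matrix()` wraps this as a standard R model fit: it returns a
`kernel_fit` object with `print`, `summary`, `coef` (the learned matrix or
its factor), `fitted`, `residuals` (of the linear calibration of $Y$ on
$X$), `predict` (kernel values for new pairs under the learned matrix) and
`plot` (the optimization trace) methods.

## What the synthetic generators emulate — and what they do not

Real benchmarks for this method take a structural classification (folds),
a set of remote-homolog domains, and structure-alignment scores. None of
that can ship in a package, so two seeded generators provide a stated,
fixed stand-in world:

* `simulate_fold_dataset()` draws one uniform-random ancestor per fold and
  derives members by independent per-site substitutions (to a uniformly
  random *different* residue). Defaults: 5 folds × 20 members, 120
  residues, rate 0.3 — a desk-scale analogue of a five-fold benchmark with
  clearly related but non-identical within-fold members. It captures
  "within-fold pairs are more similar than between-fold pairs" and nothing
  else: no indels, no position-specific conservation, no real mutation
  process, no shared architecture between folds.
* `simulate_supervision()` selects random distinct pairs, computes their
  kernel values $X^*$ under a planted matrix (default: BL62 to the power
  0.2), and maps them affinely and *decreasingly* onto a score range
  (default 0–20, the span typical of structure-alignment SAS scores), plus
  Gaussian noise (default $\sigma = 0.05$). With zero noise,
  $P(X^*, Y) = -1$ exactly by construction.

A green recovery test therefore establishes that the optimizer can drive
$P$ from its identity-start value to below $-0.9$ when a perfectly
recoverable signal exists — a correctness check of the gradient/optimizer
stack, *not* evidence about real structure data, where the attainable
correlation is far from $-1$. Benchmark-scale AUC values on curated domain
sets are likewise out of reach at desk scale; the evaluation module is
instead checked for its exact statistical properties (Mann–Whitney
equivalence, tie handling, orientation) and for the directional claim that
an informative matrix beats the degenerate ones matrix on the synthetic
folds.

## PCA of a substitution matrix

Treating the matrix as 20 objects × 20 features, `sm_pca()` centers each
column, forms the row covariance $C = K_c K_c^\top/(N-1)$, and
eigendecomposes it. The eigenvalue fractions measure how much of the
matrix's variance each component carries; amino-acid coordinates are the
centered rows projected on the leading components. Two conventions are
fixed for reproducibility: the $N-1$ denominator (feature means are
estimated from the same matrix), and each component's sign is chosen so
its largest-magnitude coordinate is positive — `index_correlation()`
reports absolute correlations against user-supplied residue scales, so the
sign never matters scientifically.

Note that the covariance is formed over *rows* of the column-centered
matrix. For a symmetric input the distinction is immaterial up to
transposition, and this orientation is the package's fixed convention; the
bundled matrix calibrates to 75% of variance in the first three components
(63% after the 0.2 Hadamard power, whose first component alone carries
33%) — numbers the acceptance tests pin at nearest-percent precision.

```{r pca-example, eval = FALSE}
p <- sm_pca(bl62())
round(100 * cumsum(p$variance_fraction)[3])   # 75
plot(p)                                        # residues on PC1/PC2
```

## Numerical choices

* Symmetry of stored matrices is enforced at $10^{-12}$ relative and
  exactified by averaging with the transpose; positive definiteness uses
  the scale-free criterion $\lambda_{min} > -10^{-10}\lambda_{max}$.
* All kernel arithmetic is plain double precision in linear space.
  Log-space is unusable (sums of products), and overflow is not a concern
  at sane operating points: the largest bundled entry is about 38, and
  $38^{20}$ is still far below the double ceiling.
* $\hat K_3$ is clamped into $[0, 1]$ after a $1 + 10^{-10}$ tolerance
  check, so floating-point jitter near 1 cannot produce an invalid
  distance; the optimizer works with unclamped values to stay smooth.
* Sequences containing letters outside the 20-letter alphabet are rejected
  by default with the offending residue and position named; an explicit
  `drop_illegal = TRUE` removes them with a reported count. Ambiguity
  codes are deliberately not mapped to anything.
* ROC ties receive half credit (tie-corrected Mann–Whitney), which makes
  "all scores equal" exactly 0.5 rather than an artifact of sort order;
  self-pairs are excluded from fold-recognition ROC since their similarity
  is 1 by construction.

## Known limitations

* No gaps: a single frame-shifting insertion between two otherwise
  identical sequences sharply reduces long-k-mer matches.
* $O(nm\,k_{max})$ per pair is quadratic in sequence length; all-vs-all on
  thousands of sequences is an overnight job, not an interactive one. The
  implementation is vectorized base R; the structure (per-layer
  elementwise products) would port directly to compiled code if needed.
* The learned matrix interpolates the supervision it is given; with
  hundreds of free parameters and small training sets it will overfit, and
  no regularization is provided (none is part of the model).
* The kernel assumes neighboring positions contribute independently
  through products; correlated substitution processes are not modeled.
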