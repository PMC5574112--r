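# Weighted k-mer convolution string kernel.
#
# The similarity of two sequences S (length n) and T (length m) is built in
# three layers: a residue kernel K1 (a positive-definite substitution matrix,
# optionally Hadamard-powered by beta), a k-mer kernel that multiplies K1
# along aligned positions of two gap-free k-mers, and a sequence kernel that
# sums the k-mer kernel over all k-mer pairs and all k up to kmax, each k
# weighted by a scheme omega(k). Normalizing by the self-kernels yields a
# correlation kernel with unit self-similarity and an induced metric
# D = sqrt(2 - 2*Khat) in [0, sqrt(2)].

#' Kernel parameters
#'
#' Bundles the three tuning knobs of the weighted string kernel: the
#' Hadamard exponent \code{beta} applied to the substitution matrix, the
#' longest k-mer \code{kmax}, and the weighting \code{scheme} that combines
#' the fixed-k kernels.
#'
#' The schemes are \describe{
#'   \item{uniform}{\eqn{\omega(k) = 1}: every k-mer length counts equally.}
#'   \item{degree}{\eqn{\omega(k) = 2(k_{max}-k+1)/(k_{max}(k_{max}+1))}:
#'     linearly decaying weights that sum to 1 over \eqn{k = 1 \ldots k_{max}}.}
#'   \item{mean}{\eqn{\omega(k) = 1/((n-k+1)(m-k+1))}: averages the
#'     contributions of the \eqn{(n-k+1)} and \eqn{(m-k+1)} k-mers of the two
#'     sequences, removing the sequence-length bias of the raw sums.}
#' }
#'
#' The defaults \code{beta = 0.2}, \code{kmax = 10}, \code{scheme = "mean"}
#' are the recommended operating point for fold recognition.
#'
#' @param beta Strictly positive Hadamard exponent.
#' @param kmax Positive integer, longest k-mer length considered.
#' @param scheme One of \code{"mean"}, \code{"uniform"}, \code{"degree"}.
#' @return An object of class \code{"kernel_params"}.
#' @export
kernel_params <- function(beta = 0.2, kmax = 10,
                          scheme = c("mean", "uniform", "degree")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single strictly positive number", call. = FALSE)
  kmax <- as.integer(kmax)
  if (is.na(kmax) || kmax < 1L)
    stop("kmax must be a positive integer", call. = FALSE)
  structure(list(beta = beta, kmax = kmax, scheme = scheme),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("Kernel parameters: beta = %g, kmax = %d, scheme = %s\n",
              x$beta, x$kmax, x$scheme))
  invisible(x)
}

#' Per-k weight of the weighted string kernel
#'
#' Evaluates \eqn{\omega(k)} for the selected scheme (see
#' \code{\link{kernel_params}}). The mean scheme uses the actual sequence
#' lengths \code{n} and \code{m}.
#'
#' @param scheme \code{"uniform"}, \code{"degree"} or \code{"mean"}.
#' @param k Integer vector of k-mer lengths, each in
#'   \code{1..min(kmax, n, m)}.
#' @param kmax Longest k-mer length.
#' @param n,m Lengths of the two sequences (required for \code{"mean"}).
#' @return Numeric vector of positive weights.
#' @examples
#' kmer_weight("degree", 1, kmax = 10)          # 2/11
#' kmer_weight("mean", 5, kmax = 10, n = 5, m = 5)  # 1
#' @export
kmer_weight <- function(scheme, k, kmax, n = NULL, m = NULL) {
  scheme <- match.arg(scheme, c("uniform", "degree", "mean"))
  k <- as.integer(k)
  kcap <- kmax
  if (!is.null(n) && !is.null(m)) kcap <- min(kmax, n, m)
  if (any(k < 1L) || any(k > kcap))
    stop(sprintf("k must lie in 1..%d", kcap), call. = FALSE)
  switch(scheme,
    uniform = rep(1, length(k)),
    degree  = 2 * (kmax - k + 1) / (kmax * (kmax + 1)),
    mean    = {
      if (is.null(n) || is.null(m))
        stop("the mean scheme needs the sequence lengths n and m",
             call. = FALSE)
      1 / ((n - k + 1) * (m - k + 1))
    })
}

# Resolve a matrix argument: accepts a substitution_matrix or a plain
# symmetric matrix with residue dimnames.
.as_sm <- function(K1) {
  if (inherits(K1, "substitution_matrix")) K1 else substitution_matrix(K1)
}

#' k-mer kernel: product of residue similarities along two k-mers
#'
#' For two gap-free k-mers of equal length, multiplies the \code{K1} entries
#' of the aligned residue pairs.
#'
#' @param K1 Residue kernel (a \code{\link{substitution_matrix}}), used as
#'   is (apply \code{\link{hadamard_power}} beforehand if needed).
#' @param sk,tk Character strings of equal length.
#' @return A single nonnegative number (for nonnegative \code{K1}).
#' @examples
#' k2_kmer(bl62(), "ACD", "ACD")
#' @export
k2_kmer <- function(K1, sk, tk) {
  K1 <- .as_sm(K1)
  si <- encode_sequence(sk, K1$alphabet)
  ti <- encode_sequence(tk, K1$alphabet)
  if (length(si) != length(ti))
    stop("k-mers must have equal length", call. = FALSE)
  prod(K1$values[cbind(si, ti)])
}

#' Fixed-k string kernel by brute-force enumeration
#'
#' Sums the k-mer kernel over all \code{(n-k+1)(m-k+1)} pairs of k-mers of
#' the two sequences. This is the reference implementation: exact, but
#' quadratic in the number of k-mers; \code{\link{kmer_profile}} computes
#' the same values by dynamic programming. For \code{k > min(n, m)} there
#' are no k-mers and the value is 0.
#'
#' @param K1 Residue kernel matrix.
#' @param s,t Sequences (character strings).
#' @param k k-mer length.
#' @return The fixed-k kernel value.
#' @export
k3_fixed_k <- function(K1, s, t, k) {
  K1 <- .as_sm(K1)
  si <- encode_sequence(s, K1$alphabet)
  ti <- encode_sequence(t, K1$alphabet)
  n <- length(si); m <- length(ti)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  if (k > min(n, m)) return(0)
  total <- 0
  for (i in seq_len(n - k + 1L)) {
    for (j in seq_len(m - k + 1L)) {
      total <- total +
        prod(K1$values[cbind(si[i:(i + k - 1L)], ti[j:(j + k - 1L)])])
    }
  }
  total
}

# Core DP on an n x m matrix of residue similarities M1[i, j] = K1(s_i, t_j).
# Layer k holds products of K1 along diagonal runs of length k ending at
# (i, j); each layer is an elementwise product of the shifted previous layer
# with M1, so time is O(n m kmax) and memory O(n m).
.profile_from_M1 <- function(M1, kmax) {
  n <- nrow(M1); m <- ncol(M1)
  kk <- min(kmax, n, m)
  out <- numeric(kk)
  layer <- M1
  out[1L] <- sum(layer)
  for (k in seq_len(kk)[-1L]) {
    layer <- layer[-nrow(layer), -ncol(layer), drop = FALSE] *
      M1[k:n, k:m, drop = FALSE]
    out[k] <- sum(layer)
  }
  out
}

#' Fixed-k kernel profile by dynamic programming
#'
#' Computes the full vector of fixed-k kernel values for
#' \code{k = 1..min(kmax, n, m)} in \code{O(n m kmax)} time, matching
#' \code{\link{k3_fixed_k}} exactly up to floating-point roundoff.
#'
#' @param K1 Residue kernel matrix.
#' @param s,t Sequences (character strings).
#' @param kmax Longest k-mer length.
#' @return Numeric vector of per-k kernel values, length
#'   \code{min(kmax, n, m)}.
#' @examples
#' kmer_profile(bl62(), "ACDEF", "ACDEF", kmax = 3)
#' @export
kmer_profile <- function(K1, s, t, kmax) {
  K1 <- .as_sm(K1)
  si <- encode_sequence(s, K1$alphabet)
  ti <- encode_sequence(t, K1$alphabet)
  .profile_from_M1(K1$values[si, ti, drop = FALSE], kmax)
}

# weighted sum over the per-k profile
.weighted_sum <- function(per_k, scheme, kmax, n, m) {
  kk <- length(per_k)
  if (!kk) return(0)
  w <- kmer_weight(scheme, seq_len(kk), kmax, n, m)
  sum(w * per_k)
}

#' Weighted string kernel (unnormalized)
#'
#' The weighted sum \eqn{K_3 = \sum_k \omega(k) K_3^k} over
#' \code{k = 1..min(kmax, n, m)}.
#'
#' @param K1 Residue kernel matrix (beta already applied).
#' @param s,t Sequences.
#' @param params A \code{\link{kernel_params}}; its \code{beta} is ignored
#'   here (the matrix is used as passed).
#' @return The kernel value, a nonnegative number for nonnegative \code{K1}.
#' @export
k3_weighted <- function(K1, s, t, params = kernel_params()) {
  K1 <- .as_sm(K1)
  si <- encode_sequence(s, K1$alphabet)
  ti <- encode_sequence(t, K1$alphabet)
  per_k <- .profile_from_M1(K1$values[si, ti, drop = FALSE], params$kmax)
  .weighted_sum(per_k, params$scheme, params$kmax, length(si), length(ti))
}

#' Distance induced by the correlation kernel
#'
#' Maps a normalized kernel value to the metric
#' \eqn{D = \sqrt{2 - 2 \hat K_3}}; 0 for identical sequences, \eqn{\sqrt 2}
#' for orthogonal ones.
#'
#' @param khat Normalized kernel value, at most \code{1 + 1e-10} (values in
#'   \code{(1, 1 + 1e-10]} are clamped to 1).
#' @return Nonnegative distance.
#' @examples
#' kernel_distance(c(1, 0.5, 0))   # 0, 1, sqrt(2)
#' @export
kernel_distance <- function(khat) {
  if (any(khat > 1 + 1e-10))
    stop("normalized kernel value exceeds 1 beyond tolerance", call. = FALSE)
  sqrt(pmax(2 - 2 * pmin(khat, 1), 0))
}

#' Correlation string kernel of two sequences
#'
#' The user-level entry point: applies the Hadamard power
#' \code{params$beta} to \code{sm}, runs the dynamic program for the three
#' pairs (S,T), (S,S), (T,T), and returns the normalized kernel
#' \eqn{\hat K_3 = K_3(S,T)/\sqrt{K_3(S,S) K_3(T,T)}} together with the
#' per-k profile and the induced distance. \eqn{\hat K_3(S,S) = 1} for every
#' sequence; values are clamped into \code{[0, 1]} (after a 1e-10 tolerance
#' check at the top) before the distance is formed.
#'
#' @param s,t Sequences (character strings over the matrix alphabet).
#' @param sm Substitution matrix (default the bundled BL62).
#' @param params \code{\link{kernel_params}}.
#' @param drop_illegal Drop residues outside the alphabet instead of
#'   erroring.
#' @return An object of class \code{"kernel_profile"}: list with
#'   \code{per_k}, \code{k3_st}, \code{k3_ss}, \code{k3_tt}, \code{khat},
#'   \code{distance}, \code{params}.
#' @examples
#' p <- string_kernel("ACDEFGHIK", "ACDEFGHIK")
#' p$khat       # 1: self-similarity is always 1
#' @export
string_kernel <- function(s, t, sm = bl62(), params = kernel_params(),
                          drop_illegal = FALSE) {
  sm <- .as_sm(sm)
  K1 <- if (params$beta == 1) sm$values else {
    if (any(sm$values < 0))
      stop("Hadamard power requires nonnegative entries", call. = FALSE)
    sm$values^params$beta
  }
  si <- encode_sequence(s, sm$alphabet, drop_illegal)
  ti <- encode_sequence(t, sm$alphabet, drop_illegal)
  n <- length(si); m <- length(ti)
  per_k <- .profile_from_M1(K1[si, ti, drop = FALSE], params$kmax)
  k3_st <- .weighted_sum(per_k, params$scheme, params$kmax, n, m)
  k3_ss <- .weighted_sum(.profile_from_M1(K1[si, si, drop = FALSE],
                                          params$kmax),
                         params$scheme, params$kmax, n, n)
  k3_tt <- .weighted_sum(.profile_from_M1(K1[ti, ti, drop = FALSE],
                                          params$kmax),
                         params$scheme, params$kmax, m, m)
  if (k3_ss <= 0 || k3_tt <= 0)
    stop(sprintf("zero self-kernel (K(S,S)=%.3g, K(T,T)=%.3g): the residue kernel is degenerate",
                 k3_ss, k3_tt), call. = FALSE)
  khat <- k3_st / sqrt(k3_ss * k3_tt)
  if (khat > 1 + 1e-10)
    stop(sprintf("normalized kernel %.12g exceeds 1 beyond tolerance", khat),
         call. = FALSE)
  khat <- min(max(khat, 0), 1)
  structure(list(per_k = per_k, k3_st = k3_st, k3_ss = k3_ss, k3_tt = k3_tt,
                 khat = khat, distance = kernel_distance(khat),
                 params = params),
            class = "kernel_profile")
}

#' @export
print.kernel_profile <- function(x, ...) {
  cat(sprintf("String kernel profile (beta = %g, kmax = %d, scheme = %s)\n",
              x$params$beta, x$params$kmax, x$params$scheme))
  cat(sprintf("  K3(S,T) = %.6g   Khat3 = %.6g   D = %.6g\n",
              x$k3_st, x$khat, x$distance))
  cat("  per-k profile:", format(signif(x$per_k, 6)), "\n")
  invisible(x)
}
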