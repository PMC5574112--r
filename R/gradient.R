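# Analytic derivatives of the weighted string kernel with respect to the
# residue kernel matrix K1.
#
# The fixed-k kernel is a sum of products of K1 entries along diagonal runs.
# The derivative with respect to the entry used at aligned position (i, j)
# is the product of the remaining factors of the run; summing over all runs
# through (i, j) gives a per-position weight G(i, j) that factorizes into
# prefix products F_a (run of length a ending at (i-1, j-1)) and suffix
# products B_b (run of length b starting at (i+1, j+1)):
#   G(i,j) = sum_{a,b >= 0, a+b+1 <= kmax} omega(a+b+1) F_a(i-1,j-1) B_b(i+1,j+1)
# This forward/backward scheme is division-free, so zero entries of K1 (for
# instance an identity start) pose no problem. Cost O(n m kmax^2) with
# kmax small.

.grad_positions <- function(M1, scheme, kmax, n, m) {
  kk <- min(kmax, n, m)
  w <- kmer_weight(scheme, seq_len(kk), kmax, n, m)
  ones <- matrix(1, n, m)
  # prefix products shifted to (i-1, j-1); index a+1 holds length a
  FS <- vector("list", kk)
  FS[[1L]] <- ones
  if (kk > 1L) {
    Fa <- M1
    for (a in seq_len(kk - 1L)) {
      if (a > 1L) {
        Fnew <- matrix(0, n, m)
        Fnew[a:n, a:m] <- Fa[(a - 1L):(n - 1L), (a - 1L):(m - 1L)] *
          M1[a:n, a:m]
        Fa <- Fnew
      }
      SF <- matrix(0, n, m)
      SF[2:n, 2:m] <- Fa[1:(n - 1L), 1:(m - 1L)]
      FS[[a + 1L]] <- SF
    }
  }
  # suffix products shifted to (i+1, j+1)
  BS <- vector("list", kk)
  BS[[1L]] <- ones
  if (kk > 1L) {
    Bb <- M1
    for (b in seq_len(kk - 1L)) {
      if (b > 1L) {
        Bnew <- matrix(0, n, m)
        Bnew[1:(n - b + 1L), 1:(m - b + 1L)] <-
          M1[1:(n - b + 1L), 1:(m - b + 1L)] * Bb[2:(n - b + 2L), 2:(m - b + 2L)]
        Bb <- Bnew
      }
      SB <- matrix(0, n, m)
      SB[1:(n - 1L), 1:(m - 1L)] <- Bb[2:n, 2:m]
      BS[[b + 1L]] <- SB
    }
  }
  G <- matrix(0, n, m)
  for (a in 0:(kk - 1L)) {
    for (b in 0:(kk - 1L - a)) {
      G <- G + w[a + b + 1L] * FS[[a + 1L]] * BS[[b + 1L]]
    }
  }
  G
}

# Accumulate per-position weights into an alphabet x alphabet matrix:
# entry (c, d) collects positions where S carries residue c and T residue d.
.accumulate_alphabet <- function(G, si, ti, n_letters) {
  n <- length(si); m <- length(ti)
  grp <- rep.int(si, m) + n_letters * (rep(ti, each = n) - 1L)
  sums <- rowsum(as.vector(G), grp)
  out <- matrix(0, n_letters, n_letters)
  out[as.integer(rownames(sums))] <- sums
  out
}

#' Gradient of the weighted string kernel with respect to the residue kernel
#'
#' Computes the matrix of partial derivatives
#' \eqn{\partial K_3(S,T) / \partial K_1(a,b)}, treating \eqn{K_1(a,b)} and
#' \eqn{K_1(b,a)} as independent entries: entry \code{(a, b)} collects the
#' contributions of aligned positions where \code{S} carries residue
#' \code{a} and \code{T} carries residue \code{b}. The matrix is used as
#' passed (\code{params$beta} plays no role here).
#'
#' @param K1 Residue kernel matrix.
#' @param s,t Sequences.
#' @param params \code{\link{kernel_params}} (weighting scheme and kmax).
#' @return A matrix of the alphabet's dimensions with the partial
#'   derivatives, dimnames set to the letters.
#' @examples
#' # with kmax = 1 the kernel is linear in K1: the gradient counts pairs
#' kernel_gradient(diag(2, 20) |> `dimnames<-`(list(AA_LETTERS, AA_LETTERS)),
#'                 "AC", "AA", kernel_params(beta = 1, kmax = 1,
#'                                           scheme = "uniform"))
#' @export
kernel_gradient <- function(K1, s, t, params = kernel_params()) {
  K1 <- .as_sm(K1)
  si <- encode_sequence(s, K1$alphabet)
  ti <- encode_sequence(t, K1$alphabet)
  n <- length(si); m <- length(ti)
  nl <- length(K1$alphabet)
  M1 <- K1$values[si, ti, drop = FALSE]
  G <- .grad_positions(M1, params$scheme, params$kmax, n, m)
  out <- .accumulate_alphabet(G, si, ti, nl)
  dimnames(out) <- list(unclass(K1$alphabet), unclass(K1$alphabet))
  out
}

#' Pearson correlation between kernel and structure scores
#'
#' The optimization objective: the sample Pearson correlation of the kernel
#' values \code{x} with the structure-similarity scores \code{y}. Structure
#' scores are distance-like (smaller = more similar) while the kernel is a
#' similarity, so a good kernel matrix drives this toward -1.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither constant.
#' @return The correlation, in \code{[-1, 1]}.
#' @export
pearson_objective <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  sx <- sum(x); sy <- sum(y)
  dx2 <- n * sum(x^2) - sx^2
  dy2 <- n * sum(y^2) - sy^2
  if (dx2 <= 0 || dy2 <= 0)
    stop("correlation undefined: constant scores", call. = FALSE)
  (n * sum(x * y) - sx * sy) / sqrt(dx2 * dy2)
}

# dP/dx_n in closed form, given x, y non-constant.
.pearson_grad_x <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  dx2 <- n * sum(x^2) - sx^2
  dy2 <- n * sum(y^2) - sy^2
  A <- n * sum(x * y) - sx * sy
  P <- A / sqrt(dx2 * dy2)
  (n * y - sy) / sqrt(dx2 * dy2) - P * (n * x - sx) / dx2
}

# Internal per-iteration evaluation of the training objective and, on
# request, its gradient with respect to the Cholesky factor L.
#
# enc: list of encoded sequences (integer vectors), named by id
# i1, i2: per-pair indices into enc
# Self-kernel quantities are cached per unique sequence, and the three
# gradient DPs per pair reuse them.
.objective_eval <- function(L, enc, i1, i2, y, params, with_grad = FALSE) {
  K1 <- tcrossprod(L)
  nl <- nrow(K1)
  nseq <- length(enc)
  kmax <- params$kmax; scheme <- params$scheme

  self_k3 <- numeric(nseq)
  self_grad <- if (with_grad) vector("list", nseq)
  need <- sort(unique(c(i1, i2)))
  for (u in need) {
    si <- enc[[u]]
    M1 <- K1[si, si, drop = FALSE]
    nu <- length(si)
    self_k3[u] <- .weighted_sum(.profile_from_M1(M1, kmax), scheme, kmax,
                                nu, nu)
    if (with_grad) {
      G <- .grad_positions(M1, scheme, kmax, nu, nu)
      self_grad[[u]] <- .accumulate_alphabet(G, si, si, nl)
    }
  }
  if (any(self_k3[need] <= 0))
    stop("zero self-kernel during optimization", call. = FALSE)

  npair <- length(i1)
  x <- numeric(npair)
  pair_dat <- if (with_grad) vector("list", npair)
  for (p in seq_len(npair)) {
    si <- enc[[i1[p]]]; ti <- enc[[i2[p]]]
    n <- length(si); m <- length(ti)
    M1 <- K1[si, ti, drop = FALSE]
    k3_st <- .weighted_sum(.profile_from_M1(M1, kmax), scheme, kmax, n, m)
    ss <- self_k3[i1[p]]; tt <- self_k3[i2[p]]
    x[p] <- k3_st / sqrt(ss * tt)
    if (with_grad) pair_dat[[p]] <- list(M1 = M1, k3_st = k3_st)
  }
  P <- pearson_objective(x, y)
  if (!with_grad) return(list(P = P, X = x))

  dPdx <- .pearson_grad_x(x, y)
  Gk1 <- matrix(0, nl, nl)
  for (p in seq_len(npair)) {
    si <- enc[[i1[p]]]; ti <- enc[[i2[p]]]
    ss <- self_k3[i1[p]]; tt <- self_k3[i2[p]]
    dat <- pair_dat[[p]]
    G_st <- .accumulate_alphabet(
      .grad_positions(dat$M1, scheme, kmax, length(si), length(ti)),
      si, ti, nl)
    root <- sqrt(ss * tt)
    # quotient rule on Khat = K_st / sqrt(K_ss K_tt)
    dX <- G_st / root -
      0.5 * dat$k3_st / root^3 *
        (self_grad[[i1[p]]] * tt + ss * self_grad[[i2[p]]])
    Gk1 <- Gk1 + dPdx[p] * dX
  }
  # chain through K1 = L L^T: dP/dL = (G + G^T) L, lower triangle
  GL <- (Gk1 + t(Gk1)) %*% L
  GL[upper.tri(GL)] <- 0
  list(P = P, X = x, grad_L = GL, grad_norm = sqrt(sum(GL^2)))
}

#' Objective and gradient with respect to the Cholesky factor
#'
#' Evaluates the Pearson objective for a training set at a given Cholesky
#' factor \code{L} (the kernel matrix being \code{L L'}), together with its
#' analytic gradient with respect to the lower triangle of \code{L}. The
#' gradient chains the closed-form Pearson derivative, the quotient rule on
#' the normalized kernel (three dynamic programs per pair, self terms cached
#' per unique sequence), and
#' \eqn{\partial K_1(a,b)/\partial L(p,q) = \delta_{ap} L(b,q) + \delta_{bp} L(a,q)}.
#'
#' @param pairs Data frame with columns \code{id1}, \code{id2}, \code{Y}.
#' @param sequences Named character vector of sequences.
#' @param L A \code{"cholesky_factor"} (or lower-triangular matrix).
#' @param params \code{\link{kernel_params}}; \code{beta} must be 1 (the
#'   learned object is the kernel matrix itself).
#' @return List with \code{P}, \code{X} (per-pair normalized kernel values),
#'   \code{grad_L} (lower-triangular gradient matrix) and \code{grad_norm}.
#' @export
objective_gradient <- function(pairs, sequences, L,
                               params = kernel_params(beta = 1, kmax = 2)) {
  if (params$beta != 1)
    stop("optimization operates on the kernel matrix itself: beta must be 1",
         call. = FALSE)
  Lm <- if (inherits(L, "cholesky_factor")) L$L else as.matrix(L)
  alphabet <- if (inherits(L, "cholesky_factor")) L$alphabet
              else if (!is.null(rownames(Lm))) aa_alphabet(rownames(Lm))
              else if (nrow(Lm) == 20L) aa_alphabet()
              else stop("provide dimnames (the alphabet) on L", call. = FALSE)
  ts <- .training_setup(pairs, sequences, alphabet)
  out <- .objective_eval(Lm, ts$enc, ts$i1, ts$i2, ts$y, params,
                         with_grad = TRUE)
  dimnames(out$grad_L) <- dimnames(Lm)
  out
}

# Validate and index a training set against its sequence pool.
.training_setup <- function(pairs, sequences, alphabet = aa_alphabet()) {
  pairs <- as.data.frame(pairs)
  need <- c("id1", "id2", "Y")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns id1, id2, Y", call. = FALSE)
  if (nrow(pairs) < 3L)
    stop("need at least 3 training pairs", call. = FALSE)
  if (!all(is.finite(pairs$Y)))
    stop("structure scores Y must be finite", call. = FALSE)
  if (is.list(sequences)) sequences <- unlist(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by id", call. = FALSE)
  miss <- setdiff(unique(c(pairs$id1, pairs$id2)), ids)
  if (length(miss))
    stop(sprintf("sequence id(s) not found: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  enc <- lapply(sequences, encode_sequence, alphabet = alphabet)
  list(enc = enc, i1 = match(pairs$id1, ids), i2 = match(pairs$id2, ids),
       y = pairs$Y, pairs = pairs)
}
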