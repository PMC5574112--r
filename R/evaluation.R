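# All-vs-all kernel computation and ROC analysis of fold recognition.

#' Pairwise normalized kernel matrix for a sequence set
#'
#' Computes the symmetric matrix of normalized string-kernel values for all
#' pairs in a set. Each sequence's self-kernel is computed once and reused,
#' so the cost is \code{N(N-1)/2} cross-kernel dynamic programs plus
#' \code{N} self-kernels.
#'
#' @param sequences Named character vector of sequences (or a
#'   \code{"fold_set"} from \code{\link{simulate_fold_dataset}}).
#' @param sm Substitution matrix (default bundled BL62).
#' @param params \code{\link{kernel_params}}.
#' @return Symmetric numeric matrix with unit diagonal, dimnames the
#'   sequence ids.
#' @export
pairwise_kernel_matrix <- function(sequences, sm = bl62(),
                                   params = kernel_params()) {
  if (inherits(sequences, "fold_set")) sequences <- sequences$sequences
  if (is.list(sequences)) sequences <- unlist(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique ids", call. = FALSE)
  sm <- .as_sm(sm)
  K1 <- if (params$beta == 1) sm$values else sm$values^params$beta
  enc <- lapply(sequences, encode_sequence, alphabet = sm$alphabet)
  N <- length(enc)
  selfs <- vapply(enc, function(si) {
    .weighted_sum(.profile_from_M1(K1[si, si, drop = FALSE], params$kmax),
                  params$scheme, params$kmax, length(si), length(si))
  }, numeric(1))
  if (any(selfs <= 0))
    stop("zero self-kernel: the residue kernel is degenerate", call. = FALSE)
  out <- diag(1, N)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) {
      si <- enc[[i]]
      for (j in (i + 1L):N) {
        ti <- enc[[j]]
        k3 <- .weighted_sum(
          .profile_from_M1(K1[si, ti, drop = FALSE], params$kmax),
          params$scheme, params$kmax, length(si), length(ti))
        kh <- k3 / sqrt(selfs[i] * selfs[j])
        kh <- min(max(kh, 0), 1)
        out[i, j] <- out[j, i] <- kh
      }
    }
  }
  dimnames(out) <- list(ids, ids)
  out
}

#' ROC curve and AUC from pairwise scores
#'
#' Quantifies how well a score ranks positive pairs (e.g. same-fold) above
#' negative ones. The AUC is the tie-corrected Mann-Whitney statistic
#' \code{(wins + 0.5 ties) / (n_pos n_neg)}; a constant score therefore
#' gives exactly 0.5 (random ranking). The curve is traced by sweeping the
#' score threshold with tied scores grouped, so its trapezoidal area equals
#' the Mann-Whitney AUC.
#'
#' @param scores Numeric score per pair.
#' @param positives Logical per pair: is the pair a true (same-fold) pair?
#' @param higher_is_similar If \code{FALSE}, the score is distance-like and
#'   its orientation is inverted first.
#' @return An object of class \code{"roc_result"}: \code{auc},
#'   \code{curve} (data frame fpr/tpr, from (0,0) to (1,1)), \code{n_pos},
#'   \code{n_neg}.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, positives, higher_is_similar = TRUE) {
  scores <- as.numeric(scores)
  positives <- as.logical(positives)
  if (length(scores) != length(positives))
    stop("scores and positives must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(positives))
    stop("scores and positives must not contain NA", call. = FALSE)
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative pair", call. = FALSE)
  if (!higher_is_similar) scores <- -scores
  r <- rank(scores)   # average ranks on ties = half credit
  auc <- (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep, ties grouped
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positives[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC = %.4f (%d positive, %d negative pairs)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Fold-recognition ROC from a kernel matrix and fold labels
#'
#' Enumerates all unordered pairs (self-pairs excluded: self-similarity is 1
#' by construction and uninformative), marks pairs sharing a fold label as
#' positives, and runs \code{\link{roc_auc}} on the kernel values.
#'
#' @param kmat Symmetric pairwise kernel (or distance) matrix with ids as
#'   dimnames.
#' @param labels Named character vector of fold labels, covering the ids.
#' @param higher_is_similar Set \code{FALSE} for distance matrices.
#' @return A \code{"roc_result"}.
#' @export
fold_roc <- function(kmat, labels, higher_is_similar = TRUE) {
  ids <- rownames(kmat)
  if (is.null(ids)) stop("kmat must have ids as dimnames", call. = FALSE)
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop(sprintf("missing fold label(s) for: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  lab <- labels[ids]
  ut <- upper.tri(kmat)
  same <- outer(lab, lab, "==")[ut]
  roc_auc(kmat[ut], same, higher_is_similar = higher_is_similar)
}
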