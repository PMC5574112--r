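# Learning the residue kernel matrix from structural supervision.
#
# The model: for pairs of protein sequences with a structure-similarity
# score Y (distance-like, e.g. a structure-alignment SAS value), find the
# residue kernel K1 whose normalized string-kernel values X correlate as
# negatively as possible with Y. K1 is parametrized by its Cholesky factor
# L (K1 = L L'), which keeps it positive definite throughout; the optimizer
# is plain gradient descent with Armijo backtracking, so the objective trace
# is non-increasing by construction.

#' Control parameters for \code{\link{fit_kernel_matrix}}
#'
#' @param max_iter Maximum gradient-descent iterations.
#' @param ftol Stop when the objective decrease falls below this.
#' @param gtol Stop when the gradient norm falls below this.
#' @param armijo Sufficient-decrease constant of the backtracking line
#'   search.
#' @param shrink Step shrink factor on a rejected trial.
#' @param step0 Initial step size (adapted between iterations).
#' @param verbose Print the objective every iteration.
#' @return A list of class \code{"fit_control"}.
#' @export
fit_control <- function(max_iter = 500, ftol = 1e-6, gtol = 1e-6,
                        armijo = 1e-4, shrink = 0.5, step0 = 1,
                        verbose = FALSE) {
  stopifnot(max_iter >= 1, ftol >= 0, gtol >= 0,
            armijo > 0, armijo < 1, shrink > 0, shrink < 1, step0 > 0)
  structure(list(max_iter = as.integer(max_iter), ftol = ftol, gtol = gtol,
                 armijo = armijo, shrink = shrink, step0 = step0,
                 verbose = isTRUE(verbose)),
            class = "fit_control")
}

#' Learn a residue kernel matrix from structure-similarity supervision
#'
#' Minimizes the Pearson correlation between normalized string-kernel values
#' and distance-like structure scores (driving it toward -1) over the
#' residue kernel \code{K1 = L L'}, by gradient descent on the lower
#' triangle of the Cholesky factor \code{L}. The diagonal of \code{L} is
#' kept away from zero (magnitude at least 1e-8, sign preserved), so every
#' iterate's kernel matrix is positive definite. The default start is the
#' identity matrix, which encodes no similarity between distinct residues.
#'
#' During the fit the Hadamard exponent is fixed at 1: the learned object is
#' the kernel matrix itself, and a separate exponent would not be jointly
#' identifiable with its entries.
#'
#' @param pairs Data frame with columns \code{id1}, \code{id2}, \code{Y}
#'   (structure score; lower = more similar).
#' @param sequences Named character vector of sequences covering all ids.
#' @param params \code{\link{kernel_params}} with \code{beta = 1}; the
#'   default uses \code{kmax = 2} and the mean scheme.
#' @param L0 Optional starting \code{"cholesky_factor"} (default: identity).
#' @param control A \code{\link{fit_control}} list.
#' @return An object of class \code{"kernel_fit"} with components
#'   \code{K1} (the learned \code{\link{substitution_matrix}}), \code{L},
#'   \code{trace} (data frame: iteration, P, grad_norm, step),
#'   \code{converged}, \code{P_start}, \code{P_final}, \code{X}, \code{Y},
#'   \code{pairs}, \code{params}, \code{control}, \code{call}.
#' @seealso \code{\link{predict.kernel_fit}}, \code{\link{coef.kernel_fit}},
#'   \code{\link{simulate_supervision}}
#' @examples
#' \donttest{
#' set.seed(1)
#' seqs <- random_sequences(12, 20)
#' sup <- simulate_supervision(seqs, n_pairs = 12, noise_sigma = 0,
#'                             params = kernel_params(beta = 1, kmax = 2),
#'                             seed = 1)
#' fit <- fit_kernel_matrix(sup, seqs,
#'                          control = fit_control(max_iter = 25))
#' fit
#' }
#' @export
fit_kernel_matrix <- function(pairs, sequences,
                              params = kernel_params(beta = 1, kmax = 2,
                                                     scheme = "mean"),
                              L0 = NULL, control = fit_control()) {
  if (params$beta != 1)
    stop("optimization operates on the kernel matrix itself: beta must be 1",
         call. = FALSE)
  alphabet <- if (!is.null(L0)) L0$alphabet else aa_alphabet()
  ts <- .training_setup(pairs, sequences, alphabet)
  nl <- length(alphabet)
  L <- if (is.null(L0)) diag(nl) else as.matrix(L0$L)
  dimnames(L) <- list(unclass(alphabet), unclass(alphabet))

  ev <- .objective_eval(L, ts$enc, ts$i1, ts$i2, ts$y, params,
                        with_grad = TRUE)
  P_start <- ev$P
  trace <- data.frame(iteration = 0L, P = ev$P, grad_norm = ev$grad_norm,
                      step = NA_real_)
  converged <- FALSE
  step <- control$step0
  for (it in seq_len(control$max_iter)) {
    if (ev$grad_norm < control$gtol) { converged <- TRUE; break }
    g <- ev$grad_L
    gnorm2 <- sum(g^2)
    accepted <- FALSE
    t_try <- step
    while (t_try > 1e-14) {
      L_try <- clamp_diagonal(L - t_try * g)
      ev_try <- tryCatch(
        .objective_eval(L_try, ts$enc, ts$i1, ts$i2, ts$y, params,
                        with_grad = FALSE),
        error = function(e) NULL)
      if (!is.null(ev_try) &&
          ev_try$P <= ev$P - control$armijo * t_try * gnorm2) {
        accepted <- TRUE
        break
      }
      t_try <- t_try * control$shrink
    }
    if (!accepted) {
      # no descent direction at the working precision
      converged <- TRUE
      break
    }
    dP <- ev$P - ev_try$P
    L <- L_try
    ev <- .objective_eval(L, ts$enc, ts$i1, ts$i2, ts$y, params,
                          with_grad = TRUE)
    trace <- rbind(trace,
                   data.frame(iteration = it, P = ev$P,
                              grad_norm = ev$grad_norm, step = t_try))
    if (control$verbose)
      message(sprintf("iter %4d  P = %.6f  |grad| = %.3g  step = %.3g",
                      it, ev$P, ev$grad_norm, t_try))
    step <- t_try * 2   # try a bolder step next time
    if (dP < control$ftol) { converged <- TRUE; break }
  }

  K1 <- substitution_matrix(tcrossprod(L), alphabet, name = "optimized")
  structure(list(K1 = K1,
                 L = structure(list(L = L, alphabet = alphabet),
                               class = "cholesky_factor"),
                 trace = trace, converged = converged,
                 P_start = P_start, P_final = ev$P,
                 X = ev$X, Y = ts$y, pairs = ts$pairs, params = params,
                 control = control, call = match.call()),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("Learned residue kernel matrix\n")
  cat(sprintf("  training pairs: %d   kmax = %d, scheme = %s\n",
              nrow(x$pairs), x$params$kmax, x$params$scheme))
  cat(sprintf("  objective P: %.4f -> %.4f in %d iterations (%s)\n",
              x$P_start, x$P_final, max(x$trace$iteration),
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

#' @export
summary.kernel_fit <- function(object, ...) {
  pd <- is_positive_definite(object$K1)
  out <- list(n_pairs = nrow(object$pairs),
              params = object$params,
              iterations = max(object$trace$iteration),
              converged = object$converged,
              P_start = object$P_start, P_final = object$P_final,
              grad_norm = object$trace$grad_norm[nrow(object$trace)],
              lambda_min = pd$lambda_min,
              cor_check = stats::cor(object$X, object$Y))
  class(out) <- "summary.kernel_fit"
  out
}

#' @export
print.summary.kernel_fit <- function(x, ...) {
  cat("Residue kernel fit\n")
  cat(sprintf("  pairs: %d   kmax = %d   scheme = %s\n", x$n_pairs,
              x$params$kmax, x$params$scheme))
  cat(sprintf("  P: %.4f -> %.4f (%d iterations, %s)\n", x$P_start,
              x$P_final, x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  final gradient norm: %.3g\n", x$grad_norm))
  cat(sprintf("  smallest eigenvalue of K1: %.4g (positive definite)\n",
              x$lambda_min))
  invisible(x)
}

#' Extract the learned matrix from a kernel fit
#'
#' @param object A \code{"kernel_fit"}.
#' @param what \code{"K1"} for the learned kernel matrix (default) or
#'   \code{"L"} for its Cholesky factor.
#' @param ... Unused.
#' @return A numeric matrix with residue dimnames.
#' @export
coef.kernel_fit <- function(object, what = c("K1", "L"), ...) {
  what <- match.arg(what)
  if (what == "K1") object$K1$values else object$L$L
}

#' @export
fitted.kernel_fit <- function(object, ...) object$X

#' Residuals of the linear calibration of structure scores on kernel values
#'
#' The objective is a correlation, so the natural residuals are those of the
#' straight line relating the structure scores \code{Y} to the fitted kernel
#' values \code{X}.
#'
#' @param object A \code{"kernel_fit"}.
#' @param ... Unused.
#' @export
residuals.kernel_fit <- function(object, ...) {
  stats::residuals(stats::lm(object$Y ~ object$X))
}

#' Predict normalized kernel values under a learned matrix
#'
#' @param object A \code{"kernel_fit"}.
#' @param pairs Data frame with columns \code{id1}, \code{id2}.
#' @param sequences Named character vector covering the ids; defaults to
#'   re-using ids from the training sequences is not possible, so it must be
#'   supplied.
#' @param ... Unused.
#' @return Numeric vector of normalized kernel values, one per row of
#'   \code{pairs}.
#' @export
predict.kernel_fit <- function(object, pairs, sequences, ...) {
  pairs <- as.data.frame(pairs)
  vapply(seq_len(nrow(pairs)), function(i) {
    string_kernel(sequences[[pairs$id1[i]]], sequences[[pairs$id2[i]]],
                  sm = object$K1, params = object$params)$khat
  }, numeric(1))
}

#' Plot the optimization trace of a kernel fit
#'
#' @param x A \code{"kernel_fit"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.kernel_fit <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$P, type = "b", pch = 20,
                 xlab = "iteration", ylab = "Pearson correlation P", ...)
  graphics::abline(h = -1, lty = 3)
  invisible(x)
}
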