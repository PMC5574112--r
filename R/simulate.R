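# Seeded generators for synthetic data.
#
# Two stand-ins are provided for the data a real fold-recognition study
# would draw from a structural classification: (i) fold-structured sequence
# families, where each fold descends from a random ancestor by independent
# per-site substitutions, so within-fold pairs are more similar than
# between-fold pairs; (ii) supervision pairs whose structure score Y is an
# affine decreasing transform of the kernel value under a planted matrix
# plus Gaussian noise, covering a stated score range uniformly in the
# noise-free limit.

#' Random amino-acid sequences
#'
#' Draws sequences with residues i.i.d. uniform over the alphabet.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence (recycled to length \code{n}).
#' @param alphabet An \code{\link{aa_alphabet}}.
#' @param seed Optional integer seed; when given, output is a pure function
#'   of the arguments.
#' @param prefix Id prefix.
#' @return Named character vector of sequences.
#' @export
random_sequences <- function(n, length, alphabet = aa_alphabet(),
                             seed = NULL, prefix = "s") {
  if (!is.null(seed)) set.seed(seed)
  length <- rep_len(length, n)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(unclass(alphabet), length[i], replace = TRUE),
          collapse = "")
  }, character(1))
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

#' Simulate a fold-structured sequence set
#'
#' Emulates a set of protein domains grouped into folds: each fold draws one
#' ancestor sequence uniformly over the alphabet, and every member is the
#' ancestor with independent per-site substitutions at the given rate (a
#' substituted site receives a uniformly random \emph{different} residue).
#' Within-fold pairs therefore share most of their sequence while
#' between-fold pairs are unrelated. Output is deterministic given the
#' seed.
#'
#' The defaults (5 folds, 20 members, 120 residues, rate 0.3) produce a
#' small desk-scale analogue of a five-fold benchmark set with remote but
#' detectable within-fold similarity.
#'
#' @param n_folds Number of folds.
#' @param members_per_fold Sequences per fold.
#' @param ancestor_length Residues per sequence.
#' @param mutation_rate Per-site substitution probability in \code{[0, 1)}.
#' @param seed Integer seed.
#' @param alphabet An \code{\link{aa_alphabet}}.
#' @return An object of class \code{"fold_set"}: list with
#'   \code{sequences} (named character vector) and \code{labels} (named
#'   character vector of fold ids).
#' @examples
#' fs <- simulate_fold_dataset(n_folds = 2, members_per_fold = 3,
#'                             ancestor_length = 30, mutation_rate = 0.1,
#'                             seed = 7)
#' table(fs$labels)
#' @export
simulate_fold_dataset <- function(n_folds = 5, members_per_fold = 20,
                                  ancestor_length = 120,
                                  mutation_rate = 0.3, seed = 42,
                                  alphabet = aa_alphabet()) {
  stopifnot(n_folds >= 1, members_per_fold >= 1, ancestor_length >= 1,
            mutation_rate >= 0, mutation_rate < 1)
  set.seed(seed)
  letters <- unclass(alphabet)
  nl <- length(letters)
  seqs <- character(0)
  labels <- character(0)
  for (f in seq_len(n_folds)) {
    ancestor <- sample.int(nl, ancestor_length, replace = TRUE)
    fold_id <- sprintf("F%d", f)
    for (mb in seq_len(members_per_fold)) {
      member <- ancestor
      hit <- which(stats::runif(ancestor_length) < mutation_rate)
      if (length(hit)) {
        # uniformly random different residue
        shift <- sample.int(nl - 1L, length(hit), replace = TRUE)
        member[hit] <- 1L + (member[hit] - 1L + shift) %% nl
      }
      id <- sprintf("%s_%02d", fold_id, mb)
      seqs[id] <- paste(letters[member], collapse = "")
      labels[id] <- fold_id
    }
  }
  structure(list(sequences = seqs, labels = labels), class = "fold_set")
}

#' @export
print.fold_set <- function(x, ...) {
  cat(sprintf("Fold-structured sequence set: %d sequences in %d folds, lengths %s\n",
              length(x$sequences), length(unique(x$labels)),
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

#' Simulate structure-score supervision from a planted kernel matrix
#'
#' Selects distinct sequence pairs, computes their normalized kernel values
#' \code{X*} under a planted substitution matrix, and maps them to
#' distance-like structure scores by an affine decreasing transform spanning
#' \code{[score_low, score_high]} (most similar pair gets \code{score_low}),
#' plus Gaussian noise. With zero noise the Pearson correlation of \code{Y}
#' with \code{X*} is exactly -1, so an optimizer that recovers the planted
#' kernel can drive the objective to -1.
#'
#' The default score range 0-20 mirrors the span of structure-alignment SAS
#' scores typically used to supervise such fits, and the default planted
#' matrix is BL62 with Hadamard exponent 0.2.
#'
#' @param sequences Named character vector (or \code{"fold_set"}).
#' @param n_pairs Number of distinct pairs to select.
#' @param sm Planted substitution matrix.
#' @param params \code{\link{kernel_params}} used for the planted kernel
#'   values; defaults to the fitting defaults (\code{beta = 1},
#'   \code{kmax = 2}, mean scheme) applied to the planted matrix as passed.
#' @param score_low,score_high Score range, \code{score_low < score_high}.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return Data frame with columns \code{id1}, \code{id2}, \code{Y} and
#'   attribute \code{"X_star"} (the planted kernel values).
#' @export
simulate_supervision <- function(sequences, n_pairs = 60,
                                 sm = hadamard_power(bl62(), 0.2),
                                 params = kernel_params(beta = 1, kmax = 2,
                                                        scheme = "mean"),
                                 score_low = 0, score_high = 20,
                                 noise_sigma = 0.05, seed = 1) {
  if (inherits(sequences, "fold_set")) sequences <- sequences$sequences
  if (score_low >= score_high)
    stop("score_low must be below score_high", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative", call. = FALSE)
  ids <- names(sequences)
  N <- length(ids)
  n_avail <- N * (N - 1) / 2
  if (n_pairs > n_avail)
    stop(sprintf("requested %d pairs but only %d distinct pairs exist",
                 n_pairs, n_avail), call. = FALSE)
  set.seed(seed)
  pick <- sample.int(n_avail, n_pairs)
  # unrank the upper-triangle linear index
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  i1 <- ut[pick, 1L]; i2 <- ut[pick, 2L]
  x_star <- vapply(seq_len(n_pairs), function(p) {
    string_kernel(sequences[[i1[p]]], sequences[[i2[p]]], sm = sm,
                  params = params)$khat
  }, numeric(1))
  rng <- range(x_star)
  if (diff(rng) == 0)
    stop("planted kernel values are constant; cannot span a score range",
         call. = FALSE)
  y <- score_high - (x_star - rng[1]) / diff(rng) * (score_high - score_low)
  if (noise_sigma > 0) y <- y + stats::rnorm(n_pairs, 0, noise_sigma)
  out <- data.frame(id1 = ids[i1], id2 = ids[i2], Y = y,
                    stringsAsFactors = FALSE)
  attr(out, "X_star") <- x_star
  out
}
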