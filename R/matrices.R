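# Substitution / kernel matrices over an amino-acid alphabet.
#
# A substitution matrix here lives on the raw (odds-ratio) scale, not the
# logarithmic scale of alignment scoring: entries multiply along k-mers, so
# they must be usable as a positive-definite kernel between residues.

.EPS_DIAG <- 1e-8      # minimum |L(i,i)| kept on Cholesky factors
.SYM_RTOL <- 1e-12     # relative symmetry tolerance
.PD_RTOL  <- 1e-10     # relative eigenvalue tolerance for positive definiteness

#' Construct a substitution matrix
#'
#' Wraps a square symmetric numeric matrix together with its alphabet. Rows
#' and columns are reordered into the canonical (alphabetical) letter order,
#' so matrices read from files with shuffled rows compare equal.
#'
#' @param values Square numeric matrix. If \code{alphabet} is missing, row
#'   names are used as the alphabet letters.
#' @param alphabet An \code{\link{aa_alphabet}} (defaults to the row names).
#' @param name Free-text label carried along for printing and file output.
#' @return An object of class \code{"substitution_matrix"} with fields
#'   \code{values} (the reordered matrix, dimnames set), \code{alphabet} and
#'   \code{name}.
#' @examples
#' m <- diag(2); rownames(m) <- colnames(m) <- c("A", "C")
#' substitution_matrix(m, name = "toy")
#' @export
substitution_matrix <- function(values, alphabet = NULL, name = "custom") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("substitution matrix must be square", call. = FALSE)
  if (!all(is.finite(values)))
    stop("substitution matrix entries must all be finite", call. = FALSE)
  if (is.null(alphabet)) {
    if (is.null(rownames(values)))
      stop("provide an alphabet or name the matrix rows", call. = FALSE)
    alphabet <- aa_alphabet(rownames(values))
  } else {
    alphabet <- aa_alphabet(unclass(alphabet))
  }
  if (length(alphabet) != nrow(values))
    stop("alphabet size does not match matrix dimension", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- unclass(alphabet)
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!setequal(rownames(values), unclass(alphabet)) ||
      !setequal(colnames(values), unclass(alphabet)))
    stop("matrix dimnames do not match the alphabet", call. = FALSE)
  values <- values[unclass(alphabet), unclass(alphabet), drop = FALSE]
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1)
  if (asym > .SYM_RTOL * scale) {
    ij <- which(abs(values - t(values)) == asym, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is asymmetric: entry (%s,%s)=%.6g but (%s,%s)=%.6g",
      rownames(values)[ij[1]], colnames(values)[ij[2]], values[ij[1], ij[2]],
      rownames(values)[ij[2]], colnames(values)[ij[1]], values[ij[2], ij[1]]),
      call. = FALSE)
  }
  values <- (values + t(values)) / 2   # remove roundoff asymmetry
  structure(list(values = values, alphabet = alphabet, name = name),
            class = "substitution_matrix")
}

#' @export
as.matrix.substitution_matrix <- function(x, ...) x$values

#' @export
dim.substitution_matrix <- function(x) dim(x$values)

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("Substitution matrix '%s' (%d x %d)\n", x$name,
              nrow(x$values), ncol(x$values)))
  pd <- is_positive_definite(x)
  cat(sprintf("  positive definite: %s (min eigenvalue %.4g)\n",
              pd$pd, pd$lambda_min))
  print(round(x$values[seq_len(min(6, nrow(x$values))),
                       seq_len(min(6, ncol(x$values)))], 4))
  if (nrow(x$values) > 6) cat("  ...\n")
  invisible(x)
}

#' Read a substitution matrix from a text file
#'
#' The file format is whitespace-delimited: optional \code{#} comment lines,
#' one header line listing the residue letters, then one row per letter
#' starting with its letter followed by the numeric values (full square
#' matrix, not triangular). Rows may appear in any order; the matrix is
#' reordered into canonical order.
#'
#' @param path Path to the matrix file.
#' @param name Label for the matrix; defaults to the file name.
#' @return A \code{\link{substitution_matrix}}.
#' @export
read_substitution_matrix <- function(path,
                                     name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop(sprintf("matrix file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("matrix file has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  n <- length(header)
  rows <- strsplit(lines[-1L], "[[:space:]]+")
  if (length(rows) != n)
    stop(sprintf("expected %d data rows, found %d", n, length(rows)),
         call. = FALSE)
  values <- matrix(NA_real_, n, n, dimnames = list(rep("", n), header))
  seen <- character(0)
  for (r in rows) {
    letter <- r[1L]
    if (!letter %in% header)
      stop(sprintf("row letter '%s' is missing from the header", letter),
           call. = FALSE)
    if (letter %in% seen)
      stop(sprintf("duplicate row for letter '%s'", letter), call. = FALSE)
    if (length(r) != n + 1L)
      stop(sprintf("row '%s' has %d values, expected %d", letter,
                   length(r) - 1L, n), call. = FALSE)
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v))
      stop(sprintf("row '%s' contains a non-numeric cell", letter),
           call. = FALSE)
    seen <- c(seen, letter)
    values[match(letter, header), ] <- v
  }
  rownames(values) <- header
  missing <- setdiff(header, seen)
  if (length(missing))
    stop(sprintf("missing data row(s) for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  substitution_matrix(values, aa_alphabet(header), name = name)
}

#' Write a substitution matrix to a text file
#'
#' Inverse of \code{\link{read_substitution_matrix}}; round trips preserve
#' values to the printed precision.
#'
#' @param sm A \code{\link{substitution_matrix}}.
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @export
write_substitution_matrix <- function(sm, path, digits = 10) {
  stopifnot(inherits(sm, "substitution_matrix"))
  letters <- unclass(sm$alphabet)
  lines <- c(sprintf("# %s", sm$name),
             paste(letters, collapse = " "),
             vapply(seq_along(letters), function(i) {
               paste(c(letters[i],
                       formatC(sm$values[i, ], digits = digits, format = "g")),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' The bundled raw-scale BLOSUM62 kernel matrix (BL62)
#'
#' The 20x20 matrix of target-to-background frequency ratios
#' \eqn{q_{ij}/(p_i p_j)} underlying BLOSUM62, on the raw (exponential)
#' scale rather than the usual half-bit log-odds scale. Unlike log-odds
#' scores, these entries are positive and the matrix is symmetric positive
#' definite, so it can serve directly as a kernel between residues. Values
#' are the full double-precision frequency ratios distributed with NCBI
#' BLAST+.
#'
#' @return A \code{\link{substitution_matrix}} named \code{"BL62"}.
#' @examples
#' bl62()
#' @export
bl62 <- function() {
  path <- system.file("extdata", "BL62.txt", package = "strkernel",
                      mustWork = TRUE)
  read_substitution_matrix(path, name = "BL62")
}

#' Entrywise (Hadamard) power of a substitution matrix
#'
#' Raises every entry to the power \code{beta}. With \code{beta} strictly
#' positive and a symmetric positive-definite input of nonnegative entries,
#' the result remains a valid residue kernel; \code{beta} below 1 compresses
#' the dynamic range of the matrix.
#'
#' @param sm A \code{\link{substitution_matrix}} with nonnegative entries.
#' @param beta Strictly positive exponent.
#' @return A \code{\link{substitution_matrix}} with entries
#'   \code{sm$values^beta}.
#' @examples
#' hadamard_power(bl62(), 0.2)
#' @export
hadamard_power <- function(sm, beta) {
  stopifnot(inherits(sm, "substitution_matrix"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single strictly positive number", call. = FALSE)
  if (any(sm$values < 0))
    stop("Hadamard power requires nonnegative entries", call. = FALSE)
  out <- sm
  out$values <- sm$values^beta
  out$name <- if (beta == 1) sm$name else sprintf("%s^%g", sm$name, beta)
  out
}

#' Test positive definiteness of a substitution matrix
#'
#' A matrix passes when its smallest eigenvalue exceeds
#' \code{-1e-10 * largest eigenvalue}; the tolerance is relative so that
#' optimized matrices of any magnitude are judged on the same footing.
#'
#' @param sm A \code{\link{substitution_matrix}} (or square symmetric matrix).
#' @return A list with \code{pd} (logical), \code{lambda_min} and
#'   \code{lambda_max}.
#' @export
is_positive_definite <- function(sm) {
  values <- if (inherits(sm, "substitution_matrix")) sm$values else as.matrix(sm)
  if (!all(is.finite(values)))
    stop("matrix entries must be finite", call. = FALSE)
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  lmax <- max(ev)
  list(pd = lmin > -.PD_RTOL * max(abs(lmax), 1e-300),
       lambda_min = lmin, lambda_max = lmax)
}

#' Cholesky factor of a positive-definite substitution matrix
#'
#' Decomposes \code{sm = L L'} with \code{L} lower triangular and positive
#' diagonal. The factor is the natural parametrization for optimizing a
#' kernel matrix while keeping it positive definite.
#'
#' @param sm A positive-definite \code{\link{substitution_matrix}}.
#' @return An object of class \code{"cholesky_factor"}: list with \code{L}
#'   (lower-triangular matrix, dimnames set) and \code{alphabet}.
#' @examples
#' cholesky_factor(bl62())
#' @export
cholesky_factor <- function(sm) {
  stopifnot(inherits(sm, "substitution_matrix"))
  U <- tryCatch(chol(sm$values), error = function(e) {
    piv <- regmatches(conditionMessage(e),
                      regexpr("[0-9]+", conditionMessage(e)))
    stop(sprintf("matrix is not positive definite (failing pivot %s)",
                 if (length(piv)) piv else "?"), call. = FALSE)
  })
  L <- t(U)
  structure(list(L = L, alphabet = sm$alphabet), class = "cholesky_factor")
}

# Validate / construct a cholesky_factor from a raw lower-triangular matrix.
#' Wrap a lower-triangular matrix as a Cholesky factor
#'
#' @param L Lower-triangular square matrix (strict zeros above the diagonal).
#' @param alphabet Alphabet for the rows; defaults to row names.
#' @param clamp If \code{TRUE}, diagonal entries with magnitude below the
#'   package minimum (1e-8) are pushed to it, preserving sign, so that the
#'   factor stays invertible.
#' @return A \code{"cholesky_factor"}.
#' @export
as_cholesky <- function(L, alphabet = NULL, clamp = FALSE) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("L must be square", call. = FALSE)
  if (any(L[upper.tri(L)] != 0))
    stop("L must be strictly zero above the diagonal", call. = FALSE)
  if (is.null(alphabet)) {
    alphabet <- if (!is.null(rownames(L))) aa_alphabet(rownames(L))
                else if (nrow(L) == 20L) aa_alphabet()
                else stop("provide an alphabet for L", call. = FALSE)
  } else alphabet <- aa_alphabet(unclass(alphabet))
  dimnames(L) <- list(unclass(alphabet), unclass(alphabet))
  if (clamp) L <- clamp_diagonal(L)
  d <- diag(L)
  if (any(abs(d) < .EPS_DIAG))
    stop(sprintf("diagonal entry %d of L is below the minimum magnitude %g",
                 which(abs(d) < .EPS_DIAG)[1], .EPS_DIAG), call. = FALSE)
  structure(list(L = L, alphabet = alphabet), class = "cholesky_factor")
}

# Sign-preserving clamp of the diagonal away from zero.
clamp_diagonal <- function(L, eps = .EPS_DIAG) {
  d <- diag(L)
  small <- abs(d) < eps
  if (any(small)) diag(L)[small] <- ifelse(d[small] < 0, -eps, eps)
  L
}

#' @export
print.cholesky_factor <- function(x, ...) {
  cat(sprintf("Cholesky factor (%d x %d), diag range [%.4g, %.4g]\n",
              nrow(x$L), ncol(x$L), min(diag(x$L)), max(diag(x$L))))
  invisible(x)
}

#' Reconstruct a kernel matrix from its Cholesky factor
#'
#' Computes \code{L L'}, which is symmetric positive semi-definite by
#' construction and positive definite whenever no diagonal entry of \code{L}
#' is zero.
#'
#' @param L A \code{"cholesky_factor"} (or lower-triangular matrix).
#' @param name Label for the resulting matrix.
#' @return A \code{\link{substitution_matrix}}.
#' @export
reconstruct_kernel <- function(L, name = "LLt") {
  if (inherits(L, "cholesky_factor")) {
    values <- tcrossprod(L$L)
    substitution_matrix(values, L$alphabet, name = name)
  } else {
    L <- as.matrix(L)
    substitution_matrix(tcrossprod(L), name = name)
  }
}

#' Row-normalize a substitution matrix
#'
#' Divides each row by its sum so rows sum to one. Row normalization of a
#' symmetric matrix generally breaks symmetry, so the result is returned as
#' a plain matrix with a \code{"symmetric"} attribute rather than as a
#' \code{substitution_matrix}; a row-normalized matrix is in general not a
#' kernel and cannot be fed back into the kernel computations directly.
#'
#' @param sm A \code{\link{substitution_matrix}} with positive row sums.
#' @return A numeric matrix whose rows each sum to 1, with attribute
#'   \code{symmetric} indicating whether symmetry survived.
#' @export
normalize_rows <- function(sm) {
  stopifnot(inherits(sm, "substitution_matrix"))
  rs <- rowSums(sm$values)
  if (any(rs <= 0))
    stop(sprintf("row '%s' has non-positive sum",
                 rownames(sm$values)[which(rs <= 0)[1]]), call. = FALSE)
  out <- sm$values / rs
  sym <- max(abs(out - t(out))) <= .SYM_RTOL * max(abs(out), 1)
  attr(out, "symmetric") <- sym
  out
}
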