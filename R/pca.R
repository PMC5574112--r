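# Principal component analysis of a substitution matrix.
#
# A 20 x 20 substitution matrix is read as a data matrix: 20 amino-acid
# "objects" described by 20 substitution-score "features". Centering each
# feature (column) and eigendecomposing the row covariance yields principal
# components along which the amino acids can be placed as points; the
# leading components of informative matrices line up with physico-chemical
# scales such as hydrophobicity.

#' Column-center a square matrix
#'
#' Subtracts each column's mean, so every column of the result sums to zero.
#' Centering is idempotent.
#'
#' @param K Square numeric matrix (or \code{\link{substitution_matrix}}).
#' @return The centered matrix.
#' @export
center_columns <- function(K) {
  K <- if (inherits(K, "substitution_matrix")) K$values else as.matrix(K)
  if (!all(is.finite(K))) stop("matrix entries must be finite", call. = FALSE)
  sweep(K, 2L, colMeans(K))
}

#' Row covariance of a centered matrix
#'
#' \code{C = Kc Kc' / (N - 1)}; the \code{N - 1} denominator reflects that
#' the feature means were estimated from the matrix itself.
#'
#' @param Kc Column-centered square matrix.
#' @return Symmetric positive semi-definite covariance matrix.
#' @export
row_covariance <- function(Kc) {
  Kc <- as.matrix(Kc)
  N <- nrow(Kc)
  if (N < 2L) stop("need at least 2 rows", call. = FALSE)
  tcrossprod(Kc) / (N - 1)
}

#' Principal component analysis of a substitution matrix
#'
#' Centers the columns, forms the row covariance, and eigendecomposes it.
#' Eigenvalues give the variance carried by each component; amino-acid
#' coordinates are the projections of the centered rows onto the leading
#' components. The sign of each component is fixed by making its
#' largest-magnitude coordinate positive, so results are reproducible.
#'
#' @param K A \code{\link{substitution_matrix}} or square labeled matrix.
#' @param n_components Number of leading components for which coordinates
#'   are returned (default 3).
#' @return An object of class \code{"sm_pca"}: \code{eigenvalues}
#'   (non-increasing), \code{variance_fraction}, \code{components}
#'   (orthonormal columns), \code{coordinates} (rows = amino acids,
#'   columns = PC1..), \code{alphabet}, \code{name}.
#' @examples
#' p <- sm_pca(bl62())
#' round(100 * cumsum(p$variance_fraction)[3])   # percent variance in 3 PCs
#' @export
sm_pca <- function(K, n_components = 3) {
  name <- if (inherits(K, "substitution_matrix")) K$name else "matrix"
  letters <- if (inherits(K, "substitution_matrix")) unclass(K$alphabet)
             else rownames(as.matrix(K))
  Kc <- center_columns(K)
  if (is.null(letters)) letters <- paste0("r", seq_len(nrow(Kc)))
  C <- row_covariance(Kc)
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values
  ev[ev < 0 & ev > -1e-10 * max(ev)] <- 0   # clip eigen roundoff
  n_components <- min(as.integer(n_components), length(ev))
  V <- e$vectors
  coords <- Kc %*% V
  # deterministic sign: largest-magnitude coordinate positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) { V[, j] <- -V[, j]; coords[, j] <- -coords[, j] }
  }
  coords <- coords[, seq_len(n_components), drop = FALSE]
  dimnames(coords) <- list(letters, paste0("PC", seq_len(n_components)))
  rownames(V) <- letters
  structure(list(eigenvalues = ev, variance_fraction = ev / sum(ev),
                 components = V, coordinates = coords,
                 alphabet = letters, name = name),
            class = "sm_pca")
}

#' @export
print.sm_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("PCA of substitution matrix '%s'\n", x$name))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  cat(sprintf("  first three components: %.1f%%\n",
              100 * sum(x$variance_fraction[1:min(3, k)])))
  invisible(x)
}

#' Plot amino acids on the leading principal components
#'
#' @param x An \code{"sm_pca"}.
#' @param components Length-2 integer vector of components to plot.
#' @param ... Passed to \code{plot}.
#' @export
plot.sm_pca <- function(x, components = c(1, 2), ...) {
  cc <- x$coordinates[, components, drop = FALSE]
  graphics::plot(cc, type = "n",
                 xlab = colnames(cc)[1], ylab = colnames(cc)[2], ...)
  graphics::text(cc[, 1], cc[, 2], labels = rownames(cc))
  invisible(x)
}

#' Correlation of a principal component with an amino-acid index scale
#'
#' Pearson correlation (absolute value: component signs are arbitrary)
#' between the amino-acid coordinates of one component and a user-supplied
#' index of 20 per-residue values, e.g. a hydrophobicity scale.
#'
#' @param pca An \code{"sm_pca"}.
#' @param component Component number (within the returned coordinates).
#' @param index Named numeric vector covering every residue of the
#'   alphabet.
#' @return Absolute Pearson correlation, in \code{[0, 1]}.
#' @export
index_correlation <- function(pca, component, index) {
  stopifnot(inherits(pca, "sm_pca"))
  component <- as.integer(component)
  if (component < 1L || component > ncol(pca$coordinates))
    stop("component out of range of the stored coordinates", call. = FALSE)
  miss <- setdiff(pca$alphabet, names(index))
  if (length(miss))
    stop(sprintf("index is missing residue(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  v <- as.numeric(index[pca$alphabet])
  if (anyNA(v)) stop("index contains NA values", call. = FALSE)
  abs(stats::cor(pca$coordinates[, component], v))
}
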