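#' strkernel: weighted string kernels for protein sequences
#'
#' Alignment-free comparison of protein sequences through weighted k-mer
#' convolution kernels, learning of the underlying amino-acid similarity
#' matrix from structural supervision, ROC evaluation of fold recognition,
#' and principal component analysis of substitution matrices.
#'
#' @keywords internal
"_PACKAGE"

#' The canonical 20-letter amino-acid alphabet
#'
#' One-letter residue codes in the package's canonical (alphabetical) order.
#' All substitution matrices are stored with rows and columns in this order,
#' and sequences are validated against it.
#'
#' @format A character vector of length 20.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an amino-acid alphabet
#'
#' An alphabet is an ordered set of distinct uppercase one-letter residue
#' codes. The default is the canonical 20-letter protein alphabet; smaller
#' alphabets (2 letters or more) are accepted so that toy matrices can be
#' used in exact, hand-checkable computations.
#'
#' @param letters Character vector of distinct single uppercase letters.
#' @return A character vector of class \code{"aa_alphabet"}, sorted into
#'   canonical (alphabetical) order.
#' @examples
#' aa_alphabet()            # the 20 standard residues
#' aa_alphabet(c("A", "C")) # a 2-letter toy alphabet
#' @export
aa_alphabet <- function(letters = AA_LETTERS) {
  letters <- as.character(letters)
  if (length(letters) < 2L)
    stop("an alphabet needs at least 2 letters", call. = FALSE)
  if (anyDuplicated(letters))
    stop("alphabet letters must be distinct", call. = FALSE)
  if (!all(grepl("^[A-Z]$", letters)))
    stop("alphabet letters must be single uppercase characters", call. = FALSE)
  structure(sort(letters), class = "aa_alphabet")
}

#' Position of letters in an alphabet
#'
#' @param alphabet An \code{aa_alphabet}.
#' @param letters Character vector of single letters.
#' @return Integer positions; \code{NA} for letters not in the alphabet.
#' @export
alphabet_index <- function(alphabet, letters) {
  match(letters, unclass(alphabet))
}

# Encode a residue string as integer indices into `alphabet`.
# strict mode errors on the first illegal residue, naming it and its
# position; otherwise illegal residues are dropped (count reported via a
# message), mirroring the package's sanitization policy.
encode_sequence <- function(x, alphabet = aa_alphabet(), drop_illegal = FALSE,
                            id = NULL) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, unclass(alphabet))
  bad <- which(is.na(idx))
  if (length(bad)) {
    if (!drop_illegal) {
      where <- if (is.null(id)) "" else sprintf(" in sequence '%s'", id)
      stop(sprintf("illegal residue '%s' at position %d%s",
                   chars[bad[1]], bad[1], where), call. = FALSE)
    }
    message(sprintf("dropped %d illegal residue(s)%s", length(bad),
                    if (is.null(id)) "" else sprintf(" from '%s'", id)))
    idx <- idx[-bad]
  }
  if (!length(idx))
    stop("sequence has no residues after sanitization", call. = FALSE)
  idx
}
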