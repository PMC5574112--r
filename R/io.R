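# File formats: FASTA sequences, pair/label/index tables.

#' Read protein sequences from a FASTA file
#'
#' Ids are taken from the header up to the first whitespace; residues are
#' uppercased and validated against the alphabet. In strict mode (default)
#' a residue outside the alphabet is an error naming the residue and its
#' position; with \code{drop_illegal = TRUE} such residues are removed and
#' the count reported.
#'
#' @param path FASTA file path.
#' @param drop_illegal Drop out-of-alphabet residues instead of erroring.
#' @param alphabet An \code{\link{aa_alphabet}}.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, drop_illegal = FALSE, alphabet = aa_alphabet()) {
  if (!file.exists(path))
    stop(sprintf("FASTA file '%s' does not exist", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("FASTA file contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  letters <- unclass(alphabet)
  for (i in seq_along(seqs)) {
    idx <- encode_sequence(seqs[[i]], alphabet, drop_illegal, id = ids[i])
    seqs[[i]] <- paste(letters[idx], collapse = "")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (or \code{"fold_set"}).
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "fold_set")) sequences <- sequences$sequences
  set <- Biostrings::AAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read training pairs (id1, id2, Y) from a TSV file
#'
#' @param path Tab-separated file with header columns \code{id1},
#'   \code{id2}, \code{Y}.
#' @return Data frame.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id1", "id2", "Y")
  if (!all(need %in% names(df)))
    stop("pairs file must have header columns id1, id2, Y", call. = FALSE)
  df[need]
}

#' Write training pairs to a TSV file
#' @param pairs Data frame with columns id1, id2, Y.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read fold labels (id, fold) from a TSV file
#' @param path Tab-separated file with header columns \code{id},
#'   \code{fold}.
#' @return Named character vector of fold labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "fold") %in% names(df)))
    stop("labels file must have header columns id, fold", call. = FALSE)
  stats::setNames(as.character(df$fold), df$id)
}

#' Write fold labels to a TSV file
#' @param labels Named character vector (or \code{"fold_set"}).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "fold_set")) labels <- labels$labels
  utils::write.table(data.frame(id = names(labels), fold = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an amino-acid index scale (residue, value) from a TSV file
#' @param path Tab-separated file with header columns \code{residue},
#'   \code{value}.
#' @return Named numeric vector.
#' @export
read_index <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df)))
    stop("index file must have header columns residue, value", call. = FALSE)
  stats::setNames(as.numeric(df$value), df$residue)
}
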