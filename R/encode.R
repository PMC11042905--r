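# Internal alphabet tables. Channel order A,C,G,T is fixed so that encoded
# tensors (and any saved models) are portable across sessions.
.base_channels <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

.check_dna <- function(seq, arg = "seq") {
  if (!is.character(seq)) {
    rlang::abort(sprintf("`%s` must be a character vector of DNA sequences.", arg))
  }
  up <- toupper(seq)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    rlang::abort(sprintf(
      "invalid DNA character '%s' at position %d of sequence %d (alphabet is A,C,G,T,N)",
      substr(up[i], bad[i], bad[i]), bad[i], i
    ))
  }
  up
}

#' One-hot encode a DNA sequence
#'
#' Encodes a DNA string over the alphabet A,C,G,T,N as an integer matrix with
#' one row per position and four channels in the fixed order A,C,G,T. `N`
#' (unknown base) becomes an all-zero row, so every row sums to 1 for a called
#' base and 0 for an uncalled one.
#'
#' @param seq A single DNA string (case-insensitive).
#' @return An integer matrix of shape `(nchar(seq), 4)` with column names
#'   `A,C,G,T`.
#' @examples
#' one_hot("ACGTN")
#' @export
one_hot <- function(seq) {
  stopifnot(length(seq) == 1L)
  up <- .check_dna(seq)
  codes <- .base_channels[strsplit(up, "", fixed = TRUE)[[1L]]]
  m <- matrix(0L, nrow = length(codes), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  hit <- codes > 0L
  m[cbind(which(hit), codes[hit])] <- 1L
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot()]: all-zero rows decode to `N`.
#'
#' @param mat A matrix of shape `(L, 4)` with 0/1 entries, channels A,C,G,T.
#' @return A DNA string of length `nrow(mat)`.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  idx <- max.col(mat, ties.method = "first")
  idx[rowSums(mat) == 0] <- 5L
  paste(c("A", "C", "G", "T", "N")[idx], collapse = "")
}

#' Reverse complement DNA sequences
#'
#' Vectorised reverse complement over the alphabet A,C,G,T,N; the complement
#' of `N` is `N`. Used for strand augmentation during training.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length, each entry reverse
#'   complemented and uppercased.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(seq) {
  up <- .check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

#' Resize sequences about their midpoint
#'
#' Trims or pads each sequence symmetrically about its centre so the output
#' has exactly `target_len` bases, the convention used to make homologous
#' sequences match a model's fixed input length. When the amount trimmed is
#' odd, one extra base is dropped from the right; when the amount padded is
#' odd, the extra `N` goes on the right. Both tie-breaks are fixed and tested.
#'
#' @param seq Character vector of DNA strings (nonempty).
#' @param target_len Target length, a positive integer.
#' @return Character vector of sequences, all of length `target_len`.
#' @examples
#' resize_from_midpoint("AACCGGTT", 4) # "CCGG"
#' resize_from_midpoint("ACG", 5)      # "NACGN"
#' @export
resize_from_midpoint <- function(seq, target_len) {
  stopifnot(length(target_len) == 1L, target_len >= 1L)
  target_len <- as.integer(target_len)
  up <- .check_dna(seq)
  if (any(nchar(up) == 0L)) rlang::abort("empty sequence cannot be resized")
  len <- nchar(up)
  out <- character(length(up))
  long <- len >= target_len
  if (any(long)) {
    trim_left <- (len[long] - target_len) %/% 2L
    out[long] <- substr(up[long], trim_left + 1L, trim_left + target_len)
  }
  if (any(!long)) {
    pad <- target_len - len[!long]
    pad_left <- pad %/% 2L
    pad_right <- pad - pad_left
    out[!long] <- paste0(
      strrep("N", pad_left), up[!long], strrep("N", pad_right)
    )
  }
  out
}

# Encode a character vector of equal-length sequences into a (B, L, 4) array.
# This is the hot path for batch generation; it avoids per-sequence R loops.
encode_seqs <- function(seqs, input_len = NULL) {
  up <- .check_dna(seqs)
  lens <- nchar(up)
  if (length(unique(lens)) != 1L) {
    rlang::abort("all sequences in a batch must have equal length")
  }
  L <- lens[1L]
  if (!is.null(input_len) && L != input_len) {
    rlang::abort(sprintf("sequence length %d does not match expected input length %d", L, input_len))
  }
  B <- length(up)
  codes <- matrix(.base_channels[unlist(strsplit(up, "", fixed = TRUE), use.names = FALSE)],
                  nrow = L, ncol = B)
  x <- array(0, dim = c(B, L, 4L))
  tc <- t(codes) # (B, L)
  for (k in 1:4) {
    sel <- tc == k
    xk <- array(0, dim = c(B, L))
    xk[sel] <- 1
    x[, , k] <- xk
  }
  x
}
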