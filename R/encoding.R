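#' Segment an IPA string into phone symbols
#'
#' Splits a transcription into the phone symbols of a feature table using
#' greedy longest-match scanning from left to right (multi-character IPA
#' symbols such as affricates or diacritic combinations require a
#' disambiguation rule; longest-match is the conventional one). Whitespace
#' separates tokens and is never part of a symbol.
#'
#' @param s a non-empty character scalar.
#' @param table a [phone_feature_table] supplying the symbol inventory.
#' @return character vector of phone symbols.
#' @examples
#' tab <- phone_feature_table(rbind(a = 1, b = -1, ab = 0:1)[, 1:2])
#' @export
segment_ipa <- function(s, table) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop_fmt("`s` must be a non-empty string")
  syms <- phones(table)
  # longest symbols first so the first startsWith hit is the longest match
  syms <- syms[order(-nchar(syms))]
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    rest <- substr(s, i, n)
    hit <- syms[startsWith(rest, syms)]
    if (!length(hit))
      stop_fmt("cannot segment '%s': no phone symbol matches at offset %d ('%s...')",
               s, i, substr(s, i, min(n, i + 4L)))
    out <- c(out, hit[1])
    i <- i + nchar(hit[1])
  }
  if (!length(out)) stop_fmt("`s` contains no phones")
  out
}

#' Encode a phone sequence as a padded feature matrix
#'
#' Stacks the phones' feature vectors into a fixed-shape 15 x F matrix.
#' Sequences shorter than 15 phones are zero-padded with a mask marking the
#' padding rows; sequences longer than 15 phones are truncated to their first
#' 15 phones (word-initial material is retained, the rest discarded).
#'
#' @param phones_seq character vector of phone symbols, all present in `table`.
#' @param table a [phone_feature_table].
#' @return an object of class `encoded_word`: a list with `matrix` (15 x F),
#'   `mask` (logical 15, `TRUE` on the first `length` positions) and `length`.
#' @examples
#' tab <- make_feature_table(5, 4, seed = 1)
#' w <- encode_word(c("p1", "p3", "p2"), tab)
#' w$length
#' @export
encode_word <- function(phones_seq, table) {
  if (!length(phones_seq)) stop_fmt("cannot encode an empty phone sequence")
  unknown <- setdiff(phones_seq, phones(table))
  if (length(unknown))
    stop_fmt("unknown phone symbol(s): %s", paste(unknown, collapse = ", "))
  f <- feature_dim(table)
  len <- min(length(phones_seq), MAX_PHONES)
  m <- matrix(0, MAX_PHONES, f)
  m[seq_len(len), ] <- unclass(table)[phones_seq[seq_len(len)], , drop = FALSE]
  structure(list(matrix = m,
                 mask = seq_len(MAX_PHONES) <= len,
                 length = len),
            class = "encoded_word")
}

#' @export
print.encoded_word <- function(x, ...) {
  cat(sprintf("<encoded_word: length %d, %d features, %d padded rows>\n",
              x$length, ncol(x$matrix), MAX_PHONES - x$length))
  invisible(x)
}

#' Decode an encoded word back into phone symbols
#'
#' Inverts [encode_word()] by matching each unmasked row against the feature
#' table (rows are pairwise distinct by construction, so the inverse is
#' well-defined). Used to verify the injectivity of the encoding.
#'
#' @param word an `encoded_word`.
#' @param table the [phone_feature_table] it was encoded with.
#' @return character vector of phone symbols.
#' @export
decode_word <- function(word, table) {
  stopifnot(inherits(word, "encoded_word"))
  keys <- apply(unclass(table), 1, paste, collapse = ",")
  vapply(seq_len(word$length), function(i) {
    key <- paste(word$matrix[i, ], collapse = ",")
    j <- match(key, keys)
    if (is.na(j)) stop_fmt("row %d matches no phone in the table", i)
    phones(table)[j]
  }, character(1))
}

#' Encode a list of words into a batched array
#'
#' Stacks encoded words into the dense array form consumed by the sequence
#' mapper: an `n x 15 x F` input array plus an `n x 15` mask matrix.
#'
#' @param phone_seqs list of character vectors (one phone sequence per word),
#'   or a character vector of space-separated phone strings.
#' @param table a [phone_feature_table].
#' @return an object of class `encoded_batch`: list with `x` (array
#'   n x 15 x F), `mask` (n x 15 logical matrix), `lengths`, `feature_dim`.
#' @export
encode_words <- function(phone_seqs, table) {
  if (is.character(phone_seqs))
    phone_seqs <- strsplit(phone_seqs, " ", fixed = TRUE)
  n <- length(phone_seqs)
  if (!n) stop_fmt("`phone_seqs` is empty")
  f <- feature_dim(table)
  x <- array(0, dim = c(n, MAX_PHONES, f))
  mask <- matrix(FALSE, n, MAX_PHONES)
  lengths <- integer(n)
  tab <- unclass(table)
  for (i in seq_len(n)) {
    ph <- phone_seqs[[i]]
    if (!length(ph)) stop_fmt("word %d has an empty phone sequence", i)
    unknown <- setdiff(ph, rownames(tab))
    if (length(unknown))
      stop_fmt("word %d: unknown phone symbol(s) %s", i,
               paste(unknown, collapse = ", "))
    len <- min(length(ph), MAX_PHONES)
    x[i, seq_len(len), ] <- tab[ph[seq_len(len)], , drop = FALSE]
    mask[i, seq_len(len)] <- TRUE
    lengths[i] <- len
  }
  structure(list(x = x, mask = mask, lengths = lengths, feature_dim = f),
            class = "encoded_batch")
}

# subset an encoded_batch by row indices (with replacement allowed, for
# oversampling)
batch_subset <- function(batch, idx) {
  structure(list(x = batch$x[idx, , , drop = FALSE],
                 mask = batch$mask[idx, , drop = FALSE],
                 lengths = batch$lengths[idx],
                 feature_dim = batch$feature_dim),
            class = "encoded_batch")
}

# concatenate encoded_batches along the word axis
batch_rbind <- function(batches) {
  stopifnot(length(batches) >= 1L)
  f <- batches[[1]]$feature_dim
  n <- sum(vapply(batches, function(b) dim(b$x)[1], integer(1)))
  x <- array(0, dim = c(n, MAX_PHONES, f))
  mask <- matrix(FALSE, n, MAX_PHONES)
  lengths <- integer(n)
  at <- 0L
  for (b in batches) {
    nb <- dim(b$x)[1]
    idx <- at + seq_len(nb)
    x[idx, , ] <- b$x
    mask[idx, ] <- b$mask
    lengths[idx] <- b$lengths
    at <- at + nb
  }
  structure(list(x = x, mask = mask, lengths = lengths, feature_dim = f),
            class = "encoded_batch")
}
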