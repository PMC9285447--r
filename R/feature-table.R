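#' Phone feature tables
#'
#' A phone feature table maps each phone symbol to a fixed-length vector of
#' subsegmental articulatory feature values in \{-1, 0, +1\} (the ternary
#' coding conventional for articulatory feature systems: -1 = feature absent,
#' 0 = not applicable, +1 = feature present). The all-zero vector is reserved
#' for sequence padding and is therefore not a legal phone vector.
#'
#' @param features numeric matrix with one row per phone (row names are the
#'   phone symbols) and one column per feature; entries must be -1, 0 or +1.
#' @return an object of class `phone_feature_table`: the validated feature
#'   matrix with attributes `feature_dim` and `phones`.
#' @examples
#' m <- rbind(a = c(1, 0, -1), b = c(-1, 1, 0))
#' tab <- phone_feature_table(m)
#' feature_dim(tab)
#' @export
phone_feature_table <- function(features) {
  if (!is.matrix(features) || !is.numeric(features))
    stop_fmt("`features` must be a numeric matrix")
  if (is.null(rownames(features)) || anyNA(rownames(features)) ||
      any(rownames(features) == ""))
    stop_fmt("feature matrix must have non-empty phone symbols as row names")
  dup <- rownames(features)[duplicated(rownames(features))]
  if (length(dup))
    stop_fmt("duplicate phone symbol(s): %s", paste(unique(dup), collapse = ", "))
  bad <- !(features %in% c(-1, 0, 1))
  if (any(bad)) {
    row <- rownames(features)[which(bad)[1] %% nrow(features)]
    stop_fmt("feature values must be -1, 0 or +1 (offending phone: '%s')",
             if (is.na(row) || row == "") "?" else row)
  }
  zero <- rowSums(abs(features)) == 0
  if (any(zero))
    stop_fmt("all-zero feature vector for phone(s) %s: the zero vector is reserved for padding",
             paste(rownames(features)[zero], collapse = ", "))
  structure(features,
            feature_dim = ncol(features),
            phones = rownames(features),
            class = c("phone_feature_table", class(features)))
}

#' @rdname phone_feature_table
#' @param table a `phone_feature_table`.
#' @export
feature_dim <- function(table) attr(table, "feature_dim")

#' @rdname phone_feature_table
#' @export
phones <- function(table) rownames(table)

#' @export
print.phone_feature_table <- function(x, ...) {
  cat(sprintf("<phone_feature_table: %d phones x %d features>\n",
              nrow(x), feature_dim(x)))
  utils::str(unclass(x)[seq_len(min(4L, nrow(x))), , drop = FALSE])
  invisible(x)
}

#' Generate a random phone feature table
#'
#' Draws `p` distinct phone symbols (`p01`, `p02`, ...) with feature vectors
#' sampled uniformly from the nonzero elements of \{-1, 0, +1\}^`f`. Rows are
#' pairwise distinct and never all-zero, so the padding vector stays
#' unambiguous. The result is deterministic given `seed`.
#'
#' @param p number of phones (inventory size), at least 2.
#' @param f feature dimensionality, at least 1; `3^f` must exceed `p` so that
#'   `p` distinct nonzero vectors exist.
#' @param seed integer seed.
#' @return a [phone_feature_table].
#' @examples
#' tab <- make_feature_table(10, 4, seed = 1)
#' @export
make_feature_table <- function(p, f, seed = 1L) {
  assert_scalar_number(p, "p", lower = 2, integer = TRUE)
  assert_scalar_number(f, "f", lower = 1, integer = TRUE)
  p <- as.integer(p); f <- as.integer(f)
  if (3^f <= p)
    stop_fmt("cannot draw %d distinct phones from {-1,0,1}^%d without duplicates", p, f)
  feats <- with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    rows <- vector("list", p)
    got <- 0L
    # rejection sampling over nonzero distinct vectors; inventory sizes are
    # tiny relative to 3^f so this terminates quickly
    while (got < p) {
      v <- sample(c(-1, 0, 1), f, replace = TRUE)
      key <- paste(v, collapse = ",")
      if (all(v == 0) || !is.null(seen[[key]])) next
      got <- got + 1L
      seen[[key]] <- TRUE
      rows[[got]] <- v
    }
    do.call(rbind, rows)
  })
  rownames(feats) <- sprintf("p%0*d", nchar(p), seq_len(p))
  phone_feature_table(feats)
}

#' Read and write phone feature tables as CSV
#'
#' The interchange format is a CSV with header `phone,f1,...,fF`: one row per
#' phone, feature values in \{-1, 0, +1\}. Malformed files (duplicate phones,
#' ragged rows, out-of-range values) raise an error naming the offending row.
#'
#' @param path file path.
#' @return `read_feature_table()` returns a [phone_feature_table];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_fmt("empty feature table file: %s", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  header <- parts[[1]]
  if (header[1] != "phone" || length(header) < 2L)
    stop_fmt("feature table header must be 'phone,f1,...,fF', got '%s'", lines[1])
  f <- length(header) - 1L
  body <- parts[-1]
  body <- body[vapply(body, function(x) length(x) > 0L && any(nzchar(x)), logical(1))]
  syms <- character(length(body))
  feats <- matrix(NA_real_, length(body), f)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != f + 1L)
      stop_fmt("row %d ('%s'): expected %d feature values, found %d",
               i, row[1], f, length(row) - 1L)
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals) || !all(vals %in% c(-1, 0, 1)))
      stop_fmt("row %d ('%s'): feature values must be -1, 0 or +1", i, row[1])
    syms[i] <- row[1]
    feats[i, ] <- vals
  }
  if (anyDuplicated(syms))
    stop_fmt("duplicate phone symbol '%s' in %s", syms[duplicated(syms)][1], path)
  rownames(feats) <- syms
  phone_feature_table(feats)
}

#' @rdname read_feature_table
#' @param table a [phone_feature_table].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "phone_feature_table"))
  f <- feature_dim(table)
  header <- paste(c("phone", paste0("f", seq_len(f))), collapse = ",")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(unclass(table)[i, ], trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
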