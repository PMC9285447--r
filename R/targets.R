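#' Read and write dense target vectors (word-embedding text format)
#'
#' The interchange format is the plain-text word-embedding format: a header
#' line `"N dim"` followed by N rows `"id v1 ... vdim"`. Visual stores are
#' additionally required to be elementwise nonnegative (they play the role of
#' rectified convolutional feature maps).
#'
#' @param path file path.
#' @param kind `"visual"` or `"semantic"`.
#' @return `load_dense_vectors()` returns a `dense_target_store`: list with
#'   `vectors` (matrix, row names = concept ids), `dim`, `kind`.
#' @export
load_dense_vectors <- function(path, kind = c("semantic", "visual")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_fmt("empty vector file: %s", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header))))
    stop_fmt("header must be 'N dim', got '%s'", lines[1])
  n <- as.integer(header[1]); d <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop_fmt("header promises %d rows, found %d", n, length(body))
  ids <- character(n)
  m <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != d + 1L)
      stop_fmt("row %d ('%s'): expected %d values, found %d",
               i, parts[1], d, length(parts) - 1L)
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop_fmt("row %d ('%s'): non-numeric value", i, parts[1])
    ids[i] <- parts[1]
    m[i, ] <- vals
  }
  if (anyDuplicated(ids))
    stop_fmt("duplicate id '%s' in %s", ids[duplicated(ids)][1], path)
  if (kind == "visual" && any(m < 0))
    stop_fmt("visual vectors must be nonnegative; row '%s' has a negative entry",
             ids[which(rowSums(m < 0) > 0)[1]])
  rownames(m) <- ids
  structure(list(vectors = m, dim = d, kind = kind),
            class = "dense_target_store")
}

#' @rdname load_dense_vectors
#' @param vectors numeric matrix with concept ids as row names.
#' @export
write_dense_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(vectors), ncol(vectors)), con)
  for (i in seq_len(nrow(vectors))) {
    writeLines(paste(c(rownames(vectors)[i],
                       format(vectors[i, ], trim = TRUE, digits = 17)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Keep only words with a unique part-of-speech tag
#'
#' Words attested under more than one raw tag are ambiguous with respect to
#' word class and are removed before classification; the survivors carry
#' their single tag. The operation is idempotent.
#'
#' @param entries data.frame with columns `word` and `tag` (one row per
#'   attested word-tag combination).
#' @return data.frame `word`, `tag` restricted to unambiguous words, in first
#'   appearance order.
#' @examples
#' filter_unambiguous(data.frame(word = c("run", "run", "dog"),
#'                               tag = c("V", "N", "N")))
#' @export
filter_unambiguous <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("word", "tag") %in% names(entries)))
  entries <- unique(entries[, c("word", "tag")])
  n_tags <- table(entries$word)
  keep <- entries$word %in% names(n_tags)[n_tags == 1L]
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Word-class encoding schemes
#'
#' A scheme collapses a fine-grained tagset into coarse supertags and encodes
#' each supertag as a one-hot vector. Supertags listed in `dropped` are
#' excluded from the encoding (their dimension is removed) and words mapping
#' to them are skipped rather than rejected, mirroring the silent removal of
#' classes that do not survive preprocessing.
#'
#' @param collapse_map data.frame with columns `raw_tag`, `supertag`; every
#'   raw tag must map to exactly one supertag.
#' @param supertags optional character vector fixing the supertag order;
#'   defaults to first appearance order in `collapse_map`.
#' @param dropped character vector of supertags to exclude from the encoding.
#' @return an object of class `word_class_scheme` with fields `collapse_map`,
#'   `supertags`, `dropped`, `active` (encoded supertags, in order) and
#'   `dim` (= length of `active`).
#' @export
word_class_scheme <- function(collapse_map, supertags = NULL, dropped = character(0)) {
  stopifnot(is.data.frame(collapse_map),
            all(c("raw_tag", "supertag") %in% names(collapse_map)))
  collapse_map <- unique(collapse_map[, c("raw_tag", "supertag")])
  if (anyDuplicated(collapse_map$raw_tag))
    stop_fmt("raw tag '%s' maps to more than one supertag",
             collapse_map$raw_tag[duplicated(collapse_map$raw_tag)][1])
  supertags <- supertags %||% unique(collapse_map$supertag)
  if (!all(collapse_map$supertag %in% supertags))
    stop_fmt("collapse map contains supertags missing from `supertags`")
  if (!all(dropped %in% supertags))
    stop_fmt("`dropped` must be a subset of the supertags")
  active <- setdiff(supertags, dropped)
  if (!length(active)) stop_fmt("all supertags are dropped")
  structure(list(collapse_map = collapse_map, supertags = supertags,
                 dropped = dropped, active = active, dim = length(active)),
            class = "word_class_scheme")
}

#' @rdname word_class_scheme
#' @param path CSV file with header `raw_tag,supertag`.
#' @export
read_class_scheme <- function(path, dropped = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  word_class_scheme(df, dropped = dropped)
}

#' @rdname word_class_scheme
#' @param n_classes number of synthetic classes.
#' @details `default_class_scheme()` is the bundled identity scheme for the
#'   synthetic generator's classes `c1..cC` (no collapsing, nothing dropped).
#' @export
default_class_scheme <- function(n_classes) {
  tags <- paste0("c", seq_len(n_classes))
  word_class_scheme(data.frame(raw_tag = tags, supertag = tags,
                               stringsAsFactors = FALSE))
}

#' Skip marker for dropped word classes
#'
#' [encode_class()] returns this sentinel instead of a vector when a tag
#' collapses to a dropped supertag; callers exclude such words silently.
#'
#' @return `class_skip()` returns the sentinel; `is_skipped()` tests for it.
#' @export
class_skip <- function() structure(list(), class = "class_skip")

#' @rdname class_skip
#' @param x object to test.
#' @export
is_skipped <- function(x) inherits(x, "class_skip")

#' One-hot encode a raw word-class tag
#'
#' Collapses `raw_tag` through the scheme's map and emits a one-hot vector
#' over the active (non-dropped) supertags, or the [class_skip()] marker if
#' the supertag was dropped.
#'
#' @param raw_tag a single raw tag present in the scheme's collapse map.
#' @param scheme a [word_class_scheme()].
#' @return numeric one-hot vector of length `scheme$dim`, or the skip marker.
#' @examples
#' sch <- default_class_scheme(5)
#' encode_class("c3", sch)
#' @export
encode_class <- function(raw_tag, scheme) {
  stopifnot(inherits(scheme, "word_class_scheme"))
  j <- match(raw_tag, scheme$collapse_map$raw_tag)
  if (is.na(j)) stop_fmt("unknown raw tag '%s'", raw_tag)
  st <- scheme$collapse_map$supertag[j]
  if (st %in% scheme$dropped) return(class_skip())
  v <- numeric(scheme$dim)
  v[match(st, scheme$active)] <- 1
  names(v) <- scheme$active
  v
}
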