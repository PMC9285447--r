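#' Split concepts into disjoint train and test sets
#'
#' Uniform random partition of the concept inventory. The train size is
#' `round(ratio * n)` with half-up rounding, which reproduces printed splits
#' such as 1161 -> 929/232 and 24612 -> 19690/4922.
#'
#' @param concept_ids character vector of concept ids (at least 2).
#' @param ratio train fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return an object of class `concept_split`: list with `train_ids`,
#'   `test_ids`, `ratio`, `seed`.
#' @examples
#' split_concepts(paste0("c", 1:10), ratio = 0.5, seed = 1)
#' @export
split_concepts <- function(concept_ids, ratio = 0.8, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1)
    stop_fmt("`ratio` must be strictly between 0 and 1")
  concept_ids <- as.character(concept_ids)
  if (anyDuplicated(concept_ids)) stop_fmt("`concept_ids` must be unique")
  n <- length(concept_ids)
  if (n < 2L) stop_fmt("need at least 2 concepts to split")
  n_train <- as.integer(round_half_up(ratio * n))
  train <- with_seed(seed, sample(concept_ids, n_train))
  structure(list(train_ids = sort(train),
                 test_ids = sort(setdiff(concept_ids, train)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "concept_split")
}

#' @export
print.concept_split <- function(x, ...) {
  cat(sprintf("<concept_split: %d train / %d test (ratio %.2f, seed %d)>\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}

#' Build one zero-shot transfer condition
#'
#' Constructs the train/test material for one fold of the leave-one-language-
#' family-out design: the training set concatenates the encoded train-split
#' entries of every language whose family differs from the held-out
#' language's family; the test set holds the test-split entries of the
#' held-out language only. Train and test are therefore disjoint in concepts,
#' languages, and families. Order is deterministic: languages in lexicon
#' order, concepts in split order within language.
#'
#' @param lexicon a `multilingual_lexicon`.
#' @param targets numeric matrix of target vectors with concept ids as row
#'   names (every split concept must have a row).
#' @param split a [split_concepts()] result.
#' @param heldout language id to hold out.
#' @param classes optional named vector (concept id -> class label) carried
#'   along for class-aware operations (oversampling, McNemar).
#' @param oversample if `TRUE`, balance the training classes per language via
#'   [oversample_classes()] before concatenation (requires `classes`).
#' @param oversample_seed seed for the oversampler.
#' @return an object of class `transfer_condition` with fields
#'   `heldout_language`, `heldout_family`, `train` / `test`
#'   (`encoded_batch`es), `train_targets` / `test_targets` (matrices),
#'   `train_prov` / `test_prov` (provenance data.frames), and optionally
#'   `train_classes` / `test_classes`.
#' @export
build_condition <- function(lexicon, targets, split, heldout,
                            classes = NULL, oversample = FALSE,
                            oversample_seed = 1L) {
  stopifnot(inherits(lexicon, "multilingual_lexicon"),
            inherits(split, "concept_split"), is.matrix(targets))
  if (!heldout %in% lexicon$languages)
    stop_fmt("unknown held-out language '%s'", heldout)
  if (oversample && is.null(classes))
    stop_fmt("oversampling requires `classes`")
  covered <- c(split$train_ids, split$test_ids) %in% rownames(targets)
  if (!all(covered))
    stop_fmt("no target vector for concept(s): %s",
             paste(utils::head(c(split$train_ids, split$test_ids)[!covered], 5),
                   collapse = ", "))
  heldout_family <- lexicon$families[match(heldout, lexicon$languages)]
  train_langs <- lexicon$languages[lexicon$families != heldout_family]
  if (!length(train_langs)) stop_fmt("no training languages left")

  take <- function(lang, ids) {
    e <- lexicon$entries[lexicon$entries$language_id == lang, , drop = FALSE]
    e <- e[match(ids, e$concept_id), , drop = FALSE]
    if (anyNA(e$concept_id))
      stop_fmt("language %s is missing entries for some split concepts", lang)
    e
  }

  train_parts <- lapply(seq_along(train_langs), function(li) {
    lang <- train_langs[li]
    e <- take(lang, split$train_ids)
    idx <- seq_len(nrow(e))
    if (oversample) {
      # per-language sub-seed so the languages draw independent resamples
      idx <- oversample_classes(classes[e$concept_id],
                                seed = as.integer(oversample_seed) + li)
    }
    e <- e[idx, , drop = FALSE]
    list(batch = encode_words(e$phones, lexicon$feature_table),
         targets = targets[e$concept_id, , drop = FALSE],
         prov = data.frame(concept_id = e$concept_id,
                           language_id = e$language_id,
                           family_id = e$family_id,
                           stringsAsFactors = FALSE))
  })
  test_e <- take(heldout, split$test_ids)
  if (!nrow(test_e)) stop_fmt("empty test set for language %s", heldout)

  train_prov <- do.call(rbind, lapply(train_parts, `[[`, "prov"))
  cond <- structure(list(
    heldout_language = heldout,
    heldout_family = heldout_family,
    train = batch_rbind(lapply(train_parts, `[[`, "batch")),
    train_targets = do.call(rbind, lapply(train_parts, `[[`, "targets")),
    train_prov = train_prov,
    test = encode_words(test_e$phones, lexicon$feature_table),
    test_targets = targets[test_e$concept_id, , drop = FALSE],
    test_prov = data.frame(concept_id = test_e$concept_id,
                           language_id = test_e$language_id,
                           family_id = test_e$family_id,
                           stringsAsFactors = FALSE)),
    class = "transfer_condition")
  if (!is.null(classes)) {
    cond$train_classes <- unname(classes[cond$train_prov$concept_id])
    cond$test_classes <- unname(classes[cond$test_prov$concept_id])
  }
  cond
}

#' @export
print.transfer_condition <- function(x, ...) {
  cat(sprintf("<transfer_condition: heldout %s (%s); %d train pairs from %d languages, %d test pairs>\n",
              x$heldout_language, x$heldout_family,
              nrow(x$train_targets), length(unique(x$train_prov$language_id)),
              nrow(x$test_targets)))
  invisible(x)
}

#' Shuffle training targets to build the randomized baseline
#'
#' Destroys the input-output pairing of a condition's training set by
#' permuting the target vectors (and class labels, if present) while leaving
#' every input untouched: the baseline twin is trained on exactly the same
#' encoded words against a random pairing, so any performance advantage of
#' the experimental model over it is attributable to the form-target link.
#' By default one global permutation is drawn over the concatenated
#' multi-language training set; `per_language = TRUE` permutes within each
#' language instead.
#'
#' @param condition a [build_condition()] result.
#' @param seed integer seed.
#' @param per_language permute within languages rather than globally.
#' @param permutation optional explicit permutation (overrides the seed),
#'   e.g. the identity for debugging.
#' @return the condition with `train_targets` (and `train_classes`) permuted
#'   and the permutation stored in `$permutation`; class gains
#'   `"baseline_pairing"`.
#' @export
shuffle_targets <- function(condition, seed = 1L, per_language = FALSE,
                            permutation = NULL) {
  stopifnot(inherits(condition, "transfer_condition"))
  n <- nrow(condition$train_targets)
  if (n < 2L) stop_fmt("need at least 2 training pairs to shuffle")
  if (is.null(permutation)) {
    permutation <- with_seed(seed, {
      if (per_language) {
        perm <- seq_len(n)
        for (lang in unique(condition$train_prov$language_id)) {
          idx <- which(condition$train_prov$language_id == lang)
          perm[idx] <- idx[sample.int(length(idx))]
        }
        perm
      } else {
        sample.int(n)
      }
    })
  }
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop_fmt("`permutation` must be a permutation of 1..%d", n)
  condition$train_targets <- condition$train_targets[permutation, , drop = FALSE]
  if (!is.null(condition$train_classes))
    condition$train_classes <- condition$train_classes[permutation]
  condition$permutation <- permutation
  class(condition) <- c("baseline_pairing", class(condition))
  condition
}

#' Random oversampling to the majority-class count
#'
#' Returns indices into `classes` in which every minority class has been
#' raised to the majority class's count by sampling with replacement from
#' that class's own positions; the majority class (and a single-class input)
#' is left untouched. Original positions are always retained.
#'
#' @param classes vector of class labels (one per training pair).
#' @param seed integer seed.
#' @return integer index vector; `classes[result]` is class-balanced.
#' @examples
#' table(c("A","A","A","A","A","B","B","C","C","C")[
#'   oversample_classes(c("A","A","A","A","A","B","B","C","C","C"), seed = 1)])
#' @export
oversample_classes <- function(classes, seed = 1L) {
  if (!length(classes)) stop_fmt("`classes` is empty")
  counts <- table(classes)
  majority <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(k) {
      need <- majority - counts[[k]]
      if (need == 0L) return(integer(0))
      pos <- which(classes == k)
      pos[sample.int(length(pos), need, replace = TRUE)]
    }), use.names = FALSE)
  })
  c(seq_along(classes), extra)
}

#' Verify the disjointness invariants of a transfer condition
#'
#' Checks that (i) no concept occurs in both train and test provenance,
#' (ii) the held-out language's family is absent from the training set, and
#' (iii) the test set contains only the held-out language. Violations are
#' listed rather than raised, so mutated conditions can be audited.
#'
#' @param condition a [build_condition()] result.
#' @return an object of class `disjointness_report`: list with `pass`
#'   (logical) and `violations` (character vector).
#' @export
verify_disjoint <- function(condition) {
  stopifnot(inherits(condition, "transfer_condition"))
  violations <- character(0)
  overlap <- intersect(condition$train_prov$concept_id,
                       condition$test_prov$concept_id)
  if (length(overlap))
    violations <- c(violations,
                    sprintf("concept '%s' occurs in both train and test", overlap))
  fam <- unique(condition$train_prov$family_id)
  if (condition$heldout_family %in% fam)
    violations <- c(violations,
                    sprintf("held-out family '%s' present in the training set",
                            condition$heldout_family))
  bad_lang <- setdiff(unique(condition$test_prov$language_id),
                      condition$heldout_language)
  if (length(bad_lang))
    violations <- c(violations,
                    sprintf("test set contains non-held-out language '%s'", bad_lang))
  structure(list(pass = length(violations) == 0L, violations = violations),
            class = "disjointness_report")
}

#' @export
print.disjointness_report <- function(x, ...) {
  if (x$pass) cat("disjointness: PASS\n")
  else cat("disjointness: FAIL\n -", paste(x$violations, collapse = "\n - "), "\n")
  invisible(x)
}
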