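#' Configuration for the synthetic multilingual lexicon generator
#'
#' The generator emulates the statistical structure a cross-lingual transfer
#' study of sound symbolism assumes: the same concept inventory lexicalized
#' in several languages (one language family each), variable-length phone
#' strings over a shared phone inventory, per-phone articulatory feature
#' vectors, nonnegative high-dimensional "visual" targets, dense "semantic"
#' targets, and a skewed word-class distribution. Two knobs plant a
#' cross-lingually shared signal: `beta` (iconicity: phone choice biased
#' toward the concept's meaning) and `gamma` (systematicity: phone choice
#' biased toward the concept's word class). At `beta = gamma = 0` the lexicon
#' is arbitrary and serves as the null for calibration.
#'
#' @param n_concepts number of concepts.
#' @param n_languages number of languages; each gets its own family.
#' @param inventory_size number of phones in the shared inventory.
#' @param feature_dim articulatory feature dimensionality F.
#' @param meaning_dim latent meaning dimensionality M.
#' @param visual_dim visual target dimensionality V (nonnegative vectors).
#' @param semantic_dim semantic target dimensionality D.
#' @param n_classes number of word classes C.
#' @param class_probs probability vector of length `n_classes`; defaults to a
#'   skewed 1/rank (Zipf-like) distribution, mirroring the imbalance of
#'   natural part-of-speech inventories.
#' @param word_len_range integer range (within `[1, 15]`) from which word
#'   lengths are drawn uniformly.
#' @param beta iconicity strength in `[0, 1]`.
#' @param gamma systematicity strength in `[0, 1]`.
#' @param lambda_lang nonnegative weight of the language-specific phone bias
#'   (language phonotactics).
#' @param sigma target noise scale.
#' @param temperature softmax temperature for phone sampling.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_concepts = 50, beta = 1, seed = 1)
#' @export
synthetic_config <- function(n_concepts,
                             n_languages = 6L,
                             inventory_size = 40L,
                             feature_dim = 24L,
                             meaning_dim = 16L,
                             visual_dim = 64L,
                             semantic_dim = 32L,
                             n_classes = 5L,
                             class_probs = NULL,
                             word_len_range = c(3L, 9L),
                             beta = 0,
                             gamma = 0,
                             lambda_lang = 1.0,
                             sigma = 0.1,
                             temperature = 0.5,
                             seed = 1L) {
  assert_scalar_number(n_concepts, "n_concepts", lower = 1, integer = TRUE)
  assert_scalar_number(n_languages, "n_languages", lower = 1, integer = TRUE)
  assert_scalar_number(inventory_size, "inventory_size", lower = 2, integer = TRUE)
  assert_scalar_number(feature_dim, "feature_dim", lower = 1, integer = TRUE)
  assert_scalar_number(meaning_dim, "meaning_dim", lower = 1, integer = TRUE)
  assert_scalar_number(visual_dim, "visual_dim", lower = 1, integer = TRUE)
  assert_scalar_number(semantic_dim, "semantic_dim", lower = 1, integer = TRUE)
  assert_scalar_number(n_classes, "n_classes", lower = 1, integer = TRUE)
  assert_scalar_number(beta, "beta", lower = 0, upper = 1)
  assert_scalar_number(gamma, "gamma", lower = 0, upper = 1)
  assert_scalar_number(lambda_lang, "lambda_lang", lower = 0)
  assert_scalar_number(sigma, "sigma", lower = 0)
  assert_scalar_number(temperature, "temperature", lower = 1e-12)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (is.null(class_probs)) {
    class_probs <- (1 / seq_len(n_classes))
    class_probs <- class_probs / sum(class_probs)
  }
  if (length(class_probs) != n_classes || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop_fmt("`class_probs` must be %d nonnegative values summing to 1", n_classes)
  if (length(word_len_range) != 2L || any(word_len_range != round(word_len_range)) ||
      word_len_range[1] < 1L || word_len_range[2] > MAX_PHONES ||
      word_len_range[1] > word_len_range[2])
    stop_fmt("`word_len_range` must be an integer interval within [1, %d]", MAX_PHONES)
  structure(list(n_concepts = as.integer(n_concepts),
                 n_languages = as.integer(n_languages),
                 inventory_size = as.integer(inventory_size),
                 feature_dim = as.integer(feature_dim),
                 meaning_dim = as.integer(meaning_dim),
                 visual_dim = as.integer(visual_dim),
                 semantic_dim = as.integer(semantic_dim),
                 n_classes = as.integer(n_classes),
                 class_probs = as.numeric(class_probs),
                 word_len_range = as.integer(word_len_range),
                 beta = beta, gamma = gamma,
                 lambda_lang = lambda_lang, sigma = sigma,
                 temperature = temperature, seed = as.integer(seed)),
            class = "synthetic_config")
}

# stage-specific sub-seeds, kept within the 32-bit integer range
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage
}

#' Draw concepts with latent meanings, classes and target vectors
#'
#' Each concept i gets a latent meaning `m_i ~ N(0, I_M)` and a word class
#' `c_i ~ Categorical(class_probs)`. Targets are noisy linear images of the
#' meaning: the visual target is `max(0, A m_i + sigma * eps)` (rectified, so
#' nonnegative like pooled convolutional feature maps) and the semantic
#' target is `B m_i + sigma * eps`, with A and B fixed random matrices whose
#' entries are `N(0, 1/M)` so target scales are O(1).
#'
#' @param cfg a [synthetic_config()].
#' @return a list of class `concept_set` with `ids`, `meaning` (n x M),
#'   `class` (integer in 1..C), `visual` (n x V, nonnegative), `semantic`
#'   (n x D).
#' @export
make_concepts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_concepts
  ids <- sprintf("c%0*d", nchar(n), seq_len(n))
  with_seed(derive_seed(cfg$seed, 1L), {
    m <- matrix(stats::rnorm(n * cfg$meaning_dim), n, cfg$meaning_dim)
    cls <- sample.int(cfg$n_classes, n, replace = TRUE, prob = cfg$class_probs)
    A <- matrix(stats::rnorm(cfg$visual_dim * cfg$meaning_dim,
                             sd = 1 / sqrt(cfg$meaning_dim)),
                cfg$visual_dim, cfg$meaning_dim)
    B <- matrix(stats::rnorm(cfg$semantic_dim * cfg$meaning_dim,
                             sd = 1 / sqrt(cfg$meaning_dim)),
                cfg$semantic_dim, cfg$meaning_dim)
    visual <- m %*% t(A) +
      cfg$sigma * matrix(stats::rnorm(n * cfg$visual_dim), n, cfg$visual_dim)
    visual[visual < 0] <- 0  # rectification keeps the targets nonnegative
    semantic <- m %*% t(B) +
      cfg$sigma * matrix(stats::rnorm(n * cfg$semantic_dim), n, cfg$semantic_dim)
    rownames(m) <- rownames(visual) <- rownames(semantic) <- ids
    structure(list(ids = ids, meaning = m, class = cls,
                   visual = visual, semantic = semantic),
              class = "concept_set")
  })
}

# cosine of each table row against the columns of a matrix of direction
# vectors; returns phones x directions
phone_cosines <- function(table, dirs) {
  tab <- unclass(table)
  tn <- tab / pmax(sqrt(rowSums(tab^2)), 1e-12)
  dn <- sweep(dirs, 2, pmax(sqrt(colSums(dirs^2)), 1e-12), "/")
  tn %*% dn
}

#' Generate word forms with a planted cross-lingual signal
#'
#' For concept i in language l a word length is drawn uniformly from
#' `word_len_range`, then each phone position is sampled independently from a
#' softmax over the inventory with logits
#' `(beta * cos(feat(p), u_i) + gamma * cos(feat(p), w_ci) +
#'   lambda_lang * b_lp) / temperature`,
#' where `u_i = tanh(G m_i)` and `w_c = tanh(H onehot(c))` are feature-space
#' readouts of meaning and class through fixed random matrices G and H shared
#' by all languages (this sharing is what makes the signal cross-lingually
#' transferable), and `b_lp` are fixed i.i.d. standard normal phone biases per
#' (language, phone) emulating language-specific phonotactics.
#'
#' @param concepts a `concept_set` from [make_concepts()].
#' @param languages character vector of language ids.
#' @param table a [phone_feature_table] with `inventory_size` phones.
#' @param cfg the [synthetic_config()] used for `concepts`.
#' @return data.frame with columns `concept_id`, `language_id`, `phones`
#'   (space-separated phone symbols).
#' @export
make_forms <- function(concepts, languages, table, cfg) {
  stopifnot(inherits(concepts, "concept_set"), inherits(cfg, "synthetic_config"))
  if (!nrow(table)) stop_fmt("empty phone inventory")
  n <- length(concepts$ids)
  nl <- length(languages)
  p <- nrow(table)
  with_seed(derive_seed(cfg$seed, 2L), {
    G <- matrix(stats::rnorm(cfg$feature_dim * cfg$meaning_dim,
                             sd = 1 / sqrt(cfg$meaning_dim)),
                cfg$feature_dim, cfg$meaning_dim)
    H <- matrix(stats::rnorm(cfg$feature_dim * cfg$n_classes),
                cfg$feature_dim, cfg$n_classes)
    u <- tanh(G %*% t(concepts$meaning))            # F x n
    w <- tanh(H)                                    # F x C (columns = onehot images)
    cos_u <- phone_cosines(table, u)                # p x n
    cos_w <- phone_cosines(table, w)                # p x C
    bias <- matrix(stats::rnorm(nl * p), nl, p)     # language-specific phonotactics
    lens <- matrix(sample(seq.int(cfg$word_len_range[1], cfg$word_len_range[2]),
                          n * nl, replace = TRUE), n, nl)
    out <- vector("list", nl)
    for (l in seq_len(nl)) {
      forms <- character(n)
      for (i in seq_len(n)) {
        logits <- (cfg$beta * cos_u[, i] +
                   cfg$gamma * cos_w[, concepts$class[i]] +
                   cfg$lambda_lang * bias[l, ]) / cfg$temperature
        probs <- exp(logits - max(logits))
        idx <- sample.int(p, lens[i, l], replace = TRUE, prob = probs)
        forms[i] <- paste(phones(table)[idx], collapse = " ")
      }
      out[[l]] <- data.frame(concept_id = concepts$ids,
                             language_id = languages[l],
                             phones = forms,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a full synthetic multilingual lexicon
#'
#' Composes [make_feature_table()], [make_concepts()] and [make_forms()] into
#' a concept-aligned multilingual lexicon: every concept has a form in every
#' language, a word class, a nonnegative visual target and a dense semantic
#' target. Languages are named `L1..Ln` and assigned one family each
#' (`F1..Fn`), so holding out a language holds out its whole family.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `multilingual_lexicon`: list with
#'   `feature_table`, `concepts`, `entries` (data.frame concept_id,
#'   language_id, family_id, phones, word_class), `visual_targets`,
#'   `semantic_targets`, `languages`, `families`, `config`.
#' @examples
#' lex <- generate_lexicon(synthetic_config(n_concepts = 20, seed = 1))
#' nrow(lex$entries)  # 20 concepts x 6 languages
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  table <- make_feature_table(cfg$inventory_size, cfg$feature_dim,
                              seed = derive_seed(cfg$seed, 0L))
  concepts <- make_concepts(cfg)
  languages <- paste0("L", seq_len(cfg$n_languages))
  families <- paste0("F", seq_len(cfg$n_languages))
  entries <- make_forms(concepts, languages, table, cfg)
  entries$family_id <- families[match(entries$language_id, languages)]
  entries$word_class <- concepts$class[match(entries$concept_id, concepts$ids)]
  entries <- entries[, c("concept_id", "language_id", "family_id",
                         "phones", "word_class")]
  structure(list(feature_table = table,
                 concepts = concepts,
                 entries = entries,
                 visual_targets = concepts$visual,
                 semantic_targets = concepts$semantic,
                 languages = languages,
                 families = families,
                 config = cfg),
            class = "multilingual_lexicon")
}

#' @export
print.multilingual_lexicon <- function(x, ...) {
  cat(sprintf("<multilingual_lexicon: %d concepts x %d languages (%d entries), F=%d, beta=%.2f, gamma=%.2f>\n",
              length(x$concepts$ids), length(x$languages), nrow(x$entries),
              feature_dim(x$feature_table), x$config$beta, x$config$gamma))
  invisible(x)
}

#' Write or read a lexicon as plain-text files
#'
#' `write_lexicon()` serializes a lexicon into a directory: `entries.tsv`
#' (concept_id, language_id, family_id, phones, word_class),
#' `feature_table.csv` (phone, f1..fF) and `visual.vec` / `semantic.vec` in
#' the word-embedding text format. `read_lexicon()` inverts it.
#'
#' @param lexicon a `multilingual_lexicon`.
#' @param dir directory path (created if missing).
#' @return the directory path (write) or a `multilingual_lexicon` (read).
#' @export
write_lexicon <- function(lexicon, dir) {
  stopifnot(inherits(lexicon, "multilingual_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(lexicon$entries, file.path(dir, "entries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_table(lexicon$feature_table, file.path(dir, "feature_table.csv"))
  write_dense_vectors(lexicon$visual_targets, file.path(dir, "visual.vec"))
  write_dense_vectors(lexicon$semantic_targets, file.path(dir, "semantic.vec"))
  invisible(dir)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(dir) {
  entries <- utils::read.table(file.path(dir, "entries.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "character", "character",
                                              "integer"))
  table <- read_feature_table(file.path(dir, "feature_table.csv"))
  visual <- load_dense_vectors(file.path(dir, "visual.vec"), kind = "visual")
  semantic <- load_dense_vectors(file.path(dir, "semantic.vec"), kind = "semantic")
  ids <- unique(entries$concept_id)
  languages <- unique(entries$language_id)
  families <- entries$family_id[match(languages, entries$language_id)]
  cls <- entries$word_class[match(ids, entries$concept_id)]
  structure(list(feature_table = table,
                 concepts = list(ids = ids, meaning = NULL, class = cls),
                 entries = entries,
                 visual_targets = visual$vectors[ids, , drop = FALSE],
                 semantic_targets = semantic$vectors[ids, , drop = FALSE],
                 languages = languages,
                 families = families,
                 config = NULL),
            class = "multilingual_lexicon")
}
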