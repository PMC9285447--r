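# Shared fixtures, all built in code at test time.

# a tiny hand-written feature table with multi-character symbols, for
# segmentation and encoding tests
toy_table <- function() {
  phone_feature_table(rbind(
    a  = c( 1, 0, -1, 1),
    b  = c(-1, 1,  0, 0),
    ab = c( 0, 1,  1, -1),
    ts = c( 1, 1,  1, 1),
    o  = c(-1, -1, 0, 1)
  ))
}

# a small lexicon fast enough for end-to-end pipeline tests
tiny_lexicon <- function(beta = 0, gamma = 0, n = 24, seed = 7) {
  generate_lexicon(synthetic_config(
    n_concepts = n, n_languages = 3L, inventory_size = 12L, feature_dim = 8L,
    meaning_dim = 4L, visual_dim = 10L, semantic_dim = 6L, n_classes = 3L,
    word_len_range = c(2L, 5L), beta = beta, gamma = gamma, seed = seed))
}

# small mapper configuration for fast training in tests
tiny_mapper <- function(output_dim, loss = "negative_cosine",
                        activation = "relu", hidden = 6L, epochs = 3L,
                        seed = 5L, ...) {
  mapper_config(hidden_units = hidden, output_dim = output_dim,
                output_activation = activation, loss = loss,
                epochs = epochs, seed = seed, ...)
}
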