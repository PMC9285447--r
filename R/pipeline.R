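#' Configure an end-to-end transfer experiment
#'
#' Bundles everything one leave-one-language-family-out run needs: the
#' experiment kind (which output space is predicted), the data source, the
#' concept split ratio, the mapper settings and the per-role random seeds.
#' Per-experiment defaults follow the reference design: visual models use a
#' 500-unit LSTM with rectified outputs, semantic models 50 units with linear
#' outputs (both trained under the cosine objective with a 0.8 split);
#' word-class models use 25 units with softmax outputs, cross-entropy, a 0.5
#' split, and per-language random oversampling of the minority classes.
#'
#' @param experiment `"visual"`, `"semantic"` or `"wordclass"`.
#' @param synthetic a [synthetic_config()] describing the lexicon to
#'   generate, or `NULL` when `data_dir` is given.
#' @param data_dir directory holding a lexicon written by [write_lexicon()].
#' @param ratio train fraction; defaults to 0.8 (regression) or 0.5
#'   (classification).
#' @param mapper named list of [mapper_config()] overrides (e.g.
#'   `list(hidden_units = 64, epochs = 5)`).
#' @param seeds named list with elements `split`, `shuffle`, `model`,
#'   `oversample`; seeds are split by role so ablating one source of
#'   randomness leaves the others fixed.
#' @param out_dir optional output directory for result tables and manifests.
#' @return an object of class `run_config`.
#' @export
run_config <- function(experiment = c("visual", "semantic", "wordclass"),
                       synthetic = NULL, data_dir = NULL,
                       ratio = NULL, mapper = list(),
                       seeds = list(), out_dir = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(synthetic) && is.null(data_dir))
    stop_fmt("provide either `synthetic` or `data_dir`")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  ratio <- ratio %||% if (experiment == "wordclass") 0.5 else 0.8
  if (ratio <= 0 || ratio >= 1) stop_fmt("`ratio` must be in (0, 1)")
  defaults <- list(split = 101L, shuffle = 202L, model = 303L, oversample = 404L)
  seeds <- utils::modifyList(defaults, seeds)
  structure(list(experiment = experiment, synthetic = synthetic,
                 data_dir = data_dir, ratio = ratio, mapper = mapper,
                 seeds = seeds, out_dir = out_dir),
            class = "run_config")
}

# per-experiment mapper defaults, with user overrides applied
resolve_mapper_config <- function(experiment, output_dim, overrides, seed) {
  base <- switch(experiment,
    visual = list(hidden_units = 500L, output_activation = "relu",
                  loss = "negative_cosine"),
    semantic = list(hidden_units = 50L, output_activation = "linear",
                    loss = "negative_cosine"),
    wordclass = list(hidden_units = 25L, output_activation = "softmax",
                     loss = "categorical_cross_entropy"))
  args <- utils::modifyList(c(base, list(output_dim = output_dim, seed = seed)),
                            overrides)
  do.call(mapper_config, args)
}

#' Run a leave-one-language-family-out transfer experiment
#'
#' For every language L in the lexicon: build the transfer condition with L
#' held out, train the experimental model on the true input-target pairing
#' and a baseline model of identical architecture and seed on the
#' shuffled-target pairing, predict on L's test set, and contrast the two
#' models (paired t-test on per-item cosines for regression; McNemar
#' chi-square plus weighted classification metrics for classification). With
#' n languages this is an n-fold non-random cross-validation in which each
#' language is held out exactly once. Reruns with an identical configuration
#' are bit-identical.
#'
#' @param config a [run_config()].
#' @return an object of class `run_result`: list with `experiment`, `folds`
#'   (per held-out language: contrast statistics and summaries), `table`
#'   (the [report()] data.frame), `consistency` (word-class runs only),
#'   `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lexicon <- if (!is.null(config$synthetic)) generate_lexicon(config$synthetic)
             else read_lexicon(config$data_dir)
  experiment <- config$experiment

  if (experiment == "wordclass") {
    scheme <- default_class_scheme(max(lexicon$concepts$class))
    raw <- paste0("c", lexicon$concepts$class)
    enc <- lapply(raw, encode_class, scheme = scheme)
    keep <- !vapply(enc, is_skipped, logical(1))
    ids <- lexicon$concepts$ids[keep]
    targets <- do.call(rbind, enc[keep])
    rownames(targets) <- ids
    classes <- stats::setNames(scheme$collapse_map$supertag[
      match(raw[keep], scheme$collapse_map$raw_tag)], ids)
    class_set <- scheme$active
  } else {
    targets <- if (experiment == "visual") lexicon$visual_targets
               else lexicon$semantic_targets
    ids <- rownames(targets)
    classes <- NULL
    class_set <- NULL
  }

  split <- split_concepts(ids, ratio = config$ratio, seed = config$seeds$split)
  folds <- vector("list", length(lexicon$languages))
  names(folds) <- lexicon$languages
  per_class_acc <- list()

  for (fi in seq_along(lexicon$languages)) {
    lang <- lexicon$languages[fi]
    cond <- build_condition(lexicon, targets, split, heldout = lang,
                            classes = classes,
                            oversample = experiment == "wordclass",
                            oversample_seed = config$seeds$oversample)
    chk <- verify_disjoint(cond)
    if (!chk$pass)
      stop_fmt("fold %s failed the disjointness check: %s", lang,
               paste(chk$violations, collapse = "; "))
    baseline_cond <- shuffle_targets(cond, seed = config$seeds$shuffle + fi)
    mcfg <- resolve_mapper_config(experiment, ncol(targets), config$mapper,
                                  seed = config$seeds$model)
    if (experiment == "wordclass") {
      model <- train_classifier(cond$train, cond$train_targets, mcfg)
      baseline <- train_classifier(baseline_cond$train,
                                   baseline_cond$train_targets, mcfg)
      pred_m <- class_set[max.col(predict(model, cond$test))]
      pred_b <- class_set[max.col(predict(baseline, cond$test))]
      truth <- cond$test_classes
      metrics_m <- classification_metrics(truth, pred_m, class_set)
      metrics_b <- classification_metrics(truth, pred_b, class_set)
      mc <- mcnemar_chisq(pred_m == truth, pred_b == truth)
      per_class_acc[[lang]] <- metrics_m$per_class_accuracy
      folds[[fi]] <- list(heldout = lang, model = metrics_m,
                          baseline = metrics_b, mcnemar = mc,
                          n_test = length(truth))
    } else {
      model <- train_regressor(cond$train, cond$train_targets, mcfg)
      baseline <- train_regressor(baseline_cond$train,
                                  baseline_cond$train_targets, mcfg)
      pred_m <- predict(model, cond$test)
      pred_b <- predict(baseline, cond$test)
      cos_m <- vapply(seq_len(nrow(pred_m)), function(i)
        cosine_sim(pred_m[i, ], cond$test_targets[i, ]), numeric(1))
      cos_b <- vapply(seq_len(nrow(pred_b)), function(i)
        cosine_sim(pred_b[i, ], cond$test_targets[i, ]), numeric(1))
      folds[[fi]] <- list(heldout = lang,
                          contrast = paired_contrast(cos_m, cos_b),
                          cos_model = cos_m, cos_baseline = cos_b,
                          n_test = length(cos_m))
    }
    if (!is.null(config$out_dir))
      write_fold_manifest(cond, config$out_dir)
  }

  result <- structure(list(experiment = experiment, folds = folds,
                           config = config),
                      class = "run_result")
  if (experiment == "wordclass")
    result$consistency <- cross_language_consistency(per_class_acc)
  result$table <- report(result)
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

#' Tabulate the results of a transfer run
#'
#' Renders one row per held-out language. Regression runs report the mean,
#' SD and 95% CI of the per-item test cosine for the experimental and the
#' baseline model plus the paired contrast (t, p, Cohen's d); classification
#' runs report accuracy, weighted precision and weighted F1 for both models
#' plus the McNemar chi-square and p.
#'
#' @param result a [run_experiment()] result.
#' @return a data.frame, one row per fold.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "run_result"))
  if (!length(result$folds) || any(vapply(result$folds, is.null, logical(1))))
    stop_fmt("incomplete run: missing fold results")
  if (result$experiment == "wordclass") {
    do.call(rbind, lapply(result$folds, function(f) {
      data.frame(language = f$heldout,
                 accuracy = f$model$accuracy,
                 precision = f$model$weighted_precision,
                 f1 = f$model$weighted_f1,
                 baseline_accuracy = f$baseline$accuracy,
                 baseline_precision = f$baseline$weighted_precision,
                 baseline_f1 = f$baseline$weighted_f1,
                 chi2 = f$mcnemar$chi2,
                 p = f$mcnemar$p,
                 n_test = f$n_test,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  } else {
    do.call(rbind, lapply(result$folds, function(f) {
      sm <- f$contrast$summary_a
      sb <- f$contrast$summary_b
      data.frame(language = f$heldout,
                 cosine = sm$mean, sd = sm$sd,
                 ci_low = sm$ci_low, ci_high = sm$ci_high,
                 baseline_cosine = sb$mean, baseline_sd = sb$sd,
                 baseline_ci_low = sb$ci_low, baseline_ci_high = sb$ci_high,
                 t = f$contrast$t, p = f$contrast$p, d = f$contrast$d,
                 n_test = f$n_test,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result: %s experiment, %d folds>\n",
              x$experiment, length(x$folds)))
  print(x$table, digits = 4)
  if (!is.null(x$consistency))
    cat(sprintf("mean pairwise per-class accuracy correlation r = %.4f\n",
                x$consistency$mean_pairwise_r))
  invisible(x)
}

# audit trail: which (concept, language) pair played which role in a fold
write_fold_manifest <- function(cond, out_dir) {
  dir.create(file.path(out_dir, "manifests"), showWarnings = FALSE,
             recursive = TRUE)
  manifest <- rbind(cbind(cond$train_prov, role = "train"),
                    cbind(cond$test_prov, role = "test"))
  utils::write.table(manifest,
                     file.path(out_dir, "manifests",
                               sprintf("fold_%s.tsv", cond$heldout_language)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$table,
                     file.path(out_dir, sprintf("results_%s.tsv",
                                                result$experiment)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$consistency)) {
    pc <- result$consistency$per_class_mean
    utils::write.table(data.frame(class = names(pc), mean_accuracy = pc,
                                  row.names = NULL),
                       file.path(out_dir, "per_class_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- result$config
  snapshot <- list(experiment = cfg$experiment, ratio = cfg$ratio,
                   seeds = cfg$seeds, mapper = cfg$mapper,
                   synthetic = if (!is.null(cfg$synthetic))
                     unclass(cfg$synthetic))
  writeLines(yaml::as.yaml(snapshot), file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' Load a run configuration from YAML or JSON
#'
#' The file may contain `experiment`, `ratio`, `mapper` (overrides),
#' `seeds`, `out_dir`, and either `synthetic` (fields of
#' [synthetic_config()]) or `data_dir`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  syn <- if (!is.null(raw$synthetic)) do.call(synthetic_config, raw$synthetic)
  run_config(experiment = raw$experiment %||% "visual",
             synthetic = syn,
             data_dir = raw$data_dir,
             ratio = raw$ratio,
             mapper = raw$mapper %||% list(),
             seeds = raw$seeds %||% list(),
             out_dir = raw$out_dir)
}
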