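# Orchestration of the two studies: equal-token sampling, layer building,
# embedding training, discrimination scoring against random-pair baselines,
# and hierarchical regression per window, with derived per-stage seeds.

#' Derive a deterministic stage seed
#'
#' Hashes the master seed together with the stage labels (stage name, genre,
#' window, layer, ...) into a 31-bit integer, so no two stages reuse a seed
#' and every stage is reproducible from the master seed alone.
#'
#' @param master master seed (integer).
#' @param ... stage labels (coerced to character).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character, character(1))),
             collapse = "/")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1L)
}

#' Pipeline configuration
#'
#' @param windows window sizes to run (subset of 1..6).
#' @param layers annotation layers for Study 2 (always includes `"raw"`).
#' @param dim,epochs,negatives,min_count embedding hyperparameters (defaults
#'   200 / 100 / 5 / 1).
#' @param n_baseline_pairs random verb pairs per baseline (default 10000).
#' @param frequent_floor verb-frequency floor for baseline candidates
#'   (default 10).
#' @param exclude_targets_from_baseline drop the 32 target verbs from the
#'   baseline candidate pool? Default `FALSE` (they are frequent verbs too).
#' @param chains,iter,warmup MCMC settings for the hierarchical fits.
#' @param equal_tokens sample every corpus down to the smallest corpus's
#'   token count before training (session-wise)? Default `TRUE`.
#' @param seed master seed; all stage seeds derive from it via [stage_seed()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(windows = 1:6,
                            layers = c("raw", "wordclass", "syntax", "lexicon"),
                            dim = 200L, epochs = 100L, negatives = 5L,
                            min_count = 1L, n_baseline_pairs = 10000L,
                            frequent_floor = 10L,
                            exclude_targets_from_baseline = FALSE,
                            chains = 4L, iter = 1000L, warmup = 1000L,
                            equal_tokens = TRUE, seed = 1L) {
  stopifnot(all(windows %in% 1:6), "raw" %in% layers)
  structure(list(windows = as.integer(windows), layers = layers,
                 dim = as.integer(dim), epochs = as.integer(epochs),
                 negatives = as.integer(negatives),
                 min_count = as.integer(min_count),
                 n_baseline_pairs = as.integer(n_baseline_pairs),
                 frequent_floor = as.integer(frequent_floor),
                 exclude_targets_from_baseline = isTRUE(exclude_targets_from_baseline),
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), equal_tokens = isTRUE(equal_tokens),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# equal-token sampling across the supplied corpora (whole sessions)
equalize_corpora <- function(corpora, config) {
  if (!config$equal_tokens || length(corpora) < 2L) return(corpora)
  budget <- min(vapply(corpora, n_tokens, numeric(1)))
  out <- lapply(names(corpora), function(g) {
    sample_to_token_budget(corpora[[g]], budget,
                           seed = stage_seed(config$seed, "sample", g))
  })
  names(out) <- names(corpora)
  out
}

train_layer_model <- function(corpus, layer, window, config, genre) {
  cfg <- layer_config(layer,
                      shuffle_seed = stage_seed(config$seed, "shuffle", genre, layer))
  stream <- assemble_training_stream(corpus, cfg)
  sgns_train(stream, window = window, dim = config$dim, epochs = config$epochs,
             negatives = config$negatives, min_count = config$min_count,
             seed = stage_seed(config$seed, "train", genre, window, layer))
}

baseline_for <- function(model, corpus, config, genre, window, layer = "raw") {
  verbs <- frequent_verbs(corpus, config$frequent_floor)
  if (config$exclude_targets_from_baseline) {
    sets <- verb_sets()
    verbs <- setdiff(verbs, c(sets$causatives, sets$noncausatives))
  }
  estimate_baseline(model, verbs, n_pairs = config$n_baseline_pairs,
                    seed = stage_seed(config$seed, "baseline", genre, window, layer),
                    frequent_floor = config$frequent_floor)
}

#' Run Study 1: genre effects on raw-utterance discrimination
#'
#' Trains raw-layer embeddings per genre and window, computes pairwise
#' causative/non-causative distances, subtracts the reference genre's
#' random-pair baseline for that window (reference = `"cds"` if present,
#' else the first corpus), and fits the hierarchical genre regression per
#' window, comparing it against an intercept-only model by PSIS-LOO /
#' Pseudo-BMA+ weights.
#'
#' @param corpora named list of `sem_corpus`, one per genre; names are the
#'   genre labels used in the regression.
#' @param config a [pipeline_config()].
#' @param sets a [verb_sets()].
#' @return a list with `models`, `tables`, `baselines` (per window), `rows`,
#'   `fits` and `weights` (per window: Pseudo-BMA+ weights plus the PSIS
#'   Pareto-k reliability flag), and a `manifest` of stage seeds.
#' @export
run_study1 <- function(corpora, config = pipeline_config(), sets = verb_sets()) {
  stopifnot(length(corpora) >= 2L, !is.null(names(corpora)))
  genres <- names(corpora)
  reference <- if ("cds" %in% genres) "cds" else genres[[1]]
  corpora <- equalize_corpora(corpora, config)
  models <- list(); tables <- list(); baselines <- list()
  manifest <- list(seed = config$seed, reference = reference, stages = list())
  for (g in genres) {
    for (w in config$windows) {
      key <- paste(g, w, sep = ".")
      models[[key]] <- train_layer_model(corpora[[g]], "raw", w, config, g)
      tables[[key]] <- pairwise_distances(models[[key]], sets, genre = g,
                                          layer = "raw")
      manifest$stages[[key]] <- stage_seed(config$seed, "train", g, w, "raw")
    }
  }
  for (w in config$windows) {
    baselines[[as.character(w)]] <-
      baseline_for(models[[paste(reference, w, sep = ".")]],
                   corpora[[reference]], config, reference, w)
  }
  fits <- list(); weights <- list(); rows_all <- list()
  for (w in config$windows) {
    b <- baselines[[as.character(w)]]
    scored <- lapply(genres, function(g) {
      above_baseline(tables[[paste(g, w, sep = ".")]], b, check_window = w)
    })
    rows <- discrimination_rows(scored)
    rows_all[[as.character(w)]] <- rows
    fit_seed <- stage_seed(config$seed, "fit", "study1", w)
    fits[[as.character(w)]] <-
      fit_hierarchical(rows, "genre", chains = config$chains,
                       iter = config$iter, warmup = config$warmup,
                       seed = fit_seed)
    null_fit <- fit_hierarchical(rows, "genre", intercept_only = TRUE,
                                 chains = config$chains, iter = config$iter,
                                 warmup = config$warmup, seed = fit_seed + 1L)
    cmp <- suppressWarnings(
      compare_models(list(genre = fits[[as.character(w)]],
                          intercept_only = null_fit),
                     seed = stage_seed(config$seed, "bma", "study1", w)))
    cmp$loos <- NULL # keep the bundle light
    weights[[as.character(w)]] <- cmp
  }
  list(models = models, tables = tables, baselines = baselines,
       rows = rows_all, fits = fits, weights = weights, manifest = manifest)
}

#' Run Study 2: annotation-layer effects within each genre
#'
#' Trains one model per genre, window and layer; baselines come from each
#' genre's own raw-layer model for that window (one baseline per genre x
#' window), so the raw layer's scores are centered on zero by construction
#' and layer coefficients measure deltas. Fits the hierarchical layer
#' regression per genre and window.
#'
#' @inheritParams run_study1
#' @return a list with `models`, `tables`, `baselines` (per genre x window),
#'   `rows`, `fits` and `weights` (per genre x window, as in [run_study1()]),
#'   and a `manifest`.
#' @export
run_study2 <- function(corpora, config = pipeline_config(), sets = verb_sets()) {
  stopifnot(length(corpora) >= 1L, !is.null(names(corpora)))
  genres <- names(corpora)
  corpora <- equalize_corpora(corpora, config)
  models <- list(); tables <- list(); baselines <- list()
  fits <- list(); weights <- list(); rows_all <- list()
  manifest <- list(seed = config$seed, stages = list())
  for (g in genres) {
    for (w in config$windows) {
      for (lay in config$layers) {
        key <- paste(g, w, lay, sep = ".")
        models[[key]] <- train_layer_model(corpora[[g]], lay, w, config, g)
        tables[[key]] <- pairwise_distances(models[[key]], sets, genre = g,
                                            layer = lay)
        manifest$stages[[key]] <- stage_seed(config$seed, "train", g, w, lay)
      }
      bkey <- paste(g, w, sep = ".")
      baselines[[bkey]] <- baseline_for(models[[paste(g, w, "raw", sep = ".")]],
                                        corpora[[g]], config, g, w)
      scored <- lapply(config$layers, function(lay) {
        above_baseline(tables[[paste(g, w, lay, sep = ".")]],
                       baselines[[bkey]], check_window = w)
      })
      rows <- discrimination_rows(scored)
      rows_all[[bkey]] <- rows
      fit_seed <- stage_seed(config$seed, "fit", "study2", g, w)
      fits[[bkey]] <- fit_hierarchical(rows, "layer", chains = config$chains,
                                       iter = config$iter,
                                       warmup = config$warmup, seed = fit_seed)
      null_fit <- fit_hierarchical(rows, "layer", intercept_only = TRUE,
                                   chains = config$chains, iter = config$iter,
                                   warmup = config$warmup, seed = fit_seed + 1L)
      cmp <- suppressWarnings(
        compare_models(list(layer = fits[[bkey]],
                            intercept_only = null_fit),
                       seed = stage_seed(config$seed, "bma", "study2", g, w)))
      cmp$loos <- NULL
      weights[[bkey]] <- cmp
    }
  }
  list(models = models, tables = tables, baselines = baselines,
       rows = rows_all, fits = fits, weights = weights, manifest = manifest)
}
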