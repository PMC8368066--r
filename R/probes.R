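# Distributional-feature probes of verbal constructions: nominal proportion,
# Shannon entropy of nominals, Shannon entropy of word-class construction
# frames, each with bootstrap error estimates.

#' Extract verbal constructions
#'
#' One construction per VERB-tagged token: the verb plus up to `window`
#' context tokens on each side, truncated at utterance boundaries.
#' Overlapping constructions (several verbs per utterance) are allowed.
#'
#' @param corpus a UPOS-tagged `sem_corpus`.
#' @param window context size per side (>= 1).
#' @return a list of records, each with `verb` (lemma), `left_upos`,
#'   `right_upos` (context UPOS tags, surface order), `left_lemma`,
#'   `right_lemma` (the corresponding lemmas).
#' @export
extract_constructions <- function(corpus, window = 1L) {
  stopifnot(inherits(corpus, "sem_corpus"), window >= 1L)
  out <- list()
  for (u in utterance_list(corpus)) {
    vi <- which(u$upos == "VERB")
    for (i in vi) {
      lo <- max(1L, i - window)
      hi <- min(nrow(u), i + window)
      li <- if (lo < i) lo:(i - 1L) else integer(0)
      ri <- if (hi > i) (i + 1L):hi else integer(0)
      out[[length(out) + 1L]] <- list(
        verb = u$lemma[[i]],
        left_upos = u$upos[li], right_upos = u$upos[ri],
        left_lemma = u$lemma[li], right_lemma = u$lemma[ri]
      )
    }
  }
  out
}

# UPOS tags counted as nominal; pronouns included (the pronoun-heavy frames
# of child-directed speech are precisely the signal of interest).
nominal_tags <- function() c("NOUN", "PROPN", "PRON")

#' Average proportion of nominals in verbal constructions
#'
#' Mean over constructions of (nominal context tokens / context tokens).
#' Nominal = `NOUN`, `PROPN` or `PRON` by default. Constructions with an
#' empty context (one-word verb utterances) have no defined ratio and are
#' excluded from the average.
#'
#' @param constructions output of [extract_constructions()].
#' @param nominals UPOS tags counted as nominal.
#' @return a proportion in `[0, 1]`.
#' @export
nominal_proportion <- function(constructions, nominals = nominal_tags()) {
  props <- vapply(constructions, function(c) {
    ctx <- c(c$left_upos, c$right_upos)
    if (length(ctx) == 0L) return(NA_real_)
    mean(ctx %in% nominals)
  }, numeric(1))
  props <- props[!is.na(props)]
  if (length(props) == 0L) stop("no construction has a non-empty context")
  mean(props)
}

#' Shannon entropy of a symbol sample
#'
#' `H = -sum p log2 p` over the empirical distribution of the symbols, in
#' bits. Zero for a constant sample; `log2(k)` for a uniform sample over k
#' distinct symbols.
#'
#' @param items non-empty vector of symbols.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(items) {
  if (length(items) == 0L) stop("entropy of an empty sample is undefined")
  p <- as.numeric(table(items)) / length(items)
  -sum(p * log2(p))
}

#' Word-class signature of a construction
#'
#' The frame string of context UPOS tags around the abstracted verb slot,
#' e.g. `"NOUN verb NOUN"`; a bare verb yields `"verb"`.
#'
#' @param construction one element of [extract_constructions()] output.
#' @return a character scalar.
#' @export
construction_signature <- function(construction) {
  paste(c(construction$left_upos, "verb", construction$right_upos),
        collapse = " ")
}

# the nominal context tokens (as lemmas) pooled over constructions — the
# resampling unit for nominal entropy, which measures how varied the nominal
# words around verbs are
nominal_units <- function(constructions, nominals = nominal_tags()) {
  unlist(lapply(constructions, function(c) {
    tags <- c(c$left_upos, c$right_upos)
    lem <- c(c$left_lemma, c$right_lemma)
    lem[tags %in% nominals]
  }), use.names = FALSE)
}

#' Bootstrap a distributional probe
#'
#' Per iteration, resamples `n_units` units with replacement — constructions
#' for `nominal_proportion` and `construction_entropy`, individual nominal
#' context tokens for `nominal_entropy` — computes the statistic, and reports
#' the mean and SD over iterations. Defaults follow the 1000-unit x
#' 1000-iteration scheme.
#'
#' @param corpus a UPOS-tagged `sem_corpus`.
#' @param window context window per side.
#' @param statistic one of `"nominal_proportion"`, `"nominal_entropy"`,
#'   `"construction_entropy"`.
#' @param n_units resample size per iteration (default 1000).
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed; the result is seed-deterministic.
#' @param nominals UPOS tags counted as nominal.
#' @return a list of class `probe_result` with `statistic`, `window`,
#'   `genre`, `point` (bootstrap mean), `sd`, `n_units`, `n_iter`, `seed`.
#' @export
bootstrap_probe <- function(corpus, window, statistic = c("nominal_proportion",
                                                          "nominal_entropy",
                                                          "construction_entropy"),
                            n_units = 1000L, n_iter = 1000L, seed = 1L,
                            nominals = nominal_tags()) {
  statistic <- match.arg(statistic)
  cons <- extract_constructions(corpus, window)
  if (statistic == "nominal_entropy") {
    units <- nominal_units(cons, nominals)
    if (length(units) == 0L) stop("no nominal context tokens to resample")
    stat_fun <- shannon_entropy
  } else if (statistic == "construction_entropy") {
    units <- vapply(cons, construction_signature, character(1))
    if (length(units) == 0L) stop("no verbal constructions to resample")
    stat_fun <- shannon_entropy
  } else {
    units <- cons[vapply(cons, function(c)
      length(c(c$left_upos, c$right_upos)) > 0L, logical(1))]
    if (length(units) == 0L) stop("no verbal constructions with context to resample")
    stat_fun <- function(s) nominal_proportion(s, nominals)
  }
  vals <- with_seed(seed, vapply(seq_len(n_iter), function(b) {
    idx <- sample.int(length(units), n_units, replace = TRUE)
    stat_fun(if (is.list(units)) units[idx] else units[idx])
  }, numeric(1)))
  structure(list(statistic = statistic, window = as.integer(window),
                 genre = corpus$genre, point = mean(vals), sd = stats::sd(vals),
                 n_units = as.integer(n_units), n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result> %s | genre=%s window=%d: %.4f (bootstrap sd %.4f)\n",
              x$statistic, x$genre, x$window, x$point, x$sd))
  invisible(x)
}
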