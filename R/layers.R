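# Training layers: raw utterances, word-class frames, minimal dependency
# subtrees (relation tags or lexical items), and shuffled training streams.

#' Layer configuration
#'
#' Settings for building training instances from annotated utterances. The
#' start/end markers bracket raw and word-class instances only; subtree-based
#' layers (`syntax`, `lexicon`) are fragments of an utterance and carry no
#' boundary markers.
#'
#' @param layer one of `"raw"`, `"wordclass"`, `"syntax"`, `"lexicon"`.
#' @param start_marker,end_marker utterance boundary symbols. Defaults `"^^"`
#'   and `"$$"`; they are reserved and rejected as lemmas at corpus
#'   validation time.
#' @param shuffle_seed integer seed for interleaving layer instances with the
#'   raw utterance in [assemble_training_stream()].
#' @param syntax_include_lemmas if `TRUE`, syntax-layer dependents contribute
#'   their relation label *and* their lemma; the default (`FALSE`) encodes
#'   dependents by relation label alone (verbs always keep their lemma).
#' @return a list of class `layer_config`.
#' @export
layer_config <- function(layer = c("raw", "wordclass", "syntax", "lexicon"),
                         start_marker = "^^", end_marker = "$$",
                         shuffle_seed = 1L, syntax_include_lemmas = FALSE) {
  layer <- match.arg(layer)
  if (!nzchar(start_marker) || !nzchar(end_marker) || start_marker == end_marker) {
    stop("boundary markers must be non-empty and distinct")
  }
  structure(list(layer = layer, start_marker = start_marker,
                 end_marker = end_marker, shuffle_seed = as.integer(shuffle_seed),
                 syntax_include_lemmas = isTRUE(syntax_include_lemmas)),
            class = "layer_config")
}

#' Construct a training instance
#'
#' @param items ordered character vector of symbols (lemmas, UPOS tags,
#'   relation labels, or boundary markers).
#' @param origin one of `"raw"`, `"wordclass"`, `"syntax"`, `"lexicon"`.
#' @return a `training_instance` (a character vector with an `origin`
#'   attribute).
#' @export
training_instance <- function(items, origin) {
  stopifnot(length(items) >= 1L)
  structure(as.character(items), origin = origin, class = "training_instance")
}

#' @export
print.training_instance <- function(x, ...) {
  cat(sprintf("[%s] %s\n", attr(x, "origin"), paste(unclass(x), collapse = " ")))
  invisible(x)
}

# Split a corpus into per-utterance data.tables, corpus order.
utterance_list <- function(corpus) {
  stopifnot(inherits(corpus, "sem_corpus"))
  split(corpus$tokens, by = "utt_id", sorted = TRUE)
}

#' Build the raw-layer instance for one utterance
#'
#' The raw layer is the lemmatized utterance bracketed by the start and end
#' markers, so that even one-word utterances ("Run!") yield co-occurrence
#' pairs that can encode, e.g., imperative/intransitive use.
#'
#' @param utt a per-utterance token table (see [utterance_list()]) or a
#'   character vector of lemmas.
#' @param cfg a [layer_config()].
#' @return a `training_instance` with origin `"raw"`.
#' @export
build_raw_instance <- function(utt, cfg = layer_config("raw")) {
  lemmas <- if (is.character(utt)) utt else utt$lemma
  training_instance(c(cfg$start_marker, lemmas, cfg$end_marker), "raw")
}

#' Build the word-class-layer instance for one utterance
#'
#' Verbs are kept as their lemmas (the categorization target); every other
#' token is abstracted to its UPOS tag. Boundary markers are included, as in
#' the raw layer.
#'
#' @inheritParams build_raw_instance
#' @return a `training_instance` with origin `"wordclass"`.
#' @export
build_wordclass_instance <- function(utt, cfg = layer_config("wordclass")) {
  syms <- ifelse(utt$upos == "VERB", utt$lemma, utt$upos)
  training_instance(c(cfg$start_marker, syms, cfg$end_marker), "wordclass")
}

#' Extract minimal dependency subtrees
#'
#' A minimal subtree is a dependency head together with its direct dependents;
#' one subtree is produced per token that heads at least one dependent, so the
#' number of subtrees equals the number of dependency heads in the utterance.
#'
#' @param utt a per-utterance token table with `tok_id`, `lemma`, `upos`,
#'   `head`, `deprel` columns; must be single-rooted.
#' @return a list of records, each with `head_idx` (token id of the head) and
#'   `member_idx` (token ids of head + direct dependents in surface order).
#' @export
extract_subtrees <- function(utt) {
  n <- nrow(utt)
  if (sum(utt$head == 0L) != 1L) {
    stop("extract_subtrees requires a single-rooted utterance")
  }
  heads <- sort(unique(utt$head[utt$head != 0L]))
  lapply(heads, function(h) {
    deps <- utt$tok_id[utt$head == h]
    list(head_idx = h, member_idx = sort(c(h, deps)))
  })
}

#' Build syntax-layer instances for one utterance
#'
#' One instance per minimal dependency subtree. In surface order, the head
#' contributes its lemma if it is a verb and its UPOS tag otherwise, while
#' each dependent contributes its dependency relation label (plus its lemma if
#' `cfg$syntax_include_lemmas`), except that verb dependents always keep their
#' lemma. No boundary markers are used.
#'
#' @inheritParams build_raw_instance
#' @return a list of `training_instance`s with origin `"syntax"` (possibly
#'   empty, e.g. for one-word utterances).
#' @export
build_syntax_instances <- function(utt, cfg = layer_config("syntax")) {
  subs <- extract_subtrees(utt)
  lapply(subs, function(s) {
    syms <- vapply(s$member_idx, function(i) {
      row <- utt[utt$tok_id == i, ]
      if (i == s$head_idx) {
        if (row$upos == "VERB") row$lemma else row$upos
      } else if (row$upos == "VERB") {
        row$lemma
      } else if (cfg$syntax_include_lemmas) {
        paste(row$deprel, row$lemma, sep = ":")
      } else {
        row$deprel
      }
    }, character(1))
    training_instance(syms, "syntax")
  })
}

#' Build lexicon-layer instances for one utterance
#'
#' Dependency structure rendered in concrete words: one instance per minimal
#' subtree, holding the lemmas of the head and its direct dependents in
#' surface order. No boundary markers.
#'
#' @inheritParams build_raw_instance
#' @return a list of `training_instance`s with origin `"lexicon"`.
#' @export
build_lexicon_instances <- function(utt, cfg = layer_config("lexicon")) {
  subs <- extract_subtrees(utt)
  lapply(subs, function(s) {
    training_instance(utt$lemma[match(s$member_idx, utt$tok_id)], "lexicon")
  })
}

#' Assemble the training stream for a corpus and layer
#'
#' For `layer = "raw"` the stream is one raw instance per utterance in corpus
#' order. For the other layers, each utterance contributes a bundle of its raw
#' instance plus its layer instances; the bundle is shuffled in a seeded
#' random order (so the trainer sees semantics and syntax of each utterance in
#' an unbiased order) and bundles are concatenated in corpus order.
#'
#' @param corpus a `sem_corpus`.
#' @param cfg a [layer_config()]; `cfg$layer` selects the layer and
#'   `cfg$shuffle_seed` fixes the interleaving.
#' @return a list of `training_instance`s.
#' @export
assemble_training_stream <- function(corpus, cfg = layer_config("raw")) {
  utts <- utterance_list(corpus)
  if (cfg$layer == "raw") {
    return(lapply(utts, build_raw_instance, cfg = cfg))
  }
  builder <- switch(cfg$layer,
    wordclass = function(u) list(build_wordclass_instance(u, cfg)),
    syntax = function(u) build_syntax_instances(u, cfg),
    lexicon = function(u) build_lexicon_instances(u, cfg)
  )
  with_seed(cfg$shuffle_seed, {
    out <- lapply(utts, function(u) {
      bundle <- c(list(build_raw_instance(u, cfg)), builder(u))
      bundle[sample.int(length(bundle))]
    })
    unlist(out, recursive = FALSE, use.names = FALSE)
  })
}
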