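# Shared fixture builders. Everything is constructed in code at test time.

# a single utterance as the per-utterance token table used by the layer
# builders
utt_table <- function(lemma, upos, head, deprel, utt_id = 1L,
                      session_id = "s1") {
  data.table::data.table(
    session_id = session_id, utt_id = as.integer(utt_id),
    tok_id = seq_along(lemma), lemma = lemma, upos = upos,
    head = as.integer(head), deprel = deprel
  )
}

# "you open the box": verb-rooted transitive utterance
utt_open_box <- function(utt_id = 1L) {
  utt_table(c("you", "open", "the", "box"),
            c("PRON", "VERB", "DET", "NOUN"),
            c(2L, 0L, 4L, 2L),
            c("nsubj", "root", "det", "dobj"), utt_id = utt_id)
}

# small three-utterance corpus over two sessions
tiny_corpus <- function() {
  toks <- data.table::rbindlist(list(
    utt_table("run", "VERB", 0L, "root", utt_id = 1L, session_id = "a"),
    utt_open_box(utt_id = 2L),
    utt_table(c("you", "go", "now"), c("PRON", "VERB", "ADV"),
              c(2L, 0L, 2L), c("nsubj", "root", "advmod"),
              utt_id = 3L, session_id = "b")
  ))
  toks$session_id[toks$utt_id == 2L] <- "a"
  sem_corpus(toks, genre = "cds")
}

# a corpus of n sessions x m single-utterance sessions with fixed utterance
# length (for the sampling tests)
uniform_session_corpus <- function(n_sessions = 10L, tokens_per_session = 100L) {
  utt_len <- 5L
  n_utt <- tokens_per_session %/% utt_len
  toks <- data.table::rbindlist(lapply(seq_len(n_sessions), function(s) {
    data.table::rbindlist(lapply(seq_len(n_utt), function(u) {
      utt_table(c("you", "open", "it", "again", "now"),
                c("PRON", "VERB", "PRON", "ADV", "ADV"),
                c(2L, 0L, 2L, 2L, 2L),
                c("nsubj", "root", "dobj", "advmod", "advmod"),
                utt_id = (s - 1L) * n_utt + u,
                session_id = sprintf("s%02d", s))
    }))
  }))
  sem_corpus(toks, genre = "cds")
}

# deterministic embedding model with prescribed vectors (bypasses training)
manual_model <- function(vectors, window = 1L) {
  words <- rownames(vectors)
  structure(list(
    vocab = structure(list(
      id_of = stats::setNames(seq_along(words), words),
      count_of = stats::setNames(rep(100L, length(words)), words),
      min_count = 1L
    ), class = "sgns_vocab"),
    vectors = vectors, context_vectors = vectors,
    window = as.integer(window), dim = ncol(vectors), epochs = 1L,
    negatives = 5L, seed = 1L, loss_trace = 0
  ), class = "embedding_model")
}

# full-coverage random model over the 32 target verbs plus filler
full_coverage_model <- function(seed = 1L, dim = 8L, extra = character(0)) {
  sets <- verb_sets()
  words <- c(sets$causatives, sets$noncausatives, extra)
  set.seed(seed)
  V <- matrix(rnorm(length(words) * dim), length(words), dim,
              dimnames = list(words, NULL))
  manual_model(V)
}

# synthetic regression rows with known generating values, mirroring the
# crossed verbs x genre design (207 rows per genre level)
make_genre_rows <- function(seed, genres = c("cds", "ads", "wri"),
                            beta = c(0.05, -0.08, -0.06), sd_verb = 0.02,
                            sd_resid = 0.05) {
  sets <- verb_sets()
  set.seed(seed)
  grid <- expand.grid(caus = sets$causatives, noncaus = sets$noncausatives,
                      genre = genres, stringsAsFactors = FALSE)
  L <- length(genres)
  uc <- matrix(stats::rnorm(23 * L, 0, sd_verb), 23, L,
               dimnames = list(sets$causatives, NULL))
  un <- matrix(stats::rnorm(9 * L, 0, sd_verb), 9, L,
               dimnames = list(sets$noncausatives, NULL))
  X <- stats::model.matrix(~factor(grid$genre, levels = genres))
  mu <- as.numeric(X %*% beta[seq_len(L)]) +
    rowSums(X * uc[grid$caus, , drop = FALSE]) +
    rowSums(X * un[grid$noncaus, , drop = FALSE])
  grid$response <- mu + stats::rnorm(nrow(grid), 0, sd_resid)
  # the generating value of the reported (finite-population) fixed effects:
  # population beta plus the realized verb-effect means
  attr(grid, "truth_sweep") <- beta[seq_len(L)] + colMeans(uc) + colMeans(un)
  grid
}

# write a canonical CoNLL-U fixture file and return its path
conllu_fixture_path <- function() {
  path <- tempfile(fileext = ".conllu")
  write_conllu(tiny_corpus(), path)
  path
}
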