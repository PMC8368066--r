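# Session-organized annotated corpora: construction, CoNLL-U I/O,
# equal-token session sampling, summary statistics.

#' Construct an annotated corpus
#'
#' A corpus is a flat token table organized into sessions and utterances.
#' Each token carries a lowercased lemma, a universal word-class (UPOS) tag,
#' and a dependency arc (1-based head index within the utterance, 0 for the
#' root, plus a relation label). Every utterance must have exactly one root.
#'
#' @param tokens a data.frame/data.table with columns `session_id` (character),
#'   `utt_id` (integer, unique per utterance across the corpus), `tok_id`
#'   (integer, 1..n within each utterance), `lemma`, `upos`, `head` (integer),
#'   `deprel`.
#' @param genre one of `"cds"`, `"adult_conversation"`, `"written"`, or any
#'   other label tagging the corpus provenance.
#' @param validate check utterance-level invariants (single root, head indices
#'   in range)? Defaults to `TRUE`.
#' @return an object of class `sem_corpus`.
#' @export
sem_corpus <- function(tokens, genre = "cds", validate = TRUE) {
  tok <- data.table::as.data.table(tokens)
  needed <- c("session_id", "utt_id", "tok_id", "lemma", "upos", "head", "deprel")
  missing_cols <- setdiff(needed, names(tok))
  if (length(missing_cols) > 0L) {
    stop("corpus token table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tok <- tok[, needed, with = FALSE]
  tok[, `:=`(
    session_id = as.character(session_id),
    utt_id = as.integer(utt_id),
    tok_id = as.integer(tok_id),
    lemma = as.character(lemma),
    upos = as.character(upos),
    head = as.integer(head),
    deprel = as.character(deprel)
  )]
  obj <- structure(list(genre = genre, tokens = tok), class = "sem_corpus")
  if (validate) validate_corpus(obj)
  obj
}

#' Validate corpus invariants
#'
#' Checks that every utterance is non-empty, has exactly one root (head = 0),
#' head indices stay within the utterance and never point to the token itself,
#' lemmas are non-empty, and no lemma collides with the reserved utterance
#' boundary markers `"^^"` / `"$$"`.
#'
#' @param corpus a `sem_corpus`.
#' @return the corpus, invisibly; errors describe the offending utterance.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "sem_corpus"))
  tok <- corpus$tokens
  if (nrow(tok) == 0L) return(invisible(corpus))
  if (any(!nzchar(tok$lemma))) stop("corpus contains empty lemmas")
  bad_marker <- intersect(unique(tok$lemma), c("^^", "$$"))
  if (length(bad_marker) > 0L) {
    stop("reserved boundary marker used as lemma: ", paste(bad_marker, collapse = ", "))
  }
  utt_id <- tok_id <- head <- NULL # data.table NSE
  chk <- tok[, .(
    n = .N,
    n_root = sum(head == 0L),
    bad_head = any(head < 0L | head > .N | head == tok_id)
  ), by = utt_id]
  multi <- chk[chk$n_root != 1L, ]
  if (nrow(multi) > 0L) {
    stop("utterance(s) without exactly one root: ",
         paste(utils::head(multi$utt_id, 5L), collapse = ", "))
  }
  oob <- chk[chk$bad_head == TRUE, ]
  if (nrow(oob) > 0L) {
    stop("utterance(s) with out-of-range or self-referential head: ",
         paste(utils::head(oob$utt_id, 5L), collapse = ", "))
  }
  invisible(corpus)
}

#' @export
print.sem_corpus <- function(x, ...) {
  st <- if (nrow(x$tokens) > 0L) corpus_stats(x) else
    list(n_sessions = 0L, n_utterances = 0L, n_tokens = 0L)
  cat(sprintf("<sem_corpus> genre=%s | %d session(s), %d utterance(s), %d token(s)\n",
              x$genre, st$n_sessions, st$n_utterances, st$n_tokens))
  invisible(x)
}

#' Number of tokens in a corpus
#' @param corpus a `sem_corpus`.
#' @return integer token count.
#' @export
n_tokens <- function(corpus) nrow(corpus$tokens)

#' Read a session-organized corpus from CoNLL-U
#'
#' Sessions are delimited by `# newdoc id = <session>` comment lines; tokens
#' before any such marker fall into an implicit session `"1"`. Multiword-token
#' ranges (`1-2`) and empty nodes (`1.1`) are skipped. The LEMMA, UPOS, HEAD
#' and DEPREL columns are retained; all others are ignored.
#'
#' @param path path to a CoNLL-U file (UTF-8, LF).
#' @param genre genre label to attach to the corpus.
#' @return a `sem_corpus`.
#' @export
read_conllu <- function(path, genre = "cds") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  session <- character(0); utt <- integer(0); tokid <- integer(0)
  lemma <- character(0); upos <- character(0); headv <- integer(0); depr <- character(0)
  cur_session <- "1"
  cur_utt <- 0L
  in_sentence <- FALSE
  buf <- list()
  flush_sentence <- function() {
    if (length(buf) == 0L) return(invisible(NULL))
    cur_utt <<- cur_utt + 1L
    m <- do.call(rbind, buf)
    session <<- c(session, rep(cur_session, nrow(m)))
    utt <<- c(utt, rep(cur_utt, nrow(m)))
    tokid <<- c(tokid, as.integer(m[, 1L]))
    lemma <<- c(lemma, m[, 2L])
    upos <<- c(upos, m[, 3L])
    headv <<- c(headv, as.integer(m[, 4L]))
    depr <<- c(depr, m[, 5L])
    buf <<- list()
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) { flush_sentence(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*newdoc id\\s*=\\s*(.+?)\\s*$", ln))[[1]]
      if (length(m) == 2L) { flush_sentence(); cur_session <- m[[2]] }
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      stop(sprintf("malformed CoNLL-U line %d: expected 10 tab-separated fields, got %d",
                   i, length(fields)))
    }
    id <- fields[[1]]
    if (grepl("-", id, fixed = TRUE) || grepl(".", id, fixed = TRUE)) next
    if (!grepl("^[0-9]+$", id)) stop(sprintf("malformed CoNLL-U line %d: bad token id '%s'", i, id))
    hd <- fields[[7]]
    if (!grepl("^[0-9]+$", hd)) stop(sprintf("malformed CoNLL-U line %d: bad HEAD '%s'", i, hd))
    buf[[length(buf) + 1L]] <- c(id, fields[[3]], fields[[4]], hd, fields[[8]])
  }
  flush_sentence()
  tok <- data.table::data.table(
    session_id = session, utt_id = utt, tok_id = tokid,
    lemma = lemma, upos = upos, head = headv, deprel = depr
  )
  sem_corpus(tok, genre = genre)
}

#' Write a corpus to CoNLL-U
#'
#' The FORM column is filled with the lemma (the corpus stores lemmas only);
#' XPOS, FEATS, DEPS and MISC are written as `_`. Session ids are serialized
#' as `# newdoc id = <session>` comments.
#'
#' @param corpus a `sem_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(corpus, path) {
  stopifnot(inherits(corpus, "sem_corpus"))
  tok <- corpus$tokens
  out <- character(0)
  if (nrow(tok) > 0L) {
    utts <- split(tok, by = "utt_id", sorted = TRUE)
    prev_session <- NA_character_
    pieces <- vector("list", length(utts))
    for (k in seq_along(utts)) {
      u <- utts[[k]]
      head_line <- character(0)
      if (is.na(prev_session) || u$session_id[[1]] != prev_session) {
        head_line <- sprintf("# newdoc id = %s", u$session_id[[1]])
        prev_session <- u$session_id[[1]]
      }
      body <- sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
                      u$tok_id, u$lemma, u$lemma, u$upos, u$head, u$deprel)
      pieces[[k]] <- c(head_line, body, "")
    }
    out <- unlist(pieces)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Sample whole sessions to an approximate token budget
#'
#' Sessions are drawn whole, uniformly at random without replacement, until
#' adding the next drawn session would exceed the budget. That overshooting
#' session is still included if and only if the total with it is closer to the
#' budget than the total without it. If the whole corpus fits within the
#' budget it is returned in full.
#'
#' @param corpus a `sem_corpus`.
#' @param budget target token count (> 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `sem_corpus` containing the sampled sessions (original session
#'   order preserved).
#' @export
sample_to_token_budget <- function(corpus, budget, seed = 1L) {
  stopifnot(inherits(corpus, "sem_corpus"), budget > 0)
  tok <- corpus$tokens
  sessions <- unique(tok$session_id)
  if (length(sessions) == 0L) stop("cannot sample from a corpus with zero sessions")
  session_id <- NULL
  sizes <- tok[, .N, by = session_id]
  if (sum(sizes$N) <= budget) return(corpus)
  perm <- with_seed(seed, sample(sessions))
  size_of <- stats::setNames(sizes$N, sizes$session_id)
  tot <- 0L
  chosen <- character(0)
  for (s in perm) {
    nxt <- tot + size_of[[s]]
    if (nxt > budget) {
      if (abs(nxt - budget) < abs(tot - budget)) chosen <- c(chosen, s)
      break
    }
    chosen <- c(chosen, s)
    tot <- nxt
    if (tot == budget) break
  }
  sem_corpus(tok[tok$session_id %in% chosen, ], genre = corpus$genre, validate = FALSE)
}

#' Corpus summary statistics
#'
#' @param corpus a non-empty `sem_corpus`.
#' @return a list with `n_tokens`, `n_utterances`, `n_sessions`, `mlu` (mean
#'   length of utterances in tokens), `p_one_word` (proportion of one-word
#'   utterances), and `n_types` (distinct lemmas).
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "sem_corpus"))
  tok <- corpus$tokens
  if (nrow(tok) == 0L) stop("corpus_stats requires a non-empty corpus")
  utt_id <- NULL
  lens <- tok[, .N, by = utt_id]$N
  list(
    n_tokens = nrow(tok),
    n_utterances = length(lens),
    n_sessions = length(unique(tok$session_id)),
    mlu = mean(lens),
    p_one_word = mean(lens == 1L),
    n_types = length(unique(tok$lemma))
  )
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
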