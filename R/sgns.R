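# Skip-gram negative-sampling embeddings: vocabulary, context pairs,
# training, lookup, and word2vec text serialization.

#' Build a vocabulary from a training stream
#'
#' Counts every symbol in the stream (boundary markers and tag symbols are
#' ordinary types) and keeps those occurring at least `min_count` times.
#' Types are assigned contiguous integer ids from 1, ordered by decreasing
#' frequency with alphabetical tie-break, so ids are deterministic.
#'
#' @param stream list of [training_instance()]s (or plain character vectors).
#' @param min_count frequency floor; rarer types are dropped from training
#'   pairs. Default 1 (the downstream "frequent verb" floor of 10 is applied
#'   when baselines are built, not here).
#' @return a list of class `sgns_vocab` with `id_of` and `count_of` (named
#'   integer vectors) and `min_count`.
#' @export
build_vocab <- function(stream, min_count = 1L) {
  if (length(stream) == 0L) stop("cannot build a vocabulary from an empty stream")
  counts <- table(unlist(lapply(stream, unclass), use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) stop("no type reaches min_count = ", min_count)
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  counts <- counts[ord]
  structure(list(
    id_of = stats::setNames(seq_along(counts), names(counts)),
    count_of = stats::setNames(as.integer(counts), names(counts)),
    min_count = as.integer(min_count)
  ), class = "sgns_vocab")
}

#' Enumerate (center, context) pairs for one instance
#'
#' For each position i, every position j with `0 < |i - j| <= window` inside
#' the same instance contributes the pair (item i, item j). No positional
#' information is kept (contexts are order-dissolved) and the window never
#' crosses an instance boundary; with window 1 a center sees exactly the one
#' word on each side.
#'
#' @param instance a [training_instance()] or character vector.
#' @param window symmetric window size (>= 1).
#' @return a data.frame with character columns `center` and `context`; zero
#'   rows for a single-item instance.
#' @export
generate_pairs <- function(instance, window) {
  stopifnot(window >= 1L)
  items <- as.character(unclass(instance))
  L <- length(items)
  if (L < 2L) return(data.frame(center = character(0), context = character(0)))
  centers <- character(0); contexts <- character(0)
  for (i in seq_len(L)) {
    js <- max(1L, i - window):min(L, i + window)
    js <- js[js != i]
    centers <- c(centers, rep(items[[i]], length(js)))
    contexts <- c(contexts, items[js])
  }
  data.frame(center = centers, context = contexts)
}

#' Train skip-gram negative-sampling embeddings
#'
#' Stochastic gradient descent on the SGNS objective: for each (center,
#' context) pair within the window, maximize
#' `log sigmoid(u_c . v_w) + sum_k log sigmoid(-u_nk . v_w)` with `negatives`
#' noise words drawn from the unigram^0.75 distribution. Contexts are
#' order-dissolved and bounded by instance boundaries. The reference path is
#' single-threaded and bit-deterministic given `seed`.
#'
#' @param stream list of [training_instance()]s.
#' @param window symmetric context window, 1..6.
#' @param dim embedding dimension (default 200).
#' @param epochs passes over the stream (default 100).
#' @param negatives negative samples per pair (default 5).
#' @param seed integer seed for initialization and noise draws.
#' @param min_count vocabulary frequency floor (default 1).
#' @param alpha,alpha_min initial/final learning rate of the linear decay
#'   schedule (defaults 0.025 and 1e-4).
#' @return an object of class `embedding_model`: `vocab`, `vectors` (types x
#'   dim input embeddings, rownames = types), `context_vectors`, the
#'   hyperparameters, and `loss_trace` (mean per-pair loss per epoch).
#' @export
sgns_train <- function(stream, window, dim = 200L, epochs = 100L,
                       negatives = 5L, seed = 1L, min_count = 1L,
                       alpha = 0.025, alpha_min = 1e-4) {
  stopifnot(window >= 1L, window <= 6L, dim >= 2L, epochs >= 1L, negatives >= 0L)
  vocab <- build_vocab(stream, min_count = min_count)
  ids <- lapply(stream, function(inst) {
    x <- vocab$id_of[as.character(unclass(inst))]
    as.integer(x[!is.na(x)]) - 1L # drop OOV, 0-based for C++
  })
  ids <- ids[lengths(ids) > 0L]
  if (length(ids) == 0L) stop("no in-vocabulary tokens to train on")
  offsets <- c(0L, cumsum(lengths(ids)))
  noise <- as.numeric(vocab$count_of)^0.75
  fit <- .sgns_train_cpp(unlist(ids, use.names = FALSE), offsets,
                         length(vocab$id_of), cumsum(noise) / sum(noise),
                         as.integer(window), as.integer(dim),
                         as.integer(epochs), as.integer(negatives),
                         alpha, alpha_min, as.numeric(seed))
  rownames(fit$vectors) <- names(vocab$id_of)
  rownames(fit$context_vectors) <- names(vocab$id_of)
  structure(list(
    vocab = vocab, vectors = fit$vectors,
    context_vectors = fit$context_vectors,
    window = as.integer(window), dim = as.integer(dim),
    epochs = as.integer(epochs), negatives = as.integer(negatives),
    seed = as.integer(seed), loss_trace = as.numeric(fit$loss_trace)
  ), class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d types, dim %d, window %d, %d epoch(s); final loss %.4f\n",
              nrow(x$vectors), x$dim, x$window, x$epochs,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Look up a word's embedding
#'
#' @param model an `embedding_model`.
#' @param word a type string.
#' @return the input-side embedding (numeric vector of length `model$dim`).
#'   Out-of-vocabulary words raise an error, never a silent zero vector.
#' @export
word_vector <- function(model, word) {
  stopifnot(inherits(model, "embedding_model"), length(word) == 1L)
  if (!word %in% rownames(model$vectors)) {
    stop("word not in vocabulary: '", word, "'")
  }
  model$vectors[word, ]
}

#' SGNS loss and analytic gradients for a single training pair
#'
#' The per-pair objective is
#' `loss = -log sigmoid(u_c . v) - sum_k log sigmoid(-u_nk . v)`, where `v` is
#' the center word's input vector, `u_c` the context word's output vector and
#' `u_nk` the negative samples' output vectors. Used by the trainer (in C++)
#' and exposed here for gradient verification.
#'
#' @param v center (input) vector.
#' @param u_ctx context (output) vector.
#' @param u_neg matrix of negative-sample output vectors, one per row (may
#'   have zero rows).
#' @return list with `loss`, `grad_center` (d loss / d v), `grad_context`
#'   (d loss / d u_ctx), `grad_neg` (matrix, rows d loss / d u_nk).
#' @export
sgns_loss_grad <- function(v, u_ctx, u_neg = matrix(0, 0, length(v))) {
  u_neg <- matrix(u_neg, ncol = length(v))
  s_pos <- stats::plogis(sum(u_ctx * v))
  loss <- -log(s_pos)
  grad_center <- -(1 - s_pos) * u_ctx
  grad_context <- -(1 - s_pos) * v
  grad_neg <- matrix(0, nrow(u_neg), length(v))
  if (nrow(u_neg) > 0L) {
    s_neg <- stats::plogis(as.numeric(u_neg %*% v))
    loss <- loss - sum(log(1 - s_neg))
    grad_center <- grad_center + as.numeric(t(u_neg) %*% s_neg)
    grad_neg <- s_neg * matrix(v, nrow(u_neg), length(v), byrow = TRUE)
  }
  list(loss = loss, grad_center = grad_center,
       grad_context = grad_context, grad_neg = grad_neg)
}

#' Write embeddings in word2vec text format
#'
#' Header line `"<types> <dim>"`, then one `"word v1 ... vD"` line per type.
#'
#' @param model an `embedding_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  V <- nrow(model$vectors)
  writeLines(sprintf("%d %d", V, ncol(model$vectors)), con, useBytes = TRUE)
  rows <- vapply(seq_len(V), function(i) {
    paste(rownames(model$vectors)[i],
          paste(sprintf("%.17g", model$vectors[i, ]), collapse = " "))
  }, character(1))
  writeLines(rows, con, useBytes = TRUE)
  invisible(path)
}

#' Read embeddings from word2vec text format
#'
#' @param path path to a word2vec text file.
#' @return a minimal `embedding_model` (vectors and a frequency-less vocab);
#'   training metadata is not stored in the format.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[[1]], " ", fixed = TRUE)[[1]])
  V <- hdr[[1]]; d <- hdr[[2]]
  parts <- strsplit(lines[1L + seq_len(V)], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(vec) <- words
  structure(list(
    vocab = structure(list(id_of = stats::setNames(seq_len(V), words),
                           count_of = stats::setNames(rep(NA_integer_, V), words),
                           min_count = NA_integer_), class = "sgns_vocab"),
    vectors = vec, context_vectors = NULL,
    window = NA_integer_, dim = d, epochs = NA_integer_,
    negatives = NA_integer_, seed = NA_integer_, loss_trace = numeric(0)
  ), class = "embedding_model")
}
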