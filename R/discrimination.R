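# Causative-discrimination statistics: pairwise cosine distances between
# causative and non-causative verb embeddings, random-pair baselines,
# above-baseline scores, and neighbor-joining clustering of distances.

#' The causative / non-causative verb test sets
#'
#' 23 prototypical causatives (verbs entailing an agent bringing about a
#' change of state in a patient) and 9 non-causatives, chosen so that both
#' sets mix transitive and intransitive uses and transitivity alone cannot
#' drive the discrimination.
#'
#' @param causatives,noncausatives optional replacement lemma lists.
#' @return a list of class `verb_sets` with disjoint `causatives` and
#'   `noncausatives`.
#' @export
verb_sets <- function(causatives = NULL, noncausatives = NULL) {
  if (is.null(causatives)) {
    causatives <- c("begin", "boil", "break", "burn", "change", "close",
                    "destroy", "dry", "fill", "finish", "freeze", "gather",
                    "kill", "lose", "melt", "open", "raise", "roll", "sink",
                    "spread", "stop", "teach", "turn")
  }
  if (is.null(noncausatives)) {
    noncausatives <- c("die", "go", "look", "talk", "want", "like", "think",
                       "say", "take")
  }
  if (length(intersect(causatives, noncausatives)) > 0L) {
    stop("causative and non-causative sets must be disjoint")
  }
  structure(list(causatives = causatives, noncausatives = noncausatives),
            class = "verb_sets")
}

#' Cosine distance between two vectors
#'
#' `1 - cos(theta) = 1 - (u . v) / (|u| |v|)`, ranging from 0 (identical
#' direction) through 1 (orthogonal) to 2 (antiparallel).
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @return the cosine distance in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2) # clamp floating-point spill outside [0, 2]
}

#' Pairwise causative x non-causative distance table
#'
#' One row per (causative, non-causative) pair with both verbs in the model's
#' vocabulary; with full coverage of the default sets that is 23 x 9 = 207
#' rows. Missing verbs are dropped with a warning listing them (mirroring
#' realistic corpus coverage); a model covering no pair is an error.
#'
#' @param model an `embedding_model`.
#' @param sets a [verb_sets()].
#' @param genre,layer optional labels stored on the table for bookkeeping.
#' @return a data.frame `(causative, noncausative, distance, window, genre,
#'   layer)` with attribute `missing_verbs`.
#' @export
pairwise_distances <- function(model, sets = verb_sets(),
                               genre = NA_character_, layer = NA_character_) {
  vocab <- rownames(model$vectors)
  caus <- intersect(sets$causatives, vocab)
  nonc <- intersect(sets$noncausatives, vocab)
  missing <- setdiff(c(sets$causatives, sets$noncausatives), vocab)
  if (length(missing) > 0L) {
    warning("verbs missing from model vocabulary: ", paste(missing, collapse = ", "))
  }
  if (length(caus) == 0L || length(nonc) == 0L) {
    stop("no causative x non-causative pair is covered by the vocabulary")
  }
  grid <- expand.grid(causative = caus, noncausative = nonc,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$distance <- mapply(function(ci, nj) {
    cosine_distance(model$vectors[ci, ], model$vectors[nj, ])
  }, grid$causative, grid$noncausative, USE.NAMES = FALSE)
  grid$window <- model$window
  grid$genre <- genre
  grid$layer <- layer
  attr(grid, "missing_verbs") <- missing
  grid
}

#' Frequent verbs of a corpus
#'
#' Lemmas whose VERB-tagged occurrence count reaches the floor (counting verb
#' uses only: "open" used as a noun does not count).
#'
#' @param corpus a `sem_corpus` with UPOS tags.
#' @param floor minimum VERB-tagged occurrences (default 10).
#' @return character vector of lemmas.
#' @export
frequent_verbs <- function(corpus, floor = 10L) {
  stopifnot(inherits(corpus, "sem_corpus"))
  tok <- corpus$tokens
  lemma <- upos <- NULL
  counts <- tok[upos == "VERB", .N, by = lemma]
  sort(counts$lemma[counts$N >= floor])
}

#' Random-pair baseline distance
#'
#' Mean cosine distance over `n_pairs` random pairs of distinct verbs,
#' sampled uniformly (unordered, with replacement across pairs). This is the
#' chance level against which causative/non-causative distances are judged.
#'
#' @param model an `embedding_model`.
#' @param verbs candidate verbs (e.g. [frequent_verbs()] output); verbs not
#'   in the vocabulary are dropped.
#' @param n_pairs number of random pairs (default 10000).
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @param frequent_floor bookkeeping: the floor used to build `verbs`.
#' @return a list of class `baseline_estimate` with `mean_distance`, `sd`
#'   (across sampled pairs), `n_pairs`, `n_verbs`, `frequent_floor`, `seed`.
#' @export
estimate_baseline <- function(model, verbs, n_pairs = 10000L, seed = 1L,
                              frequent_floor = 10L) {
  verbs <- intersect(verbs, rownames(model$vectors))
  n <- length(verbs)
  if (n < 2L) stop("baseline needs at least 2 in-vocabulary verbs")
  V <- model$vectors[verbs, , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  draws <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j) # uniform over distinct partners
    cbind(i, j)
  })
  d <- 1 - rowSums(V[draws[, 1L], , drop = FALSE] * V[draws[, 2L], , drop = FALSE])
  d <- pmin(pmax(d, 0), 2)
  structure(list(mean_distance = mean(d), sd = stats::sd(d),
                 n_pairs = as.integer(n_pairs), n_verbs = n,
                 frequent_floor = as.integer(frequent_floor),
                 seed = as.integer(seed)),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> mean %.4f (sd %.4f) over %d pairs of %d verbs\n",
              x$mean_distance, x$sd, x$n_pairs, x$n_verbs))
  invisible(x)
}

#' Above-baseline discrimination scores
#'
#' Subtracts the random-pair baseline from every pairwise distance; positive
#' scores mean the causative/non-causative contrast is larger than expected
#' by chance.
#'
#' @param table a [pairwise_distances()] table.
#' @param baseline a [estimate_baseline()] result.
#' @param check_window if non-NULL, error unless the table's window equals it
#'   (study designs pair each table with the baseline of a matching window).
#' @return the table with an added `score` column (`distance - baseline`).
#' @export
above_baseline <- function(table, baseline, check_window = NULL) {
  stopifnot(inherits(baseline, "baseline_estimate"))
  if (!is.null(check_window) && any(table$window != check_window)) {
    stop("distance table window (", unique(table$window),
         ") does not match the baseline's window (", check_window, ")")
  }
  table$score <- table$distance - baseline$mean_distance
  table
}

#' Pairwise cosine-distance matrix over words
#'
#' @param model an `embedding_model`.
#' @param words words to include; all must be in the vocabulary.
#' @return a symmetric matrix of cosine distances with zero diagonal.
#' @export
embedding_distance_matrix <- function(model, words) {
  missing <- setdiff(words, rownames(model$vectors))
  if (length(missing) > 0L) stop("not in vocabulary: ", paste(missing, collapse = ", "))
  V <- model$vectors[words, , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  D <- 1 - tcrossprod(V)
  D <- pmin(pmax(D, 0), 2)
  diag(D) <- 0
  dimnames(D) <- list(words, words)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` (with `r` the row sums), assign
#' branch lengths `l_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`, and reduce the
#' matrix with `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties on Q are
#' broken by the lowest (row, column) index pair, so the output is
#' deterministic. Negative branch lengths are retained (not clamped) and
#' flagged with a warning.
#'
#' @param dist a square symmetric matrix with zero diagonal and (typically)
#'   non-negative entries; rownames label the taxa.
#' @param names optional taxa labels overriding the dimnames.
#' @return an unrooted tree of class `phylo` (see \pkg{ape}), with a
#'   `newick` attribute carrying the serialized form.
#' @export
neighbor_joining <- function(dist, names = NULL) {
  D <- as.matrix(dist)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8)) {
    stop("neighbor joining requires a square symmetric matrix")
  }
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- if (!is.null(names)) names else rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.10g", x)
  nodes <- labels # current newick fragment per active cluster
  saw_negative <- FALSE
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest-index pair among the minima (row-major, i < j)
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) saw_negative <- TRUE
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    nodes <- c(nodes[keep], merged)
    D <- D2
    n <- n - 1L
  }
  # final 3-star: branch lengths from the three-point equations
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (min(l1, l2, l3) < 0) saw_negative <- TRUE
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nodes[1], fmt(l1), nodes[2], fmt(l2), nodes[3], fmt(l3))
  if (saw_negative) warning("neighbor joining produced negative branch length(s); retained")
  tree <- ape::read.tree(text = newick)
  attr(tree, "newick") <- newick
  tree
}
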