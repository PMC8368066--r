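test_that("vocabulary building counts types and applies the floor", {
  stream <- list(training_instance(rep("a", 5), "raw"),
                 training_instance(c("a", "b"), "raw"))
  v1 <- build_vocab(stream, min_count = 2)
  expect_equal(names(v1$id_of), "a")
  expect_equal(unname(v1$count_of[["a"]]), 6L)
  v2 <- build_vocab(stream, min_count = 1)
  expect_setequal(names(v2$id_of), c("a", "b"))
  expect_error(build_vocab(list()), "empty")
  # counts equal an independent recount on a generated stream
  gen <- generate_corpus(preset("cds_like"), 2, 50, seed = 6)$corpus
  stream <- assemble_training_stream(gen, layer_config("raw"))
  v <- build_vocab(stream)
  flat <- unlist(lapply(stream, unclass))
  recount <- table(flat)
  expect_equal(unname(v$count_of[names(recount)]),
               unname(as.integer(recount)))
})

test_that("context pairs are symmetric-window, order-dissolved, in-instance", {
  # window 1 spans exactly three tokens: the target plus one on each side
  p <- generate_pairs(c("^^", "run", "$$"), window = 1)
  expect_equal(nrow(p), 4L)
  expect_setequal(paste(p$center, p$context),
                  c("^^ run", "run ^^", "run $$", "$$ run"))
  expect_equal(nrow(generate_pairs("lonely", window = 3)), 0L)
  # full window: L(L-1) ordered pairs
  inst <- letters[1:5]
  expect_equal(nrow(generate_pairs(inst, window = 4)), 5L * 4L)
  expect_equal(nrow(generate_pairs(inst, window = 10)), 5L * 4L)
  # brute-force double-loop oracle on random fixtures
  brute <- function(items, w) {
    out <- NULL
    for (i in seq_along(items)) for (j in seq_along(items)) {
      if (i != j && abs(i - j) <= w) out <- rbind(out, c(items[i], items[j]))
    }
    out
  }
  set.seed(42)
  for (rep in 1:1000) {
    L <- sample(1:8, 1)
    w <- sample(1:6, 1)
    items <- sample(letters[1:6], L, replace = TRUE)
    got <- generate_pairs(items, w)
    want <- brute(items, w)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(sort(paste(got$center, got$context)),
                   sort(paste(want[, 1], want[, 2])))
    }
  }
})

test_that("analytic SGNS gradients match central differences", {
  set.seed(7)
  d <- 6L
  for (rep in 1:5) {
    v <- rnorm(d); u <- rnorm(d); negs <- matrix(rnorm(3 * d), 3, d)
    g <- sgns_loss_grad(v, u, negs)
    eps <- 1e-6
    num_grad <- function(f, x) {
      vapply(seq_along(x), function(i) {
        xp <- x; xm <- x
        xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
        (f(xp) - f(xm)) / (2 * eps)
      }, numeric(1))
    }
    gc_num <- num_grad(function(x) sgns_loss_grad(x, u, negs)$loss, v)
    gu_num <- num_grad(function(x) sgns_loss_grad(v, x, negs)$loss, u)
    expect_lt(max(abs(g$grad_center - gc_num)) / max(abs(gc_num)), 1e-5)
    expect_lt(max(abs(g$grad_context - gu_num)) / max(abs(gu_num)), 1e-5)
    for (k in 1:3) {
      gn_num <- num_grad(function(x) {
        nm <- negs; nm[k, ] <- x
        sgns_loss_grad(v, u, nm)$loss
      }, negs[k, ])
      expect_lt(max(abs(g$grad_neg[k, ] - gn_num)) /
                  max(abs(gn_num), 1e-8), 1e-4)
    }
  }
})

test_that("training is seed-deterministic and loss decreases", {
  gen <- generate_corpus(preset("cds_like"), 2, 80, seed = 8)$corpus
  stream <- assemble_training_stream(gen, layer_config("raw"))
  m1 <- sgns_train(stream, window = 1, dim = 12, epochs = 8, seed = 99)
  m2 <- sgns_train(stream, window = 1, dim = 12, epochs = 8, seed = 99)
  expect_identical(m1$vectors, m2$vectors)
  expect_length(m1$loss_trace, 8L)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_lt(m1$loss_trace[8], m1$loss_trace[1])
  m3 <- sgns_train(stream, window = 1, dim = 12, epochs = 8, seed = 100)
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("co-occurrence structure separates word pairs after training", {
  # "a" only ever co-occurs with "b", "c" only with "d"
  stream <- c(
    replicate(60, training_instance(c("a", "b"), "raw"), simplify = FALSE),
    replicate(60, training_instance(c("c", "d"), "raw"), simplify = FALSE)
  )
  m <- sgns_train(stream, window = 1, dim = 8, epochs = 40, seed = 5)
  # the objective aligns a word's center vector with its co-occurring
  # partner's context vector, and pushes it away from noise words
  d_ab <- cosine_distance(word_vector(m, "a"), m$context_vectors["b", ])
  d_ac <- cosine_distance(word_vector(m, "a"), m$context_vectors["c", ])
  expect_lt(d_ab, d_ac)
})

test_that("vector lookup returns rows and refuses OOV silently", {
  m <- full_coverage_model()
  expect_length(word_vector(m, "open"), m$dim)
  expect_identical(word_vector(m, "open"), word_vector(m, "open"))
  expect_error(word_vector(m, "zzz_not_a_word"), "vocabulary")
})

test_that("word2vec text serialization round-trips vectors", {
  gen <- generate_corpus(preset("cds_like"), 1, 40, seed = 9)$corpus
  stream <- assemble_training_stream(gen, layer_config("raw"))
  m <- sgns_train(stream, window = 1, dim = 6, epochs = 3, seed = 1)
  path <- tempfile(fileext = ".vec")
  write_word2vec(m, path)
  m2 <- read_word2vec(path)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-12)
  expect_equal(rownames(m2$vectors), rownames(m$vectors))
})
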