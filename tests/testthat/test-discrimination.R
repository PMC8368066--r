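test_that("cosine distance attains its closed-form values and bounds", {
  u <- c(1, 2, 3)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(u, -u), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(u, 5 * u), 0) # positive scalar multiples
  expect_error(cosine_distance(c(0, 0), u[1:2]), "zero vector")
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(5); b <- rnorm(5)
    d <- cosine_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, cosine_distance(b, a))
  }
})

test_that("pairwise tables cover causative x non-causative pairs", {
  m <- full_coverage_model()
  tab <- pairwise_distances(m, genre = "cds", layer = "raw")
  expect_equal(nrow(tab), 207L) # 23 x 9
  expect_true(all(tab$distance >= 0 & tab$distance <= 2))
  # values match per-pair recomputation
  i <- c(1L, 100L, 207L)
  recomputed <- mapply(function(ci, nj)
    cosine_distance(word_vector(m, ci), word_vector(m, nj)),
    tab$causative[i], tab$noncausative[i])
  expect_equal(unname(recomputed), tab$distance[i])
  # one causative missing: 22 x 9 entries plus a warning
  m2 <- manual_model(m$vectors[rownames(m$vectors) != "open", ])
  expect_warning(tab2 <- pairwise_distances(m2), "open")
  expect_equal(nrow(tab2), 198L)
  # zero coverage errors
  m3 <- manual_model(matrix(rnorm(4), 2, 2,
                            dimnames = list(c("x", "y"), NULL)))
  expect_error(suppressWarnings(pairwise_distances(m3)), "no causative")
})

test_that("frequent verbs are counted by VERB-tagged occurrences", {
  toks <- data.table::rbindlist(c(
    replicate(10, utt_table(c("you", "open"), c("PRON", "VERB"), c(2L, 0L),
                            c("nsubj", "root")), simplify = FALSE),
    replicate(9, utt_table(c("you", "go"), c("PRON", "VERB"), c(2L, 0L),
                           c("nsubj", "root")), simplify = FALSE),
    # "open" as a non-verb must not count
    replicate(5, utt_table(c("the", "open"), c("DET", "ADJ"), c(2L, 0L),
                           c("det", "root")), simplify = FALSE)
  ))
  toks$utt_id <- rep(seq_len(24), each = 2)
  corp <- sem_corpus(toks)
  fv <- frequent_verbs(corp, floor = 10)
  expect_equal(fv, "open")
  expect_setequal(frequent_verbs(corp, floor = 9), c("go", "open"))
  # recount oracle on a generated corpus
  gen <- generate_corpus(preset("cds_like"), 5, 100, seed = 10)$corpus
  fv2 <- frequent_verbs(gen, floor = 10)
  tab <- table(gen$tokens$lemma[gen$tokens$upos == "VERB"])
  expect_setequal(fv2, names(tab)[tab >= 10])
})

test_that("random-pair baselines estimate the exhaustive pair mean", {
  # identical vectors: baseline exactly 0
  V <- matrix(rep(c(1, 2, 3), each = 4), 4, 3,
              dimnames = list(c("v1", "v2", "v3", "v4"), NULL))
  m_same <- manual_model(V)
  b0 <- estimate_baseline(m_same, rownames(V), n_pairs = 100, seed = 1)
  expect_equal(b0$mean_distance, 0)
  # two verbs: baseline equals their pairwise distance exactly
  set.seed(4)
  V2 <- matrix(rnorm(6), 2, 3, dimnames = list(c("v1", "v2"), NULL))
  m2 <- manual_model(V2)
  b2 <- estimate_baseline(m2, c("v1", "v2"), n_pairs = 500, seed = 2)
  expect_equal(b2$mean_distance, cosine_distance(V2[1, ], V2[2, ]))
  # 5-verb fixture: large-n estimate within Monte-Carlo error of the
  # exhaustive unordered-pair mean
  V5 <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("v", 1:5), NULL))
  m5 <- manual_model(V5)
  pairs <- utils::combn(5, 2)
  exact <- mean(apply(pairs, 2, function(p)
    cosine_distance(V5[p[1], ], V5[p[2], ])))
  b5 <- estimate_baseline(m5, paste0("v", 1:5), n_pairs = 40000, seed = 3)
  expect_equal(b5$mean_distance, exact, tolerance = 0.02)
  # determinism and error cases
  expect_identical(estimate_baseline(m5, paste0("v", 1:5), 1000, seed = 9),
                   estimate_baseline(m5, paste0("v", 1:5), 1000, seed = 9))
  expect_error(estimate_baseline(m5, "v1"), "at least 2")
})

test_that("above-baseline scores subtract elementwise with window checks", {
  m <- full_coverage_model()
  tab <- pairwise_distances(m)
  b <- estimate_baseline(m, rownames(m$vectors), n_pairs = 1000, seed = 1)
  sc <- above_baseline(tab, b)
  expect_equal(nrow(sc), 207L)
  expect_equal(sc$score, sc$distance - b$mean_distance)
  expect_equal(mean(sc$score), mean(sc$distance) - b$mean_distance)
  # distance equal to the baseline scores zero
  expect_equal(above_baseline(
    transform(tab[1, ], distance = b$mean_distance), b)$score, 0)
  expect_error(above_baseline(tab, b, check_window = 4), "window")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: closed-form star
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_s3_class(t3, "phylo")
  # branch lengths solve the three-point equations: 1, 2, 3
  lens <- stats::setNames(t3$edge.length,
                          t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  # additive 4-taxon distances: topology and branch lengths recovered
  true4 <- ape::read.tree(text = "((a:1,b:2):0.7,c:3,d:1.5);")
  D4 <- stats::cophenetic(true4)[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
  t4 <- neighbor_joining(D4)
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(true4)), 0,
               ignore_attr = TRUE)
  expect_equal(stats::cophenetic(t4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-8)
  # additive 6-taxon case
  true6 <- ape::read.tree(
    text = "(((a:0.5,b:0.9):0.4,c:1.2):0.3,(d:0.6,e:0.2):0.8,f:1.1);")
  D6 <- stats::cophenetic(true6)
  t6 <- neighbor_joining(D6)
  expect_equal(stats::cophenetic(t6)[rownames(D6), colnames(D6)], D6,
               tolerance = 1e-8)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining agrees with the ape reference implementation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    M <- matrix(runif(n * n, 0.3, 2), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(letters[1:n], letters[1:n])
    mine <- neighbor_joining(M)
    ref <- ape::nj(stats::as.dist(M))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    # same path-length matrix up to numerical error
    expect_equal(stats::cophenetic(mine)[letters[1:n], letters[1:n]],
                 stats::cophenetic(ref)[letters[1:n], letters[1:n]],
                 tolerance = 1e-6)
  }
})

test_that("embedding distance matrices feed clustering", {
  m <- full_coverage_model(extra = "filler")
  words <- c("open", "break", "go", "think", "filler")
  D <- embedding_distance_matrix(m, words)
  expect_equal(dim(D), c(5L, 5L))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(D["open", "go"],
               cosine_distance(word_vector(m, "open"), word_vector(m, "go")))
  tree <- neighbor_joining(D)
  expect_setequal(tree$tip.label, words)
})
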