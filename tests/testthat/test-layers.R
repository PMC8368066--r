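test_that("raw instances are marker-bracketed lemma sequences", {
  cfg <- layer_config("raw")
  one <- build_raw_instance(utt_table("run", "VERB", 0L, "root"), cfg)
  expect_equal(unclass(one), c("^^", "run", "$$"), ignore_attr = TRUE)
  three <- build_raw_instance(utt_table(c("you", "open", "it"),
                                        c("PRON", "VERB", "PRON"),
                                        c(2L, 0L, 2L),
                                        c("nsubj", "root", "dobj")), cfg)
  expect_equal(unclass(three), c("^^", "you", "open", "it", "$$"),
               ignore_attr = TRUE)
  expect_equal(attr(one, "origin"), "raw")
  # length property over generated utterances
  gen <- generate_corpus(preset("cds_like"), 2, 100, seed = 2)$corpus
  for (u in seminfer:::utterance_list(gen)) {
    expect_length(build_raw_instance(u, cfg), nrow(u) + 2L)
  }
})

test_that("word-class instances keep verb lemmas and abstract the rest", {
  cfg <- layer_config("wordclass")
  wc <- build_wordclass_instance(utt_open_box(), cfg)
  expect_equal(unclass(wc), c("^^", "PRON", "open", "DET", "NOUN", "$$"),
               ignore_attr = TRUE)
  # no verb: all tags
  noverb <- build_wordclass_instance(
    utt_table(c("the", "ball"), c("DET", "NOUN"), c(2L, 0L), c("det", "root")),
    cfg)
  expect_equal(unclass(noverb), c("^^", "DET", "NOUN", "$$"),
               ignore_attr = TRUE)
  # all verbs: all lemmas
  allverb <- build_wordclass_instance(
    utt_table(c("go", "look"), c("VERB", "VERB"), c(0L, 1L),
              c("root", "conj")), cfg)
  expect_equal(unclass(allverb), c("^^", "go", "look", "$$"),
               ignore_attr = TRUE)
})

test_that("minimal subtrees are heads with their direct dependents", {
  # chain a -> b -> c (b heads a, c heads b): two subtrees
  chain <- utt_table(c("a", "b", "c"), c("NOUN", "NOUN", "NOUN"),
                     c(2L, 3L, 0L), c("dep", "dep", "root"))
  subs <- extract_subtrees(chain)
  expect_length(subs, 2L)
  expect_equal(subs[[1]]$head_idx, 2L)
  expect_equal(subs[[1]]$member_idx, c(1L, 2L))
  expect_equal(subs[[2]]$head_idx, 3L)
  expect_equal(subs[[2]]$member_idx, c(2L, 3L))
  # flat utterance: the root heads all others, one subtree with n-1 deps
  flat <- utt_table(c("w1", "w2", "w3", "w4"), rep("NOUN", 4),
                    c(0L, 1L, 1L, 1L), c("root", "dep", "dep", "dep"))
  fs <- extract_subtrees(flat)
  expect_length(fs, 1L)
  expect_equal(fs[[1]]$member_idx, 1:4)
  # single token: no subtree
  expect_length(extract_subtrees(utt_table("run", "VERB", 0L, "root")), 0L)
  # multi-root is rejected
  bad <- utt_table(c("a", "b"), c("NOUN", "NOUN"), c(0L, 0L),
                   c("root", "root"))
  expect_error(extract_subtrees(bad), "single-rooted")
})

test_that("syntax instances encode subtrees as relation labels around verbs", {
  cfg <- layer_config("syntax")
  out <- build_syntax_instances(utt_open_box(), cfg)
  # subtree 1: open heads you (nsubj) and box (dobj); verb keeps its lemma
  expect_equal(unclass(out[[1]]), c("nsubj", "open", "dobj"),
               ignore_attr = TRUE)
  # subtree 2: non-verb head box rendered as its UPOS, dependent as deprel
  expect_equal(unclass(out[[2]]), c("det", "NOUN"), ignore_attr = TRUE)
  expect_true(all(vapply(out, attr, character(1), "origin") == "syntax"))
  # optional lexicalized dependents
  cfg2 <- layer_config("syntax", syntax_include_lemmas = TRUE)
  out2 <- build_syntax_instances(utt_open_box(), cfg2)
  expect_equal(unclass(out2[[1]]), c("nsubj:you", "open", "dobj:box"),
               ignore_attr = TRUE)
  # every verb that heads a dependent yields an instance containing its lemma
  gen <- generate_corpus(preset("cds_like"), 2, 60, seed = 3)$corpus
  for (u in seminfer:::utterance_list(gen)) {
    ins <- build_syntax_instances(u, cfg)
    verb_heads <- intersect(unique(u$head[u$head > 0L]),
                            u$tok_id[u$upos == "VERB"])
    covered <- vapply(verb_heads, function(h) {
      any(vapply(ins, function(x) u$lemma[u$tok_id == h] %in% unclass(x),
                 logical(1)))
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("lexicon instances are subtree lemmas and cover all arcs", {
  out <- build_lexicon_instances(utt_open_box())
  expect_equal(unclass(out[[1]]), c("you", "open", "box"), ignore_attr = TRUE)
  expect_equal(unclass(out[[2]]), c("the", "box"), ignore_attr = TRUE)
  # union of lexicon instances covers every token on at least one arc
  gen <- generate_corpus(preset("ads_like"), 1, 40, seed = 4)$corpus
  for (u in seminfer:::utterance_list(gen)) {
    ins <- build_lexicon_instances(u)
    seen <- unique(unlist(lapply(ins, unclass)))
    on_arc <- u$lemma[u$head > 0L | u$tok_id %in% u$head]
    expect_true(all(on_arc %in% seen))
  }
})

test_that("assembled streams interleave deterministically per utterance", {
  corp <- tiny_corpus()
  raw <- assemble_training_stream(corp, layer_config("raw"))
  expect_length(raw, 3L)
  expect_equal(unclass(raw[[2]]), c("^^", "you", "open", "the", "box", "$$"),
               ignore_attr = TRUE)
  # wordclass: exactly raw + tag frame per utterance
  wc <- assemble_training_stream(corp, layer_config("wordclass",
                                                    shuffle_seed = 5))
  expect_length(wc, 6L)
  origins <- vapply(wc, attr, character(1), "origin")
  expect_equal(sum(origins == "raw"), 3L)
  expect_equal(sum(origins == "wordclass"), 3L)
  # same seed: identical; different seed: same multiset
  wc2 <- assemble_training_stream(corp, layer_config("wordclass",
                                                     shuffle_seed = 5))
  expect_identical(wc, wc2)
  wc3 <- assemble_training_stream(corp, layer_config("wordclass",
                                                     shuffle_seed = 6))
  canon <- function(s) sort(unname(vapply(s, function(x)
    paste(unclass(x), collapse = " "), character(1))))
  expect_identical(canon(wc), canon(wc3))
  # raw instances inside any stream equal the raw layer exactly (multiset)
  syn <- assemble_training_stream(corp, layer_config("syntax",
                                                     shuffle_seed = 1))
  raw_in_syn <- Filter(function(x) attr(x, "origin") == "raw", syn)
  expect_identical(canon(raw_in_syn), canon(raw))
  # no boundary markers inside syntax or lexicon instances
  for (lay in c("syntax", "lexicon")) {
    s <- assemble_training_stream(corp, layer_config(lay, shuffle_seed = 2))
    for (x in Filter(function(i) attr(i, "origin") != "raw", s)) {
      expect_false(any(unclass(x) %in% c("^^", "$$")))
    }
  }
  # syntax instances per utterance = heads with >= 1 dependent
  syn_origins <- vapply(syn, attr, character(1), "origin")
  n_heads <- sum(vapply(seminfer:::utterance_list(corp), function(u)
    length(unique(u$head[u$head > 0L])), numeric(1)))
  expect_equal(sum(syn_origins == "syntax"), n_heads)
})
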