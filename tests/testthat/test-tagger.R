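make_tiny_config <- function(seed = 1L, epochs = 2L, ...) {
  train_config(bs = 4, lr = 0.01, epochs = epochs, seed = seed,
               gat = gat_config(layers = 2, heads = 2, units = 4),
               encoder = encoder_spec(d = 8, seed = seed), ...)
}

tiny_corpus <- function(n, seed, rho = 1, epsilon = 0) {
  cfg <- synthetic_config(n_sentences = n, seed = seed, rho = rho,
                          epsilon = epsilon)
  gatner:::with_private_seed(seed, lapply(seq_len(n),
    function(i) generate_sentence(cfg)))
}

test_that("softmax decoder rows are probabilities", {
  corpus <- tiny_corpus(3, 5)
  tc <- make_tiny_config()
  model <- init_tagger(tc, c("O", "B-ENT", "I-ENT"))
  p <- forward_probs(model, corpus[[1]])
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  # zero classifier weights give uniform rows
  model$params[["cls.W"]][] <- 0
  model$params[["cls.b"]][] <- 0
  p0 <- forward_probs(model, corpus[[1]])
  expect_equal(p0, matrix(1 / 3, nrow(p0), 3, dimnames = dimnames(p0)))
  # deterministic for fixed parameters
  expect_identical(p, forward_probs(init_tagger(tc, c("O", "B-ENT", "I-ENT")),
                                    corpus[[1]]))
})

test_that("training reduces the loss and is seed-reproducible", {
  corpus <- tiny_corpus(20, 11)
  tc <- make_tiny_config(epochs = 5L)
  m1 <- train_tagger(corpus, tc)
  expect_lt(m1$log$loss[5], m1$log$loss[1])
  m2 <- train_tagger(corpus, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log$loss, m2$log$loss)
  # a different seed gives a different trajectory
  m3 <- train_tagger(corpus, make_tiny_config(seed = 2L, epochs = 5L))
  expect_false(identical(m1$params, m3$params))
  expect_error(train_tagger(list(), tc), "empty")
})

test_that("the model can overfit a single sentence to perfect entity F1", {
  corpus <- tiny_corpus(60, 21)
  has_ent <- vapply(corpus, function(s) any(s$labels != "O"), TRUE)
  s <- corpus[has_ent][[1]]
  tc <- train_config(bs = 1, lr = 0.02, epochs = 200, seed = 4,
                     gat = gat_config(layers = 2, heads = 2, units = 8),
                     encoder = encoder_spec(d = 8, seed = 4))
  mod <- train_tagger(list(s), tc)
  pred <- predict_words(s, mod)
  sc <- score_entities(list(s$labels), list(pred))
  expect_equal(sc$f1, 1)
})

test_that("word labels come from first pieces and CLS/SEP are dropped", {
  corpus <- tiny_corpus(10, 31)
  tc <- make_tiny_config()
  mod <- train_tagger(corpus, tc)
  for (s in corpus[1:3]) {
    p <- predict_words(s, mod)
    expect_identical(length(p), n_words(s))
    expect_silent(validate_bio(p))
  }
  # a multi-piece word yields exactly one label
  s5 <- ner_sentence(c("abcdefghijklmnopqrstuvwxyzab", "vrb"),
                     pos = c("NOUN", "VERB"), heads = c(2L, 0L),
                     rels = c("nsubj", "root"))
  expect_identical(lengths(wordpiece_split(s5$surface))[1], 5L)
  expect_identical(length(predict_words(s5, mod)), 2L)
})

test_that("BIO repair fixes orphan I- tags and nothing else", {
  expect_identical(repair_bio(c("O", "I-Chem")), c("O", "B-Chem"))
  valid <- c("B-A", "I-A", "O", "B-B")
  expect_identical(repair_bio(valid), valid)
  expect_identical(repair_bio(c("I-A", "I-B")), c("B-A", "B-B"))
  # idempotent; O and types preserved
  set.seed(3)
  for (rep in 1:20) {
    labs <- sample(c("O", "B-A", "I-A", "B-B", "I-B"), 12, replace = TRUE)
    fixed <- repair_bio(labs)
    expect_identical(repair_bio(fixed), fixed)
    expect_identical(fixed == "O", labs == "O")
    expect_identical(substring(fixed, 3), substring(labs, 3))
    expect_silent(validate_bio(fixed))
  }
})

test_that("CLS/SEP nodes are excluded from supervision", {
  corpus <- tiny_corpus(4, 41)
  tc <- make_tiny_config()
  label_set <- gatner:::corpus_label_set(corpus)
  model <- init_tagger(tc, label_set)
  inst <- gatner:::make_instance(corpus[[1]], tc, label_set)
  cls_sep <- which(inst$graph$nodes$kind %in% c("CLS", "SEP"))
  expect_true(all(!inst$supervised[cls_sep]))
  g1 <- gatner:::loss_and_grad(model, list(inst))
  # toggling (hypothetical) gold labels on CLS/SEP changes nothing
  inst2 <- inst
  inst2$targets[cls_sep] <- 1L
  g2 <- gatner:::loss_and_grad(model, list(inst2))
  expect_identical(g1$loss, g2$loss)
  expect_identical(g1$grads, g2$grads)
})

test_that("continuation pieces are supervised with the I- form of the word label", {
  s <- ner_sentence(c("abcdefghijkl", "vrb"), pos = c("NOUN", "VERB"),
                    heads = c(2L, 0L), rels = c("nsubj", "root"),
                    labels = c("B-ENT", "O"))
  tc <- make_tiny_config()
  label_set <- c("O", "B-ENT", "I-ENT")
  inst <- gatner:::make_instance(s, tc, label_set)
  word1_nodes <- which(!is.na(inst$graph$nodes$word_index) &
                         inst$graph$nodes$word_index == 1L)
  tgts <- label_set[inst$targets[word1_nodes]]
  expect_identical(tgts[1], "B-ENT")
  expect_true(all(tgts[-1] == "I-ENT"))
})

test_that("over-long sentences split at word boundaries and stay trees", {
  cfg <- synthetic_config(n_sentences = 1, seed = 3, len_min = 30,
                          len_max = 30)
  s <- gatner:::with_private_seed(3L, generate_sentence(cfg))
  chunks <- gatner:::split_to_msl(s, msl = 20L)
  expect_gt(length(chunks), 1L)
  expect_identical(unlist(lapply(chunks, `[[`, "surface")), s$surface)
  for (ch in chunks) {
    expect_silent(gatner:::validate_parse_tree(ch$heads))
    g <- sentence_graph(ch)
    expect_lte(g$n, 20L)
  }
  # prediction on a long sentence still yields one label per word
  corpus <- tiny_corpus(6, 43)
  mod <- train_tagger(corpus, make_tiny_config(msl = 16L))
  p <- predict_words(s, mod)
  expect_identical(length(p), 30L)
})

test_that("model checkpoints round-trip through JSON", {
  corpus <- tiny_corpus(6, 51)
  mod <- train_tagger(corpus, make_tiny_config())
  f <- withr::local_tempfile(fileext = ".json")
  save_model(mod, f)
  back <- load_model(f)
  expect_equal(back$params, mod$params, tolerance = 1e-12)
  expect_identical(back$label_set, mod$label_set)
  s <- corpus[[1]]
  expect_identical(predict_words(s, back), predict_words(s, mod))
})

test_that("per-dataset presets carry the documented hyperparameters", {
  p <- preset_config("bc5cdr_chem")
  expect_identical(p$msl, 256L)
  expect_identical(p$bs, 32L)
  expect_equal(p$lr, 3e-5)
  expect_identical(c(p$layers, p$heads, p$units), c(4L, 12L, 64L))
  p2 <- preset_config("jnlpba")
  expect_identical(c(p2$layers, p2$heads, p2$units), c(2L, 8L, 96L))
  expect_error(preset_config("nope"), "preset")
})
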