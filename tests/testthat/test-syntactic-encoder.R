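test_that("default inventory matches the retained tag lists", {
  inv <- default_inventory()
  expect_identical(inv$pos_tags,
                   c("NOUN", "PROPN", "PUNCT", "NUM", "ADJ", "VERB", "SYM",
                     "CCONJ", "ADP", "PART"))
  expect_identical(inv$dep_relations,
                   c("compound", "punct", "nmod", "amod", "pobj", "conj",
                     "appos", "det", "nummod", "npadvmod", "cc", "nsubj",
                     "dobj", "prep", "nsubjpass", "acl", "root", "case"))
  expect_identical(inv$threshold, 0.01)
  expect_identical(synt_dim(inv), 54L)
})

test_that("salient-tag selection thresholds and orders by frequency", {
  expect_identical(select_salient_tags(c(X = 0.02, Y = 0.005), 0.01), "X")
  freq <- c(a = 0.3, b = 0.05, c = 0.001)
  expect_identical(select_salient_tags(freq, 0), c("a", "b", "c"))
  expect_identical(select_salient_tags(c(b = 0.05, a = 0.3), 0.01),
                   c("a", "b"))
  expect_error(select_salient_tags(c(x = -0.1), 0.01), "non-negative")
})

test_that("POS block is one-hot with catch-all and special tags", {
  inv <- default_inventory()
  v <- encode_pos("NOUN", inv)
  expect_identical(length(v), 14L)
  expect_identical(which(v == 1), 1L)      # NOUN is the first retained slot
  expect_identical(sum(v), 1)
  # unknown tag -> OTHERS (slot 11)
  expect_identical(which(encode_pos("INTJ", inv) == 1), 11L)
  # special tags override any POS
  expect_identical(which(encode_pos("NOUN", inv, special = "CLS") == 1), 12L)
  expect_identical(which(encode_pos("VERB", inv, special = "SEP") == 1), 13L)
  expect_identical(which(encode_pos(NULL, inv, special = "X") == 1), 14L)
})

test_that("dependency block splits in/out degrees and clamps repeats", {
  inv <- default_inventory()
  tr <- data.frame(head = c(2L, 2L, 1L), tail = c(1L, 3L, 4L),
                   relation = c("nsubj", "dobj", "amod"))
  v2 <- encode_dependencies(2L, tr, NULL, inv)
  expect_identical(length(v2), 40L)
  # node 2 heads an nsubj and a dobj: two out bits, no in bits
  expect_identical(sum(v2), 2)
  expect_identical(sum(v2[1:20]), 0)
  # node 1: nsubj in-bit plus amod out-bit
  v1 <- encode_dependencies(1L, tr, NULL, inv)
  expect_identical(v1[match("nsubj", inv$dep_relations)], 1)
  expect_identical(v1[20 + match("amod", inv$dep_relations)], 1)
  # isolated node: all zero
  expect_identical(sum(encode_dependencies(9L, tr, NULL, inv)), 0)
  # repeated relation stays binary
  tr2 <- data.frame(head = c(1L, 1L), tail = c(2L, 3L),
                    relation = c("amod", "amod"))
  expect_identical(sum(encode_dependencies(1L, tr2, NULL, inv)), 1)
  # unretained relation -> others slot
  tr3 <- data.frame(head = 2L, tail = 1L, relation = "advcl")
  expect_identical(which(encode_dependencies(1L, tr3, NULL, inv) == 1), 19L)
  # next pair sets out on the left node and in on the right node
  nx <- cbind(from = 1L, to = 2L)
  expect_identical(which(encode_dependencies(1L, NULL, nx, inv) == 1), 40L)
  expect_identical(which(encode_dependencies(2L, NULL, nx, inv) == 1), 20L)
})

test_that("in/out bits swap when head and tail swap", {
  inv <- default_inventory()
  tr <- data.frame(head = 1L, tail = 2L, relation = "nmod")
  sw <- data.frame(head = 2L, tail = 1L, relation = "nmod")
  v <- encode_dependencies(1L, tr, NULL, inv)
  vs <- encode_dependencies(1L, sw, NULL, inv)
  expect_identical(v[1:20], vs[21:40])
  expect_identical(v[21:40], vs[1:20])
})

test_that("full syntactic vector is 54-dimensional with the documented layout", {
  inv <- default_inventory()
  v <- encode_syntactic("NOUN", 1L, NULL, NULL, inv)
  expect_identical(length(v), 54L)
  expect_identical(14L + 20L + 20L, 54L)
  # CLS node with no dependencies: CLS bit plus 40 zeros
  vc <- encode_syntactic(NULL, 1L, NULL, NULL, inv, special = "CLS")
  expect_identical(sum(vc), 1)
  expect_identical(which(vc == 1), 12L)
})

test_that("sentence encoding is one-hot per POS block and order-invariant", {
  set.seed(42)
  cfg <- synthetic_config(n_sentences = 1, seed = 1)
  s <- generate_sentence(cfg)
  g <- sentence_graph(s)
  m <- encode_sentence_syntax(g)
  expect_identical(ncol(m), 54L)
  expect_true(all(rowSums(m[, 1:14, drop = FALSE]) == 1))
  expect_true(all(m %in% c(0, 1)))
  # encoding does not depend on the order triples are listed in
  tr <- dependency_triples(s)
  perm <- sample(nrow(tr))
  inv <- default_inventory()
  for (w in seq_len(n_words(s)))
    expect_identical(encode_dependencies(w, tr, NULL, inv),
                     encode_dependencies(w, tr[perm, ], NULL, inv))
})

test_that("each triple contributes one in-bit and one out-bit", {
  # single-piece words, no duplicated (word, relation) pairs
  inv <- default_inventory()
  tr <- data.frame(head = c(2L, 2L, 3L), tail = c(1L, 3L, 4L),
                   relation = c("nsubj", "dobj", "amod"))
  bits <- t(vapply(1:4, function(w) encode_dependencies(w, tr, NULL, inv),
                   numeric(40)))
  expect_equal(sum(bits[, 1:20]), nrow(tr))      # in-degree block
  expect_equal(sum(bits[, 21:40]), nrow(tr))     # out-degree block
})

test_that("root word carries a synthesized root in-degree bit", {
  s <- ner_sentence(c("binds", "IL2"), pos = c("VERB", "NOUN"),
                    heads = c(0L, 1L), rels = c("root", "dobj"))
  g <- sentence_graph(s)
  m <- encode_sentence_syntax(g)
  root_in_slot <- 14L + match("root", default_inventory()$dep_relations)
  expect_identical(m[2, root_in_slot], 1)  # node 2 = first piece of word 1
  expect_identical(sum(m[, root_in_slot]), 1)
})

test_that("continuation pieces take X POS but inherit dependency bits", {
  s <- ner_sentence(c("dyskinesia", "worsens"), pos = c("NOUN", "VERB"),
                    heads = c(2L, 0L), rels = c("nsubj", "root"))
  pieces <- list(c("dysk", "##inesia"), "worsens")
  g <- sentence_graph(s, pieces)
  m <- encode_sentence_syntax(g)
  # node 3 is the continuation piece of word 1
  expect_identical(which(m[3, 1:14] == 1), 14L)           # X tag
  nsubj_in <- 14L + match("nsubj", default_inventory()$dep_relations)
  expect_identical(m[3, nsubj_in], 1)                     # inherited
  expect_identical(m[2, nsubj_in], 1)
  expect_identical(which(m[2, 1:14] == 1), 1L)            # NOUN on first piece
  # next bits: out on node 2, in on node 3
  expect_identical(m[2, 54], 1)
  expect_identical(m[3, 34], 1)
  # alternative convention: continuations keep the word POS
  m2 <- encode_sentence_syntax(g, continuation_pos_inherit = TRUE)
  expect_identical(which(m2[3, 1:14] == 1), 1L)
})

test_that("inventory YAML round trip preserves labels and threshold", {
  inv <- tag_inventory(c("NOUN", "VERB"), c("nsubj", "dobj"), 0.05)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_inventory(inv, f)
  back <- read_inventory(f)
  expect_identical(back$pos_tags, inv$pos_tags)
  expect_identical(back$dep_relations, inv$dep_relations)
  expect_identical(back$threshold, 0.05)
  expect_identical(synt_dim(back), (2L + 4L) + 2L * (2L + 2L))
})
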