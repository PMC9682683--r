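# Seeded generator for dependency-parsed, BIO-labeled corpora.
#
# Entity placement follows a syntactic motif: a NOUN/PROPN attached to a
# VERB head by nsubj/dobj/nmod is an entity trigger (selected with
# probability rho), a NOUN/PROPN compound child of a selected trigger is
# pulled into the entity, and any other word turns into a singleton
# entity with noise probability epsilon.  At rho = 1, epsilon = 0 the
# labels are a deterministic function of POS, relation and neighbor POS,
# so syntactic features suffice for perfect tagging.

.trigger_rels <- c("nsubj", "dobj", "nmod")
.np_tags <- c("NOUN", "PROPN")

# Relation weights for non-root words ('root' is reserved for the root).
default_rel_weights <- function() c(
  compound = 0.12, punct = 0.06, nmod = 0.10, amod = 0.07, det = 0.05,
  dobj = 0.09, nsubj = 0.10, prep = 0.07, pobj = 0.07, conj = 0.04,
  cc = 0.04, case = 0.04, nummod = 0.03, appos = 0.02, npadvmod = 0.02,
  nsubjpass = 0.02, acl = 0.02, others = 0.04)

# POS distribution conditional on the incoming relation.  Tags outside
# the retained inventory (DET, ADV, PRON, INTJ) exercise the OTHERS slot.
default_pos_given_rel <- function() list(
  compound = c(NOUN = 0.7, PROPN = 0.3),
  punct = c(PUNCT = 1),
  nmod = c(NOUN = 0.6, PROPN = 0.3, NUM = 0.1),
  amod = c(ADJ = 0.9, VERB = 0.1),
  det = c(DET = 1),
  dobj = c(NOUN = 0.6, PROPN = 0.25, PRON = 0.15),
  nsubj = c(NOUN = 0.55, PROPN = 0.3, PRON = 0.15),
  prep = c(ADP = 1),
  pobj = c(NOUN = 0.55, PROPN = 0.3, NUM = 0.15),
  conj = c(NOUN = 0.5, PROPN = 0.2, VERB = 0.2, ADJ = 0.1),
  cc = c(CCONJ = 1),
  case = c(ADP = 0.9, PART = 0.1),
  nummod = c(NUM = 1),
  appos = c(PROPN = 0.5, NOUN = 0.5),
  npadvmod = c(NOUN = 0.6, ADV = 0.4),
  nsubjpass = c(NOUN = 0.6, PROPN = 0.4),
  acl = c(VERB = 1),
  others = c(ADV = 0.5, INTJ = 0.3, SYM = 0.2))

# POS distribution of the root word.
default_root_pos <- function() c(VERB = 0.75, NOUN = 0.2, ADJ = 0.05)

#' Configuration of the synthetic corpus generator
#'
#' @param n_sentences Number of sentences to generate.
#' @param len_min,len_max Sentence length bounds (words, uniform).
#' @param rho Entity rule strength in `[0, 1]`: probability that a
#'   syntactic trigger (NOUN/PROPN attached to a VERB head by
#'   nsubj/dobj/nmod) is selected as an entity.
#' @param epsilon Label noise in `[0, 1]`: probability that a non-rule
#'   word becomes a singleton entity.
#' @param multiword_prob Probability that a selected trigger acquires an
#'   adjacent compound NOUN modifier, producing a multi-word span.
#' @param seed Mandatory integer seed.
#' @param entity_type Entity type used in B-/I- tags.
#' @param splits Named train/dev/test proportions (must sum to 1).
#' @param rel_weights Named relation sampling weights for non-root words.
#' @param pos_given_rel Named list of POS distributions per relation.
#' @param root_pos POS distribution of the root word.
#' @param root_attach Probability that a word attaches directly to the
#'   root rather than to a uniformly chosen earlier word; verb-rooted
#'   clauses hang most arguments off the main verb.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_sentences = 100L, len_min = 4L, len_max = 14L,
                             rho = 1, epsilon = 0, multiword_prob = 0.3,
                             seed, entity_type = "ENT",
                             splits = c(train = 0.8, dev = 0.1, test = 0.1),
                             rel_weights = default_rel_weights(),
                             pos_given_rel = default_pos_given_rel(),
                             root_pos = default_root_pos(),
                             root_attach = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sentences >= 1L, len_min >= 1L, len_max >= len_min,
            rho >= 0, rho <= 1, epsilon >= 0, epsilon <= 1,
            multiword_prob >= 0, multiword_prob <= 1,
            root_attach >= 0, root_attach <= 1,
            abs(sum(splits) - 1) < 1e-9,
            abs(sum(rel_weights) - 1) < 1e-6)
  structure(list(n_sentences = as.integer(n_sentences),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 rho = rho, epsilon = epsilon,
                 multiword_prob = multiword_prob, seed = as.integer(seed),
                 entity_type = entity_type, splits = splits,
                 rel_weights = rel_weights, pos_given_rel = pos_given_rel,
                 root_pos = root_pos, root_attach = root_attach),
            class = "synthetic_config")
}

# Synthetic lexicon: word shapes per POS, fixed across configs so that
# surface identity is informative of POS for the hash-embedding stub.
synthetic_lexicon <- function(words_per_tag = 40L) {
  make_word <- function(tag) {
    letters_lc <- letters
    switch(tag,
      PUNCT = sample(c(",", ";", ":", "(", ")", "-"), 1L),
      SYM = sample(c("%", "+", "=", "/", "<", ">"), 1L),
      NUM = paste(sample(0:9, sample(1:4, 1L), replace = TRUE), collapse = ""),
      PROPN = paste0(paste(sample(LETTERS, sample(2:3, 1L), replace = TRUE),
                           collapse = ""),
                     sample(0:9, 1L),
                     if (runif(1) < 0.4) paste0("-",
                       paste(sample(letters_lc, 3L, TRUE), collapse = ""))
                     else ""),
      {
        n <- sample(3:12, 1L)
        paste(sample(letters_lc, n, replace = TRUE), collapse = "")
      })
  }
  tags <- c("NOUN", "PROPN", "PUNCT", "NUM", "ADJ", "VERB", "SYM",
            "CCONJ", "ADP", "PART", "DET", "ADV", "PRON", "INTJ")
  with_private_seed(901237L, {
    lex <- lapply(tags, function(tag)
      unique(vapply(seq_len(words_per_tag), function(i) make_word(tag), "")))
    names(lex) <- tags
    lex
  })
}

.lexicon_cache <- new.env(parent = emptyenv())
get_lexicon <- function() {
  if (is.null(.lexicon_cache$lex)) .lexicon_cache$lex <- synthetic_lexicon()
  .lexicon_cache$lex
}

#' Generate a random single-root dependency tree
#'
#' Word 1 is the root; every later word attaches to a uniformly chosen
#' earlier word, which guarantees a single root and no cycles.  Relations
#' are drawn from the configured weights (the root keeps relation
#' `root`).
#'
#' @param n_words Number of words.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param rel_weights Named relation weights for non-root words.
#' @param root_attach Probability of attaching directly to the root.
#' @return List with integer `heads` (0 for the root) and character
#'   `rels`.
#' @export
generate_tree <- function(n_words, seed = NULL,
                          rel_weights = default_rel_weights(),
                          root_attach = 0.5) {
  stopifnot(n_words >= 1L)
  gen <- function() {
    heads <- integer(n_words); rels <- character(n_words)
    heads[1L] <- 0L; rels[1L] <- "root"
    for (i in seq_len(n_words)[-1L]) {
      heads[i] <- if (i == 2L || runif(1) < root_attach) 1L
                  else sample.int(i - 1L, 1L)
      rels[i] <- sample(names(rel_weights), 1L, prob = rel_weights)
    }
    list(heads = heads, rels = rels)
  }
  if (is.null(seed)) gen() else with_private_seed(seed, gen())
}

sample_pos <- function(rel, pos_given_rel) {
  tab <- pos_given_rel[[rel]]
  if (is.null(tab)) return("NOUN")
  if (length(tab) == 1L) names(tab) else sample(names(tab), 1L, prob = tab)
}

# TRUE for words matching the entity trigger motif.
trigger_words <- function(pos, heads, rels) {
  vapply(seq_along(pos), function(i) {
    heads[i] > 0L && pos[i] %in% .np_tags &&
      rels[i] %in% .trigger_rels && pos[heads[i]] == "VERB"
  }, logical(1))
}

# is `anc` an ancestor of `node` (or the node itself)?
is_ancestor <- function(heads, anc, node) {
  v <- node
  while (v != 0L) {
    if (v == anc) return(TRUE)
    v <- heads[v]
  }
  FALSE
}

#' Generate one parsed, BIO-labeled synthetic sentence
#'
#' Draws a dependency tree, assigns POS conditional on each word's
#' relation, applies the entity rule (see [synthetic_config()]), and
#' emits IOB2 labels in which adjacent entity words merge into one span.
#' Uses the current RNG stream; [generate_corpus()] seeds it once per
#' corpus.
#'
#' @param config A `synthetic_config`.
#' @param n_words Optional fixed length; drawn uniformly from the
#'   configured bounds when `NULL`.
#' @return A labeled, parsed `ner_sentence`.
#' @export
generate_sentence <- function(config, n_words = NULL) {
  if (is.null(n_words)) {
    lens <- config$len_min:config$len_max
    n_words <- lens[sample.int(length(lens), 1L)]
  }
  tree <- generate_tree(n_words, seed = NULL, config$rel_weights,
                        config$root_attach)
  heads <- tree$heads; rels <- tree$rels
  pos <- character(n_words)
  pos[1L] <- sample(names(config$root_pos), 1L, prob = config$root_pos)
  for (i in seq_len(n_words)[-1L])
    pos[i] <- sample_pos(rels[i], config$pos_given_rel)

  trig <- trigger_words(pos, heads, rels)
  selected <- trig & (runif(n_words) < config$rho)

  # optionally give a selected trigger an adjacent compound modifier
  for (t in which(selected)) {
    if (t > 1L && runif(1) < config$multiword_prob) {
      m <- t - 1L
      # never steal a VERB (it may license another word's trigger motif)
      if (heads[m] != 0L && !trig[m] && pos[m] != "VERB" &&
          !is_ancestor(heads, m, t)) {
        heads[m] <- t; rels[m] <- "compound"; pos[m] <- "NOUN"
      }
    }
  }
  # deterministic propagation: compound NOUN/PROPN child of a selected
  # trigger joins the entity (one level; triggers are never compounds)
  entity <- selected
  prop <- !selected & rels == "compound" & pos %in% .np_tags &
    heads > 0L & selected[pmax(heads, 1L)]
  entity <- entity | prop
  # noise: any other word becomes a singleton entity
  entity <- entity | (!entity & runif(n_words) < config$epsilon)

  labels <- rep("O", n_words)
  prev_entity <- FALSE
  for (i in seq_len(n_words)) {
    if (entity[i]) {
      labels[i] <- paste0(if (prev_entity) "I-" else "B-", config$entity_type)
      prev_entity <- TRUE
    } else prev_entity <- FALSE
  }
  lex <- get_lexicon()
  surfaces <- vapply(pos, function(tag) {
    words <- lex[[tag]] %||% lex[["NOUN"]]
    words[sample.int(length(words), 1L)]
  }, "")
  ner_sentence(surfaces, pos = pos, heads = heads, rels = rels,
               labels = labels)
}

#' Generate a synthetic corpus and write it to disk
#'
#' Draws `n_sentences` sentences from one seeded stream, splits them into
#' disjoint train/dev/test sets by the configured proportions, and writes
#' per-split BIO CoNLL (`<split>.bio`) and CoNLL-U (`<split>.conllu`)
#' files plus a `manifest.yaml` recording config and seed.  Regenerating
#' from the same manifest is byte-identical.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the named list of split sentence lists.
#' @export
generate_corpus <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop(sprintf("output directory '%s' exists; use force = TRUE", dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sentences <- with_private_seed(config$seed,
    lapply(seq_len(config$n_sentences), function(i) {
      s <- generate_sentence(config)
      s$id <- sprintf("synth%05d", i)
      s
    }))
  n <- config$n_sentences
  n_train <- floor(n * config$splits[["train"]])
  n_dev <- floor(n * config$splits[["dev"]])
  splits <- list(train = sentences[seq_len(n_train)],
                 dev = sentences[n_train + seq_len(n_dev)],
                 test = sentences[seq((n_train + n_dev + 1L), n)])
  for (nm in names(splits)) {
    write_predictions(splits[[nm]], NULL, file.path(dir, paste0(nm, ".bio")))
    write_conllu(splits[[nm]], file.path(dir, paste0(nm, ".conllu")))
  }
  manifest <- list(format_version = 1L,
                   config = list(
                     n_sentences = config$n_sentences,
                     len_min = config$len_min, len_max = config$len_max,
                     rho = config$rho, epsilon = config$epsilon,
                     multiword_prob = config$multiword_prob,
                     seed = config$seed, entity_type = config$entity_type,
                     splits = as.list(config$splits),
                     root_attach = config$root_attach))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(splits)
}

#' Regenerate a corpus from its manifest
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [generate_corpus()].
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the named list of split sentence lists.
#' @export
regenerate_corpus <- function(manifest_path, dir, force = FALSE) {
  m <- yaml::read_yaml(manifest_path)
  cfg <- m$config
  config <- synthetic_config(n_sentences = cfg$n_sentences,
                             len_min = cfg$len_min, len_max = cfg$len_max,
                             rho = cfg$rho, epsilon = cfg$epsilon,
                             multiword_prob = cfg$multiword_prob,
                             seed = cfg$seed, entity_type = cfg$entity_type,
                             splits = unlist(cfg$splits),
                             root_attach = cfg$root_attach %||% 0.5)
  generate_corpus(config, dir, force = force)
}

#' Read a generated corpus directory
#'
#' Merges each split's BIO labels with its CoNLL-U parse into fully
#' populated sentences.
#'
#' @param dir Directory written by [generate_corpus()].
#' @param splits Which splits to read.
#' @return Named list of sentence lists.
#' @export
read_corpus_dir <- function(dir, splits = c("train", "dev", "test")) {
  out <- lapply(splits, function(nm) {
    bio <- read_bio_conll(file.path(dir, paste0(nm, ".bio")))
    parsed <- read_conllu(file.path(dir, paste0(nm, ".conllu")))
    if (length(bio) != length(parsed))
      stop(sprintf("split '%s': BIO and CoNLL-U sentence counts differ", nm))
    Map(function(b, p) {
      if (!identical(b$surface, p$surface))
        stop(sprintf("split '%s': token mismatch between BIO and CoNLL-U", nm))
      p$labels <- b$labels
      p
    }, bio, parsed)
  })
  names(out) <- splits
  out
}
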