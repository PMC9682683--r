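# End-to-end node-classification tagger: [Cont || Synt] -> stacked GAT
# -> linear + softmax over BIO labels, trained with Adam on mean
# cross-entropy over supervised nodes.

#' Training configuration for the graph tagger
#'
#' Defaults mirror the reference hyperparameter table of the method
#' (max sequence length 256 nodes, batch size 32, learning rate 5e-5,
#' 50 epochs); see [preset_config()] for the per-dataset presets.
#' Desk-scale experiments override them with smaller values.
#'
#' @param msl Maximum nodes per graph; longer sentences are split at the
#'   last word boundary before the limit.
#' @param bs Batch size (sentences per optimizer step).
#' @param lr Learning rate of the Adam optimizer.
#' @param epochs Training epochs.
#' @param seed Integer seed governing initialization and shuffling.
#' @param gat A [gat_config()].
#' @param encoder An [encoder_spec()] for the contextual features.
#' @param inventory A [tag_inventory()] for the syntactic features.
#' @param feature_set `"cont+synt"`, `"cont"` or `"synt"`: which feature
#'   blocks enter the model (ablation switch).
#' @param synt_blocks `"both"`, `"no_pos"` or `"no_dep"`: zero out the POS
#'   or dependency block of the syntactic vector (finer ablation switch;
#'   the graph topology is kept either way).
#' @param clip Global gradient-norm clip (default 1.0).
#' @param weight_decay Decoupled L2 weight decay coefficient (default 0).
#' @param word_dropout Probability of blanking a word's surface-hash
#'   channels during training (position channels are kept), discouraging
#'   surface memorization; standard regularizer for neural sequence
#'   taggers (default 0).
#' @param patience Early-stopping patience in epochs on dev entity F1
#'   (used only when a dev set is supplied).
#' @param continuation_pos_inherit Passed to [encode_sentence_syntax()].
#' @return A `train_config` object.
#' @export
train_config <- function(msl = 256L, bs = 32L, lr = 5e-5, epochs = 50L,
                         seed = 1L, gat = gat_config(),
                         encoder = encoder_spec(),
                         inventory = default_inventory(),
                         feature_set = c("cont+synt", "cont", "synt"),
                         synt_blocks = c("both", "no_pos", "no_dep"),
                         clip = 1.0, weight_decay = 0, word_dropout = 0,
                         patience = 10L,
                         continuation_pos_inherit = FALSE) {
  feature_set <- match.arg(feature_set)
  synt_blocks <- match.arg(synt_blocks)
  stopifnot(msl >= 4L, bs >= 1L, lr > 0, epochs >= 1L, weight_decay >= 0,
            word_dropout >= 0, word_dropout < 1)
  structure(list(msl = as.integer(msl), bs = as.integer(bs), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 gat = gat, encoder = encoder, inventory = inventory,
                 feature_set = feature_set, synt_blocks = synt_blocks,
                 clip = clip, weight_decay = weight_decay,
                 word_dropout = word_dropout,
                 patience = as.integer(patience),
                 continuation_pos_inherit = continuation_pos_inherit),
            class = "train_config")
}

# Width of the initial node attributes under a config.
input_width <- function(config) {
  d <- config$encoder$d
  s <- synt_dim(config$inventory)
  switch(config$feature_set,
         "cont+synt" = d + s, "cont" = d, "synt" = s)
}

# ---- instances -------------------------------------------------------------

# Split an over-long parsed sentence into word chunks whose graphs fit
# within msl nodes.  Words whose head falls outside their chunk are
# re-rooted: the first becomes the chunk root, later ones attach to it
# with the catch-all relation.
split_to_msl <- function(sentence, msl) {
  pieces <- wordpiece_split(sentence$surface)
  per_word <- lengths(pieces)
  if (sum(per_word) + 2L <= msl) return(list(sentence))
  budget <- msl - 2L
  chunks <- list(); start <- 1L
  while (start <= length(per_word)) {
    acc <- cumsum(per_word[start:length(per_word)])
    take <- max(1L, sum(acc <= budget))
    idx <- start:(start + take - 1L)
    heads <- sentence$heads[idx]
    rels <- sentence$rels[idx]
    inside <- heads %in% idx
    local <- ifelse(inside, match(heads, idx), 0L)
    outside <- which(!inside)
    if (length(outside) > 1L) {
      local[outside[-1L]] <- outside[1L]
      rels[outside[-1L]] <- "others"
    }
    rels[outside[1L]] <- "root"
    chunks[[length(chunks) + 1L]] <-
      ner_sentence(sentence$surface[idx],
                   id = sprintf("%s.%d", sentence$id, length(chunks) + 1L),
                   pos = sentence$pos[idx], heads = local, rels = rels,
                   labels = if (is.null(sentence$labels)) NULL
                            else repair_bio(sentence$labels[idx]))
    start <- start + take
  }
  chunks
}

# Per-node supervision targets: first piece takes the word label,
# continuation pieces its I- form, CLS/SEP are never supervised.
node_targets <- function(graph, labels, label_set) {
  n <- graph$n
  tgt <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    w <- graph$nodes$word_index[i]
    if (is.na(w)) next
    lab <- labels[w]
    if (graph$nodes$is_continuation[i] && startsWith(lab, "B-"))
      lab <- paste0("I-", substring(lab, 3))
    tgt[i] <- match(lab, label_set)
  }
  tgt
}

# Build one training/prediction instance from a parsed sentence.
make_instance <- function(sentence, config, label_set = NULL) {
  graph <- sentence_graph(sentence, self_loops = config$gat$self_loops)
  synt <- encode_sentence_syntax(graph, config$inventory,
                                 config$continuation_pos_inherit)
  if (config$synt_blocks == "no_pos")
    synt[, seq_len(pos_block_size(config$inventory))] <- 0
  if (config$synt_blocks == "no_dep")
    synt[, pos_block_size(config$inventory) +
           seq_len(2L * dep_block_size(config$inventory))] <- 0
  cont <- encode_context(graph, config$encoder)
  h0 <- switch(config$feature_set,
               "cont+synt" = concat_features(cont, synt),
               "cont" = cont, "synt" = synt)
  first_piece <- vapply(split(seq_len(graph$n), graph$nodes$word_index),
                        min, 1L)
  tgt <- if (!is.null(label_set) && !is.null(sentence$labels))
    node_targets(graph, sentence$labels, label_set) else NULL
  supervised <- graph$nodes$kind == "piece" & !is.na(tgt %||% NA)
  list(graph = graph, h0 = h0, targets = tgt,
       supervised = if (is.null(tgt)) NULL else supervised,
       first_piece = first_piece, sentence = sentence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label set of a corpus: O first, then sorted B-/I- tags.
corpus_label_set <- function(corpus) {
  labs <- unique(unlist(lapply(corpus, `[[`, "labels")))
  if (is.null(labs)) stop("corpus has no gold labels")
  c("O", sort(setdiff(labs, "O")))
}

# ---- model -----------------------------------------------------------------

#' Initialize tagger parameters
#'
#' Glorot-uniform GAT parameters for every layer and head plus a linear
#' softmax classifier, all drawn from a private seeded stream.
#'
#' @param config A [train_config()].
#' @param label_set Character vector of BIO labels (O first).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `gat_tagger` model object.
#' @export
init_tagger <- function(config, label_set, seed = config$seed) {
  f0 <- input_width(config)
  params <- init_gat_params(f0, config$gat, seed = seed)
  f_rep <- config$gat$heads * config$gat$units
  k <- length(label_set)
  lim <- sqrt(6 / (f_rep + k))
  cls <- with_private_seed(seed + 1L,
                           matrix(runif(f_rep * k, -lim, lim), f_rep, k))
  params[["cls.W"]] <- cls
  params[["cls.b"]] <- numeric(k)
  structure(list(params = params, config = config, label_set = label_set),
            class = "gat_tagger")
}

#' @export
print.gat_tagger <- function(x, ...) {
  cfg <- x$config$gat
  cat(sprintf("<gat_tagger: %d layers x %d heads x %d units, %d labels, input %d>\n",
              cfg$layers, cfg$heads, cfg$units, length(x$label_set),
              input_width(x$config)))
  invisible(x)
}

softmax_rows <- function(x) {
  mx <- apply(x, 1L, max)
  ex <- exp(x - mx)
  ex / rowSums(ex)
}

#' Per-node label probabilities for a parsed sentence
#'
#' Runs the stacked GAT on the sentence graph and applies the softmax
#' decoder; rows are graph nodes (CLS and SEP included), columns the
#' model's label set.
#'
#' @param model A `gat_tagger`.
#' @param sentence A parsed `ner_sentence` (or a prepared instance).
#' @return Numeric matrix `n` x `K` with rows summing to 1.
#' @export
forward_probs <- function(model, sentence) {
  inst <- if (inherits(sentence, "ner_sentence"))
    make_instance(sentence, model$config) else sentence
  fw <- gat_forward_cache(inst$h0, model$params, model$config$gat,
                          inst$graph$adjacency)
  logits <- fw$rep %*% model$params[["cls.W"]] +
    matrix(model$params[["cls.b"]], nrow(fw$rep), length(model$label_set),
           byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- model$label_set
  p
}

# Mean cross-entropy over supervised nodes of a batch, with gradients
# for every parameter.  Instances must carry targets.
loss_and_grad <- function(model, instances) {
  params <- model$params
  config <- model$config
  k <- length(model$label_set)
  grads <- lapply(params, function(p) p * 0)
  loss_sum <- 0
  n_sup <- sum(vapply(instances, function(i) sum(i$supervised), 0L))
  if (n_sup == 0L) stop("no supervised nodes in batch")
  for (inst in instances) {
    fw <- gat_forward_cache(inst$h0, params, config$gat,
                            inst$graph$adjacency)
    logits <- fw$rep %*% params[["cls.W"]] +
      matrix(params[["cls.b"]], nrow(fw$rep), k, byrow = TRUE)
    p <- softmax_rows(logits)
    sup <- which(inst$supervised)
    tgt <- inst$targets[sup]
    loss_sum <- loss_sum - sum(log(pmax(p[cbind(sup, tgt)], 1e-12)))
    y <- matrix(0, nrow(p), k)
    y[cbind(sup, tgt)] <- 1
    dlogits <- (p - y) / n_sup
    dlogits[-sup, ] <- 0
    grads[["cls.W"]] <- grads[["cls.W"]] + t(fw$rep) %*% dlogits
    grads[["cls.b"]] <- grads[["cls.b"]] + colSums(dlogits)
    d_rep <- dlogits %*% t(params[["cls.W"]])
    bk <- gat_backward(d_rep, params, config$gat, inst$graph$adjacency, fw)
    for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
  }
  if (!is.finite(loss_sum)) stop("non-finite training loss")
  list(loss = loss_sum / n_sup, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, clip = 1.0,
                      weight_decay = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > clip)
    grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) -
      lr * weight_decay * params[[nm]]   # decoupled decay
  }
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the graph attention tagger
#'
#' Minimizes mean cross-entropy over supervised nodes (CLS/SEP are
#' excluded; continuation pieces take their word's label in `I-` form)
#' with Adam, seeded end to end: two runs with the same corpus, config
#' and seed produce identical parameters.  When a dev set is given,
#' entity-level F1 is computed each epoch and the best-dev parameters
#' are retained (early stopping on `config$patience`).
#'
#' @param corpus List of parsed, labeled `ner_sentence` objects.
#' @param config A [train_config()].
#' @param dev Optional dev corpus for early stopping.
#' @param log_path Optional JSONL file receiving one record per epoch
#'   (`epoch`, `loss`, dev `precision`/`recall`/`f1`, `seed`).
#' @param verbose Print per-epoch progress.
#' @return A trained `gat_tagger` with a `log` data.frame attached.
#' @export
train_tagger <- function(corpus, config = train_config(), dev = NULL,
                         log_path = NULL, verbose = FALSE) {
  if (length(corpus) == 0L) stop("empty training corpus")
  label_set <- corpus_label_set(corpus)
  corpus <- unlist(lapply(corpus, split_to_msl, msl = config$msl),
                   recursive = FALSE)
  instances <- lapply(corpus, make_instance, config = config,
                      label_set = label_set)
  model <- init_tagger(config, label_set)
  state <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    dev_precision = numeric(0), dev_recall = numeric(0),
                    dev_f1 = numeric(0))
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  con <- if (!is.null(log_path)) file(log_path, open = "wb") else NULL
  if (!is.null(con)) on.exit(close(con))
  with_private_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(instances))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$bs)) {
        batch <- instances[ord[start:min(start + config$bs - 1L, length(ord))]]
        if (config$gat$dropout > 0) {
          keep <- 1 - config$gat$dropout
          batch <- lapply(batch, function(inst) {
            mask <- matrix(rbinom(length(inst$h0), 1L, keep) / keep,
                           nrow(inst$h0))
            inst$h0 <- inst$h0 * mask
            inst
          })
        }
        if (config$word_dropout > 0 && config$feature_set != "synt") {
          d <- config$encoder$d
          d_pe <- if (config$encoder$positional) min(8L, d %/% 2L) else 0L
          hash_cols <- seq_len(d - d_pe)
          batch <- lapply(batch, function(inst) {
            wi <- inst$graph$nodes$word_index
            words <- unique(wi[!is.na(wi)])
            blank <- words[runif(length(words)) < config$word_dropout]
            if (length(blank))
              inst$h0[wi %in% blank, hash_cols] <- 0
            inst
          })
        }
        lg <- loss_and_grad(model, batch)
        up <- adam_step(model$params, lg$grads, state, config$lr,
                        config$clip, config$weight_decay)
        model$params <- up$params; state <- up$state
        losses <- c(losses, lg$loss)
      }
      dev_prf <- c(NA_real_, NA_real_, NA_real_)
      if (!is.null(dev)) {
        preds <- lapply(dev, predict_words, model = model)
        sc <- score_entities(lapply(dev, `[[`, "labels"), preds)
        dev_prf <- c(sc$precision, sc$recall, sc$f1)
        if (sc$f1 > best$f1)
          best <- list(f1 = sc$f1, params = model$params, epoch = epoch)
      }
      log[nrow(log) + 1L, ] <- c(epoch, mean(losses), dev_prf)
      if (!is.null(con))
        writeLines(jsonlite::toJSON(list(epoch = epoch,
                                         loss = mean(losses),
                                         dev_precision = dev_prf[1],
                                         dev_recall = dev_prf[2],
                                         dev_f1 = dev_prf[3],
                                         seed = config$seed),
                                    auto_unbox = TRUE, na = "null",
                                    digits = 8), con)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f%s", epoch, mean(losses),
                        if (!is.null(dev))
                          sprintf(", dev F1 %.3f", dev_prf[3]) else ""))
      if (!is.null(dev) && epoch - best$epoch >= config$patience) break
    }
  })
  if (!is.null(dev) && is.finite(best$f1)) model$params <- best$params
  model$log <- log
  model
}

# ---- prediction ------------------------------------------------------------

#' Predict word-level BIO labels for a sentence
#'
#' Per-node argmax of the softmax decoder (ties resolved toward the
#' lowest label index); each word takes the label of its first piece,
#' CLS/SEP are discarded, and the sequence is made grammar-valid with
#' [repair_bio()].
#'
#' @param sentence A parsed `ner_sentence`.
#' @param model A trained `gat_tagger`.
#' @return Character vector of IOB2 labels, one per word.
#' @export
predict_words <- function(sentence, model) {
  chunks <- split_to_msl(sentence, model$config$msl)
  labs <- unlist(lapply(chunks, function(ch) {
    inst <- make_instance(ch, model$config)
    p <- forward_probs(model, inst)
    node_lab <- model$label_set[apply(p, 1L, which.max)]
    node_lab[inst$first_piece]
  }))
  repair_bio(unname(labs))
}

#' Repair an illegal BIO sequence
#'
#' The softmax decoder classifies nodes independently and can emit an
#' `I-` tag with no opener; any `I-X` not preceded by `B-X` or `I-X` is
#' rewritten to `B-X`.  The result is grammar-valid and the operation is
#' idempotent; `O` tags and entity types are never changed.
#'
#' @param labels Character vector of BIO tags.
#' @return Repaired character vector.
#' @export
#' @examples
#' repair_bio(c("O", "I-Chemical"))
repair_bio <- function(labels) {
  out <- labels
  prev <- "O"
  for (i in seq_along(out)) {
    if (startsWith(out[i], "I-")) {
      typ <- substring(out[i], 3)
      if (!(prev %in% paste0(c("B-", "I-"), typ)))
        out[i] <- paste0("B-", typ)
    }
    prev <- out[i]
  }
  out
}

# ---- checkpoints -----------------------------------------------------------

#' Save a trained tagger as a versioned JSON checkpoint
#' @param model A `gat_tagger`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "gatner-model-v1",
    label_set = model$label_set,
    config = serialize_config(model$config),
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a tagger checkpoint written by [save_model()]
#' @param path Checkpoint file path.
#' @return A `gat_tagger` ready for inference.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "gatner-model-v1"))
    stop("unrecognized checkpoint format")
  params <- lapply(x$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = deserialize_config(x$config),
                 label_set = x$label_set),
            class = "gat_tagger")
}

serialize_config <- function(config) {
  list(msl = config$msl, bs = config$bs, lr = config$lr,
       epochs = config$epochs, seed = config$seed,
       gat = unclass(config$gat),
       encoder = list(kind = config$encoder$kind, d = config$encoder$d,
                      seed = config$encoder$seed),
       inventory = list(pos_tags = config$inventory$pos_tags,
                        dep_relations = config$inventory$dep_relations,
                        threshold = config$inventory$threshold),
       feature_set = config$feature_set, synt_blocks = config$synt_blocks,
       clip = config$clip, weight_decay = config$weight_decay,
       word_dropout = config$word_dropout,
       patience = config$patience,
       continuation_pos_inherit = config$continuation_pos_inherit)
}

deserialize_config <- function(x) {
  train_config(msl = x$msl, bs = x$bs, lr = x$lr, epochs = x$epochs,
               seed = x$seed,
               gat = do.call(gat_config, x$gat),
               encoder = encoder_spec(x$encoder$kind, x$encoder$d,
                                      x$encoder$seed),
               inventory = tag_inventory(x$inventory$pos_tags,
                                         x$inventory$dep_relations,
                                         x$inventory$threshold),
               feature_set = x$feature_set, synt_blocks = x$synt_blocks,
               clip = x$clip, weight_decay = x$weight_decay %||% 0,
               word_dropout = x$word_dropout %||% 0,
               patience = x$patience,
               continuation_pos_inherit = x$continuation_pos_inherit)
}
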