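# Single entry point wiring simulate -> encode -> train -> predict ->
# evaluate, with YAML configs, seeds, structured JSONL logs and a run
# manifest per stage.

# key sets accepted per command (schema validation)
.schema <- list(
  simulate = c("n_sentences", "len_min", "len_max", "rho", "epsilon",
               "multiword_prob", "seed", "entity_type", "splits", "out"),
  encode = c("data", "out", "encoder_d", "encoder_seed", "self_loops"),
  train = c("data", "out", "seed", "msl", "bs", "lr", "epochs", "layers",
            "heads", "units", "dropout", "encoder_d", "encoder_seed",
            "feature_set", "synt_blocks", "clip", "weight_decay",
            "word_dropout", "patience"),
  predict = c("model", "data", "out"),
  evaluate = c("gold", "pred", "out"))

validate_config <- function(command, config) {
  unknown <- setdiff(names(config), .schema[[command]])
  if (length(unknown))
    stop(sprintf("unknown config key(s) for '%s': %s", command,
                 paste(unknown, collapse = ", ")))
  config
}

# deterministic hash of a config list (for the run manifest)
config_hash <- function(config) {
  ser <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%x", string_hash(ser))
}

file_digest <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  sprintf("%x", string_hash(paste(readLines(path, warn = FALSE),
                                  collapse = "\n")))
}

write_manifest <- function(dir, command, config, inputs = character(0),
                           elapsed = NA_real_) {
  manifest <- list(command = command,
                   config_hash = config_hash(config),
                   config = config,
                   seed = config$seed %||% NA,
                   package_version = as.character(utils::packageVersion("gatner")),
                   input_digests = as.list(vapply(inputs, file_digest, "")),
                   elapsed_sec = round(elapsed, 3))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

train_config_from_yaml <- function(config) {
  train_config(
    msl = config$msl %||% 256L, bs = config$bs %||% 32L,
    lr = config$lr %||% 5e-5, epochs = config$epochs %||% 50L,
    seed = config$seed %||% 1L,
    gat = gat_config(layers = config$layers %||% 2L,
                     heads = config$heads %||% 12L,
                     units = config$units %||% 64L,
                     dropout = config$dropout %||% 0),
    encoder = encoder_spec("stub", d = config$encoder_d %||% 16L,
                           seed = config$encoder_seed %||%
                             (config$seed %||% 1L)),
    feature_set = config$feature_set %||% "cont+synt",
    synt_blocks = config$synt_blocks %||% "both",
    clip = config$clip %||% 1.0,
    weight_decay = config$weight_decay %||% 0,
    word_dropout = config$word_dropout %||% 0,
    patience = config$patience %||% 10L)
}

#' Run one pipeline stage
#'
#' Commands: `"simulate"` (generate a synthetic corpus), `"encode"`
#' (dump graphs and syntactic feature matrices for a corpus), `"train"`,
#' `"predict"` and `"evaluate"`.  Configuration comes from a YAML file
#' and/or an override list; unknown keys are rejected before any work
#' starts, and every stage writes a `manifest.json` (config hash, seed,
#' package version, input digests, timing) into its output directory.
#'
#' @param command One of simulate/encode/train/predict/evaluate.
#' @param config_path Optional YAML config file.
#' @param overrides Named list merged over the file config (e.g.
#'   `list(seed = 7)`).
#' @return The stage's main artifact, invisibly: the split list, the
#'   trained model, the prediction path, or the `ner_eval`.
#' @export
run_pipeline <- function(command = c("simulate", "encode", "train",
                                     "predict", "evaluate"),
                         config_path = NULL, overrides = list()) {
  command <- match.arg(command)
  config <- if (!is.null(config_path)) yaml::read_yaml(config_path) else list()
  config[names(overrides)] <- overrides
  config <- validate_config(command, config)
  t0 <- proc.time()[["elapsed"]]
  result <- switch(command,
    simulate = {
      out <- config$out %||% stop("simulate requires 'out'")
      cfg <- synthetic_config(
        n_sentences = config$n_sentences %||% 100L,
        len_min = config$len_min %||% 4L, len_max = config$len_max %||% 14L,
        rho = config$rho %||% 1, epsilon = config$epsilon %||% 0,
        multiword_prob = config$multiword_prob %||% 0.3,
        seed = config$seed %||% stop("simulate requires 'seed'"),
        entity_type = config$entity_type %||% "ENT",
        splits = unlist(config$splits %||%
                          list(train = 0.8, dev = 0.1, test = 0.1)))
      generate_corpus(cfg, out, force = TRUE)
    },
    encode = {
      out <- config$out %||% stop("encode requires 'out'")
      data <- config$data %||% stop("encode requires 'data'")
      if (!dir.exists(data)) stop(sprintf("missing input '%s'", data))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      corpus <- read_corpus_dir(data)
      inv <- default_inventory()
      for (nm in names(corpus)) {
        for (i in seq_along(corpus[[nm]])) {
          g <- sentence_graph(corpus[[nm]][[i]],
                              self_loops = config$self_loops %||% TRUE)
          write_graph_dump(g, file.path(out, sprintf("%s_%04d.graph", nm, i)))
          synt <- encode_sentence_syntax(g, inv)
          writeLines(apply(synt, 1L, paste, collapse = " "),
                     file.path(out, sprintf("%s_%04d.synt", nm, i)))
        }
      }
      invisible(out)
    },
    train = {
      out <- config$out %||% stop("train requires 'out'")
      data <- config$data %||% stop("train requires 'data'")
      if (!dir.exists(data)) stop(sprintf("missing input '%s'", data))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      corpus <- read_corpus_dir(data)
      tc <- train_config_from_yaml(config)
      model <- train_tagger(corpus$train, tc, dev = corpus$dev,
                            log_path = file.path(out, "train_log.jsonl"))
      save_model(model, file.path(out, "model.json"))
      model
    },
    predict = {
      model_dir <- config$model %||% stop("predict requires 'model'")
      data <- config$data %||% stop("predict requires 'data'")
      out <- config$out %||% stop("predict requires 'out'")
      mp <- file.path(model_dir, "model.json")
      if (!file.exists(mp)) stop(sprintf("missing input '%s'", mp))
      if (!file.exists(data)) stop(sprintf("missing input '%s'", data))
      model <- load_model(mp)
      sentences <- read_conllu(data)
      preds <- lapply(sentences, predict_words, model = model)
      dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
      write_predictions(sentences, preds, out)
      out
    },
    evaluate = {
      gold <- config$gold %||% stop("evaluate requires 'gold'")
      pred <- config$pred %||% stop("evaluate requires 'pred'")
      for (f in c(gold, pred))
        if (!file.exists(f)) stop(sprintf("missing input '%s'", f))
      evaluate_files(gold, pred, config$out)
    })
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest_dir <- switch(command,
    simulate = config$out, encode = config$out, train = config$out,
    predict = dirname(config$out), evaluate = NULL)
  if (!is.null(manifest_dir)) {
    inputs <- switch(command,
      predict = config$data,
      train = file.path(config$data, c("train.bio", "train.conllu")),
      character(0))
    write_manifest(manifest_dir, command, config, inputs, elapsed)
  }
  invisible(result)
}

#' Named hyperparameter presets for the benchmark corpora
#'
#' Returns the per-dataset defaults (max sequence length, batch size,
#' learning rate, GAT layers/heads/units) shipped with the package for
#' the eight benchmark corpora.  Full-scale runs additionally need an
#' external contextual encoder and parser; the presets document the
#' reference configuration.
#'
#' @param dataset One of `"bc2gm"`, `"bc4chemd"`, `"bc5cdr_chem"`,
#'   `"bc5cdr_disease"`, `"ncbi_disease"`, `"jnlpba"`, `"linnaeus"`,
#'   `"species_800"`.
#' @return A named list of hyperparameters.
#' @export
preset_config <- function(dataset) {
  path <- system.file("presets", paste0(dataset, ".yaml"),
                      package = "gatner")
  if (!nzchar(path))
    stop(sprintf("no preset '%s'", dataset))
  yaml::read_yaml(path)
}
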