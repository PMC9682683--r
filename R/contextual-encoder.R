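# Polynomial rolling hash of a string, returned as a non-negative double
# below 2^31 (stable across platforms; doubles hold the products exactly).
string_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(enc2utf8(x)))
    h <- (h * 127 + b) %% 2147483647
  h
}

# run expr with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic hash embeddings for token surfaces
#'
#' Desk-scale stand-in for a pre-trained contextual encoder: each distinct
#' surface form is mapped to a fixed unit-norm Gaussian vector seeded by a
#' hash of the surface and the global seed.  Identical surfaces give
#' identical rows; the caller's RNG state is left untouched.
#'
#' @param surfaces Character vector of token surfaces.
#' @param d Embedding dimension (default 16).
#' @param seed Integer seed mixed into every row's hash.
#' @return Numeric matrix `length(surfaces)` x `d` with unit-norm rows.
#' @export
hash_embed <- function(surfaces, d = 16L, seed = 0L) {
  stopifnot(d >= 1L)
  out <- matrix(0, length(surfaces), d)
  for (i in seq_along(surfaces)) {
    h <- (string_hash(surfaces[i]) + as.double(seed) * 97561) %% 2147483647
    row <- with_private_seed(as.integer(h), rnorm(d))
    out[i, ] <- row / sqrt(sum(row^2))
  }
  out
}

#' Contextual encoder specification
#'
#' The pipeline is agnostic to where contextual vectors come from.  The
#' built-in `"stub"` kind combines [hash_embed()] with sinusoidal word
#' position channels, emulating the two properties of a contextual
#' encoder the tagger relies on: distinct surfaces get distinct vectors,
#' and the same surface at different positions gets different vectors
#' (without word order no encoder can separate `B-` from `I-` tags at
#' span boundaries).  Kind `"external"` wraps any function (e.g. an
#' adapter around a pre-trained biomedical transformer's final hidden
#' layer) that maps the node surface list to an `n` x `d` matrix.
#'
#' @param kind `"stub"` or `"external"`.
#' @param d Embedding dimension (default 16 for the stub; a BioBERT-class
#'   adapter would use 768).
#' @param seed Stub seed.
#' @param fun For `kind = "external"`: `function(surfaces) -> matrix`.
#' @param positional For the stub: reserve `min(8, d/2)` trailing channels
#'   for the position encoding (default `TRUE`).
#' @param trainable Flag recorded for adapters that fine-tune upstream
#'   (the stub is always frozen).
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(kind = c("stub", "external"), d = 16L, seed = 0L,
                         fun = NULL, positional = TRUE, trainable = FALSE) {
  kind <- match.arg(kind)
  stopifnot(d >= 1L)
  if (kind == "external" && !is.function(fun))
    stop("external encoder requires `fun`")
  structure(list(kind = kind, d = as.integer(d), seed = as.integer(seed),
                 fun = fun, positional = isTRUE(positional),
                 trainable = isTRUE(trainable)),
            class = "encoder_spec")
}

#' Word position encoding
#'
#' First channel is the position itself on a 1/10 scale, so differences
#' of aggregated neighbor positions are linear in the features; the
#' remaining channels are sine/cosine pairs at dyadic frequencies
#' `pi / 2^(k-1)` (the highest alternates sign between consecutive
#' positions).
#'
#' @param positions Integer vector of word positions.
#' @param d Number of channels.
#' @return Matrix `length(positions)` x `d`.
#' @export
position_encoding <- function(positions, d = 8L) {
  stopifnot(d >= 2L)
  out <- matrix(0, length(positions), d)
  out[, 1L] <- positions / 10
  n_pairs <- (d - 1L) %/% 2L
  omega <- pi / 2^(seq_len(n_pairs) - 1L)
  for (k in seq_len(n_pairs)) {
    out[, 2L * k] <- sin(positions * omega[k])
    out[, 2L * k + 1L] <- cos(positions * omega[k])
  }
  out
}

#' Contextual vectors for the nodes of a sentence graph
#'
#' Returns one `d`-vector per graph node (CLS and SEP included), aligned
#' 1:1 with the node list from [align_wordpieces()].
#'
#' @param graph A `sentence_graph` (or any object with a `nodes$surface`
#'   column).
#' @param spec An [encoder_spec()].
#' @return Numeric matrix `n` x `d`.
#' @export
encode_context <- function(graph, spec = encoder_spec()) {
  surfaces <- graph$nodes$surface
  m <- if (spec$kind == "stub") {
    emb <- hash_embed(surfaces, spec$d, spec$seed)
    d_pe <- min(8L, spec$d %/% 2L)
    if (spec$positional && d_pe >= 2L) {
      # word position per node; CLS sits before word 1, SEP after the last
      w <- graph$nodes$word_index
      w[graph$nodes$kind == "CLS"] <- 0L
      w[graph$nodes$kind == "SEP"] <- max(w, na.rm = TRUE) + 1L
      emb[, spec$d - d_pe + seq_len(d_pe)] <- position_encoding(w, d_pe)
    }
    emb
  } else {
    spec$fun(surfaces)
  }
  m <- as.matrix(m)
  if (nrow(m) != length(surfaces) || ncol(m) != spec$d)
    stop(sprintf("encoder returned %d x %d but %d x %d nodes expected",
                 nrow(m), ncol(m), length(surfaces), spec$d))
  if (!all(is.finite(m))) stop("encoder returned non-finite values")
  m
}

#' Concatenate contextual and syntactic feature matrices
#'
#' Row-wise concatenation `[Cont || Synt]`; the result is the initial
#' node attribute matrix fed to the graph attention stack.
#'
#' @param cont Numeric matrix `n` x `d` of contextual vectors.
#' @param synt Numeric matrix `n` x 54 of syntactic vectors.
#' @return Numeric matrix `n` x `(d + 54)`.
#' @export
concat_features <- function(cont, synt) {
  if (nrow(cont) != nrow(synt))
    stop(sprintf("row mismatch: %d contextual vs %d syntactic rows",
                 nrow(cont), nrow(synt)))
  cbind(cont, synt)
}
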