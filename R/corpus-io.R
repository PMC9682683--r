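#' Sentence container for parsed, BIO-labeled text
#'
#' A sentence is an ordered token sequence with optional part-of-speech
#' tags, a dependency parse (one head per word, head 0 marking the root),
#' and optional gold BIO labels.  Word indices are 1-based throughout the
#' package.
#'
#' @param surfaces Character vector of token surface forms.
#' @param id Sentence identifier.
#' @param pos Optional character vector of POS tags, one per word.
#' @param heads Optional integer vector of head indices (0 = root).
#' @param rels Optional character vector of dependency relation labels.
#' @param labels Optional character vector of BIO labels.
#' @return An object of class `ner_sentence`.
#' @export
#' @examples
#' s <- ner_sentence(c("IL", "-", "2"), pos = c("NOUN", "PUNCT", "NUM"),
#'                   heads = c(0L, 1L, 1L), rels = c("root", "punct", "nummod"))
#' n_words(s)
ner_sentence <- function(surfaces, id = "s1", pos = NULL, heads = NULL,
                         rels = NULL, labels = NULL) {
  surfaces <- as.character(surfaces)
  n <- length(surfaces)
  if (n == 0L) stop("a sentence must contain at least one token")
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n)
      stop(sprintf("%s has length %d but sentence has %d tokens",
                   what, length(x), n))
  }
  check_len(pos, "pos"); check_len(heads, "heads")
  check_len(rels, "rels"); check_len(labels, "labels")
  if (!is.null(heads)) {
    heads <- as.integer(heads)
    if (anyNA(heads) || any(heads < 0L) || any(heads > n))
      stop("head indices must lie in 0..n")
  }
  if (!is.null(labels)) validate_bio(labels)
  structure(list(id = as.character(id), surface = surfaces, pos = pos,
                 heads = heads, rels = rels, labels = labels),
            class = "ner_sentence")
}

#' @export
print.ner_sentence <- function(x, ...) {
  cat(sprintf("<ner_sentence '%s': %d tokens%s%s>\n", x$id,
              length(x$surface),
              if (!is.null(x$heads)) ", parsed" else "",
              if (!is.null(x$labels)) ", labeled" else ""))
  invisible(x)
}

#' Number of words in a sentence
#' @param sentence An `ner_sentence`.
#' @return Integer word count.
#' @export
n_words <- function(sentence) length(sentence$surface)

#' Dependency triples of a parsed sentence
#'
#' Returns one row per (head, tail, relation) triple.  The root word has
#' no incoming triple here; locate it with `which(sentence$heads == 0)`.
#'
#' @param sentence A parsed `ner_sentence`.
#' @return A data.frame with columns `head`, `tail`, `relation`
#'   (1-based word indices).
#' @export
dependency_triples <- function(sentence) {
  if (is.null(sentence$heads)) stop("sentence has no dependency parse")
  keep <- sentence$heads > 0L
  data.frame(head = sentence$heads[keep],
             tail = seq_along(sentence$heads)[keep],
             relation = sentence$rels[keep],
             stringsAsFactors = FALSE)
}

# ---- BIO label grammar -----------------------------------------------------

#' Validate a BIO (IOB2) label sequence
#'
#' Checks that every tag is `O`, `B-<type>` or `I-<type>` and that every
#' `I-` continues a span of the same type opened by `B-` (IOB2 grammar).
#'
#' @param labels Character vector of tags.
#' @param strict If `TRUE` (default) an `I-` tag that does not continue a
#'   same-type span is an error; if `FALSE` only the tag lexicon is checked.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_bio <- function(labels, strict = TRUE) {
  ok <- grepl("^(O|[BI]-.+)$", labels)
  if (!all(ok))
    stop(sprintf("illegal BIO tag(s): %s",
                 paste(unique(labels[!ok]), collapse = ", ")))
  if (strict) {
    prev <- c("O", labels[-length(labels)])
    bad <- startsWith(labels, "I-") &
      !(prev == paste0("B-", substring(labels, 3)) |
        prev == paste0("I-", substring(labels, 3)))
    if (any(bad))
      stop(sprintf("I- tag without matching opener at position(s) %s; run repair_bio()",
                   paste(which(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

# IOB1 -> IOB2: an I-X that does not continue a same-type span opens one.
iob1_to_iob2 <- function(labels) {
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

# ---- naive segmentation ----------------------------------------------------

#' Split raw text into sentences at periods
#'
#' Deliberately naive rule used for raw-text input: every period ends a
#' sentence.  The only exception is a decimal point flanked by digits,
#' which is kept inside its number.  Benchmark corpora arrive
#' pre-segmented, so this is a convenience for unsegmented text; no
#' abbreviation protection is attempted.
#'
#' @param text A character scalar.
#' @return Character vector of sentence strings (periods retained,
#'   surrounding whitespace trimmed); empty input gives `character(0)`.
#' @export
#' @examples
#' segment_sentences("Azotemia was found. Stress led to dysfunction.")
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(character(0))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_digit <- chars %in% as.character(0:9)
  cut <- logical(n)
  for (i in seq_len(n)) {
    if (chars[i] == "." &&
        !(i > 1L && i < n && is_digit[i - 1L] && is_digit[i + 1L]))
      cut[i] <- TRUE
  }
  starts <- c(1L, which(cut) + 1L)
  ends <- c(which(cut), n)
  keep <- starts <= ends
  segs <- substring(text, starts[keep], ends[keep])
  segs <- trimws(segs)
  segs[nzchar(segs)]
}

#' Split a sentence into word and symbol tokens
#'
#' Maximal runs of letters/digits form one token each; every other
#' non-whitespace character is its own token.
#'
#' @param sentence_text A character scalar.
#' @return Character vector of surface tokens.
#' @export
#' @examples
#' tokenize_words("tacrolimus (FK506) therapy")
tokenize_words <- function(sentence_text) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1L)
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", sentence_text)
  toks <- regmatches(sentence_text, m)[[1]]
  as.character(toks)
}

# ---- two-column BIO CoNLL dialect ------------------------------------------

#' Read a two-column BIO CoNLL file
#'
#' Each non-blank line is `token<sep>label` where `<sep>` is a tab or a
#' run of spaces; blank lines delimit sentences.  Labels are validated
#' against the IOB2 grammar.
#'
#' @param path File path.
#' @param iob1 If `TRUE`, input uses IOB1 and is converted to IOB2 on read.
#' @return List of `ner_sentence` objects with `labels` populated.
#' @export
read_bio_conll <- function(path, iob1 = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(0); labs <- character(0)
  flush <- function() {
    if (length(toks) == 0L) return()
    labs2 <- if (iob1) iob1_to_iob2(labs) else labs
    validate_bio(labs2)
    sentences[[length(sentences) + 1L]] <<-
      ner_sentence(toks, id = sprintf("s%d", length(sentences) + 1L),
                   labels = labs2)
    toks <<- character(0); labs <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(ln, "\t| +")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != 2L)
      stop(sprintf("line %d: expected 'token<sep>label', got %d field(s)",
                   i, length(fields)))
    toks <- c(toks, fields[1]); labs <- c(labs, fields[2])
  }
  flush()
  sentences
}

#' Write sentences with predicted labels in the two-column dialect
#'
#' Emits `token<TAB>label` lines with a blank line after each sentence;
#' output is deterministic (UTF-8, LF line endings).
#'
#' @param sentences List of `ner_sentence` objects.
#' @param predicted List of character label vectors, one per sentence; if
#'   `NULL` the sentences' own `labels` are written.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_predictions <- function(sentences, predicted = NULL, path) {
  if (is.null(predicted)) predicted <- lapply(sentences, `[[`, "labels")
  if (length(predicted) != length(sentences))
    stop("number of label sequences does not match number of sentences")
  out <- character(0)
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]; p <- predicted[[i]]
    if (length(p) != n_words(s))
      stop(sprintf("sentence %d: %d tokens but %d labels",
                   i, n_words(s), length(p)))
    out <- c(out, paste0(s$surface, "\t", p), "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# ---- CoNLL-U ---------------------------------------------------------------

#' Read a CoNLL-U dependency-parse file
#'
#' Consumes the ID, FORM, UPOS, HEAD and DEPREL columns; other columns
#' and comment lines are ignored.  Every sentence must be a single-root
#' tree: exactly one token with HEAD = 0 and all tokens reachable from it.
#'
#' @param path File path.
#' @return List of `ner_sentence` objects with `pos`, `heads`, `rels`.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  rows <- list()
  flush <- function() {
    if (length(rows) == 0L) return()
    n <- length(rows)
    form <- vapply(rows, `[`, "", 2)
    upos <- vapply(rows, `[`, "", 4)
    headc <- vapply(rows, `[`, "", 7)
    rel <- vapply(rows, `[`, "", 8)
    heads <- suppressWarnings(as.integer(headc))
    if (anyNA(heads))
      stop("non-integer HEAD field in CoNLL-U sentence")
    if (any(heads < 0L | heads > n))
      stop(sprintf("HEAD index out of range (sentence of %d tokens)", n))
    validate_parse_tree(heads)
    sentences[[length(sentences) + 1L]] <<-
      ner_sentence(form, id = sprintf("s%d", length(sentences) + 1L),
                   pos = upos, heads = heads, rels = rel)
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (grepl("[.-]", fields[1])) next  # multiword/empty-node lines
    if (length(fields) < 8L)
      stop(sprintf("line %d: expected >= 8 tab-separated fields, got %d",
                   i, length(fields)))
    rows[[length(rows) + 1L]] <- fields
  }
  flush()
  sentences
}

# Single root, no cycles, full reachability.
validate_parse_tree <- function(heads) {
  n <- length(heads)
  roots <- which(heads == 0L)
  if (length(roots) != 1L)
    stop(sprintf("invalid tree: %d roots (exactly 1 required)",
                 length(roots)))
  children <- split(seq_len(n), factor(heads, levels = 0:n))
  seen <- logical(n)
  stack <- roots
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[v]) stop("invalid tree: cycle detected")
    seen[v] <- TRUE
    kids <- children[[as.character(v)]]
    if (length(kids)) stack <- c(stack, kids)
  }
  if (!all(seen))
    stop("invalid tree: cycle detected (nodes unreachable from root)")
  invisible(TRUE)
}

#' Write parsed sentences as CoNLL-U
#'
#' Emits the 10-column format with ID, FORM, UPOS, HEAD and DEPREL
#' populated and `_` elsewhere.
#'
#' @param sentences List of parsed `ner_sentence` objects.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_conllu <- function(sentences, path) {
  out <- character(0)
  for (s in sentences) {
    if (is.null(s$heads)) stop("sentence has no dependency parse")
    n <- n_words(s)
    pos <- if (is.null(s$pos)) rep("_", n) else s$pos
    out <- c(out,
             paste(seq_len(n), s$surface, "_", pos, "_", "_",
                   s$heads, s$rels, "_", "_", sep = "\t"),
             "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}
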