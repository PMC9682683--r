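# Retained tag inventories: POS and dependency labels whose corpus
# frequency among biomedical entity mentions clears a 1% threshold.
.default_pos <- c("NOUN", "PROPN", "PUNCT", "NUM", "ADJ", "VERB", "SYM",
                  "CCONJ", "ADP", "PART")
.default_dep <- c("compound", "punct", "nmod", "amod", "pobj", "conj",
                  "appos", "det", "nummod", "npadvmod", "cc", "nsubj",
                  "dobj", "prep", "nsubjpass", "acl", "root", "case")
.pos_special <- c("OTHERS", "CLS", "SEP", "X")
.dep_special <- c("others", "next")

#' Construct a tag inventory for the one-hot syntactic encoding
#'
#' The inventory fixes the slot order of the syntactic feature vector:
#' retained POS labels followed by the `OTHERS`/`CLS`/`SEP`/`X` extension
#' tags, and retained dependency relations followed by `others` and
#' `next`, each dependency split into an in-degree and an out-degree
#' slot.  With the defaults (10 POS, 18 relations) the encoded vector has
#' (10+4) + 2*(18+2) = 54 dimensions.
#'
#' @param pos_tags Character vector of retained POS labels.
#' @param dep_relations Character vector of retained dependency labels.
#' @param threshold Frequency fraction used to select the labels
#'   (recorded for provenance; see [select_salient_tags()]).
#' @return A `tag_inventory` object.
#' @export
tag_inventory <- function(pos_tags = .default_pos,
                          dep_relations = .default_dep,
                          threshold = 0.01) {
  if (anyDuplicated(pos_tags) || anyDuplicated(dep_relations))
    stop("inventory labels must be unique")
  if (any(pos_tags %in% .pos_special) || any(dep_relations %in% .dep_special))
    stop("extension tag names are reserved")
  structure(list(pos_tags = as.character(pos_tags),
                 dep_relations = as.character(dep_relations),
                 threshold = threshold, version = 1L),
            class = "tag_inventory")
}

#' Default tag inventory
#' @return The `tag_inventory` with the 10 retained POS labels and the 18
#'   retained dependency relations.
#' @export
default_inventory <- function() tag_inventory()

#' @export
print.tag_inventory <- function(x, ...) {
  cat(sprintf("<tag_inventory v%d: %d POS + %d dependency labels, threshold %g>\n",
              x$version, length(x$pos_tags), length(x$dep_relations),
              x$threshold))
  invisible(x)
}

#' Dimensionality of the syntactic vector under an inventory
#' @param inventory A `tag_inventory`.
#' @return Integer vector length: `(|POS|+4) + 2*(|dep|+2)`.
#' @export
synt_dim <- function(inventory = default_inventory()) {
  pos_block_size(inventory) + 2L * dep_block_size(inventory)
}

pos_block_size <- function(inventory) length(inventory$pos_tags) + 4L
dep_block_size <- function(inventory) length(inventory$dep_relations) + 2L

#' Select salient labels by corpus frequency
#'
#' Labels whose frequency fraction reaches `threshold` are retained, in
#' descending-frequency order; all others fall into the catch-all class
#' at encoding time.
#'
#' @param freq Named numeric vector of frequency fractions in `[0, 1]`.
#' @param threshold Retention threshold (default 0.01, i.e. 1%).
#' @return Character vector of retained labels.
#' @export
#' @examples
#' select_salient_tags(c(NOUN = 0.4, INTJ = 0.002), threshold = 0.01)
select_salient_tags <- function(freq, threshold = 0.01) {
  if (any(freq < 0)) stop("frequencies must be non-negative")
  if (any(freq > 1)) stop("frequencies are fractions in [0, 1]")
  kept <- freq[freq >= threshold]
  names(kept)[order(-kept)]
}

#' One-hot POS block of the syntactic vector
#'
#' @param tag POS label (ignored when `special` is set).
#' @param inventory A `tag_inventory`.
#' @param special One of `"none"`, `"CLS"`, `"SEP"`, `"X"`: graph nodes
#'   that are not first pieces of a word take their special tag instead
#'   of a POS label.
#' @return Binary vector of length `|POS| + 4` with exactly one bit set;
#'   tags outside the inventory map to the `OTHERS` slot.
#' @export
encode_pos <- function(tag, inventory = default_inventory(),
                       special = c("none", "CLS", "SEP", "X")) {
  special <- match.arg(special)
  slots <- c(inventory$pos_tags, .pos_special)
  v <- numeric(length(slots))
  slot <- if (special != "none") special
          else if (!is.null(tag) && !is.na(tag) && tag %in% inventory$pos_tags) tag
          else "OTHERS"
  v[match(slot, slots)] <- 1
  v
}

#' Dependency degree block of the syntactic vector
#'
#' Each relation occupies two slots: an in-degree slot set when the node
#' is the tail of a triple with that relation, and an out-degree slot set
#' when it is the head.  A triple with `head = 0` marks the parse root
#' and sets only the in-degree slot of its relation on the tail.  A
#' `next` pair `(k, k+1)` sets next-out on `k` and next-in on `k+1`.
#' Bits are binary: repeated relations do not increment.
#'
#' @param node Node index the block is computed for.
#' @param triples data.frame with `head`, `tail`, `relation` over node
#'   indices (`head = 0` allowed for the root).
#' @param next_edges Integer matrix with columns `from`, `to` (may be
#'   `NULL`).
#' @param inventory A `tag_inventory`.
#' @return Binary vector of length `2 * (|dep| + 2)`, in-block first.
#' @export
encode_dependencies <- function(node, triples = NULL, next_edges = NULL,
                                inventory = default_inventory()) {
  slots <- c(inventory$dep_relations, .dep_special)
  k <- length(slots)
  inb <- numeric(k); outb <- numeric(k)
  slot_of <- function(rel)
    if (rel %in% inventory$dep_relations) match(rel, slots)
    else match("others", slots)
  if (!is.null(triples) && nrow(triples) > 0L) {
    for (l in seq_len(nrow(triples))) {
      s <- slot_of(triples$relation[l])
      if (triples$tail[l] == node) inb[s] <- 1
      if (triples$head[l] == node) outb[s] <- 1
    }
  }
  if (!is.null(next_edges) && NROW(next_edges) > 0L) {
    nx <- match("next", slots)
    if (any(next_edges[, 2] == node)) inb[nx] <- 1
    if (any(next_edges[, 1] == node)) outb[nx] <- 1
  }
  c(inb, outb)
}

#' Full one-hot syntactic vector for one node
#'
#' Concatenation `[POS block | in-degree block | out-degree block]`;
#' 54-dimensional with the default inventory.
#'
#' @inheritParams encode_pos
#' @inheritParams encode_dependencies
#' @return Binary vector of length [synt_dim()].
#' @export
encode_syntactic <- function(tag, node, triples = NULL, next_edges = NULL,
                             inventory = default_inventory(),
                             special = c("none", "CLS", "SEP", "X")) {
  c(encode_pos(tag, inventory, special),
    encode_dependencies(node, triples, next_edges, inventory))
}

#' Syntactic feature matrix for a sentence graph
#'
#' Applies the one-hot encoding to every node of a [sentence_graph()].
#' Wordpiece inheritance: every piece carries the dependency bits of its
#' originating word (the parse root contributes a root in-degree bit),
#' `next` bits are added to the pieces they touch, the first piece keeps
#' the word's POS while continuation pieces take the `X` tag (unless
#' `continuation_pos_inherit` is on), and CLS/SEP nodes carry only their
#' own POS-block tag.
#'
#' @param graph A `sentence_graph`.
#' @param inventory A `tag_inventory`.
#' @param continuation_pos_inherit If `TRUE`, continuation pieces keep the
#'   word's POS label instead of `X`.
#' @return Numeric matrix `n` x [synt_dim()].
#' @export
encode_sentence_syntax <- function(graph, inventory = default_inventory(),
                                   continuation_pos_inherit = FALSE) {
  s <- graph$sentence
  nw <- n_words(s)
  triples <- dependency_triples(s)
  root <- which(s$heads == 0L)
  triples <- rbind(triples,
                   data.frame(head = 0L, tail = root,
                              relation = s$rels[root],
                              stringsAsFactors = FALSE))
  # word-level degree bits, inherited by every piece of the word
  word_dep <- t(vapply(seq_len(nw), function(w)
    encode_dependencies(w, triples, NULL, inventory),
    numeric(2L * dep_block_size(inventory))))
  nodes <- graph$nodes
  out <- matrix(0, graph$n, synt_dim(inventory))
  for (i in seq_len(graph$n)) {
    kind <- nodes$kind[i]
    if (kind %in% c("CLS", "SEP")) {
      out[i, ] <- encode_syntactic(NULL, i, NULL, NULL, inventory,
                                   special = kind)
      next
    }
    w <- nodes$word_index[i]
    special <- if (nodes$is_continuation[i] && !continuation_pos_inherit)
      "X" else "none"
    pos <- encode_pos(s$pos[w], inventory, special)
    dep <- word_dep[w, ]
    nx <- encode_dependencies(i, NULL, graph$next_edges, inventory)
    out[i, ] <- c(pos, pmin(dep + nx, 1))
  }
  out
}

#' Write a tag inventory to a YAML file
#' @param inventory A `tag_inventory`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_inventory <- function(inventory, path) {
  yaml::write_yaml(unclass(inventory), path)
  invisible(path)
}

#' Read a tag inventory from a YAML file
#' @param path File path written by [write_inventory()].
#' @return A `tag_inventory`.
#' @export
read_inventory <- function(path) {
  x <- yaml::read_yaml(path)
  inv <- tag_inventory(x$pos_tags, x$dep_relations, x$threshold)
  inv$version <- x$version
  inv
}
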