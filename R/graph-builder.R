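#' Deterministic sub-word splitter
#'
#' Splits each surface form into fixed-width sub-word pieces, marking
#' continuation pieces with the conventional `##` prefix.  This is a
#' deterministic stand-in for a transformer wordpiece tokenizer: it
#' exercises the same alignment machinery (piece nodes, `next` links,
#' feature inheritance) without a learned vocabulary.
#'
#' @param surfaces Character vector of word surface forms.
#' @param max_piece Maximum characters per piece (default 6).
#' @return List (one element per word) of character vectors of pieces.
#' @export
#' @examples
#' wordpiece_split(c("dyskinesia", "to"))
wordpiece_split <- function(surfaces, max_piece = 6L) {
  stopifnot(max_piece >= 1L)
  lapply(surfaces, function(w) {
    nc <- nchar(w)
    if (nc <= max_piece) return(w)
    starts <- seq(1L, nc, by = max_piece)
    pieces <- substring(w, starts, pmin(starts + max_piece - 1L, nc))
    c(pieces[1], paste0("##", pieces[-1]))
  })
}

#' Align sub-word pieces to words and add CLS/SEP nodes
#'
#' Produces the node list of the sentence graph: one `[CLS]` node, one
#' node per sub-word piece in order, and one `[SEP]` node.  Consecutive
#' pieces of the same word are linked by a directed `next` edge, and each
#' piece records the word it descends from so that syntactic features can
#' be inherited.
#'
#' @param sentence An `ner_sentence`.
#' @param pieces Per-word list of piece surface vectors, as produced by
#'   [wordpiece_split()]; defaults to splitting `sentence` itself.
#' @return A list with elements
#'   `nodes` (data.frame: `surface`, `kind` in CLS/piece/SEP,
#'   `word_index`, `is_continuation`), and
#'   `next_edges` (integer matrix, columns `from`, `to`, node indices).
#' @export
align_wordpieces <- function(sentence, pieces = wordpiece_split(sentence$surface)) {
  nw <- n_words(sentence)
  if (length(pieces) != nw)
    stop(sprintf("pieces cover %d words but sentence has %d",
                 length(pieces), nw))
  if (any(lengths(pieces) == 0L))
    stop("every word must yield at least one piece")
  surf <- c("[CLS]", unlist(pieces, use.names = FALSE), "[SEP]")
  word_index <- c(NA_integer_,
                  rep(seq_len(nw), lengths(pieces)),
                  NA_integer_)
  n <- length(surf)
  kind <- c("CLS", rep("piece", n - 2L), "SEP")
  is_cont <- logical(n)
  nxt_from <- integer(0); nxt_to <- integer(0)
  pos <- 2L  # first piece node
  for (w in seq_len(nw)) {
    k <- length(pieces[[w]])
    if (k > 1L) {
      idx <- pos + seq_len(k - 1L)
      is_cont[idx] <- TRUE
      nxt_from <- c(nxt_from, idx - 1L)
      nxt_to <- c(nxt_to, idx)
    }
    pos <- pos + k
  }
  list(nodes = data.frame(surface = surf, kind = kind,
                          word_index = word_index,
                          is_continuation = is_cont,
                          stringsAsFactors = FALSE),
       next_edges = cbind(from = nxt_from, to = nxt_to))
}

#' Build the binary symmetric adjacency matrix of a sentence graph
#'
#' Every supplied edge (dependency pair or `next` pair) sets both
#' `a[i, j]` and `a[j, i]` to 1: message passing is over an undirected
#' graph, while edge direction survives only in the feature encoding.
#' Duplicate edges collapse (entries are binary).
#'
#' @param n Node count.
#' @param edges Integer matrix with two columns of node indices (may have
#'   zero rows).
#' @param self_loops If `TRUE` (default) the diagonal is set to 1 so every
#'   node is its own neighbor.
#' @return An `n` x `n` binary symmetric matrix.
#' @export
build_adjacency <- function(n, edges = NULL, self_loops = TRUE) {
  stopifnot(n >= 1L)
  adj <- matrix(0, n, n)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges < 1L) || any(edges > n))
      stop("edge index out of range")
    adj[edges] <- 1
    adj[edges[, 2:1, drop = FALSE]] <- 1
  }
  if (self_loops) diag(adj) <- 1
  adj
}

#' Neighbor sets of a graph
#'
#' @param adjacency Binary symmetric adjacency matrix.
#' @return List of integer vectors, `N[[i]] = { j : a[i, j] = 1 }`.
#' @export
neighbor_sets <- function(adjacency) {
  apply(adjacency, 1L, function(row) which(row != 0), simplify = FALSE)
}

#' Build the full attributed sentence graph
#'
#' Combines wordpiece alignment and adjacency construction: node-level
#' edges are derived from the word-level dependency triples (every piece
#' of the head word linked to every piece of the tail word when
#' `inherit_adjacency` is on, first pieces only otherwise), plus the
#' `next` links between consecutive pieces.  CLS and SEP carry self-loops
#' only: no dependency triple involves them and the parse gives no reason
#' to wire them to the tree.
#'
#' @param sentence A parsed `ner_sentence`.
#' @param pieces Per-word piece list; defaults to [wordpiece_split()].
#' @param self_loops Put 1 on the diagonal (default `TRUE`).
#' @param inherit_adjacency If `TRUE` (default) continuation pieces attach
#'   to all dependency neighbors of their word, not only the first piece.
#' @return A `sentence_graph`: list with `n`, `nodes`, `next_edges`,
#'   `adjacency`, `neighbors`, `sentence`.
#' @export
sentence_graph <- function(sentence, pieces = wordpiece_split(sentence$surface),
                           self_loops = TRUE, inherit_adjacency = TRUE) {
  if (is.null(sentence$heads)) stop("sentence has no dependency parse")
  al <- align_wordpieces(sentence, pieces)
  nodes <- al$nodes
  n <- nrow(nodes)
  word_nodes <- split(seq_len(n), nodes$word_index)  # drops CLS/SEP (NA)
  first_node <- vapply(word_nodes, min, 1L)
  triples <- dependency_triples(sentence)
  edges <- al$next_edges
  if (nrow(triples) > 0L) {
    dep_edges <- do.call(rbind, lapply(seq_len(nrow(triples)), function(l) {
      h <- as.character(triples$head[l]); t <- as.character(triples$tail[l])
      if (inherit_adjacency)
        as.matrix(expand.grid(from = word_nodes[[h]], to = word_nodes[[t]]))
      else
        cbind(from = first_node[[h]], to = first_node[[t]])
    }))
    edges <- rbind(edges, dep_edges)
  }
  adj <- build_adjacency(n, edges, self_loops = self_loops)
  structure(list(n = n, nodes = nodes, next_edges = al$next_edges,
                 adjacency = adj, neighbors = neighbor_sets(adj),
                 sentence = sentence),
            class = "sentence_graph")
}

#' @export
print.sentence_graph <- function(x, ...) {
  cat(sprintf("<sentence_graph: %d nodes, %d undirected edges%s>\n",
              x$n, (sum(x$adjacency != 0) - sum(diag(x$adjacency) != 0)) / 2,
              if (any(diag(x$adjacency) != 0)) ", self-loops" else ""))
  invisible(x)
}

#' Dump a sentence graph as text
#'
#' Writes a versioned edge-list section followed by the dense adjacency
#' matrix, for debugging and external inspection.
#'
#' @param graph A `sentence_graph`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_graph_dump <- function(graph, path) {
  out <- c("# gatner graph dump v1",
           sprintf("# nodes: %d", graph$n),
           paste(graph$nodes$surface, graph$nodes$kind, sep = "\t"),
           "# edges (i j)")
  idx <- which(graph$adjacency != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  out <- c(out, paste(idx[, 1], idx[, 2]),
           "# adjacency",
           apply(graph$adjacency, 1L, paste, collapse = " "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}
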