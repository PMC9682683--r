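# Independent oracles used by the tests.  These deliberately re-derive
# results along different code paths than the package (per-node loops,
# streaming chunk detection, closed-form expectations) so agreement is
# informative.

# ---- brute-force graph attention (per-node, per-neighbor loops) ------------

bf_gat_layer <- function(h, params, layer, config, adj) {
  n <- nrow(h)
  out <- NULL
  for (m in seq_len(config$heads)) {
    W <- params[[sprintf("gat.l%d.h%d.W", layer, m)]]
    a <- params[[sprintf("gat.l%d.h%d.a", layer, m)]]
    fp <- ncol(W)
    hm <- matrix(0, n, fp)
    for (i in seq_len(n)) {
      ni <- which(adj[i, ] != 0)
      coef <- vapply(ni, function(j) {
        x <- sum(a * c(drop(h[i, ] %*% W), drop(h[j, ] %*% W)))
        if (x > 0) x else config$leaky_slope * x
      }, 0)
      w <- exp(coef - max(coef))
      w <- w / sum(w)
      s <- rep(0, fp)
      for (k in seq_along(ni))
        s <- s + w[k] * drop(h[ni[k], ] %*% W)
      hm[i, ] <- ifelse(s > 0, s, exp(s) - 1)
    }
    out <- cbind(out, hm)
  }
  out
}

bf_gat_stack <- function(h0, params, config, adj) {
  h <- h0
  for (l in seq_len(config$layers))
    h <- bf_gat_layer(h, params, l, config, adj)
  h
}

# random connected-ish graph + matching random parameters
random_gat_case <- function(n, heads, units, input_dim) {
  adj <- matrix(rbinom(n * n, 1L, 0.4), n, n)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  diag(adj) <- 1
  config <- gat_config(layers = 1L, heads = heads, units = units)
  params <- list()
  for (m in seq_len(heads)) {
    params[[sprintf("gat.l1.h%d.W", m)]] <-
      matrix(rnorm(input_dim * units), input_dim, units)
    params[[sprintf("gat.l1.h%d.a", m)]] <- rnorm(2 * units)
  }
  list(adj = adj, config = config, params = params,
       h = matrix(rnorm(n * input_dim), n, input_dim))
}

# ---- streaming chunk scorer (conlleval-style state machine) ----------------

oracle_chunks <- function(labels) {
  res <- character(0)
  start <- NA_integer_
  prev_tag <- "O"; prev_type <- ""
  for (i in seq_along(labels)) {
    lab <- labels[i]
    tag <- if (lab == "O") "O" else substring(lab, 1L, 1L)
    typ <- if (lab == "O") "" else substring(lab, 3L)
    ends <- prev_tag != "O" && (tag == "O" || tag == "B" || typ != prev_type)
    begins <- tag == "B" || (tag == "I" && (prev_tag == "O" || prev_type != typ))
    if (ends) {
      res <- c(res, paste(start, i - 1L, prev_type, sep = "|"))
      start <- NA_integer_
    }
    if (begins) start <- i
    prev_tag <- tag; prev_type <- typ
  }
  if (prev_tag != "O")
    res <- c(res, paste(start, length(labels), prev_type, sep = "|"))
  res
}

oracle_counts <- function(gold_list, pred_list) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold_list)) {
    g <- oracle_chunks(gold_list[[i]])
    p <- oracle_chunks(pred_list[[i]])
    tp <- tp + sum(p %in% g)
    fp <- fp + sum(!p %in% g)
    fn <- fn + sum(!g %in% p)
  }
  c(tp = tp, fp = fp, fn = fn)
}

# grammar-valid random BIO sequence over given types
random_bio <- function(n, types = c("Chem", "Dis")) {
  labs <- character(n)
  prev <- "O"
  for (i in seq_len(n)) {
    r <- runif(1)
    labs[i] <- if (prev == "O") {
      if (r < 0.6) "O" else paste0("B-", sample(types, 1L))
    } else {
      typ <- substring(prev, 3L)
      if (r < 0.4) "O"
      else if (r < 0.65) paste0("I-", typ)
      else paste0("B-", sample(types, 1L))
    }
    prev <- labs[i]
  }
  labs
}

# ---- closed-form expected entity rate of the generator ---------------------
# Exact for multiword_prob = 0 (no tree rewiring).  Derivation: a word is
# an entity either by the trigger motif (NOUN/PROPN tail of nsubj/dobj/
# nmod under a VERB head, selected w.p. rho), by one-level compound
# propagation from a selected trigger parent, or by epsilon noise; the
# three relation events are disjoint.  Head identity follows the
# generator's attachment law: word 2 attaches to the root, word i >= 3
# attaches to the root w.p. root_attach and uniformly otherwise.
analytic_entity_rate <- function(config) {
  w <- config$rel_weights
  pg <- config$pos_given_rel
  np <- c("NOUN", "PROPN")
  p_np_given <- function(rel) sum(pg[[rel]][names(pg[[rel]]) %in% np])
  q_verb <- sum(vapply(names(w), function(rel)
    w[[rel]] * sum(pg[[rel]][names(pg[[rel]]) == "VERB"]), 0))
  pv_root <- sum(config$root_pos[names(config$root_pos) == "VERB"])
  t_np <- sum(vapply(c("nsubj", "dobj", "nmod"), function(rel)
    w[[rel]] * p_np_given(rel), 0))
  p_comp_np <- w[["compound"]] * p_np_given("compound")
  ra <- config$root_attach
  p_par_root <- function(i) if (i == 2L) 1 else ra + (1 - ra) / (i - 1)
  p_trig <- function(j) {
    if (j < 2L) return(0)
    pr <- p_par_root(j)
    t_np * (pr * pv_root + (1 - pr) * q_verb)
  }
  rates <- vapply(config$len_min:config$len_max, function(n) {
    p_ent <- numeric(n)
    p_ent[1L] <- config$epsilon
    for (i in seq_len(n)[-1L]) {
      # parent index distribution of word i
      p_parent_trig <- if (i == 2L) 0 else {
        pr <- p_par_root(i)
        sum(vapply(2:(i - 1L), function(j) p_trig(j), 0)) *
          (1 - pr) / (i - 2L + (i == 2L))
      }
      p_rule <- config$rho * p_trig(i) +
        p_comp_np * config$rho * p_parent_trig
      p_ent[i] <- p_rule + (1 - p_rule) * config$epsilon
    }
    mean(p_ent)
  }, 0)
  mean(rates)
}

# plug-in mutual information between two binary vectors (nats)
binary_mi <- function(x, y) {
  mi <- 0
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) {
    pxy <- mean(x == a & y == b)
    if (pxy > 0) mi <- mi + pxy * log(pxy / (mean(x == a) * mean(y == b)))
  }
  mi
}
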