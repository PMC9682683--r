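# Multi-head graph attention over sentence graphs.
#
# Per head: coef_ij = LeakyReLU(a' [W h_i || W h_j]) for j in N_i,
# alpha = softmax over N_i, h'_i = ELU(sum_j alpha_ij W h_j); head
# outputs are concatenated, layers are stacked over the same graph.

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
d_leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
d_elu <- function(x) ifelse(x > 0, 1, exp(x))

#' Graph attention network configuration
#'
#' @param layers Number of stacked attention layers `L`.
#' @param heads Attention heads `M` per layer.
#' @param units Output units `F'` per head; a layer's output width is
#'   `M * units`.
#' @param leaky_slope Negative slope of the LeakyReLU applied to raw
#'   attention logits (default 0.2, the canonical value for this layer
#'   family).
#' @param self_loops Whether sentence graphs built for this model include
#'   self-loops, so each node attends to itself (default `TRUE`).
#' @param dropout Feature dropout probability applied to layer inputs
#'   during training (default 0 = off).
#' @return A `gat_config` object.
#' @export
gat_config <- function(layers = 2L, heads = 12L, units = 64L,
                       leaky_slope = 0.2, self_loops = TRUE, dropout = 0) {
  stopifnot(layers >= 1L, heads >= 1L, units >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 units = as.integer(units), leaky_slope = leaky_slope,
                 self_loops = isTRUE(self_loops), dropout = dropout),
            class = "gat_config")
}

# Glorot-uniform initialization of all heads of all layers.
# Returns a named flat list: gat.l<l>.h<m>.W (F x F'), gat.l<l>.h<m>.a (2F').
init_gat_params <- function(input_dim, config, seed = 1L) {
  params <- list()
  with_private_seed(seed, {
    f_in <- input_dim
    for (l in seq_len(config$layers)) {
      for (m in seq_len(config$heads)) {
        lim_w <- sqrt(6 / (f_in + config$units))
        lim_a <- sqrt(6 / (2 * config$units + 1))
        params[[sprintf("gat.l%d.h%d.W", l, m)]] <-
          matrix(runif(f_in * config$units, -lim_w, lim_w),
                 f_in, config$units)
        params[[sprintf("gat.l%d.h%d.a", l, m)]] <-
          runif(2 * config$units, -lim_a, lim_a)
      }
      f_in <- config$heads * config$units
    }
  })
  params
}

#' Masked attention logits for one head
#'
#' Computes `coef_ij = LeakyReLU(a' [W h_i || W h_j])` for neighbor pairs
#' and `-Inf` elsewhere, so that the subsequent softmax assigns zero
#' weight outside `N_i`.
#'
#' @param h Node attribute matrix `n` x `F`.
#' @param W Head transform `F` x `F'`.
#' @param a Attention vector of length `2 F'`.
#' @param adjacency Binary adjacency matrix defining the neighbor mask.
#' @param leaky_slope LeakyReLU negative slope.
#' @return List with `coef` (`n` x `n`, masked entries `-Inf`), plus the
#'   intermediates `z = h W` and raw logits `e` used by backpropagation.
#' @export
attention_logits <- function(h, W, a, adjacency, leaky_slope = 0.2) {
  h <- as.matrix(h)
  if (!all(is.finite(h))) stop("non-finite node attributes")
  if (ncol(h) != nrow(W))
    stop(sprintf("attribute width %d does not match W input %d",
                 ncol(h), nrow(W)))
  if (length(a) != 2L * ncol(W))
    stop("attention vector must have length 2 * ncol(W)")
  n <- nrow(h)
  z <- h %*% W
  fp <- ncol(W)
  e <- matrix(drop(z %*% a[seq_len(fp)]), n, n) +
       matrix(drop(z %*% a[fp + seq_len(fp)]), n, n, byrow = TRUE)
  coef <- leaky_relu(e, leaky_slope)
  coef[adjacency == 0] <- -Inf
  list(coef = coef, z = z, e = e)
}

#' Softmax-normalize masked attention logits over neighbor sets
#'
#' Row-wise softmax restricted to each node's neighbors, computed with
#' row-max subtraction for overflow safety.
#'
#' @param coef Masked logit matrix (`-Inf` outside neighbor sets).
#' @return Matrix `alpha` with `alpha[i, j] >= 0`, zero outside `N_i`,
#'   and every row summing to 1.
#' @export
normalize_attention <- function(coef) {
  mx <- apply(coef, 1L, max)
  if (any(!is.finite(mx)))
    stop("node with empty neighbor set; enable self-loops")
  ex <- exp(coef - mx)
  ex[coef == -Inf] <- 0
  ex / rowSums(ex)
}

#' Attention-weighted neighbor aggregation for one head
#'
#' `h'_i = sigma(sum_{j in N_i} alpha_ij W h_j)` with an ELU activation.
#'
#' @param alpha Normalized attention matrix from [normalize_attention()].
#' @param z Transformed attributes `h W` (`n` x `F'`).
#' @return Head output matrix `n` x `F'`.
#' @export
aggregate_neighbors <- function(alpha, z) {
  if (ncol(alpha) != nrow(z)) stop("alpha and z dimensions disagree")
  elu(alpha %*% z)
}

# One full layer with cached intermediates (for backprop).
gat_layer_forward <- function(h, params, layer, config, adjacency) {
  heads <- vector("list", config$heads)
  for (m in seq_len(config$heads)) {
    W <- params[[sprintf("gat.l%d.h%d.W", layer, m)]]
    a <- params[[sprintf("gat.l%d.h%d.a", layer, m)]]
    at <- attention_logits(h, W, a, adjacency, config$leaky_slope)
    alpha <- normalize_attention(at$coef)
    s <- alpha %*% at$z
    heads[[m]] <- list(z = at$z, e = at$e, alpha = alpha, s = s,
                       out = elu(s))
  }
  list(input = h,
       out = do.call(cbind, lapply(heads, `[[`, "out")),
       heads = heads)
}

#' Multi-head attention forward pass (single layer)
#'
#' Runs every head of one layer independently and concatenates the head
#' outputs in head order.
#'
#' @param h Node attribute matrix `n` x `F`.
#' @param params Flat named parameter list (see [init_tagger()]).
#' @param graph A `sentence_graph` (its adjacency defines the mask).
#' @param config A [gat_config()].
#' @param layer Layer index within `params` (default 1).
#' @return Matrix `n` x `(M * units)`.
#' @export
multi_head_forward <- function(h, params, graph, config, layer = 1L) {
  gat_layer_forward(h, params, layer, config, graph$adjacency)$out
}

#' Stacked graph attention forward pass
#'
#' Applies every configured layer in sequence over the same graph; the
#' result is the fused node representation used by the decoder.  The
#' inter-layer activation is the ELU inside each aggregation step.
#'
#' @inheritParams multi_head_forward
#' @param h0 Initial node attributes (`[Cont || Synt]`).
#' @param return_attention If `TRUE`, attach per-layer/per-head `alpha`
#'   matrices as attribute `"attention"`.
#' @return Matrix `n` x `(M * units)` of final node representations.
#' @export
stack_layers <- function(h0, params, graph, config, return_attention = FALSE) {
  h <- as.matrix(h0)
  expected <- nrow(params[["gat.l1.h1.W"]])
  if (ncol(h) != expected)
    stop(sprintf("layer 1 expects width %d, got %d", expected, ncol(h)))
  attn <- list()
  for (l in seq_len(config$layers)) {
    fw <- gat_layer_forward(h, params, l, config, graph$adjacency)
    if (return_attention)
      attn[[l]] <- lapply(fw$heads, `[[`, "alpha")
    h <- fw$out
  }
  if (return_attention) attr(h, "attention") <- attn
  h
}

# Forward through all layers keeping every intermediate (training path).
gat_forward_cache <- function(h0, params, config, adjacency) {
  caches <- vector("list", config$layers)
  h <- h0
  for (l in seq_len(config$layers)) {
    caches[[l]] <- gat_layer_forward(h, params, l, config, adjacency)
    h <- caches[[l]]$out
  }
  list(rep = h, caches = caches)
}

# Backward through the stacked GAT. d_rep: gradient at the output.
# Returns list(grads = named list over gat.* params, dh0 = gradient
# at the input attributes).
gat_backward <- function(d_rep, params, config, adjacency, fw) {
  grads <- list()
  d_out <- d_rep
  fp <- config$units
  for (l in rev(seq_len(config$layers))) {
    cache <- fw$caches[[l]]
    h <- cache$input
    dh <- matrix(0, nrow(h), ncol(h))
    for (m in seq_len(config$heads)) {
      hd <- cache$heads[[m]]
      cols <- (m - 1L) * fp + seq_len(fp)
      ds <- d_out[, cols, drop = FALSE] * d_elu(hd$s)
      # s = alpha %*% z
      dalpha <- ds %*% t(hd$z)
      dalpha[adjacency == 0] <- 0
      dz <- t(hd$alpha) %*% ds
      # softmax rows over neighbors
      rowdot <- rowSums(hd$alpha * dalpha)
      dcoef <- hd$alpha * (dalpha - rowdot)
      de <- dcoef * d_leaky_relu(hd$e, config$leaky_slope)
      r <- rowSums(de); cs <- colSums(de)
      a <- params[[sprintf("gat.l%d.h%d.a", l, m)]]
      a1 <- a[seq_len(fp)]; a2 <- a[fp + seq_len(fp)]
      dz <- dz + outer(r, a1) + outer(cs, a2)
      grads[[sprintf("gat.l%d.h%d.a", l, m)]] <-
        c(drop(t(hd$z) %*% r), drop(t(hd$z) %*% cs))
      W <- params[[sprintf("gat.l%d.h%d.W", l, m)]]
      grads[[sprintf("gat.l%d.h%d.W", l, m)]] <- t(h) %*% dz
      dh <- dh + dz %*% t(W)
    }
    d_out <- dh
  }
  list(grads = grads, dh0 = d_out)
}
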