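test_that("attention logits match the hand-computed scalar case", {
  # F = F' = 1, W = [2], a = (1,1)', h = (1,-1)', slope 0.2, full
  # adjacency with self-loops: z = (2,-2);
  # coef_11 = LR(4) = 4, coef_12 = LR(0) = 0, coef_21 = 0, coef_22 = -0.8
  h <- matrix(c(1, -1), 2, 1)
  W <- matrix(2, 1, 1)
  a <- c(1, 1)
  adj <- matrix(1, 2, 2)
  at <- attention_logits(h, W, a, adj, leaky_slope = 0.2)
  expect_equal(at$coef, matrix(c(4, 0, 0, -0.8), 2, 2, byrow = TRUE))
  # identical attribute rows give symmetric logits
  h2 <- matrix(1, 2, 3)
  at2 <- attention_logits(h2, matrix(rnorm(3), 3, 1), rnorm(2), adj)
  expect_equal(at2$coef[1, 2], at2$coef[2, 1])
  expect_error(attention_logits(matrix(1, 2, 3), matrix(1, 2, 1), c(1, 1),
                                adj), "width")
  expect_error(attention_logits(matrix(c(1, NaN), 1, 2),
                                matrix(1, 2, 1), c(1, 1),
                                matrix(1, 1, 1)), "finite")
})

test_that("attention normalization is a masked row softmax", {
  coef <- matrix(c(1, -Inf, 0.5, 2), 2, 2, byrow = TRUE)
  alpha <- normalize_attention(coef)
  expect_equal(alpha[1, ], c(1, 0))              # single neighbor
  expect_equal(rowSums(alpha), c(1, 1), tolerance = 1e-9)
  # equal logits over k neighbors -> 1/k each
  alpha_eq <- normalize_attention(matrix(0, 3, 3))
  expect_equal(alpha_eq, matrix(1 / 3, 3, 3))
  # huge logits do not overflow (row-max subtraction)
  expect_equal(rowSums(normalize_attention(matrix(c(1e4, 9e3), 1, 2))), 1)
  # a node with no neighbors is an error
  expect_error(normalize_attention(matrix(-Inf, 1, 1)), "empty neighbor")
  set.seed(7)
  for (rep in 1:10) {
    case <- random_gat_case(sample(3:10, 1), 2, 3, 4)
    at <- attention_logits(case$h, case$params[["gat.l1.h1.W"]],
                           case$params[["gat.l1.h1.a"]], case$adj)
    alpha <- normalize_attention(at$coef)
    expect_equal(rowSums(alpha), rep(1, nrow(alpha)), tolerance = 1e-9)
    expect_true(all(alpha >= 0 & alpha <= 1))
    expect_true(all(alpha[case$adj == 0] == 0))
  }
})

test_that("aggregation reduces to ELU(W h) for an isolated self-loop node", {
  W <- matrix(rnorm(6), 3, 2)
  h <- matrix(rnorm(3), 1, 3)
  z <- h %*% W
  out <- aggregate_neighbors(matrix(1, 1, 1), z)
  expect_equal(out, ifelse(z > 0, z, exp(z) - 1))
  # splitting weight over two identical neighbors changes nothing
  z2 <- rbind(z, z)
  out2 <- aggregate_neighbors(matrix(c(0.3, 0.7), 1, 2), z2)
  expect_equal(out2, out)
})

test_that("vectorized multi-head forward equals the brute-force loop", {
  set.seed(101)
  for (rep in 1:25) {
    case <- random_gat_case(n = sample(2:10, 1), heads = sample(1:4, 1),
                            units = sample(1:5, 1), input_dim = sample(2:6, 1))
    graph <- list(adjacency = case$adj)
    fast <- multi_head_forward(case$h, case$params, graph, case$config)
    slow <- bf_gat_layer(case$h, case$params, 1L, case$config, case$adj)
    expect_equal(fast, slow, tolerance = 1e-6)
  }
})

test_that("multi-head output width is heads x units", {
  set.seed(3)
  n <- 5
  config <- gat_config(layers = 1, heads = 12, units = 64)
  params <- gatner:::init_gat_params(10L, config, seed = 1)
  graph <- list(adjacency = build_adjacency(n, cbind(1:4, 2:5)))
  out <- multi_head_forward(matrix(rnorm(n * 10), n, 10), params, graph,
                            config)
  expect_identical(dim(out), c(5L, 768L))
})

test_that("stacked layers compose single-layer forwards", {
  set.seed(13)
  n <- 6
  config <- gat_config(layers = 2, heads = 2, units = 4)
  params <- gatner:::init_gat_params(5L, config, seed = 2)
  adj <- build_adjacency(n, cbind(sample(n, 6, TRUE), sample(n, 6, TRUE)))
  graph <- list(adjacency = adj)
  h0 <- matrix(rnorm(n * 5), n, 5)
  rep2 <- stack_layers(h0, params, graph, config)
  manual <- multi_head_forward(
    multi_head_forward(h0, params, graph, config, layer = 1L),
    params, graph, config, layer = 2L)
  expect_equal(rep2, manual)
  # L = 1 equals a single multi-head forward
  config1 <- gat_config(layers = 1, heads = 2, units = 4)
  expect_equal(stack_layers(h0, params, graph, config1),
               multi_head_forward(h0, params, graph, config1))
  # deterministic for fixed parameters
  expect_identical(rep2, stack_layers(h0, params, graph, config))
  expect_error(stack_layers(h0[, 1:3], params, graph, config), "width")
})

test_that("masking blocks non-neighbor influence within a layer", {
  set.seed(23)
  n <- 7
  case <- random_gat_case(n, heads = 2, units = 3, input_dim = 4)
  graph <- list(adjacency = case$adj)
  base <- multi_head_forward(case$h, case$params, graph, case$config)
  for (i in seq_len(n)) {
    outside <- which(case$adj[i, ] == 0)
    if (!length(outside)) next
    j <- outside[1]
    h2 <- case$h
    h2[j, ] <- h2[j, ] + rnorm(4, sd = 5)
    pert <- multi_head_forward(h2, case$params, graph, case$config)
    expect_equal(pert[i, ], base[i, ], tolerance = 1e-12)
  }
})

test_that("influence propagates at most L hops through L layers", {
  set.seed(31)
  # path graph 1-2-3-4-5-6 with self-loops: distances are explicit
  n <- 6
  adj <- build_adjacency(n, cbind(1:5, 2:6))
  graph <- list(adjacency = adj)
  for (L in 1:2) {
    config <- gat_config(layers = L, heads = 2, units = 3)
    params <- gatner:::init_gat_params(4L, config, seed = L)
    h0 <- matrix(rnorm(n * 4), n, 4)
    base <- stack_layers(h0, params, graph, config)
    h2 <- h0
    h2[n, ] <- h2[n, ] + 10     # perturb the far end
    pert <- stack_layers(h2, params, graph, config)
    changed <- rowSums(abs(pert - base)) > 1e-12
    dist_from_n <- (n - 1):0
    expect_true(all(!changed[dist_from_n > L]))
    expect_true(changed[n])
  }
})

test_that("the full stack is permutation equivariant", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    case <- random_gat_case(n, heads = 3, units = 4, input_dim = 5)
    config <- gat_config(layers = 2, heads = 3, units = 4)
    params <- gatner:::init_gat_params(5L, config, seed = rep)
    base <- stack_layers(case$h, params, list(adjacency = case$adj), config)
    perm <- sample(n)
    out_p <- stack_layers(case$h[perm, , drop = FALSE], params,
                          list(adjacency = case$adj[perm, perm]), config)
    expect_equal(out_p, base[perm, , drop = FALSE], tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(57)
  cfg <- synthetic_config(n_sentences = 1, seed = 2)
  s <- generate_sentence(cfg, n_words = 5)
  tc <- train_config(bs = 1, lr = 0.01, epochs = 1, seed = 1,
                     gat = gat_config(layers = 2, heads = 2, units = 3),
                     encoder = encoder_spec(d = 6, seed = 1))
  label_set <- c("O", "B-ENT", "I-ENT")
  model <- init_tagger(tc, label_set)
  inst <- gatner:::make_instance(s, tc, label_set)
  if (all(!inst$supervised)) skip("degenerate instance")
  lg <- gatner:::loss_and_grad(model, list(inst))
  eps <- 1e-6
  for (nm in c("gat.l1.h1.W", "gat.l2.h2.a", "cls.W", "cls.b")) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (k in idx) {
      m2 <- model
      m2$params[[nm]][k] <- p[k] + eps
      up <- gatner:::loss_and_grad(m2, list(inst))$loss
      m2$params[[nm]][k] <- p[k] - eps
      dn <- gatner:::loss_and_grad(m2, list(inst))$loss
      expect_equal(lg$grads[[nm]][k], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
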