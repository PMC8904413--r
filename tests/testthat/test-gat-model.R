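test_that("attention rows are softmax-normalized over the neighborhood", {
  pr <- random_gat_problem(7, seed = 3)
  al <- attention_coefficients(pr$h, pr$model$layer1[[1]], pr$adj)
  expect_equal(rowSums(al), rep(1, 7))
  expect_true(all(al[pr$adj == 0] == 0))
  expect_true(all(al >= 0))
  # isolated node with only a self-loop attends fully to itself
  a2 <- pr$adj; a2[3, ] <- 0; a2[, 3] <- 0; a2[3, 3] <- 1
  al2 <- attention_coefficients(pr$h, pr$model$layer1[[1]], a2)
  expect_equal(al2[3, 3], 1)
})

test_that("attention matches a loop-based evaluation on a path graph", {
  # 3-node path with identity-like W and a fixed attention vector
  h <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE)
  params <- list(W = diag(2), a1 = c(0.3, -0.2), a2 = c(0.1, 0.4))
  adj <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  al <- attention_coefficients(h, params, adj, leaky_slope = 0.2)
  oracle <- oracle_head(h, params, adj, slope = 0.2)$alpha
  expect_equal(al, oracle, tolerance = 1e-12)
})

test_that("fused forward equals the brute-force loop oracle (n <= 8)", {
  for (seed in 1:6) {
    n <- sample(3:8, 1)
    pr <- random_gat_problem(n, seed = seed)
    fw <- gat_forward(pr$h, pr$adj, pr$model, record_attention = TRUE)
    orc <- oracle_gat_forward(pr$h, pr$adj, pr$model)
    expect_equal(unname(fw$prob), orc$prob, tolerance = 1e-6)
    expect_equal(fw$nodes, orc$nodes)
    for (al in c(fw$attention$layer1, fw$attention$layer2)) {
      expect_equal(rowSums(al), rep(1, n), tolerance = 1e-12)
    }
  }
})

test_that("forward equals the manual composition of its four stages", {
  pr <- random_gat_problem(6, seed = 12)
  m <- pr$model
  h1 <- gat_layer_forward(pr$h, m$layer1, pr$adj, concat = TRUE)
  expect_equal(ncol(h1), m$cfg$heads1 * m$cfg$hidden_dim)
  h2 <- gat_layer_forward(h1, m$layer2, pr$adj, concat = FALSE)
  ro <- topk_readout(h2, m$cfg$readout_k)
  pp <- classify(ro$embedding, m$mlp)
  fw <- gat_forward(pr$h, pr$adj, m)
  expect_equal(fw$prob, pp, tolerance = 1e-12)
  expect_equal(fw$nodes, ro$nodes)
  # purity: same inputs twice
  expect_identical(fw$prob, gat_forward(pr$h, pr$adj, m)$prob)
})

test_that("top-k readout ranks by L2 norm with index tie-break", {
  H <- rbind(c(3, 4), c(1, 0), c(0, 3))   # norms 5, 1, 3
  ro <- topk_readout(H, 2)
  expect_equal(ro$nodes, c(1, 3))
  expect_equal(ro$embedding, c(3, 4, 0, 3))
  full <- topk_readout(H, 3)
  expect_equal(full$nodes, c(1, 3, 2))
  expect_error(topk_readout(H, 4), "k must be")
  # ties broken by lower index
  Ht <- rbind(c(1, 0), c(0, 1), c(2, 0))
  expect_equal(topk_readout(Ht, 2)$nodes, c(3, 1))
  # default k on an 86-node graph selects 20 nodes
  H86 <- matrix(rnorm(86 * 4), 86, 4)
  expect_length(topk_readout(H86, 20)$nodes, 20)
})

test_that("classifier head is a proper softmax", {
  mlp <- list(list(W = matrix(0, 4, 3), b = numeric(4)),
              list(W = matrix(0, 2, 4), b = numeric(2)))
  expect_equal(unname(classify(c(1, 2, 3), mlp)), c(0.5, 0.5))
  # logits (2, 0) via the bias of the last layer
  mlp2 <- list(list(W = matrix(0, 2, 3), b = c(2, 0)))
  p <- classify(c(0, 0, 0), mlp2)
  expect_equal(unname(p), c(0.8808, 0.1192), tolerance = 1e-4)
  expect_equal(sum(p), 1)
  expect_error(classify(c(1, 2), mlp), "width")
})

test_that("layer-1 output of a node ignores features outside its neighborhood", {
  pr <- random_gat_problem(7, seed = 21)
  i <- 2
  outside <- which(pr$adj[i, ] == 0)
  skip_if(length(outside) == 0)
  h1 <- gat_layer_forward(pr$h, pr$model$layer1, pr$adj)
  h_mod <- pr$h
  h_mod[outside, ] <- 0
  h1_mod <- gat_layer_forward(h_mod, pr$model$layer1, pr$adj)
  expect_equal(h1_mod[i, ], h1[i, ], tolerance = 1e-12)
})

test_that("layers are permutation-equivariant and prediction invariant", {
  pr <- random_gat_problem(7, seed = 31)
  set.seed(99)
  perm <- sample(7)
  h1 <- gat_layer_forward(pr$h, pr$model$layer1, pr$adj)
  h1p <- gat_layer_forward(pr$h[perm, ], pr$model$layer1,
                           pr$adj[perm, perm])
  expect_equal(h1p, h1[perm, ], tolerance = 1e-10)
  fw <- gat_forward(pr$h, pr$adj, pr$model)
  fwp <- gat_forward(pr$h[perm, ], pr$adj[perm, perm], pr$model)
  expect_equal(fwp$prob, fw$prob, tolerance = 1e-10)
})

test_that("analytic input gradients match central finite differences", {
  pr <- random_gat_problem(8, f = 6, seed = 41)
  fw <- gat_forward(pr$h, pr$adj, pr$model, keep_cache = TRUE)
  c_idx <- fw$pred + 1L
  p <- fw$prob
  dlogits <- -p[c_idx] * p
  dlogits[c_idx] <- dlogits[c_idx] + p[c_idx]
  g <- braingat:::gat_backward(fw, pr$model, dlogits)
  set.seed(5)
  eps <- 1e-4
  for (trial in 1:5) {
    i <- sample(nrow(pr$h), 1); j <- sample(ncol(pr$h), 1)
    hp <- pr$h; hp[i, j] <- hp[i, j] + eps
    hm <- pr$h; hm[i, j] <- hm[i, j] - eps
    fd <- (gat_forward(hp, pr$adj, pr$model)$prob[c_idx] -
             gat_forward(hm, pr$adj, pr$model)$prob[c_idx]) / (2 * eps)
    denom <- max(abs(fd), abs(g$dh[i, j]), 1e-8)
    expect_lt(abs(fd - g$dh[i, j]) / denom, 1e-4)
  }
})

test_that("analytic parameter gradients match finite differences", {
  pr <- random_gat_problem(6, seed = 51)
  y <- 1L
  loss_of <- function(model) {
    unname(-log(gat_forward(pr$h, pr$adj, model)$prob[y + 1]))
  }
  fw <- gat_forward(pr$h, pr$adj, pr$model, keep_cache = TRUE)
  dlogits <- fw$prob
  dlogits[y + 1] <- dlogits[y + 1] - 1
  g <- braingat:::gat_backward(fw, pr$model, dlogits)
  eps <- 1e-5
  probes <- list(
    list(path = c("layer1", 1L, "W"), idx = c(2, 3)),
    list(path = c("layer1", 2L, "a1"), idx = 2),
    list(path = c("layer2", 1L, "W"), idx = c(1, 4)),
    list(path = c("mlp", 1L, "W"), idx = c(3, 2)),
    list(path = c("mlp", 2L, "b"), idx = 1))
  for (pb in probes) {
    bump <- function(model, delta) {
      part <- model[[pb$path[1]]][[as.integer(pb$path[2])]][[pb$path[3]]]
      if (length(pb$idx) == 2) {
        part[pb$idx[1], pb$idx[2]] <- part[pb$idx[1], pb$idx[2]] + delta
      } else part[pb$idx] <- part[pb$idx] + delta
      model[[pb$path[1]]][[as.integer(pb$path[2])]][[pb$path[3]]] <- part
      model
    }
    fd <- (loss_of(bump(pr$model, eps)) -
             loss_of(bump(pr$model, -eps))) / (2 * eps)
    ga <- g[[pb$path[1]]][[as.integer(pb$path[2])]][[pb$path[3]]]
    an <- if (length(pb$idx) == 2) ga[pb$idx[1], pb$idx[2]] else ga[pb$idx]
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("head masking replaces coefficients and zero-W heads are inert", {
  pr <- random_gat_problem(6, seed = 61)
  msk <- list(layer = 1L, head = 1L, mode = "uniform")
  fw <- gat_forward(pr$h, pr$adj, pr$model, record_attention = TRUE,
                    mask = msk)
  al <- fw$attention$layer1[[1]]
  unif <- pr$adj / rowSums(pr$adj)
  expect_equal(al, unif, tolerance = 1e-12)
  # other heads untouched
  fw0 <- gat_forward(pr$h, pr$adj, pr$model, record_attention = TRUE)
  expect_equal(fw$attention$layer1[[2]], fw0$attention$layer1[[2]])
})
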