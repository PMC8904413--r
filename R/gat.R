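#' Graph attention network configuration
#'
#' Architecture of the two-layer multi-head GAT graph classifier: a hidden
#' attention layer with `heads1` heads whose outputs are concatenated, an
#' output attention layer with a single head, a top-k node-embedding
#' readout, and a three-layer fully connected classifier ending in a 2-way
#' softmax. Defaults: 6 + 1 heads, k = 20,
#' 24 input features.
#'
#' @param n_features Input features per node F (24 multimodal, 13
#'   unimodal-SC, 11 unimodal-FC).
#' @param hidden_dim Per-head output width F' of the hidden layer.
#' @param heads1 Number of attention heads in the hidden layer.
#' @param out_dim Output width of the single-head output layer.
#' @param readout_k Number of top-ranked node embeddings concatenated into
#'   the graph embedding.
#' @param mlp_hidden Hidden widths of the classifier head.
#' @param leaky_slope Negative slope of the LeakyReLU inside attention.
#' @param dropout Dropout probability between fully connected layers
#'   (training only).
#' @return A `gat_config` list.
#' @export
gat_config <- function(n_features = 24L, hidden_dim = 8L, heads1 = 6L,
                       out_dim = 8L, readout_k = 20L,
                       mlp_hidden = c(64L, 16L), leaky_slope = 0.2,
                       dropout = 0.5) {
  stopifnot(n_features >= 1, hidden_dim >= 1, heads1 >= 1, out_dim >= 1,
            readout_k >= 1, leaky_slope > 0, dropout >= 0, dropout < 1)
  structure(list(n_features = as.integer(n_features),
                 hidden_dim = as.integer(hidden_dim),
                 heads1 = as.integer(heads1),
                 out_dim = as.integer(out_dim),
                 readout_k = as.integer(readout_k),
                 mlp_hidden = as.integer(mlp_hidden),
                 leaky_slope = leaky_slope, dropout = dropout),
            class = "gat_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize GAT parameters
#'
#' Glorot-uniform initialization of all attention and classifier weights,
#' deterministic for a fixed seed.
#'
#' @param cfg A `gat_config`.
#' @param seed Integer seed.
#' @return A `gat_model`: list with `layer1` (list of per-head parameters
#'   `W` (F' x F), `a1`, `a2` (length F')), `layer2` (one head over the
#'   concatenated width), `mlp` (weight/bias pairs), and `cfg`.
#' @export
init_gat <- function(cfg, seed = 1L) {
  withr_seed(seed, {
    fp <- cfg$hidden_dim
    layer1 <- lapply(seq_len(cfg$heads1), function(p) {
      list(W = glorot(fp, cfg$n_features),
           a1 = stats::runif(fp, -0.1, 0.1),
           a2 = stats::runif(fp, -0.1, 0.1))
    })
    in2 <- cfg$heads1 * fp
    layer2 <- list(list(W = glorot(cfg$out_dim, in2),
                        a1 = stats::runif(cfg$out_dim, -0.1, 0.1),
                        a2 = stats::runif(cfg$out_dim, -0.1, 0.1)))
    widths <- c(cfg$readout_k * cfg$out_dim, cfg$mlp_hidden, 2L)
    mlp <- lapply(seq_len(length(widths) - 1), function(l) {
      list(W = glorot(widths[l + 1], widths[l]),
           b = numeric(widths[l + 1]))
    })
    structure(list(layer1 = layer1, layer2 = layer2, mlp = mlp, cfg = cfg,
                   seed = as.integer(seed), trained = FALSE),
              class = "gat_model")
  })
}

# branch-free forms: cheaper than ifelse() in the per-graph inner loop
leaky_relu <- function(x, slope) slope * x + (1 - slope) * pmax(x, 0)
leaky_relu_grad <- function(x, slope) slope + (1 - slope) * (x > 0)
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0))
relu <- function(x) pmax(x, 0)

#' Attention coefficients of one head
#'
#' Computes the softmax-normalized attention coefficients
#' `alpha_ij = softmax_j(LeakyReLU(a' [W h_i || W h_j]))` over each node's
#' neighborhood (first-order neighbors in the binarized graph, self-loop
#' included). Entries outside the neighborhood are exactly 0 and every row
#' sums to 1.
#'
#' @param h n x F node-feature matrix.
#' @param params Head parameters: list `W` (F' x F), `a1`, `a2` (the two
#'   halves of the attention vector a, applied to W h_i and W h_j).
#' @param adjacency n x n binary matrix with self-loops.
#' @param leaky_slope LeakyReLU negative slope.
#' @return n x n matrix of attention coefficients.
#' @export
attention_coefficients <- function(h, params, adjacency, leaky_slope = 0.2) {
  head_forward(h, params, adjacency, leaky_slope)$alpha
}

# single attention head forward; returns cache of all intermediates
head_forward <- function(h, params, adjacency, leaky_slope,
                         mask_mode = NULL) {
  z <- h %*% t(params$W)                       # n x F'
  f <- as.vector(z %*% params$a1)
  g <- as.vector(z %*% params$a2)
  s <- outer(f, g, "+")                        # s_ij = f_i + g_j
  e <- leaky_relu(s, leaky_slope)
  # arithmetic masking (non-neighbors -> -1e30) is much cheaper than
  # logical indexing here; exp() then yields exactly 0 outside N_i
  emask <- e * adjacency - 1e30 * (1 - adjacency)
  n <- nrow(emask)
  emax <- emask[cbind(seq_len(n), max.col(emask, ties.method = "first"))]
  ex <- exp(emask - emax)
  alpha <- ex / rowSums(ex)
  if (!is.null(mask_mode)) {
    alpha <- masked_alpha(alpha, adjacency, mask_mode)
  }
  m <- alpha %*% z                             # pre-activation aggregate
  list(h = h, z = z, s = s, alpha = alpha, m = m,
       out = elu(m), adjacency = adjacency)
}

masked_alpha <- function(alpha, adjacency, mode) {
  if (mode == "uniform") {
    adjacency / rowSums(adjacency)
  } else if (mode == "zero") {
    alpha * 0
  } else stop("unknown attention mask mode: ", mode)
}

# backward through one head: dout is gradient wrt post-ELU output.
# Returns parameter grads and gradient wrt the input features h.
head_backward <- function(cache, params, dout, leaky_slope,
                          mask_mode = NULL) {
  dm <- dout * elu_grad(cache$m)
  dalpha <- dm %*% t(cache$z)
  dz <- t(cache$alpha) %*% dm
  if (is.null(mask_mode)) {
    # row-softmax backward, restricted to the neighborhood support
    rs <- rowSums(cache$alpha * dalpha)
    de <- cache$alpha * (dalpha - rs)
    ds <- de * leaky_relu_grad(cache$s, leaky_slope)
    df <- rowSums(ds)
    dg <- colSums(ds)
    dz <- dz + outer(df, params$a1) + outer(dg, params$a2)
    da1 <- as.vector(t(cache$z) %*% df)
    da2 <- as.vector(t(cache$z) %*% dg)
  } else {
    # masked coefficients do not depend on z
    da1 <- numeric(length(params$a1))
    da2 <- numeric(length(params$a2))
  }
  list(W = t(dz) %*% cache$h,
       a1 = da1, a2 = da2,
       dh = dz %*% params$W)
}

#' One GAT layer forward
#'
#' Applies every head of a layer and combines them: hidden layers
#' concatenate head outputs (width P F'), the output layer averages
#' (a no-op for its single head). Node update nonlinearity is ELU.
#'
#' @param h n x F input features.
#' @param heads List of per-head parameter lists.
#' @param adjacency Binary adjacency with self-loops.
#' @param concat Concatenate (`TRUE`, hidden layer) or average heads.
#' @param leaky_slope LeakyReLU slope inside attention.
#' @return n x F_out matrix of node embeddings.
#' @export
gat_layer_forward <- function(h, heads, adjacency, concat = TRUE,
                              leaky_slope = 0.2) {
  caches <- lapply(heads, function(p) {
    head_forward(h, p, adjacency, leaky_slope)
  })
  outs <- lapply(caches, function(cc) cc$out)
  if (concat) do.call(cbind, outs) else Reduce(`+`, outs) / length(outs)
}

#' Top-k node-embedding readout
#'
#' Ranks nodes by the L2 norm of their final-layer embedding (ties broken
#' by lower node index) and concatenates the top k embeddings in
#' descending-score order into one graph-level vector of length
#' `k * ncol(H)`.
#'
#' @param H n x F_out node-embedding matrix.
#' @param k Number of nodes to keep, `1 <= k <= n`.
#' @return List with `embedding` (length k * F_out) and `nodes` (selected
#'   row indices, descending score).
#' @export
topk_readout <- function(H, k) {
  n <- nrow(H)
  if (k < 1 || k > n) {
    stop(sprintf("readout k must be in [1, %d], got %d", n, k))
  }
  norms <- sqrt(rowSums(H^2))
  sel <- order(-norms, seq_len(n))[seq_len(k)]
  list(embedding = as.vector(t(H[sel, , drop = FALSE])), nodes = sel)
}

# classifier head forward; returns cache when requested
mlp_forward <- function(x, mlp, dropout_masks = NULL) {
  acts <- list(x)
  pre <- list()
  nl <- length(mlp)
  for (l in seq_len(nl)) {
    z <- as.vector(mlp[[l]]$W %*% acts[[l]]) + mlp[[l]]$b
    pre[[l]] <- z
    a <- if (l < nl) relu(z) else z
    if (l < nl && !is.null(dropout_masks)) a <- a * dropout_masks[[l]]
    acts[[l + 1]] <- a
  }
  logits <- acts[[nl + 1]]
  p <- softmax2(logits)
  list(acts = acts, pre = pre, logits = logits, prob = p)
}

softmax2 <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classifier head probabilities
#'
#' Passes a graph embedding through the fully connected layers and the
#' final 2-way softmax.
#'
#' @param embedding Graph-level embedding vector.
#' @param mlp List of `W`/`b` layer parameters (from a `gat_model`).
#' @return Probability pair summing to 1; names `c("HC", "PD")`.
#' @export
classify <- function(embedding, mlp) {
  if (length(embedding) != ncol(mlp[[1]]$W)) {
    stop(sprintf("embedding width %d does not match classifier input %d",
                 length(embedding), ncol(mlp[[1]]$W)))
  }
  stats::setNames(mlp_forward(embedding, mlp)$prob, c("HC", "PD"))
}

mlp_backward <- function(cache, mlp, dlogits, dropout_masks = NULL) {
  nl <- length(mlp)
  grads <- vector("list", nl)
  da <- dlogits
  for (l in rev(seq_len(nl))) {
    dz <- if (l == nl) da else {
      dd <- da
      if (!is.null(dropout_masks)) dd <- dd * dropout_masks[[l]]
      dd * (cache$pre[[l]] > 0)
    }
    grads[[l]] <- list(W = outer(dz, cache$acts[[l]]), b = dz)
    da <- as.vector(t(mlp[[l]]$W) %*% dz)
  }
  list(grads = grads, dx = da)
}

#' Full GAT forward pass
#'
#' Composition hidden layer -> output layer -> top-k readout -> classifier.
#' Optionally records every head's attention coefficients, applies an
#' attention-head mask (for fidelity scoring), or returns the full cache
#' needed for backpropagation.
#'
#' @param h n x F node-feature matrix (normalized).
#' @param adjacency Binary adjacency with self-loops (see
#'   [graph_adjacency()]).
#' @param model A `gat_model`.
#' @param record_attention Return per-head attention matrices.
#' @param mask Optional list `(layer, head, mode)` replacing that head's
#'   coefficients with `"uniform"` (over the neighborhood) or `"zero"`.
#' @param dropout_masks Internal: training-time dropout masks.
#' @param keep_cache Internal: retain intermediates for backprop.
#' @return List with `prob` (length-2, HC/PD), `pred` (0/1), `nodes`
#'   (top-k selection), and optionally `attention` (nested list
#'   `layer1[[head]]`, `layer2[[1]]`) and `cache`.
#' @export
gat_forward <- function(h, adjacency, model, record_attention = FALSE,
                        mask = NULL, dropout_masks = NULL,
                        keep_cache = FALSE) {
  cfg <- model$cfg
  mask_for <- function(layer, head) {
    if (!is.null(mask) && mask$layer == layer && mask$head == head) {
      mask$mode
    } else NULL
  }
  c1 <- lapply(seq_along(model$layer1), function(p) {
    head_forward(h, model$layer1[[p]], adjacency, cfg$leaky_slope,
                 mask_mode = mask_for(1L, p))
  })
  h1 <- do.call(cbind, lapply(c1, function(cc) cc$out))
  c2 <- lapply(seq_along(model$layer2), function(p) {
    head_forward(h1, model$layer2[[p]], adjacency, cfg$leaky_slope,
                 mask_mode = mask_for(2L, p))
  })
  h2 <- Reduce(`+`, lapply(c2, function(cc) cc$out)) / length(c2)
  ro <- topk_readout(h2, cfg$readout_k)
  mc <- mlp_forward(ro$embedding, model$mlp, dropout_masks)
  out <- list(prob = stats::setNames(mc$prob, c("HC", "PD")),
              pred = as.integer(which.max(mc$prob) == 2L),
              nodes = ro$nodes)
  if (record_attention) {
    out$attention <- list(layer1 = lapply(c1, function(cc) cc$alpha),
                          layer2 = lapply(c2, function(cc) cc$alpha))
  }
  if (keep_cache) {
    out$cache <- list(c1 = c1, h1 = h1, c2 = c2, h2 = h2, ro = ro, mc = mc,
                      h = h, adjacency = adjacency,
                      masks = list(l1 = lapply(seq_along(c1),
                                               function(p) mask_for(1L, p)),
                                   l2 = lapply(seq_along(c2),
                                               function(p) mask_for(2L, p))))
  }
  out
}

# backward through the whole network from dlogits (gradient wrt the two
# logits). Returns grads mirroring the model structure plus dh (n x F).
gat_backward <- function(fw, model, dlogits, dropout_masks = NULL) {
  cfg <- model$cfg
  cache <- fw$cache
  mb <- mlp_backward(cache$mc, model$mlp, dlogits, dropout_masks)
  # readout backward: embedding rows map back to the selected nodes
  dh2 <- matrix(0, nrow(cache$h2), ncol(cache$h2))
  demb <- matrix(mb$dx, nrow = cfg$readout_k, byrow = TRUE)
  dh2[cache$ro$nodes, ] <- demb
  dh2 <- dh2 / length(cache$c2)               # head-averaging of layer 2
  g2 <- vector("list", length(cache$c2))
  dh1 <- 0
  for (p in seq_along(cache$c2)) {
    hb <- head_backward(cache$c2[[p]], model$layer2[[p]], dh2,
                        cfg$leaky_slope, mask_mode = cache$masks$l2[[p]])
    g2[[p]] <- hb[c("W", "a1", "a2")]
    dh1 <- dh1 + hb$dh
  }
  fp <- cfg$hidden_dim
  g1 <- vector("list", length(cache$c1))
  dh <- 0
  for (p in seq_along(cache$c1)) {
    cols <- (p - 1L) * fp + seq_len(fp)
    hb <- head_backward(cache$c1[[p]], model$layer1[[p]],
                        dh1[, cols, drop = FALSE],
                        cfg$leaky_slope, mask_mode = cache$masks$l1[[p]])
    g1[[p]] <- hb[c("W", "a1", "a2")]
    dh <- dh + hb$dh
  }
  list(layer1 = g1, layer2 = g2, mlp = mb$grads, dh = dh)
}

#' Attention graph from a thresholded connectivity matrix
#'
#' Binarizes the surviving edges and adds self-loops, producing the
#' neighborhood structure the attention mechanism softmaxes over (edge
#' weights are not used inside attention).
#'
#' @param m A thresholded `connectivity_matrix`.
#' @return n x n binary matrix with unit diagonal.
#' @export
graph_adjacency <- function(m) binarize(m, self_loops = TRUE)
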