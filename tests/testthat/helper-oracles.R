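# Independent brute-force oracles used to validate the package's graph
# measures and the attention network. Everything here is deliberately
# naive (path enumeration, explicit loops) and shares no code with R/.

# random symmetric weighted graph with zero diagonal
random_weighted_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edges <- stats::runif(sum(ut)) < p_edge
  w[ut][edges] <- stats::runif(sum(edges), 0.2, 1)
  w + t(w)
}

# enumerate all simple paths s -> t; returns list of node vectors
enumerate_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nb in which(w[last, ] > 0)) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

path_length <- function(w, path, transform = function(x) 1 / x) {
  if (length(path) < 2) return(0)
  sum(vapply(seq_len(length(path) - 1), function(i) {
    transform(w[path[i], path[i + 1]])
  }, numeric(1)))
}

# shortest-path distance matrix by exhaustive simple-path enumeration
oracle_distances <- function(w, transform = function(x) 1 / x) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_simple_paths(w, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, path_length, numeric(1), w = w,
                     transform = transform)
      d[s, t] <- d[t, s] <- min(lens)
    }
  }
  d
}

# weighted betweenness by enumerating shortest paths (lengths 1/w);
# each unordered pair counted once, endpoints excluded
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_simple_paths(w, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, path_length, numeric(1), w = w)
      sp <- paths[lens <= min(lens) + tol]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        on_path <- vapply(sp, function(p) v %in% p, logical(1))
        bc[v] <- bc[v] + sum(on_path) / length(sp)
      }
    }
  }
  bc
}

# Onnela weighted clustering coefficient, triple loop
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wh <- w / mx
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

# local efficiency: neighbor-subgraph distances by path enumeration on
# cube-rooted lengths
oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wh <- w / mx
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wh[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- wh[nb, nb, drop = FALSE]
    d <- oracle_distances(sub, transform = function(x) (1 / x)^(1 / 3))
    acc <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b && is.finite(d[a, b]) && d[a, b] > 0) {
          acc <- acc + (wh[i, nb[a]] * wh[i, nb[b]])^(1 / 3) / d[a, b]
        }
      }
    }
    le[i] <- acc / (k * (k - 1))
  }
  le
}

# Newman Q and nodal decomposition by direct double loop
oracle_modularity <- function(w, memb) {
  n <- nrow(w)
  tw2 <- sum(w)
  s <- rowSums(w)
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        contrib[i] <- contrib[i] + (w[i, j] - s[i] * s[j] / tw2) / tw2
      }
    }
  }
  contrib
}

oracle_participation <- function(w, memb) {
  n <- nrow(w)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ])
    if (k == 0) next
    acc <- 0
    for (mod in unique(memb)) {
      acc <- acc + (sum(w[i, memb == mod]) / k)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

# ---- brute-force GAT (explicit loops over nodes and heads) ----

oracle_lrelu <- function(x, slope) if (x > 0) x else slope * x
oracle_elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

oracle_head <- function(h, params, adj, slope) {
  n <- nrow(h)
  fp <- nrow(params$W)
  z <- matrix(0, n, fp)
  for (i in seq_len(n)) z[i, ] <- params$W %*% h[i, ]
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- which(adj[i, ] == 1)
    e <- vapply(nbr, function(j) {
      oracle_lrelu(sum(params$a1 * z[i, ]) + sum(params$a2 * z[j, ]), slope)
    }, numeric(1))
    ex <- exp(e - max(e))
    alpha[i, nbr] <- ex / sum(ex)
  }
  out <- matrix(0, n, fp)
  for (i in seq_len(n)) {
    acc <- numeric(fp)
    for (j in which(adj[i, ] == 1)) acc <- acc + alpha[i, j] * z[j, ]
    out[i, ] <- oracle_elu(acc)
  }
  list(alpha = alpha, out = out)
}

oracle_gat_forward <- function(h, adj, model) {
  cfg <- model$cfg
  outs1 <- lapply(model$layer1, function(p) {
    oracle_head(h, p, adj, cfg$leaky_slope)$out
  })
  h1 <- do.call(cbind, outs1)
  outs2 <- lapply(model$layer2, function(p) {
    oracle_head(h1, p, adj, cfg$leaky_slope)$out
  })
  h2 <- Reduce(`+`, outs2) / length(outs2)
  norms <- apply(h2, 1, function(r) sqrt(sum(r^2)))
  sel <- order(-norms, seq_len(nrow(h2)))[seq_len(cfg$readout_k)]
  emb <- as.vector(t(h2[sel, , drop = FALSE]))
  x <- emb
  nl <- length(model$mlp)
  for (l in seq_len(nl)) {
    x <- as.vector(model$mlp[[l]]$W %*% x) + model$mlp[[l]]$b
    if (l < nl) x <- pmax(x, 0)
  }
  e <- exp(x - max(x))
  list(prob = e / sum(e), nodes = sel)
}

# small random GAT problem: features, adjacency with self-loops, tiny model
random_gat_problem <- function(n, f = 5, seed = 1, cfg = NULL) {
  set.seed(seed)
  if (is.null(cfg)) {
    cfg <- gat_config(n_features = f, hidden_dim = 3, heads1 = 2,
                      out_dim = 3, readout_k = min(3, n),
                      mlp_hidden = c(6, 4), dropout = 0)
  }
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2) < 0.5
  a <- a + t(a); diag(a) <- 1
  list(h = matrix(stats::rnorm(n * f), n, f), adj = a,
       model = init_gat(cfg, seed = seed + 100))
}

# small preprocessed graph dataset used across model/training tests
tiny_graph_dataset <- function(n_patients = 10, n_controls = 10,
                               n_nodes = 16, sc_effect = 0.6, seed = 42) {
  cfg <- synthetic_config(n_patients = n_patients, n_controls = n_controls,
                          n_nodes = n_nodes,
                          affected_nodes = c(0, 1, 2),
                          sc_effect = sc_effect, fc_effect = 0.3,
                          morph_effect = 0.2, seed = seed)
  ds <- generate_cohort(cfg)
  ds <- braingat:::preprocess_cohort(ds, 0.1, 0.5)
  list(ds = ds,
       gds = build_graph_dataset(ds, preprocessed = TRUE, seed = seed))
}
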