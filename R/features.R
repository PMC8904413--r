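#' Community detection for modularity-based nodal measures
#'
#' Runs the Louvain heuristic (via igraph) on the weighted graph to obtain
#' the module partition used by the nodal modularity-contribution and
#' participation-coefficient measures. Negative weights (possible in
#' Fisher-z FC matrices) are zeroed first, the standard convention for
#' these measures. Deterministic for a fixed seed.
#'
#' @param m A `connectivity_matrix` (thresholded).
#' @param seed Integer RNG seed for the Louvain heuristic.
#' @return A `community_partition`: list with `assignment` (0-based module
#'   ids, length n), `modularity_q`, `seed`.
#' @export
detect_communities <- function(m, seed = 1L) {
  check_modality(m, NULL)
  w <- pmax(m$values, 0)
  n <- nrow(w)
  if (all(w == 0)) {
    return(structure(list(assignment = seq_len(n) - 1L, modularity_q = 0,
                          seed = as.integer(seed)),
                     class = "community_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- withr_seed(seed, igraph::cluster_louvain(g))
  memb <- as.integer(igraph::membership(comm)) - 1L
  structure(list(assignment = memb,
                 modularity_q = newman_q(w, memb),
                 seed = as.integer(seed)),
            class = "community_partition")
}

# evaluate expr under a temporary seed without disturbing the global RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Newman modularity Q of a hard partition on nonnegative weights
newman_q <- function(w, memb) {
  tw2 <- sum(w)              # 2W for an undirected matrix stored densely
  if (tw2 == 0) return(0)
  s <- rowSums(w)
  same <- outer(memb, memb, "==")
  sum(((w - outer(s, s) / tw2) / tw2)[same])
}

# per-node contribution to Q: Mod_i = sum_{j in module(i)} (w_ij - s_i s_j/2W)/2W
nodal_modularity <- function(w, memb) {
  tw2 <- sum(w)
  if (tw2 == 0) return(numeric(length(memb)))
  s <- rowSums(w)
  same <- outer(memb, memb, "==")
  rowSums(((w - outer(s, s) / tw2) / tw2) * same)
}

# participation coefficient with module strengths: 1 - sum_m (k_im/k_i)^2
participation_coef <- function(w, memb) {
  k <- rowSums(w)
  n <- length(k)
  pc <- numeric(n)
  mods <- sort(unique(memb))
  kim <- vapply(mods, function(mod) rowSums(w[, memb == mod, drop = FALSE]),
                numeric(n))
  pos <- k > 0
  pc[pos] <- 1 - rowSums((kim[pos, , drop = FALSE] / k[pos])^2)
  pc
}

# Onnela weighted clustering coefficient, weights rescaled to max 1
weighted_clustering <- function(w) {
  mx <- max(w)
  if (mx == 0) return(numeric(nrow(w)))
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  cyc <- diag(wh %*% wh %*% wh)           # 2 x weighted triangles around i
  cc <- numeric(nrow(w))
  ok <- k >= 2
  cc[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  cc
}

# weighted local efficiency (Rubinov-Sporns / BCT efficiency_wei local form):
# E_loc(i) = (1/(k_i(k_i-1))) sum_{j!=h in N(i)} (w_ij w_ih)^(1/3) / d_jh,
# with d_jh the shortest path between neighbors j,h restricted to the
# neighbor-induced subgraph on cube-rooted lengths (1/w)^(1/3); weights
# rescaled to max 1 per matrix
weighted_local_efficiency <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  le <- numeric(n)
  if (mx == 0) return(le)
  wh <- w / mx
  for (i in seq_len(n)) {
    nb <- which(wh[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- wh[nb, nb, drop = FALSE]
    dinv <- inverse_distance(sub^(1 / 3))  # lengths (1/w)^(1/3) in neighborhood
    wi <- wh[i, nb]^(1 / 3)
    le[i] <- sum(outer(wi, wi) * dinv) / (k * (k - 1))
  }
  le
}

# matrix of 1/shortest-path-length on lengths 1/w (0 where disconnected)
inverse_distance <- function(w) {
  n <- nrow(w)
  if (n == 1) return(matrix(0, 1, 1))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  } else {
    matrix(Inf, n, n)
  }
  dinv <- 1 / d
  dinv[!is.finite(dinv)] <- 0
  diag(dinv) <- 0
  dinv
}

#' Nodal network measures
#'
#' Computes the seven weighted nodal graph-theory measures used as network
#' features: clustering coefficient (CC, Onnela weighted form), betweenness
#' centrality (BC, weighted shortest paths with edge length 1/weight),
#' degree (D, count of surviving edges), strength (S, sum of weights),
#' local efficiency (LE, neighbor-subgraph efficiency, weighted), nodal
#' modularity contribution (Mod, node's within-module share of Newman's Q,
#' so that the column sums to global Q), and participation coefficient
#' (PC = 1 - sum_m (k_im/k_i)^2 over module strengths). Negative weights
#' (signed FC) are zeroed before computation. Isolated nodes get 0 for
#' CC, LE, PC and BC.
#'
#' @param m A thresholded `connectivity_matrix`.
#' @param partition A `community_partition` from [detect_communities()];
#'   computed on the fly if `NULL`.
#' @param seed Seed used when `partition` is `NULL`.
#' @return n x 7 matrix with columns `CC, BC, D, S, LE, Mod, PC`.
#' @export
compute_network_features <- function(m, partition = NULL, seed = 1L) {
  check_modality(m, NULL)
  w <- pmax(m$values, 0)
  n <- nrow(w)
  if (is.null(partition)) {
    mm <- m; mm$values <- w
    partition <- detect_communities(mm, seed = seed)
  }
  deg <- rowSums(w > 0)
  stren <- rowSums(w)
  bc <- if (any(w > 0)) {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else numeric(n)
  out <- cbind(CC = weighted_clustering(w),
               BC = as.numeric(bc),
               D = deg,
               S = stren,
               LE = weighted_local_efficiency(w),
               Mod = nodal_modularity(w, partition$assignment),
               PC = participation_coef(w, partition$assignment))
  rownames(out) <- NULL
  out
}

#' Nodal edge-distribution statistics
#'
#' For each node, the first four moments of its full off-diagonal row of
#' edge values (zeros from thresholding included; signed values for FC):
#' mean, population standard deviation, skewness and excess kurtosis.
#' Zero-variance rows yield skew = kurt = 0 by convention.
#'
#' @param m A `connectivity_matrix`.
#' @param include_zeros Include zeroed (sub-threshold) entries in the
#'   per-node sample (default) or restrict to surviving edges.
#' @return n x 4 matrix with columns `mean, std, skew, kurt`.
#' @export
compute_statistical_features <- function(m, include_zeros = TRUE) {
  check_modality(m, NULL)
  v <- m$values
  n <- nrow(v)
  out <- t(vapply(seq_len(n), function(i) {
    x <- v[i, -i]
    if (!include_zeros) x <- x[x != 0]
    if (length(x) == 0) return(c(0, 0, 0, 0))
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    s <- sqrt(s2)
    if (s2 <= 0) return(c(mu, 0, 0, 0))
    c(mu, s, mean((x - mu)^3) / s^3, mean((x - mu)^4) / s2^2 - 3)
  }, numeric(4)))
  colnames(out) <- c("mean", "std", "skew", "kurt")
  out
}

network_feature_names <- function() c("CC", "BC", "D", "S", "LE", "Mod", "PC")
stat_feature_names <- function() c("mean", "std", "skew", "kurt")

#' Assemble the multimodal node-feature matrix
#'
#' Concatenates the per-node blocks in the fixed column order
#' `[morphology | SC network | SC statistical | FC network | FC statistical]`,
#' giving the 24-feature multimodal set: 13 structural-side columns
#' (2 morphological + 7 SC network + 4 SC statistical) and 11
#' functional-side columns (7 FC network + 4 FC statistical). Unimodal
#' variants drop whole blocks.
#'
#' @param morphology n x 2 block (volume, thickness), or `NULL` in
#'   unimodal-FC mode.
#' @param sc_net,sc_stat SC-derived n x 7 and n x 4 blocks, or `NULL`.
#' @param fc_net,fc_stat FC-derived n x 7 and n x 4 blocks, or `NULL`.
#' @return A `node_feature_matrix`: numeric matrix with `feature_names`
#'   column names (e.g. `SC_BC`, `FC_mean`) and a `modality_tags` attribute.
#' @export
assemble_multimodal_features <- function(morphology, sc_net, sc_stat,
                                         fc_net, fc_stat) {
  blocks <- list()
  tags <- character(0)
  add <- function(blk, names, tag) {
    colnames(blk) <- names
    blocks[[length(blocks) + 1]] <<- blk
    tags <<- c(tags, rep(tag, ncol(blk)))
  }
  if (!is.null(morphology)) {
    add(as.matrix(morphology), c("volume", "thickness"), "morphological")
  }
  if (!is.null(sc_net)) {
    add(sc_net, paste0("SC_", network_feature_names()), "structural")
  }
  if (!is.null(sc_stat)) {
    add(sc_stat, paste0("SC_", stat_feature_names()), "structural")
  }
  if (!is.null(fc_net)) {
    add(fc_net, paste0("FC_", network_feature_names()), "functional")
  }
  if (!is.null(fc_stat)) {
    add(fc_stat, paste0("FC_", stat_feature_names()), "functional")
  }
  if (length(blocks) == 0) stop("no feature blocks supplied")
  nr <- vapply(blocks, nrow, integer(1))
  if (length(unique(nr)) != 1) {
    stop(sprintf("feature blocks disagree on node count: %s",
                 paste(nr, collapse = ", ")))
  }
  out <- do.call(cbind, blocks)
  attr(out, "modality_tags") <- tags
  class(out) <- c("node_feature_matrix", class(out))
  out
}

#' Per-subject multimodal features for a whole cohort
#'
#' Applies the standard preprocessing (SC absolute threshold, FC Fisher z +
#' density threshold unless `preprocessed = TRUE`), computes the network and
#' statistical blocks per subject and assembles the feature matrices.
#'
#' @param ds A `cohort_dataset`.
#' @param mode One of `"multimodal"` (24 columns), `"unimodal-sc"` (13),
#'   `"unimodal-fc"` (11).
#' @param sc_threshold Absolute SC threshold (default 0.1).
#' @param fc_density FC density cutoff (default 0.5).
#' @param preprocessed Set `TRUE` when matrices are already thresholded /
#'   Fisher-z transformed (e.g. after SMOTE reconstruction).
#' @param seed Seed for community detection.
#' @return List with `features` (list of n x F matrices), `graphs` (list of
#'   thresholded `connectivity_matrix` used as the attention graph),
#'   `labels`.
#' @export
cohort_features <- function(ds, mode = c("multimodal", "unimodal-sc",
                                         "unimodal-fc"),
                            sc_threshold = 0.1, fc_density = 0.5,
                            preprocessed = FALSE, seed = 1L,
                            graph_modality = c("SC", "FC")) {
  mode <- match.arg(mode)
  graph_modality <- match.arg(graph_modality)
  feats <- vector("list", length(ds$subjects))
  graphs <- vector("list", length(ds$subjects))
  for (i in seq_along(ds$subjects)) {
    s <- ds$subjects[[i]]
    sc <- if (preprocessed) s$sc else threshold_absolute(s$sc, sc_threshold)
    fc <- if (preprocessed) s$fc else {
      threshold_density(fisher_z(s$fc), fc_density)
    }
    need_sc <- mode != "unimodal-fc"
    need_fc <- mode != "unimodal-sc"
    sc_net <- sc_stat <- fc_net <- fc_stat <- NULL
    if (need_sc) {
      sc_net <- compute_network_features(sc, seed = seed)
      sc_stat <- compute_statistical_features(sc)
    }
    if (need_fc) {
      fc_net <- compute_network_features(fc, seed = seed)
      fc_stat <- compute_statistical_features(fc)
    }
    morph <- if (mode == "unimodal-fc") NULL else s$morphology
    feats[[i]] <- assemble_multimodal_features(morph, sc_net, sc_stat,
                                               fc_net, fc_stat)
    graphs[[i]] <- if (graph_modality == "SC") sc else fc
  }
  list(features = feats, graphs = graphs, labels = cohort_labels(ds))
}

#' Min-max feature normalization
#'
#' Fits per-feature min/max over all nodes of all training subjects and maps
#' features affinely into [0, 1]; held-out subjects are mapped with the
#' training scaler (values may fall outside [0, 1]). Constant features map
#' to 0. The scaler is invertible on non-constant features.
#'
#' @param train List of node-feature matrices (the training subjects).
#' @return A `minmax_scaler` with elements `min`, `range`.
#' @export
fit_minmax <- function(train) {
  if (length(train) == 0) stop("empty training list")
  stacked <- do.call(rbind, train)
  lo <- apply(stacked, 2, min)
  hi <- apply(stacked, 2, max)
  structure(list(min = lo, range = hi - lo, names = colnames(stacked)),
            class = "minmax_scaler")
}

#' @param scaler A fitted `minmax_scaler`.
#' @param x A node-feature matrix (or list of them).
#' @rdname fit_minmax
#' @export
apply_minmax <- function(scaler, x) {
  if (is.list(x) && !is.matrix(x)) {
    return(lapply(x, apply_minmax, scaler = scaler))
  }
  r <- ifelse(scaler$range > 0, scaler$range, 1)
  shifted <- sweep(x, 2, scaler$min, "-")
  out <- sweep(shifted, 2, r, "/")
  out[, scaler$range == 0] <- 0
  out
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(scaler, x) {
  if (is.list(x) && !is.matrix(x)) {
    return(lapply(x, invert_minmax, scaler = scaler))
  }
  r <- ifelse(scaler$range > 0, scaler$range, 1)
  sweep(sweep(x, 2, r, "*"), 2, scaler$min, "+")
}
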