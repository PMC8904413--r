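sc_of <- function(w) connectivity_matrix(w, "SC")

test_that("community detection separates components and is deterministic", {
  micro <- generate_worked_micro()
  part <- detect_communities(micro$two_cliques, seed = 5)
  expect_equal(length(unique(part$assignment)), 2)
  expect_equal(length(unique(part$assignment[1:4])), 1)
  expect_equal(length(unique(part$assignment[5:8])), 1)
  part2 <- detect_communities(micro$two_cliques, seed = 5)
  expect_identical(part$assignment, part2$assignment)
  # empty graph: singleton modules, q = 0
  empty <- detect_communities(sc_of(matrix(0, 4, 4)), seed = 1)
  expect_equal(length(unique(empty$assignment)), 4)
  expect_equal(empty$modularity_q, 0)
})

test_that("modularity Q matches direct summation on a toy partition", {
  # 6-node graph: two triangles joined by one weak edge
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 3] <- w[1, 3] <- 1
  w[4, 5] <- w[5, 6] <- w[4, 6] <- 1
  w[3, 4] <- 0.5
  w <- w + t(w)
  memb <- c(0, 0, 0, 1, 1, 1)
  contrib <- oracle_modularity(w, memb)
  expect_equal(braingat:::newman_q(w, memb), sum(contrib))
  expect_equal(braingat:::nodal_modularity(w, memb), contrib)
  part <- detect_communities(sc_of(w), seed = 2)
  expect_equal(sort(unique(part$assignment)), c(0, 1))
  expect_equal(part$modularity_q, sum(oracle_modularity(w, part$assignment)))
})

test_that("closed-form motifs: triangle, star, participation", {
  micro <- generate_worked_micro()
  tri <- compute_network_features(micro$triangle)
  expect_equal(unname(tri[, "CC"]), rep(1, 3))
  expect_equal(unname(tri[, "BC"]), rep(0, 3))
  expect_equal(unname(tri[, "D"]), rep(2, 3))
  expect_equal(unname(tri[, "S"]), rep(2, 3))
  expect_equal(unname(tri[, "LE"]), rep(1, 3))
  star <- compute_network_features(micro$star5)
  expect_equal(unname(star[, "BC"]), c(6, 0, 0, 0, 0))
  expect_equal(unname(star[, "CC"]), rep(0, 5))
  # all edges inside one module -> PC = 0
  clq <- compute_network_features(micro$two_cliques)
  expect_equal(unname(clq[, "PC"]), rep(0, 8))
  # strength equals degree at unit weights
  expect_equal(unname(clq[, "S"]), unname(clq[, "D"]))
})

test_that("all seven nodal measures match brute-force oracles", {
  for (seed in 1:4) {
    n <- c(6, 7, 8, 8)[seed]
    w <- random_weighted_graph(n, p_edge = 0.45, seed = seed)
    part <- detect_communities(sc_of(w), seed = seed)
    nf <- compute_network_features(sc_of(w), partition = part)
    expect_equal(unname(nf[, "D"]), rowSums(w > 0))
    expect_equal(unname(nf[, "S"]), rowSums(w))
    expect_equal(unname(nf[, "BC"]), oracle_betweenness(w),
                 tolerance = 1e-8)
    expect_equal(unname(nf[, "CC"]), oracle_clustering(w),
                 tolerance = 1e-10)
    expect_equal(unname(nf[, "LE"]), oracle_local_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(nf[, "Mod"]),
                 oracle_modularity(w, part$assignment), tolerance = 1e-10)
    expect_equal(unname(nf[, "PC"]),
                 oracle_participation(w, part$assignment),
                 tolerance = 1e-10)
    # ranges
    expect_true(all(nf[, "PC"] >= 0 & nf[, "PC"] < 1))
    expect_true(all(nf[, "CC"] >= 0 & nf[, "CC"] <= 1))
  }
})

test_that("node relabeling permutes every feature row identically", {
  set.seed(9)
  w <- random_weighted_graph(8, p_edge = 0.5, seed = 11)
  perm <- sample(8)
  wp <- w[perm, perm]
  part <- detect_communities(sc_of(w), seed = 1)
  part_p <- part
  part_p$assignment <- part$assignment[perm]
  nf <- compute_network_features(sc_of(w), partition = part)
  nfp <- compute_network_features(sc_of(wp), partition = part_p)
  expect_equal(nfp, nf[perm, ], tolerance = 1e-10)
  sf <- compute_statistical_features(sc_of(w))
  sfp <- compute_statistical_features(sc_of(wp))
  expect_equal(sfp, sf[perm, ], tolerance = 1e-10)
})

test_that("nodal moments are population moments over the full row", {
  # row {1,2,3,4}: mean 2.5, population std sqrt(1.25)
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- c(1, 2, 3, 4)
  w <- w + t(w)
  sf <- compute_statistical_features(sc_of(w))
  expect_equal(unname(sf[1, "mean"]), 2.5)
  expect_equal(unname(sf[1, "std"]), 1.1180, tolerance = 1e-4)
  expect_equal(unname(sf[1, "std"]), sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  # constant row: std = skew = kurt = 0
  wc <- matrix(2, 4, 4); diag(wc) <- 0
  sfc <- compute_statistical_features(sc_of(wc))
  expect_equal(unname(sfc[1, ]), c(2, 0, 0, 0))
  # symmetric values about the mean: skew 0
  ws <- matrix(0, 4, 4)
  ws[1, 2:4] <- c(1, 2, 3)
  ws <- ws + t(ws)
  expect_equal(unname(compute_statistical_features(sc_of(ws))[1, "skew"]), 0,
               tolerance = 1e-12)
  # agreement with an independent moment implementation on random data
  skip_if_not_installed("e1071")
  set.seed(4)
  wr <- random_weighted_graph(7, p_edge = 0.8, seed = 21)
  sfr <- compute_statistical_features(sc_of(wr))
  for (i in 1:7) {
    x <- wr[i, -i]
    expect_equal(unname(sfr[i, "skew"]), e1071::skewness(x, type = 1),
                 tolerance = 1e-10)
    expect_equal(unname(sfr[i, "kurt"]), e1071::kurtosis(x, type = 1),
                 tolerance = 1e-10)
  }
})

test_that("multimodal assembly has the 2+7+4 | 7+4 block layout", {
  set.seed(5)
  n <- 9
  morph <- cbind(runif(n, 1000, 2000), runif(n, 2, 3))
  blk <- function(k) matrix(rnorm(n * k), n, k)
  fm <- assemble_multimodal_features(morph, blk(7), blk(4), blk(7), blk(4))
  expect_equal(dim(fm), c(n, 24))
  tags <- attr(fm, "modality_tags")
  expect_equal(sum(tags %in% c("morphological", "structural")), 13)
  expect_equal(sum(tags == "functional"), 11)
  expect_equal(colnames(fm)[1:2], c("volume", "thickness"))
  expect_equal(colnames(fm)[3], "SC_CC")
  expect_equal(colnames(fm)[14], "FC_CC")
  expect_true(all(c("SC_mean", "SC_S", "SC_BC", "FC_BC") %in% colnames(fm)))
  # unimodal variants
  sc_only <- assemble_multimodal_features(morph, blk(7), blk(4), NULL, NULL)
  expect_equal(ncol(sc_only), 13)
  fc_only <- assemble_multimodal_features(NULL, NULL, NULL, blk(7), blk(4))
  expect_equal(ncol(fc_only), 11)
  # mismatched rows
  expect_error(assemble_multimodal_features(morph[1:5, ], blk(7), blk(4),
                                            blk(7), blk(4)),
               "node count")
})

test_that("min-max scaling maps train to [0,1] and inverts exactly", {
  set.seed(6)
  train <- lapply(1:3, function(i) matrix(rnorm(5 * 4), 5, 4))
  test <- list(matrix(rnorm(5 * 4, sd = 3), 5, 4))
  scaler <- fit_minmax(train)
  strain <- apply_minmax(scaler, train)
  stacked <- do.call(rbind, strain)
  expect_true(all(stacked >= 0 & stacked <= 1))
  back <- invert_minmax(scaler, strain)
  for (i in 1:3) expect_equal(back[[i]], train[[i]], tolerance = 1e-12)
  # held-out data may exceed [0,1]
  stest <- apply_minmax(scaler, test)
  expect_true(any(stest[[1]] < 0 | stest[[1]] > 1))
  # single feature spanning [2,6] -> (x-2)/4
  one <- list(matrix(c(2, 4, 6), 3, 1))
  s1 <- fit_minmax(one)
  expect_equal(apply_minmax(s1, one)[[1]][, 1], c(0, 0.5, 1))
  # constant column maps to 0
  const <- list(matrix(5, 3, 2))
  expect_equal(apply_minmax(fit_minmax(const), const)[[1]],
               matrix(0, 3, 2))
  expect_error(fit_minmax(list()), "empty")
})
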