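# one small trained model shared across interpretability tests
trained_setup <- local({
  tg <- tiny_graph_dataset(n_patients = 10, n_controls = 10, n_nodes = 16,
                           sc_effect = 0.6, seed = 42)
  scaler <- fit_minmax(tg$gds$features)
  scaled <- apply_minmax(scaler, tg$gds$features)
  cfgm <- gat_config(n_features = 24, readout_k = 5, dropout = 0.3)
  tc <- train_config(epochs = 35, batch_size = 8, patience = 35, seed = 5)
  model <- train_gat(tg$gds, scaled, seq_len(20), val_idx = NULL,
                     model_cfg = cfgm, train_cfg = tc)
  list(tg = tg, scaled = scaled, model = model)
})

test_that("fidelity arithmetic reproduces hand-computed values", {
  # 4 graphs: all correct originally, 2 correct after masking -> F = 0.5
  expect_equal(fidelity_from_indicators(c(TRUE, TRUE, TRUE, TRUE),
                                        c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # identical indicators -> F = 0
  expect_equal(fidelity_from_indicators(c(TRUE, FALSE), c(TRUE, FALSE)), 0)
  # masking can help: negative fidelity
  expect_equal(fidelity_from_indicators(c(FALSE, FALSE), c(TRUE, TRUE)), -1)
  expect_error(fidelity_from_indicators(TRUE, c(TRUE, FALSE)), "length")
})

test_that("fidelity scores rank heads and live on a 1/N grid", {
  st <- trained_setup
  n_eval <- 20
  fid <- fidelity_scores(st$model, st$scaled, st$tg$gds$adj,
                         st$tg$gds$labels, idx = seq_len(n_eval))
  expect_equal(nrow(fid), st$model$cfg$heads1 + 1)
  expect_true(all(fid$fidelity >= -1 & fid$fidelity <= 1))
  # values are multiples of 1/N
  expect_equal(fid$fidelity * n_eval, round(fid$fidelity * n_eval),
               tolerance = 1e-9)
  expect_true(!is.unsorted(rev(fid$fidelity)))
  expect_error(fidelity_scores(init_gat(st$model$cfg), st$scaled,
                               st$tg$gds$adj, st$tg$gds$labels),
               "trained")
})

test_that("a head with zero weights has zero fidelity under uniform mask", {
  st <- trained_setup
  m <- st$model
  # zero-W head: z = 0 so scores are constant and alpha is already uniform
  m$layer1[[2]]$W[] <- 0
  m$layer1[[2]]$a1[] <- 0
  m$layer1[[2]]$a2[] <- 0
  fid <- fidelity_scores(m, st$scaled, st$tg$gds$adj, st$tg$gds$labels)
  f2 <- fid$fidelity[fid$layer == 1 & fid$head == 2]
  expect_equal(f2, 0)
})

test_that("saliency is the mean |gradient| over correct predictions", {
  st <- trained_setup
  sal <- saliency_map(st$model, st$scaled, st$tg$gds$adj,
                      st$tg$gds$labels)
  expect_equal(dim(sal), c(16, 24))
  expect_true(all(sal >= 0))
  expect_equal(colnames(sal), colnames(st$scaled[[1]]))
  expect_gte(attr(sal, "sample_count"), 1)
  # order of samples does not matter
  sal_rev <- saliency_map(st$model, st$scaled, st$tg$gds$adj,
                          st$tg$gds$labels, idx = rev(seq_len(20)))
  expect_equal(unclass(sal), unclass(sal_rev), tolerance = 1e-12)
  # model that ignores its input: all layer-1 weights zero
  m0 <- st$model
  for (p in seq_along(m0$layer1)) {
    m0$layer1[[p]]$W[] <- 0
    m0$layer1[[p]]$a1[] <- 0
    m0$layer1[[p]]$a2[] <- 0
  }
  res <- try(saliency_map(m0, st$scaled, st$tg$gds$adj, st$tg$gds$labels),
             silent = TRUE)
  if (!inherits(res, "try-error")) {
    expect_equal(max(abs(res)), 0)
  } else {
    expect_match(attr(res, "condition")$message, "correctly predicted")
  }
})

test_that("salient-entry selection respects the threshold boundary", {
  sal <- matrix(0.001, 4, 3,
                dimnames = list(NULL, c("SC_S", "SC_BC", "FC_BC")))
  sal[1, 1] <- 0.5; sal[2, 2] <- 0.1; sal[3, 3] <- 0.021
  cls <- structure(sal, class = c("saliency_map", "matrix", "array"))
  out <- select_salient(cls, 0.02)
  expect_equal(nrow(out), 3)
  expect_equal(out$score, c(0.5, 0.1, 0.021))
  expect_equal(out$feature, c("SC_S", "SC_BC", "FC_BC"))
  # threshold 0 on a strictly positive map keeps every entry
  expect_equal(nrow(select_salient(cls, 0)), 12)
  # threshold above the maximum keeps none
  expect_equal(nrow(select_salient(cls, 1)), 0)
  expect_error(select_salient(cls, -1), "threshold")
})

test_that("attention summaries average, symmetrize, and threshold", {
  st <- trained_setup
  labs <- st$tg$gds$labels
  att <- attention_summary(st$model, st$scaled, st$tg$gds$adj, labs)
  expect_length(att$layer1, st$model$cfg$heads1)
  for (head in c(att$layer1, att$layer2)) {
    expect_equal(head$symmetric, t(head$symmetric))
    # directed mean keeps row-normalization
    expect_equal(rowSums(head$mean), rep(1, 16), tolerance = 1e-9)
  }
  # single correctly predicted sample: summary equals that sample's alpha
  one <- which(vapply(seq_along(labs), function(i) {
    gat_forward(st$scaled[[i]], st$tg$gds$adj[[i]], st$model)$pred ==
      labs[i]
  }, logical(1)))[1]
  att1 <- attention_summary(st$model, st$scaled, st$tg$gds$adj, labs,
                            idx = one)
  fw <- gat_forward(st$scaled[[one]], st$tg$gds$adj[[one]], st$model,
                    record_attention = TRUE)
  expect_equal(att1$layer1[[1]]$mean, fw$attention$layer1[[1]])
  # raising the display threshold never increases surviving edges
  counts <- vapply(c(0, 0.01, 0.045, 0.085, 0.2), function(tr) {
    a <- attention_summary(st$model, st$scaled, st$tg$gds$adj, labs,
                           idx = one, display_threshold = tr)
    sum(a$layer1[[5]]$thresholded != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clinical correlation matches the Pearson formula", {
  # x = 1..5, y = (2,1,4,3,5) -> r = 0.8
  expect_equal(unname(cor(1:5, c(2, 1, 4, 3, 5))), 0.8)
  micro_n <- 8
  cfg <- synthetic_config(n_patients = 12, n_controls = 4,
                          n_nodes = micro_n, affected_nodes = 0L,
                          sc_effect = 0, fc_effect = 0, morph_effect = 0,
                          clinical_coupling = list(
                            AAO = list(node = 0L, slope = -8)),
                          seed = 13)
  ds <- generate_cohort(cfg)
  feats <- lapply(ds$subjects, function(s) {
    assemble_multimodal_features(
      s$morphology,
      compute_network_features(s$sc, seed = 1),
      compute_statistical_features(s$sc),
      compute_network_features(s$fc, seed = 1),
      compute_statistical_features(s$fc))
  })
  salient <- data.frame(node = 1L, feature = "SC_S", score = 1)
  cc <- correlate_clinical(salient, ds, feats, alpha = 0.05)
  aao <- cc[cc$clinical == "AAO", ]
  expect_equal(nrow(aao), 1)
  expect_lt(aao$r, 0)                  # planted negative slope recovered
  expect_equal(aao$n_used, 12)         # controls have no AAO
  # perfect linear dependence
  ds2 <- ds
  for (i in seq_along(ds2$subjects)) {
    if (ds2$subjects[[i]]$label == 1) {
      ds2$subjects[[i]]$clinical[["DOI"]] <- feats[[i]][1, "SC_S"]
    }
  }
  cc2 <- correlate_clinical(salient, ds2, feats, alpha = 0.005)
  doi <- cc2[cc2$clinical == "DOI", ]
  expect_equal(doi$r, 1, tolerance = 1e-10)
  expect_true(doi$significant)
  # zero-variance series flagged undefined, not an error
  ds3 <- ds
  for (i in seq_along(ds3$subjects)) {
    ds3$subjects[[i]]$clinical[["HY"]] <- 2
  }
  cc3 <- correlate_clinical(salient, ds3, feats, alpha = 0.005)
  hy <- cc3[cc3$clinical == "HY", ]
  expect_true(is.na(hy$r))
  expect_false(hy$significant)
})
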