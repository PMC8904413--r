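#' Build a trainable graph dataset from a cohort
#'
#' Computes per-subject node features and attention graphs
#' (via [cohort_features()]) and the binary adjacencies with self-loops the
#' GAT attends over.
#'
#' @inheritParams cohort_features
#' @return A `graph_dataset`: list with `features` (un-normalized), `adj`,
#'   `labels`, `mode`, `subject_ids`, `synthetic` flags.
#' @export
build_graph_dataset <- function(ds, mode = "multimodal", sc_threshold = 0.1,
                                fc_density = 0.5, preprocessed = FALSE,
                                seed = 1L, graph_modality = "SC") {
  cf <- cohort_features(ds, mode = mode, sc_threshold = sc_threshold,
                        fc_density = fc_density,
                        preprocessed = preprocessed, seed = seed,
                        graph_modality = graph_modality)
  structure(list(features = cf$features,
                 adj = lapply(cf$graphs, graph_adjacency),
                 labels = cf$labels, mode = mode,
                 subject_ids = vapply(ds$subjects,
                                      function(s) s$subject_id, character(1)),
                 synthetic = vapply(ds$subjects,
                                    function(s) s$synthetic, logical(1))),
            class = "graph_dataset")
}

#' Stratified train/validation/test split
#'
#' Splits subjects into disjoint test (default 10%), then validation
#' (default 20% of the remainder) and training sets, stratified by label
#' with largest-remainder rounding (ties to the lower label) and
#' deterministic for a fixed seed. A balanced 150-subject cohort yields
#' sizes 108/27/15.
#'
#' @param labels Integer 0/1 label vector.
#' @param test_fraction Fraction held out for testing.
#' @param val_fraction Fraction of the remainder used for validation.
#' @param seed RNG seed.
#' @return List of index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, test_fraction = 0.10, val_fraction = 0.20,
                          seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction > 0, val_fraction < 1)
  if (any(table(labels) < 2)) {
    stop("need at least 2 subjects per class for a stratified split")
  }
  withr_seed(seed, {
    take <- function(idx_by_class, frac) {
      counts <- vapply(idx_by_class, length, integer(1))
      raw <- counts * frac
      base <- floor(raw)
      extra <- round(sum(raw)) - sum(base)
      if (extra > 0) {
        ord <- order(-(raw - base), seq_along(counts))
        base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
      }
      unlist(lapply(seq_along(idx_by_class), function(ci) {
        sample(idx_by_class[[ci]], base[ci])
      }))
    }
    classes <- sort(unique(labels))
    by_class <- lapply(classes, function(cl) which(labels == cl))
    test <- take(by_class, test_fraction)
    rest_by_class <- lapply(by_class, setdiff, y = test)
    val <- take(rest_by_class, val_fraction)
    train <- setdiff(unlist(rest_by_class), val)
    list(train = sort(train), val = sort(val), test = sort(test))
  })
}

#' Stratified fold assignment
#'
#' @param labels 0/1 labels of the subjects entering cross-validation.
#' @param folds Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
make_folds <- function(labels, folds = 10L, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  if (folds > min(table(labels))) {
    stop(sprintf("folds (%d) exceeds the minority class count (%d)",
                 folds, min(table(labels))))
  }
  withr_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on validation loss (ignored when
#'   no validation set is given).
#' @param restarts Number of independent seeded initializations; the run
#'   with the best final validation loss (training loss when no validation
#'   set exists) is kept. Guards against occasional collapse of attention
#'   training into a constant-prediction optimum.
#' @param class_weights Weight the cross-entropy of each class inversely to
#'   its training frequency (`FALSE` by default). An alternative to SMOTE
#'   for imbalanced cohorts: it balances the objective without creating
#'   interpolated subjects a model could learn to recognize.
#' @param seed Seed for initialization order, batching and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, lr = 5e-3, weight_decay = 5e-4,
                         batch_size = 16L, patience = 30L, restarts = 2L,
                         class_weights = FALSE, seed = 1L) {
  stopifnot(epochs >= 0, lr > 0, weight_decay >= 0, batch_size >= 1,
            patience >= 1, restarts >= 1, is.logical(class_weights))
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 restarts = as.integer(restarts),
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "train_config")
}

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

param_tree <- function(model) model[c("layer1", "layer2", "mlp")]

cross_entropy <- function(prob, y) -log(max(prob[y + 1L], 1e-12))

eval_loss_acc <- function(model, gds, idx, scaled) {
  losses <- numeric(length(idx))
  preds <- integer(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    fw <- gat_forward(scaled[[i]], gds$adj[[i]], model)
    losses[j] <- cross_entropy(fw$prob, gds$labels[i])
    preds[j] <- fw$pred
  }
  list(loss = mean(losses), acc = mean(preds == gds$labels[idx]),
       preds = preds)
}

#' Train the GAT classifier
#'
#' Minimizes mean cross-entropy with Adam over minibatches of graphs, with
#' L2 weight decay on weight matrices, dropout between the fully connected
#' layers, and early stopping on validation loss (the best-validation
#' parameters are restored). All randomness flows from `train_cfg$seed`.
#' Features must already be normalized ([fit_minmax()] on the training
#' subjects only).
#'
#' @param gds A `graph_dataset`.
#' @param scaled List of normalized feature matrices (same indexing as
#'   `gds`).
#' @param train_idx,val_idx Subject indices; `val_idx = NULL` disables
#'   early stopping.
#' @param model An initialized `gat_model` (or `NULL` to initialize from
#'   `model_cfg`).
#' @param model_cfg A `gat_config` used when `model` is `NULL`.
#' @param train_cfg A `train_config`.
#' @return The trained `gat_model` with a `history` data frame attached
#'   (per-epoch train loss/accuracy and, when available, validation
#'   loss/accuracy).
#' @export
train_gat <- function(gds, scaled, train_idx, val_idx = NULL, model = NULL,
                      model_cfg = gat_config(), train_cfg = train_config()) {
  restarts <- if (is.null(train_cfg$restarts)) 1L else train_cfg$restarts
  if (restarts > 1L && train_cfg$epochs > 0L && is.null(model)) {
    best <- NULL
    best_score <- Inf
    for (r in seq_len(restarts)) {
      tc <- train_cfg
      tc$restarts <- 1L
      tc$seed <- as.integer((train_cfg$seed + (r - 1L) * 7919L) %%
                              .Machine$integer.max)
      cand <- train_gat(gds, scaled, train_idx, val_idx, model = NULL,
                        model_cfg = model_cfg, train_cfg = tc)
      score <- if (!is.null(val_idx) &&
                   any(is.finite(cand$history$val_loss))) {
        min(cand$history$val_loss, na.rm = TRUE)
      } else {
        utils::tail(cand$history$train_loss, 1)
      }
      if (score < best_score) {
        best <- cand
        best_score <- score
      }
    }
    return(best)
  }
  if (is.null(model)) model <- init_gat(model_cfg, seed = train_cfg$seed)
  cfg <- model$cfg
  if (train_cfg$epochs == 0L) {
    model$history <- data.frame()
    return(model)
  }
  params <- param_tree(model)
  mstate <- tree_map(function(x) x * 0, params)
  vstate <- tree_map(function(x) x * 0, params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- vector("list", train_cfg$epochs)
  drop_p <- cfg$dropout
  n_drop_layers <- length(model$mlp) - 1L
  cw <- c(1, 1)
  if (isTRUE(train_cfg$class_weights)) {
    n_by_class <- tabulate(gds$labels[train_idx] + 1L, nbins = 2L)
    if (any(n_by_class == 0)) stop("both classes needed for class weights")
    cw <- length(train_idx) / (2 * n_by_class)
  }
  withr_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample(train_idx)
      batches <- split(perm, ceiling(seq_along(perm) / train_cfg$batch_size))
      ep_loss <- 0
      ep_correct <- 0L
      for (batch in batches) {
        gsum <- NULL
        for (i in batch) {
          dm <- if (drop_p > 0) {
            lapply(seq_len(n_drop_layers), function(l) {
              w <- length(model$mlp[[l]]$b)
              (stats::runif(w) > drop_p) / (1 - drop_p)
            })
          } else NULL
          fw <- gat_forward(scaled[[i]], gds$adj[[i]], model,
                            dropout_masks = dm, keep_cache = TRUE)
          y <- gds$labels[i]
          ep_loss <- ep_loss + cw[y + 1L] * cross_entropy(fw$prob, y)
          ep_correct <- ep_correct + (fw$pred == y)
          dlogits <- fw$prob
          dlogits[y + 1L] <- dlogits[y + 1L] - 1
          dlogits <- cw[y + 1L] * dlogits
          g <- gat_backward(fw, model, dlogits, dropout_masks = dm)
          g <- g[c("layer1", "layer2", "mlp")]
          gsum <- if (is.null(gsum)) g else tree_map(`+`, gsum, g)
        }
        g <- tree_map(function(x) x / length(batch), gsum)
        if (train_cfg$weight_decay > 0) {
          g <- tree_map(function(gr, p) {
            if (is.matrix(p)) gr + train_cfg$weight_decay * p else gr
          }, g, params)
        }
        step <- step + 1L
        mstate <- tree_map(function(mm, gg) beta1 * mm + (1 - beta1) * gg,
                           mstate, g)
        vstate <- tree_map(function(vv, gg) beta2 * vv + (1 - beta2) * gg^2,
                           vstate, g)
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        params <- tree_map(function(p, mm, vv) {
          p - train_cfg$lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
        }, params, mstate, vstate)
        model$layer1 <- params$layer1
        model$layer2 <- params$layer2
        model$mlp <- params$mlp
      }
      ep_loss <- ep_loss / length(train_idx)
      if (!is.finite(ep_loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch))
      }
      # training loss/accuracy accumulated during the minibatch sweep
      # (dropout active), avoiding a second full pass per epoch
      row <- data.frame(epoch = epoch, train_loss = ep_loss,
                        train_acc = ep_correct / length(train_idx),
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val_idx) && length(val_idx) > 0) {
        vl <- eval_loss_acc(model, gds, val_idx, scaled)
        row$val_loss <- vl$loss; row$val_acc <- vl$acc
        if (vl$loss < best$loss - 1e-9) {
          best <- list(loss = vl$loss, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[epoch]] <- row
      if (!is.null(val_idx) && wait >= train_cfg$patience) break
    }
  })
  if (!is.null(val_idx) && is.finite(best$loss)) {
    model$layer1 <- best$params$layer1
    model$layer2 <- best$params$layer2
    model$mlp <- best$params$mlp
  }
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 with the patient class (label 1)
#' positive: `F1 = 2 P R / (P + R)` (0 when the denominator is 0).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return A `classification_metrics` list with `accuracy`, `precision`,
#'   `recall`, `f1` and the 2 x 2 `confusion` table (rows = truth,
#'   columns = prediction).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0, 1))) stop("labels must be 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c("0", "1"),
                                      pred = c("0", "1")))
  structure(list(accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 confusion = confusion),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' For each fold: refit the min-max scaler on the training subjects only,
#' train the GAT from a fresh seeded initialization, and score the held-out
#' fold. The reported CV accuracy is the mean of the per-fold validation
#' accuracies.
#'
#' With `augment_within` set, class balancing happens leakage-safely
#' *inside* each fold: the training subjects alone are SMOTE-balanced,
#' synthetic graphs are reconstructed and their features recomputed, and
#' the held-out fold stays untouched raw data. (Balancing a cohort once
#' balances once before splitting; that order lets fold models recognize
#' interpolated subjects and their parents, which inflates fold accuracy —
#' most visibly on effect-free data.)
#'
#' @param gds A `graph_dataset`.
#' @param idx Subject indices entering CV (e.g. everything but the test
#'   set).
#' @param folds Number of folds (default 10).
#' @param model_cfg A `gat_config`.
#' @param train_cfg A `train_config`.
#' @param seed Seed for the fold assignment (training seeds derive from
#'   it).
#' @param augment_within `NULL`, or a list `(ds, k_neighbors)` where `ds`
#'   is the preprocessed raw cohort behind `gds`; enables fold-internal
#'   SMOTE balancing.
#' @return A `cv_result`: per-fold `classification_metrics`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_f1`, `fold_assignment`.
#' @export
cross_validate <- function(gds, idx = seq_along(gds$labels), folds = 10L,
                           model_cfg = gat_config(),
                           train_cfg = train_config(), seed = 1L,
                           augment_within = NULL) {
  labels <- gds$labels[idx]
  fold <- make_folds(labels, folds, seed = seed)
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- idx[fold != k]
    va <- idx[fold == k]
    g_run <- gds
    tr_run <- tr
    if (!is.null(augment_within)) {
      ext <- fold_augmented_features(augment_within$ds, tr,
                                     k_neighbors = augment_within$k_neighbors,
                                     seed = seed * 100L + k,
                                     mode = gds$mode)
      if (length(ext$features) > 0) {
        n0 <- length(g_run$features)
        g_run$features <- c(g_run$features, ext$features)
        g_run$adj <- c(g_run$adj, ext$adj)
        g_run$labels <- c(g_run$labels, ext$labels)
        tr_run <- c(tr, n0 + seq_along(ext$features))
      }
    }
    scaler <- fit_minmax(g_run$features[tr_run])
    scaled <- apply_minmax(scaler, g_run$features)
    tc <- train_cfg
    tc$seed <- as.integer((seed * 1000L + k) %% .Machine$integer.max)
    model <- train_gat(g_run, scaled, tr_run, va, model_cfg = model_cfg,
                       train_cfg = tc)
    ev <- eval_loss_acc(model, g_run, va, scaled)
    per_fold[[k]] <- compute_metrics(g_run$labels[va], ev$preds)
  }
  accs <- vapply(per_fold, function(mm) mm$accuracy, numeric(1))
  f1s <- vapply(per_fold, function(mm) mm$f1, numeric(1))
  structure(list(fold_metrics = per_fold, mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs), mean_f1 = mean(f1s),
                 fold_assignment = fold),
            class = "cv_result")
}

# SMOTE-balance the training subjects of one fold and compute features /
# adjacencies for the synthetic records only (raw features are reused)
fold_augmented_features <- function(ds, tr_idx, k_neighbors, seed, mode) {
  sub <- subset_cohort(ds, tr_idx)
  flats <- lapply(sub$subjects, flatten_subject)
  balanced <- smote_balance(flats, k_neighbors = k_neighbors,
                            seed = as.integer(seed %% .Machine$integer.max))
  synth <- balanced[vapply(balanced, function(f) f$synthetic, logical(1))]
  if (length(synth) == 0) {
    return(list(features = list(), adj = list(), labels = integer(0)))
  }
  synth_ds <- reconstruct_subjects(synth, ds$atlas)
  sg <- build_graph_dataset(synth_ds, mode = mode, preprocessed = TRUE)
  list(features = sg$features, adj = sg$adj, labels = sg$labels)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.3f +/- %.3f, F1 %.3f\n",
              length(x$fold_metrics), x$mean_accuracy, x$sd_accuracy,
              x$mean_f1))
  invisible(x)
}

#' Label-permutation significance test
#'
#' Tests whether the observed classification accuracy exceeds chance by
#' refitting (or, in cheap mode, re-scoring) under permuted labels. The
#' p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' `mode = "retrain"` permutes the labels of the train+eval subjects and
#' repeats the full train/evaluate pipeline per permutation (faithful but
#' expensive). `mode = "cheap"` trains once and permutes only the
#' evaluation labels against the fixed predictions; an approximation
#' suitable for smoke testing and calibration checks.
#'
#' @param gds A `graph_dataset`.
#' @param train_idx,eval_idx Disjoint subject index vectors.
#' @param model_cfg,train_cfg Model / training configuration.
#' @param n_permutations Number of label permutations (the reference
#'   analysis uses 1000).
#' @param seed RNG seed.
#' @param mode `"retrain"` or `"cheap"`.
#' @return List with `p_value`, `observed` accuracy, `null` accuracy
#'   vector, `mode`.
#' @export
permutation_test <- function(gds, train_idx, eval_idx,
                             model_cfg = gat_config(),
                             train_cfg = train_config(),
                             n_permutations = 1000L, seed = 1L,
                             mode = c("retrain", "cheap")) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  scaler <- fit_minmax(gds$features[train_idx])
  scaled <- apply_minmax(scaler, gds$features)
  model <- train_gat(gds, scaled, train_idx, val_idx = NULL,
                     model_cfg = model_cfg, train_cfg = train_cfg)
  ev <- eval_loss_acc(model, gds, eval_idx, scaled)
  observed <- ev$acc
  null_acc <- withr_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      if (mode == "cheap") {
        yperm <- sample(gds$labels[eval_idx])
        mean(ev$preds == yperm)
      } else {
        all_idx <- c(train_idx, eval_idx)
        yperm <- sample(gds$labels[all_idx])
        g2 <- gds
        g2$labels[all_idx] <- yperm
        tc <- train_cfg
        tc$seed <- as.integer((seed * 10000L + b) %% .Machine$integer.max)
        m2 <- train_gat(g2, scaled, train_idx, val_idx = NULL,
                        model_cfg = model_cfg, train_cfg = tc)
        eval_loss_acc(m2, g2, eval_idx, scaled)$acc
      }
    }, numeric(1))
  })
  list(p_value = (1 + sum(null_acc >= observed)) / (1 + n_permutations),
       observed = observed, null = null_acc, mode = mode)
}
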