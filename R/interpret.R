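#' Attention-head fidelity scores
#'
#' Quantifies each attention head's contribution to classification
#' accuracy: the head's learned coefficients are replaced by a mask
#' (uniform over each node's neighborhood by default, preserving message
#' magnitude while removing learned attention; or zeroed), predictions are
#' recomputed, and the fidelity is
#' `F = mean_i [1(yhat_i = y_i) - 1(yhat_masked_i = y_i)]` over the
#' evaluation graphs — the drop in per-graph correctness caused by masking.
#' Heads are ranked by F descending; F takes values in \[-1, 1\] in steps
#' of 1/N.
#'
#' @param model A trained `gat_model`.
#' @param scaled List of normalized feature matrices.
#' @param adj List of adjacency matrices.
#' @param labels 0/1 labels.
#' @param idx Indices of the evaluation subjects (conventionally the
#'   validation split).
#' @param mask_mode `"uniform"` (default) or `"zero"`.
#' @return A `fidelity_result`: data frame with `layer`, `head`,
#'   `fidelity`, ordered descending, plus `baseline_accuracy` and `n`
#'   attributes.
#' @export
fidelity_scores <- function(model, scaled, adj, labels,
                            idx = seq_along(labels),
                            mask_mode = c("uniform", "zero")) {
  mask_mode <- match.arg(mask_mode)
  if (!isTRUE(model$trained)) stop("model has not been trained")
  orig <- vapply(idx, function(i) {
    gat_forward(scaled[[i]], adj[[i]], model)$pred
  }, integer(1))
  correct0 <- orig == labels[idx]
  heads <- rbind(data.frame(layer = 1L, head = seq_along(model$layer1)),
                 data.frame(layer = 2L, head = seq_along(model$layer2)))
  fid <- vapply(seq_len(nrow(heads)), function(r) {
    msk <- list(layer = heads$layer[r], head = heads$head[r],
                mode = mask_mode)
    masked <- vapply(idx, function(i) {
      gat_forward(scaled[[i]], adj[[i]], model, mask = msk)$pred
    }, integer(1))
    fidelity_from_indicators(correct0, masked == labels[idx])
  }, numeric(1))
  out <- cbind(heads, fidelity = fid)
  out <- out[order(-out$fidelity, out$layer, out$head), ]
  rownames(out) <- NULL
  structure(out, class = c("fidelity_result", "data.frame"),
            baseline_accuracy = mean(correct0), n = length(idx),
            mask_mode = mask_mode)
}

#' Fidelity from correctness indicators
#'
#' The fidelity statistic on per-graph correctness indicators:
#' `F = (1/N) sum_i [1(yhat_i = y_i) - 1(yhat_masked_i = y_i)]`, the mean
#' drop in correctness caused by masking. E.g. 4 graphs all originally
#' correct with 2 correct after masking give F = 0.5.
#'
#' @param orig_correct,masked_correct Logical vectors of per-graph
#'   correctness before and after masking.
#' @return Fidelity in \[-1, 1\], a multiple of 1/N.
#' @export
fidelity_from_indicators <- function(orig_correct, masked_correct) {
  if (length(orig_correct) != length(masked_correct)) {
    stop("indicator vectors must have equal length")
  }
  mean(orig_correct) - mean(masked_correct)
}

#' Gradient saliency map
#'
#' Backpropagates from the model prediction to the multimodal input
#' features: for each correctly predicted evaluation graph, the gradient of
#' the predicted-class probability with respect to the n x F input matrix
#' is computed analytically; absolute values are averaged across those
#' graphs. High entries mark node/feature combinations driving correct
#' predictions.
#'
#' @inheritParams fidelity_scores
#' @param signed Keep the signed mean instead of the mean absolute
#'   gradient.
#' @return A `saliency_map`: n x F nonnegative (unless `signed`) matrix
#'   with feature column names, and attribute `sample_count`.
#' @export
saliency_map <- function(model, scaled, adj, labels,
                         idx = seq_along(labels), signed = FALSE) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  acc <- 0L
  total <- NULL
  for (i in idx) {
    fw <- gat_forward(scaled[[i]], adj[[i]], model, keep_cache = TRUE)
    if (fw$pred != labels[i]) next
    c_idx <- fw$pred + 1L
    p <- fw$prob
    # d p_c / d logits = p_c * (onehot(c) - p)
    dlogits <- -p[c_idx] * p
    dlogits[c_idx] <- dlogits[c_idx] + p[c_idx]
    g <- gat_backward(fw, model, dlogits)
    gh <- if (signed) g$dh else abs(g$dh)
    total <- if (is.null(total)) gh else total + gh
    acc <- acc + 1L
  }
  if (acc == 0L) {
    stop(sprintf("no correctly predicted samples among the %d evaluated",
                 length(idx)))
  }
  sal <- total / acc
  colnames(sal) <- colnames(scaled[[idx[1]]])
  structure(sal, class = c("saliency_map", class(sal)),
            sample_count = acc)
}

#' Select salient node/feature entries
#'
#' Entries of the saliency map exceeding `threshold` (default 0.02, the
#' conventional cut for moderately high gradients), sorted descending.
#'
#' @param sal A `saliency_map`.
#' @param threshold Nonnegative score cutoff; entries strictly above it are
#'   kept.
#' @param atlas Optional `brain_atlas` used to attach region names.
#' @return Data frame with `node` (1-based row), `region` (if atlas given),
#'   `feature`, `score`, ordered by descending score.
#' @export
select_salient <- function(sal, threshold = 0.02, atlas = NULL) {
  if (threshold < 0) stop("threshold must be >= 0")
  hits <- which(sal > threshold, arr.ind = TRUE)
  score <- sal[hits]
  out <- data.frame(node = hits[, 1],
                    feature = colnames(sal)[hits[, 2]],
                    score = score)
  if (!is.null(atlas)) out$region <- atlas$name[out$node]
  out[order(-out$score, out$node), , drop = FALSE]
}

#' Averaged attention maps
#'
#' Mean attention-coefficient matrix per head over the correctly predicted
#' evaluation graphs, plus a symmetrized variant `(A + t(A))/2` for display
#' as an undirected region-by-region weight matrix; a display threshold
#' zeroes small entries.
#'
#' @inheritParams fidelity_scores
#' @param display_threshold Entries of the symmetrized matrix at or below
#'   this value are zeroed in `$thresholded`.
#' @return An `attention_summary`: nested list per layer/head with `mean`
#'   (directed, rows sum to 1 over neighborhoods), `symmetric`,
#'   `thresholded`; attribute `sample_count`.
#' @export
attention_summary <- function(model, scaled, adj, labels,
                              idx = seq_along(labels),
                              display_threshold = 0) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  sums <- NULL
  acc <- 0L
  for (i in idx) {
    fw <- gat_forward(scaled[[i]], adj[[i]], model, record_attention = TRUE)
    if (fw$pred != labels[i]) next
    sums <- if (is.null(sums)) fw$attention else {
      list(layer1 = Map(`+`, sums$layer1, fw$attention$layer1),
           layer2 = Map(`+`, sums$layer2, fw$attention$layer2))
    }
    acc <- acc + 1L
  }
  if (acc == 0L) {
    stop(sprintf("no correctly predicted samples among the %d evaluated",
                 length(idx)))
  }
  summarize <- function(a) {
    mean_a <- a / acc
    sym <- (mean_a + t(mean_a)) / 2
    thr <- sym
    thr[thr <= display_threshold] <- 0
    list(mean = mean_a, symmetric = sym, thresholded = thr)
  }
  structure(list(layer1 = lapply(sums$layer1, summarize),
                 layer2 = lapply(sums$layer2, summarize)),
            class = "attention_summary", sample_count = acc,
            display_threshold = display_threshold)
}

#' Correlate salient features with clinical variables
#'
#' Pearson correlation between each salient node/feature value (across real
#' patients; SMOTE-synthetic subjects carry no clinical data and are
#' excluded) and each clinical variable, with two-sided p-values flagged at
#' the uncorrected `alpha` (default 0.005). Zero-variance series give an
#' undefined (NA) result rather than an error.
#'
#' @param salient Data frame from [select_salient()].
#' @param ds The cohort the model was derived from.
#' @param features List of per-subject (un-normalized) feature matrices
#'   aligned with `ds$subjects`.
#' @param alpha Significance threshold on the uncorrected p-value.
#' @param label_filter Labels of subjects to correlate over (default
#'   patients, label 1).
#' @return Data frame with `node`, `feature`, `clinical`, `r`, `p`,
#'   `n_used`, `significant`.
#' @export
correlate_clinical <- function(salient, ds, features, alpha = 0.005,
                               label_filter = 1L) {
  labs <- cohort_labels(ds)
  synth <- vapply(ds$subjects, function(s) s$synthetic, logical(1))
  keep <- which(labs %in% label_filter & !synth)
  rows <- list()
  for (r in seq_len(nrow(salient))) {
    node <- salient$node[r]
    feat <- salient$feature[r]
    x_all <- vapply(keep, function(i) features[[i]][node, feat], numeric(1))
    for (cv in clinical_vars()) {
      y_all <- vapply(keep, function(i) ds$subjects[[i]]$clinical[[cv]],
                      numeric(1))
      ok <- is.finite(x_all) & is.finite(y_all)
      n_used <- sum(ok)
      if (n_used < 3) next
      if (stats::sd(x_all[ok]) == 0 || stats::sd(y_all[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          node = node, feature = feat, clinical = cv,
          r = NA_real_, p = NA_real_, n_used = n_used,
          significant = FALSE)
        next
      }
      ct <- stats::cor.test(x_all[ok], y_all[ok], method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        node = node, feature = feat, clinical = cv,
        r = unname(ct$estimate), p = ct$p.value, n_used = n_used,
        significant = is.finite(ct$p.value) && ct$p.value < alpha)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(node = integer(0), feature = character(0),
                      clinical = character(0), r = numeric(0),
                      p = numeric(0), n_used = integer(0),
                      significant = logical(0)))
  }
  do.call(rbind, rows)
}
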