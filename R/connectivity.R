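#' Connectivity matrices
#'
#' A `connectivity_matrix` holds one subject's undirected weighted brain
#' graph: an n x n symmetric matrix with zero diagonal whose node order is
#' fixed by an atlas. Structural connectivity (SC) carries nonnegative
#' tractography-derived connection probabilities; functional connectivity
#' (FC) carries signed correlations (raw Pearson r, or Fisher-z after
#' [fisher_z()]).
#'
#' @param values n x n numeric matrix.
#' @param modality `"SC"` or `"FC"`.
#' @param subject_id Subject identifier string.
#' @param asym_tol Maximum tolerated asymmetry `max|M - t(M)|`; matrices
#'   within tolerance are symmetrized as `(M + t(M))/2`, larger asymmetry is
#'   an error rather than a silent fix.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, modality = c("SC", "FC"),
                                subject_id = "", asym_tol = 1e-6) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    stop(sprintf("connectivity matrix must be square, got %dx%d",
                 nrow(values), ncol(values)))
  }
  asym <- max(abs(values - t(values)))
  if (asym > asym_tol) {
    stop(sprintf("subject '%s': matrix asymmetry %.3g exceeds tolerance %.3g",
                 subject_id, asym, asym_tol))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (modality == "SC" && any(values < 0)) {
    stop(sprintf("subject '%s': SC weights must be nonnegative", subject_id))
  }
  structure(list(values = values, modality = modality,
                 subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  nz <- sum(x$values[upper.tri(x$values)] != 0)
  cat(sprintf("<connectivity_matrix> %s subject='%s' %dx%d, %d edges\n",
              x$modality, x$subject_id, nrow(x$values), ncol(x$values), nz))
  invisible(x)
}

n_nodes <- function(m) nrow(m$values)

check_modality <- function(m, expected) {
  if (!inherits(m, "connectivity_matrix")) {
    stop("expected a connectivity_matrix")
  }
  if (!is.null(expected) && m$modality != expected) {
    stop(sprintf("operation requires %s modality, got %s",
                 expected, m$modality))
  }
  invisible(m)
}

#' Absolute thresholding of structural connectivity
#'
#' Zeroes all edges weaker than `t`, keeping values `>= t` unchanged
#' (non-strict, so an edge exactly at the threshold survives). The default
#' threshold 0.1 is the standard cut for probabilistic-tractography SC
#' matrices, removing weak, likely spurious connections while keeping the
#' stronger ones.
#'
#' @param m An SC `connectivity_matrix`.
#' @param t Nonnegative threshold.
#' @return A thresholded `connectivity_matrix`.
#' @export
threshold_absolute <- function(m, t = 0.1) {
  check_modality(m, "SC")
  if (!is.numeric(t) || length(t) != 1 || t < 0) {
    stop("threshold t must be a single nonnegative number")
  }
  v <- m$values
  v[v < t] <- 0
  diag(v) <- 0
  m$values <- v
  m
}

#' Fisher r-to-z transform of functional connectivity
#'
#' Replaces each off-diagonal correlation r by `atanh(r)`, the variance-
#' stabilizing transform conventionally applied to FC matrices before
#' thresholding. The diagonal stays zero.
#'
#' @param m An FC `connectivity_matrix` of raw correlations, `|r| < 1`.
#' @return A `connectivity_matrix` of Fisher-z values.
#' @export
fisher_z <- function(m) {
  check_modality(m, "FC")
  v <- m$values
  off <- abs(v) >= 1
  diag(off) <- FALSE
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("subject '%s': |r| >= 1 at entry (%d, %d); Fisher z undefined",
                 m$subject_id, idx[1], idx[2]))
  }
  z <- atanh(v)
  diag(z) <- 0
  m$values <- z
  m
}

#' Density thresholding of functional connectivity
#'
#' Retains the top `ceiling(density * E)` undirected off-diagonal edges,
#' where `E = n(n-1)/2`, and zeroes the rest. By default edges are ranked by
#' signed value (the most positive connections are the "strongest" after
#' Fisher z); set `rank_by = "absolute"` to rank by magnitude instead. Ties
#' at the boundary are broken by (row, col) lexicographic order so the
#' result is deterministic. Exactly-zero entries are treated as absent
#' edges and never retained, which makes the operation idempotent.
#'
#' @param m An FC `connectivity_matrix` (typically Fisher-z transformed).
#' @param density Fraction of all possible edges to keep, in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return A thresholded `connectivity_matrix`.
#' @export
threshold_density <- function(m, density = 0.5,
                              rank_by = c("signed", "absolute")) {
  check_modality(m, "FC")
  rank_by <- match.arg(rank_by)
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stop("density must be in (0, 1]")
  }
  v <- m$values
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)  # already (row, col) lexicographic
                                             # within each column; reorder below
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- v[ut]
  score <- if (rank_by == "absolute") abs(vals) else vals
  score[vals == 0] <- -Inf            # absent edges never count as "strong"
  n_edges <- nrow(ut)
  n_keep <- min(ceiling(density * n_edges), sum(vals != 0))
  # stable sort: descending score, ties by (row, col)
  keep <- order(-score, ut[, 1], ut[, 2])[seq_len(n_keep)]
  out <- matrix(0, n, n)
  ik <- ut[keep, , drop = FALSE]
  out[ik] <- vals[keep]
  out <- out + t(out)
  m$values <- out
  m
}

#' Binary adjacency of surviving edges
#'
#' @param m A `connectivity_matrix`.
#' @param self_loops Add self-loops (used by the attention neighborhoods).
#' @return n x n binary matrix.
#' @export
binarize <- function(m, self_loops = FALSE) {
  a <- (m$values != 0) * 1
  if (self_loops) diag(a) <- 1 else diag(a) <- 0
  a
}
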