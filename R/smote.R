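#' Flatten a subject for SMOTE
#'
#' Concatenates, in a fixed deterministic order, the SC upper triangle
#' (row-major), the FC upper triangle (row-major) and the morphology block
#' (row-major), giving a vector of length `2 n(n-1)/2 + 2n` (7482 for the
#' 86-node atlas). SMOTE interpolation operates on these vectors; the
#' flatten/reconstruct pair round-trips exactly.
#'
#' @param rec A `subject_record` whose SC/FC are already thresholded and
#'   (FC) Fisher-z transformed.
#' @return A `flattened_subject`: list with `vector`, `label`,
#'   `subject_id`, `clinical`, `synthetic`.
#' @export
flatten_subject <- function(rec) {
  n <- n_nodes(rec$sc)
  ut <- upper_tri_rowmajor(n)
  structure(list(vector = c(rec$sc$values[ut], rec$fc$values[ut],
                            as.vector(t(rec$morphology))),
                 label = rec$label, subject_id = rec$subject_id,
                 clinical = rec$clinical, synthetic = rec$synthetic),
            class = "flattened_subject")
}

# linear indices of the strict upper triangle in row-major order
upper_tri_rowmajor <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  (idx[, 2] - 1L) * n + idx[, 1]
}

#' SMOTE class balancing
#'
#' Oversamples the minority class to the majority count by synthetic
#' minority oversampling: each synthetic vector is drawn on the segment
#' between a random minority sample and one of its `k_neighbors` nearest
#' minority neighbors (Euclidean), with interpolation coefficient uniform
#' in [0, 1]. Originals are preserved; synthetic records are tagged and
#' carry no clinical values (none exist for an interpolated subject).
#'
#' @param flats List of `flattened_subject`s containing both classes.
#' @param k_neighbors Number of nearest minority neighbors (default 5).
#' @param seed RNG seed; fixed seed gives a byte-identical result.
#' @return List of `flattened_subject`s with equal class counts; synthetic
#'   entries carry attributes `parents` (indices into the minority set) and
#'   `gap` (interpolation coefficient) for auditability.
#' @export
smote_balance <- function(flats, k_neighbors = 5L, seed = 1L) {
  labels <- vapply(flats, function(f) f$label, integer(1))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present for SMOTE")
  if (counts[["0"]] == counts[["1"]]) return(flats)
  minority <- as.integer(names(which.min(counts)))
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  n_new <- abs(diff(as.integer(counts)))
  if (n_min <= k_neighbors) {
    stop(sprintf(paste0("minority class has %d samples but k_neighbors = %d; ",
                        "use k_neighbors < %d"), n_min, k_neighbors, n_min))
  }
  x <- do.call(rbind, lapply(flats[min_idx], function(f) f$vector))
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k_neighbors)])
  nn <- t(matrix(nn, nrow = k_neighbors))   # n_min x k even when k = 1
  synth <- withr_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    gap <- stats::runif(n_new)
    lapply(seq_len(n_new), function(j) {
      i <- base[j]; nb <- nn[i, pick[j]]
      vec <- x[i, ] + gap[j] * (x[nb, ] - x[i, ])
      out <- structure(list(vector = vec, label = minority,
                            subject_id = sprintf("smote_%03d", j),
                            clinical = stats::setNames(
                              rep(NA_real_, length(clinical_vars())),
                              clinical_vars()),
                            synthetic = TRUE),
                       class = "flattened_subject")
      attr(out, "parents") <- c(i, nb)
      attr(out, "gap") <- gap[j]
      out
    })
  })
  c(flats, synth)
}

#' Rebuild subject records from flattened vectors
#'
#' Inverse of [flatten_subject()] applied to a whole list: symmetric
#' matrices are rebuilt from the stored triangles and negative synthetic SC
#' entries (possible only through interpolation artifacts; SMOTE of
#' nonnegative parents cannot create them, but clipping keeps the invariant
#' explicit) are clipped to 0. Reconstructed graphs feed the downstream
#' recomputation of network features.
#'
#' @param flats List of `flattened_subject`s.
#' @param atlas A `brain_atlas` fixing n.
#' @return A `cohort_dataset` with provenance `smote_augmented` when any
#'   record is synthetic.
#' @export
reconstruct_subjects <- function(flats, atlas) {
  n <- atlas_size(atlas)
  e <- n * (n - 1) / 2
  want <- 2 * e + 2 * n
  ut <- upper_tri_rowmajor(n)
  subjects <- lapply(flats, function(f) {
    if (length(f$vector) != want) {
      stop(sprintf("flattened vector has length %d, expected %d for n = %d",
                   length(f$vector), want, n))
    }
    unflat <- function(tri) {
      mmat <- matrix(0, n, n)
      mmat[ut] <- tri
      mmat + t(mmat)
    }
    sc_v <- pmax(unflat(f$vector[seq_len(e)]), 0)
    fc_v <- unflat(f$vector[e + seq_len(e)])
    morph <- matrix(f$vector[2 * e + seq_len(2 * n)], n, 2, byrow = TRUE)
    subject_record(f$subject_id, f$label,
                   connectivity_matrix(sc_v, "SC", f$subject_id),
                   connectivity_matrix(fc_v, "FC", f$subject_id),
                   morph, as.list(f$clinical), synthetic = f$synthetic)
  })
  prov <- if (any(vapply(subjects, function(s) s$synthetic, logical(1)))) {
    "smote_augmented"
  } else "synthetic"
  cohort_dataset(subjects, atlas, provenance = prov)
}

#' SMOTE-balance a cohort end to end
#'
#' Flattens every subject, balances classes with [smote_balance()] and
#' reconstructs a `cohort_dataset`; a convenience wrapper for the standard
#' flatten -> interpolate -> rebuild sequence applied to preprocessed
#' (thresholded, Fisher-z) cohorts.
#'
#' @inheritParams smote_balance
#' @param ds A preprocessed `cohort_dataset`.
#' @return A balanced `cohort_dataset`.
#' @export
augment_cohort <- function(ds, k_neighbors = 5L, seed = 1L) {
  flats <- lapply(ds$subjects, flatten_subject)
  reconstruct_subjects(smote_balance(flats, k_neighbors, seed), ds$atlas)
}
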