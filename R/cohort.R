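#' Subject records and cohort datasets
#'
#' A `subject_record` bundles one participant: binary group label (patient
#' = 1, control = 0), SC and FC connectivity matrices, an n x 2 morphology
#' block (regional volume in mm^3, cortical thickness in mm; thickness of
#' subcortical regions, anatomically undefined, is imputed as 0), and a
#' named list of clinical variables (AAO, DOI, UPDRS_III, HY, MMSE, LEDD;
#' `NA` when missing). A `cohort_dataset` is a list of such records sharing
#' one atlas, tagged with provenance (`real`, `smote_augmented`,
#' `synthetic`).
#'
#' @param subject_id Identifier string.
#' @param label Group label, 0 (control) or 1 (patient).
#' @param sc,fc `connectivity_matrix` objects (modalities SC and FC).
#' @param morphology n x 2 numeric matrix, columns `volume`, `thickness`.
#' @param clinical Named list/vector of clinical values (may contain `NA`).
#' @param synthetic Logical; `TRUE` for SMOTE-generated records.
#' @return A `subject_record`.
#' @export
subject_record <- function(subject_id, label, sc, fc, morphology,
                           clinical = NULL, synthetic = FALSE) {
  if (!label %in% c(0, 1)) {
    stop(sprintf("subject '%s': label must be 0 or 1, got '%s'",
                 subject_id, as.character(label)))
  }
  check_modality(sc, "SC"); check_modality(fc, "FC")
  n <- n_nodes(sc)
  if (n_nodes(fc) != n) {
    stop(sprintf("subject '%s': SC is %d nodes but FC is %d",
                 subject_id, n, n_nodes(fc)))
  }
  morphology <- as.matrix(morphology)
  if (nrow(morphology) != n || ncol(morphology) != 2) {
    stop(sprintf("subject '%s': morphology must be %d x 2", subject_id, n))
  }
  colnames(morphology) <- c("volume", "thickness")
  clin <- stats::setNames(rep(NA_real_, length(clinical_vars())),
                          clinical_vars())
  if (!is.null(clinical)) {
    known <- intersect(names(clinical), clinical_vars())
    clin[known] <- as.numeric(unlist(clinical[known]))
  }
  structure(list(subject_id = as.character(subject_id),
                 label = as.integer(label), sc = sc, fc = fc,
                 morphology = morphology, clinical = clin,
                 synthetic = isTRUE(synthetic)),
            class = "subject_record")
}

clinical_vars <- function() c("AAO", "DOI", "UPDRS_III", "HY", "MMSE", "LEDD")

#' @param subjects List of `subject_record`s.
#' @param atlas A `brain_atlas`.
#' @param provenance `"real"`, `"smote_augmented"` or `"synthetic"`.
#' @rdname subject_record
#' @export
cohort_dataset <- function(subjects, atlas,
                           provenance = c("real", "smote_augmented",
                                          "synthetic")) {
  provenance <- match.arg(provenance)
  n <- atlas_size(atlas)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (s in subjects) {
    if (n_nodes(s$sc) != n) {
      stop(sprintf("subject '%s': matrices are %d nodes but atlas has %d",
                   s$subject_id, n_nodes(s$sc), n))
    }
  }
  structure(list(subjects = subjects, atlas = atlas,
                 provenance = provenance),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  labs <- cohort_labels(x)
  cat(sprintf(
    "<cohort_dataset> %d subjects (%d patients, %d controls), %d nodes, %s\n",
    length(x$subjects), sum(labs == 1), sum(labs == 0),
    atlas_size(x$atlas), x$provenance))
  invisible(x)
}

#' @export
length.cohort_dataset <- function(x) length(x$subjects)

#' Group labels of a cohort
#' @param ds A `cohort_dataset`.
#' @return Integer vector of 0/1 labels, one per subject.
#' @export
cohort_labels <- function(ds) {
  vapply(ds$subjects, function(s) s$label, integer(1))
}

subset_cohort <- function(ds, idx) {
  cohort_dataset(ds$subjects[idx], ds$atlas, provenance = ds$provenance)
}

#' Load a cohort from a manifest and matrix directory
#'
#' The manifest is a CSV with header
#' `subject_id,label,AAO,DOI,UPDRS_III,HY,MMSE,LEDD` (clinical cells may be
#' empty; an optional `provenance` column with values `real`/`smote` marks
#' augmented records). For each subject the matrix directory must contain
#' `<id>_SC.csv`, `<id>_FC.csv` (n x n delimited matrices) and
#' `<id>_morph.csv` (n x 2: volume, thickness). Matrices with asymmetry
#' within 1e-6 are symmetrized; larger asymmetry is an error.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param matrix_dir Directory holding the per-subject matrix files.
#' @param atlas A `brain_atlas`; matrix dimensions must match.
#' @return A validated `cohort_dataset`.
#' @export
load_cohort <- function(manifest_path, matrix_dir, atlas = dk_atlas()) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(man))) {
    stop("manifest must have subject_id and label columns")
  }
  n <- atlas_size(atlas)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    id <- as.character(man$subject_id[i])
    lab <- man$label[i]
    if (!lab %in% c(0, 1)) {
      stop(sprintf("subject '%s': non-binary label '%s'",
                   id, as.character(lab)))
    }
    read_mat <- function(suffix) {
      f <- file.path(matrix_dir, paste0(id, "_", suffix, ".csv"))
      if (!file.exists(f)) {
        stop(sprintf("subject '%s': missing matrix file '%s'", id, f))
      }
      as.matrix(utils::read.csv(f, header = FALSE))
    }
    sc_v <- unname(read_mat("SC")); fc_v <- unname(read_mat("FC"))
    for (v in list(sc_v, fc_v)) {
      if (nrow(v) != n || ncol(v) != n) {
        stop(sprintf("subject '%s': matrix is %dx%d but atlas has %d regions",
                     id, nrow(v), ncol(v), n))
      }
    }
    morph <- unname(read_mat("morph"))
    clin <- as.list(man[i, intersect(clinical_vars(), names(man))])
    synth <- "provenance" %in% names(man) && man$provenance[i] == "smote"
    subject_record(id, lab,
                   connectivity_matrix(sc_v, "SC", id),
                   connectivity_matrix(fc_v, "FC", id),
                   morph, clin, synthetic = synth)
  })
  prov <- if (any(vapply(subjects, function(s) s$synthetic, logical(1)))) {
    "smote_augmented"
  } else "real"
  cohort_dataset(subjects, atlas, provenance = prov)
}

#' Write a cohort as a manifest plus matrix directory
#'
#' Inverse of [load_cohort()]: emits `manifest.csv` and per-subject
#' `<id>_SC.csv`, `<id>_FC.csv`, `<id>_morph.csv` under `dir`.
#'
#' @param ds A `cohort_dataset`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(ds$subjects, function(s) {
    w <- function(m, suffix) {
      utils::write.table(m, file.path(dir, paste0(s$subject_id, "_",
                                                  suffix, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    w(s$sc$values, "SC"); w(s$fc$values, "FC"); w(s$morphology, "morph")
    c(list(subject_id = s$subject_id, label = s$label),
      as.list(s$clinical),
      list(provenance = if (s$synthetic) "smote" else "real"))
  })
  man <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, na = "")
  invisible(path)
}
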