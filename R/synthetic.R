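#' Synthetic cohort configuration
#'
#' Defines the study conditions a generated cohort emulates: a two-group
#' cohort (75 patients / 34 controls by default, matching a typical
#' single-center movement-disorders sample) over an 86-node parcellation,
#' with a disease effect planted on a small set of motor-circuit nodes:
#' SC edges touching affected nodes are scaled down in patients
#' (`sc_effect`), their functional coupling to their community factor is
#' reduced (`fc_effect`), and their morphology shrinks (`morph_effect`).
#' Clinical variables are drawn around published movement-disorder cohort
#' statistics (e.g. UPDRS-III mean ~34.5); `clinical_coupling` adds linear
#' dependence of a clinical variable on a planted nodal quantity so
#' correlation-recovery is testable.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_nodes Parcellation size; 86 uses the bundled atlas.
#' @param affected_nodes 0-based node indices carrying the planted effect.
#'   Default: bilateral putamen and pallidum plus right thalamus on the
#'   86-node atlas; the first five nodes on other parcellation sizes.
#' @param sc_effect Fractional reduction of patient SC weights incident to
#'   affected nodes, in \[0, 1).
#' @param fc_effect Fractional reduction of patient FC factor loadings on
#'   affected nodes, in \[0, 1).
#' @param morph_effect Fractional reduction of patient morphology on
#'   affected nodes, in \[0, 1).
#' @param sc_noise Log-normal sd of subject-level SC edge noise.
#' @param fc_timepoints Latent time-series length behind each FC matrix.
#' @param clinical_coupling Named list: clinical variable ->
#'   `list(node, slope)`; the variable gains `slope` per standard deviation
#'   of that node's SC strength across patients. Default: AAO coupled with
#'   slope -6 to the first affected node.
#' @param seed Integer seed; the whole cohort is deterministic in it.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 75L, n_controls = 34L,
                             n_nodes = 86L,
                             affected_nodes = NULL,
                             sc_effect = 0.5, fc_effect = 0.3,
                             morph_effect = 0.1, sc_noise = 0.25,
                             fc_timepoints = 120L,
                             clinical_coupling = NULL,
                             seed = 1L) {
  stopifnot(n_patients >= 2, n_controls >= 2, n_nodes >= 4,
            sc_effect >= 0, sc_effect < 1, fc_effect >= 0, fc_effect < 1,
            morph_effect >= 0, morph_effect < 1)
  if (is.null(affected_nodes)) {
    affected_nodes <- if (n_nodes == 86L) {
      c(70L, 71L, 79L, 80L, 77L)   # bilateral putamen/pallidum, R thalamus
    } else {
      seq_len(min(5L, n_nodes)) - 1L
    }
  }
  if (any(affected_nodes < 0 | affected_nodes >= n_nodes)) {
    stop(sprintf("affected node index out of range [0, %d)", n_nodes))
  }
  if (is.null(clinical_coupling)) {
    # couple age-at-onset negatively to the first affected node's SC
    # strength (later onset <-> weaker planted structural influence)
    clinical_coupling <- list(AAO = list(node = affected_nodes[1],
                                         slope = -6))
  }
  for (cp in clinical_coupling) {
    if (cp$node < 0 || cp$node >= n_nodes) {
      stop("clinical_coupling node index out of range")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_nodes = as.integer(n_nodes),
                 affected_nodes = as.integer(affected_nodes),
                 sc_effect = sc_effect, fc_effect = fc_effect,
                 morph_effect = morph_effect, sc_noise = sc_noise,
                 fc_timepoints = as.integer(fc_timepoints),
                 clinical_coupling = clinical_coupling,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

generic_atlas <- function(n) {
  df <- data.frame(index = 0:(n - 1L),
                   name = sprintf("region_%02d", 0:(n - 1L)),
                   hemisphere = "none",
                   class = "cortical")
  structure(df, class = c("brain_atlas", "data.frame"))
}

#' Generate a synthetic two-group cohort
#'
#' Draws a full `cohort_dataset` under a `synthetic_config`:
#' \itemize{
#'   \item SC: a community-structured nonnegative template (4 modules;
#'     within-module edges strong, between-module edges weak so absolute
#'     thresholding at 0.1 sparsens realistically) with multiplicative
#'     log-normal subject noise; patient edges touching affected nodes are
#'     scaled by `1 - sc_effect`.
#'   \item FC: correlation matrices from a latent-factor model sharing the
#'     SC community structure (each node loads on its module factor), so
#'     entries lie in (-1, 1) and Fisher z / density thresholding behave
#'     realistically; patient loadings on affected nodes are reduced by
#'     `fc_effect`.
#'   \item Morphology: Gaussian around region-typical volume and cortical
#'     thickness (thickness 0 for subcortical regions); patient values on
#'     affected nodes reduced by `morph_effect`.
#'   \item Clinical: patient variables drawn around movement-disorder
#'     cohort statistics, plus the linear couplings of
#'     `clinical_coupling`; controls carry MMSE only.
#' }
#'
#' @param cfg A `synthetic_config`.
#' @return A `cohort_dataset` with provenance `synthetic`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  n <- cfg$n_nodes
  atlas <- if (n == 86L) dk_atlas() else generic_atlas(n)
  aff <- cfg$affected_nodes + 1L
  withr_seed(cfg$seed, {
    module <- rep_len(seq_len(4L), n)[sample.int(n)]
    within <- outer(module, module, "==")
    tmpl <- matrix(0, n, n)
    ut <- upper.tri(tmpl)
    tmpl[ut & within] <- stats::runif(sum(ut & within), 0.10, 0.80)
    tmpl[ut & !within] <- stats::runif(sum(ut & !within), 0.00, 0.20)
    tmpl <- tmpl + t(tmpl)
    vol_base <- stats::runif(n, 2000, 18000)
    thick_base <- stats::rnorm(n, 2.5, 0.25)
    is_cortical <- atlas$class == "cortical"
    thick_base[!is_cortical] <- 0        # imputed-0 convention, subcortical
    rho <- stats::runif(n, 0.35, 0.60)   # factor loadings (shared template)

    n_total <- cfg$n_patients + cfg$n_controls
    labels <- c(rep(1L, cfg$n_patients), rep(0L, cfg$n_controls))
    edge_mask <- outer(seq_len(n) %in% aff, seq_len(n) %in% aff, "|")

    subjects <- lapply(seq_len(n_total), function(si) {
      lab <- labels[si]
      id <- sprintf("%s%03d", if (lab == 1) "pd" else "hc", si)
      noise <- matrix(0, n, n)
      noise[ut] <- stats::rnorm(sum(ut), 0, cfg$sc_noise)
      noise <- noise + t(noise)
      sc <- tmpl * exp(noise)
      if (lab == 1 && cfg$sc_effect > 0) {
        sc[edge_mask] <- sc[edge_mask] * (1 - cfg$sc_effect)
      }
      diag(sc) <- 0

      rho_s <- rho
      if (lab == 1 && cfg$fc_effect > 0) {
        rho_s[aff] <- rho_s[aff] * (1 - cfg$fc_effect)
      }
      tt <- cfg$fc_timepoints
      f <- matrix(stats::rnorm(tt * 4L), tt, 4L)
      e <- matrix(stats::rnorm(tt * n), tt, n)
      y <- f[, module] * rep(sqrt(rho_s), each = tt) +
        e * rep(sqrt(1 - rho_s), each = tt)
      fc <- stats::cor(y)
      diag(fc) <- 0

      vol <- vol_base * stats::rnorm(n, 1, 0.08)
      thick <- thick_base + stats::rnorm(n, 0, 0.10)
      thick[!is_cortical] <- 0
      if (lab == 1 && cfg$morph_effect > 0) {
        vol[aff] <- vol[aff] * (1 - cfg$morph_effect)
        thick[aff] <- thick[aff] * (1 - cfg$morph_effect)
      }
      thick <- pmax(thick, 0)

      list(id = id, label = lab, sc = sc, fc = fc,
           morph = cbind(vol, thick))
    })

    # clinical variables: cohort-typical distributions + planted couplings
    pat_idx <- which(labels == 1L)
    strength <- vapply(subjects, function(s) rowSums(s$sc), numeric(n))
    base <- list(AAO = c(51.14, 9.08), DOI = c(5.87, 2.74),
                 UPDRS_III = c(34.53, 8.25), HY = c(2.31, 0.28),
                 MMSE = c(28.04, 1.61), LEDD = c(616.01, 277.65))
    clin <- matrix(NA_real_, n_total, length(clinical_vars()),
                   dimnames = list(NULL, clinical_vars()))
    for (v in clinical_vars()) {
      draw <- stats::rnorm(n_total, base[[v]][1], base[[v]][2])
      cp <- cfg$clinical_coupling[[v]]
      if (!is.null(cp)) {
        s_aff <- strength[cp$node + 1L, pat_idx]
        z <- (s_aff - mean(s_aff)) / stats::sd(s_aff)
        draw[pat_idx] <- base[[v]][1] + cp$slope * z +
          stats::rnorm(length(pat_idx), 0, base[[v]][2] / 2)
      }
      clin[pat_idx, v] <- draw[pat_idx]
      if (v == "MMSE") clin[, v] <- draw   # controls screened with MMSE too
    }
    clin[, "MMSE"] <- pmin(clin[, "MMSE"], 30)
    clin[, "HY"] <- pmax(clin[, "HY"], 1)

    recs <- lapply(seq_len(n_total), function(si) {
      s <- subjects[[si]]
      subject_record(s$id, s$label,
                     connectivity_matrix(s$sc, "SC", s$id),
                     connectivity_matrix(s$fc, "FC", s$id),
                     s$morph, as.list(clin[si, ]))
    })
    cohort_dataset(recs, atlas, provenance = "synthetic")
  })
}

#' Tiny cohort with hand-checkable graph motifs
#'
#' Builds closed-form fixtures for oracle tests: a unit-weight triangle
#' (every node has clustering coefficient 1 and betweenness 0), a 5-node
#' star (center betweenness 6 = number of dependent leaf pairs), two
#' disconnected 4-cliques (community detection must separate them), and a
#' 2-subject micro-cohort over `n_nodes` nodes embedding the triangle in
#' nodes 1..3 with the remaining nodes on a path.
#'
#' @param n_nodes Micro-cohort size, 4..6.
#' @param seed RNG seed for the FC part of the micro-cohort.
#' @return List with `triangle`, `star5`, `two_cliques`
#'   (`connectivity_matrix` objects), `cohort` (2-subject
#'   `cohort_dataset`), and `notes` (named closed-form values).
#' @export
generate_worked_micro <- function(n_nodes = 6L, seed = 1L) {
  stopifnot(n_nodes >= 4, n_nodes <= 6)
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  cl <- matrix(0, 8, 8)
  cl[1:4, 1:4] <- 1; cl[5:8, 5:8] <- 1; diag(cl) <- 0
  n <- n_nodes
  sc <- matrix(0, n, n)
  sc[1, 2] <- sc[2, 3] <- sc[1, 3] <- 1          # triangle in nodes 1..3
  if (n > 3) for (i in 3:(n - 1)) sc[i, i + 1] <- 0.5
  sc <- sc + t(sc)
  fc <- withr_seed(seed, {
    y <- matrix(stats::rnorm(40 * n), 40, n)
    f <- stats::cor(y); diag(f) <- 0; f
  })
  morph <- cbind(stats::setNames(rep(1000, n), NULL), rep(2.5, n))
  atlas <- generic_atlas(n)
  cohort <- cohort_dataset(list(
    subject_record("micro_pd", 1L, connectivity_matrix(sc, "SC", "micro_pd"),
                   connectivity_matrix(fc, "FC", "micro_pd"), morph,
                   list(AAO = 50, UPDRS_III = 30)),
    subject_record("micro_hc", 0L, connectivity_matrix(sc * 0.8, "SC",
                                                       "micro_hc"),
                   connectivity_matrix(fc * 0.5, "FC", "micro_hc"), morph,
                   list(MMSE = 29))), atlas, provenance = "synthetic")
  list(triangle = connectivity_matrix(tri, "SC", "triangle"),
       star5 = connectivity_matrix(star, "SC", "star5"),
       two_cliques = connectivity_matrix(cl, "SC", "two_cliques"),
       cohort = cohort,
       notes = c(triangle_cc = 1, triangle_bc = 0,
                 star_center_bc = 6, star_leaf_bc = 0,
                 two_clique_modules = 2))
}
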