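#' Atlas parcellations
#'
#' An atlas parcellation fixes the node order of every connectivity matrix:
#' row/column `i + 1` of a matrix is region `index = i` of the atlas
#' (indices are 0-based, contiguous and unique). The bundled default is an
#' 86-region Desikan-Killiany parcellation (68 cortical + 18 subcortical
#' regions), the standard whole-brain node set for multimodal connectome
#' studies.
#'
#' @param path Path to a TSV with columns `index`, `name`, `hemisphere`
#'   (`left`/`right`/`none`) and `class` (`cortical`/`subcortical`).
#' @return An object of class `brain_atlas`: a data frame with the four
#'   columns above, ordered by `index`.
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas)            # 86
#' table(atlas$class)     # 68 cortical, 18 subcortical
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("index", "name", "hemisphere", "class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("atlas table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[order(df$index), required]
  validate_atlas(df)
  structure(df, class = c("brain_atlas", "data.frame"))
}

#' @rdname read_atlas
#' @export
dk_atlas <- function() {
  path <- system.file("extdata", "desikan_killiany_86.tsv",
                      package = "braingat", mustWork = TRUE)
  read_atlas(path)
}

validate_atlas <- function(df) {
  n <- nrow(df)
  if (!identical(as.integer(df$index), 0:(n - 1L))) {
    stop("atlas indices must be 0..n-1, contiguous and unique")
  }
  if (anyDuplicated(df$name)) stop("atlas region names must be unique")
  if (!all(df$hemisphere %in% c("left", "right", "none"))) {
    stop("atlas hemisphere must be left/right/none")
  }
  if (!all(df$class %in% c("cortical", "subcortical"))) {
    stop("atlas class must be cortical/subcortical")
  }
  invisible(df)
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d regions (%d cortical, %d subcortical)\n",
              nrow(x), sum(x$class == "cortical"),
              sum(x$class == "subcortical")))
  invisible(x)
}

atlas_size <- function(atlas) nrow(atlas)
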