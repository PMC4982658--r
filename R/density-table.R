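# The density table: one row per focal adhesion, one column per labeled
# component, plus geometry and category metadata. This is the common
# currency passed between the simulator, the image-analysis chain, the
# preprocessing stage and the statistical stages.

#' Default component panel
#'
#' The ten labeled components measured per adhesion: eight structural /
#' signaling proteins plus two phosphorylation sites.
#'
#' @return Character vector of component names.
#' @export
fa_components_default <- function() {
  c("actin", "alpha_actinin", "FAK", "Hic5", "paxillin",
    "VASP", "vinculin", "zyxin", "FAK_pY397", "paxillin_pY118")
}

#' The eight non-phospho protein components
#'
#' Components entering the mean-normalized internal density score; the two
#' phosphorylation-site channels are excluded.
#'
#' @param components Full component vector.
#' @return Character vector.
#' @export
fa_protein_components <- function(components = fa_components_default()) {
  setdiff(components, c("FAK_pY397", "paxillin_pY118"))
}

#' Construct a density table
#'
#' @param data A data frame with one row per focal adhesion. Must contain a
#'   `dataset` column and one numeric column per entry of `components`.
#'   Recognised metadata columns: `adhesion`, `pixels`, `area`,
#'   `eccentricity`, `age`, `dynamics`, `area_cat`, `ecc_cat`, `density_cat`,
#'   `labeling_order`.
#' @param components Character vector naming the component density columns.
#' @return A tibble of class `fa_density_table` with a `components`
#'   attribute.
#' @export
fa_density_table <- function(data, components = fa_components_default()) {
  data <- as_tibble(data)
  if (!"dataset" %in% names(data)) {
    stopf("density table requires a 'dataset' column")
  }
  missing <- setdiff(components, names(data))
  if (length(missing)) {
    stopf("missing component columns: %s", paste(missing, collapse = ", "))
  }
  for (cc in components) {
    if (!is.numeric(data[[cc]])) stopf("component column '%s' not numeric", cc)
    if (any(data[[cc]] < 0, na.rm = TRUE)) {
      stopf("component column '%s' has negative densities", cc)
    }
  }
  if (anyDuplicated(components)) stopf("component names must be unique")
  attr(data, "components") <- components
  class(data) <- unique(c("fa_density_table", class(data)))
  data
}

#' Component names of a density table
#' @param x An `fa_density_table`.
#' @return Character vector of component column names.
#' @export
fa_components <- function(x) {
  comps <- attr(x, "components")
  if (is.null(comps)) stopf("not a density table: no 'components' attribute")
  comps
}

#' Extract the component density matrix
#' @param x An `fa_density_table`.
#' @return Numeric matrix, adhesions x components.
#' @export
fa_density_matrix <- function(x) {
  as.matrix(x[, fa_components(x), drop = FALSE])
}

#' Split a density table by dataset
#' @param x An `fa_density_table`.
#' @return Named list of `fa_density_table`, one per dataset id.
#' @export
fa_split_datasets <- function(x) {
  comps <- fa_components(x)
  lapply(split(as_tibble(x), x$dataset), fa_density_table, components = comps)
}

#' Write a density table as CSV with a JSON sidecar
#'
#' The sidecar records the component panel, the seed (if known) and any
#' transform state, so a table can be re-read without guessing its schema.
#'
#' @param x An `fa_density_table`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
fa_write_table <- function(x, path, extra = list()) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- c(list(components = fa_components(x)), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a density table written by [fa_write_table()]
#' @param path CSV path with an adjacent `<path>.json` sidecar.
#' @return An `fa_density_table`.
#' @export
fa_read_table <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fa_density_table(read.csv(path, stringsAsFactors = FALSE),
                   components = side$components)
}
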