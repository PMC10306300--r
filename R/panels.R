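#' Analyte-by-sample panel container
#'
#' Lightweight container for a plasma analyte panel: an analyte x column
#' matrix of positive values (missing allowed) plus platform-specific
#' structure. For `proteomics` and `metabolomics` panels the columns are
#' samples. For `immunoassay` panels the columns may be individual wells:
#' `sample_id` maps each well to its sample (duplicate wells share a
#' sample), `plate` gives the assay plate per well, and `flags` records the
#' fit-range status of every value (`in_range`, `below_range`,
#' `above_range`, `missing`); out-of-range values are missing until
#' resolved by [resolve_out_of_range()].
#'
#' @param values Numeric analyte x column matrix with dimnames.
#' @param platform One of `"proteomics"`, `"immunoassay"`, `"metabolomics"`.
#' @param sample_id Character vector mapping columns to samples (defaults
#'   to column names).
#' @param plate Plate/batch ID per column (immunoassay only).
#' @param flags Character matrix of fit-range flags, same shape as
#'   `values` (immunoassay only).
#' @param flagged_analytes Analytes flagged for a high out-of-range
#'   fraction (filled by [resolve_out_of_range()]).
#' @return An `analyte_panel` object.
#' @export
analyte_panel <- function(values, platform = c("proteomics", "immunoassay", "metabolomics"),
                          sample_id = NULL, plate = NULL, flags = NULL,
                          flagged_analytes = character()) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have analyte row names and column names")
  }
  if (any(is.infinite(values), na.rm = TRUE)) abort("values must be finite or missing")
  if (is.null(sample_id)) sample_id <- colnames(values)
  if (length(sample_id) != ncol(values)) {
    abort("`sample_id` must have one entry per column")
  }
  if (!is.null(flags)) {
    if (!identical(dim(flags), dim(values))) abort("`flags` must match `values` shape")
    ok <- c("in_range", "below_range", "above_range", "missing")
    if (!all(flags %in% ok)) abort("unknown flag value in `flags`")
    if (platform != "immunoassay" && any(flags %in% c("below_range", "above_range"))) {
      abort("below/above fit-range flags are only valid on the immunoassay platform")
    }
  }
  structure(list(values = values, platform = platform, sample_id = sample_id,
                 plate = plate, flags = flags,
                 flagged_analytes = flagged_analytes),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel: %s> %d analytes x %d columns (%d samples)%s\n",
              x$platform, nrow(x$values), ncol(x$values),
              length(unique(x$sample_id)),
              if (length(x$flagged_analytes))
                sprintf("; %d flagged analytes", length(x$flagged_analytes)) else ""))
  invisible(x)
}

#' @rdname analyte_panel
#' @param x An object.
#' @export
is_analyte_panel <- function(x) inherits(x, "analyte_panel")

# Accept either a panel or a bare matrix where a panel is expected.
.panel_values <- function(x) {
  if (is_analyte_panel(x)) x$values else x
}
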