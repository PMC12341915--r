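#' TMT reporter-ion intensity matrix
#'
#' Lightweight container (in the style of limma's `EList`) holding a
#' protein x sample matrix of nonnegative reporter-ion intensities together
#' with per-sample annotations (bait, bait compartment, replicate).  The
#' `scale` field records whether values are on the raw intensity scale
#' (`"intensity"`) or natural-log scale (`"ln"`), so that transforms cannot
#' silently be applied twice.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with one row per sample and columns
#'   `sample_id`, `bait`, `bait_compartment`, `replicate`.
#' @param scale `"intensity"` or `"ln"`.
#' @return An object of class `intensity_matrix` with fields `values`,
#'   `samples`, `scale`.
#' @export
intensity_matrix <- function(values, samples,
                             scale = c("intensity", "ln")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (scale == "intensity" && any(values < 0, na.rm = TRUE))
    stop("intensity values must be nonnegative")
  req <- c("sample_id", "bait", "bait_compartment", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples)))
    stop("'samples' must contain columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(values)))
    stop("every sample must have an annotation and vice versa")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  comp <- table(x$samples$bait_compartment)
  cat("samples per bait compartment:",
      paste(sprintf("%s=%d", names(comp), comp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

.assert_scale <- function(m, scale) {
  if (!inherits(m, "intensity_matrix"))
    stop("expected an intensity_matrix")
  if (m$scale != scale)
    stop(sprintf("expected matrix on '%s' scale, got '%s'", scale, m$scale))
  invisible(m)
}

#' Samples belonging to a bait compartment
#'
#' @param m An `intensity_matrix`.
#' @param compartment Bait compartment label (e.g. `"lumen"`).
#' @return Character vector of sample ids.
#' @export
compartment_samples <- function(m, compartment) {
  if (!inherits(m, "intensity_matrix")) stop("expected an intensity_matrix")
  ids <- m$samples$sample_id[m$samples$bait_compartment == compartment]
  if (!length(ids)) stop("no samples with bait_compartment '", compartment, "'")
  ids
}
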