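#' ln(x+1) transform of an intensity matrix
#'
#' @param m An `intensity_matrix` on the intensity scale.
#' @return The matrix with every value x replaced by ln(x+1), marked as
#'   ln-scale.
#' @export
log_transform <- function(m) {
  .assert_scale(m, "intensity")
  if (any(m$values < 0, na.rm = TRUE)) stop("negative intensities")
  m$values <- log(m$values + 1)
  m$scale <- "ln"
  m
}

#' Back-transform a normalized ln-scale matrix
#'
#' Applies the literal published back-transform `exp(x)`; note the +1 offset
#' of [log_transform()] is deliberately not subtracted, because the
#' downstream enrichment formula re-adds +1 to every value.
#'
#' @param m An `intensity_matrix` on the ln scale.
#' @return Intensity-scale matrix with every value x replaced by exp(x).
#' @export
back_transform <- function(m) {
  .assert_scale(m, "ln")
  if (any(!is.finite(m$values))) stop("non-finite ln values")
  m$values <- exp(m$values)
  m$scale <- "intensity"
  m
}

# one M-vs-A lowess adjustment for a sample pair; returns the fitted trend
.pair_trend <- function(xi, xj, span) {
  m <- xi - xj
  a <- (xi + xj) / 2
  fit <- stats::lowess(a, m, f = span)
  stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
}

#' Cyclic loess normalization
#'
#' Removes intensity-dependent biases between samples by iterating MA-plot
#' loess fits: for each sample pair (i, j), the smooth trend of
#' M = x_i - x_j against A = (x_i + x_j)/2 is estimated with a local-linear
#' smoother and half of it is subtracted from sample i and added to sample
#' j, so each pair adjustment is zero-sum and the grand mean is preserved.
#' `method = "fast"` (default, matching the default of the limma routine
#' used by the motivating study) normalizes each sample against the mean of
#' all samples; `method = "pairs"` visits all unordered pairs per cycle,
#' with exactly zero-sum pair adjustments.  On proximity-labeling data with
#' strong compartment structure the pairwise variant removes more genuine
#' biology (see the methods vignette), which is why `"fast"` is the
#' default here.
#'
#' @param m An `intensity_matrix` on the ln scale.
#' @param span Loess span (fraction of points in each window; default 0.7).
#' @param cycles Number of full cycles (default 3).
#' @param method `"fast"` (default) or `"pairs"`.
#' @return The normalized ln-scale matrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, cycles = 3,
                                   method = c("fast", "pairs")) {
  .assert_scale(m, "ln")
  method <- match.arg(method)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (cycles < 1) stop("cycles must be >= 1")
  x <- m$values
  if (ncol(x) < 2L) stop("need at least 2 samples")
  if (nrow(x) < 20L)
    stop("need at least 20 proteins for a stable loess smooth")
  ns <- ncol(x)
  for (cyc in seq_len(cycles)) {
    if (method == "pairs") {
      for (i in seq_len(ns - 1L)) {
        for (j in seq(i + 1L, ns)) {
          trend <- .pair_trend(x[, i], x[, j], span)
          x[, i] <- x[, i] - trend / 2
          x[, j] <- x[, j] + trend / 2
        }
      }
    } else {
      ref <- rowMeans(x)
      for (i in seq_len(ns)) {
        m_i <- x[, i] - ref
        fit <- stats::lowess(ref, m_i, f = span)
        x[, i] <- x[, i] -
          stats::approx(fit$x, fit$y, xout = ref, rule = 2, ties = mean)$y
      }
    }
  }
  m$values <- x
  m
}

#' Per-protein enrichment between two samples
#'
#' Computes `log2((a + 1) / (b + 1))` where a and b are (back-transformed,
#' normalized) intensities of each protein in the numerator and denominator
#' samples.  Always finite for nonnegative input.
#'
#' @param m An `intensity_matrix` on the intensity scale.
#' @param numerator,denominator Sample ids.
#' @return data.frame `protein_id`, `numerator`, `denominator`,
#'   `enrichment` (log2 units).
#' @export
compute_enrichment <- function(m, numerator, denominator) {
  .assert_scale(m, "intensity")
  for (s in c(numerator, denominator))
    if (!s %in% colnames(m$values)) stop("unknown sample id: ", s)
  e <- log2((m$values[, numerator] + 1) / (m$values[, denominator] + 1))
  data.frame(protein_id = rownames(m$values), numerator = numerator,
             denominator = denominator, enrichment = unname(e),
             stringsAsFactors = FALSE)
}

#' Mean enrichment over all replicate pairs of two sample groups
#'
#' Arithmetic mean, per protein, of the pairwise enrichments of every
#' numerator-group sample over every denominator-group sample (9 values for
#' a strain pair with 3 replicates each; 36 for a 2-bait compartment pair).
#'
#' @param m An `intensity_matrix` on the intensity scale.
#' @param numerator_samples,denominator_samples Character vectors of sample
#'   ids.
#' @return Named numeric vector of per-protein mean enrichments (log2).
#' @export
mean_enrichment <- function(m, numerator_samples, denominator_samples) {
  .assert_scale(m, "intensity")
  missing <- setdiff(c(numerator_samples, denominator_samples),
                     colnames(m$values))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  acc <- matrix(0, nrow(m$values),
                length(numerator_samples) * length(denominator_samples))
  k <- 0L
  for (a in numerator_samples) {
    for (b in denominator_samples) {
      k <- k + 1L
      acc[, k] <- log2((m$values[, a] + 1) / (m$values[, b] + 1))
    }
  }
  stats::setNames(rowMeans(acc), rownames(m$values))
}

#' Pairwise Pearson correlation between samples
#'
#' Computed on the (back-transformed) normalized intensity values, matching
#' the QC heatmap convention of the motivating study.  Samples with zero
#' variance yield NA entries (flagged with a warning).
#'
#' @param m An `intensity_matrix`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(m) {
  if (!inherits(m, "intensity_matrix")) stop("expected an intensity_matrix")
  if (nrow(m$values) < 3L) stop("need at least 3 proteins")
  sds <- apply(m$values, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(m$values)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(m$values))
  diag(r) <- 1
  r
}

#' PCA scores of samples (QC)
#'
#' Centered singular-value decomposition of the ln-scale normalized matrix
#' with samples as observations.
#'
#' @param m An `intensity_matrix` on the ln scale.
#' @param n_components Number of components to return (default all).
#' @return List with `scores` (samples x components), `sdev` (component
#'   standard deviations, non-increasing) and `variance_explained`.
#' @export
pca_scores <- function(m, n_components = NULL) {
  .assert_scale(m, "ln")
  if (ncol(m$values) < 2L) stop("need at least 2 samples")
  pc <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(pc$x)
       else min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       sdev = pc$sdev,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}
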