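#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample t-test (df = n1 + n2 - 2) with a two-sided
#' p-value, the convention of the motivating analysis; Welch's unequal
#' variance form is available with `var_equal = FALSE`.  Missing values are
#' dropped per group.  Groups with fewer than 2 finite values, or a zero
#' pooled variance with equal means, make the result untestable / degenerate
#' rather than an error.
#'
#' @param a,b Numeric vectors.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE).
#' @return List of class `t_test_result`: `n1`, `n2`, `mean1`, `mean2`,
#'   `t`, `p`, `df`, `untestable`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  out <- list(n1 = n1, n2 = n2,
              mean1 = if (n1) mean(a) else NA_real_,
              mean2 = if (n2) mean(b) else NA_real_,
              t = NA_real_, p = NA_real_, df = NA_real_, untestable = FALSE)
  class(out) <- "t_test_result"
  if (n1 < 2L || n2 < 2L) {
    out$untestable <- TRUE
    return(out)
  }
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0)
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    else NA_real_
  }
  d <- out$mean1 - out$mean2
  if (se == 0) {
    # zero variance: identical constant groups are a clean null; distinct
    # constants are an exact separation
    out$t <- if (d == 0) 0 else sign(d) * Inf
    out$p <- if (d == 0) 1 else 0
    out$df <- df
    return(out)
  }
  out$t <- d / se
  out$df <- df
  out$p <- 2 * stats::pt(-abs(out$t), df)
  out
}

.groups_from_calls <- function(features, calls, exclude_dual) {
  if (is.null(calls)) {
    loc <- features$localization[!duplicated(features$protein_id)]
    names(loc) <- features$protein_id[!duplicated(features$protein_id)]
  } else {
    loc <- stats::setNames(as.character(calls$final), calls$protein_id)
  }
  g1 <- names(loc)[loc == "lumen"]
  g2 <- names(loc)[loc == "pom"]
  if (!exclude_dual) {
    dual <- names(loc)[loc == "dual"]
    g1 <- c(g1, dual)
    g2 <- c(g2, dual)
  }
  list(lumen = g1, pom = g2)
}

#' Compare every signal-sequence characteristic between localizations
#'
#' Runs one t-test per (region, feature) pair contrasting thylakoid-lumen
#' against P-OM peptides of one signal-sequence category, and counts
#' significant characteristics at `alpha`.  No multiple-testing correction
#' is applied to the significance flag (mirroring the raw P < 0.05
#' convention of the motivating analysis); a Benjamini-Hochberg column
#' `p_bh` is emitted alongside as a clearly-marked extension.
#'
#' @param features Long feature table from [feature_table()].
#' @param calls Optional call table (`protein_id`, `final`) from
#'   [merge_calls()]; when NULL, the feature table's `localization` column
#'   defines the groups.
#' @param category Signal-peptide category to analyze (default `"SP"`).
#' @param exclude_dual Drop dually localized proteins (default TRUE); when
#'   FALSE they are counted in both groups.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Passed to [students_t()].
#' @return List with `results` (data.frame: region, feature, n1, n2,
#'   mean_lumen, mean_pom, t, p, p_bh, significant, untestable),
#'   `n_significant`, `n_tested`.
#' @export
compare_localizations <- function(features, calls = NULL, category = "SP",
                                  exclude_dual = TRUE, alpha = 0.05,
                                  var_equal = TRUE) {
  f <- features[features$category == category, , drop = FALSE]
  if (!nrow(f)) stop("no peptides of category '", category, "'")
  groups <- .groups_from_calls(features, calls, exclude_dual)
  g1 <- intersect(groups$lumen, f$protein_id)
  g2 <- intersect(groups$pom, f$protein_id)
  if (length(g1) < 2L)
    stop("lumen group empty/too small after filtering category '",
         category, "'", if (exclude_dual) " with dual excluded")
  if (length(g2) < 2L)
    stop("pom group empty/too small after filtering category '",
         category, "'", if (exclude_dual) " with dual excluded")
  keys <- unique(f[, c("region", "feature")])
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- f[f$region == keys$region[i] & f$feature == keys$feature[i], ]
    v <- stats::setNames(sub$value, sub$protein_id)
    tt <- students_t(v[names(v) %in% g1], v[names(v) %in% g2],
                     var_equal = var_equal)
    res[[i]] <- data.frame(
      category = category, region = keys$region[i],
      feature = keys$feature[i], n1 = tt$n1, n2 = tt$n2,
      mean_lumen = tt$mean1, mean_pom = tt$mean2, t = tt$t, p = tt$p,
      untestable = tt$untestable, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  res$p_bh <- NA_real_
  testable <- !res$untestable & is.finite(res$p)
  res$p_bh[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  res$significant <- !res$untestable & !is.na(res$p) & res$p < alpha
  list(results = res,
       n_significant = sum(res$significant),
       n_tested = sum(testable))
}

#' Cross-species signal-sequence comparison
#'
#' Transfers the reference species' localization calls to other species
#' through best-reciprocal-hit homolog pairs and repeats the per-category
#' feature comparison in each species.  Unmapped homologs are dropped with
#' a message.
#'
#' @param species_features Named list of feature tables (one per species,
#'   from [feature_table()]), excluding the reference species.
#' @param homolog_maps Named list (same names) of data.frames with columns
#'   `ref_id`, `other_id` (best reciprocal BLAST pairs).
#' @param ref_calls Reference call table (`protein_id`, `final`) or NULL to
#'   use each reference feature table's own localization (then
#'   `ref_groups` must be supplied via `ref_calls`).
#' @param ref_features Reference feature table (used when `ref_calls` is
#'   NULL to derive localizations).
#' @param categories Categories to test per species (default SP and LIPO).
#' @param exclude_dual,alpha,var_equal Passed through.
#' @param combined_compartments Character vector of species names whose
#'   thylakoid lumen and periplasm are one physical compartment (expected
#'   null; flagged in the output).
#' @return List with `results` (rbind of per-species results, with
#'   `species` and `combined_compartments` columns) and `summary`
#'   (significant counts per species x category).
#' @export
cross_species_summary <- function(species_features, homolog_maps,
                                  ref_calls = NULL, ref_features = NULL,
                                  categories = c("SP", "LIPO"),
                                  exclude_dual = TRUE, alpha = 0.05,
                                  var_equal = TRUE,
                                  combined_compartments = character()) {
  if (!length(species_features)) {
    warning("no species feature tables supplied; empty output")
    return(list(results = data.frame(), summary = data.frame()))
  }
  if (is.null(ref_calls) && is.null(ref_features))
    stop("supply ref_calls or ref_features to define localizations")
  ref_loc <- if (!is.null(ref_calls))
    stats::setNames(as.character(ref_calls$final), ref_calls$protein_id)
  else {
    u <- !duplicated(ref_features$protein_id)
    stats::setNames(ref_features$localization[u], ref_features$protein_id[u])
  }
  all_res <- list()
  summ <- list()
  for (sp in names(species_features)) {
    map <- homolog_maps[[sp]]
    if (is.null(map)) stop("no homolog map for species '", sp, "'")
    feats <- species_features[[sp]]
    mapped <- map$ref_id %in% names(ref_loc) & map$other_id %in% feats$protein_id
    if (any(!mapped))
      message(sp, ": dropped ", sum(!mapped), " unmapped homolog pair(s)")
    map <- map[mapped, , drop = FALSE]
    loc <- stats::setNames(ref_loc[map$ref_id], map$other_id)
    feats <- feats[feats$protein_id %in% names(loc), , drop = FALSE]
    feats$localization <- unname(loc[feats$protein_id])
    for (cat_i in categories) {
      cmp <- tryCatch(
        compare_localizations(feats, calls = NULL, category = cat_i,
                              exclude_dual = exclude_dual, alpha = alpha,
                              var_equal = var_equal),
        error = function(e) NULL)
      if (is.null(cmp)) next
      r <- cmp$results
      r$species <- sp
      r$combined_compartments <- sp %in% combined_compartments
      all_res[[paste(sp, cat_i)]] <- r
      summ[[paste(sp, cat_i)]] <- data.frame(
        species = sp, category = cat_i,
        n_significant = cmp$n_significant, n_tested = cmp$n_tested,
        combined_compartments = sp %in% combined_compartments,
        stringsAsFactors = FALSE)
    }
  }
  list(results = if (length(all_res)) do.call(rbind, all_res)
       else data.frame(),
       summary = if (length(summ)) do.call(rbind, summ) else data.frame())
}
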