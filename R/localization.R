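#' Control set for one localization analysis
#'
#' Curated control proteins anchoring the ROC cutoffs: true positives from
#' the compartment of interest and false positives from the cytoplasm.
#'
#' @param analysis `"lumen_vs_cyto"` or `"pom_vs_cyto"`.
#' @param tp_ids,fp_ids Character vectors of protein ids (disjoint).
#' @return Object of class `control_set`.
#' @export
control_set <- function(analysis = c("lumen_vs_cyto", "pom_vs_cyto"),
                        tp_ids, fp_ids) {
  analysis <- match.arg(analysis)
  tp_ids <- unique(as.character(tp_ids))
  fp_ids <- unique(as.character(fp_ids))
  if (length(intersect(tp_ids, fp_ids)))
    stop("TP and FP control lists must be disjoint")
  structure(list(analysis = analysis, tp_ids = tp_ids, fp_ids = fp_ids),
            class = "control_set")
}

#' Voting configuration
#'
#' @param min_votes Minimum comparisons a protein must pass (default 35).
#' @param n_comparisons Total comparisons per analysis (default 36 =
#'   2 baits x 3 replicates vs 2 baits x 3 replicates).
#' @return Object of class `vote_config`.
#' @export
vote_config <- function(min_votes = 35, n_comparisons = 36) {
  if (min_votes < 1 || min_votes > n_comparisons)
    stop("need 1 <= min_votes <= n_comparisons")
  structure(list(min_votes = as.integer(min_votes),
                 n_comparisons = as.integer(n_comparisons)),
            class = "vote_config")
}

# number of elements of v that are >= each threshold in t
.n_ge <- function(v, t) {
  sv <- sort(v)
  length(v) - findInterval(t, sv, left.open = TRUE)
}

#' Control-anchored ROC cutoff for one comparison
#'
#' For every attained enrichment value t, the true-positive rate is the
#' fraction of detected TP controls with enrichment >= t and the
#' false-positive rate the analogous fraction of FP controls.  The cutoff
#' is the attained enrichment maximizing TPR - FPR.  When several
#' thresholds attain the maximum (e.g. the whole gap between two separated
#' control distributions), `tie_break` selects the smallest (default; the
#' sensitive end of the optimal plateau) or the largest (most stringent)
#' maximizer.
#'
#' @param enrichments Named numeric vector of per-protein enrichment values
#'   (log2) for one comparison.
#' @param controls A [control_set()].
#' @param tie_break `"smallest"` or `"largest"`.
#' @param comparison Optional label stored in the result.
#' @return Object of class `comparison_cutoff`: fields `comparison`,
#'   `cutoff`, `tpr_at_cutoff`, `fpr_at_cutoff`, `n_tp`, `n_fp`.
#' @export
roc_cutoff <- function(enrichments, controls,
                       tie_break = c("smallest", "largest"),
                       comparison = NA_character_) {
  tie_break <- match.arg(tie_break)
  if (is.null(names(enrichments)))
    stop("'enrichments' must be named by protein id")
  e_tp <- enrichments[names(enrichments) %in% controls$tp_ids]
  e_fp <- enrichments[names(enrichments) %in% controls$fp_ids]
  if (!length(e_tp)) stop("no TP control proteins detected in this dataset")
  if (!length(e_fp)) stop("no FP control proteins detected in this dataset")
  cand <- sort(unique(unname(enrichments)))
  tpr <- .n_ge(e_tp, cand) / length(e_tp)
  fpr <- .n_ge(e_fp, cand) / length(e_fp)
  d <- tpr - fpr
  # diffs are multiples of 1/(n_tp * n_fp); the tolerance only absorbs
  # floating-point noise between mathematically equal values
  best <- which(d >= max(d) - 1e-12)
  pick <- if (tie_break == "smallest") best[1L] else best[length(best)]
  structure(list(comparison = comparison, cutoff = cand[pick],
                 tpr_at_cutoff = tpr[pick], fpr_at_cutoff = fpr[pick],
                 n_tp = length(e_tp), n_fp = length(e_fp)),
            class = "comparison_cutoff")
}

#' Vote across per-comparison positives
#'
#' @param positives Logical matrix, proteins x comparisons; TRUE when the
#'   protein's enrichment was at or above that comparison's cutoff.
#' @param cfg A [vote_config()]; its `n_comparisons` must match
#'   `ncol(positives)`.
#' @return Character vector of protein ids positive in at least
#'   `min_votes` comparisons.
#' @export
call_by_vote <- function(positives, cfg = vote_config()) {
  if (!is.logical(positives) || !is.matrix(positives))
    stop("'positives' must be a logical matrix")
  if (ncol(positives) != cfg$n_comparisons)
    stop(sprintf("config expects %d comparisons but %d were supplied",
                 cfg$n_comparisons, ncol(positives)))
  rownames(positives)[rowSums(positives) >= cfg$min_votes]
}

#' Forward/reverse directional analysis for one compartment
#'
#' Runs the full voting analysis for one compartment-vs-cytoplasm contrast:
#' the forward pass computes, for each (target sample, reference sample)
#' pair, per-protein enrichments and a control-anchored ROC cutoff
#' (TP = compartment controls, FP = cytoplasm controls), then labels
#' `target` the proteins at or above the cutoff in at least `min_votes`
#' comparisons.  The reverse pass inverts the ratios and swaps the control
#' roles to label `reference` (cytoplasm) proteins.  Proteins passing
#' neither pass, or pathologically both, are `unknown`.
#'
#' @param m An `intensity_matrix` of normalized back-transformed values
#'   (intensity scale).
#' @param target_samples,reference_samples Disjoint sample-id vectors
#'   (6 each in the default 2-bait x 3-replicate design).
#' @param controls A [control_set()] (TPs = target compartment,
#'   FPs = cytoplasm).
#' @param cfg A [vote_config()]; `n_comparisons` must equal
#'   `length(target_samples) * length(reference_samples)`.
#' @param tie_break Passed to [roc_cutoff()].
#' @return List with `assignment` (named factor with levels target /
#'   reference / unknown), `forward_votes`, `reverse_votes`, and `cutoffs`
#'   (data.frame of per-comparison cutoffs for both passes).
#' @export
run_directional_analysis <- function(m, target_samples, reference_samples,
                                     controls, cfg = vote_config(),
                                     tie_break = c("smallest", "largest")) {
  .assert_scale(m, "intensity")
  tie_break <- match.arg(tie_break)
  if (length(intersect(target_samples, reference_samples)))
    stop("target and reference sample sets must be disjoint")
  n_comp <- length(target_samples) * length(reference_samples)
  if (n_comp != cfg$n_comparisons)
    stop(sprintf("design yields %d comparisons but config expects %d",
                 n_comp, cfg$n_comparisons))
  proteins <- rownames(m$values)
  rev_controls <- control_set(controls$analysis,
                              tp_ids = controls$fp_ids,
                              fp_ids = controls$tp_ids)
  fwd <- matrix(FALSE, length(proteins), n_comp,
                dimnames = list(proteins, NULL))
  rev <- fwd
  cuts <- vector("list", 2L * n_comp)
  k <- 0L
  for (t in target_samples) {
    for (r in reference_samples) {
      k <- k + 1L
      e <- log2((m$values[, t] + 1) / (m$values[, r] + 1))
      names(e) <- proteins
      cc_f <- roc_cutoff(e, controls, tie_break,
                         comparison = paste0(t, "/", r))
      fwd[, k] <- e >= cc_f$cutoff
      cc_r <- roc_cutoff(-e, rev_controls, tie_break,
                         comparison = paste0(r, "/", t))
      rev[, k] <- -e >= cc_r$cutoff
      cuts[[2L * k - 1L]] <- data.frame(
        direction = "forward", comparison = cc_f$comparison,
        cutoff = cc_f$cutoff, tpr = cc_f$tpr_at_cutoff,
        fpr = cc_f$fpr_at_cutoff, stringsAsFactors = FALSE)
      cuts[[2L * k]] <- data.frame(
        direction = "reverse", comparison = cc_r$comparison,
        cutoff = cc_r$cutoff, tpr = cc_r$tpr_at_cutoff,
        fpr = cc_r$fpr_at_cutoff, stringsAsFactors = FALSE)
    }
  }
  fwd_pos <- call_by_vote(fwd, cfg)
  rev_pos <- call_by_vote(rev, cfg)
  assignment <- rep("unknown", length(proteins))
  names(assignment) <- proteins
  assignment[proteins %in% fwd_pos] <- "target"
  assignment[proteins %in% rev_pos] <- "reference"
  assignment[proteins %in% intersect(fwd_pos, rev_pos)] <- "unknown"
  list(assignment = factor(assignment,
                           levels = c("target", "reference", "unknown")),
       forward_votes = stats::setNames(rowSums(fwd), proteins),
       reverse_votes = stats::setNames(rowSums(rev), proteins),
       cutoffs = do.call(rbind, cuts))
}

#' Merge the lumen and P-OM analysis outcomes into final calls
#'
#' Merge table: (target, target) -> dual; (target, .) -> lumen;
#' (., target) -> pom; (reference, reference) -> cytoplasm; everything else
#' -> unknown.  A compartment call always takes precedence over a
#' cytoplasm or unknown outcome from the other analysis.
#'
#' @param lumen_result,pom_result Results of [run_directional_analysis()]
#'   (or bare named assignment factors) covering the same protein set.
#' @return data.frame `protein_id`, `lumen_analysis`, `pom_analysis`,
#'   `final` with final in lumen / pom / dual / cytoplasm / unknown.
#' @export
merge_calls <- function(lumen_result, pom_result) {
  get_assign <- function(x)
    if (is.list(x) && !is.null(x$assignment)) x$assignment else x
  la <- get_assign(lumen_result)
  pa <- get_assign(pom_result)
  if (!setequal(names(la), names(pa)))
    stop("analyses cover different protein sets: ",
         paste(utils::head(c(setdiff(names(la), names(pa)),
                             setdiff(names(pa), names(la)))), collapse = ", "))
  pa <- pa[names(la)]
  la_c <- as.character(la)
  pa_c <- as.character(pa)
  final <- ifelse(la_c == "target" & pa_c == "target", "dual",
           ifelse(la_c == "target", "lumen",
           ifelse(pa_c == "target", "pom",
           ifelse(la_c == "reference" & pa_c == "reference", "cytoplasm",
                  "unknown"))))
  data.frame(protein_id = names(la),
             lumen_analysis = la_c, pom_analysis = pa_c,
             final = factor(final, levels = c("lumen", "pom", "dual",
                                              "cytoplasm", "unknown")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Control recovery statistics for one analysis
#'
#' @param assignment Named factor from [run_directional_analysis()].
#' @param controls The [control_set()] used.
#' @param detected Protein ids detected in the dataset (defaults to the
#'   assignment's names).
#' @return List with detected/total control fractions and the fraction of
#'   detected controls assigned their expected outcome.
#' @export
coverage_stats <- function(assignment, controls,
                           detected = names(assignment)) {
  tp_det <- intersect(controls$tp_ids, detected)
  fp_det <- intersect(controls$fp_ids, detected)
  list(analysis = controls$analysis,
       tp_detected_fraction = length(tp_det) / max(1L, length(controls$tp_ids)),
       fp_detected_fraction = length(fp_det) / max(1L, length(controls$fp_ids)),
       tp_recovery = if (length(tp_det))
         mean(assignment[tp_det] == "target") else NA_real_,
       fp_recovery = if (length(fp_det))
         mean(assignment[fp_det] == "reference") else NA_real_)
}

#' Full two-analysis compartmentalome classification
#'
#' Convenience wrapper running the lumen-vs-cytoplasm and P-OM-vs-cytoplasm
#' directional analyses on a normalized matrix and merging the calls.
#' Sample groups are taken from the `bait_compartment` annotation
#' (`lumen`, `pom`, `cytoplasm`).
#'
#' @param m Normalized back-transformed `intensity_matrix`.
#' @param controls Named list with [control_set()]s `lumen_vs_cyto` and
#'   `pom_vs_cyto` (as from [truth_control_sets()] or
#'   [read_control_sets()]).
#' @param cfg A [vote_config()].
#' @param tie_break Passed to [roc_cutoff()].
#' @return List with `calls` (merged call table), `lumen`, `pom` (the two
#'   directional results), `summary` (category counts and control
#'   recovery).
#' @export
classify_compartmentalome <- function(m, controls, cfg = vote_config(),
                                      tie_break = c("smallest", "largest")) {
  tie_break <- match.arg(tie_break)
  cyto <- compartment_samples(m, "cytoplasm")
  lum <- run_directional_analysis(m, compartment_samples(m, "lumen"), cyto,
                                  controls$lumen_vs_cyto, cfg, tie_break)
  pom <- run_directional_analysis(m, compartment_samples(m, "pom"), cyto,
                                  controls$pom_vs_cyto, cfg, tie_break)
  calls <- merge_calls(lum, pom)
  summary <- list(
    category_counts = as.list(table(calls$final)),
    lumen_controls = coverage_stats(lum$assignment, controls$lumen_vs_cyto),
    pom_controls = coverage_stats(pom$assignment, controls$pom_vs_cyto))
  list(calls = calls, lumen = lum, pom = pom, summary = summary)
}
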