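#' Simulation configuration for proximity-labeling intensities
#'
#' Describes the ground-truthed synthetic world the generators emulate:
#' log-normal reporter-ion abundances, a compartment-match labeling effect
#' with per-protein heterogeneity, Tat-leak background labeling of
#' cytoplasmic proteins by periplasmic baits, and replicate noise.  All
#' ln-scale parameters act on the natural-log scale of intensities.
#'
#' @param n_lumen,n_pom,n_dual,n_cytoplasm,n_membrane Proteins per true
#'   compartment (`pom` = combined periplasm/outer membrane; `dual` =
#'   present in both lumen and P-OM).
#' @param n_baits_per_compartment Baits per compartment (default 2: one
#'   membrane-associated, one soluble, as in the 6-fusion design).
#' @param n_replicates Replicate cultures per bait (default 3).
#' @param base_abundance_meanlog,base_abundance_sdlog ln-scale mean/sd of
#'   per-protein baseline abundance.
#' @param enrichment_effect ln-scale mean shift applied when the bait
#'   compartment matches the protein compartment (default 4 log2 units).
#' @param effect_sd ln-scale SD of the per-protein match effect (labeling
#'   efficiency varies between proteins within a compartment; default
#'   1 log2 unit).
#' @param tat_leak Fraction in [0,1] of cytoplasmic-level labeling applied
#'   to cytoplasmic proteins by periplasmic baits (periplasmic baits carry
#'   Tat signal sequences and fold, hence label, in the cytoplasm first).
#' @param noise_sd ln-scale replicate noise SD.
#' @param bait_scale_sd ln-scale SD of a per-sample labeling-efficiency
#'   factor (default 0; no published value to match).
#' @param n_tp_lumen,n_tp_pom,n_fp_cytoplasm Control-list sizes drawn from
#'   the matching compartments (defaults follow the detected control counts
#'   of the motivating study: 40 lumen TP, 65 P-OM TP, 381 cytoplasm FP).
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lumen = 100, n_pom = 100, n_dual = 20,
                       n_cytoplasm = 800, n_membrane = 0,
                       n_baits_per_compartment = 2, n_replicates = 3,
                       base_abundance_meanlog = 8, base_abundance_sdlog = 1.5,
                       enrichment_effect = 4 * log(2), effect_sd = log(2),
                       tat_leak = 0.3, noise_sd = 0.5, bait_scale_sd = 0,
                       n_tp_lumen = 40, n_tp_pom = 65, n_fp_cytoplasm = 381,
                       seed = 1L) {
  cfg <- list(n_lumen = n_lumen, n_pom = n_pom, n_dual = n_dual,
              n_cytoplasm = n_cytoplasm, n_membrane = n_membrane,
              n_baits_per_compartment = n_baits_per_compartment,
              n_replicates = n_replicates,
              base_abundance_meanlog = base_abundance_meanlog,
              base_abundance_sdlog = base_abundance_sdlog,
              enrichment_effect = enrichment_effect, effect_sd = effect_sd,
              tat_leak = tat_leak, noise_sd = noise_sd,
              bait_scale_sd = bait_scale_sd,
              n_tp_lumen = n_tp_lumen, n_tp_pom = n_tp_pom,
              n_fp_cytoplasm = n_fp_cytoplasm, seed = as.integer(seed))
  counts <- cfg[c("n_lumen", "n_pom", "n_dual", "n_cytoplasm", "n_membrane",
                  "n_tp_lumen", "n_tp_pom", "n_fp_cytoplasm")]
  if (any(unlist(counts) < 0)) stop("counts must be nonnegative")
  if (cfg$n_baits_per_compartment < 1 || cfg$n_replicates < 1)
    stop("bait and replicate counts must be >= 1")
  if (cfg$tat_leak < 0 || cfg$tat_leak > 1) stop("tat_leak must be in [0,1]")
  if (cfg$noise_sd < 0 || cfg$effect_sd < 0 || cfg$bait_scale_sd < 0)
    stop("noise/effect/scale SDs must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a ground-truth compartment proteome with control sets
#'
#' Assigns every protein a true compartment and draws disjoint
#' control lists: thylakoid-lumen true positives from lumen proteins,
#' P-OM true positives from P-OM proteins, and cytoplasm false positives
#' from cytoplasmic proteins.  Dual proteins are never controls.
#'
#' @param cfg A [sim_config()].
#' @return data.frame (class `ground_truth`) with columns `protein_id`,
#'   `true_compartment`, `is_tp_lumen`, `is_fp_cytoplasm`, `is_tp_pom`.
#' @export
generate_compartment_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c(lumen = cfg$n_lumen, pom = cfg$n_pom, cytoplasm = cfg$n_cytoplasm)
  ctrl <- c(lumen = cfg$n_tp_lumen, pom = cfg$n_tp_pom,
            cytoplasm = cfg$n_fp_cytoplasm)
  empty <- names(need)[need == 0 & ctrl > 0]
  if (length(empty))
    stop("zero proteins in required compartment(s): ",
         paste(empty, collapse = ", "))
  infeasible <- names(ctrl)[ctrl > need]
  if (length(infeasible))
    stop("control list larger than compartment for: ",
         paste(infeasible, collapse = ", "))
  set.seed(cfg$seed)
  comp <- c(rep("lumen", cfg$n_lumen), rep("pom", cfg$n_pom),
            rep("dual", cfg$n_dual), rep("cytoplasm", cfg$n_cytoplasm),
            rep("membrane", cfg$n_membrane))
  n <- length(comp)
  if (n == 0L) stop("empty proteome")
  comp <- sample(comp, n)
  ids <- sprintf("P%04d", seq_len(n))
  truth <- data.frame(protein_id = ids, true_compartment = comp,
                      is_tp_lumen = FALSE, is_fp_cytoplasm = FALSE,
                      is_tp_pom = FALSE, stringsAsFactors = FALSE)
  pick <- function(compartment, k) {
    pool <- truth$protein_id[truth$true_compartment == compartment]
    sample(pool, k)
  }
  truth$is_tp_lumen <- truth$protein_id %in% pick("lumen", cfg$n_tp_lumen)
  truth$is_tp_pom <- truth$protein_id %in% pick("pom", cfg$n_tp_pom)
  truth$is_fp_cytoplasm <-
    truth$protein_id %in% pick("cytoplasm", cfg$n_fp_cytoplasm)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

# sample annotation table implied by a sim_config
.sim_sample_design <- function(cfg) {
  comps <- c("cytoplasm", "lumen", "pom")
  baits <- unlist(lapply(comps, function(cp)
    sprintf("%s_b%d", cp, seq_len(cfg$n_baits_per_compartment))))
  bait_comp <- rep(comps, each = cfg$n_baits_per_compartment)
  df <- data.frame(
    sample_id = as.vector(t(outer(baits, seq_len(cfg$n_replicates),
                                  function(b, r) sprintf("%s_r%d", b, r)))),
    bait = rep(baits, each = cfg$n_replicates),
    bait_compartment = rep(bait_comp, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(baits)),
    stringsAsFactors = FALSE)
  df
}

#' Generate a TMT reporter-ion intensity matrix from ground truth
#'
#' Intensity of protein p in sample s is
#' `exp(base_p + match_effect + leak + bait_scale_s + noise)`, where the
#' match effect `enrichment_effect + delta_p` applies when the bait
#' compartment equals the protein compartment (dual proteins match both
#' lumen and P-OM baits; membrane proteins receive half the effect from
#' both, labeled on either membrane face), and cytoplasmic proteins receive
#' `tat_leak` times their cytoplasmic labeling level from P-OM baits.
#'
#' @param truth A `ground_truth` table from [generate_compartment_proteome()].
#' @param cfg The same [sim_config()].
#' @return An `intensity_matrix` on the intensity scale.
#' @export
generate_tmt_intensities <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!nrow(truth)) stop("empty ground truth")
  set.seed(cfg$seed + 1L)
  samples <- .sim_sample_design(cfg)
  n <- nrow(truth); m <- nrow(samples)
  base <- stats::rnorm(n, cfg$base_abundance_meanlog, cfg$base_abundance_sdlog)
  delta <- stats::rnorm(n, 0, cfg$effect_sd)
  scale_s <- stats::rnorm(m, 0, cfg$bait_scale_sd)
  eff <- cfg$enrichment_effect + delta
  lnval <- matrix(base, n, m)
  for (j in seq_len(m)) {
    bc <- samples$bait_compartment[j]
    match <- truth$true_compartment == bc |
      (truth$true_compartment == "dual" & bc %in% c("lumen", "pom"))
    lnval[match, j] <- lnval[match, j] + eff[match]
    half <- truth$true_compartment == "membrane" & bc %in% c("lumen", "pom")
    lnval[half, j] <- lnval[half, j] + 0.5 * eff[half]
    if (bc == "pom") {
      leak <- truth$true_compartment == "cytoplasm"
      lnval[leak, j] <- lnval[leak, j] + cfg$tat_leak * eff[leak]
    }
    lnval[, j] <- lnval[, j] + scale_s[j]
  }
  lnval <- lnval + matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m)
  values <- exp(lnval)
  dimnames(values) <- list(truth$protein_id, samples$sample_id)
  intensity_matrix(values, samples, scale = "intensity")
}

#' Control sets implied by a ground-truth table
#'
#' @param truth A `ground_truth` table.
#' @return Named list with [control_set()]s `lumen_vs_cyto` and
#'   `pom_vs_cyto`.
#' @export
truth_control_sets <- function(truth) {
  fp <- truth$protein_id[truth$is_fp_cytoplasm]
  list(
    lumen_vs_cyto = control_set("lumen_vs_cyto",
                                tp_ids = truth$protein_id[truth$is_tp_lumen],
                                fp_ids = fp),
    pom_vs_cyto = control_set("pom_vs_cyto",
                              tp_ids = truth$protein_id[truth$is_tp_pom],
                              fp_ids = fp))
}
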