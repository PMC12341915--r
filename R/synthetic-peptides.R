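#' Simulation configuration for synthetic signal peptides
#'
#' Controls the generator for SignalP-style signal peptides whose H-region
#' composition differs by target compartment: thylakoid-lumen peptides are
#' drawn from a residue distribution tilted toward lower z1 (more
#' hydrophobic) by `h_hydrophobicity_shift` relative to P-OM peptides.
#'
#' @param n_per_group Named counts per category, generated once per
#'   localization group (lumen and pom).  Defaults mirror the category
#'   frequencies of the motivating study (SP-rich, some LIPO, few
#'   Tat-translocated, rare PILIN).
#' @param h_hydrophobicity_shift Difference in mean H-region z1 between the
#'   pom and lumen groups (z1 units; positive = lumen more hydrophobic).
#' @param h_helix_bias In [0,1]; probability mass forced onto the helix
#'   state inside the H-region by the structure generator (1 = H-region
#'   predicted all-helix).
#' @param region_length_ranges List of `c(min, max)` lengths for the N, H
#'   (core, excluding the lipobox) and C regions.
#' @param seed Integer seed.
#' @return A validated list of class `sp_sim_config`.
#' @export
sp_sim_config <- function(n_per_group = c(SP = 40, LIPO = 18, TAT = 3,
                                          TATLIPO = 2, PILIN = 1),
                          h_hydrophobicity_shift = 0.8,
                          h_helix_bias = 0.4,
                          region_length_ranges = list(n = c(4, 8),
                                                      h = c(7, 15),
                                                      c = c(3, 7)),
                          seed = 1L) {
  cfg <- list(n_per_group = n_per_group,
              h_hydrophobicity_shift = h_hydrophobicity_shift,
              h_helix_bias = h_helix_bias,
              region_length_ranges = region_length_ranges,
              seed = as.integer(seed))
  rng <- cfg$region_length_ranges
  if (!all(c("n", "h", "c") %in% names(rng)))
    stop("region_length_ranges must name n, h and c")
  if (any(vapply(rng, min, 0) < 1)) stop("region lengths must be >= 1")
  # motif constraints: N holds M + charge (+ terminal RR for Tat); C carries
  # the A-X-A motif.  The lipobox is appended beyond the sampled H length.
  if (rng$n[1L] < 3) stop("N-region range cannot satisfy the M/RR motifs")
  if (rng$c[1L] < 3) stop("C-region range cannot satisfy the A-X-A motif")
  if (cfg$h_helix_bias < 0 || cfg$h_helix_bias > 1)
    stop("h_helix_bias must be in [0,1]")
  if (min(rng$n) + min(rng$h) + min(rng$c) <= 5)
    stop("total signal length must exceed 5")
  class(cfg) <- "sp_sim_config"
  cfg
}

# residue pools
.N_POOL <- c("K", "R", "N", "Q", "S", "T", "A", "G")
.N_W    <- c( 3 ,  3 ,  1 ,  1 ,  2 ,  2 ,  2 ,  1 )
.H_POOL <- c("A", "C", "F", "G", "I", "L", "M", "P", "S", "T", "V", "W", "Y")
.C_POOL <- c("A", "S", "G", "T", "V")

# exponential tilt of the H-region residue distribution so that the mean z1
# hits `target`; solved once per group
.h_weights <- function(target) {
  z1 <- ZSCALES[.H_POOL, "z1"]
  w0 <- exp(-0.4 * z1)
  mean_at <- function(s) {
    w <- w0 * exp(-s * z1)
    sum(w * z1) / sum(w)
  }
  if (target <= min(z1) || target >= max(z1))
    stop("requested H-region hydrophobicity shift is unattainable")
  s <- stats::uniroot(function(s) mean_at(s) - target, c(-25, 25))$root
  w <- w0 * exp(-s * z1)
  w / sum(w)
}

.sample_len <- function(rng) {
  if (rng[1L] == rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
}

.make_peptide <- function(id, category, localization, h_weights, rng) {
  n_len <- .sample_len(rng$n)
  n_seq <- c("M", sample(c("K", "R"), 1L),
             sample(.N_POOL, max(0L, n_len - 2L), replace = TRUE,
                    prob = .N_W))[seq_len(n_len)]
  if (category %in% c("TAT", "TATLIPO")) {
    n_seq[c(n_len - 1L, n_len)] <- "R"  # twin-arginine motif
  }
  h_len <- .sample_len(rng$h)
  h_seq <- sample(.H_POOL, h_len, replace = TRUE, prob = h_weights)
  if (category %in% c("LIPO", "TATLIPO")) {
    lipobox <- c(sample(c("L", "V", "I"), 1L), sample(c("A", "S", "G"), 1L),
                 sample(c("G", "A"), 1L), "C")
    h_seq <- c(h_seq, lipobox)
    c_seq <- character(0)
  } else {
    c_len <- .sample_len(rng$c)
    c_seq <- sample(.C_POOL, c_len, replace = TRUE)
    c_seq[c(c_len - 2L, c_len)] <- "A"  # A-X-A cleavage motif
  }
  n_end <- length(n_seq)
  h_end <- n_end + length(h_seq)
  cleave <- h_end + length(c_seq)
  signal_peptide(
    protein_id = id,
    sequence = paste(c(n_seq, h_seq, c_seq), collapse = ""),
    category = category,
    n = c(1L, n_end), h = c(n_end + 1L, h_end),
    c = if (length(c_seq)) c(h_end + 1L, cleave) else NULL,
    cleavage_pos = cleave, localization = localization)
}

#' Generate synthetic signal peptides
#'
#' Generates `n_per_group[category]` peptides for each (category,
#' localization) pair.  N-regions start with M and contain at least one
#' positively charged residue; TAT/TATLIPO N-regions end in the RR
#' twin-arginine dipeptide; LIPO/TATLIPO sequences end in a lipobox
#' `[LVI][ASG][GA]C` with no C-region; SP/TAT carry an A-X-A C-region.
#' Lumen-group H-region residues are drawn from a distribution whose mean
#' z1 is lower (more hydrophobic) than the pom group by
#' `h_hydrophobicity_shift`.  PILIN records are emitted without region
#' annotation and are excluded by [load_signal_annotations()].
#'
#' @param cfg An [sp_sim_config()].
#' @return Named list of `signal_peptide` objects.
#' @export
generate_signal_peptides <- function(cfg) {
  stopifnot(inherits(cfg, "sp_sim_config"))
  set.seed(cfg$seed + 2L)
  z1 <- ZSCALES[.H_POOL, "z1"]
  w0 <- exp(-0.4 * z1)
  base_mean <- sum(w0 * z1) / sum(w0)
  wts <- list(
    lumen = .h_weights(base_mean - cfg$h_hydrophobicity_shift / 2),
    pom = .h_weights(base_mean + cfg$h_hydrophobicity_shift / 2))
  rng <- cfg$region_length_ranges
  out <- list()
  for (loc in c("lumen", "pom")) {
    for (cat_i in names(cfg$n_per_group)) {
      k <- cfg$n_per_group[[cat_i]]
      if (k < 1) next
      for (i in seq_len(k)) {
        id <- sprintf("%s_%s_%03d", tolower(cat_i), loc, i)
        if (cat_i == "PILIN") {
          len <- sample(12:25, 1L)
          out[[id]] <- signal_peptide(
            protein_id = id,
            sequence = paste(c("M", sample(AA_LETTERS, len - 1L,
                                           replace = TRUE)), collapse = ""),
            category = "PILIN", localization = loc)
        } else {
          out[[id]] <- .make_peptide(id, cat_i, loc, wts[[loc]], rng)
        }
      }
    }
  }
  out
}

#' Generate JPred-style predictions for synthetic peptides
#'
#' Per-residue helix probability increases with residue hydrophobicity
#' (lower z1); inside the annotated H-region the helix probability is mixed
#' toward 1 with weight `h_helix_bias`, producing contiguous helices.
#' Burial probabilities at the three exposure cutoffs are nested per
#' residue.  Confidence digits encode the model probability of the emitted
#' state.
#'
#' @param peptides List of `signal_peptide`s.
#' @param cfg The [sp_sim_config()] used to generate them.
#' @return Named list of `sspred` objects (one per peptide).
#' @export
generate_ss_predictions <- function(peptides, cfg) {
  stopifnot(inherits(cfg, "sp_sim_config"))
  if (!length(peptides)) stop("no peptides supplied")
  set.seed(cfg$seed + 3L)
  lapply_named <- function(x, f) {
    out <- lapply(x, f)
    names(out) <- vapply(x, `[[`, "", "protein_id")
    out
  }
  lapply_named(peptides, function(p) {
    r <- .residues(p$sequence)
    L <- length(r)
    z1 <- ZSCALES[r, "z1"]
    p_h <- stats::plogis(-1.0 - 0.7 * z1)
    in_h <- rep(FALSE, L)
    if (!is.null(p$regions$h))
      in_h[p$regions$h[1L]:p$regions$h[2L]] <- TRUE
    p_h[in_h] <- (1 - cfg$h_helix_bias) * p_h[in_h] + cfg$h_helix_bias
    p_e <- 0.2 * (1 - p_h)
    states <- vapply(seq_len(L), function(i)
      sample(c("H", "E", "-"), 1L,
             prob = c(p_h[i], p_e[i], 1 - p_h[i] - p_e[i])), "")
    # one smoothing pass: flip isolated states flanked by agreeing neighbors
    if (L >= 3L) {
      for (i in 2:(L - 1L)) {
        if (states[i] != states[i - 1L] && states[i - 1L] == states[i + 1L])
          states[i] <- states[i - 1L]
      }
    }
    p_state <- ifelse(states == "H", p_h,
                      ifelse(states == "E", p_e, 1 - p_h - p_e))
    conf <- pmin(9L, pmax(0L, as.integer(round(9 * p_state))))
    u <- stats::runif(L)
    p_bury <- function(off) stats::plogis(-0.8 * z1 - off)
    bur <- function(off) paste(ifelse(u < p_bury(off), "B", "-"),
                               collapse = "")
    sspred(protein_id = p$protein_id,
           states = paste(states, collapse = ""),
           conf = paste(conf, collapse = ""),
           burial = c(sol0 = bur(2.0), sol5 = bur(1.2), sol25 = bur(0.4)))
  })
}
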