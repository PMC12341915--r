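test_that("ground-truth proteome has forced counts, partition and determinism", {
  cfg <- sim_config(n_lumen = 10, n_pom = 10, n_dual = 0, n_cytoplasm = 80,
                    n_tp_lumen = 4, n_tp_pom = 4, n_fp_cytoplasm = 20,
                    seed = 7)
  truth <- generate_compartment_proteome(cfg)
  expect_equal(nrow(truth), 100)
  expect_equal(anyDuplicated(truth$protein_id), 0L)
  expect_equal(as.vector(table(truth$true_compartment)[c("cytoplasm", "lumen", "pom")]),
               c(80, 10, 10))
  expect_identical(truth, generate_compartment_proteome(cfg))
})

test_that("control sets are feasible, disjoint and never dual", {
  cfg <- sim_config(seed = 3)
  truth <- generate_compartment_proteome(cfg)
  expect_equal(sum(truth$is_tp_lumen), cfg$n_tp_lumen)
  expect_true(all(truth$true_compartment[truth$is_tp_lumen] == "lumen"))
  expect_true(all(truth$true_compartment[truth$is_tp_pom] == "pom"))
  expect_true(all(truth$true_compartment[truth$is_fp_cytoplasm] == "cytoplasm"))
  expect_false(any(truth$is_tp_lumen & truth$is_fp_cytoplasm))
  expect_false(any(truth$is_tp_lumen[truth$true_compartment == "dual"]))
  # infeasible draws error
  expect_error(generate_compartment_proteome(
    sim_config(n_lumen = 0, n_pom = 10, n_cytoplasm = 50, n_dual = 0,
               n_tp_lumen = 5, n_tp_pom = 5, n_fp_cytoplasm = 10)),
    "required compartment")
  expect_error(generate_compartment_proteome(
    sim_config(n_lumen = 3, n_pom = 10, n_cytoplasm = 50, n_dual = 0,
               n_tp_lumen = 5, n_tp_pom = 5, n_fp_cytoplasm = 10)),
    "larger than compartment")
})

test_that("intensities: no effect + no noise gives identical samples", {
  cfg <- sim_config(n_lumen = 5, n_pom = 5, n_dual = 0, n_cytoplasm = 20,
                    n_tp_lumen = 2, n_tp_pom = 2, n_fp_cytoplasm = 5,
                    enrichment_effect = 0, effect_sd = 0, noise_sd = 0,
                    bait_scale_sd = 0, seed = 1)
  m <- generate_tmt_intensities(generate_compartment_proteome(cfg), cfg)
  expect_equal(ncol(m$values), 18)  # 6 baits x 3 replicates
  expect_true(all(abs(m$values - m$values[, 1]) < 1e-12))
})

test_that("replicates correlate more than cross-compartment samples", {
  s <- small_sim(11)
  r <- sample_correlation(s$m)
  expect_gt(r["lumen_b1_r1", "lumen_b1_r2"], r["lumen_b1_r1", "pom_b1_r1"])
  expect_gt(r["pom_b1_r1", "pom_b1_r2"], r["pom_b1_r1", "lumen_b2_r1"])
})

test_that("tat leak raises periplasm-bait labeling of cytoplasmic proteins and Fig-3A-style correlation asymmetry", {
  base <- sim_config(n_lumen = 30, n_pom = 30, n_dual = 0, n_cytoplasm = 150,
                     n_tp_lumen = 10, n_tp_pom = 10, n_fp_cytoplasm = 50,
                     seed = 5)
  leak0 <- base; leak0$tat_leak <- 0
  leak5 <- base; leak5$tat_leak <- 0.5
  truth <- generate_compartment_proteome(base)
  m0 <- generate_tmt_intensities(truth, leak0)
  m5 <- generate_tmt_intensities(truth, leak5)
  cyto <- truth$protein_id[truth$true_compartment == "cytoplasm"]
  pom_samp <- compartment_samples(m0, "pom")
  expect_gt(mean(m5$values[cyto, pom_samp]), mean(m0$values[cyto, pom_samp]))
  # with leak, cytoplasm/periplasm correlation exceeds cytoplasm/lumen
  r <- sample_correlation(m5)
  cs <- compartment_samples(m5, "cytoplasm")
  ls <- compartment_samples(m5, "lumen")
  expect_gt(mean(r[cs, pom_samp]), mean(r[cs, ls]))
})

test_that("mean lumen enrichment is monotone in the labeling effect", {
  for (seed in c(2, 9)) {
    prev <- -Inf
    for (eff in c(1, 2, 4) * log(2)) {
      cfg <- sim_config(n_lumen = 25, n_pom = 25, n_dual = 0,
                        n_cytoplasm = 100, n_tp_lumen = 8, n_tp_pom = 8,
                        n_fp_cytoplasm = 30, enrichment_effect = eff,
                        seed = seed)
      truth <- generate_compartment_proteome(cfg)
      m <- generate_tmt_intensities(truth, cfg)
      e <- mean_enrichment(m, compartment_samples(m, "lumen"),
                           compartment_samples(m, "cytoplasm"))
      cur <- mean(e[truth$protein_id[truth$true_compartment == "lumen"]])
      expect_gt(cur, prev)
      prev <- cur
    }
  }
})

test_that("generated peptides satisfy the motif and span contracts", {
  pc <- sp_sim_config(seed = 21)
  peps <- generate_signal_peptides(pc)
  expect_identical(vapply(generate_signal_peptides(pc), `[[`, "", "sequence"),
                   vapply(peps, `[[`, "", "sequence"))
  for (p in peps) {
    if (p$category == "PILIN") {
      expect_null(p$regions$n)
      next
    }
    spans <- p$regions
    expect_equal(spans$n[1], 1)
    expect_equal(spans$h[1], spans$n[2] + 1)
    last <- if (!is.null(spans$c)) spans$c else spans$h
    expect_equal(last[2], p$cleavage_pos)
    # N-region: starts with M, has a positive residue
    n_seq <- substr(p$sequence, spans$n[1], spans$n[2])
    expect_match(n_seq, "^M")
    expect_match(n_seq, "[KR]")
    if (p$category %in% c("TAT", "TATLIPO")) expect_match(n_seq, "RR")
    if (p$category %in% c("LIPO", "TATLIPO")) {
      expect_null(spans$c)
      expect_equal(substr(p$sequence, p$cleavage_pos, p$cleavage_pos), "C")
      expect_match(substr(p$sequence, p$cleavage_pos - 3, p$cleavage_pos),
                   "^[LVI][ASG][GA]C$")
    } else {
      expect_false(is.null(spans$c))
    }
    expect_gt(p$cleavage_pos, 5)
  }
})

test_that("zero hydrophobicity shift gives matched H-region GRAVY between groups", {
  pc <- sp_sim_config(n_per_group = c(SP = 250), h_hydrophobicity_shift = 0,
                      seed = 31)
  peps <- generate_signal_peptides(pc)
  g <- vapply(peps, function(p)
    gravy(substr(p$sequence, p$regions$h[1], p$regions$h[2])), 0)
  loc <- vapply(peps, `[[`, "", "localization")
  a <- g[loc == "lumen"]; b <- g[loc == "pom"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("infeasible region ranges are rejected", {
  expect_error(sp_sim_config(region_length_ranges =
    list(n = c(1, 2), h = c(7, 15), c = c(3, 7))), "M/RR")
  expect_error(sp_sim_config(region_length_ranges =
    list(n = c(4, 8), h = c(7, 15), c = c(1, 2))), "A-X-A")
})

test_that("structure predictions align with peptides and obey the helix-bias limit", {
  pc <- sp_sim_config(n_per_group = c(SP = 5, LIPO = 3), seed = 13)
  peps <- generate_signal_peptides(pc)
  preds <- generate_ss_predictions(peps, pc)
  expect_identical(
    vapply(preds, `[[`, "", "states"),
    vapply(generate_ss_predictions(peps, pc), `[[`, "", "states"))
  for (id in names(peps)) {
    L <- nchar(peps[[id]]$sequence)
    expect_equal(nchar(preds[[id]]$states), L)
    expect_equal(nchar(preds[[id]]$conf), L)
    expect_true(all(nchar(preds[[id]]$burial) == L))
    # burial tracks are nested: sol0 implies sol5 implies sol25
    b <- lapply(preds[[id]]$burial, function(s) strsplit(s, "")[[1]] == "B")
    expect_true(all(b$sol5[b$sol0]))
    expect_true(all(b$sol25[b$sol5]))
  }
  pc1 <- sp_sim_config(n_per_group = c(SP = 4), h_helix_bias = 1, seed = 13)
  peps1 <- generate_signal_peptides(pc1)
  preds1 <- generate_ss_predictions(peps1, pc1)
  for (id in names(peps1)) {
    h <- peps1[[id]]$regions$h
    expect_equal(substr(preds1[[id]]$states, h[1], h[2]),
                 strrep("H", h[2] - h[1] + 1))
  }
})
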