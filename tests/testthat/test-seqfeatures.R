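test_that("gravy matches the published hydropathy table", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("IR"), 0)
  expect_error(gravy("AXZ"), "unknown residue")
  set.seed(20)
  for (i in 1:20) {
    s <- random_peptide()
    expect_gte(gravy(s), -4.5)
    expect_lte(gravy(s), 4.5)
  }
})

test_that("molecular weight, composition and charged counts are exact", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  cmp <- aa_composition("AAG")
  expect_equal(unname(cmp$proportions[c("A", "G")]), c(2 / 3, 1 / 3))
  expect_equal(sum(cmp$proportions), 1)
  expect_equal(unname(charged_counts("KKDD")), c(2L, 2L))
  expect_equal(unname(charged_counts("KHR", include_histidine = TRUE)[1]), 3L)
  expect_equal(unname(charged_counts("KHR")[1]), 2L)
})

test_that("charge is monotone in pH and vanishes at the isoelectric point", {
  for (s in c("MKKLLDE", "DDDAA", "KKKAY")) {
    ph <- seq(1, 13, by = 0.5)
    q <- charge_at_pH(s, ph)
    expect_true(all(diff(q) < 0))
    expect_lt(abs(charge_at_pH(s, isoelectric_point(s))), 1e-4)
  }
  expect_gt(isoelectric_point("KKKKAA"), isoelectric_point("DDDDAA"))
})

test_that("z-scale means respect homopolymers and length-weighted concatenation", {
  zt <- zscale_table()
  expect_equal(unname(zscale_means("LLLL")),
               unname(unlist(zt["L", c("z1", "z2", "z3")])))
  a <- "MKA"; b <- "LLWYS"
  za <- zscale_means(a); zb <- zscale_means(b)
  expect_equal(zscale_means(paste0(a, b)),
               (nchar(a) * za + nchar(b) * zb) / (nchar(a) + nchar(b)))
  hand <- (zt["M", "z2"] + zt["K", "z2"] + zt["A", "z2"]) / 3
  expect_equal(unname(zscale_means("MKA")["z2"]), hand)
})

test_that("ACC equals the brute-force double loop to 1e-12", {
  # constant sequence: A_jj(d) = z_j^2 for every valid lag
  zt <- zscale_table()
  for (d in 1:3)
    expect_equal(zscale_autocorrelation("AAAAAA", 1, d), zt["A", "z1"]^2)
  set.seed(21)
  for (i in 1:25) {
    s <- random_peptide(6, 25)
    d <- sample(1:4, 1)
    j <- sample(1:3, 1); k <- sample(1:3, 1)
    expect_equal(zscale_crosscorrelation(s, j, k, d), oracle_acc(s, j, k, d),
                 tolerance = 1e-12)
    expect_equal(zscale_autocorrelation(s, j, d),
                 zscale_crosscorrelation(s, j, j, d))
  }
  expect_true(is.na(zscale_autocorrelation("ML", 1, 2)))
  expect_true(is.na(zscale_autocorrelation("ML", 1, 5)))
})

test_that("ss_features computes run lengths, proportions and confidences", {
  pr <- sspred("x", states = "---HHHH--HH",
               conf = "12345678901",
               burial = c(sol0 = "-----------", sol5 = "B----------",
                          sol25 = "BB--------B"))
  f <- ss_features(pr)
  expect_equal(unname(f["helix_longest"]), 4)
  expect_equal(unname(f["helix_count"]), 6)
  expect_equal(unname(f["helix_prop"]), 6 / 11)
  expect_equal(unname(f["coil_prop"] + f["helix_prop"] + f["strand_prop"]), 1)
  expect_equal(unname(f["buried_count_sol25"]), 3)
  expect_equal(unname(f["buried_longest_sol25"]), 2)
  # all-coil span: zero helix run, missing helix confidence
  f2 <- ss_features(pr, span = c(1, 3))
  expect_equal(unname(f2["helix_longest"]), 0)
  expect_true(is.na(f2["helix_conf"]))
  expect_equal(unname(f2["coil_conf"]), 2)
  # helix-or-strand runs bridge the two states
  pr3 <- sspred("y", "HHEE-", "99999",
                burial = c(sol0 = "-----", sol5 = "-----", sol25 = "-----"))
  expect_equal(unname(ss_features(pr3)["helix_or_strand_longest"]), 4)
  expect_error(ss_features(pr, span = c(5, 3)), "span")
  expect_error(ss_features(pr, span = c(0, 3)), "span")
})

test_that("ss_features agrees with a naive run-length oracle on random strings", {
  set.seed(22)
  for (i in 1:40) {
    L <- sample(6:40, 1)
    st <- paste(sample(c("H", "E", "-"), L, TRUE, prob = c(.4, .2, .4)),
                collapse = "")
    cf <- paste(sample(0:9, L, TRUE), collapse = "")
    b <- paste(sample(c("B", "-"), L, TRUE), collapse = "")
    pr <- sspred("r", st, cf, burial = c(sol0 = b, sol5 = b, sol25 = b))
    f <- ss_features(pr)
    chars <- strsplit(st, "")[[1]]
    expect_equal(unname(f["helix_longest"]), oracle_longest_run(chars, "H"))
    expect_equal(unname(f["strand_longest"]), oracle_longest_run(chars, "E"))
    expect_equal(unname(f["helix_or_strand_longest"]),
                 oracle_longest_run(chars, c("H", "E")))
    expect_equal(unname(f["buried_longest_sol5"]),
                 oracle_longest_run(strsplit(b, "")[[1]], "B"))
    expect_equal(unname(f["helix_count"]), sum(chars == "H"))
  }
})

test_that("signal-peptide loader enforces the category and length filters", {
  dir <- withr::local_tempdir()
  peps <- list(
    signal_peptide("ok_sp", "MKKLLLLLLASA", "SP",
                   n = c(1, 3), h = c(4, 9), c = c(10, 12)),
    signal_peptide("short", "MKLLA", "SP", n = c(1, 2), h = c(3, 4),
                   c = c(5, 5)),
    signal_peptide("pilin", "MKALSYTREQW", "PILIN"))
  write_signal_peptides(peps, file.path(dir, "p.fasta"),
                        file.path(dir, "p.tsv"))
  msgs <- capture_messages(
    loaded <- load_signal_annotations(file.path(dir, "p.fasta"),
                                      file.path(dir, "p.tsv")))
  expect_true(any(grepl("PILIN", msgs)))
  expect_true(any(grepl("length <= 5", msgs)))
  expect_named(loaded, "ok_sp")
  expect_length(loaded$ok_sp$regions, 3)
  # malformed spans name the record
  expect_error(signal_peptide("bad", "MKKLLLLLLASA", "SP", n = c(1, 3),
                              h = c(3, 9), c = c(10, 12)), "bad")
  expect_error(signal_peptide("gap", "MKKLLLLLLASA", "SP", n = c(1, 3),
                              h = c(5, 9), c = c(10, 12)), "contiguous")
})

test_that("feature_table emits one row set per region and is permutation-stable", {
  pc <- sp_sim_config(n_per_group = c(SP = 3, LIPO = 2, PILIN = 1), seed = 30)
  peps <- generate_signal_peptides(pc)
  preds <- generate_ss_predictions(peps, pc)
  ft <- feature_table(peps, preds)
  sp_regions <- unique(ft$region[ft$category == "SP"])
  expect_setequal(sp_regions, c("full", "n", "h", "c"))
  expect_setequal(unique(ft$region[ft$category == "LIPO"]),
                  c("full", "n", "h"))
  expect_false("PILIN" %in% ft$category)
  # permutation of the input reorders rows only
  ft2 <- feature_table(rev(peps), preds)
  key <- function(d) d[order(d$protein_id, d$region, d$feature), "value"]
  expect_equal(key(ft2), key(ft))
  # determinism
  expect_identical(ft, feature_table(peps, preds))
  # missing prediction: physics present, structure absent
  ft3 <- feature_table(peps[1], predictions = NULL)
  expect_false("helix_longest" %in% ft3$feature)
  expect_true("gravy" %in% ft3$feature)
})

test_that("jpred concise files round into sspred objects", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.concise")
  writeLines(c("jnetpred:-,-,H,H,H,E,E,-,",
               "JNETCONF:7,7,8,9,8,5,4,3,",
               "JNETSOL25:B,-,B,B,-,-,-,B,",
               "JNETSOL5:-,-,B,B,-,-,-,-,",
               "JNETSOL0:-,-,B,-,-,-,-,-,"), path)
  pr <- read_jpred_concise(path, "x")
  expect_equal(pr$states, "--HHHEE-")
  expect_equal(pr$conf, "77898543")
  expect_equal(unname(pr$burial["sol25"]), "B-BB---B")
  f <- ss_features(pr)
  expect_equal(unname(f["helix_longest"]), 3)
})
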