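# Independent brute-force oracles.  These deliberately re-derive every
# quantity with naive loops and their own copies of the published constant
# tables, so they share no code path with the implementation.

oracle_roc <- function(e, tp_ids, fp_ids, tie = c("smallest", "largest")) {
  tie <- match.arg(tie)
  e_tp <- e[names(e) %in% tp_ids]
  e_fp <- e[names(e) %in% fp_ids]
  cand <- sort(unique(unname(e)))
  best_diff <- -Inf
  best <- c()
  for (t in cand) {
    tpr <- sum(e_tp >= t) / length(e_tp)
    fpr <- sum(e_fp >= t) / length(e_fp)
    d <- tpr - fpr
    if (d > best_diff + 1e-15) {
      best_diff <- d
      best <- t
    } else if (abs(d - best_diff) <= 1e-15) {
      best <- c(best, t)
    }
  }
  if (tie == "smallest") min(best) else max(best)
}

ORACLE_KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

ORACLE_MASS <- c(A = 89.0935, R = 174.2017, N = 132.1184, D = 133.1032,
                 C = 121.1590, Q = 146.1451, E = 147.1293, G = 75.0669,
                 H = 155.1552, I = 131.1736, L = 131.1736, K = 146.1882,
                 M = 149.2124, F = 165.1900, P = 115.1310, S = 105.0930,
                 T = 119.1197, W = 204.2262, Y = 181.1894, V = 117.1469)

oracle_gravy <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  tot <- 0
  for (a in r) tot <- tot + ORACLE_KD[[a]]
  tot / length(r)
}

oracle_mw <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  tot <- 0
  for (a in r) tot <- tot + ORACLE_MASS[[a]]
  tot - (length(r) - 1) * 18.01528
}

oracle_charge <- function(seq, pH) {
  r <- strsplit(seq, "")[[1]]
  pos_pka <- c(7.50, c(K = 10, R = 12, H = 5.98)[r[r %in% c("K", "R", "H")]])
  neg_pka <- c(3.55,
               c(D = 4.05, E = 4.45, C = 9, Y = 10)[r[r %in% c("D", "E", "C", "Y")]])
  q <- 0
  for (pk in pos_pka) q <- q + 1 / (1 + 10^(pH - pk))
  for (pk in neg_pka) q <- q - 1 / (1 + 10^(pk - pH))
  q
}

oracle_zmean <- function(seq, col) {
  zt <- apexloc::zscale_table()
  r <- strsplit(seq, "")[[1]]
  tot <- 0
  for (a in r) tot <- tot + zt[a, col]
  tot / length(r)
}

oracle_acc <- function(seq, j, k, d) {
  zt <- apexloc::zscale_table()
  r <- strsplit(seq, "")[[1]]
  n <- length(r)
  if (d >= n) return(NA_real_)
  tot <- 0
  for (i in 1:(n - d))
    tot <- tot + zt[r[i], paste0("z", j)] * zt[r[i + d], paste0("z", k)]
  tot / (n - d)
}

oracle_longest_run <- function(chars, accept) {
  best <- 0L
  cur <- 0L
  for (ch in chars) {
    if (ch %in% accept) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else cur <- 0L
  }
  best
}

random_peptide <- function(min_len = 5, max_len = 30) {
  paste(sample(names(ORACLE_KD), sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# small simulated world used by several localization tests
small_sim <- function(seed = 42) {
  cfg <- sim_config(n_lumen = 30, n_pom = 30, n_dual = 6, n_cytoplasm = 150,
                    n_tp_lumen = 12, n_tp_pom = 12, n_fp_cytoplasm = 60,
                    seed = seed)
  truth <- generate_compartment_proteome(cfg)
  m <- generate_tmt_intensities(truth, cfg)
  list(cfg = cfg, truth = truth, m = m,
       controls = truth_control_sets(truth))
}
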