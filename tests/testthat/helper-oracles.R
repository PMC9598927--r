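# Independent brute-force oracles used to validate the package's
# implementations. These are deliberately written as naive loops /
# closed forms, sharing no code with the functions they check.

# Brute-force ceRNA axis miner: triple loop over all (lncRNA, miRNA,
# mRNA) combinations applying the sponge sign rule and linear FC gates.
brute_force_axes <- function(de_lnc, de_mir, de_mrna, lnc_edges, mrna_edges,
                             polarity, partner_min_fc = 2, lnc_min_fc = 2) {
  mir_dir <- if (polarity == "oncogenic") "down" else "up"
  part_dir <- if (polarity == "oncogenic") "up" else "down"
  lnc_key <- paste(normalize_mirna_id(lnc_edges$mirna_id), lnc_edges$partner_id)
  mrna_key <- paste(normalize_mirna_id(mrna_edges$mirna_id), mrna_edges$partner_id)
  lid <- de_lnc$feature_id; ldir <- de_lnc$direction; lfc <- de_lnc$fold_change
  mid <- de_mir$feature_id; mdir <- de_mir$direction
  mkey <- normalize_mirna_id(mid)
  gid <- de_mrna$feature_id; gdir <- de_mrna$direction; gfc <- de_mrna$fold_change
  out <- character(0)
  for (i in seq_along(lid)) {
    for (j in seq_along(mid)) {
      for (k in seq_along(gid)) {
        ok <- mdir[j] == mir_dir &&
          ldir[i] == part_dir && gdir[k] == part_dir &&
          abs(lfc[i]) >= partner_min_fc &&
          abs(gfc[k]) >= partner_min_fc &&
          abs(lfc[i]) >= lnc_min_fc &&
          paste(mkey[j], lid[i]) %in% lnc_key &&
          paste(mkey[j], gid[k]) %in% mrna_key
        if (ok) out <- c(out, paste(lid[i], mid[j], gid[k]))
      }
    }
  }
  sort(out)
}

# Random direction-classified DE table for property tests.
random_de_table <- function(ids, up_down_only = FALSE) {
  n <- length(ids)
  log2fc <- round(runif(n, -3, 3), 2)
  p <- runif(n)
  dir <- sample(c("up", "down", "ns"), n, replace = TRUE)
  dir[dir == "up" & log2fc <= 0] <- "down"
  dir[dir == "down" & log2fc >= 0] <- "up"
  tibble::tibble(
    feature_id = ids, log2fc = log2fc,
    fold_change = sign(log2fc) * 2^abs(log2fc),
    p_value = p, fdr = pmin(1, p * 2), direction = dir
  )
}

# Hand product-limit estimator (no survival package).
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

# Hand two-group log-rank chi-square from per-event-time 2x2 tables.
hand_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    n_at <- sum(time >= t)
    n1_at <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1_at / n_at
    if (n_at > 1) {
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Exhaustive hypergeometric upper tail by enumerating all draws.
enum_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the term members
  mean(hits >= k)
}
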