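# Independent brute-force oracles. These deliberately take the slow,
# obviously-correct route (full pairwise matrices, exhaustive enumeration)
# and share no code with the implementation paths they check.

# EDC via the full pairwise distance matrix
edc_oracle <- function(xyz, mutated, keep = rep(TRUE, nrow(xyz))) {
  idx <- which(keep)
  D <- as.matrix(dist(xyz[idx, , drop = FALSE]))
  lab <- idx %in% mutated
  dmin <- vapply(seq_along(idx), function(i) {
    cand <- which(lab & seq_along(idx) != i)
    min(D[i, cand])
  }, numeric(1))
  mean(log(dmin[!lab])) / mean(log(dmin[lab]))
}

# exact two-sided Mann-Whitney p by exhaustive subset enumeration
wilcox_enum_oracle <- function(a, b) {
  n_a <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)])
  subs <- combn(length(r), n_a)
  ws <- apply(subs, 2, function(ix) sum(r[ix]))
  eps <- 1e-9
  p_le <- mean(ws <= w_obs + eps)
  p_ge <- mean(ws >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Fisher p by enumerating the 2x2 support with factorials
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  prob <- function(a) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(r1 - a) - lfactorial(c1 - a) -
          lfactorial(r2 - c1 + a))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(m[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# straight C-alpha chain at fixed spacing (worked-example geometry)
line_coords <- function(n, spacing = 3.8) {
  cbind((seq_len(n) - 1) * spacing, 0, 0)
}

# small in-memory stability table builder
toy_stability <- function(ddg, protein_id = "P") {
  alts <- setdiff(c("C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), "A")
  ddg_rank(tibble::tibble(protein_id = protein_id,
                          position = seq_along(ddg),
                          ref_aa = "A",
                          alt_aa = rep_len(alts, length(ddg)),
                          ddg = ddg))
}

# minimal predicted-model PDB text (CA-only) for read_structure tests
ca_pdb_lines <- function(bfactors, start_res = 1, chain = "A",
                         spacing = 3.8) {
  n <- length(bfactors)
  c(sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), chain, start_res + seq_len(n) - 1,
    (seq_len(n) - 1) * spacing, 0, 0, 1.00, bfactors), "END")
}

# rank-based (Mann-Whitney) AUC of a score for recovering positive labels
rank_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
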