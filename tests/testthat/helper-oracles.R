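# Brute-force plug-in oracles: direct evaluation of the entropy / MI /
# correction formulas by explicit loops over empirical probability
# tables.  Deliberately naive and independent of the package's
# vectorised implementation paths.

oracle_entropy <- function(x) {
  h <- 0
  for (s in unique(x)) {
    p <- sum(x == s) / length(x)
    if (p > 0) h <- h - p * log(p)
  }
  h
}

oracle_joint_entropy <- function(x, y) {
  h <- 0
  for (s in unique(x)) for (t in unique(y)) {
    p <- sum(x == s & y == t) / length(x)
    if (p > 0) h <- h - p * log(p)
  }
  h
}

oracle_mi <- function(x, y) {
  v <- oracle_entropy(x) + oracle_entropy(y) - oracle_joint_entropy(x, y)
  max(v, 0)
}

# Direct evaluation of the triple sum P(j,k,l) log[P(j,k,l)/(P(j)P(k)P(l))]
oracle_mi3d <- function(x, y, z) {
  n <- length(x)
  v <- 0
  for (s in unique(x)) for (t in unique(y)) for (u in unique(z)) {
    p <- sum(x == s & y == t & z == u) / n
    if (p > 0)
      v <- v + p * log(p / ((sum(x == s) / n) * (sum(y == t) / n) * (sum(z == u) / n)))
  }
  max(v, 0)
}

# Raw inter-domain MI list for an MSA, after zero exclusion.
oracle_mi_pairs <- function(msa, eligible1, eligible2) {
  out <- NULL
  for (j in eligible1) for (k in eligible2) {
    v <- oracle_mi(msa$seq[, j], msa$seq[, k])
    if (abs(v) > 1e-12)
      out <- rbind(out, data.frame(col1 = j, col2 = k, raw = v))
  }
  out
}

oracle_apc <- function(pairs, j, k) {
  mj <- mean(pairs$raw[pairs$col1 == j | pairs$col2 == j])
  mk <- mean(pairs$raw[pairs$col1 == k | pairs$col2 == k])
  mj * mk / mean(pairs$raw)
}

# CPS with L over all eligible columns except J and K.
oracle_cps <- function(msa, cols, j, k) {
  Ls <- setdiff(cols, c(j, k))
  tot <- 0
  for (L in Ls) tot <- tot + oracle_mi(msa$seq[, j], msa$seq[, L]) *
    oracle_mi(msa$seq[, k], msa$seq[, L])
  tot / length(Ls)
}

oracle_upper_binom <- function(hits, k, p) {
  tot <- 0
  for (i in hits:k) tot <- tot + choose(k, i) * p^i * (1 - p)^(k - i)
  tot
}

# Small random paired MSA over a reduced alphabet, for exhaustive
# oracle-equivalence checks.
random_small_msa <- function(seed, n_seq = 6, n1 = 3, n2 = 2, alphabet = c("A", "C", "D", "E")) {
  set.seed(seed)
  m <- matrix(sample(alphabet, n_seq * (n1 + n2), replace = TRUE), n_seq, n1 + n2)
  paired_msa(m, reference = 1L, domain1_range = c(1, n1),
             domain2_range = c(n1 + 1, n1 + n2), id = paste0("toy", seed))
}

# Candidate pool with a prescribed top-k hit pattern: n_pos contacts out
# of n total, exactly `hits` of them among the k top unique scores.
make_pool <- function(n, n_pos, k, hits) {
  contact <- c(rep(TRUE, hits), rep(FALSE, k - hits),
               rep(TRUE, n_pos - hits), rep(FALSE, n - k - (n_pos - hits)))
  data.frame(column = seq_len(n), contact = contact,
             surface = TRUE, score = seq(n, 1))
}
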