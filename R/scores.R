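# Coevolution scores between domain columns: MI, MIp (average product
# correction), MIc (coevolutionary pattern similarity correction), the
# triangle scores MI3D / MIp3D, and their shared standardisation and
# zero-score exclusion rules.

new_score_table <- function(df, variant, alphabet, excluded, n_eligible) {
  rownames(df) <- NULL
  structure(df, variant = variant, alphabet = alphabet,
            excluded = excluded, n_eligible = n_eligible,
            class = c("pair_score_table", "data.frame"))
}

#' @export
print.pair_score_table <- function(x, ...) {
  cat(sprintf("%s%s score table: %d surviving entries, %d excluded\n",
              attr(x, "variant"),
              if (identical(attr(x, "alphabet"), "RA")) "RA" else "",
              nrow(x), nrow(attr(x, "excluded"))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

eligible_domain_cols <- function(msa, mask) {
  el <- mask$col[mask$eligible]
  list(e1 = intersect(msa$domain1_cols, el),
       e2 = intersect(msa$domain2_cols, el))
}

# Raw MI values for all ordered pairs (cols1 x cols2) of integer-coded
# columns; tiny negatives from floating point are clamped to 0.
mi_pair_matrix <- function(code, nsym, cols1, cols2) {
  H <- vapply(unique(c(cols1, cols2)),
              function(j) col_entropy_int(code[, j], nsym), 0)
  names(H) <- as.character(unique(c(cols1, cols2)))
  out <- matrix(0, length(cols1), length(cols2),
                dimnames = list(cols1, cols2))
  for (i in seq_along(cols1)) {
    a <- code[, cols1[i]]
    ha <- H[[as.character(cols1[i])]]
    for (j in seq_along(cols2)) {
      if (cols1[i] == cols2[j]) { out[i, j] <- ha; next }
      v <- ha + H[[as.character(cols2[j])]] -
        joint_entropy_int(a, code[, cols2[j]], nsym)
      out[i, j] <- if (v < 1e-12) 0 else v
    }
  }
  out
}

#' Mutual information between two columns
#'
#' \eqn{MI(J;K) = H(J) + H(K) - H(J;K)} in nats.  Perfectly covarying
#' columns over k equiprobable states give \eqn{\log_e k}; independent
#' columns give 0.  Tiny negative values arising from floating point are
#' clamped to 0.
#'
#' @param x,y character vectors (two alignment columns over the same rows).
#' @return raw MI in nats.
#' @export
mi <- function(x, y) {
  v <- column_entropy(x) + column_entropy(y) - joint_entropy(x, y)
  if (v < 1e-12) 0 else v
}

#' Raw and standardised MI for all inter-domain column pairs
#'
#' Computes MI for every eligible (domain-1, domain-2) column pair.
#' Pairs with a raw MI of exactly 0 carry no covariation signal and are
#' moved to the exclusion list; the surviving scores are standardised to
#' z-scores (mean 0, sample sd 1) over the alignment's own surviving
#' inter-domain pairs.
#'
#' @param msa a [paired_msa()].
#' @param mask a [column_mask()]; defaults to `column_mask(msa)`.
#' @return a `pair_score_table` data frame with columns `col1`, `col2`,
#'   `raw`, `z`, and attributes `variant`, `alphabet`, `excluded`,
#'   `n_eligible`.
#' @export
mi_table <- function(msa, mask = column_mask(msa)) {
  ec <- eligible_domain_cols(msa, mask)
  if (length(ec$e1) == 0L || length(ec$e2) == 0L)
    mi_error("no_pairs", "no eligible columns in one of the domains")
  enc <- encode_msa(msa$seq)
  M <- mi_pair_matrix(enc$code, length(enc$symbols), ec$e1, ec$e2)
  df <- data.frame(col1 = rep(ec$e1, times = length(ec$e2)),
                   col2 = rep(ec$e2, each = length(ec$e1)),
                   raw = as.vector(M))
  zero <- df$raw == 0
  excluded <- data.frame(col1 = df$col1[zero], col2 = df$col2[zero],
                         reason = rep("zero_mi", sum(zero)),
                         stringsAsFactors = FALSE)
  df <- df[!zero, , drop = FALSE]
  if (nrow(df) == 0L)
    mi_error("no_pairs", "every inter-domain pair has an MI of 0")
  df$z <- zscore(df$raw)
  new_score_table(df, "MI", msa$alphabet, excluded,
                  n_eligible = length(ec$e1) + length(ec$e2))
}

#' Average product correction for one pair
#'
#' \eqn{APC(J;K) = \bar{MI}(J)\,\bar{MI}(K)/\bar{MI}}, where
#' \eqn{\bar{MI}(J)} is the mean raw MI of surviving pairs containing
#' column J, and \eqn{\bar{MI}} the overall mean over surviving
#' inter-domain pairs.  This estimates the background (phylogenetic and
#' entropic) signal shared by the two columns.
#'
#' @param table an MI `pair_score_table` (survivors only, as returned by
#'   [mi_table()]).
#' @param j,k column indices of the pair.
#' @return the correction term.
#' @export
apc <- function(table, j, k) {
  overall <- mean(table$raw)
  if (overall == 0) mi_error("zero_mean", "overall mean MI is 0")
  mj <- mean(table$raw[table$col1 == j | table$col2 == j])
  mk <- mean(table$raw[table$col1 == k | table$col2 == k])
  if (is.nan(mj) || is.nan(mk))
    mi_error("no_pairs", "no surviving pair contains the requested column")
  mj * mk / overall
}

#' MIp: MI with the average product correction
#'
#' \eqn{MIp(J;K) = MI(J;K) - APC(J;K)} for every surviving inter-domain
#' pair; zero-MI pairs are excluded before the APC means are computed.
#' Standardised like MI, over the surviving pairs.
#'
#' @inheritParams mi_table
#' @return a `pair_score_table` with variant `"MIp"` (columns as
#'   [mi_table()] plus `mi` and `apc`).
#' @export
mip_table <- function(msa, mask = column_mask(msa)) {
  t0 <- mi_table(msa, mask)
  overall <- mean(t0$raw)
  mj <- tapply(c(t0$raw, t0$raw), c(t0$col1, t0$col2), mean)
  raw <- t0$raw - mj[as.character(t0$col1)] * mj[as.character(t0$col2)] / overall
  df <- data.frame(col1 = t0$col1, col2 = t0$col2,
                   mi = t0$raw,
                   apc = t0$raw - raw,
                   raw = unname(raw))
  df$z <- zscore(df$raw)
  new_score_table(df, "MIp", attr(t0, "alphabet"), attr(t0, "excluded"),
                  attr(t0, "n_eligible"))
}

# Full symmetric raw-MI matrix over a set of columns (diagonal set to 0 so
# matrix products sum over third columns L distinct from both endpoints).
mi_full_matrix <- function(msa, cols) {
  enc <- encode_msa(msa$seq)
  M <- mi_pair_matrix(enc$code, length(enc$symbols), cols, cols)
  diag(M) <- 0
  M
}

#' Coevolutionary pattern similarity of one pair
#'
#' \eqn{CPS(J;K) = \frac{1}{|L|}\sum_{L \ne J,K} MI(J;L)\,MI(K;L)}: the
#' mean product of the two columns' MI profiles against third columns,
#' measuring how similarly J and K coevolve with the rest of the
#' alignment.
#'
#' @param table a data frame of raw MI values with columns `col1`,
#'   `col2`, `raw` covering all pairs needed (treated as symmetric).
#' @param j,k the pair's column indices.
#' @return the CPS value.
#' @export
cps <- function(table, j, k) {
  cols <- sort(unique(c(table$col1, table$col2)))
  Ls <- setdiff(cols, c(j, k))
  if (length(Ls) == 0L) mi_error("no_third_column", "no admissible third column")
  look <- function(a, b) {
    hit <- (table$col1 == a & table$col2 == b) | (table$col1 == b & table$col2 == a)
    if (!any(hit)) 0 else table$raw[which(hit)[1]]
  }
  mean(vapply(Ls, function(L) look(j, L) * look(k, L), 0))
}

#' MIc: MI corrected by normalised coevolutionary pattern similarity
#'
#' For each surviving inter-domain pair, \eqn{NCPS(J;K) =
#' CPS(J;K)/\sqrt{\overline{CPS}}} with the mean taken over the surviving
#' inter-domain pairs, and \eqn{MIc(J;K) = MI(J;K) - NCPS(J;K)}.  Raw MIc
#' may be negative.  Because the CPS sum runs over arbitrary third
#' columns L, the MI profile against both domains' columns is used by
#' default (`cps_l_scope = "all"`, with the divisor counting all eligible
#' columns minus two); `"opposite"` restricts L to the second domain's
#' eligible columns.
#'
#' @inheritParams mi_table
#' @param cps_l_scope `"all"` or `"opposite"`; see Details.
#' @return a `pair_score_table` with variant `"MIc"` (columns as
#'   [mi_table()] plus `mi`, `cps` and `ncps`).
#' @export
mic_table <- function(msa, mask = column_mask(msa),
                      cps_l_scope = c("all", "opposite")) {
  cps_l_scope <- match.arg(cps_l_scope)
  t0 <- mi_table(msa, mask)
  ec <- eligible_domain_cols(msa, mask)
  cols <- c(ec$e1, ec$e2)
  M <- mi_full_matrix(msa, cols)
  i <- match(as.character(t0$col1), colnames(M))
  j <- match(as.character(t0$col2), colnames(M))
  if (cps_l_scope == "all") {
    P <- M %*% M                       # diag(M)=0 drops L in {J, K}
    cpsv <- P[cbind(i, j)] / (length(cols) - 2L)
  } else {
    k2 <- match(as.character(ec$e2), colnames(M))
    M2 <- M[, k2, drop = FALSE]
    P <- M2 %*% t(M2)
    # exclude L = K (L = J is never in domain 2); M[K,K] = 0 already
    cpsv <- (P[cbind(i, j)] - M[cbind(i, j)] * 0) / (length(ec$e2) - 1L)
  }
  mean_cps <- mean(cpsv)
  if (mean_cps <= 0) mi_error("zero_mean", "mean inter-domain CPS is not positive")
  ncps <- cpsv / sqrt(mean_cps)
  df <- data.frame(col1 = t0$col1, col2 = t0$col2,
                   mi = t0$raw, cps = cpsv, ncps = ncps,
                   raw = t0$raw - ncps)
  df$z <- zscore(df$raw)
  new_score_table(df, "MIc", attr(t0, "alphabet"), attr(t0, "excluded"),
                  attr(t0, "n_eligible"))
}

#' Enumerate same-patch column triplets
#'
#' A triangle score couples a column J of one domain with a spatial patch
#' (K, L) of the other: the reference-structure residues of K and L must
#' lie strictly closer than `cutoff` angstroms (minimum inter-atomic
#' distance).  Both directions are enumerated when both domains'
#' intra-domain distances are available.
#'
#' @param msa a [paired_msa()] with domain residue ranges.
#' @param mask a [column_mask()].
#' @param distances a `distance_map` from [min_atom_distances()] (fields
#'   `intra1`, `intra2` used).
#' @param cutoff patch distance threshold in angstroms (default 4.5).
#' @return data frame of class `patch_triplets` with columns `col1` (J),
#'   `col2` (K), `col3` (L), `col2 < col3`; empty when no residue pair is
#'   close enough.
#' @export
patch_triplets <- function(msa, mask, distances, cutoff = 4.5) {
  map <- reference_mapping(msa)
  ec <- eligible_domain_cols(msa, mask)
  res2col <- function(res, dom) map$col[match(paste(dom, res), paste(map$domain, map$residue))]
  one_direction <- function(intra, patch_dom, j_cols) {
    if (is.null(intra) || nrow(intra) == 0L || length(j_cols) == 0L) return(NULL)
    close <- intra[intra$dist < cutoff, , drop = FALSE]
    if (nrow(close) == 0L) return(NULL)
    ck <- res2col(close$res1, patch_dom)
    cl <- res2col(close$res2, patch_dom)
    elig <- c(ec$e1, ec$e2)
    ok <- !is.na(ck) & !is.na(cl) & ck %in% elig & cl %in% elig
    if (!any(ok)) return(NULL)
    kk <- pmin(ck[ok], cl[ok]); ll <- pmax(ck[ok], cl[ok])
    data.frame(col1 = rep(j_cols, each = length(kk)),
               col2 = rep(kk, times = length(j_cols)),
               col3 = rep(ll, times = length(j_cols)))
  }
  out <- rbind(one_direction(distances$intra2, "D2", ec$e1),
               one_direction(distances$intra1, "D1", ec$e2))
  if (is.null(out))
    out <- data.frame(col1 = integer(), col2 = integer(), col3 = integer())
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("patch_triplets", "data.frame")
  out
}

#' Triangle mutual information of three columns
#'
#' The total correlation \eqn{\sum_{j,k,l} P(j,k,l)\log_e
#' \frac{P(j,k,l)}{P(j)P(k)P(l)} = H(J)+H(K)+H(L)-H(J,K,L)}; 0 for
#' mutually independent columns and \eqn{2\log_e k} for three identical
#' columns uniform over k states.
#'
#' @param x,y,z character vectors (three columns over the same rows).
#' @return raw MI3D in nats (clamped at 0).
#' @export
mi3d <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    mi_error("length_mismatch", "columns must pair the same sequence rows")
  enc <- encode_msa(rbind(x, y, z))
  # rows of enc$code are the three columns here
  S <- length(enc$symbols)
  v <- col_entropy_int(enc$code[1, ], S) + col_entropy_int(enc$code[2, ], S) +
    col_entropy_int(enc$code[3, ], S) -
    triple_entropy_int(enc$code[1, ], enc$code[2, ], enc$code[3, ], S)
  if (v < 1e-12) 0 else v
}

#' Raw and standardised MI3D over patch triplets
#'
#' Computes the triangle score for every (J, K, L) triple; triples with a
#' raw score of exactly 0 are excluded, and survivors are standardised to
#' z-scores over the alignment's own surviving triples.
#'
#' @inheritParams mi_table
#' @param triples a [patch_triplets()] table.
#' @return a `pair_score_table` with variant `"MI3D"` and columns `col1`
#'   (J), `col2` (K), `col3` (L), `raw`, `z`.
#' @export
mi3d_table <- function(msa, mask = column_mask(msa), triples) {
  if (nrow(triples) == 0L)
    mi_error("no_triples", "no same-patch column triplets to score")
  enc <- encode_msa(msa$seq)
  S <- length(enc$symbols)
  cols <- sort(unique(unlist(triples[c("col1", "col2", "col3")])))
  H <- vapply(cols, function(j) col_entropy_int(enc$code[, j], S), 0)
  names(H) <- as.character(cols)
  raw <- vapply(seq_len(nrow(triples)), function(r) {
    a <- enc$code[, triples$col1[r]]
    b <- enc$code[, triples$col2[r]]
    cc <- enc$code[, triples$col3[r]]
    v <- H[[as.character(triples$col1[r])]] + H[[as.character(triples$col2[r])]] +
      H[[as.character(triples$col3[r])]] - triple_entropy_int(a, b, cc, S)
    if (v < 1e-12) 0 else v
  }, 0)
  zero <- raw == 0
  excluded <- data.frame(triples[zero, , drop = FALSE],
                         reason = rep("zero_mi", sum(zero)))
  df <- data.frame(triples[!zero, , drop = FALSE], raw = raw[!zero])
  if (nrow(df) == 0L) mi_error("no_triples", "every triple has an MI3D of 0")
  df$z <- zscore(df$raw)
  new_score_table(df, "MI3D", msa$alphabet, excluded, n_eligible = length(cols))
}

#' MIp3D: triangle MI with the product-of-means correction
#'
#' \eqn{MIp3D(J;K;L) = MI3D(J;K;L) - APC3D(J;K;L)} with
#' \eqn{APC3D = \bar{MI3D}(J)\,\bar{MI3D}(K)\,\bar{MI3D}(L)/\bar{MI3D}},
#' where \eqn{\bar{MI3D}(c)} is the mean raw MI3D of surviving triples
#' containing column c and \eqn{\bar{MI3D}} the overall mean.  Zero-MI3D
#' triples are excluded before the means are computed; survivors are
#' standardised as usual.
#'
#' @inheritParams mi3d_table
#' @return a `pair_score_table` with variant `"MIp3D"` (columns as
#'   [mi3d_table()] plus `mi3d` and `apc3d`).
#' @export
mip3d_table <- function(msa, mask = column_mask(msa), triples) {
  t0 <- mi3d_table(msa, mask, triples)
  overall <- mean(t0$raw)
  if (overall == 0) mi_error("zero_mean", "overall mean MI3D is 0")
  colv <- c(t0$col1, t0$col2, t0$col3)
  mcol <- tapply(rep(t0$raw, 3L), colv, mean)
  apc3d <- mcol[as.character(t0$col1)] * mcol[as.character(t0$col2)] *
    mcol[as.character(t0$col3)] / overall
  df <- data.frame(col1 = t0$col1, col2 = t0$col2, col3 = t0$col3,
                   mi3d = t0$raw, apc3d = unname(apc3d),
                   raw = t0$raw - unname(apc3d))
  df$z <- zscore(df$raw)
  new_score_table(df, "MIp3D", attr(t0, "alphabet"), attr(t0, "excluded"),
                  attr(t0, "n_eligible"))
}

#' Standardise a vector of raw scores
#'
#' z-scores over the table's own surviving entries using the sample
#' (n-1) standard deviation; every score table in the package uses this
#' convention so that scores from different alignments are comparable.
#'
#' @param raw numeric vector of raw scores (length >= 2, non-constant).
#' @return numeric vector with mean 0 and sample sd 1.
#' @export
standardize_scores <- function(raw) zscore(raw)

#' Compute any score variant by name
#'
#' Dispatcher used by the evaluation pipeline: `"MI"`, `"MIp"`, `"MIc"`,
#' `"MI3D"`, `"MIp3D"`.  The triangle variants require a `distances`
#' map to enumerate patches (or an explicit `triples` table).
#'
#' @inheritParams mic_table
#' @param variant score variant name.
#' @param distances a `distance_map`, required for triangle variants.
#' @param triples optional precomputed [patch_triplets()].
#' @return a `pair_score_table`.
#' @export
score_table <- function(msa, variant = c("MI", "MIp", "MIc", "MI3D", "MIp3D"),
                        mask = column_mask(msa), distances = NULL,
                        triples = NULL, cps_l_scope = "all") {
  variant <- match.arg(variant)
  if (variant %in% c("MI3D", "MIp3D") && is.null(triples)) {
    if (is.null(distances))
      mi_error("missing_distances",
               sprintf("%s requires intra-domain distances to enumerate patches", variant))
    triples <- patch_triplets(msa, mask, distances)
  }
  switch(variant,
         MI = mi_table(msa, mask),
         MIp = mip_table(msa, mask),
         MIc = mic_table(msa, mask, cps_l_scope = cps_l_scope),
         MI3D = mi3d_table(msa, mask, triples),
         MIp3D = mip3d_table(msa, mask, triples))
}

#' Fraction of inter-domain pairs with an MI of 0
#'
#' Diagnostic for the zero-score exclusion rule: over all ungapped domain
#' column pairs (zero-entropy columns deliberately retained), the
#' fraction whose raw MI is exactly 0.  Pairing any column with a fully
#' conserved one yields MI 0, so this fraction grows roughly linearly
#' with the fraction of zero-entropy columns.
#'
#' @param msa a [paired_msa()].
#' @return list with `zero_mi_fraction`, `zero_entropy_fraction` (among
#'   ungapped domain columns) and `n_pairs`.
#' @export
zero_mi_fraction <- function(msa) {
  mask <- column_mask(msa)
  ok <- mask$reason %in% c("ok", "zero_entropy")
  c1 <- intersect(msa$domain1_cols, mask$col[ok])
  c2 <- intersect(msa$domain2_cols, mask$col[ok])
  if (length(c1) == 0L || length(c2) == 0L)
    mi_error("no_pairs", "no ungapped columns in one of the domains")
  enc <- encode_msa(msa$seq)
  M <- mi_pair_matrix(enc$code, length(enc$symbols), c1, c2)
  zent <- mask$reason[mask$col %in% c(c1, c2)] == "zero_entropy"
  list(zero_mi_fraction = mean(M == 0),
       zero_entropy_fraction = mean(zent),
       n_pairs = length(M))
}
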