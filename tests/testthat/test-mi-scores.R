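# MI, MIp, MIc, MI3D and MIp3D scores: closed-form cases, hand-worked
# corrections, brute-force oracle equivalence and the exclusion and
# standardisation rules.

test_that("pairwise MI matches closed forms and the plug-in oracle", {
  # perfectly covarying pair over 20 equiprobable states
  aa <- names(ra_alphabet())
  expect_equal(mi(aa, rev(aa)), log(20), tolerance = 1e-12)
  # product design: independent uniform pair
  expect_identical(mi(c("A", "A", "C", "C"), c("D", "E", "D", "E")), 0)
  # 4-row toy table, frozen from the explicit probability-table oracle
  xj <- c("A", "A", "A", "C"); xk <- c("D", "D", "E", "E")
  expect_equal(oracle_mi(xj, xk), 0.215761554338836, tolerance = 1e-12)
  expect_equal(mi(xj, xk), oracle_mi(xj, xk), tolerance = 1e-12)
  expect_equal(mi(xj, xk), mi(xk, xj), tolerance = 1e-12)
})

test_that("mi_table scores all eligible inter-domain pairs and excludes zero MI", {
  # column 2 against column 3 is an exact product factorisation (MI = 0);
  # the other three inter-domain pairs carry distinct positive MI
  m <- cbind(c("A", "A", "C", "C", "A", "C"),
             c("A", "C", "A", "C", "C", "C"),
             c("D", "D", "E", "E", "D", "E"),
             c("D", "E", "D", "E", "E", "D"))
  msa <- paired_msa(m, reference = 1, domain1_range = c(1, 2),
                    domain2_range = c(3, 4))
  want <- oracle_mi_pairs(msa, 1:2, 3:4)
  tab <- mi_table(msa)
  exc <- attr(tab, "excluded")
  expect_identical(paste(exc$col1, exc$col2), "2 3")
  expect_identical(unique(exc$reason), "zero_mi")
  expect_identical(paste(tab$col1, tab$col2) %in% paste(want$col1, want$col2),
                   rep(TRUE, nrow(tab)))
  expect_identical(nrow(tab), nrow(want))
  expect_true(all(tab$raw > 0))
  expect_equal(mean(tab$z), 0, tolerance = 1e-9)
  expect_equal(sd(tab$z), 1, tolerance = 1e-9)

  # a fully conserved domain leaves no scorable pair
  m2 <- m; m2[, 3] <- "D"; m2[, 4] <- "E"
  msa2 <- paired_msa(m2, reference = 1, domain1_range = c(1, 2),
                     domain2_range = c(3, 4))
  expect_error(mi_table(msa2), class = "micontact_no_pairs")
})

test_that("the average product correction reproduces hand arithmetic", {
  toy <- data.frame(col1 = c(1, 1, 2, 2), col2 = c(11, 12, 11, 12),
                    raw = c(0.4, 0.2, 0.2, 0.2))
  class(toy) <- c("pair_score_table", "data.frame")
  expect_equal(apc(toy, 1, 11), 0.3 * 0.3 / 0.25, tolerance = 1e-12)  # 0.36
  expect_equal(apc(toy, 1, 11), oracle_apc(toy, 1, 11), tolerance = 1e-12)
  # all-equal table: APC collapses to the common value, so raw MIp is 0
  const <- data.frame(col1 = c(1, 2), col2 = c(11, 12), raw = c(0.3, 0.3))
  expect_equal(apc(const, 1, 11), 0.3, tolerance = 1e-12)
  single <- data.frame(col1 = 1, col2 = 11, raw = 0.17)
  expect_equal(apc(single, 1, 11), 0.17, tolerance = 1e-12)
})

test_that("MIp equals MI minus APC, pair by pair, and never exceeds MI", {
  for (seed in 1:5) {
    msa <- random_small_msa(seed, n_seq = 12, n1 = 3, n2 = 3)
    tab <- mip_table(msa)
    for (r in seq_len(nrow(tab))) {
      expect_equal(tab$raw[r],
                   tab$mi[r] - oracle_apc(tab[c("col1", "col2", "mi")] |>
                                            setNames(c("col1", "col2", "raw")),
                                          tab$col1[r], tab$col2[r]),
                   tolerance = 1e-12)
      expect_lte(tab$raw[r], tab$mi[r] + 1e-12)  # APC >= 0
    }
    expect_equal(mean(tab$z), 0, tolerance = 1e-9)
  }
})

test_that("CPS matches direct summation and its closed forms", {
  # all pairwise MI equal to c: CPS = c^2
  cols <- c(1, 2, 11, 12)
  const <- expand.grid(col1 = cols, col2 = cols)
  const <- const[const$col1 < const$col2, ]
  const$raw <- 0.3
  expect_equal(cps(const, 1, 11), 0.09, tolerance = 1e-12)
  # hand-set 4-column table checked by explicit summation over L
  tab <- data.frame(col1 = c(1, 1, 2, 1, 2, 11),
                    col2 = c(2, 11, 11, 12, 12, 12),
                    raw = c(0.1, 0.4, 0.3, 0.2, 0.5, 0.6))
  # pair (1, 11), L in {2, 12}: MI(1,2) MI(11,2) + MI(1,12) MI(11,12)
  by_hand <- (0.1 * 0.3 + 0.2 * 0.6) / 2
  expect_equal(cps(tab, 1, 11), by_hand, tolerance = 1e-12)
  # a column with all-zero MI profile forces CPS to 0
  tab$raw[tab$col1 == 1] <- 0
  expect_equal(cps(tab, 1, 11), 0, tolerance = 1e-12)
})

test_that("MIc pairs MI with the normalised pattern-similarity correction", {
  for (seed in 1:5) {
    msa <- random_small_msa(seed, n_seq = 12, n1 = 3, n2 = 3)
    mask <- column_mask(msa)
    tab <- mic_table(msa, mask)
    elig <- mask$col[mask$eligible]
    cpsv <- vapply(seq_len(nrow(tab)),
                   function(r) oracle_cps(msa, elig, tab$col1[r], tab$col2[r]), 0)
    expect_equal(tab$cps, cpsv, tolerance = 1e-12)
    expect_equal(tab$ncps, cpsv / sqrt(mean(cpsv)), tolerance = 1e-12)
    expect_equal(tab$raw, tab$mi - tab$ncps, tolerance = 1e-12)
    expect_equal(mean(tab$z), 0, tolerance = 1e-9)
  }
  # raw MIc may legitimately be negative
  found_negative <- any(vapply(1:10, function(s) {
    any(mic_table(random_small_msa(s, n_seq = 10, n1 = 3, n2 = 3))$raw < 0)
  }, TRUE))
  expect_true(found_negative)
})

test_that("the opposite-domain CPS scope restricts the third column", {
  msa <- random_small_msa(3, n_seq = 12, n1 = 3, n2 = 3)
  mask <- column_mask(msa)
  tab <- mic_table(msa, mask, cps_l_scope = "opposite")
  e2 <- intersect(msa$domain2_cols, mask$col[mask$eligible])
  for (r in seq_len(min(nrow(tab), 4))) {
    Ls <- setdiff(e2, tab$col2[r])
    by_hand <- mean(vapply(Ls, function(L)
      oracle_mi(msa$seq[, tab$col1[r]], msa$seq[, L]) *
        oracle_mi(msa$seq[, tab$col2[r]], msa$seq[, L]), 0))
    expect_equal(tab$cps[r], by_hand, tolerance = 1e-12)
  }
})

test_that("triangle MI matches closed forms and the triple-loop oracle", {
  # mutually independent uniform triple: all 8 combinations equifrequent
  g <- expand.grid(a = c("A", "C"), b = c("D", "E"), c = c("F", "G"),
                   stringsAsFactors = FALSE)
  expect_identical(mi3d(g$a, g$b, g$c), 0)
  # three perfectly covarying columns over k equiprobable states
  x <- c("A", "C", "D", "E")
  expect_equal(mi3d(x, x, x), 2 * log(4), tolerance = 1e-12)
  # 6-row partially coupled toy against the brute-force oracle
  a <- c("A", "A", "C", "C", "A", "C")
  b <- c("D", "D", "E", "E", "E", "D")
  cc <- c("F", "G", "F", "G", "G", "G")
  expect_equal(mi3d(a, b, cc), oracle_mi3d(a, b, cc), tolerance = 1e-12)
})

test_that("patch triplets honour the strict 4.5 angstrom same-patch rule", {
  spec <- synthetic_spec(n_sequences = 40, len1 = 4, len2 = 6,
                         coupled_triples = data.frame(col1 = 2, col2 = 6,
                                                      col3 = 7, coupling = 0.9),
                         seed = 2)
  msa <- generate_msa(spec)
  ga <- generate_annotations(spec, msa)
  mask <- column_mask(msa)
  tr <- patch_triplets(msa, mask, ga$distances)
  # one close domain-2 pair and |eligible D1| J columns
  e1 <- sum(mask$eligible[msa$domain1_cols])
  expect_identical(nrow(tr), e1)
  expect_true(all(tr$col2 == 6 & tr$col3 == 7))
  expect_true(all(tr$col2 < tr$col3))

  # distance exactly at the cutoff is excluded; strictly inside is kept
  coords <- data.frame(resno = c(1, 5, 6), domain = c("D1", "D2", "D2"),
                       elety = "CA",
                       x = c(0, 0, 4.5), y = c(0, 1000, 1000), z = 0)
  dm <- min_atom_distances(coords)
  expect_identical(nrow(patch_triplets(msa, mask, dm)), 0L)
  coords$x[3] <- 4.4999
  expect_gt(nrow(patch_triplets(msa, mask, min_atom_distances(coords))), 0L)
})

test_that("MIp3D applies the product-of-means correction over survivors", {
  # small alphabet keeps the finite-sample MI3D bias far below the
  # planted three-body signal, so the correction cannot drown it
  spec <- synthetic_spec(n_sequences = 300, len1 = 6, len2 = 10,
                         alphabet_size = 4,
                         coupled_triples = data.frame(col1 = 2, col2 = 8,
                                                      col3 = 9, coupling = 0.9),
                         patch_pairs = data.frame(res1 = c(2, 5, 7),
                                                  res2 = c(3, 6, 8)),
                         seed = 9)
  msa <- generate_msa(spec)
  ga <- generate_annotations(spec, msa)
  mask <- column_mask(msa)
  tr <- patch_triplets(msa, mask, ga$distances)
  t3 <- mi3d_table(msa, mask, tr)
  tp <- mip3d_table(msa, mask, tr)
  overall <- mean(t3$raw)
  for (r in seq_len(nrow(tp))) {
    mean_of <- function(col) mean(t3$raw[t3$col1 == col | t3$col2 == col | t3$col3 == col])
    expect_equal(tp$apc3d[r],
                 mean_of(tp$col1[r]) * mean_of(tp$col2[r]) * mean_of(tp$col3[r]) / overall,
                 tolerance = 1e-12)
    expect_equal(tp$raw[r], tp$mi3d[r] - tp$apc3d[r], tolerance = 1e-12)
  }
  # planted coupled triple ranks first by standardised MIp3D (and MI3D)
  expect_identical(unlist(tp[which.max(tp$z), c("col1", "col2", "col3")],
                          use.names = FALSE), c(2L, 8L, 9L))
  expect_identical(unlist(t3[which.max(t3$z), c("col1", "col2", "col3")],
                          use.names = FALSE), c(2L, 8L, 9L))
})

test_that("standardisation is affine-invariant and refuses constants", {
  x <- c(0.2, 0.9, 1.7, 0.4)
  expect_equal(standardize_scores(3 * x + 5), standardize_scores(x),
               tolerance = 1e-12)
  expect_error(standardize_scores(rep(0.3, 4)),
               class = "micontact_degenerate_standardisation")
})

test_that("reduced-alphabet scores equal full scoring of the merged symbols", {
  for (seed in 1:3) {
    msa <- random_small_msa(seed, n_seq = 12, n1 = 3, n2 = 3,
                            alphabet = c("S", "G", "K", "R", "E", "W", "Q"))
    map <- ra_alphabet()
    merged <- msa
    merged$seq[] <- unname(map[merged$seq])
    t_ra <- mi_table(reduce_alphabet(msa))
    t_merged <- mi_table(merged)
    expect_equal(t_ra$raw, t_merged$raw, tolerance = 1e-12)
    expect_lte(max(t_ra$raw), log(7) + 1e-12)
  }
})

test_that("planted-pair rank improves monotonically with coupling strength", {
  ranks <- vapply(c(0.2, 0.5, 0.9), function(coup) {
    spec <- synthetic_spec(n_sequences = 300, len1 = 10, len2 = 10,
                           coupled_pairs = data.frame(col1 = 3, col2 = 15,
                                                      coupling = coup),
                           seed = 77)
    tab <- mi_table(generate_msa(spec))
    rank(-tab$raw)[which(tab$col1 == 3 & tab$col2 == 15)]
  }, 0)
  expect_true(all(diff(ranks) <= 0))
  expect_identical(ranks[3], 1)
})

test_that("zero-MI diagnostics count product-design and conserved pairings", {
  spec <- synthetic_spec(n_sequences = 100, len1 = 6, len2 = 6,
                         conserved_cols = c(2, 9), seed = 4)
  msa <- generate_msa(spec)
  zf <- zero_mi_fraction(msa)
  # every pair involving a conserved column has MI exactly 0
  expect_gte(zf$zero_mi_fraction, (6 + 6 - 1) / 36)
  expect_equal(zf$zero_entropy_fraction, 2 / 12, tolerance = 1e-12)
})
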