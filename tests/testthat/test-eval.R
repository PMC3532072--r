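# Residue aggregation, precision-recall and MCC evaluation, subsampling
# stability and the binomial top-k test.

test_that("residue scores aggregate surviving entries by max or mean", {
  tab <- data.frame(col1 = c(1, 1, 1), col2 = c(11, 12, 13),
                    z = c(0.2, 1.5, -0.3), raw = 1)
  attr(tab, "variant") <- "MI"
  class(tab) <- c("pair_score_table", "data.frame")
  ann <- data.frame(residue = c(1, 30), domain = "D1", column = c(1, 30),
                    surface = TRUE, contact = FALSE)
  rs_max <- suppressMessages(residue_scores(tab, ann, "max"))
  expect_equal(rs_max$score, 1.5, tolerance = 1e-12)
  rs_mean <- suppressMessages(residue_scores(tab, ann, "mean"))
  expect_equal(rs_mean$score, mean(c(0.2, 1.5, -0.3)), tolerance = 1e-12)
  # the unscored residue (column 30 survives nowhere) is dropped
  expect_identical(nrow(rs_max), 1L)
  expect_message(residue_scores(tab, ann), "dropping 1 residue")
})

test_that("triplet tables aggregate over all three slots", {
  tab <- data.frame(col1 = c(1, 2), col2 = c(11, 11), col3 = c(12, 13),
                    z = c(2, -1), raw = 1)
  class(tab) <- c("pair_score_table", "data.frame")
  ann <- data.frame(residue = c(11, 13), domain = "D2", column = c(11, 13),
                    surface = TRUE, contact = FALSE)
  rs <- residue_scores(tab, ann, "max")
  expect_equal(rs$score, c(2, -1), tolerance = 1e-12)  # col 11 in slot 2 twice
})

test_that("P-ROC curves honour the percentile-cutoff convention", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  pc <- proc_curve(scores, labels)
  expect_equal(attr(pc, "baseline"), 0.4, tolerance = 1e-12)
  # perfect separation: precision 1 wherever recall < 1
  expect_true(all(pc$precision[pc$recall < 1] == 1))
  # all-inclusive cutoff: precision = prevalence, recall = 1
  expect_equal(pc$precision[pc$percentile == 0], 0.4, tolerance = 1e-12)
  expect_equal(pc$recall[pc$percentile == 0], 1, tolerance = 1e-12)
  # recall is non-increasing in the cutoff percentile
  expect_true(all(diff(pc$recall) <= 1e-12))

  # identical scores: every cutoff keeps everything
  pc2 <- proc_curve(rep(1, 6), c(TRUE, rep(FALSE, 5)))
  expect_true(all(abs(pc2$precision - 1 / 6) < 1e-12))
  expect_true(all(pc2$recall == 1))

  expect_error(proc_curve(scores, rep(TRUE, 5)), class = "micontact_single_class")
})

test_that("prevalence reproduces printed baselines", {
  expect_equal(round(prevalence(1342, 5483), 3), 0.245)
  expect_equal(round(prevalence(1306, 5362), 3), 0.244)
  expect_error(prevalence(10, 0), class = "micontact_bad_counts")
})

test_that("precision at target recall uses the conservative step rule", {
  curve <- data.frame(percentile = 1:3, recall = c(1, 0.25, 0.1),
                      precision = c(0.24, 0.6, 0.9))
  expect_equal(precision_at_recall(curve, 0.2), 0.6, tolerance = 1e-12)
  expect_equal(precision_at_recall(curve, 1.0), 0.24, tolerance = 1e-12)
  expect_error(precision_at_recall(curve[curve$recall < 0.2, ], 0.5),
               class = "micontact_recall_unreachable")

  # random scores score close to the prevalence baseline on average
  set.seed(42)
  prec <- replicate(100, {
    s <- rnorm(200)
    l <- rep(c(TRUE, FALSE), each = 100)
    precision_at_recall(proc_curve(s, l), 0.2)
  })
  expect_lt(abs(mean(prec) - 0.5), 3 * sd(prec) / sqrt(100))
})

test_that("MCC reaches the closed-form extremes and equals binary correlation", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  mc <- mcc_curve(scores, labels)
  expect_equal(max(mc$mcc), 1, tolerance = 1e-12)
  mc_inv <- mcc_curve(-scores, labels)
  expect_equal(min(mc_inv$mcc), -1, tolerance = 1e-12)

  set.seed(7)
  s <- rnorm(120)
  l <- s + rnorm(120) > 0
  mc2 <- mcc_curve(s, l)
  for (pct in c(10, 50, 90)) {
    ct <- mc2$cutoff[mc2$percentile == pct]
    expect_equal(mc2$mcc[mc2$percentile == pct],
                 suppressWarnings(cor(as.numeric(s >= ct), as.numeric(l))),
                 tolerance = 1e-12)
  }
  # random labels: MCC stays near zero
  set.seed(8)
  mc3 <- mcc_curve(rnorm(2000), sample(c(TRUE, FALSE), 2000, TRUE))
  expect_lt(max(abs(mc3$mcc)), 0.15)
})

test_that("binomial top-k agrees with the exhaustive tail sum", {
  pool <- make_pool(46, 9, k = 9, hits = 3)
  res <- binomial_topk(pool, 9)
  expect_equal(res$p_value, oracle_upper_binom(3, 9, 9 / 46), tolerance = 1e-9)
  expect_equal(res$expected, 9 * 9 / 46, tolerance = 1e-12)
  expect_identical(res$hits, 3L)

  for (case in list(c(20, 5, 4, 2), c(30, 10, 6, 6), c(12, 3, 5, 0))) {
    pool <- make_pool(case[1], case[2], case[3], case[4])
    res <- binomial_topk(pool, case[3])
    expect_equal(res$p_value,
                 oracle_upper_binom(case[4], case[3], case[2] / case[1]),
                 tolerance = 1e-9)
  }
  expect_error(binomial_topk(make_pool(10, 2, 3, 1), 0), class = "micontact_bad_k")
})

test_that("top-k score ties expand k with a warning, or truncate by column", {
  pool <- make_pool(10, 4, k = 3, hits = 2)
  pool$score[3:5] <- 7           # tie spanning the k-th rank
  expect_warning(res <- binomial_topk(pool, 3), "tied")
  expect_identical(res$k, 5L)
  res2 <- binomial_topk(pool, 3, ties = "truncate")
  expect_identical(res2$k, 3L)
  # truncation is deterministic: lowest column indices win the tie
  expect_identical(res2$hits, 2L)
})

test_that("stability runs produce the promised replicate structure", {
  spec <- synthetic_spec(n_sequences = 210, len1 = 8, len2 = 8,
                         coupled_pairs = data.frame(col1 = c(2, 5), col2 = c(11, 14),
                                                    coupling = 0.9),
                         seed = 31)
  msa <- generate_msa(spec)
  ga <- generate_annotations(spec, msa)
  st <- stability_run(msa, ga$annotations, "MI", n_reps = 5, seed = 3)
  expect_length(st$precisions, 5)
  expect_equal(st$mean, mean(st$precisions), tolerance = 1e-12)
  expect_equal(st$sd, sd(st$precisions), tolerance = 1e-12)
  expect_equal(st$se, st$sd / sqrt(5), tolerance = 1e-12)
  # bit-identical under the same master seed
  st2 <- stability_run(msa, ga$annotations, "MI", n_reps = 5, seed = 3)
  expect_identical(st$precisions, st2$precisions)

  small <- generate_msa(synthetic_spec(n_sequences = 50, len1 = 8, len2 = 8, seed = 1))
  expect_error(stability_run(small, ga$annotations, "MI", n_reps = 2, seed = 1),
               class = "micontact_too_few_sequences")
})

test_that("strong and weak coupling stay separated across subsample replicates", {
  build <- function(coup, seed) {
    spec <- synthetic_spec(n_sequences = 210, len1 = 30, len2 = 30,
                           coupled_pairs = data.frame(col1 = seq(2, 29, 3),
                                                      col2 = seq(32, 59, 3),
                                                      coupling = coup),
                           seed = seed)
    msa <- generate_msa(spec)
    list(msa = msa, ann = generate_annotations(spec, msa)$annotations)
  }
  strong <- build(0.95, 13)
  weak <- build(0, 13)
  st_s <- stability_run(strong$msa, strong$ann, "MI", n_reps = 8, seed = 5)
  st_w <- stability_run(weak$msa, weak$ann, "MI", n_reps = 8, seed = 5)
  gap <- st_s$mean - st_w$mean
  expect_gt(gap, 0)
  expect_gt(gap, 2 * max(st_s$sd, st_w$sd))
  tt <- compare_stability(st_s, st_w)
  expect_lt(tt$p.value, 0.01)
})

test_that("null-coupling hit counts follow the binomial model", {
  k <- 5
  hits <- vapply(1:400, function(s) {
    spec <- synthetic_spec(n_sequences = 60, len1 = 8, len2 = 80,
                           surface_fraction = 1,
                           contact_pairs = data.frame(res1 = rep(1:4, 4),
                                                      res2 = 1:16),
                           seed = s)
    msa <- generate_msa(spec)
    tab <- mi_table(msa)
    ga <- generate_annotations(spec, msa)
    rs <- suppressMessages(residue_scores(tab, ga$annotations))
    pool <- rs[rs$domain == "D2", , drop = FALSE]
    sum(pool$contact[order(-pool$score, pool$column)][seq_len(k)])
  }, 0)
  p0 <- 16 / 80
  expected <- 400 * dbinom(0:k, k, p0)
  grp <- pmin(hits, 3)                    # pool sparse upper tail
  obs <- tabulate(grp + 1L, 4)
  exp_grp <- c(expected[1:3], sum(expected[4:6]))
  chisq <- sum((obs - exp_grp)^2 / exp_grp)
  expect_lt(chisq, qchisq(0.99, df = 3))
})
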