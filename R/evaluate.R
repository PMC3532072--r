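# Residue-level scoring and classifier evaluation: precision-recall over
# percentile cutoffs, MCC, subsampling stability and the binomial top-k
# enrichment test.

#' Aggregate column-pair scores to residues
#'
#' Each annotated residue receives the maximum (default) or mean
#' standardised score over all surviving pairs or triples in which its
#' alignment column appears, in any slot.  Maximum aggregation is the
#' default because averaging was found to weaken contact prediction.
#' Residues whose column survives in no entry (for instance because the
#' column is gapped or has zero entropy) are dropped with a message.
#'
#' @param table a `pair_score_table`.
#' @param annotations annotations with a `column` field, as from
#'   [annotate_columns()].
#' @param aggregate `"max"` or `"mean"`.
#' @return data frame of class `residue_scores`: annotations plus
#'   `score`, with attributes `variant` and `aggregate`.
#' @export
residue_scores <- function(table, annotations, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(table) == 0L) mi_error("empty_table", "score table has no surviving entries")
  slot_cols <- intersect(c("col1", "col2", "col3"), names(table))
  long_col <- unlist(table[slot_cols], use.names = FALSE)
  long_z <- rep(table$z, length(slot_cols))
  agg <- tapply(long_z, long_col, if (aggregate == "max") max else mean)
  sc <- agg[as.character(annotations$column)]
  drop <- is.na(sc)
  if (any(drop))
    message(sprintf("dropping %d residue(s) whose columns survive in no scored entry",
                    sum(drop)))
  out <- annotations[!drop, , drop = FALSE]
  out$score <- as.vector(sc[!drop])
  structure(out, variant = attr(table, "variant"),
            aggregate = aggregate,
            class = c("residue_scores", "data.frame"))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    mi_error("single_class", "need at least one positive and one negative")
}

confusion_at <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  c(tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

#' Precision-recall curve over percentile cutoffs
#'
#' Score percentiles serve as classification cutoffs (predict positive
#' when score >= cutoff); the default grid runs from the all-inclusive
#' 0th to the 100th percentile in steps of one.  At the all-inclusive
#' cutoff precision equals the positive prevalence (the baseline) and
#' recall is 1.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical vector, `TRUE` for positives.
#' @param percentiles percentile grid (default `0:100`).
#' @return data frame of class `proc_curve` with `percentile`, `cutoff`,
#'   `precision`, `recall`, and attributes `baseline`, `positives`,
#'   `total`.
#' @export
proc_curve <- function(scores, labels, percentiles = 0:100) {
  if (length(scores) != length(labels))
    mi_error("length_mismatch", "scores and labels differ in length")
  check_two_classes(labels)
  cutoffs <- stats::quantile(scores, percentiles / 100, names = FALSE, type = 7)
  pts <- t(vapply(cutoffs, function(ct) {
    cf <- confusion_at(scores, labels, ct)
    c(precision = unname(cf["tp"] / (cf["tp"] + cf["fp"])),
      recall = unname(cf["tp"] / (cf["tp"] + cf["fn"])))
  }, c(precision = 0, recall = 0)))
  out <- data.frame(percentile = percentiles, cutoff = cutoffs,
                    precision = pts[, "precision"], recall = pts[, "recall"])
  structure(out, baseline = mean(labels), positives = sum(labels),
            total = length(labels),
            class = c("proc_curve", "data.frame"))
}

#' Positive prevalence baseline
#'
#' The precision of a random classifier: positives / total.  This is the
#' flat baseline drawn on precision-recall plots.
#'
#' @param positives,total counts.
#' @return the prevalence.
#' @examples
#' prevalence(1342, 5483)  # ~0.245
#' @export
prevalence <- function(positives, total) {
  if (total <= 0 || positives < 0 || positives > total)
    mi_error("bad_counts", "need 0 <= positives <= total, total > 0")
  positives / total
}

#' Precision at a target recall
#'
#' Returns the precision at the highest (most stringent) percentile
#' cutoff whose recall still reaches the target; no interpolation is
#' performed, so the value is reproducible from the curve points alone.
#'
#' @param curve a [proc_curve()].
#' @param target_recall required recall in (0, 1].
#' @return precision at that operating point.
#' @export
precision_at_recall <- function(curve, target_recall = 0.2) {
  ok <- which(curve$recall >= target_recall)
  if (length(ok) == 0L)
    mi_error("recall_unreachable", "no cutoff reaches the target recall")
  curve$precision[ok[which.max(curve$percentile[ok])]]
}

#' Matthews correlation coefficient over percentile cutoffs
#'
#' \eqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} at
#' each percentile cutoff; defined as 0 when any factor of the
#' denominator vanishes.  +1 is perfect prediction, -1 total
#' disagreement.
#'
#' @inheritParams proc_curve
#' @return data frame of class `mcc_curve` with `percentile`, `cutoff`,
#'   `mcc`.
#' @export
mcc_curve <- function(scores, labels, percentiles = 0:100) {
  check_two_classes(labels)
  cutoffs <- stats::quantile(scores, percentiles / 100, names = FALSE, type = 7)
  mcc <- vapply(cutoffs, function(ct) {
    cf <- as.numeric(confusion_at(scores, labels, ct))  # tp fp fn tn
    den <- (cf[1] + cf[2]) * (cf[1] + cf[3]) * (cf[4] + cf[2]) * (cf[4] + cf[3])
    if (den == 0) 0 else (cf[1] * cf[4] - cf[2] * cf[3]) / sqrt(den)
  }, 0)
  structure(data.frame(percentile = percentiles, cutoff = cutoffs, mcc = mcc),
            class = c("mcc_curve", "data.frame"))
}

#' Subsampling stability of a score variant
#'
#' Repeatedly subsamples a fraction of the alignment's sequences,
#' recomputes the variant scores and the contact-versus-non-contact
#' precision at the target recall (surface residues only), and reports
#' the replicate precisions with their mean, sample standard deviation
#' and standard error.  By default the analysis is gated to alignments
#' with at least 200 sequences so that 70-percent subsamples keep at
#' least about 125 sequences, below which MI becomes noisy.
#'
#' @param msa a [paired_msa()].
#' @param annotations column-annotated residues ([annotate_columns()]).
#' @param variant score variant name (see [score_table()]).
#' @param fraction subsample fraction (default 0.7).
#' @param n_reps number of replicates (default 100).
#' @param seed master seed; replicate seeds are derived from it.
#' @param target_recall recall at which precision is read off (default 0.2).
#' @param min_sequences gate on alignment depth (default 200); set
#'   `enforce_min = FALSE` to override.
#' @param enforce_min logical.
#' @param distances,cps_l_scope passed to [score_table()].
#' @param aggregate residue aggregation rule.
#' @return object of class `stability_result`: list with `variant`,
#'   `precisions`, `mean`, `sd`, `se`.
#' @export
stability_run <- function(msa, annotations, variant = "MI", fraction = 0.7,
                          n_reps = 100, seed = 1, target_recall = 0.2,
                          min_sequences = 200, enforce_min = TRUE,
                          distances = NULL, cps_l_scope = "all",
                          aggregate = "max") {
  if (enforce_min && nrow(msa$seq) < min_sequences)
    mi_error("too_few_sequences",
             sprintf("stability analysis requires >= %d sequences (got %d); set enforce_min = FALSE to override",
                     min_sequences, nrow(msa$seq)))
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))
  prec <- vapply(rep_seeds, function(s) {
    sub <- subsample_msa(msa, fraction, seed = s)
    tab <- score_table(sub, variant, mask = column_mask(sub),
                       distances = distances, cps_l_scope = cps_l_scope)
    rs <- suppressMessages(residue_scores(tab, annotations, aggregate = aggregate))
    rs <- rs[rs$surface, , drop = FALSE]
    precision_at_recall(proc_curve(rs$score, rs$contact), target_recall)
  }, 0)
  structure(list(variant = variant, precisions = prec,
                 mean = mean(prec), sd = stats::sd(prec),
                 se = stats::sd(prec) / sqrt(n_reps)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("%s precision over %d subsample replicates: mean %.3f, sd %.3f (se %.4f)\n",
              x$variant, length(x$precisions), x$mean, x$sd, x$se))
  invisible(x)
}

#' Binomial test on the top-k predictions
#'
#' With no relation between scores and contacts, the number of contacts
#' among the k top-scored candidates follows Binomial(k, p) with p the
#' contact fraction of the candidate pool.  The p-value is the upper
#' tail P(X >= hits).  Score ties at the k-th rank are included by
#' default (enlarging k, with a warning); `ties = "truncate"` breaks
#' them deterministically by column order instead.
#'
#' @param scored a `residue_scores` data frame restricted to the
#'   candidate pool (must carry `score` and logical `contact`).
#' @param k number of top predictions to assess.
#' @param ties `"expand"` or `"truncate"`.
#' @return object of class `topk_test`: list with `k` (effective),
#'   `hits`, `n_candidates`, `n_positives`, `expected`, `p_value`.
#' @export
binomial_topk <- function(scored, k, ties = c("expand", "truncate")) {
  ties <- match.arg(ties)
  if (nrow(scored) == 0L) mi_error("empty_table", "empty candidate pool")
  if (k <= 0 || k > nrow(scored))
    mi_error("bad_k", "k must be in 1..number of candidates")
  ord <- order(-scored$score, scored$column)
  kth <- scored$score[ord[k]]
  if (ties == "expand") {
    top <- which(scored$score >= kth)
    if (length(top) > k)
      warning(sprintf("%d candidates tied at the k-th score; k enlarged to %d",
                      length(top) - k + sum(scored$score[top] == kth), length(top)))
  } else {
    top <- ord[seq_len(k)]
  }
  k_eff <- length(top)
  hits <- sum(scored$contact[top])
  p0 <- sum(scored$contact) / nrow(scored)
  structure(list(k = k_eff, hits = hits,
                 n_candidates = nrow(scored), n_positives = sum(scored$contact),
                 expected = k_eff * p0,
                 p_value = stats::pbinom(hits - 1, k_eff, p0, lower.tail = FALSE)),
            class = "topk_test")
}

#' @export
print.topk_test <- function(x, ...) {
  cat(sprintf("top-%d test: %d/%d contacts among predictions (pool %d/%d); expected %.2f, upper-tail p = %.4g\n",
              x$k, x$hits, x$k, x$n_positives, x$n_candidates,
              x$expected, x$p_value))
  invisible(x)
}

#' Convenience two-sample t-test between variant stability runs
#'
#' Thin wrapper over [stats::t.test()] comparing the replicate precision
#' vectors of two [stability_run()] results.
#'
#' @param a,b `stability_result` objects.
#' @return the `htest` object.
#' @export
compare_stability <- function(a, b) {
  stats::t.test(a$precisions, b$precisions)
}
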