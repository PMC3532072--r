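# Column and joint Shannon entropies (natural log) and the per-MSA
# standardisation applied to them.

#' Shannon entropy of an alignment column
#'
#' Plug-in entropy \eqn{H(J) = -\sum_j p_j \log_e p_j} of the empirical
#' symbol distribution, with \eqn{0 \log 0 := 0}.  Natural logarithms are
#' used throughout the package so that scores are comparable with other
#' mutual-information studies; a column uniform over the 20 amino acids
#' attains the maximum \eqn{\log_e 20 \approx 2.9957}.
#'
#' @param x a character vector of symbols (one alignment column), or a
#'   numeric vector of symbol counts.
#' @return entropy in nats.
#' @examples
#' column_entropy(rep(c("A", "C"), each = 2))  # log(2)
#' @export
column_entropy <- function(x) {
  if (is.numeric(x)) return(entropy_from_counts(x))
  if (length(x) == 0L) mi_error("empty_column", "empty column")
  entropy_from_counts(table(x))
}

#' Entropies of every column of an alignment
#'
#' @param msa a [paired_msa()].
#' @return numeric vector of per-column entropies (nats).
#' @export
column_entropies <- function(msa) {
  enc <- encode_msa(msa$seq)
  S <- length(enc$symbols)
  apply(enc$code, 2, col_entropy_int, nsym = S)
}

#' Joint entropy of two columns
#'
#' Entropy of the empirical joint distribution of row-paired symbols,
#' \eqn{H(J;K) = -\sum_{j,k} p_{jk} \log_e p_{jk}}.
#'
#' @param x,y character vectors of equal length (two columns over the
#'   same sequence rows).
#' @return joint entropy in nats.
#' @export
joint_entropy <- function(x, y) {
  if (length(x) != length(y))
    mi_error("length_mismatch", "columns must pair the same sequence rows")
  if (length(x) == 0L) mi_error("empty_column", "empty column")
  entropy_from_counts(table(paste(x, y, sep = "\r")))
}

#' Standardise column entropies over an alignment
#'
#' Converts raw entropies to z-scores using the mean and sample standard
#' deviation computed over all eligible columns of the MSA combined, so
#' that entropies from different alignments are comparable.  Ineligible
#' columns (gapped, zero-entropy, outside the domains) do not contribute
#' to the moments and receive `NA`.
#'
#' @param raw numeric vector of per-column entropies (as from
#'   [column_entropies()]).
#' @param mask a [column_mask()] for the same alignment.
#' @return object of class `entropy_profile`: a list with `raw`,
#'   `standardized`, `mean` and `sd`.
#' @export
standardize_entropies <- function(raw, mask) {
  if (length(raw) != nrow(mask))
    mi_error("length_mismatch", "entropy vector and mask cover different columns")
  el <- mask$eligible
  z <- rep(NA_real_, length(raw))
  z[el] <- zscore(raw[el])
  structure(list(raw = raw, standardized = z,
                 mean = mean(raw[el]), sd = stats::sd(raw[el])),
            class = "entropy_profile")
}

#' Export an entropy profile as a table
#'
#' @param x an `entropy_profile`.
#' @param mask the [column_mask()] used to build it.
#' @param file optional TSV path; when given the table is also written.
#' @return data frame with column index, domain, eligibility reason, raw
#'   and standardised entropy.
#' @export
entropy_table <- function(x, mask, file = NULL) {
  out <- data.frame(col = mask$col, domain = mask$domain,
                    reason = mask$reason,
                    raw = x$raw, standardized = x$standardized,
                    stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
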