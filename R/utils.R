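# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

# Raise a condition with a package-specific class so callers can
# distinguish failure modes programmatically.
mi_error <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("micontact_", class), "micontact_error")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Integer-encode a character matrix of residues over its observed symbols.
encode_msa <- function(seqmat) {
  syms <- sort(unique(as.vector(seqmat)))
  list(code = matrix(match(seqmat, syms), nrow = nrow(seqmat)),
       symbols = syms)
}

# Shannon entropy (nats) from a vector of non-negative counts; 0 log 0 := 0.
entropy_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) mi_error("empty_column", "cannot compute entropy of an empty column")
  p <- counts / n
  -sum(p * log(p))
}

# Entropies of integer-coded columns.
col_entropy_int <- function(a, nsym) entropy_from_counts(tabulate(a, nsym))

joint_entropy_int <- function(a, b, nsym) {
  entropy_from_counts(tabulate((a - 1L) * nsym + b, nsym * nsym))
}

triple_entropy_int <- function(a, b, c, nsym) {
  entropy_from_counts(tabulate(((a - 1L) * nsym + (b - 1L)) * nsym + c,
                               nsym * nsym * nsym))
}

# Sample (n-1 denominator) z-scores used for every per-MSA standardisation.
zscore <- function(x) {
  if (length(x) < 2L)
    mi_error("degenerate_standardisation",
             "need at least two values to standardise")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    mi_error("degenerate_standardisation",
             "cannot standardise values with zero standard deviation")
  (x - mean(x)) / s
}
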