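# Paired-domain multiple sequence alignments: construction, I/O,
# sanitisation, alphabet reduction, masking and subsampling.

#' Construct a paired-domain MSA
#'
#' A `paired_msa` holds an alignment of a two-domain protein together with
#' the identity of the reference-structure sequence and the alignment
#' columns belonging to each domain.  All coevolution scores in this
#' package operate on this container.
#'
#' @param sequences character vector of equal-length aligned sequences
#'   (or a character matrix with one residue per cell).  Names, when
#'   present, are kept as sequence identifiers.
#' @param reference integer row index of the reference-structure sequence.
#' @param domain1_cols,domain2_cols integer vectors of alignment columns
#'   (1-based) covering the two domains on the reference sequence; must be
#'   disjoint.
#' @param domain1_range,domain2_range the residue-number intervals
#'   (1-based, inclusive, on the ungapped reference sequence) that the
#'   column sets represent.  Used to map structure residue numbers onto
#'   columns.
#' @param id free-text label for the alignment.
#' @return an object of class `paired_msa` with fields `seq` (character
#'   matrix), `ids`, `reference`, `domain1_cols`, `domain2_cols`,
#'   `domain1_range`, `domain2_range`, `alphabet` and `id`.
#' @examples
#' msa <- paired_msa(c(ref = "ACDEFG", s2 = "ACDEFG", s3 = "ATDEYG"),
#'                   reference = 1, domain1_range = c(1, 3),
#'                   domain2_range = c(4, 6))
#' dim(msa$seq)
#' @export
paired_msa <- function(sequences, reference = 1L,
                       domain1_cols = NULL, domain2_cols = NULL,
                       domain1_range = NULL, domain2_range = NULL,
                       id = "msa") {
  if (is.matrix(sequences)) {
    seqmat <- sequences
    ids <- rownames(sequences)
  } else {
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L)
      mi_error("ragged_alignment", "aligned sequences differ in length")
    seqmat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    ids <- names(sequences)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqmat)))
  reference <- as.integer(reference)
  if (reference < 1L || reference > nrow(seqmat))
    mi_error("missing_reference", "reference row index out of range")

  # Columns may be given directly or derived from residue ranges by
  # walking the reference row (residue r = r-th non-gap reference position).
  refrow <- seqmat[reference, ]
  nongap <- which(refrow != GAP)
  range_to_cols <- function(rng) {
    rng <- as.integer(rng)
    if (length(rng) != 2L || rng[1] > rng[2])
      mi_error("bad_range", "a domain range must be c(first, last) with first <= last")
    if (rng[1] < 1L || rng[2] > length(nongap))
      mi_error("range_out_of_bounds",
               sprintf("residue range %d-%d outside the ungapped reference (length %d)",
                       rng[1], rng[2], length(nongap)))
    nongap[rng[1]:rng[2]]
  }
  if (is.null(domain1_cols)) {
    if (is.null(domain1_range)) mi_error("bad_range", "supply domain1_cols or domain1_range")
    domain1_cols <- range_to_cols(domain1_range)
  }
  if (is.null(domain2_cols)) {
    if (is.null(domain2_range)) mi_error("bad_range", "supply domain2_cols or domain2_range")
    domain2_cols <- range_to_cols(domain2_range)
  }
  domain1_cols <- as.integer(domain1_cols)
  domain2_cols <- as.integer(domain2_cols)
  if (length(intersect(domain1_cols, domain2_cols)) > 0L)
    mi_error("overlapping_domains", "domain column sets must be disjoint")
  if (any(refrow[c(domain1_cols, domain2_cols)] == GAP))
    mi_error("reference_gap", "reference sequence is gapped inside a domain column")

  structure(list(seq = `rownames<-`(seqmat, ids),
                 ids = ids,
                 reference = reference,
                 domain1_cols = domain1_cols,
                 domain2_cols = domain2_cols,
                 domain1_range = if (is.null(domain1_range)) NULL else as.integer(domain1_range),
                 domain2_range = if (is.null(domain2_range)) NULL else as.integer(domain2_range),
                 alphabet = "full",
                 id = id),
            class = "paired_msa")
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf("paired_msa '%s': %d sequences x %d columns (%s alphabet)\n",
              x$id, nrow(x$seq), ncol(x$seq), x$alphabet))
  cat(sprintf("  domain 1: %d columns; domain 2: %d columns; reference row %d ('%s')\n",
              length(x$domain1_cols), length(x$domain2_cols),
              x$reference, x$ids[x$reference]))
  invisible(x)
}

#' Read a paired-domain alignment from FASTA or Stockholm
#'
#' Parses the alignment, locates the reference-structure sequence and
#' derives the two domains' column sets by walking the reference row:
#' domain ranges are 1-based inclusive residue numbers on the ungapped
#' reference sequence.  Sequences are upper-cased and `.` gaps normalised
#' to `-` on input; call [sanitize_msa()] afterwards to map non-standard
#' residue codes to gaps.
#'
#' @param file path to the alignment file.
#' @param format `"fasta"` (canonical) or `"stockholm"`.
#' @param domain1_range,domain2_range residue-number intervals `c(first, last)`.
#' @param reference_id identifier of the reference sequence (matched
#'   against the name up to the first whitespace).
#' @param id optional label; defaults to the file name.
#' @return a [paired_msa()].
#' @export
read_alignment <- function(file, format = c("fasta", "stockholm"),
                           domain1_range, domain2_range, reference_id,
                           id = NULL) {
  format <- match.arg(format)
  seqs <- switch(format,
                 fasta = read_fasta_strings(file),
                 stockholm = read_stockholm_strings(file))
  if (length(unique(nchar(seqs))) > 1L)
    mi_error("ragged_alignment", "aligned sequences differ in length")
  seqs <- toupper(gsub(".", GAP, seqs, fixed = TRUE))
  short <- sub("\\s.*$", "", names(seqs))
  hit <- which(short == reference_id)
  if (length(hit) == 0L)
    mi_error("missing_reference",
             sprintf("reference sequence '%s' not found in %s", reference_id, file))
  names(seqs) <- short
  paired_msa(seqs, reference = hit[1],
             domain1_range = domain1_range, domain2_range = domain2_range,
             id = if (is.null(id)) basename(file) else id)
}

read_fasta_strings <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  stats::setNames(as.character(ss), names(ss))
}

# Minimal Stockholm 1.0 reader: sequence lines are "<name> <aligned seq>",
# possibly split across blocks; markup (#=..., //) is skipped.
read_stockholm_strings <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|//|$)", lines)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) mi_error("parse_error", "malformed Stockholm sequence line")
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, `[[`, "", 2L)
  out <- vapply(split(sq, factor(nm, levels = unique(nm))), paste0,
                "", collapse = "")
  if (length(out) == 0L) mi_error("parse_error", "no sequences in Stockholm file")
  out
}

#' Write an alignment to FASTA
#'
#' @param msa a [paired_msa()].
#' @param file output path.
#' @export
write_alignment <- function(msa, file) {
  seqs <- apply(msa$seq, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' Replace non-standard residue codes with gaps
#'
#' Sequencing-uncertainty codes (B, Z, X, `*`, `?`) have no agreed
#' treatment in coevolution scoring; here they are converted to the gap
#' symbol, as are selenocysteine (U), pyrrolysine (O) and any other
#' character outside the 20-letter standard alphabet.  Lowercase letters
#' are upper-cased first.  Idempotent; sequence count and length are
#' unchanged.
#'
#' @param msa a [paired_msa()].
#' @return the sanitised [paired_msa()].
#' @examples
#' msa <- paired_msa(c("ABZXG", "ACDEG"), domain1_range = c(1, 2),
#'                   domain2_range = c(3, 5), reference = 2)
#' sanitize_msa(msa)$seq[1, ]
#' @export
sanitize_msa <- function(msa) {
  m <- toupper(msa$seq)
  m[!(m %in% c(AA20, GAP))] <- GAP
  msa$seq <- m
  # A domain column whose reference residue was non-standard would now be
  # gapped in the reference; such columns are caught by the mask, not here.
  msa
}

#' The seven-category physiochemical reduced alphabet
#'
#' Groups the 20 amino acids into Small (S, G, A, P), Hydrophobic
#' (V, M, I, L, C), Negatively charged (D, E), Aromatic (F, Y, W), Polar
#' (Q, T, N), Favoured positively-charged (R, H) and Disfavoured
#' positively-charged (K), abbreviated S, H, N, A, P, F and D
#' respectively.  Lysine is kept apart from arginine/histidine because it
#' is comparatively rare in domain interfaces.
#'
#' @return named character vector mapping each standard amino acid to its
#'   category symbol, with a `name` attribute.
#' @export
ra_alphabet <- function() {
  map <- c(S = "S", G = "S", A = "S", P = "S",
           V = "H", M = "H", I = "H", L = "H", C = "H",
           D = "N", E = "N",
           F = "A", Y = "A", W = "A",
           Q = "P", T = "P", N = "P",
           R = "F", H = "F",
           K = "D")
  attr(map, "name") <- "physiochemical7"
  map
}

#' Reduce an alignment to a category alphabet
#'
#' Replaces every residue by its category symbol under `map`; gaps are
#' unchanged.  Scores computed on the reduced alignment are the "RA"
#' variants.
#'
#' @param msa a [paired_msa()].
#' @param map a total mapping from the 20 standard amino acids to
#'   category symbols, as returned by [ra_alphabet()].
#' @return the reduced [paired_msa()] with `alphabet = "RA"`.
#' @export
reduce_alphabet <- function(msa, map = ra_alphabet()) {
  if (!all(AA20 %in% names(map)))
    mi_error("incomplete_map", "alphabet map must cover all 20 standard amino acids")
  m <- msa$seq
  res <- m != GAP
  unknown <- setdiff(unique(m[res]), names(map))
  if (length(unknown) > 0L)
    mi_error("unmapped_symbol",
             sprintf("symbols not in alphabet map (sanitize first?): %s",
                     paste(unknown, collapse = ", ")))
  m[res] <- unname(map[m[res]])
  msa$seq <- m
  msa$alphabet <- "RA"
  msa
}

#' Flag columns eligible for scoring
#'
#' A column is eligible when it belongs to one of the two domains,
#' contains no gap in any sequence, and has column entropy strictly
#' greater than zero.  Gapped and fully conserved columns carry no
#' correlated-mutation signal and are excluded from every score.
#'
#' @param msa a [paired_msa()].
#' @return data frame of class `column_mask` with one row per alignment
#'   column: `col`, `domain` (`"D1"`, `"D2"` or `NA`), `eligible`, and
#'   `reason` (one of `ok`, `gapped`, `zero_entropy`, `non_reference`).
#' @export
column_mask <- function(msa) {
  nc <- ncol(msa$seq)
  domain <- rep(NA_character_, nc)
  domain[msa$domain1_cols] <- "D1"
  domain[msa$domain2_cols] <- "D2"
  gapped <- apply(msa$seq == GAP, 2, any)
  constant <- apply(msa$seq, 2, function(x) length(unique(x)) == 1L)
  reason <- rep("ok", nc)
  reason[constant] <- "zero_entropy"
  reason[gapped] <- "gapped"             # gap flag takes precedence
  reason[is.na(domain)] <- "non_reference"
  out <- data.frame(col = seq_len(nc), domain = domain,
                    eligible = reason == "ok", reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("column_mask", "data.frame")
  out
}

#' Subsample alignment rows
#'
#' Draws `floor(fraction * (n - 1))` of the non-reference rows uniformly
#' without replacement and always retains the reference row, so that
#' structure-derived annotations remain mappable.  With `fraction = 0.7`
#' a 200-sequence alignment therefore yields 140 rows.  Deterministic for
#' a given `seed`; the caller's RNG state is untouched.
#'
#' @param msa a [paired_msa()].
#' @param fraction proportion of sequences to keep, in (0, 1].
#' @param seed integer seed.
#' @return the subsampled [paired_msa()] (same columns, row order preserved).
#' @export
subsample_msa <- function(msa, fraction, seed) {
  if (fraction <= 0 || fraction > 1)
    mi_error("bad_fraction", "fraction must be in (0, 1]")
  n <- nrow(msa$seq)
  k <- floor(fraction * (n - 1L))
  if (k < 1L)
    mi_error("too_few_sequences", "subsample would retain fewer than 2 sequences")
  others <- setdiff(seq_len(n), msa$reference)
  pick <- with_seed(seed, sample(others, k))
  rows <- sort(c(msa$reference, pick))
  out <- msa
  out$seq <- msa$seq[rows, , drop = FALSE]
  out$ids <- msa$ids[rows]
  out$reference <- match(msa$reference, rows)
  out
}

#' Map reference residues to alignment columns
#'
#' @param msa a [paired_msa()] built with domain residue ranges.
#' @return data frame with `residue` (reference residue number), `domain`
#'   and `col` for every domain residue.
#' @export
reference_mapping <- function(msa) {
  if (is.null(msa$domain1_range) || is.null(msa$domain2_range))
    mi_error("bad_range", "this alignment carries no domain residue ranges")
  data.frame(
    residue = c(seq(msa$domain1_range[1], msa$domain1_range[2]),
                seq(msa$domain2_range[1], msa$domain2_range[2])),
    domain = rep(c("D1", "D2"),
                 c(length(msa$domain1_cols), length(msa$domain2_cols))),
    col = c(msa$domain1_cols, msa$domain2_cols),
    stringsAsFactors = FALSE)
}
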