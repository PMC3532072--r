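# Synthetic paired-domain alignments with planted covarying column pairs
# or triples, plus structural annotations consistent with the surface and
# contact definitions, so the whole pipeline is testable from code alone.

#' Specify a synthetic paired-domain test case
#'
#' The generator draws background columns independently and uniformly
#' over the first `alphabet_size` amino acids, and plants covariation as
#' bijection mixtures: in a coupled pair, each row's domain-2 symbol is,
#' with probability equal to the coupling strength, the image of the
#' domain-1 symbol under a fixed random bijection, and an independent
#' draw otherwise.  Coupled triples plant a pure three-body linkage: in
#' linked rows the third column's symbol is a fixed bijective function
#' of the (first, second) symbol combination (index sum modulo the
#' alphabet size), so every pairwise margin stays independent while the
#' triple is strongly dependent -- the signal the triangle scores are
#' designed to detect.  This isolates
#' exactly the signal mutual information detects, without phylogenetic
#' structure; an optional shared-ancestry background (`shared_ancestry`)
#' instead mutates every sequence away from one ancestral sequence with
#' a per-sequence substitution rate drawn uniformly from (0, 2 *
#' `shared_ancestry`).  The rate heterogeneity couples all columns
#' through their shared divergence from the ancestor -- the
#' phylogenetic-style background MI that the APC and CPS corrections
#' are meant to suppress.
#'
#' Domain 1 occupies alignment columns `1..len1` (reference residues
#' 1..len1), domain 2 columns `len1+1..len1+len2`.  Row 1 is the
#' (ungapped) reference sequence.
#'
#' @param n_sequences number of rows (default 500).
#' @param len1,len2 domain lengths in columns (default 25 each).
#' @param alphabet_size background alphabet size, 2..20 (default 20).
#' @param coupled_pairs data frame `col1`, `col2`, `coupling` (columns in
#'   alignment numbering, coupling in `[0, 1]`), or NULL.
#' @param coupled_triples data frame `col1` (domain 1), `col2`, `col3`
#'   (both domain 2), `coupling`, or NULL.
#' @param conserved_cols columns planted fully conserved (entropy 0).
#' @param gapped_cols columns planted with one gap in a non-reference row.
#' @param surface_fraction fraction of each domain's residues labelled
#'   surface (default 0.7, roughly the surface prevalence seen in real
#'   two-domain proteins).
#' @param contact_pairs data frame `res1` (domain-1 residue), `res2`
#'   (domain-2 residue) of planted contacts; defaults to the residues of
#'   `coupled_pairs`.
#' @param patch_pairs data frame `res1`, `res2` of domain-2 residue pairs
#'   planted closer than 4.5 angstroms (patches for triangle scores);
#'   defaults to the domain-2 residue pairs of `coupled_triples`.
#' @param shared_ancestry `NA` (independent background) or a per-site
#'   substitution probability in (0, 1].
#' @param seed integer seed; the same spec always generates byte-identical
#'   data.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences = 500, len1 = 25, len2 = 25,
                           alphabet_size = 20,
                           coupled_pairs = NULL, coupled_triples = NULL,
                           conserved_cols = integer(0), gapped_cols = integer(0),
                           surface_fraction = 0.7,
                           contact_pairs = NULL, patch_pairs = NULL,
                           shared_ancestry = NA, seed = 1) {
  len <- len1 + len2
  if (n_sequences < 2 || len1 < 1 || len2 < 1)
    mi_error("inconsistent_spec", "need >= 2 sequences and positive domain lengths")
  if (alphabet_size < 2 || alphabet_size > 20)
    mi_error("inconsistent_spec", "alphabet_size must be in 2..20")
  planted <- c(if (!is.null(coupled_pairs)) c(coupled_pairs$col1, coupled_pairs$col2),
               if (!is.null(coupled_triples)) c(coupled_triples$col1,
                                                coupled_triples$col2,
                                                coupled_triples$col3))
  if (!is.null(coupled_pairs)) {
    with(coupled_pairs, {
      if (any(col1 < 1 | col1 > len1) || any(col2 <= len1 | col2 > len))
        mi_error("inconsistent_spec", "coupled pair columns outside their domains")
      if (any(coupling < 0 | coupling > 1))
        mi_error("inconsistent_spec", "couplings must be in [0, 1]")
    })
  }
  if (!is.null(coupled_triples)) {
    with(coupled_triples, {
      if (any(col1 < 1 | col1 > len1) || any(col2 <= len1 | col2 > len) ||
          any(col3 <= len1 | col3 > len) || any(col2 == col3))
        mi_error("inconsistent_spec", "coupled triple columns outside their domains")
    })
  }
  if (anyDuplicated(planted))
    mi_error("inconsistent_spec", "planted coupled columns must be distinct")
  if (length(intersect(planted, c(conserved_cols, gapped_cols))))
    mi_error("inconsistent_spec", "coupled columns cannot be conserved or gapped")
  if (any(c(conserved_cols, gapped_cols) < 1) ||
      any(c(conserved_cols, gapped_cols) > len))
    mi_error("inconsistent_spec", "planted column index out of range")
  if (is.null(contact_pairs) && !is.null(coupled_pairs))
    contact_pairs <- data.frame(res1 = coupled_pairs$col1,
                                res2 = coupled_pairs$col2 - len1)
  if (is.null(patch_pairs) && !is.null(coupled_triples))
    patch_pairs <- data.frame(res1 = coupled_triples$col2 - len1,
                              res2 = coupled_triples$col3 - len1)
  structure(list(n_sequences = n_sequences, len1 = len1, len2 = len2,
                 alphabet_size = alphabet_size,
                 coupled_pairs = coupled_pairs, coupled_triples = coupled_triples,
                 conserved_cols = as.integer(conserved_cols),
                 gapped_cols = as.integer(gapped_cols),
                 surface_fraction = surface_fraction,
                 contact_pairs = contact_pairs, patch_pairs = patch_pairs,
                 shared_ancestry = shared_ancestry, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the synthetic alignment
#'
#' @param spec a [synthetic_spec()].
#' @return a [paired_msa()]; deterministic given the spec's seed.
#' @export
generate_msa <- function(spec) {
  len <- spec$len1 + spec$len2
  syms <- AA20[seq_len(spec$alphabet_size)]
  with_seed(spec$seed, {
    n <- spec$n_sequences
    if (is.na(spec$shared_ancestry)) {
      m <- matrix(sample(syms, n * len, replace = TRUE), n, len)
    } else {
      anc <- sample(syms, len, replace = TRUE)
      m <- matrix(rep(anc, each = n), n, len)
      rate <- stats::runif(n, 0, 2 * spec$shared_ancestry)
      mut <- matrix(stats::runif(n * len) < rate, n, len)  # rate recycles by row
      m[mut] <- sample(syms, sum(mut), replace = TRUE)
    }
    if (!is.null(spec$coupled_pairs)) {
      for (r in seq_len(nrow(spec$coupled_pairs))) {
        bij <- stats::setNames(sample(syms), syms)
        linked <- stats::runif(n) < spec$coupled_pairs$coupling[r]
        c2 <- spec$coupled_pairs$col2[r]
        m[linked, c2] <- unname(bij[m[linked, spec$coupled_pairs$col1[r]]])
      }
    }
    if (!is.null(spec$coupled_triples)) {
      S <- length(syms)
      for (r in seq_len(nrow(spec$coupled_triples))) {
        bij3 <- sample(syms)
        linked <- stats::runif(n) < spec$coupled_triples$coupling[r]
        a <- match(m[linked, spec$coupled_triples$col1[r]], syms)
        b <- match(m[linked, spec$coupled_triples$col2[r]], syms)
        m[linked, spec$coupled_triples$col3[r]] <- bij3[(a + b - 2L) %% S + 1L]
      }
    }
    if (length(spec$conserved_cols))
      m[, spec$conserved_cols] <- syms[1]
    for (g in spec$gapped_cols)
      m[sample(2:n, 1), g] <- GAP      # never the reference row
    rownames(m) <- c("reference", paste0("seq", seq_len(n - 1L) + 1L))
    paired_msa(m, reference = 1L,
               domain1_range = c(1L, spec$len1),
               domain2_range = c(spec$len1 + 1L, len),
               id = sprintf("synthetic_seed%d", spec$seed))
  })
}

#' Generate annotations and coordinates consistent with the spec
#'
#' Plants a one-atom-per-residue coordinate set in which exactly the
#' specified contact pairs lie closer than 4.5 angstroms across the
#' domain interface and the specified patch pairs lie closer than 4.5
#' angstroms within domain 2; all other inter-domain distances exceed
#' the cutoff.  Surface residues receive isolated accessibility 30
#' percent, buried residues 3 percent; planted contacts lose 15
#' percentage points of accessibility in the complex, so they (and only
#' they) satisfy all three contact criteria.
#'
#' @param spec a [synthetic_spec()].
#' @param msa the alignment generated from it.
#' @return list with `annotations` (column-annotated
#'   `residue_annotation`), `coords` (atom table) and `distances`
#'   (`distance_map`).
#' @export
generate_annotations <- function(spec, msa) {
  r1 <- seq_len(spec$len1)
  r2 <- seq_len(spec$len2) + spec$len1   # reference residue numbers of D2
  cp <- spec$contact_pairs               # res2 stored 1..len2 within D2
  pp <- spec$patch_pairs
  if (!is.null(cp) && anyDuplicated(cp$res2))
    mi_error("inconsistent_spec", "each domain-2 residue may carry at most one planted contact")
  if (!is.null(cp) && !is.null(pp) &&
      length(intersect(c(pp$res1, pp$res2), cp$res2)))
    mi_error("inconsistent_spec", "patch residues cannot also be planted contact partners")

  # D1 residues on a widely spaced line; D2 residues on a distant parallel
  # line; contacts pull the D2 partner next to its D1 residue; patches
  # pull the second patch residue next to the first.
  pos1 <- cbind(x = 10 * r1, y = 0, z = 0)
  pos2 <- cbind(x = 10 * seq_len(spec$len2), y = 1000, z = 0)
  if (!is.null(cp))
    for (i in seq_len(nrow(cp)))
      pos2[cp$res2[i], ] <- pos1[cp$res1[i], ] + c(0, 3, 0)
  if (!is.null(pp))
    for (i in seq_len(nrow(pp)))
      pos2[pp$res2[i], ] <- pos2[pp$res1[i], ] + c(0, 0, 3)
  coords <- data.frame(resno = c(r1, r2),
                       domain = rep(c("D1", "D2"), c(spec$len1, spec$len2)),
                       elety = "CA",
                       x = c(pos1[, 1], pos2[, 1]),
                       y = c(pos1[, 2], pos2[, 2]),
                       z = c(pos1[, 3], pos2[, 3]),
                       stringsAsFactors = FALSE)

  n_surf1 <- round(spec$surface_fraction * spec$len1)
  n_surf2 <- round(spec$surface_fraction * spec$len2)
  surf <- with_seed(spec$seed + 1L, {
    s1 <- sample(r1, n_surf1)
    s2 <- sample(r2, n_surf2)
    c(s1, s2)
  })
  if (!is.null(cp)) surf <- union(surf, c(cp$res1, cp$res2 + spec$len1))
  residues <- c(r1, r2)
  iso <- ifelse(residues %in% surf, 30, 3)
  complexed <- iso
  if (!is.null(cp)) {
    contacts <- c(cp$res1, cp$res2 + spec$len1)
    complexed[residues %in% contacts] <- iso[residues %in% contacts] - 15
  }
  access <- data.frame(residue = residues,
                       domain = rep(c("D1", "D2"), c(spec$len1, spec$len2)),
                       rel_access_isolated = iso,
                       rel_access_complex = complexed,
                       stringsAsFactors = FALSE)
  distances <- min_atom_distances(coords)
  ann <- annotate_columns(msa, label_contacts(access, distances))
  list(annotations = ann, coords = coords, distances = distances)
}

#' Materialise the synthetic fixture files
#'
#' Writes the alignment (FASTA), the annotation table (TSV) and the
#' planted coordinates (PDB) for a spec into a directory.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msa <- generate_msa(spec)
  ga <- generate_annotations(spec, msa)
  fa <- file.path(dir, "alignment.fasta")
  tsv <- file.path(dir, "annotations.tsv")
  pdb <- file.path(dir, "coords.pdb")
  write_alignment(msa, fa)
  write_annotation_tsv(ga$annotations, tsv)
  bio3d::write.pdb(xyz = as.vector(t(as.matrix(ga$coords[, c("x", "y", "z")]))),
                   resno = ga$coords$resno,
                   resid = rep("ALA", nrow(ga$coords)),
                   chain = ifelse(ga$coords$domain == "D1", "A", "B"),
                   elety = ga$coords$elety,
                   file = pdb)
  c(alignment = fa, annotations = tsv, coords = pdb)
}
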