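# Structure-derived residue annotation: minimum inter-atomic distances,
# surface/buried classification from relative solvent accessibility, and
# the three-criteria contact definition.

#' Read reference-structure coordinates from a PDB file
#'
#' Loads ATOM records, resolves alternate locations (highest occupancy,
#' then first), and tags each atom with its domain by residue number.
#' Residue numbers in the file are assumed to follow the reference
#' sequence numbering used for the domain ranges.
#'
#' @param file path to a PDB file.
#' @param domain1_range,domain2_range residue-number intervals `c(first, last)`.
#' @param chain optional chain identifier filter.
#' @return data frame with `resno`, `domain`, `elety`, `x`, `y`, `z`.
#' @export
read_structure <- function(file, domain1_range, domain2_range, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  # altloc: keep, per residue+atom name, the highest-occupancy record
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  o <- ifelse(is.na(at$o), 1, at$o)
  at <- at[order(key, -o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
  domain <- rep(NA_character_, nrow(at))
  domain[at$resno >= domain1_range[1] & at$resno <= domain1_range[2]] <- "D1"
  domain[at$resno >= domain2_range[1] & at$resno <= domain2_range[2]] <- "D2"
  keep <- !is.na(domain)
  data.frame(resno = at$resno[keep], domain = domain[keep],
             elety = at$elety[keep],
             x = at$x[keep], y = at$y[keep], z = at$z[keep],
             stringsAsFactors = FALSE)
}

# Minimum distance between every residue of set a and every residue of
# set b, over all atom pairs.
pairwise_res_min <- function(a, b) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  ra <- a$resno
  rb <- b$resno
  ua <- sort(unique(ra))
  ub <- sort(unique(rb))
  out <- matrix(Inf, length(ua), length(ub), dimnames = list(ua, ub))
  for (i in seq_along(ua)) {
    rows <- which(ra == ua[i])
    cm <- if (length(rows) == 1L) D2[rows, ] else apply(D2[rows, , drop = FALSE], 2, min)
    out[i, ] <- tapply(cm, factor(rb, levels = ub), min)
  }
  sqrt(out)
}

mat_to_pairs <- function(M, upper_only = FALSE) {
  df <- data.frame(res1 = as.integer(rep(rownames(M), times = ncol(M))),
                   res2 = as.integer(rep(colnames(M), each = nrow(M))),
                   dist = as.vector(M))
  if (upper_only) df <- df[df$res1 < df$res2, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Minimum inter-atomic residue distances
#'
#' For every residue pair in scope, the minimum Euclidean distance over
#' all atom-atom combinations (all atoms present in the coordinate set,
#' hydrogens included when given).  Produces the inter-domain map used by
#' the contact criterion and the intra-domain maps used to define
#' triangle patches.
#'
#' @param coords data frame with `resno`, `domain` (`"D1"`/`"D2"`), `x`,
#'   `y`, `z` (one row per atom), as from [read_structure()].
#' @return object of class `distance_map`: list with data frames `inter`
#'   (`res1` in D1, `res2` in D2, `dist`), `intra1` and `intra2`
#'   (`res1 < res2`).
#' @export
min_atom_distances <- function(coords) {
  if (nrow(coords) == 0L) mi_error("no_atoms", "empty coordinate set")
  if (any(!is.finite(as.matrix(coords[, c("x", "y", "z")]))))
    mi_error("no_atoms", "residue with non-finite atom coordinates")
  d1 <- coords[coords$domain == "D1", , drop = FALSE]
  d2 <- coords[coords$domain == "D2", , drop = FALSE]
  if (nrow(d1) == 0L || nrow(d2) == 0L)
    mi_error("no_atoms", "both domains need at least one atom")
  structure(list(inter = mat_to_pairs(pairwise_res_min(d1, d2)),
                 intra1 = mat_to_pairs(pairwise_res_min(d1, d1), upper_only = TRUE),
                 intra2 = mat_to_pairs(pairwise_res_min(d2, d2), upper_only = TRUE)),
            class = "distance_map")
}

#' Classify residues as surface or buried
#'
#' A residue is on the surface when its relative solvent accessibility to
#' a 1.4-angstrom-radius water probe, with its domain treated as a
#' separate entity, exceeds 7 percent (strictly); otherwise it is buried.
#'
#' @param rel_access_isolated numeric vector of percent accessibilities
#'   in `[0, 100]`.
#' @param threshold surface threshold in percent (default 7).
#' @return logical vector, `TRUE` for surface.
#' @export
classify_surface <- function(rel_access_isolated, threshold = 7) {
  if (any(!is.finite(rel_access_isolated)) ||
      any(rel_access_isolated < 0 | rel_access_isolated > 100))
    mi_error("bad_accessibility", "accessibilities must be percentages in [0, 100]")
  rel_access_isolated > threshold
}

#' Label contact and non-contact residues
#'
#' A residue is a contact when all three criteria hold: (1) it is on the
#' surface of its individual domain; (2) its minimum inter-atomic
#' distance to any residue of the other domain is strictly less than
#' `contact_dist` angstroms; (3) its solvent accessibility differs
#' between the isolated domain and the two-domain complex (by more than
#' `access_tol` percentage points).  All other residues are non-contact.
#'
#' @param access data frame with `residue`, `domain`,
#'   `rel_access_isolated`, `rel_access_complex` (percent).
#' @param distances a `distance_map` from [min_atom_distances()].
#' @param contact_dist distance criterion in angstroms (default 4.5,
#'   strict).
#' @param access_tol minimum accessibility change in percentage points
#'   (default 0.5).
#' @param surface_threshold percent threshold for criterion 1 (default 7).
#' @return object of class `residue_annotation`: the input with logical
#'   `surface` and `contact` columns and `min_inter_dist`.
#' @export
label_contacts <- function(access, distances, contact_dist = 4.5,
                           access_tol = 0.5, surface_threshold = 7) {
  need <- c("residue", "domain", "rel_access_isolated", "rel_access_complex")
  if (!all(need %in% names(access)))
    mi_error("missing_accessibility",
             "accessibility table must have residue, domain, rel_access_isolated, rel_access_complex")
  if (any(is.na(access$rel_access_isolated)) || any(is.na(access$rel_access_complex)))
    mi_error("missing_accessibility", "missing accessibility record")
  min1 <- tapply(distances$inter$dist, distances$inter$res1, min)
  min2 <- tapply(distances$inter$dist, distances$inter$res2, min)
  key <- ifelse(access$domain == "D1",
                min1[as.character(access$residue)],
                min2[as.character(access$residue)])
  key[is.na(key)] <- Inf
  access$min_inter_dist <- unname(key)
  access$surface <- classify_surface(access$rel_access_isolated, surface_threshold)
  access$contact <- access$surface &
    access$min_inter_dist < contact_dist &
    abs(access$rel_access_isolated - access$rel_access_complex) > access_tol
  class(access) <- c("residue_annotation", "data.frame")
  access
}

#' Attach alignment columns to residue annotations
#'
#' Structure-derived labels apply to the entire MSA column of the
#' residue; this maps every annotated reference residue to its alignment
#' column by walking the reference row.
#'
#' @param msa a [paired_msa()] with domain residue ranges.
#' @param annotations a `residue_annotation` (or any data frame with
#'   `residue` and `domain`).
#' @return the annotations with a `column` field added.
#' @export
annotate_columns <- function(msa, annotations) {
  map <- reference_mapping(msa)
  idx <- match(paste(annotations$domain, annotations$residue),
               paste(map$domain, map$residue))
  if (any(is.na(idx)))
    mi_error("unmappable_residue",
             sprintf("residues outside the domain ranges: %s",
                     paste(utils::head(annotations$residue[is.na(idx)]), collapse = ", ")))
  annotations$column <- map$col[idx]
  annotations
}

#' Read or write the annotation TSV format
#'
#' The tabular interchange format has columns `residue`, `domain`,
#' `rel_access_isolated`, `rel_access_complex` and optionally `surface`,
#' `contact`, `column`.
#'
#' @param file path to a TSV file.
#' @return data frame.
#' @export
read_annotation_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_annotation_tsv
#' @param annotations data frame to write.
#' @export
write_annotation_tsv <- function(annotations, file) {
  utils::write.table(annotations, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
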