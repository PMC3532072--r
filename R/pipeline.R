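# End-to-end workflow wiring: validated run configuration and the
# read -> sanitise -> (reduce) -> mask -> score -> aggregate -> evaluate
# pipeline, with reproducible seeds and machine-readable outputs.

#' Build a validated run configuration
#'
#' Collects every input path, variant choice and threshold for a pipeline
#' run.  All thresholds default to the field-standard values: 7 percent
#' accessibility for the surface cutoff, 4.5 angstroms for the contact
#' and patch distance criteria, 0.5 percentage points for the
#' accessibility-change tolerance.
#'
#' @param alignment path to the alignment file, or a [paired_msa()].
#' @param format alignment format, `"fasta"` or `"stockholm"`.
#' @param domain1_range,domain2_range residue ranges (ignored when
#'   `alignment` is already a `paired_msa`).
#' @param reference_id reference sequence identifier.
#' @param annotations path to an accessibility/annotation TSV, or a data
#'   frame (fields of [label_contacts()]'s `access` argument, or an
#'   already labelled annotation).
#' @param coordinates optional path to a PDB file, or a coordinate data
#'   frame; required for the triangle variants and for contact labelling
#'   from raw accessibility tables.
#' @param variants character vector of score variants to run.
#' @param alphabet `"full"` or `"RA"`.
#' @param aggregate residue aggregation, `"max"` or `"mean"`.
#' @param task evaluation task: `"contact"` (contact vs non-contact,
#'   surface residues only) or `"surface"` (surface vs buried, all
#'   residues).
#' @param cps_l_scope third-column scope for MIc (see [mic_table()]).
#' @param ties top-k tie policy (see [binomial_topk()]).
#' @param surface_threshold,contact_dist,access_tol thresholds.
#' @param target_recall recall for the precision read-out (default 0.2).
#' @param seed integer seed for any subsampling the run performs.
#' @param outdir output directory, or NULL to skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(alignment, format = "fasta",
                       domain1_range = NULL, domain2_range = NULL,
                       reference_id = NULL,
                       annotations = NULL, coordinates = NULL,
                       variants = "MI", alphabet = c("full", "RA"),
                       aggregate = c("max", "mean"),
                       task = c("contact", "surface"),
                       cps_l_scope = "all", ties = "expand",
                       surface_threshold = 7, contact_dist = 4.5,
                       access_tol = 0.5, target_recall = 0.2,
                       seed = 1, outdir = NULL) {
  alphabet <- match.arg(alphabet)
  aggregate <- match.arg(aggregate)
  task <- match.arg(task)
  bad <- setdiff(variants, c("MI", "MIp", "MIc", "MI3D", "MIp3D"))
  if (length(bad))
    mi_error("bad_config", sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  structure(list(alignment = alignment, format = format,
                 domain1_range = domain1_range, domain2_range = domain2_range,
                 reference_id = reference_id,
                 annotations = annotations, coordinates = coordinates,
                 variants = variants, alphabet = alphabet,
                 aggregate = aggregate, task = task,
                 cps_l_scope = cps_l_scope, ties = ties,
                 surface_threshold = surface_threshold,
                 contact_dist = contact_dist, access_tol = access_tol,
                 target_recall = target_recall,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param file path to a YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                        class = c("micontact_stage_error", class(e))))
  })
}

#' Run the full scoring and evaluation pipeline
#'
#' Executes read, sanitise, optional alphabet reduction, masking, scoring
#' for each requested variant, residue aggregation and precision-recall
#' evaluation, returning (and optionally writing) all tables plus a
#' machine-readable summary that records the package version, the full
#' configuration and the seed, so any run is reproducible from its
#' summary alone.
#'
#' @param config a [run_config()].
#' @return list of class `run_artifacts` with `msa`, `mask`,
#'   `annotations`, `tables`, `residue_scores`, `curves`, `summary`.
#' @export
run_pipeline <- function(config) {
  msa <- stage("read", {
    if (inherits(config$alignment, "paired_msa")) config$alignment
    else read_alignment(config$alignment, config$format,
                        config$domain1_range, config$domain2_range,
                        config$reference_id)
  })
  msa <- stage("sanitize", sanitize_msa(msa))
  if (config$alphabet == "RA") msa <- stage("reduce", reduce_alphabet(msa))
  mask <- stage("mask", column_mask(msa))

  distances <- stage("distances", {
    if (is.null(config$coordinates)) NULL
    else {
      coords <- if (is.character(config$coordinates))
        read_structure(config$coordinates, msa$domain1_range, msa$domain2_range)
      else config$coordinates
      min_atom_distances(coords)
    }
  })
  ann <- stage("annotate", {
    a <- config$annotations
    if (is.character(a)) a <- read_annotation_tsv(a)
    if (is.null(a)) mi_error("bad_config", "annotations are required")
    if (!all(c("surface", "contact") %in% names(a))) {
      if (is.null(distances))
        mi_error("bad_config",
                 "coordinates are required to derive contact labels from accessibilities")
      a <- label_contacts(a, distances, config$contact_dist,
                          config$access_tol, config$surface_threshold)
    }
    annotate_columns(msa, a)
  })

  tables <- list()
  scores <- list()
  curves <- list()
  summ_variants <- list()
  for (v in config$variants) {
    tab <- stage(paste0("score_", v),
                 score_table(msa, v, mask, distances = distances,
                             cps_l_scope = config$cps_l_scope))
    rs <- stage(paste0("aggregate_", v),
                suppressMessages(residue_scores(tab, ann, config$aggregate)))
    ev <- stage(paste0("evaluate_", v), {
      if (config$task == "contact") {
        sub <- rs[rs$surface, , drop = FALSE]
        list(scores = sub, curve = proc_curve(sub$score, sub$contact),
             mcc = mcc_curve(sub$score, sub$contact))
      } else {
        list(scores = rs, curve = proc_curve(rs$score, rs$surface),
             mcc = mcc_curve(rs$score, rs$surface))
      }
    })
    tables[[v]] <- tab
    scores[[v]] <- rs
    curves[[v]] <- ev$curve
    summ_variants[[v]] <- list(
      n_pairs = nrow(tab),
      n_excluded = nrow(attr(tab, "excluded")),
      baseline = attr(ev$curve, "baseline"),
      precision_at_target_recall =
        tryCatch(precision_at_recall(ev$curve, config$target_recall),
                 micontact_error = function(e) NA_real_),
      max_mcc = max(ev$mcc$mcc))
  }

  cfg <- config
  cfg$alignment <- if (is.character(config$alignment)) config$alignment else msa$id
  cfg$annotations <- if (is.character(config$annotations)) config$annotations else "in-memory"
  cfg$coordinates <- if (is.character(config$coordinates)) config$coordinates else
    if (is.null(config$coordinates)) NULL else "in-memory"
  summary <- list(package = "micontact",
                  version = as.character(utils::packageVersion("micontact")),
                  seed = config$seed,
                  task = config$task,
                  target_recall = config$target_recall,
                  config = unclass(cfg),
                  n_sequences = nrow(msa$seq),
                  n_columns = ncol(msa$seq),
                  n_eligible = sum(mask$eligible),
                  variants = summ_variants)

  out <- structure(list(msa = msa, mask = mask, annotations = ann,
                        tables = tables, residue_scores = scores,
                        curves = curves, summary = summary),
                   class = "run_artifacts")
  if (!is.null(config$outdir)) write_artifacts(out, config$outdir)
  out
}

#' Write run artifacts to a directory
#'
#' One TSV per score table, per residue-score table and per P-ROC curve,
#' plus `summary.json`.
#'
#' @param artifacts a `run_artifacts` list from [run_pipeline()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_artifacts <- function(artifacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name)
    utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (v in names(artifacts$tables)) {
    tsv(artifacts$tables[[v]], sprintf("pairs_%s.tsv", v))
    tsv(artifacts$residue_scores[[v]], sprintf("residues_%s.tsv", v))
    tsv(artifacts$curves[[v]], sprintf("proc_%s.tsv", v))
  }
  jsonlite::write_json(artifacts$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
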