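#' Workflow configuration
#'
#' Bundles everything a full analysis run needs; fully serializable, and a
#' resolved copy is written beside every run's outputs so each number in the
#' bundle is traceable to a configuration value.
#'
#' @param target target name.
#' @param ref1_path,ref2_path paths to the two experimental reference
#'   structures (PDB).
#' @param ref1_chain,ref2_chain chain identifiers.
#' @param truncations list of inclusive residue intervals to drop.
#' @param plddt_threshold confidence cutoff for per-residue statistics.
#' @param linkage_cutoff,min_cluster misfold-exclusion parameters (see
#'   [filter_misfolded()]).
#' @param mask optional residue numbers for the PCA mask; `NULL` uses the
#'   built-in secondary-structure heuristic.
#' @param apply_confidence_filter whether per-residue correlations are
#'   restricted to residues above the confidence cutoff.
#' @param top_k extreme-model selection sizes.
#' @param seed integer seed recorded with the run.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(target = "target",
                            ref1_path = NULL, ref2_path = NULL,
                            ref1_chain = "A", ref2_chain = "A",
                            truncations = list(),
                            plddt_threshold = 75,
                            linkage_cutoff = 5, min_cluster = 3,
                            mask = NULL,
                            apply_confidence_filter = TRUE,
                            top_k = c(1, 3, 10),
                            seed = 1) {
  structure(list(target = target, ref1_path = ref1_path,
                 ref2_path = ref2_path, ref1_chain = ref1_chain,
                 ref2_chain = ref2_chain, truncations = truncations,
                 plddt_threshold = plddt_threshold,
                 linkage_cutoff = linkage_cutoff, min_cluster = min_cluster,
                 mask = mask,
                 apply_confidence_filter = apply_confidence_filter,
                 top_k = top_k, seed = as.integer(seed)),
            class = "workflow_config")
}

read_ensemble_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  lapply(files, read_structure)
}

#' Run the full ensemble analysis
#'
#' Composes the pipeline downstream of inference: misfold exclusion by
#' coclustering, per-model TM-scores against both references, per-residue
#' displacement/RMSF statistics with confidence filtering, the PCA landscape
#' with reference projections, and extreme-model selection. Stage failures
#' are caught and reported with the stage name; outputs from earlier stages
#' are retained. All outputs are deterministic in the inputs and config.
#'
#' @param config a [workflow_config()].
#' @param ensemble list of [structure_model]s, or `NULL` to read
#'   `ensemble_dir`.
#' @param ensemble_dir directory of PDB models (`*.pdb`), used when
#'   `ensemble` is `NULL`.
#' @param ref1,ref2 [structure_model] references; when `NULL` they are read
#'   from the paths in `config`.
#' @param out_dir output directory for the report bundle; `NULL` skips
#'   writing.
#' @return A `report_bundle` list: `outliers`, `tm_table`, `residue_stats`,
#'   `correlation_r2`, `landscape_summary`, `extremes`, `errors` and the
#'   resolved `config`.
#' @export
run_analysis <- function(config, ensemble = NULL, ensemble_dir = NULL,
                         ref1 = NULL, ref2 = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  if (is.null(ensemble)) {
    if (is.null(ensemble_dir)) stop("supply an ensemble or ensemble_dir")
    ensemble <- read_ensemble_dir(ensemble_dir)
  }
  if (length(ensemble) < 3)
    stop("ensemble directory must contain at least 3 parseable models")
  if (is.null(ref1) && !is.null(config$ref1_path))
    ref1 <- read_structure(config$ref1_path, config$ref1_chain,
                           is_model = FALSE)
  if (is.null(ref2) && !is.null(config$ref2_path))
    ref2 <- read_structure(config$ref2_path, config$ref2_chain,
                           is_model = FALSE)
  if (is.null(ref1) || is.null(ref2)) stop("two reference structures required")
  for (rg in config$truncations) {
    ensemble <- lapply(ensemble, truncate_model, drop_ranges = list(rg))
  }
  bundle <- list(config = config, errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  ## 1. misfold exclusion
  outliers <- stage("filter_misfolded",
                    filter_misfolded(ensemble, config$linkage_cutoff,
                                     config$min_cluster))
  bundle$outliers <- outliers
  kept <- if (is.null(outliers)) ensemble else {
    ids <- vapply(ensemble, `[[`, character(1), "model_id")
    ensemble[ids %in% outliers$kept]
  }

  ## 2. TM-scores against both references
  bundle$tm_table <- stage("tm_scores", {
    ids <- vapply(kept, `[[`, character(1), "model_id")
    data.frame(
      model_id = ids,
      tm_to_ref1 = vapply(kept, function(m)
        tm_score(ref1, m, correspond(ref1, m))$score, numeric(1)),
      tm_to_ref2 = vapply(kept, function(m)
        tm_score(ref2, m, correspond(ref2, m))$score, numeric(1)),
      stringsAsFactors = FALSE)
  })

  ## 3. per-residue statistics
  bundle$residue_stats <- stage("residue_stats", {
    aligned <- align_ensemble(kept)
    rmsf <- rmsf_profile(aligned)
    disp <- displacement_profile(ref1, ref2, correspond(ref1, ref2))
    plddt_mat <- vapply(kept, function(m) {
      if (is.null(m$plddt)) return(rep(NA_real_, length(rmsf)))
      m$plddt[match(as.integer(names(rmsf)), m$resno)]
    }, numeric(length(rmsf)))
    mean_plddt <- stats::setNames(rowMeans(plddt_mat), names(rmsf))
    shared <- intersect(names(rmsf), names(disp))
    kept_flag <- mean_plddt[shared] > config$plddt_threshold
    data.frame(residue = as.integer(shared),
               displacement = unname(disp[shared]),
               rmsf = unname(rmsf[shared]),
               plddt = unname(mean_plddt[shared]),
               kept_flag = unname(kept_flag))
  })

  bundle$correlation_r2 <- stage("correlation", {
    rs <- bundle$residue_stats
    use <- if (config$apply_confidence_filter) rs[rs$kept_flag, ] else rs
    profile_correlation(
      stats::setNames(use$displacement, use$residue),
      stats::setNames(use$rmsf, use$residue), "r_squared")
  })

  ## 4. landscape, reference projections, extreme selection
  ls_fit <- stage("landscape", {
    aligned <- align_ensemble(kept)
    ls <- fit_landscape(aligned, mask = config$mask)
    ls <- orient_landscape(ls, ref1, correspond(ref1, kept[[1]]))
    ls
  })
  if (!is.null(ls_fit)) {
    bundle$landscape_summary <- list(
      variance_fractions = ls_fit$variance_fractions,
      mask = ls_fit$mask,
      reference_projections = list(
        ref1 = project_reference(ls_fit, ref1, correspond(ref1, kept[[1]])),
        ref2 = project_reference(ls_fit, ref2, correspond(ref2, kept[[1]]))),
      projections = ls_fit$projections[, seq_len(min(2, ncol(ls_fit$projections))),
                                       drop = FALSE])
    bundle$extremes <- stage("extremes", {
      feasible <- config$top_k[config$top_k <= nrow(ls_fit$projections)]
      do.call(rbind, lapply(feasible, function(k) {
        data.frame(k = k,
                   side = rep(c("low", "high"), each = k),
                   model_id = c(select_extremes(ls_fit, k, "low"),
                                select_extremes(ls_fit, k, "high")),
                   stringsAsFactors = FALSE)
      }))
    })
    bundle$landscape <- ls_fit
  }

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  class(bundle) <- "report_bundle"
  bundle
}

## Serialize a report bundle as CSV/JSON files (deterministic content).
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (!is.null(bundle$outliers))
    wj(list(kept = bundle$outliers$kept,
            excluded = bundle$outliers$excluded,
            cluster_labels = as.list(bundle$outliers$cluster_labels)),
       "outliers.json")
  if (!is.null(bundle$tm_table))
    utils::write.csv(bundle$tm_table, file.path(out_dir, "tm_scores.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$residue_stats))
    utils::write.csv(bundle$residue_stats,
                     file.path(out_dir, "residue_stats.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$landscape_summary)) {
    ls <- bundle$landscape_summary
    wj(list(variance_fractions = ls$variance_fractions, mask = ls$mask,
            reference_projections = ls$reference_projections),
       "landscape.json")
    proj <- data.frame(model_id = rownames(ls$projections),
                       ls$projections, row.names = NULL)
    utils::write.csv(proj, file.path(out_dir, "projections.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$extremes))
    utils::write.csv(bundle$extremes, file.path(out_dir, "extremes.csv"),
                     row.names = FALSE)
  cfg <- bundle$config
  wj(unclass(cfg), "config.json")
  if (length(bundle$errors) > 0) wj(bundle$errors, "errors.json")
  invisible(out_dir)
}
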