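#' Depth ladder for MSA subsampling
#'
#' Powers of two from `min_depth` up to 512, then 1024 and 5120, restricted
#' to `[min_depth, max_depth]`. The default endpoints, 16 and 5120, span the
#' shallowest alignments that still yield folded models and the full depth
#' used by the default prediction pipeline.
#'
#' @param min_depth,max_depth inclusive bounds, `2 <= min <= max`.
#' @return Sorted integer vector of depths.
#' @export
depth_ladder <- function(min_depth = 16, max_depth = 5120) {
  if (min_depth < 2) stop("min_depth must be >= 2")
  if (min_depth > max_depth) stop("min_depth must not exceed max_depth")
  candidates <- c(2^(1:9), 1024L, 5120L)
  ladder <- candidates[candidates >= min_depth & candidates <= max_depth]
  if (length(ladder) == 0) ladder <- min_depth
  as.integer(sort(unique(ladder)))
}

#' Build a run specification for the external prediction engine
#'
#' Encodes the reduced-recycling sampling protocol: one recycle, no
#' post-prediction relaxation, cluster count coupled to depth via
#' [default_cluster_count()]. Without templates, all five networks
#' contribute ten models each; with templates, only the two template-capable
#' networks are used, at 25 models each, with the template similarity cutoff
#' lowered from 10% to 1% and template subsampling enabled. Either way a run
#' totals 50 models. Per-model seeds are `seed + ordinal` (0-based), so each
#' model's MSA subsample is independently drawn yet fully reproducible.
#'
#' @param msa_path path to the source alignment (A3M).
#' @param extra_depth MSA subsampling depth (>= 2).
#' @param templates optional character vector of template identifiers; their
#'   presence switches the run to template mode.
#' @param seed base integer seed.
#' @param cluster_count override for the cluster parameter; defaults to the
#'   protocol coupling.
#' @param networks network identifiers; defaults to `model_1..model_5`
#'   without templates and the two template-capable networks
#'   (`model_1`, `model_2`) with them.
#' @param models_per_network models per network; defaults 10 (no templates)
#'   or 25 (templates).
#' @return A `runspec` list; see fields in the JSON written by
#'   [write_runspec()].
#' @export
make_runspec <- function(msa_path, extra_depth, templates = NULL, seed = 0,
                         cluster_count = NULL, networks = NULL,
                         models_per_network = NULL) {
  if (!is.numeric(extra_depth) || extra_depth < 2)
    stop("extra_depth must be >= 2")
  use_templates <- !is.null(templates) && length(templates) > 0
  if (is.null(cluster_count))
    cluster_count <- default_cluster_count(extra_depth)
  if (is.null(networks))
    networks <- if (use_templates) c("model_1", "model_2") else
      paste0("model_", 1:5)
  if (is.null(models_per_network))
    models_per_network <- if (use_templates) 25L else 10L
  total <- length(networks) * models_per_network
  spec <- list(
    msa_path = as.character(msa_path),
    extra_depth = as.integer(extra_depth),
    cluster_count = as.integer(cluster_count),
    recycles = 1L,
    use_templates = use_templates,
    template_ids = if (use_templates) as.character(templates) else character(0),
    template_similarity_cutoff = if (use_templates) 0.01 else NULL,
    subsample_templates = if (use_templates) TRUE else NULL,
    networks = as.character(networks),
    models_per_network = as.integer(models_per_network),
    total_models = as.integer(total),
    relax = FALSE,
    seed = as.integer(seed),
    model_seeds = as.integer(seed) + 0:(total - 1L))
  structure(spec[!vapply(spec, is.null, logical(1))], class = "runspec")
}

#' Write a run specification as a JSON manifest
#'
#' @param spec a `runspec` from [make_runspec()].
#' @param file output path.
#' @export
write_runspec <- function(spec, file) {
  stopifnot(inherits(spec, "runspec"))
  jsonlite::write_json(unclass(spec), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Read a run specification manifest
#'
#' @param file path to a JSON manifest written by [write_runspec()].
#' @return A `runspec`.
#' @export
read_runspec <- function(file) {
  spec <- jsonlite::read_json(file, simplifyVector = TRUE)
  int_fields <- c("extra_depth", "cluster_count", "recycles",
                  "models_per_network", "total_models", "seed", "model_seeds")
  for (f in intersect(int_fields, names(spec)))
    spec[[f]] <- as.integer(spec[[f]])
  chr_fields <- c("template_ids", "networks")
  for (f in intersect(chr_fields, names(spec)))
    spec[[f]] <- as.character(unlist(spec[[f]]))
  structure(spec, class = "runspec")
}

#' Shell command lines for a ColabFold-compatible runner
#'
#' One line per model; the engine is never invoked by this package.
#'
#' @param spec a `runspec`.
#' @param runner executable name.
#' @param out_dir output directory passed to the runner.
#' @return Character vector of command lines.
#' @export
runspec_commands <- function(spec, runner = "colabfold_runner",
                             out_dir = "models") {
  stopifnot(inherits(spec, "runspec"))
  lines <- character(0)
  ordinal <- 0L
  for (net in spec$networks) {
    for (m in seq_len(spec$models_per_network)) {
      s <- spec$model_seeds[ordinal + 1L]
      cmd <- sprintf(
        "%s --msa %s --model-name %s --max-extra-msa %d --max-msa-clusters %d --num-recycles %d --seed %d --no-relax --out %s/%s_seed%d.pdb",
        runner, spec$msa_path, net, spec$extra_depth, spec$cluster_count,
        spec$recycles, s, out_dir, net, s)
      if (isTRUE(spec$use_templates))
        cmd <- paste(cmd, sprintf(
          "--templates %s --template-similarity-cutoff %g --subsample-templates",
          paste(spec$template_ids, collapse = ","),
          spec$template_similarity_cutoff))
      lines <- c(lines, cmd)
      ordinal <- ordinal + 1L
    }
  }
  lines
}

#' Vet candidate templates by conformation label
#'
#' Template choice is a human decision: candidates are inspected and labelled
#' by conformation (e.g. "IF"/"OF"), and this function merely filters by the
#' wanted label and reports each candidate's global sequence identity to the
#' query. Identity is reported for the record, never applied as an automatic
#' cutoff.
#'
#' @param candidates data frame with columns `id` and `sequence`.
#' @param query query amino-acid sequence.
#' @param labels named character vector mapping candidate id to label.
#' @param wanted label to retain.
#' @return Data frame with columns `id`, `label` and `identity` (percent);
#'   empty (with a warning) when nothing matches.
#' @export
vet_templates <- function(candidates, query, labels, wanted) {
  if (nrow(candidates) == 0) {
    warning("no template candidates supplied")
    return(data.frame(id = character(0), label = character(0),
                      identity = numeric(0)))
  }
  lab <- labels[candidates$id]
  keep <- !is.na(lab) & lab == wanted
  if (!any(keep)) {
    warning(sprintf("no candidate labelled '%s'", wanted))
    return(data.frame(id = character(0), label = character(0),
                      identity = numeric(0)))
  }
  sel <- candidates[keep, , drop = FALSE]
  data.frame(
    id = sel$id,
    label = unname(lab[keep]),
    identity = vapply(sel$sequence, function(s) global_identity(query, s),
                      numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
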