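#' Per-residue Calpha displacement between two superimposed structures
#'
#' Superposes `ref2` onto `ref1` (Kabsch, on the mapped Calpha pairs) and
#' returns the Euclidean Calpha distance at each mapped residue. This is the
#' movement each residue undergoes between two conformations, e.g. the
#' inward- and outward-facing states of a transporter.
#'
#' @param ref1,ref2 [structure_model]s.
#' @param map `residue_map`; `NULL` matches by residue number.
#' @return Named numeric vector (names = `ref1` residue numbers on the mapped
#'   set) of displacements in Angstrom.
#' @export
displacement_profile <- function(ref1, ref2, map = NULL) {
  if (is.null(map)) map <- match_by_resno(ref1, ref2)
  a <- ref1$xyz[map$ia, , drop = FALSE]
  b <- ref2$xyz[map$ib, , drop = FALSE]
  if (nrow(a) < 3) {
    ## degenerate maps: centering alone removes all displacement for 1 point;
    ## handle 1-2 points without a rotation fit
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    d <- sqrt(rowSums((ac - bc)^2))
  } else {
    sp <- kabsch(a, b)
    d <- sqrt(rowSums((a - apply_superposition(b, sp))^2))
  }
  stats::setNames(d, ref1$resno[map$ia])
}

#' Root mean square fluctuation over an aligned ensemble
#'
#' `RMSF_i = sqrt(mean_m |x_mi - mean_m x_mi|^2)` on the residues shared by
#' all models. Models must already be in a common frame (see
#' [align_ensemble()]).
#'
#' @param aligned list of >= 2 superposed [structure_model]s.
#' @return Named numeric vector of per-residue RMSF in Angstrom.
#' @export
rmsf_profile <- function(aligned) {
  if (length(aligned) < 2) stop("RMSF needs at least 2 models")
  shared <- Reduce(intersect, lapply(aligned, `[[`, "resno"))
  if (length(shared) == 0) stop("no shared residues across ensemble")
  coords <- lapply(aligned, function(m) m$xyz[match(shared, m$resno), ,
                                              drop = FALSE])
  mean_c <- Reduce(`+`, coords) / length(coords)
  msd <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_c)^2))) /
    length(coords)
  stats::setNames(sqrt(msd), shared)
}

#' Drop low-confidence residues from a profile
#'
#' Removes residues whose pLDDT is less than or equal to `threshold`
#' (inclusive boundary: a residue at exactly the threshold is dropped).
#'
#' @param profile named numeric vector (names = residue numbers).
#' @param plddt named numeric vector of pLDDT values on the same index frame.
#' @param threshold confidence cutoff, default 75.
#' @return The filtered profile; warns if nothing survives.
#' @export
confidence_filter <- function(profile, plddt, threshold = 75) {
  shared <- intersect(names(profile), names(plddt))
  keep <- shared[plddt[shared] > threshold]
  if (length(keep) == 0)
    warning("confidence filter removed every residue")
  profile[names(profile) %in% keep]
}

#' Correlation between two per-residue profiles
#'
#' Computed on the intersection of residue indices; standard Pearson
#' definitions.
#'
#' @param x,y named numeric vectors (names = residue numbers).
#' @param kind `"pearson_r"` or `"r_squared"`.
#' @return The correlation statistic.
#' @export
profile_correlation <- function(x, y, kind = c("pearson_r", "r_squared")) {
  kind <- match.arg(kind)
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) stop("need at least 3 shared residues")
  xv <- x[shared]; yv <- y[shared]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("correlation undefined: zero variance in a profile")
  r <- stats::cor(xv, yv)
  if (kind == "pearson_r") r else r^2
}

#' Exclude misfolded models by coclustering
#'
#' Well-folded models of the same protein cluster together even when they
#' sample different conformations, whereas misfolded models virtually never
#' cocluster. Models are clustered by average-linkage agglomerative
#' clustering on pairwise Calpha RMSD (each pair optimally superposed on its
#' shared residues); the tree is cut at `linkage_cutoff` and models falling
#' in clusters smaller than `min_cluster` are excluded.
#'
#' @param ensemble list of >= 3 [structure_model]s.
#' @param linkage_cutoff tree cut height in Angstrom (RMSD) or in 1-TM units
#'   under `metric = "tm"`; default 5 Angstrom.
#' @param min_cluster smallest cluster size retained; default 3.
#' @param metric `"rmsd"` (default) or `"tm"` (distance 1 - TM-score).
#' @return An `outlier_report`: list with `kept` (model ids), `excluded`
#'   (data frame of model_id, reason) and `cluster_labels` (named integer
#'   vector).
#' @export
filter_misfolded <- function(ensemble, linkage_cutoff = 5, min_cluster = 3,
                             metric = c("rmsd", "tm")) {
  metric <- match.arg(metric)
  n <- length(ensemble)
  if (n < 3) stop("need at least 3 models to detect outliers")
  ids <- vapply(ensemble, `[[`, character(1), "model_id")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      map <- match_by_resno(ensemble[[i]], ensemble[[j]])
      if (metric == "rmsd") {
        d[i, j] <- kabsch(ensemble[[i]]$xyz[map$ia, , drop = FALSE],
                          ensemble[[j]]$xyz[map$ib, , drop = FALSE])$rmsd
      } else {
        d[i, j] <- 1 - tm_score(ensemble[[i]], ensemble[[j]], map)$score
      }
      d[j, i] <- d[i, j]
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, h = linkage_cutoff)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_cluster])
  excluded_ids <- ids[labels %in% small]
  structure(list(
    kept = setdiff(ids, excluded_ids),
    excluded = data.frame(
      model_id = excluded_ids,
      reason = rep("singleton/undersized cluster", length(excluded_ids)),
      stringsAsFactors = FALSE),
    cluster_labels = stats::setNames(as.integer(labels), ids)),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d kept, %d excluded, %d cluster(s)\n",
              length(x$kept), nrow(x$excluded),
              length(unique(x$cluster_labels))))
  invisible(x)
}
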