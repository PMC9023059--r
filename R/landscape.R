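#' Secondary-structure residue mask from Calpha geometry
#'
#' Flags residues as helix/strand using inter-Calpha distance signatures
#' (helical turns give d(i, i+4) of about 5-7 Angstrom; extended strands give
#' d(i, i+2) above about 6.3 Angstrom). Loop residues - everything else - are
#' the ones conventionally omitted from coordinate PCA because their
#' heterogeneity swamps the collective motions of interest. This is a
#' deliberately coarse heuristic; user-supplied masks override it wherever a
#' mask is accepted.
#'
#' @param model a [structure_model].
#' @return Integer vector of residue numbers annotated helix or strand.
#' @export
ss_mask <- function(model) {
  x <- model$xyz
  n <- nrow(x)
  dist_k <- function(k) {
    d <- rep(NA_real_, n)
    if (n > k)
      d[seq_len(n - k)] <-
        sqrt(rowSums((x[seq_len(n - k) + k, , drop = FALSE] -
                        x[seq_len(n - k), , drop = FALSE])^2))
    d
  }
  d2 <- dist_k(2); d4 <- dist_k(4)
  helix <- !is.na(d4) & d4 > 4.5 & d4 < 7.2
  strand <- !is.na(d2) & d2 > 6.3
  core <- helix | strand
  ## a residue is structured if any covering window is
  mask <- rep(FALSE, n)
  for (i in which(helix)) mask[i:min(n, i + 4)] <- TRUE
  for (i in which(strand)) mask[i:min(n, i + 2)] <- TRUE
  if (!any(mask)) mask <- rep(TRUE, n)   # degenerate trace: keep everything
  model$resno[mask]
}

#' Principal component analysis of an aligned Calpha ensemble
#'
#' Eigendecomposition of the coordinate covariance over models, on the
#' flattened 3N-vector of masked Calpha coordinates. The models must already
#' be in a common frame (see [align_ensemble()]); no re-superposition happens
#' here, so an exactly collinear ensemble yields an exactly rank-one
#' landscape. Components are sorted by variance; projections are centered on
#' the ensemble mean. Loop residues are excluded by default via [ss_mask()].
#'
#' @param aligned list of >= 3 [structure_model]s in a common frame (see
#'   [align_ensemble()]).
#' @param mask residue numbers to include; `NULL` applies [ss_mask()] to the
#'   ensemble mean structure.
#' @return A `landscape`: list with `mean_coords` (flattened masked mean),
#'   `components` (3m x k orthonormal basis), `variance_fractions`,
#'   `projections` (n x k matrix, rownames = model ids), `mask` (residue
#'   numbers used) and `models` (the input models).
#' @export
fit_landscape <- function(aligned, mask = NULL) {
  if (length(aligned) < 3) stop("need at least 3 models for a landscape")
  shared <- Reduce(intersect, lapply(aligned, `[[`, "resno"))
  if (is.null(mask)) {
    mean_model <- aligned[[1]]
    mean_model$xyz <- Reduce(`+`, lapply(aligned, function(m)
      m$xyz[match(shared, m$resno), , drop = FALSE])) / length(aligned)
    mean_model$resno <- shared
    mask <- ss_mask(mean_model)
  }
  mask <- intersect(shared, mask)
  if (length(mask) == 0) stop("empty residue mask")
  coords <- t(vapply(aligned, function(m)
    as.vector(t(m$xyz[match(mask, m$resno), , drop = FALSE])),
    numeric(3 * length(mask))))
  rownames(coords) <- vapply(aligned, `[[`, character(1), "model_id")
  mean_coords <- colMeans(coords)
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  k <- sum(pc$sdev > 1e-12 * max(pc$sdev, 1e-300))
  k <- max(k, 1L)
  comps <- pc$rotation[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    ld <- comps[, j]
    if (ld[which.max(abs(ld))] < 0) {
      comps[, j] <- -ld
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  structure(list(mean_coords = mean_coords, components = comps,
                 variance_fractions = vf,
                 projections = pc$x[, seq_len(k), drop = FALSE],
                 mask = mask, models = aligned),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "landscape: %d models, %d masked residues; PC1 %.1f%% of variance\n",
    nrow(x$projections), length(x$mask), 100 * x$variance_fractions[1]))
  invisible(x)
}

#' Project a reference structure into a landscape
#'
#' Projects the reference's centered masked Calpha vector onto the component
#' basis. The landscape is fit on models only; references are projected
#' afterwards. By default the reference is first superposed onto the
#' ensemble mean on the masked residues; pass `superpose = FALSE` for a
#' structure already in the landscape frame (e.g. a member of the aligned
#' ensemble, whose projection then reproduces its stored value exactly).
#'
#' @param landscape a [fit_landscape()] result.
#' @param reference a [structure_model].
#' @param map optional `residue_map` from the reference to the ensemble's
#'   residue-number frame; `NULL` matches residue numbers directly.
#' @param superpose superpose onto the ensemble mean before projecting.
#' @return Numeric vector of component coordinates (PC1, PC2, ...).
#' @export
project_reference <- function(landscape, reference, map = NULL,
                              superpose = TRUE) {
  mask <- landscape$mask
  if (is.null(map)) {
    idx <- match(mask, reference$resno)
    if (anyNA(idx))
      stop("reference is missing masked residues: ",
           paste(mask[is.na(idx)], collapse = ", "))
  } else {
    ens_resno <- landscape$models[[1]]$resno[map$ib]
    idx <- map$ia[match(mask, ens_resno)]
    if (anyNA(idx))
      stop("reference map does not cover masked residues: ",
           paste(mask[is.na(idx)], collapse = ", "))
  }
  ref_xyz <- reference$xyz[idx, , drop = FALSE]
  if (superpose) {
    mean_xyz <- matrix(landscape$mean_coords, ncol = 3, byrow = TRUE)
    ref_xyz <- apply_superposition(ref_xyz, kabsch(mean_xyz, ref_xyz))
  }
  v <- as.vector(t(ref_xyz)) - landscape$mean_coords
  as.vector(v %*% landscape$components)
}

#' Orient a landscape so a reference projects negative on PC1
#'
#' TM-score and PCA are both sign-blind; fixing the first-listed reference to
#' the negative side of PC1 makes reports deterministic and comparable.
#'
#' @param landscape a [fit_landscape()] result.
#' @param reference a [structure_model] (typically the first reference).
#' @param map optional `residue_map` as in [project_reference()].
#' @return The landscape, with PC1 flipped if needed.
#' @export
orient_landscape <- function(landscape, reference, map = NULL) {
  p1 <- project_reference(landscape, reference, map)[1]
  if (p1 > 0) {
    landscape$components[, 1] <- -landscape$components[, 1]
    landscape$projections[, 1] <- -landscape$projections[, 1]
  }
  landscape
}

#' Select models at the extremes of PC1
#'
#' The models at the outer edges of the first principal component are
#' enriched in accurate representatives of the end-state conformations, so
#' picking the top-k extremes on each side is the selection rule for
#' candidate alternative-state models.
#'
#' @param landscape a [fit_landscape()] result.
#' @param k number of models to select (0 returns an empty vector).
#' @param side `"high"` or `"low"` end of PC1.
#' @return Character vector of model ids, outermost first; ties broken by
#'   model id (lexicographic).
#' @export
select_extremes <- function(landscape, k, side = c("high", "low")) {
  side <- match.arg(side)
  if (k == 0) return(character(0))
  pc1 <- landscape$projections[, 1]
  if (k > length(pc1)) stop("k exceeds the number of models")
  ids <- rownames(landscape$projections)
  ord <- if (side == "high") order(-pc1, ids) else order(pc1, ids)
  ids[ord][seq_len(k)]
}

#' Pearson correlation between PC1 and TM-score
#'
#' @param landscape a [fit_landscape()] result.
#' @param tm_by_model named numeric vector of TM-scores (names = model ids).
#' @return Pearson's r.
#' @export
pc_tm_correlation <- function(landscape, tm_by_model) {
  ids <- intersect(rownames(landscape$projections), names(tm_by_model))
  if (length(ids) < 3) stop("need at least 3 models with both values")
  pc1 <- landscape$projections[ids, 1]
  tm <- tm_by_model[ids]
  if (stats::sd(pc1) == 0 || stats::sd(tm) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(pc1, tm)
}
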