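#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation taking `coords_b`
#' onto `coords_a`, via singular value decomposition of the cross-covariance
#' matrix. Reflections are excluded by construction, so chiral point sets are
#' never mirrored.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates, n >= 3.
#' @return A `superposition`: list with `rotation` (3 x 3 proper orthogonal
#'   matrix), `translation` (length-3 vector), `rmsd` (Angstrom) and
#'   `n_atoms`. A transformed point is `x %*% rotation + translation` for a
#'   row vector `x`.
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 3) stop("need at least 3 points for a superposition")
  ma <- colMeans(a); mb <- colMeans(b)
  ac <- sweep(a, 2, ma); bc <- sweep(b, 2, mb)
  h <- crossprod(bc, ac)                      # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- ma - as.vector(mb %*% rot)
  fitted <- bc %*% rot
  rmsd <- sqrt(mean(rowSums((ac - fitted)^2)))
  structure(list(rotation = rot, translation = trans,
                 rmsd = rmsd, n_atoms = nrow(a)),
            class = "superposition")
}

#' Apply a superposition to coordinates or a model
#'
#' @param x an n x 3 coordinate matrix or a [structure_model].
#' @param sp a `superposition` from [kabsch()].
#' @return `x` with transformed coordinates.
#' @export
apply_superposition <- function(x, sp) {
  stopifnot(inherits(sp, "superposition"))
  if (inherits(x, "structure_model")) {
    x$xyz <- sweep(x$xyz %*% sp$rotation, 2, sp$translation, "+")
    return(x)
  }
  sweep(as.matrix(x) %*% sp$rotation, 2, sp$translation, "+")
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom.
#'
#' @param l_ref normalization length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref) {
  x <- l_ref - 15
  d0 <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  max(d0, 0.5)
}

#' TM-score of a model against a reference
#'
#' Computes `TM = (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)` maximized over
#' rigid superpositions of the mapped Calpha pairs, with the standard
#' length-dependent distance scale `d0(L_ref)`. Residue correspondence comes
#' from a precomputed map (sequence-based), never from a structural alignment
#' search. Maximization uses the standard iterative scheme: superpositions
#' are seeded from contiguous fragments (full length, halves, quarters,
#' minimum 4 residues); each seed alternates between superposing on the
#' current inlier set and recomputing inliers under a shrinking distance
#' cutoff until stable; the best score over all seeds and iterations is
#' reported.
#'
#' @param reference,model [structure_model]s.
#' @param map a `residue_map` from [correspond()] or [match_by_resno()];
#'   `NULL` matches by residue number.
#' @param length_norm normalization length `L_ref`; defaults to the
#'   reference's mapped-residue count. TM-score is asymmetric in this choice,
#'   so reports should state it.
#' @param cutoff_schedule multipliers of `d0` used as inlier distance cutoffs
#'   across iterations (shrinking toward `d0/2`).
#' @param max_iter iteration cap per seed.
#' @return A `tm_result`: list with `score`, `d0`, `reference_length`,
#'   `aligned_pairs` and the best `superposition`.
#' @export
tm_score <- function(reference, model, map = NULL, length_norm = NULL,
                     cutoff_schedule = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                     max_iter = 20) {
  if (is.null(map)) map <- match_by_resno(reference, model)
  n <- nrow(map)
  if (n < 5) stop("residue map too small for TM-score (need >= 5 pairs)")
  ra <- reference$xyz[map$ia, , drop = FALSE]
  rb <- model$xyz[map$ib, , drop = FALSE]
  l_ref <- if (is.null(length_norm)) n else length_norm
  d0 <- tm_d0(l_ref)

  tm_sum <- function(sp) {
    d2 <- rowSums((ra - apply_superposition(rb, sp))^2)
    sum(1 / (1 + d2 / d0^2))
  }

  ## seed fragments: full, halves, quarters (contiguous, >= 4 residues)
  seeds <- list(c(1L, n))
  for (parts in c(2L, 4L)) {
    len <- n %/% parts
    if (len >= 4) {
      for (p in seq_len(parts))
        seeds[[length(seeds) + 1L]] <-
          c((p - 1L) * len + 1L, if (p == parts) n else p * len)
    }
  }

  best <- -Inf; best_sp <- NULL
  for (sd in seeds) {
    idx <- sd[1]:sd[2]
    sp <- kabsch(ra[idx, , drop = FALSE], rb[idx, , drop = FALSE])
    s <- tm_sum(sp)
    if (s > best) { best <- s; best_sp <- sp }
    prev_idx <- idx
    for (it in seq_len(max_iter)) {
      mult <- cutoff_schedule[min(it, length(cutoff_schedule))]
      d <- sqrt(rowSums((ra - apply_superposition(rb, sp))^2))
      inliers <- which(d < mult * d0)
      if (length(inliers) < 4)
        inliers <- order(d)[seq_len(4)]
      if (identical(inliers, prev_idx) && it > length(cutoff_schedule)) break
      sp <- kabsch(ra[inliers, , drop = FALSE], rb[inliers, , drop = FALSE])
      s <- tm_sum(sp)
      if (s > best) { best <- s; best_sp <- sp }
      prev_idx <- inliers
    }
  }
  structure(list(score = best / l_ref, d0 = d0, reference_length = l_ref,
                 aligned_pairs = n, superposition = best_sp),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("TM-score %.4f (d0 %.2f A, L_ref %d, %d aligned pairs)\n",
              x$score, x$d0, x$reference_length, x$aligned_pairs))
  invisible(x)
}

#' Superpose an ensemble into a common frame
#'
#' Either superposes every model on a chosen reference model, or (default)
#' performs iterative mean-structure alignment: superpose all models on the
#' current mean structure, recompute the mean, and repeat until the mean
#' moves less than `tol` (RMSD, Angstrom). Models must share residue numbers
#' on a non-empty intersection; alignment uses that shared set and transforms
#' whole models.
#'
#' @param ensemble list of [structure_model]s.
#' @param reference_policy `"mean"` (iterative mean alignment, default) or
#'   `"model"` (superpose on the model at `ref_index`).
#' @param ref_index index of the reference model under policy `"model"`.
#' @param tol convergence threshold on mean movement (Angstrom).
#' @param max_iter iteration cap for the mean-structure loop.
#' @param resno_subset optional residue numbers restricting the fit (models
#'   are still transformed in full).
#' @return list of superposed [structure_model]s, same order and ids.
#' @export
align_ensemble <- function(ensemble, reference_policy = c("mean", "model"),
                           ref_index = 1, tol = 1e-6, max_iter = 100,
                           resno_subset = NULL) {
  reference_policy <- match.arg(reference_policy)
  if (length(ensemble) == 0) stop("empty ensemble")
  shared <- Reduce(intersect, lapply(ensemble, `[[`, "resno"))
  if (!is.null(resno_subset)) shared <- intersect(shared, resno_subset)
  if (length(shared) < 3) stop("shared residue set too small for alignment")
  coords_on <- function(m) m$xyz[match(shared, m$resno), , drop = FALSE]

  fit_all <- function(ens, target) {
    lapply(ens, function(m) {
      apply_superposition(m, kabsch(target, coords_on(m)))
    })
  }

  if (reference_policy == "model") {
    return(fit_all(ensemble, coords_on(ensemble[[ref_index]])))
  }
  aligned <- fit_all(ensemble, coords_on(ensemble[[1]]))
  mean_c <- Reduce(`+`, lapply(aligned, coords_on)) / length(aligned)
  for (it in seq_len(max_iter)) {
    aligned <- fit_all(aligned, mean_c)
    new_mean <- Reduce(`+`, lapply(aligned, coords_on)) / length(aligned)
    move <- sqrt(mean(rowSums((new_mean - mean_c)^2)))
    mean_c <- new_mean
    if (move < tol) break
  }
  aligned
}
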