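## Independent oracles used to freeze expected values. Each deliberately
## avoids the code path it checks: enumeration instead of dynamic
## programming, random-restart direct maximization instead of the iterative
## inlier scheme, rotation grids instead of SVD.

## ---- exhaustive global alignment ------------------------------------------
## Enumerates every global alignment of two short sequences and scores it
## with BLOSUM62 and affine gaps costing (open + len * ext) per gap run.
## Returns the maximum score and the identities (over alignment length) of
## all maximum-scoring alignments.
enumerate_alignments <- function(a, b, open = 11, ext = 1) {
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  results <- new.env()
  results$best <- -Inf
  results$idents <- numeric(0)
  walk <- function(i, j, score, len, ident, state) {
    if (i > length(av) && j > length(bv)) {
      if (score > results$best + 1e-9) {
        results$best <- score
        results$idents <- ident / len
      } else if (abs(score - results$best) <= 1e-9) {
        results$idents <- c(results$idents, ident / len)
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      walk(i + 1, j + 1, score + mat[av[i], bv[j]], len + 1,
           ident + (av[i] == bv[j]), "m")
    }
    if (i <= length(av)) {       # gap in b
      pen <- ext + if (state == "gb") 0 else open
      walk(i + 1, j, score - pen, len + 1, ident, "gb")
    }
    if (j <= length(bv)) {       # gap in a
      pen <- ext + if (state == "ga") 0 else open
      walk(i, j + 1, score - pen, len + 1, ident, "ga")
    }
  }
  walk(1, 1, 0, 0, 0, "start")
  list(score = results$best, identities = 100 * results$idents)
}

## ---- rigid-motion helpers --------------------------------------------------
rotmat_axis_angle <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}

## ---- dense rotation-grid RMSD oracle (for Kabsch) --------------------------
## Minimizes RMSD over proper rotations by axis-angle grid search plus local
## refinement; translation handled by centroid matching.
grid_min_rmsd <- function(a, b, n_axis = 60, n_angle = 36) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rmsd_of <- function(p) {
    th <- sqrt(sum(p^2))
    r <- if (th < 1e-12) diag(3) else rotmat_axis_angle(p / th, th)
    sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
  }
  set.seed(424242)
  axes <- matrix(stats::rnorm(3 * n_axis), ncol = 3)
  axes <- axes / sqrt(rowSums(axes^2))
  angles <- seq(0, 2 * pi, length.out = n_angle + 1)[-1]
  best <- rmsd_of(c(0, 0, 0)); best_p <- c(0, 0, 0)
  for (i in seq_len(n_axis)) {
    for (th in angles) {
      p <- axes[i, ] * th
      v <- rmsd_of(p)
      if (v < best) { best <- v; best_p <- p }
    }
  }
  opt <- stats::optim(best_p, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best, opt$value)
}

## ---- random-restart TM maximization oracle ---------------------------------
## Maximizes the TM sum over rigid transforms of the model directly, by
## Nelder-Mead from many random rigid starting points. Independent of the
## fragment-seeded iterative inlier scheme.
tm_oracle <- function(ref_xyz, mod_xyz, d0, n_restarts = 60, seed = 99) {
  l <- nrow(ref_xyz)
  neg_tm <- function(p) {
    th <- sqrt(sum(p[1:3]^2))
    r <- if (th < 1e-12) diag(3) else rotmat_axis_angle(p[1:3] / th, th)
    moved <- sweep(mod_xyz %*% t(r), 2, p[4:6], "+")
    -sum(1 / (1 + rowSums((ref_xyz - moved)^2) / d0^2))
  }
  set.seed(seed)
  center_shift <- colMeans(ref_xyz) - colMeans(mod_xyz)
  best <- Inf
  for (k in seq_len(n_restarts)) {
    p0 <- c(stats::rnorm(3, sd = 1.5), center_shift + stats::rnorm(3, sd = 2))
    opt <- stats::optim(p0, neg_tm, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    if (opt$value < best) best <- opt$value
  }
  -best / l
}

## ---- small builders --------------------------------------------------------
toy_model <- function(id, xyz, resno = seq_len(nrow(xyz)),
                      aa = rep("A", nrow(xyz)), plddt = NULL) {
  structure_model(id, resno, aa, xyz, plddt)
}

random_coords <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = scale), n, 3)
}

## rigidly move a coordinate matrix (deterministic in seed)
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  r <- rotmat_axis_angle(stats::rnorm(3), stats::runif(1, 0.3, 2.8))
  sweep(xyz %*% t(r), 2, stats::rnorm(3, sd = 8), "+")
}
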