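test_that("kabsch recovers constructed rigid motions exactly", {
  a <- random_coords(12, 1)
  rot <- rotmat_axis_angle(c(0, 0, 1), pi / 2)
  b <- sweep(a %*% t(rot), 2, c(1, 2, 3), "+")
  sp <- kabsch(a, b)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(apply_superposition(b, sp), a, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  ## recovered rotation inverts the applied one
  expect_equal(sp$rotation, rot, tolerance = 1e-9)

  sp_id <- kabsch(a, a)
  expect_equal(sp_id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp_id$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(sp_id$rmsd, 1e-12)

  expect_error(kabsch(a, a[1:5, ]), "differ in length")
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("kabsch agrees with an independent implementation on random pairs", {
  for (seed in 1:5) {
    a <- random_coords(20, seed)
    b <- random_coords(20, seed + 100, scale = 8)
    sp <- kabsch(a, b)
    ## bio3d fits vector-format coordinates; use it as the cross-check
    fitted <- bio3d::fit.xyz(fixed = as.vector(t(a)),
                             mobile = as.vector(t(b)),
                             fixed.inds = 1:60, mobile.inds = 1:60)
    rmsd_bio3d <- sqrt(mean(rowSums(
      (a - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
    expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
  }
})

test_that("mirror images stay chiral: proper rotation beats reflection", {
  ## chiral 4-point set and its mirror image
  a <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 3.8, 3.8, 3.8),
              ncol = 3, byrow = TRUE)
  b <- a %*% diag(c(1, 1, -1))
  sp <- kabsch(a, b)
  expect_gt(sp$rmsd, 0.1)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  ## dense rotation-grid oracle finds the same proper-rotation minimum
  expect_equal(sp$rmsd, grid_min_rmsd(a, b), tolerance = 1e-3)
})

test_that("kabsch RMSD matches the closed form for a planar 3-point case", {
  ## equilateral triangle vs the same triangle with one vertex pulled out:
  ## optimal fit is in-plane; solved analytically by symmetry for this pair
  a <- matrix(c(1, 0, 0, -0.5, sqrt(3) / 2, 0, -0.5, -sqrt(3) / 2, 0),
              ncol = 3, byrow = TRUE)
  b <- a; b[1, 1] <- 1 + 0.3   # stretch one vertex radially by delta
  ## centroids differ by (delta/3, 0, 0); by symmetry the optimal rotation is
  ## the identity, so rmsd^2 = mean of squared residuals after centering
  delta <- 0.3
  resid <- rbind(c(delta - delta / 3, 0, 0),
                 c(-delta / 3, 0, 0), c(-delta / 3, 0, 0))
  expect_equal(kabsch(a, b)$rmsd, sqrt(mean(rowSums(resid^2))),
               tolerance = 1e-9)
})

test_that("TM-score is 1 for rigid copies and invariant under rigid motions", {
  sp <- fixture_spec(seed = 4)
  es <- make_end_states(sp)
  ref <- es$stateA
  copy <- ref
  copy$xyz <- random_rigid(ref$xyz, 21)
  expect_equal(tm_score(ref, copy)$score, 1, tolerance = 1e-9)
  expect_equal(tm_score(ref, ref)$score, 1, tolerance = 1e-12)

  base <- tm_score(ref, es$stateB)$score
  moved_model <- es$stateB; moved_model$xyz <- random_rigid(moved_model$xyz, 22)
  moved_ref <- ref; moved_ref$xyz <- random_rigid(ref$xyz, 23)
  expect_equal(tm_score(ref, moved_model)$score, base, tolerance = 1e-6)
  expect_equal(tm_score(moved_ref, es$stateB)$score, base, tolerance = 1e-6)
})

test_that("d0 follows the published length dependence", {
  expect_equal(tm_d0(120), 1.24 * (120 - 15)^(1 / 3) - 1.8)
  expect_equal(tm_d0(15), 0.5)   # clamped
  expect_equal(tm_d0(20), max(0.5, 1.24 * 5^(1 / 3) - 1.8))
})

test_that("normalization uses the mapped reference length", {
  sp <- fixture_spec(seed = 4)
  ref <- make_end_states(sp)$stateA
  half <- structure_model("half", ref$resno[1:30], ref$aa[1:30],
                          ref$xyz[1:30, ], ref$plddt[1:30])
  res <- tm_score(ref, half)
  expect_equal(res$reference_length, 30)
  expect_equal(res$aligned_pairs, 30)
  expect_equal(res$score, 1, tolerance = 1e-9)
  ## explicit full-length normalization halves the self-score
  expect_equal(tm_score(ref, half, length_norm = 60)$score, 0.5,
               tolerance = 1e-6)
  expect_error(tm_score(ref, structure_model("tiny", 1:4, ref$aa[1:4],
                                             ref$xyz[1:4, ])),
               "too small")
})

test_that("iterative TM maximization matches a random-restart oracle", {
  ## 20-residue toy with a 5-residue segment swung ~10 A out
  set.seed(31)
  a <- cbind(seq(0, by = 3.8, length.out = 20), 0, 0) +
    matrix(rnorm(60, sd = 0.3), 20, 3)
  b <- a
  swing <- rotmat_axis_angle(c(0, 0, 1), 1.2)
  b[8:12, ] <- sweep(sweep(b[8:12, ], 2, b[8, ]) %*% t(swing), 2, b[8, ], "+")
  ref <- toy_model("ref", a); mod <- toy_model("mod", b)
  got <- tm_score(ref, mod)
  oracle <- tm_oracle(a, b, got$d0)
  expect_equal(got$score, oracle, tolerance = 1e-3)
  expect_gte(got$score + 1e-3, oracle)   # never below the oracle optimum

  ## second toy: hinge fixture end states, 30-residue truncation
  es <- make_end_states(fixture_spec(seed = 8))
  ref2 <- toy_model("r", es$stateA$xyz[1:30, ])
  mod2 <- toy_model("m", es$stateB$xyz[1:30, ])
  got2 <- tm_score(ref2, mod2)
  expect_equal(got2$score, tm_oracle(ref2$xyz, mod2$xyz, got2$d0, seed = 7),
               tolerance = 1e-3)
})

test_that("TM-score degrades monotonically with added noise", {
  es <- make_end_states(fixture_spec(seed = 10))
  ref <- es$stateA
  set.seed(55)
  scores <- vapply(c(0.25, 0.75, 1.5, 3, 6), function(sigma) {
    m <- ref
    m$xyz <- m$xyz + matrix(rnorm(length(m$xyz), sd = sigma), ncol = 3)
    tm_score(ref, m)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("ensemble alignment collapses rigid copies and beats single-reference policies", {
  sp <- fixture_spec(seed = 14)
  base <- make_end_states(sp)$stateA
  copies <- lapply(1:5, function(i) {
    m <- base; m$model_id <- paste0("copy_", i)
    m$xyz <- random_rigid(base$xyz, 30 + i)
    m
  })
  al <- align_ensemble(copies)
  for (m in al[-1]) expect_equal(m$xyz, al[[1]]$xyz, tolerance = 1e-6)

  ## two-model case: equal RMSD from each model to the mean
  two <- align_ensemble(list(make_end_states(sp)$stateA,
                             make_end_states(sp)$stateB))
  mean_xyz <- (two[[1]]$xyz + two[[2]]$xyz) / 2
  r1 <- sqrt(mean(rowSums((two[[1]]$xyz - mean_xyz)^2)))
  r2 <- sqrt(mean(rowSums((two[[2]]$xyz - mean_xyz)^2)))
  expect_equal(r1, r2, tolerance = 1e-6)

  ## iterative-mean alignment minimizes total ensemble variance
  ens <- make_ensemble(fixture_spec(seed = 17, n_models = 50))$ensemble[1:50]
  total_var <- function(al) {
    coords <- lapply(al, `[[`, "xyz")
    mu <- Reduce(`+`, coords) / length(coords)
    sum(vapply(coords, function(x) sum((x - mu)^2), numeric(1)))
  }
  v_mean <- total_var(align_ensemble(ens))
  for (ref_i in c(1, 10, 25)) {
    v_single <- total_var(align_ensemble(ens, "model", ref_index = ref_i))
    expect_lte(v_mean, v_single + 1e-6)
  }
})
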