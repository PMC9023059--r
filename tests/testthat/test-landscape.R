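test_that("noiseless interpolation gives an exactly rank-one landscape", {
  ens <- make_ensemble(fixture_spec(frac_intermediate = 1, noise_sigma = 0,
                                    n_decoys = 0, n_models = 20, seed = 3))
  ls <- fit_landscape(ens$ensemble, mask = 1:60)
  expect_equal(ls$variance_fractions[1], 1.0, tolerance = 1e-8)
})

test_that("two orthogonal modes with 9:1 variance are recovered exactly", {
  ## build an ensemble as mean + a*v1 + b*v2 with orthonormal coordinate
  ## modes and coefficient variances exactly 9 and 1
  n_res <- 20; n_mod <- 16
  base <- random_coords(n_res, 6, scale = 12)
  set.seed(7)
  v1 <- rnorm(3 * n_res); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(3 * n_res); v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  norm_coef <- function(x) {                   # exact sample variance 1
    x <- x - mean(x); x / sqrt(sum(x^2) / (length(x) - 1))
  }
  a <- 3 * norm_coef(rnorm(n_mod))             # variance 9
  b <- rnorm(n_mod)
  b <- b - mean(b)
  b <- norm_coef(b - a * sum(a * b) / sum(a^2))  # variance 1, orthogonal to a
  ens <- lapply(seq_len(n_mod), function(m) {
    xyz <- base + matrix(a[m] * v1 + b[m] * v2, ncol = 3, byrow = TRUE)
    toy_model(sprintf("m%02d", m), xyz)
  })
  ls <- fit_landscape(ens, mask = 1:n_res)
  expect_equal(ls$variance_fractions[1:2], c(0.9, 0.1), tolerance = 1e-6)
  ## eigen-oracle on the constructed covariance agrees
  coords <- t(vapply(ens, function(m) as.vector(t(m$xyz)),
                     numeric(3 * n_res)))
  ev <- eigen(stats::cov(coords), symmetric = TRUE)$values
  expect_equal(ls$variance_fractions[1:2], ev[1:2] / sum(ev),
               tolerance = 1e-9)
  ## PC1 recovers the injected dominant mode
  expect_gt(abs(sum(ls$components[, 1] * v1)), 0.999999)
})

test_that("components are orthonormal and reconstruction is exact", {
  ens <- make_ensemble(fixture_spec(seed = 9, n_decoys = 0,
                                    n_models = 12))$ensemble
  al <- align_ensemble(ens)
  ls <- fit_landscape(al, mask = 1:60)
  g <- unname(crossprod(ls$components))
  expect_equal(g, diag(ncol(ls$components)), tolerance = 1e-8)
  expect_equal(sum(ls$variance_fractions), 1, tolerance = 1e-8)
  expect_true(all(diff(ls$variance_fractions) <= 1e-12))
  ## reconstruct model 5 from all components
  x5 <- as.vector(t(al[[5]]$xyz))
  recon <- ls$mean_coords + as.vector(ls$components %*% ls$projections[5, ])
  expect_equal(recon, x5, tolerance = 1e-6)
})

test_that("the ensemble mean projects to the origin", {
  ens <- make_ensemble(fixture_spec(seed = 11, n_decoys = 0,
                                    n_models = 10))$ensemble
  al <- align_ensemble(ens)
  ls <- fit_landscape(al, mask = 1:60)
  expect_lt(max(abs(colMeans(ls$projections))), 1e-9)
  mean_model <- al[[1]]
  mean_model$xyz <- Reduce(`+`, lapply(al, `[[`, "xyz")) / length(al)
  p <- project_reference(ls, mean_model, superpose = FALSE)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("references flank the models on PC1 in the interpolation regime", {
  ens <- make_ensemble(fixture_spec(frac_intermediate = 1, noise_sigma = 0.5,
                                    n_decoys = 0, seed = 7))
  al <- align_ensemble(ens$ensemble)
  ls <- fit_landscape(al, mask = 1:60)
  pa <- project_reference(ls, ens$end_states$stateA)[1]
  pb <- project_reference(ls, ens$end_states$stateB)[1]
  expect_lt(pa * pb, 0)           # opposite signs
  expect_lt(min(pa, pb), min(ls$projections[, 1]))
  expect_gt(max(pa, pb), max(ls$projections[, 1]))
})

test_that("PC1 recovers the injected hinge mode when noise is small", {
  ens <- make_ensemble(fixture_spec(frac_intermediate = 1, noise_sigma = 0.5,
                                    n_decoys = 0, seed = 7))
  al <- align_ensemble(ens$ensemble)
  ls <- fit_landscape(al, mask = 1:60)
  ## injected mode: end-state difference expressed in the landscape frame
  mean_xyz <- matrix(ls$mean_coords, ncol = 3, byrow = TRUE)
  in_frame <- function(m)
    apply_superposition(m$xyz, kabsch(mean_xyz, m$xyz))
  mode <- as.vector(t(in_frame(ens$end_states$stateB))) -
    as.vector(t(in_frame(ens$end_states$stateA)))
  mode <- mode / sqrt(sum(mode^2))
  expect_gte(abs(sum(mode * ls$components[, 1])), 0.99)
})

test_that("projection of an ensemble member reproduces its stored value", {
  ens <- make_ensemble(fixture_spec(seed = 15, n_decoys = 0,
                                    n_models = 8))$ensemble
  al <- align_ensemble(ens)
  ls <- fit_landscape(al, mask = 1:60)
  for (i in c(1, 4, 8)) {
    p <- project_reference(ls, al[[i]], superpose = FALSE)
    expect_equal(p, unname(ls$projections[i, ]), tolerance = 1e-9)
  }
  ## missing masked residues are reported
  short <- structure_model("short", 1:30, al[[1]]$aa[1:30],
                           al[[1]]$xyz[1:30, ])
  expect_error(project_reference(ls, short), "missing masked residues")
})

test_that("the landscape is invariant (up to sign) under a common rigid motion", {
  ens <- make_ensemble(fixture_spec(seed = 18, n_decoys = 0,
                                    n_models = 10))$ensemble
  al <- align_ensemble(ens)
  ls1 <- fit_landscape(al, mask = 1:60)
  rot <- rotmat_axis_angle(c(0, 1, 1), 1.1)
  moved <- lapply(ens, function(m) {
    m$xyz <- sweep(m$xyz %*% t(rot), 2, c(5, -3, 2), "+"); m
  })
  ls2 <- fit_landscape(align_ensemble(moved), mask = 1:60)
  expect_equal(ls2$variance_fractions, ls1$variance_fractions,
               tolerance = 1e-8)
  expect_equal(abs(ls2$projections[, 1]), abs(ls1$projections[, 1]),
               tolerance = 1e-6)
})

test_that("orientation convention puts the first reference on the negative side", {
  ens <- make_ensemble(fixture_spec(seed = 5, n_decoys = 0))
  al <- align_ensemble(ens$ensemble)
  ls <- orient_landscape(fit_landscape(al, mask = 1:60),
                         ens$end_states$stateA)
  expect_lt(project_reference(ls, ens$end_states$stateA)[1], 0)
})

test_that("extreme-model selection sorts, breaks ties and degenerates correctly", {
  ls <- structure(list(projections = matrix(
    c(-3, -1, 0, 2, 5), ncol = 1,
    dimnames = list(c("m1", "m2", "m3", "m4", "m5"), "PC1"))),
    class = "landscape")
  expect_equal(select_extremes(ls, 1, "high"), "m5")
  expect_equal(select_extremes(ls, 1, "low"), "m1")
  expect_equal(select_extremes(ls, 5, "high"),
               c("m5", "m4", "m3", "m2", "m1"))
  expect_equal(select_extremes(ls, 0, "high"), character(0))
  expect_error(select_extremes(ls, 6, "high"), "exceeds")
  ## ties broken lexicographically by model id
  ls$projections <- matrix(c(2, 2, 1), ncol = 1,
                           dimnames = list(c("b", "a", "c"), "PC1"))
  expect_equal(select_extremes(ls, 2, "high"), c("a", "b"))
})

test_that("extreme PC1 models are the most accurate for their end state", {
  ens <- make_ensemble(fixture_spec(seed = 13))
  rep <- filter_misfolded(ens$ensemble)
  kept <- ens$ensemble[vapply(ens$ensemble, `[[`, character(1),
                              "model_id") %in% rep$kept]
  al <- align_ensemble(kept)
  ls <- orient_landscape(fit_landscape(al), ens$end_states$stateA)
  tm_best <- vapply(kept, function(m)
    max(tm_score(ens$end_states$stateA, m)$score,
        tm_score(ens$end_states$stateB, m)$score), numeric(1))
  names(tm_best) <- vapply(kept, `[[`, character(1), "model_id")
  med <- stats::median(tm_best)
  for (k in c(1, 3, 10)) {
    sel <- c(select_extremes(ls, k, "low"), select_extremes(ls, k, "high"))
    expect_gt(mean(tm_best[sel]), med)
  }
})

test_that("PC1-TM correlation matches the definitional formula and nulls", {
  ens <- make_ensemble(fixture_spec(seed = 13, n_decoys = 0))
  al <- align_ensemble(ens$ensemble)
  ls <- orient_landscape(fit_landscape(al, mask = 1:60),
                         ens$end_states$stateA)
  ## affine function of PC1 gives |r| = 1
  pc1 <- ls$projections[, 1]
  tm_aff <- stats::setNames(0.9 - 0.01 * pc1, rownames(ls$projections))
  expect_equal(abs(pc_tm_correlation(ls, tm_aff)), 1, tolerance = 1e-12)

  ## hand-listed 5-point example against the definitional formula
  ls5 <- structure(list(projections = matrix(
    c(-2, -1, 0, 1, 2), ncol = 1,
    dimnames = list(paste0("m", 1:5), "PC1"))), class = "landscape")
  tm5 <- stats::setNames(c(0.95, 0.8, 0.7, 0.75, 0.9), paste0("m", 1:5))
  x <- c(-2, -1, 0, 1, 2); y <- unname(tm5)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc_tm_correlation(ls5, tm5), r_def)

  ## real TM against stateB correlates strongly; a permutation null does not
  tm_b <- vapply(ens$ensemble, function(m)
    tm_score(ens$end_states$stateB, m)$score, numeric(1))
  names(tm_b) <- vapply(ens$ensemble, `[[`, character(1), "model_id")
  r_obs <- pc_tm_correlation(ls, tm_b)
  expect_gt(abs(r_obs), 0.8)
  set.seed(77)
  r_null <- replicate(200, {
    shuffled <- stats::setNames(sample(tm_b), names(tm_b))
    pc_tm_correlation(ls, shuffled)
  })
  expect_lt(mean(abs(r_null) >= abs(r_obs)), 0.01)
  expect_lt(stats::quantile(abs(r_null), 0.95), 0.5)
})
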