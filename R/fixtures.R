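#' Specification for the synthetic two-state fixture
#'
#' Describes a toy protein that exists in two rigid end states connected by a
#' hinge motion, and an ensemble of models distributed between those states
#' with isotropic coordinate noise and a stated number of misfolded decoys.
#' It stands in for benchmark targets with two experimentally determined
#' conformations (e.g. inward/outward-facing transporter states), so that
#' every analysis stage can be exercised without running inference.
#'
#' @param n_residues chain length.
#' @param hinge_range inclusive residue interval `c(lo, hi)` that moves
#'   between the states; must be interior (anchored on both sides).
#' @param hinge_amplitude maximum per-residue Calpha displacement between the
#'   superimposed end states, in Angstrom.
#' @param n_models number of non-decoy ensemble members.
#' @param state_weights probabilities of the two end states for end-state
#'   draws; must sum to 1.
#' @param frac_intermediate fraction of models drawn at uniform interpolation
#'   coordinates between the states rather than at an end state.
#' @param noise_sigma isotropic Gaussian noise per coordinate, Angstrom.
#' @param n_decoys number of misfolded decoys (self-avoiding random walks).
#' @param seed integer seed; all generation is deterministic in it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 60, hinge_range = c(20, 30),
                         hinge_amplitude = 10, n_models = 50,
                         state_weights = c(0.5, 0.5),
                         frac_intermediate = 0.6,
                         noise_sigma = 0.5, n_decoys = 2, seed = 1) {
  if (abs(sum(state_weights) - 1) > 1e-9) stop("state_weights must sum to 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (hinge_range[1] > hinge_range[2] || hinge_range[1] < 2 ||
      hinge_range[2] > n_residues - 12)
    stop("hinge_range must be interior, ending >= 12 residues before the C-terminus")
  if (frac_intermediate < 0 || frac_intermediate > 1)
    stop("frac_intermediate must lie in [0, 1]")
  structure(list(n_residues = as.integer(n_residues),
                 hinge_range = as.integer(hinge_range),
                 hinge_amplitude = hinge_amplitude,
                 n_models = as.integer(n_models),
                 state_weights = state_weights,
                 frac_intermediate = frac_intermediate,
                 noise_sigma = noise_sigma,
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

BOND <- 3.8   # Calpha-Calpha virtual bond length, Angstrom

## Idealized helical Calpha trace: 1.5 A rise and 100 deg turn per residue,
## radius chosen so consecutive Calpha distances are exactly BOND.
helix_points <- function(idx, z_dir = 1, origin = c(0, 0, 0)) {
  rise <- 1.5; turn <- 100 * pi / 180
  r <- sqrt(BOND^2 - rise^2) / (2 * sin(turn / 2))
  t(vapply(idx, function(i)
    origin + c(r * cos(i * turn), r * sin(i * turn), z_dir * i * rise),
    numeric(3)))
}

## Helical-hairpin Calpha trace: an ascending arm carrying the hinge, a
## 6-residue hairpin turn (circular arc), and a descending arm offset
## laterally. The second arm gives the scaffold leverage far from the hinge
## axis, so hinge motion is not absorbable by a global rigid fit.
hairpin_trace <- function(n, h1, arm_offset = 14) {
  n_turn <- 6L
  if (n < h1 + n_turn + 6)
    stop("chain too short for the hairpin scaffold (need >= hinge end + 12)")
  a_end <- h1 + ceiling((n - h1 - n_turn) / 2)
  arm2_len <- n - a_end - n_turn
  if (arm2_len < 2) stop("chain too short for the second arm")
  xyz <- matrix(NA_real_, n, 3)
  xyz[1:a_end, ] <- helix_points(0:(a_end - 1))
  z_top <- xyz[a_end, 3]
  ## descending arm, offset in +x, starting near the top of arm 1
  xyz[(a_end + n_turn + 1):n, ] <-
    helix_points(0:(arm2_len - 1), z_dir = -1,
                 origin = c(arm_offset, 0, z_top - 1.5))
  xyz[(a_end + 1):(a_end + n_turn), ] <-
    arc_bulge(xyz[a_end, ], xyz[a_end + n_turn + 1, ], c(0, 0, 1),
              n_seg = n_turn + 1)
  xyz
}

## Circular-arc bulge with n_seg equal chords of length BOND between two
## anchor points a distance `chord` apart; bulges along unit vector e2 in the
## plane spanned by the anchor axis e1 and e2. Returns the n_seg - 1 interior
## points.
arc_bulge <- function(p_start, p_end, e2, n_seg) {
  chord <- sqrt(sum((p_end - p_start)^2))
  if (n_seg * BOND <= chord + 1e-9)
    stop("hinge segment too short to span its anchors")
  ## each bond subtends beta on a circle of radius BOND / (2 sin(beta/2));
  ## solve total chord(beta) = chord
  f <- function(beta) BOND * sin(n_seg * beta / 2) / sin(beta / 2) - chord
  beta <- stats::uniroot(f, c(1e-9, 2 * pi / n_seg - 1e-9),
                         tol = 1e-12)$root
  r <- BOND / (2 * sin(beta / 2))
  phi <- n_seg * beta
  e1 <- (p_end - p_start) / chord
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  mid <- (p_start + p_end) / 2
  center <- mid - e2 * (r * cos(phi / 2))
  ## angles of the anchors about the center, in the (e1, e2) plane
  ang <- function(p) atan2(sum((p - center) * e2), sum((p - center) * e1))
  a_start <- ang(p_start)
  pts_at <- function(alphas) {
    t(vapply(alphas, function(a)
      center + r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  }
  k <- seq_len(n_seg - 1)
  for (dir in c(-1, 1)) {             # sweep direction matching the end anchor
    alphas <- a_start + dir * k * beta
    endp <- center + r * (cos(a_start + dir * phi) * e1 +
                            sin(a_start + dir * phi) * e2)
    if (sqrt(sum((endp - p_end)^2)) < 1e-6) return(pts_at(alphas))
  }
  stop("arc construction failed to close on its end anchor")
}

## Rotate points about the axis through `origin` with unit direction `u`.
rotate_about_axis <- function(pts, origin, u, theta) {
  u <- u / sqrt(sum(u^2))
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  rot <- diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
  sweep(sweep(pts, 2, origin) %*% t(rot), 2, origin, "+")
}

min_nonadjacent_dist <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(d)
  d[abs(row(d) - col(d)) <= 1] <- Inf
  min(d)
}

#' Generate the two rigid end states of the synthetic hinge protein
#'
#' State A is an idealized helical-hairpin Calpha trace (two antiparallel
#' helical arms joined by a turn) in which the hinge residues form a
#' circular-arc bulge (an omega-loop-like excursion) anchored on the first
#' arm; all consecutive Calpha distances are 3.8 Angstrom. State B
#' rotates the hinge residues rigidly about the axis through the two anchor
#' Calphas, which preserves every bond length exactly; the rotation angle is
#' solved so that the maximum per-residue displacement between the two
#' superimposed states equals `hinge_amplitude`. Both states carry pLDDT 100.
#'
#' @param spec a [fixture_spec].
#' @return List with elements `stateA` and `stateB` ([structure_model]s).
#' @export
make_end_states <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  h0 <- spec$hinge_range[1]; h1 <- spec$hinge_range[2]
  xyz <- hairpin_trace(n, h1)
  ## hinge bulge points away from the second arm (which sits at +x)
  xyz[h0:h1, ] <- arc_bulge(xyz[h0 - 1, ], xyz[h1 + 1, ], c(-1, 0, 0),
                            n_seg = h1 - h0 + 2)
  aa <- with_seed(spec$seed,
                  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                         replace = TRUE))
  mk <- function(id, coords) structure_model(id, seq_len(n), aa, coords,
                                             plddt = rep(100, n))
  state_a <- mk("stateA", xyz)
  if (spec$hinge_amplitude == 0) {
    return(list(stateA = state_a, stateB = mk("stateB", xyz)))
  }
  axis_o <- xyz[h0 - 1, ]
  axis_u <- xyz[h1 + 1, ] - xyz[h0 - 1, ]
  ## rotation sense chosen to swing the bulge away from the scaffold
  b_at <- function(theta) {
    out <- xyz
    out[h0:h1, ] <- rotate_about_axis(xyz[h0:h1, , drop = FALSE],
                                      axis_o, axis_u, -theta)
    out
  }
  peak <- function(theta) {
    b <- mk("stateB", b_at(theta))
    max(displacement_profile(state_a, b)) - spec$hinge_amplitude
  }
  if (peak(pi) < 0)
    stop("hinge_amplitude exceeds what the hinge geometry can produce")
  theta <- stats::uniroot(peak, c(0, pi), tol = 1e-10)$root
  xyz_b <- b_at(theta)
  if (min_nonadjacent_dist(xyz_b) < 1 || min_nonadjacent_dist(xyz) < 1)
    stop("generated state has steric self-overlap (< 1 Angstrom)")
  list(stateA = state_a, stateB = mk("stateB", xyz_b))
}

## Self-avoiding random walk with BOND-length steps (misfolded decoy).
random_walk_trace <- function(n, min_sep = 1.0, max_tries = 200) {
  xyz <- matrix(0, n, 3)
  i <- 2
  tries <- 0
  while (i <= n) {
    step <- stats::rnorm(3)
    cand <- xyz[i - 1, ] + BOND * step / sqrt(sum(step^2))
    prev <- xyz[seq_len(max(i - 2, 1)), , drop = FALSE]
    if (i == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
      xyz[i, ] <- cand
      i <- i + 1
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > max_tries) {      # backtrack on dead ends
        i <- max(2, i - 2)
        tries <- 0
      }
    }
  }
  xyz
}

#' Generate a synthetic conformational ensemble with decoys
#'
#' Draws `n_models` structures at interpolation coordinates between the two
#' end states: end-state draws sit exactly at interpolation parameter 0 or 1
#' (chosen by `state_weights`); intermediates are drawn uniformly on
#' \[0.05, 0.95\] - the margin keeps the three labels identifiable and lets
#' the noiseless end states genuinely bracket the interpolated models. Each
#' model is perturbed by isotropic Gaussian Calpha noise. `n_decoys` additional
#' misfolded models are generated as self-avoiding random walks with
#' 3.8-Angstrom steps. Per-residue pLDDT is emulated as `95 - s_i` where
#' `s_i` scales that model's local noise magnitudes to `[0, 40]` - a monotone
#' proxy for local reliability sufficient to exercise confidence filtering.
#'
#' @param spec a [fixture_spec].
#' @return List with `ensemble` (list of [structure_model]s, models then
#'   decoys), `labels` (named character: `stateA`, `stateB`, `intermediate`
#'   or `decoy`), `t` (interpolation parameter per non-decoy model),
#'   `end_states` and `spec`.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_models < 2) stop("need at least 2 models")
  ends <- make_end_states(spec)
  a <- ends$stateA$xyz; b <- ends$stateB$xyz
  n <- spec$n_residues
  with_seed(spec$seed + 1L, {
    classes <- sample(c("stateA", "stateB", "intermediate"), spec$n_models,
                      replace = TRUE,
                      prob = c(spec$state_weights * (1 - spec$frac_intermediate),
                               spec$frac_intermediate))
    t_par <- ifelse(classes == "stateA", 0,
                    ifelse(classes == "stateB", 1, NA))
    t_par[is.na(t_par)] <- stats::runif(sum(is.na(t_par)), 0.05, 0.95)
    ensemble <- vector("list", spec$n_models + spec$n_decoys)
    labels <- character(spec$n_models + spec$n_decoys)
    for (m in seq_len(spec$n_models)) {
      noise <- matrix(stats::rnorm(3 * n, sd = spec$noise_sigma), n, 3)
      xyz <- (1 - t_par[m]) * a + t_par[m] * b + noise
      mag <- sqrt(rowSums(noise^2))
      scaled <- if (max(mag) > 0) 40 * mag / max(mag) else rep(0, n)
      id <- sprintf("model_%03d", m)
      ensemble[[m]] <- structure_model(id, seq_len(n), ends$stateA$aa, xyz,
                                       plddt = 95 - scaled)
      labels[m] <- classes[m]
    }
    for (k in seq_len(spec$n_decoys)) {
      id <- sprintf("decoy_%03d", k)
      xyz <- random_walk_trace(n)
      ensemble[[spec$n_models + k]] <-
        structure_model(id, seq_len(n), ends$stateA$aa, xyz,
                        plddt = rep(95, n))
      labels[spec$n_models + k] <- "decoy"
    }
    names(labels) <- vapply(ensemble, `[[`, character(1), "model_id")
    list(ensemble = ensemble, labels = labels, t = t_par,
         end_states = ends, spec = spec)
  })
}

#' Generate a synthetic alignment
#'
#' A random query plus rows mutated per position at a stated rate, with
#' optional gaps and lowercase insertions to exercise the A3M dialect.
#'
#' @param n_rows total rows including the query.
#' @param length query length (match columns).
#' @param mutation_rate per-position substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @param gap_rate per-position deletion probability.
#' @param insertion_rate per-position probability of a single-residue
#'   lowercase insertion after the position.
#' @return An [alignment].
#' @export
make_msa <- function(n_rows, length, mutation_rate, seed,
                     gap_rate = 0, insertion_rate = 0) {
  if (n_rows < 1) stop("n_rows must be >= 1")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    query <- sample(pool, length, replace = TRUE)
    rows <- character(n_rows)
    rows[1] <- paste(query, collapse = "")
    for (i in seq_len(n_rows - 1)) {
      s <- query
      mut <- stats::runif(length) < mutation_rate
      if (any(mut))
        s[mut] <- vapply(query[mut], function(q)
          sample(setdiff(pool, q), 1), character(1))
      gap <- stats::runif(length) < gap_rate
      s[gap] <- "-"
      if (insertion_rate > 0) {
        ins <- stats::runif(length) < insertion_rate
        s[ins] <- paste0(s[ins], tolower(sample(pool, sum(ins),
                                                replace = TRUE)))
      }
      rows[i + 1] <- paste(s, collapse = "")
    }
    alignment(c("query", sprintf("seq_%04d", seq_len(n_rows - 1))), rows)
  })
}
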