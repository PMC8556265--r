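# Seeded synthetic fixtures --------------------------------------------------
#
# Every generator takes an explicit `seed` and routes all randomness through
# one local RNG scope (withr-style on.exit restore), so fixtures are
# byte-reproducible and never disturb the caller's RNG state.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build a toy pore structure with a prescribed radius profile
#'
#' Stacks rings of pseudo-atoms along the laboratory z axis so that the
#' maximal inscribed sphere at each ring level has radius
#' `ring_radius(z) - vdw`.  Optional waters are placed at given axial and
#' lateral offsets.  Deterministic: no randomness.
#'
#' @param radius_profile function z -> ring radius (Angstrom), or a single
#'   number for a cylinder.
#' @param z_range axial extent, Angstrom.
#' @param ring_spacing distance between rings, Angstrom.
#' @param atoms_per_ring pseudo-atoms per ring.
#' @param element wall pseudo-atom element (sets the vdW radius via the
#'   table in use; default carbon, 1.7 Angstrom).
#' @param waters optional tibble with `z`, `lateral` (and optionally
#'   `label`) giving water oxygen positions; lateral offsets are applied
#'   along +x.
#' @return an `aqp_structure`: wall atoms as chain "A" glycine pseudo-CA,
#'   waters as HOH in chain "W" numbered 1001, 1002, ...
#' @export
make_toy_pore <- function(radius_profile, z_range = c(-15, 15),
                          ring_spacing = 1, atoms_per_ring = 12,
                          element = "C",
                          waters = NULL) {
  rfun <- if (is.function(radius_profile)) radius_profile else
    function(z) rep(radius_profile, length(z))
  zs <- seq(z_range[1], z_range[2], by = ring_spacing)
  vdw <- vdw_of(element, vdw_table())
  if (any(vapply(zs, rfun, double(1)) <= vdw)) {
    abort(sprintf(
      "ring radius must exceed the wall vdW radius (%.2f) everywhere", vdw))
  }
  ang <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring + 1)]
  rows <- lapply(seq_along(zs), function(i) {
    r <- rfun(zs[i])
    tibble(chain = "A", resno = i, resname = "GLY",
           atom = sprintf("C%02d", seq_along(ang)),
           element = element,
           x = r * cos(ang), y = r * sin(ang), z = zs[i],
           b = 20, occ = 1, hetero = FALSE, water = FALSE)
  })
  atoms <- dplyr::bind_rows(rows)
  if (!is.null(waters) && nrow(waters) > 0) {
    lat <- waters$lateral %||% rep(0, nrow(waters))
    wat <- tibble(chain = "W", resno = 1000L + seq_len(nrow(waters)),
                  resname = "HOH", atom = "O", element = "O",
                  x = lat, y = 0, z = waters$z,
                  b = 30, occ = 1, hetero = TRUE, water = TRUE)
    atoms <- dplyr::bind_rows(atoms, wat)
  }
  atoms$eleno <- seq_len(nrow(atoms))
  as_structure(atoms, id = "toy_pore")
}

#' Generate a defect-modulated synthetic reflection set
#'
#' Per-lattice (unit) intensities are drawn from an exponential
#' (Wilson-like acentric) distribution, multiplied by the modulation factor
#' of `model`, and perturbed with Gaussian noise.  Returns both the truth
#' and the observed set so estimators can be scored against ground truth.
#'
#' @param n number of reflections.
#' @param model a [defect_model()].
#' @param wilson_scale mean unit intensity.
#' @param noise_sd Gaussian noise s.d. added to the modulated intensities.
#' @param seed RNG seed.
#' @param hkl_max Miller indices are drawn uniformly from
#'   `[-hkl_max, hkl_max]^3` (minus the origin), without duplicates.
#' @return list with `truth` and `observed` reflection tibbles.
#' @export
make_defect_reflections <- function(n, model, wilson_scale = 100,
                                    noise_sd = 0, seed = 1, hkl_max = 20) {
  stopifnot(n >= 1)
  with_seed(seed, {
    need <- n
    seen <- character(0)
    hkl <- matrix(0L, 0, 3)
    while (nrow(hkl) < n) {
      m <- matrix(sample(-hkl_max:hkl_max, 3 * need * 2, replace = TRUE),
                  ncol = 3)
      m <- m[rowSums(m == 0) < 3, , drop = FALSE]
      key <- paste(m[, 1], m[, 2], m[, 3])
      fresh <- !duplicated(key) & !(key %in% seen)
      m <- m[fresh, , drop = FALSE]
      seen <- c(seen, key[fresh])
      hkl <- rbind(hkl, m)
      need <- n - nrow(hkl)
    }
    hkl <- hkl[seq_len(n), , drop = FALSE]
    i_unit <- stats::rexp(n, rate = 1 / wilson_scale)
    truth <- tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    intensity = i_unit,
                    sigma = pmax(sqrt(pmax(i_unit, 0)), 1e-6))
    observed <- modulate_intensities(truth, model)
    if (noise_sd > 0) {
      observed$intensity <- observed$intensity + stats::rnorm(n, 0, noise_sd)
      observed$sigma <- sqrt(observed$sigma^2 + noise_sd^2)
    }
    list(truth = truth, observed = observed)
  })
}

#' Generate a two-state site-occupancy trajectory
#'
#' One binding site at `center` alternates occupied/vacant as a two-state
#' Markov chain with stationary occupancy `p_occ` and mean occupied dwell
#' `dwell` frames (geometric dwell times, the discrete analogue of an
#' exponential residence).  The implied mean vacant dwell is
#' `dwell (1 - p_occ) / p_occ` and must be at least 1 frame.  The occupant
#' identity is resampled from the candidate pool on every re-entry; while
#' occupied the occupant sits within `radius / 3` of the centre, everyone
#' else is parked far away.
#'
#' @param n_frames frames to simulate.
#' @param p_occ stationary occupancy probability in `[0, 1]`.
#' @param dwell mean occupied dwell, frames (>= 1).
#' @param dt ns per frame.
#' @param seed RNG seed.
#' @param n_candidates size of the candidate water pool.
#' @param center,radius site definition.
#' @return list: `traj` (`aqp_trajectory` of candidate oxygens), `site`,
#'   `candidates` (atom indices), `truth_history` (occupant per frame).
#' @export
make_two_state_trajectory <- function(n_frames, p_occ, dwell, dt = 0.1,
                                      seed = 1, n_candidates = 5,
                                      center = c(0, 0, 0), radius = 1.4) {
  if (dwell < 1) abort("mean occupied dwell must be >= 1 frame")
  if (p_occ < 0 || p_occ > 1) abort("p_occ must lie in [0, 1]")
  if (p_occ > 0 && p_occ < 1) {
    vac_dwell <- dwell * (1 - p_occ) / p_occ
    if (vac_dwell < 1) {
      abort(sprintf(
        "p_occ = %g with dwell = %g frames implies a vacant dwell of %.2f frames (< 1); increase dwell",
        p_occ, dwell, vac_dwell))
    }
  }
  with_seed(seed, {
    p_leave <- if (p_occ >= 1) 0 else 1 / dwell
    p_enter <- if (p_occ <= 0) 0 else if (p_occ >= 1) 1 else
      1 / (dwell * (1 - p_occ) / p_occ)
    occupied <- stats::runif(1) < p_occ
    occupant <- if (occupied) sample.int(n_candidates, 1) else NA_integer_
    history <- integer(n_frames)
    coords <- array(0, c(n_frames, n_candidates, 3))
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        if (occupied && stats::runif(1) < p_leave) {
          occupied <- FALSE; occupant <- NA_integer_
        } else if (!occupied && stats::runif(1) < p_enter) {
          occupied <- TRUE
          occupant <- sample.int(n_candidates, 1)
        }
      }
      history[f] <- if (occupied) occupant else NA_integer_
      for (a in seq_len(n_candidates)) {
        if (occupied && a == occupant) {
          coords[f, a, ] <- center + stats::runif(3, -radius / 3, radius / 3)
        } else {
          coords[f, a, ] <- c(50 + 10 * a, 50, 50) + stats::runif(3, -1, 1)
        }
      }
    }
    meta <- tibble(element = "O", atom = "O", resname = "HOH",
                   resno = seq_len(n_candidates))
    list(traj = trajectory(coords, meta, dt = dt),
         site = list(center = center, radius = radius, label = "site"),
         candidates = seq_len(n_candidates),
         truth_history = history)
  })
}

#' Generate a trajectory with scripted permeation paths
#'
#' Each molecule follows piecewise-linear axial waypoints (frame, z) with
#' optional Gaussian jitter; x and y stay near the axis.  Crossings are
#' therefore known by construction.
#'
#' @param script list of molecules, each a data frame/tibble with columns
#'   `frame`, `z` (waypoints; interpolated linearly between them).
#' @param n_frames total frames.
#' @param dt ns per frame.
#' @param jitter Gaussian positional noise s.d., Angstrom.
#' @param seed RNG seed.
#' @return list: `traj` (`aqp_trajectory`, one Si atom per molecule),
#'   `selection` (atom indices).
#' @export
make_permeation_trajectory <- function(script, n_frames, dt = 0.1,
                                       jitter = 0, seed = 1) {
  if (length(script) == 0) abort("script must list at least one molecule")
  with_seed(seed, {
    nmol <- length(script)
    coords <- array(0, c(n_frames, nmol, 3))
    for (m in seq_len(nmol)) {
      wp <- tibble::as_tibble(script[[m]])
      z <- stats::approx(wp$frame, wp$z, xout = seq_len(n_frames),
                         rule = 2)$y
      if (jitter > 0) z <- z + stats::rnorm(n_frames, 0, jitter)
      coords[, m, 1] <- if (jitter > 0) stats::rnorm(n_frames, 0, jitter)
                        else 0
      coords[, m, 2] <- 0
      coords[, m, 3] <- z
    }
    meta <- tibble(element = "SI", atom = "SI", resname = "SIH",
                   resno = seq_len(nmol))
    list(traj = trajectory(coords, meta, dt = dt),
         selection = seq_len(nmol))
  })
}

#' Generate a trajectory with a prescribed in-channel count distribution
#'
#' Per-frame in-region counts are drawn as a rounded Gaussian clipped to
#' `[0, n_pool]` with the requested mean and standard deviation (the study
#' condition is stated as mean and s.d. without a distributional form);
#' that many pool atoms are placed inside the channel region, the rest
#' outside.
#'
#' @param n_frames frames.
#' @param mean_count,sd_count target per-frame count moments.
#' @param n_pool pool size (>= attainable maximum count).
#' @param channel_z axial channel interval.
#' @param dt ns per frame.
#' @param seed RNG seed.
#' @return list: `traj`, `selection`, `counts_truth` (the drawn counts).
#' @export
make_count_trajectory <- function(n_frames, mean_count = 11.6,
                                  sd_count = 2.6, n_pool = 30,
                                  channel_z = c(-15, 15), dt = 0.1,
                                  seed = 1) {
  with_seed(seed, {
    counts <- pmin(pmax(round(stats::rnorm(n_frames, mean_count, sd_count)),
                        0), n_pool)
    coords <- array(0, c(n_frames, n_pool, 3))
    span <- diff(channel_z)
    for (f in seq_len(n_frames)) {
      k <- counts[f]
      if (k > 0) {
        coords[f, seq_len(k), 3] <- channel_z[1] + span *
          ((seq_len(k) - 0.5) / max(k, 1))
        coords[f, seq_len(k), 1] <- stats::runif(k, -1, 1)
        coords[f, seq_len(k), 2] <- stats::runif(k, -1, 1)
      }
      if (k < n_pool) {
        out <- (k + 1):n_pool
        coords[f, out, 1] <- 60
        coords[f, out, 2] <- 60
        coords[f, out, 3] <- 60 + 5 * out
      }
    }
    meta <- tibble(element = "O", atom = "O", resname = "HOH",
                   resno = seq_len(n_pool))
    list(traj = trajectory(coords, meta, dt = dt),
         selection = seq_len(n_pool), counts_truth = counts)
  })
}
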