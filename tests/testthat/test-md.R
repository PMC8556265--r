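zaxis <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-20, 20))

test_that("trajectory construction validates its inputs", {
  arr <- array(0, c(5, 3, 3))
  meta <- tibble::tibble(element = "O", atom = "O", resname = "HOH",
                         resno = 1:3)
  tr <- trajectory(arr, meta, dt = 0.1)
  expect_equal(tr$n_frames, 5)
  expect_equal(tr$n_atoms, 3)
  expect_error(trajectory(arr, meta[1:2, ], dt = 0.1), "atom count")
  expect_error(trajectory(arr, meta, dt = 0), "dt")
  expect_error(trajectory(array(0, c(5, 3)), meta, dt = 0.1), "array")
})

test_that("XYZ frame files round-trip through the real I/O path", {
  ts <- make_two_state_trajectory(40, 0.6, 5, seed = 19)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_frames(ts$traj, path)
  back <- read_xyz_frames(path, dt = ts$traj$dt)
  expect_equal(back$n_frames, 40)
  expect_equal(back$n_atoms, ts$traj$n_atoms)
  expect_lt(max(abs(back$coords - ts$traj$coords)), 1e-4 + 1e-9)
})

test_that("channel counts match construction and brute-force recount", {
  # five waters pinned inside the region every frame
  arr <- array(0, c(20, 6, 3))
  arr[, 6, 3] <- 100  # one water parked far outside
  meta <- tibble::tibble(element = "O", atom = "O", resname = "HOH",
                         resno = 1:6)
  tr <- trajectory(arr, meta, dt = 0.1)
  spec <- region_spec(c(-5, 5))
  cc <- channel_counts(tr, zaxis, spec, 1:6)
  expect_equal(attr(cc, "mean"), 5)
  expect_equal(attr(cc, "sd"), 0)
  # brute-force per-frame recount on a random small trajectory
  set.seed(41)
  arr2 <- array(runif(30 * 8 * 3, -12, 12), c(30, 8, 3))
  tr2 <- trajectory(arr2, meta[rep(1, 8), ], dt = 0.1)
  cc2 <- channel_counts(tr2, zaxis, spec, 1:8, lateral_max = 6)
  manual <- vapply(1:30, function(f) {
    n <- 0L
    for (a in 1:8) {
      p <- arr2[f, a, ]
      if (p[3] >= -5 && p[3] <= 5 && sqrt(p[1]^2 + p[2]^2) <= 6) n <- n + 1L
    }
    n
  }, integer(1))
  expect_equal(cc2$count, manual)
  # region moved away from all coordinates counts zero
  far <- channel_counts(tr2, channel_axis(c(500, 500, 500), c(0, 0, 1),
                                          c(-20, 20)), spec, 1:8)
  expect_equal(attr(far, "mean"), 0)
  expect_error(channel_counts(tr2, zaxis, spec, integer(0)), "empty")
})

test_that("site occupancy recovers two-state ground truth within 3 SE", {
  scenarios <- list(list(p = 0.44, dwell = 10, seed = 101),
                    list(p = 0.60, dwell = 15, seed = 102),
                    list(p = 0.94, dwell = 20, seed = 103))
  n <- 5000
  for (sc in scenarios) {
    ts <- make_two_state_trajectory(n, sc$p, sc$dwell, seed = sc$seed)
    st <- site_occupancy(ts$traj, ts$site, ts$candidates)
    se <- occupancy_se(sc$p, sc$dwell, n)
    expect_lt(abs(st$occupancy - sc$p), 3 * se)
    # the estimator reproduces the generator's own occupant record exactly
    expect_equal(is.na(st$occupant_history), is.na(ts$truth_history))
  }
  ts1 <- make_two_state_trajectory(200, 1, 10, seed = 7)
  expect_equal(site_occupancy(ts1$traj, ts1$site, ts1$candidates)$occupancy,
               1)
  empty <- trajectory(array(0, c(1, 2, 3)),
                      tibble::tibble(element = "O", atom = "O",
                                     resname = "HOH", resno = 1:2),
                      dt = 0.1)
  expect_error(site_occupancy(empty, list(center = c(0, 0, 0), radius = 0),
                              1:2), "radius")
})

test_that("occupancy estimation error shrinks with trajectory length", {
  errs <- vapply(c(500, 5000), function(n) {
    ts <- make_two_state_trajectory(n, 0.60, 15, seed = 55)
    abs(site_occupancy(ts$traj, ts$site, ts$candidates)$occupancy - 0.60)
  }, double(1))
  expect_lt(errs[2], errs[1])
})

test_that("exchange time handles constant, alternating and geometric dwell", {
  # constant occupant over 100 frames at dt = 0.1: one 10 ns episode
  hist100 <- rep(3L, 100)
  et <- exchange_time(hist100, dt = 0.1, gap_tolerance = 1)
  expect_equal(et$tau, 10)
  expect_equal(et$n_episodes, 1)
  # alternating occupants every frame, no gap bridging: tau = dt
  alt <- rep(c(1L, 2L), 50)
  et2 <- exchange_time(alt, dt = 0.1, gap_tolerance = 0)
  expect_equal(et2$tau, 0.1)
  expect_equal(et2$n_episodes, 100)
  # geometric dwell with mean 15 frames at dt = 0.1 -> tau = 1.5 ns
  ts <- make_two_state_trajectory(8000, 0.60, 15, seed = 77)
  st <- site_occupancy(ts$traj, ts$site, ts$candidates)
  et3 <- exchange_time(st, gap_tolerance = 0)
  expect_gt(et3$n_episodes, 200)
  se <- et3$mean_frames / sqrt(et3$n_episodes)  # geometric: sd ~ mean
  expect_lt(abs(et3$mean_frames - 15), 2 * se)
  expect_error(exchange_time(rep(NA_integer_, 50), dt = 0.1), "episodes")
})

test_that("gap tolerance bridges single-frame flicker", {
  hist <- c(rep(1L, 10), NA_integer_, rep(1L, 10))
  expect_equal(exchange_time(hist, dt = 1, gap_tolerance = 1)$n_episodes, 1)
  expect_equal(exchange_time(hist, dt = 1, gap_tolerance = 0)$n_episodes, 2)
  # a different occupant after the gap is never merged
  hist2 <- c(rep(1L, 10), NA_integer_, rep(2L, 10))
  expect_equal(exchange_time(hist2, dt = 1, gap_tolerance = 1)$n_episodes, 2)
})

test_that("permeation counting matches scripted crossings", {
  script <- list(
    data.frame(frame = c(1, 60, 100), z = c(-20, 20, 20)),    # full in
    data.frame(frame = c(1, 40, 60, 100), z = c(-20, -5, -20, -20)), # partial
    data.frame(frame = c(1, 60, 100), z = c(20, -20, -20)),   # full out
    data.frame(frame = c(1, 30, 50, 70, 100),
               z = c(-20, 0, -20, 5, -20)),                   # two retreats
    data.frame(frame = c(1, 100), z = c(0, 0)))               # never leaves
  pt <- make_permeation_trajectory(script, 100, seed = 3)
  ev <- count_permeations(pt$traj, zaxis, -15, 15, pt$selection)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$direction[ev$molecule == 1], "in")
  expect_equal(ev$direction[ev$molecule == 3], "out")
  expect_true(all(ev$entry_frame < ev$exit_frame))
  expect_error(count_permeations(pt$traj, zaxis, 15, -15, pt$selection),
               "z_top")
})

test_that("time reversal swaps permeation directions", {
  script <- list(data.frame(frame = c(1, 80), z = c(-20, 20)),
                 data.frame(frame = c(1, 80), z = c(20, -20)))
  pt <- make_permeation_trajectory(script, 80, seed = 2)
  fwd <- count_permeations(pt$traj, zaxis, -15, 15, pt$selection)
  rev_traj <- trajectory(pt$traj$coords[80:1, , , drop = FALSE],
                         pt$traj$atom_meta, dt = pt$traj$dt)
  bwd <- count_permeations(rev_traj, zaxis, -15, 15, pt$selection)
  expect_equal(nrow(bwd), nrow(fwd))
  swap <- c(`in` = "out", out = "in")
  expect_setequal(paste(bwd$molecule, bwd$direction),
                  paste(fwd$molecule, unname(swap[fwd$direction])))
})

test_that("axial density flags exactly the scripted bottlenecks", {
  # static waters at every z except three scripted gaps
  zs <- seq(-14.5, 14.5, by = 1)
  gaps <- list(c(-10, -8), c(-1, 1), c(7, 9))
  keep <- !vapply(zs, function(z)
    any(vapply(gaps, function(g) z > g[1] & z < g[2], logical(1))),
    logical(1))
  pos <- zs[keep]
  arr <- array(0, c(10, length(pos), 3))
  for (i in seq_along(pos)) arr[, i, 3] <- pos[i]
  tr <- trajectory(arr, tibble::tibble(element = "O", atom = "O",
                                       resname = "HOH",
                                       resno = seq_along(pos)), dt = 0.1)
  ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-15, 15))
  ad <- axial_density(tr, ax, seq_along(pos), bin = 1)
  bn <- attr(ad, "bottlenecks")
  expect_equal(nrow(bn), 3)
  for (i in 1:3) {
    expect_gte(bn$z_start[i], gaps[[i]][1] - 1)
    expect_lte(bn$z_end[i], gaps[[i]][2] + 1)
  }
  # uniform density: none
  ad0 <- axial_density(tr, ax, seq_along(pos), bin = 1,
                       bottleneck_frac = 0)
  expect_equal(nrow(attr(ad0, "bottlenecks")), 0)
  arr2 <- array(rep(seq(-14, 14, length.out = 29), each = 10 * 1),
                c(10, 29, 3))
  arr2[, , 1] <- 0; arr2[, , 2] <- 0
  for (i in 1:29) arr2[, i, 3] <- seq(-14, 14, length.out = 29)[i]
  tr2 <- trajectory(arr2, tibble::tibble(element = "O", atom = "O",
                                         resname = "HOH", resno = 1:29),
                    dt = 0.1)
  expect_equal(nrow(attr(axial_density(tr2, ax, 1:29, bin = 1),
                         "bottlenecks")), 0)
  expect_error(axial_density(tr, ax, 1, bin = 0), "bin")
})

test_that("md statistics are invariant under a uniform rigid transform", {
  ts <- make_two_state_trajectory(600, 0.6, 10, seed = 8)
  rot <- fixed_rotation(30, -50, 20)
  shift <- c(4, -7, 11)
  arr <- ts$traj$coords
  arr2 <- arr
  for (f in seq_len(dim(arr)[1])) {
    arr2[f, , ] <- sweep(arr[f, , ] %*% t(rot), 2, shift, `+`)
  }
  tr2 <- trajectory(arr2, ts$traj$atom_meta, dt = ts$traj$dt)
  site2 <- list(center = as.numeric(rot %*% ts$site$center) + shift,
                radius = ts$site$radius, label = "site")
  st1 <- site_occupancy(ts$traj, ts$site, ts$candidates)
  st2 <- site_occupancy(tr2, site2, ts$candidates)
  expect_equal(st2$occupancy, st1$occupancy)
  expect_equal(st2$occupant_history, st1$occupant_history)
})
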