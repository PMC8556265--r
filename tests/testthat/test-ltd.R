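test_that("the modulation factor matches its closed form at anchor points", {
  m <- defect_model(c(1/3, 0, 1/3), 0.30)
  # integral h.t_d: (2k^2 - 2k + 1) + 2k(1-k) = 1 identically
  expect_equal(correction_factor(data.frame(h = 3, k = 0, l = 0), m)[1], 1)
  expect_equal(correction_factor(data.frame(h = 1, k = 2, l = 2), m)[1], 1)
  # h = (1,0,0): 0.58 + 0.42 cos(2 pi / 3) = 0.37
  expect_equal(correction_factor(data.frame(h = 1, k = 0, l = 0), m)[1],
               0.37, tolerance = 1e-12)
  # single lattice: factor 1 for every reflection
  m0 <- defect_model(c(1/3, 0, 1/3), 0)
  hkl <- expand.grid(h = -3:3, k = -3:3, l = -3:3)
  hkl <- hkl[rowSums(hkl == 0) < 3, ]
  expect_true(all(abs(correction_factor(hkl, m0) - 1) < 1e-12))
})

test_that("the factor is bounded by [(1-2k)^2, 1] and periodic in phase", {
  set.seed(3)
  hkl <- data.frame(h = sample(-30:30, 400, TRUE),
                    k = sample(-30:30, 400, TRUE),
                    l = sample(-30:30, 400, TRUE))
  hkl <- hkl[rowSums(hkl == 0) < 3, ]
  for (kap in c(0.05, 0.17, 0.30, 0.5)) {
    m <- defect_model(c(1/3, 1/4, 1/2), kap)
    f <- correction_factor(hkl, m)
    expect_true(all(f <= 1 + 1e-12))
    expect_true(all(f >= (1 - 2 * kap)^2 - 1e-12))
  }
  # phase enters only mod 1: shifting h by a full period leaves f unchanged
  m <- defect_model(c(1/3, 0, 1/3), 0.3)
  f1 <- correction_factor(data.frame(h = 1, k = 5, l = 1), m)
  f2 <- correction_factor(data.frame(h = 4, k = -2, l = 1), m)  # +3 in h
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("defect_model enforces the canonical kappa range", {
  expect_error(defect_model(c(0.5, 0, 0), 0.7), "kappa")
  expect_error(defect_model(c(0.5, 0), 0.3), "three components")
  expect_equal(defect_model(c(1.25, 0, 0), 0.3)$t_d[1], 0.25)
})

test_that("intensity correction inverts the modulation", {
  m <- defect_model(c(1/3, 0, 1/3), 0.30)
  obs <- tibble::tibble(h = 1, k = 0, l = 0, intensity = 0.37, sigma = 0.037)
  cor <- correct_intensities(obs, m)
  expect_equal(cor$intensity, 1, tolerance = 1e-12)
  expect_equal(cor$sigma, 0.1, tolerance = 1e-12)
  # kappa = 0 leaves everything untouched
  gen <- make_defect_reflections(300, defect_model(c(1/2, 0, 0), 0),
                                 noise_sd = 0, seed = 2)
  cor0 <- correct_intensities(gen$observed, defect_model(c(1/2, 0, 0), 0))
  expect_equal(cor0$intensity, gen$observed$intensity)
  # modulate -> correct is an exact algebraic round trip
  gen2 <- make_defect_reflections(500, m, noise_sd = 0, seed = 9)
  cor2 <- correct_intensities(gen2$observed, m)
  expect_lt(max(abs(cor2$intensity - gen2$truth$intensity) /
                  gen2$truth$intensity), 1e-10)
  expect_error(correct_intensities(gen2$observed, m, floor = 0), "floor")
})

test_that("reflections below the correction floor are flagged, not hidden", {
  m <- defect_model(c(1/2, 0, 0), 0.45)   # f_min = 0.01 at odd h
  obs <- tibble::tibble(h = c(1, 2), k = 0, l = 0, intensity = c(5, 5),
                        sigma = 1)
  cor <- correct_intensities(obs, m, floor = 0.05)
  expect_true(cor$flagged[1])
  expect_false(cor$flagged[2])
  expect_equal(nrow(cor), 2)  # flagged reflections stay in the table
})

test_that("reflection I/O round-trips and validates", {
  gen <- make_defect_reflections(50, defect_model(c(1/2, 0, 0), 0.2),
                                 seed = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_reflections(gen$observed, path)
  back <- read_reflections(path)
  expect_equal(back$intensity, gen$observed$intensity, tolerance = 1e-12)
  expect_equal(back[, c("h", "k", "l")], gen$observed[, c("h", "k", "l")])
  # headerless whitespace files are accepted too
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 0 10.5 1.1", "2 0 0 20.5 2.2"), p2)
  expect_equal(read_reflections(p2)$intensity, c(10.5, 20.5))
  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 1 1"), p3)
  expect_error(read_reflections(p3), "0,0,0")
})

test_that("the intensity R-factor behaves as Sum|Ia-Ib|/Sum Ia", {
  a <- tibble::tibble(h = 1:5, k = 0, l = 0, intensity = c(10, 20, 30, 40, 50),
                      sigma = 1)
  expect_equal(intensity_r_factor(a, a)$r_factor, 0)
  b <- a; b$intensity <- 2 * a$intensity
  expect_equal(intensity_r_factor(a, b)$r_factor, 1)
  expect_equal(intensity_r_factor(a, b)$n_common, 5)
  c_ <- a; c_$h <- c_$h + 100
  expect_error(intensity_r_factor(a, c_), "no common")
  # correction strictly improves agreement with the truth
  m <- defect_model(c(1/3, 0, 1/3), 0.30)
  gen <- make_defect_reflections(2000, m, noise_sd = 0, seed = 21)
  r_before <- intensity_r_factor(gen$truth, gen$observed)$r_factor
  r_after <- intensity_r_factor(gen$truth,
                                correct_intensities(gen$observed, m))$r_factor
  expect_lt(r_after, r_before)
  expect_lt(r_after, 1e-10)
})

test_that("defect estimation recovers generator parameters", {
  # half-cell translocation: closed-form check, min/max bin mean = (1-2k)^2
  gen <- make_defect_reflections(5000, defect_model(c(1/2, 0, 0), 0.25),
                                 noise_sd = 0, seed = 13)
  fit <- estimate_defect(gen$observed)
  expect_equal(fit$model$t_d, c(1/2, 0, 0))
  expect_lt(abs(fit$model$kappa - 0.25), 0.02)
  bins <- fit$bins
  expect_equal(min(bins$mean_intensity) / max(bins$mean_intensity),
               (1 - 2 * 0.25)^2, tolerance = 0.1)
  # the scenario of the aquaporin deposition: t_d = (1/3, 0, 1/3), k = 0.30
  gen2 <- make_defect_reflections(5000, defect_model(c(1/3, 0, 1/3), 0.30),
                                  noise_sd = 0, seed = 17)
  fit2 <- estimate_defect(gen2$observed)
  expect_equal(fit2$model$t_d, c(1/3, 0, 1/3))
  expect_lt(abs(fit2$model$kappa - 0.30), 0.02)
  expect_equal(nrow(fit2$bins), 3)
})

test_that("the null model is recognised and degeneracy errors", {
  gen <- make_defect_reflections(20000, defect_model(c(1/3, 0, 1/3), 0),
                                 noise_sd = 0, seed = 5)
  expect_lt(estimate_defect(gen$observed)$model$kappa, 0.02)
  # single phase class: not identifiable
  obs <- tibble::tibble(h = seq(2, 40, by = 2), k = 0, l = 0,
                        intensity = 10, sigma = 1)
  expect_error(estimate_defect(obs, candidates = list(c(1/2, 0, 0))),
               "identifiable")
})

test_that("kappa recovery error shrinks with the number of reflections", {
  m <- defect_model(c(1/3, 0, 1/3), 0.30)
  seeds <- c(31, 57, 91, 123, 200)
  errs <- vapply(seeds, function(seed) {
    vapply(c(300, 5000), function(n) {
      gen <- make_defect_reflections(n, m, noise_sd = 30, seed = seed)
      abs(estimate_defect(gen$observed)$model$kappa - 0.30)
    }, double(1))
  }, double(2))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))   # consistency on average
  expect_true(all(errs[2, ] < errs[1, ]))       # and seed by seed here
})

test_that("tidy/glance/candidates expose the fit diagnostics", {
  gen <- make_defect_reflections(1000, defect_model(c(1/2, 0, 0), 0.2),
                                 noise_sd = 0, seed = 6)
  fit <- estimate_defect(gen$observed)
  expect_named(glance(fit), c("td_1", "td_2", "td_3", "kappa", "residual",
                              "r_squared", "n_bins"))
  expect_equal(nrow(tidy(fit)), 2)
  expect_true(all(diff(fit$candidates$rss) >= 0))
})
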