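test_that("hydrogen-bond calls respect the inclusive distance cutoffs", {
  two <- function(d) mk_structure(mk_atoms(rbind(c(0, 0, 0), c(d, 0, 0))))
  hb <- detect_hbonds(two(2.80))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$klass, "typical")
  expect_equal(nrow(detect_hbonds(two(3.50))), 0)
  hb2 <- detect_hbonds(two(3.40))
  expect_equal(hb2$klass, "standard")
  # water to backbone carbonyl at exactly d_max is still a bond
  mod <- mk_structure(mk_peptide("GLY"), mk_atoms(c(1.9, 2.3, 3.8)))
  o <- mod[mod$atom == "O" & !mod$hetero, ]
  w <- mod[mod$water, ]
  d <- sqrt(sum((as.numeric(o[1, c("x", "y", "z")]) -
                   as.numeric(w[1, c("x", "y", "z")]))^2))
  hb3 <- detect_hbonds(mod, d_max = d)
  expect_true(any(hb3$resname_a == "HOH" | hb3$resname_b == "HOH"))
})

test_that("bond detection equals the all-pairs brute force exactly", {
  set.seed(14)
  pts <- matrix(runif(3 * 40, 0, 12), ncol = 3)
  mod <- mk_structure(mk_atoms(pts),
                      mk_peptide(c("SER", "ASN", "GLY"), origin = c(4, 4, 4)))
  for (dmax in c(2.5, 3.4, 4.5)) {
    expect_equal(nrow(detect_hbonds(mod, d_max = dmax)),
                 brute_force_hbonds(mod, d_max = dmax))
  }
  # monotonicity: growing d_max never loses bonds
  n <- vapply(c(2.6, 3.0, 3.4, 4.0), function(d)
    nrow(detect_hbonds(mod, d_max = d)), integer(1))
  expect_true(all(diff(n) >= 0))
  # covalent neighbours within one residue are never reported
  hb <- detect_hbonds(mk_structure(mk_peptide("GLY")), d_max = 5)
  expect_equal(nrow(hb), 0)
})

test_that("water classification partitions and matches construction", {
  pore <- make_toy_pore(5, z_range = c(-20, 20), ring_spacing = 0.5,
                        waters = data.frame(
                          z = c(-4, -2, 0, 2, 4, -12, 12, 0),
                          lateral = c(0, 0, 0, 0, 0, 2, 2, 20)))
  ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-18, 18))
  pr <- compute_profile(pore, ax, step = 1)
  spec <- region_spec(c(-7, 7))
  cls <- classify_waters(pore, ax, pr, spec)
  census <- attr(cls, "census")
  expect_equal(census$n[census$region == "channel"], 5)
  expect_equal(census$n[census$region == "extracellular_vestibule"], 1)
  expect_equal(census$n[census$region == "intracellular_vestibule"], 1)
  expect_equal(census$n[census$region == "bulk"], 1)  # 20 A off-axis
  expect_equal(sum(census$n), nrow(cls))              # partition
  expect_setequal(unique(cls$region[cls$lateral > 15]), "bulk")
  expect_error(region_spec(c(-5, 5), extracellular_z = c(-4, 0)),
               "disjoint")
})

test_that("exclusive pairs equal brute force and merge transitively", {
  w <- data.frame(x = c(0, 0, 0), y = c(0, 1.2, 2.4), z = 0)
  ex <- exclusive_pairs(w, cutoff = 2.5)
  expect_equal(nrow(ex), 3)                       # 1.2, 1.2, 2.4 all < 2.5
  expect_equal(unique(attr(ex, "groups")), 1L)    # one exclusion group of 3
  # the exemplar pair distances: 2.3 is exclusive, 2.6 is not
  expect_equal(nrow(exclusive_pairs(data.frame(x = c(0, 2.3), y = 0, z = 0))),
               1)
  expect_equal(nrow(exclusive_pairs(data.frame(x = c(0, 2.6), y = 0, z = 0))),
               0)
  # brute force equality on a random cloud
  set.seed(23)
  cloud <- data.frame(x = runif(30, 0, 8), y = runif(30, 0, 8),
                      z = runif(30, 0, 8))
  ex2 <- exclusive_pairs(cloud, cutoff = 2.5)
  manual <- 0L
  for (i in 1:29) for (j in (i + 1):30) {
    d <- sqrt(sum((cloud[i, ] - cloud[j, ])^2))
    if (d < 2.5) manual <- manual + 1L
  }
  expect_equal(nrow(ex2), manual)
  expect_equal(nrow(exclusive_pairs(cloud[1, , drop = FALSE])), 0)
})

test_that("single-file segmentation reproduces scripted layouts", {
  ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-15, 15))
  mkw <- function(z, x = 0) data.frame(x = x, y = 0, z = z)
  # 5 on-axis waters spaced 2.8: one single-file run
  s1 <- single_file_segments(mkw(seq(0, 11.2, by = 2.8)), ax)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$status, "single_file")
  expect_equal(s1$n_waters, 5)
  # two coeval waters 3 A apart laterally: multi-file
  s2 <- single_file_segments(
    rbind(mkw(c(0, 2.8, 5.6)), data.frame(x = 3, y = 0, z = 2.8)), ax)
  expect_true("multi_file" %in% s2$status)
  # a 4.0 A axial gap splits the chain into two segments
  s3 <- single_file_segments(mkw(cumsum(c(0, 2.8, 2.8, 4.0, 2.8))), ax)
  expect_equal(nrow(s3), 2)
  expect_equal(sum(s3$n_waters), 5)
  expect_true(all(s3$status == "single_file"))
  # fewer than two waters: one trivial segment
  expect_equal(nrow(single_file_segments(mkw(0), ax)), 1)
})

test_that("water orientation follows the two-acceptor rule", {
  ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-10, 10))
  # water 3 A off-axis; two backbone carbonyl O further out (wall side)
  wat <- mk_atoms(c(3, 0, 0))
  carb <- mk_atoms(rbind(c(5.2, 1.2, 0.5), c(5.2, -1.2, -0.5)),
                   chain = "A", resname = "GLY", atom = "O", element = "O",
                   start_resno = 10, hetero = FALSE)
  mod <- mk_structure(wat, carb)
  bonds <- detect_hbonds(mod)
  ori <- infer_orientation(mod, water_sites(mod)[1, ], bonds, ax)
  expect_equal(ori$orientation, "oxygen_toward_channel")
  expect_match(ori$rationale, "GLY")
  # a water bonded only to another water is ambiguous
  mod2 <- mk_structure(mk_atoms(rbind(c(3, 0, 0), c(3, 2.8, 0))))
  ori2 <- infer_orientation(mod2, water_sites(mod2)[1, ],
                            detect_hbonds(mod2), ax)
  expect_equal(ori2$orientation, "ambiguous")
  # one wall-side acceptor plus one channel-side: ambiguous by the rule
  carb3 <- mk_atoms(rbind(c(5.2, 1.2, 0), c(0.5, 0, 0)),
                    chain = "A", resname = "GLY", atom = "O", element = "O",
                    start_resno = 10, hetero = FALSE)
  mod3 <- mk_structure(wat, carb3)
  ori3 <- infer_orientation(mod3, water_sites(mod3)[1, ],
                            detect_hbonds(mod3), ax)
  expect_equal(ori3$orientation, "ambiguous")
  # no bonds at all: ambiguous with empty rationale
  lone <- mk_structure(mk_atoms(c(3, 0, 0)))
  ori4 <- infer_orientation(lone, water_sites(lone)[1, ],
                            detect_hbonds(lone), ax)
  expect_equal(ori4$orientation, "ambiguous")
  expect_equal(ori4$rationale, "")
})

test_that("network outputs are invariant under rigid motion", {
  pore <- make_toy_pore(5, z_range = c(-12, 12), ring_spacing = 0.5,
                        waters = data.frame(z = seq(-5, 5.4, by = 2.6),
                                            lateral = 0.5))
  ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-10, 10))
  spec <- region_spec(c(-7, 7))
  cls <- classify_waters(pore, ax, NULL, spec)
  rot <- fixed_rotation(25, 35, -60)
  shift <- c(-4, 8, 13)
  pore2 <- transform_structure(pore, rot, shift)
  ax2 <- channel_axis(as.numeric(rot %*% ax$origin) + shift,
                      as.numeric(rot %*% ax$direction), ax$z_range)
  cls2 <- classify_waters(pore2, ax2, NULL, spec)
  expect_equal(cls2$region, cls$region)
  expect_equal(nrow(detect_hbonds(pore2)), nrow(detect_hbonds(pore)))
  expect_equal(nrow(exclusive_pairs(water_sites(pore2))),
               nrow(exclusive_pairs(water_sites(pore))))
})
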