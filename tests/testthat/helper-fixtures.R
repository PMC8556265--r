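# Fixture builders and independent oracles shared across test files.

# deterministic proper rotation from three angles (degrees)
fixed_rotation <- function(ax = 20, ay = -35, az = 55) {
  a <- ax * pi / 180; b <- ay * pi / 180; c <- az * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

# small peptide builder: one row per atom, backbone N/CA/C/O per residue,
# stretched along +x so residues never clash
mk_peptide <- function(resnames, chain = "A", start_resno = 1,
                       origin = c(0, 0, 0), b = 20) {
  rows <- lapply(seq_along(resnames), function(i) {
    base <- origin + c(3.8 * (i - 1), 0, 0)
    tibble::tibble(
      chain = chain, resno = start_resno + i - 1, resname = resnames[i],
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = base[1] + c(0, 0.5, 1.5, 1.9),
      y = base[2] + c(0, 1.2, 1.2, 2.3),
      z = base[3] + c(0, 0.1, 0.3, 0.4),
      b = b, occ = 1, hetero = FALSE, water = FALSE)
  })
  atoms <- dplyr::bind_rows(rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms
}

# place single atoms (e.g. waters, carbonyl oxygens) at given coordinates
mk_atoms <- function(xyz, chain = "W", resname = "HOH", atom = "O",
                     element = "O", start_resno = 1001, hetero = TRUE,
                     b = 30) {
  xyz <- rbind(xyz)
  tibble::tibble(chain = chain, resno = start_resno + seq_len(nrow(xyz)) - 1,
                 resname = resname, atom = atom, element = element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 b = b, occ = 1, hetero = hetero,
                 water = resname %in% c("HOH", "WAT"))
}

mk_structure <- function(...) {
  atoms <- dplyr::bind_rows(...)
  atoms$eleno <- seq_len(nrow(atoms))
  as_structure(atoms, id = "fixture")
}

# independent rigid-fit oracle: quaternion-grid search over rotations with
# centroid-matched translation, polished with Nelder-Mead on the axis-angle
# parameters; never calls kabsch()
brute_force_rigid_rmsd <- function(p, q, n_grid = 12) {
  p <- as.matrix(p); q <- as.matrix(q)
  cp <- colMeans(p); cq <- colMeans(q)
  pp <- sweep(p, 2, cp); qq <- sweep(q, 2, cq)
  rot_from_aa <- function(par) {
    th <- sqrt(sum(par^2))
    if (th < 1e-12) return(diag(3))
    u <- par / th
    ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
                 byrow = TRUE)
    cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * tcrossprod(u)
  }
  obj <- function(par) {
    r <- rot_from_aa(par)
    sqrt(mean(rowSums((pp %*% t(r) - qq)^2)))
  }
  gs <- seq(-pi, pi, length.out = n_grid)
  best <- c(0, 0, 0); best_val <- obj(best)
  for (a in gs) for (b in gs) for (c in gs) {
    v <- obj(c(a, b, c))
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# exhaustive fine-grid slice oracle for the pore optimizer
brute_force_slice_radius <- function(model, axis, z, vdw = vdw_table(),
                                     max_off_axis = 3, grid = 0.05,
                                     max_radius = 10) {
  wall <- model[model$primary & !model$hetero & model$element != "H", ,
                drop = FALSE]
  xyz <- as.matrix(wall[, c("x", "y", "z")])
  w <- unname(vdw[toupper(wall$element)])
  w[is.na(w)] <- attr(vdw, "default")
  ref <- if (abs(axis$direction[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis$direction) * axis$direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis$direction[2] * e1[3] - axis$direction[3] * e1[2],
          axis$direction[3] * e1[1] - axis$direction[1] * e1[3],
          axis$direction[1] * e1[2] - axis$direction[2] * e1[1])
  point <- axis$origin + z * axis$direction
  g <- seq(-max_off_axis, max_off_axis, by = grid)
  best <- -Inf
  for (u in g) for (v in g) {
    if (u^2 + v^2 > max_off_axis^2) next
    cen <- point + u * e1 + v * e2
    r <- min(sqrt(colSums((t(xyz) - cen)^2)) - w)
    if (r > best) best <- r
  }
  min(best, max_radius)
}

# all-pairs hydrogen-bond oracle (quadratic loop, no vectorisation tricks)
brute_force_hbonds <- function(model, d_max = 3.4, include_s = FALSE) {
  el <- c("O", "N", if (include_s) "S")
  p <- model[model$primary & model$element %in% el, , drop = FALSE]
  out <- 0L
  n <- nrow(p)
  if (n < 2) return(0L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- p$chain[i] == p$chain[j] && p$resno[i] == p$resno[j] &&
        p$insert[i] == p$insert[j]
      if (same) next
      d <- sqrt((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2 +
                  (p$z[i] - p$z[j])^2)
      if (d <= d_max) out <- out + 1L
    }
  }
  out
}

# exact closed-form variance factor of the occupancy estimator for a
# two-state Markov chain: Var(p_hat) ~ p(1-p)/n * (1+lambda)/(1-lambda)
occupancy_se <- function(p, dwell, n_frames) {
  vac <- dwell * (1 - p) / p
  lambda <- 1 - 1 / dwell - 1 / vac
  sqrt(p * (1 - p) * (1 + lambda) / (1 - lambda) / n_frames)
}

# water ladder whose 3-water windows are exact tetrahedron faces: chain
# template oxygen triangles along z so placements must exist
mk_tetra_ladder <- function(n_units = 3, z_step = 2.8) {
  tmp <- silicic_template()
  face <- tmp$oxygens[1:3, ]
  rows <- lapply(seq_len(n_units), function(i) {
    sweep(face, 2, c(0, 0, (i - 1) * z_step), `+`)
  })
  xyz <- do.call(rbind, rows)
  mk_atoms(xyz, start_resno = 2001)
}
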